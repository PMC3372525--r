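test_that("brownian covariance reads shared path lengths off the tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- brownian_covariance(tr, c("A", "B", "C"))
  expect_equal(unname(diag(V)), c(2, 2, 2), ignore_attr = TRUE)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)

  # star tree: lambda-independent diagonal
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  for (lam in c(0, 0.5, 1)) {
    Vs <- brownian_covariance(star, c("A", "B", "C", "D"), lambda = lam)
    expect_equal(unname(Vs), diag(3, 4), ignore_attr = TRUE)
  }

  # lambda scales only the off-diagonal
  V5 <- brownian_covariance(tr, c("A", "B", "C"), lambda = 0.5)
  expect_equal(V5["A", "B"], 0.5)
  expect_equal(unname(diag(V5)), c(2, 2, 2))

  expect_error(brownian_covariance(tr, c("A", "Z")), "not in tree")
})

test_that("pruning before or after building the covariance is equivalent", {
  set.seed(3)
  tr <- simulate_tree(8)
  all_sp <- tr$tip.label
  V_full <- brownian_covariance(tr, all_sp)
  keep <- all_sp[c(1, 3, 5, 8)]
  V_sub <- brownian_covariance(tr, keep)
  expect_equal(V_sub, V_full[keep, keep], ignore_attr = TRUE)
})

test_that("GLS with identity covariance equals ordinary least squares", {
  set.seed(11)
  n <- 12
  X <- cbind(mls = rnorm(n), mass = rnorm(n))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(n)
  fit <- gls_fit(y, X, diag(n))
  ref <- summary(lm(y ~ X))$coefficients
  expect_equal(unname(fit$coefficients), unname(ref[, 1]), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(ref[, 2]), tolerance = 1e-10)
  expect_equal(unname(fit$p.value), unname(ref[, 4]), tolerance = 1e-10)
})

test_that("an exactly linear response gives zero residuals and the true slope", {
  set.seed(12)
  tr <- simulate_tree(10)
  sp <- tr$tip.label
  V <- brownian_covariance(tr, sp)
  x <- rnorm(10)
  y <- 3 + 2.5 * x
  fit <- gls_fit(y, cbind(mls = x, mass = rnorm(10)), V)
  expect_equal(unname(fit$coefficients["mls"]), 2.5, tolerance = 1e-8)
  expect_lt(fit$sigma2, 1e-16)
})

test_that("whitened GLS matches the explicit-inverse oracle on random instances", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    tr <- simulate_tree(n)
    sp <- tr$tip.label
    V <- brownian_covariance(tr, sp)
    X <- cbind(mls = rnorm(n), mass = rnorm(n))
    y <- rnorm(n)
    fit <- gls_fit(y, X, V)
    oracle <- brute_gls(y, X, V)
    expect_equal(unname(fit$coefficients), unname(oracle$beta), tolerance = 1e-10)
    expect_equal(unname(fit$se), unname(oracle$se), tolerance = 1e-10)
    expect_equal(unname(fit$p.value), unname(oracle$p.value), tolerance = 1e-10)
    expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-10)
  }
})

test_that("the fit agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(31)
  tr <- simulate_tree(12)
  sp <- tr$tip.label
  V <- brownian_covariance(tr, sp)
  X <- cbind(mls = rnorm(12), mass = rnorm(12))
  y <- 1 + 0.8 * X[, 1] + drop(t(chol(V)) %*% rnorm(12))
  fit <- gls_fit(y, X, V)
  df <- data.frame(y = y, mls = X[, 1], mass = X[, 2], species = sp)
  gf <- nlme::gls(y ~ mls + mass, data = df,
                  correlation = ape::corBrownian(1, tr, form = ~species))
  expect_equal(unname(fit$coefficients), unname(coef(gf)), tolerance = 1e-6)
  tt <- summary(gf)$tTable
  expect_equal(unname(fit$se), unname(tt[, "Std.Error"]), tolerance = 1e-6)
  expect_equal(unname(fit$p.value), unname(tt[, "p-value"]), tolerance = 1e-6)
})

test_that("degenerate designs and responses are flagged, not fatal", {
  set.seed(41)
  n <- 8
  V <- diag(n)
  # constant response
  f1 <- gls_fit(rep(2, n), cbind(mls = rnorm(n), mass = rnorm(n)), V)
  expect_true(f1$degenerate)
  expect_equal(unname(f1$coefficients), rep(0, 3))
  expect_equal(unname(f1$p.value[-1]), c(1, 1))
  # collinear design
  x <- rnorm(n)
  f2 <- gls_fit(rnorm(n), cbind(mls = x, mass = 2 * x), V)
  expect_true(f2$degenerate)
  # constant predictor
  f3 <- gls_fit(rnorm(n), cbind(mls = rep(1, n), mass = rnorm(n)), V)
  expect_true(f3$degenerate)
  # too few observations is an error, not a degenerate fit
  expect_error(gls_fit(rnorm(3), cbind(mls = rnorm(3), mass = rnorm(3)),
                       diag(3)), "at least")
  # non-positive-definite covariance
  bad <- matrix(1, n, n)
  expect_error(gls_fit(rnorm(n), cbind(mls = rnorm(n), mass = rnorm(n)), bad),
               "positive definite")
})

test_that("with lambda 0 on an ultrametric tree PGLS reduces to OLS", {
  set.seed(51)
  tr <- simulate_tree(9)
  sp <- tr$tip.label
  V0 <- brownian_covariance(tr, sp, lambda = 0)
  X <- cbind(mls = rnorm(9), mass = rnorm(9))
  y <- rnorm(9)
  fit <- gls_fit(y, X, V0)
  ref <- summary(lm(y ~ X))$coefficients
  expect_equal(unname(fit$coefficients), unname(ref[, 1]), tolerance = 1e-9)
  expect_equal(unname(fit$p.value), unname(ref[, 4]), tolerance = 1e-9)
})

test_that("fit_column drops the reference and handles small columns", {
  set.seed(61)
  tr <- simulate_tree(12)
  traits <- simulate_traits(tr, simulation_spec())
  ref <- trait_reference(traits)
  sp <- setdiff(tr$tip.label, ref)

  # constant scores: degenerate convention
  sc <- setNames(rep(5, length(sp)), sp)
  f <- fit_column(sc, traits, tr)
  expect_true(f$degenerate)
  expect_equal(c(f$b_mls, f$p_mls), c(0, 1))

  # fewer than min_fit_species usable species
  f2 <- fit_column(sc[1:3], traits, tr)
  expect_true(f2$degenerate)
  expect_equal(f2$n, 3L)

  # the reference never contributes even if scored
  sc3 <- setNames(rnorm(length(sp) + 1), c(sp, ref))
  f3 <- fit_column(sc3, traits, tr)
  expect_equal(f3$n, length(sp))
})

test_that("fit_column recovers a planted positive coupling on a star tree", {
  set.seed(71)
  n <- 24
  sp <- sprintf("s%02d", 1:n)
  star <- ape::read.tree(text = paste0("(", paste(sp, ":1", collapse = ","), ");"))
  traits <- toy_traits(sp, mls = 10^seq(0.5, 2, length.out = n))
  ref <- trait_reference(traits)
  nonref <- setdiff(sp, ref)
  y <- 4 * log10(traits$mls_years[match(nonref, traits$species)]) +
    rnorm(length(nonref), 0, 0.3)
  f <- fit_column(setNames(y, nonref), traits, star)
  expect_gt(f$b_mls, 0)
  expect_lt(f$p_mls, 0.05)
  expect_equal(f$b_mls, 4, tolerance = 0.25)
})

test_that("null p-values are uniform under Brownian noise", {
  set.seed(81)
  tr <- simulate_tree(20)
  traits <- simulate_traits(tr, simulation_spec(n_species = 20))
  sp <- setdiff(tr$tip.label, trait_reference(traits))
  V <- brownian_covariance(tr, sp)
  X <- longscan:::trait_design(traits, sp, "log10")
  ctx <- longscan:::make_gls_context(X, V)
  L <- t(chol(V))
  ps <- replicate(600, {
    y <- drop(L %*% rnorm(length(sp)))
    unname(longscan:::gls_fit_ctx(ctx, y)$p.value["mls"])
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
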