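#' Brownian-motion phylogenetic covariance
#'
#' The covariance implied by Brownian trait evolution on a time-scaled tree
#' pruned to the requested species: entry (i, j) is the root-to-MRCA path
#' length of species i and j, and the diagonal holds root-to-tip depths.
#' Pagel's lambda multiplies the off-diagonal entries only (lambda = 1 full
#' phylogenetic signal, lambda = 0 independence up to per-species depth).
#'
#' @param tree A time-scaled [ape::phylo].
#' @param species Species to keep (at least 2, all tips of `tree`).
#' @param lambda Off-diagonal multiplier in `[0, 1]`.
#' @return A symmetric matrix ordered as `species`, with attributes
#'   `species` and `lambda`.
#' @export
brownian_covariance <- function(tree, species, lambda = 1) {
  stopifnot(length(species) >= 2L, lambda >= 0, lambda <= 1)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing)) {
    abort(sprintf("species not in tree: %s", paste(missing, collapse = ", ")))
  }
  pruned <- ape::keep.tip(tree, species)
  V <- ape::vcv.phylo(pruned)[species, species]
  if (lambda != 1) {
    d <- diag(V)
    V <- lambda * V
    diag(V) <- d
  }
  structure(V, species = species, lambda = lambda)
}

#' Generalized least squares with a known covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * Sigma)`, by Cholesky whitening
#' (no explicit inverse of `Sigma`): both sides are premultiplied by the
#' inverse Cholesky factor and the whitened system solved by ordinary least
#' squares. An intercept column is prepended. Standard errors come from the
#' scaled inverse normal matrix and p-values are two-sided t-tests on
#' `n - p` degrees of freedom.
#'
#' Degenerate inputs are flagged rather than failing: a constant response or
#' a design that is singular after whitening returns zero slopes with
#' p-values of 1 and `degenerate = TRUE`.
#'
#' @param y Numeric response.
#' @param X Numeric predictor matrix (no intercept; named columns).
#' @param Sigma Positive-definite covariance, e.g. [brownian_covariance()].
#' @return A `longscan_gls` object.
#' @export
gls_fit <- function(y, X, Sigma) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(Sigma) == n)
  if (n - (ncol(X) + 1L) < 1L) {
    abort(sprintf("need at least %d observations for %d coefficients",
                  ncol(X) + 2L, ncol(X) + 1L))
  }
  ctx <- make_gls_context(X, Sigma)
  gls_fit_ctx(ctx, y)
}

# Precompute the whitened design for one (species set, predictor) pair so a
# scan can reuse it across every column sharing that species set.
make_gls_context <- function(X, Sigma) {
  Xd <- cbind("(Intercept)" = 1, as.matrix(X))
  L <- tryCatch(chol(Sigma),
                error = function(e) abort("covariance is not positive definite"))
  wX <- backsolve(L, Xd, transpose = TRUE)
  XtX <- crossprod(wX)
  R <- if (qr(wX)$rank < ncol(Xd)) NULL else  # NULL => singular design
    tryCatch(chol(XtX), error = function(e) NULL)
  list(L = L, wX = wX, R = R, terms = colnames(Xd), n = nrow(Xd),
       p = ncol(Xd))
}

gls_fit_ctx <- function(ctx, y) {
  n <- ctx$n
  p <- ctx$p
  df <- n - p
  terms <- ctx$terms
  degenerate_fit <- function() {
    new_longscan_gls(
      coefficients = setNames(rep(0, p), terms),
      se = setNames(rep(NA_real_, p), terms),
      statistic = setNames(rep(NA_real_, p), terms),
      p.value = setNames(c(NA_real_, rep(1, p - 1L)), terms),
      n = n, df = df, sigma2 = NA_real_, degenerate = TRUE)
  }
  if (is.null(ctx$R)) return(degenerate_fit())
  wy <- backsolve(ctx$L, y, transpose = TRUE)
  if (stats::var(wy - ctx$wX[, 1] * (sum(ctx$wX[, 1] * wy) / sum(ctx$wX[, 1]^2))) < 1e-20 ||
      stats::var(y) < 1e-20) {
    # response constant (possibly after whitening): nothing to fit
    return(degenerate_fit())
  }
  XtXinv <- chol2inv(ctx$R)
  beta <- drop(XtXinv %*% crossprod(ctx$wX, wy))
  res <- wy - drop(ctx$wX %*% beta)
  sigma2 <- sum(res^2) / df
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  new_longscan_gls(
    coefficients = setNames(beta, terms), se = setNames(se, terms),
    statistic = setNames(tstat, terms), p.value = setNames(pval, terms),
    n = n, df = df, sigma2 = sigma2, degenerate = FALSE)
}

new_longscan_gls <- function(coefficients, se, statistic, p.value, n, df,
                             sigma2, degenerate) {
  structure(list(coefficients = coefficients, se = se, statistic = statistic,
                 p.value = p.value, n = n, df = df, sigma2 = sigma2,
                 degenerate = degenerate),
            class = "longscan_gls")
}

#' @export
print.longscan_gls <- function(x, ...) {
  cat(sprintf("<longscan_gls: n = %d, df = %d%s>\n", x$n, x$df,
              if (x$degenerate) ", degenerate" else ""))
  print(tidy.longscan_gls(x))
  invisible(x)
}

#' Fit one scored column by PGLS
#'
#' Regresses the corrected similarity scores of a fit column on transformed
#' maximum lifespan and body mass under the Brownian covariance of the
#' time-scaled tree pruned to the column's species. The reference species
#' never contributes a data point. Columns with fewer than
#' `min_fit_species` usable species, a constant response, or a singular
#' design yield a flagged degenerate fit (slopes 0, p-values 1).
#'
#' @param scores Named numeric vector from [score_column()].
#' @param traits A [trait_table()].
#' @param tree Time-scaled [ape::phylo].
#' @param lambda Pagel's lambda for the covariance.
#' @param transform `"log10"` (default) or `"identity"` applied to MLS and
#'   mass.
#' @param min_fit_species Minimum usable species.
#' @return A one-row tibble: `n`, `b_mls`, `p_mls`, `b_mass`, `p_mass`,
#'   `degenerate`.
#' @export
fit_column <- function(scores, traits, tree, lambda = 1,
                       transform = c("log10", "identity"),
                       min_fit_species = 4L) {
  transform <- match.arg(transform)
  species <- intersect(intersect(names(scores), traits$species), tree$tip.label)
  species <- setdiff(species, trait_reference(traits))
  n <- length(species)
  if (n < min_fit_species) {
    return(tibble(n = n, b_mls = 0, p_mls = 1, b_mass = 0, p_mass = 1,
                  degenerate = TRUE))
  }
  Sigma <- brownian_covariance(tree, species, lambda)
  X <- trait_design(traits, species, transform)
  fit <- gls_fit(scores[species], X, Sigma)
  tibble(n = n,
         b_mls = unname(fit$coefficients["mls"]),
         p_mls = unname(fit$p.value["mls"]),
         b_mass = unname(fit$coefficients["mass"]),
         p_mass = unname(fit$p.value["mass"]),
         degenerate = fit$degenerate)
}

trait_design <- function(traits, species, transform) {
  i <- match(species, traits$species)
  f <- if (transform == "log10") log10 else identity
  cbind(mls = f(traits$mls_years[i]), mass = f(traits$mass_g[i]))
}
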