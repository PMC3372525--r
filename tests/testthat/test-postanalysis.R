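fit_row <- function(column, p_mls, b_mls = 1, class = "fit",
                    alignment = "a") {
  tibble::tibble(alignment = alignment, column = column, class = class,
                 ref_residue = "Y", n_chars = 12L,
                 n_diff = ifelse(class == "fit", 4L, 0L),
                 n = 11L, b_mls = b_mls, p_mls = p_mls,
                 b_mass = 0.1, p_mass = 0.5, degenerate = FALSE)
}

test_that("p-value histograms are normalized densities of positive-slope fits", {
  p <- c(rep(0.005, 5), 0.4, 0.9)
  cols <- dplyr::bind_rows(fit_row(1:7, p),
                           fit_row(8, 0.001, b_mls = -2),      # negative slope
                           fit_row(9, 1, class = "conserved", b_mls = 0))
  res <- as_scan_result(cols, reference = "ref")
  h <- pvalue_histogram(res, bins = 10)
  expect_equal(sum(h$count), 7L)            # only fit columns with b_mls > 0
  expect_equal(h$count[1], 5L)
  expect_equal(sum(h$density) * 0.1, 1)
  # all mass in the first bin when every p is tiny
  h2 <- pvalue_histogram(as_scan_result(fit_row(1:4, rep(0.005, 4)), "ref"))
  expect_equal(h2$density[1] * (1 / 20), 1)
  # uniform p-values give a near-flat histogram
  set.seed(2)
  h3 <- pvalue_histogram(as_scan_result(fit_row(1:10000, runif(10000)), "ref"),
                         bins = 10)
  expect_lt(max(h3$density) / min(h3$density), 1.5)
  empty <- as_scan_result(fit_row(1, 0.5, b_mls = -1), "ref")
  expect_error(pvalue_histogram(empty), "no fit columns")
})

test_that("composition chi-squared matches hand and oracle computations", {
  expect_equal(composition_chisq_gof(c(H = 60, E = 40),
                                     c(H = 50, E = 50))$statistic, 4)
  same <- composition_chisq_gof(c(H = 30, E = 15, C = 55),
                                c(H = 60, E = 30, C = 110))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$df, 2L)

  set.seed(4)
  for (rep in 1:20) {
    obs <- setNames(rpois(3, 50) + 1, c("H", "E", "C"))
    ref <- setNames(rpois(3, 500) + 1, c("H", "E", "C"))
    got <- composition_chisq_gof(obs, ref)
    expect_equal(got$statistic, brute_chisq(obs, ref), tolerance = 1e-12)
    # and the stats::chisq.test route agrees
    expect_equal(got$statistic,
                 unname(chisq.test(obs, p = ref / sum(ref))$statistic),
                 tolerance = 1e-10)
  }
  # contingency variant has df = (2-1)(3-1) = 2 as well
  ct <- composition_chisq_gof(c(H = 30, E = 15, C = 55),
                              c(H = 65, E = 20, C = 115),
                              method = "contingency")
  expect_equal(ct$df, 2L)
  expect_error(composition_chisq_gof(c(H = 1, E = 1), c(H = 0, E = 5)),
               "positive")
})

test_that("domains aggregate longevity-selected positions in reference coordinates", {
  # reference has a gap at column 2: reference position i maps to column i+1
  # for i >= 2
  m <- toy_msa(c(ref = paste(c("A", "-", rep("A", 10)), collapse = ""),
                 s1 = strrep("A", 12), s2 = strrep("A", 12)))
  panel <- alignment_panel(list(p1 = m))
  cols <- dplyr::bind_rows(
    fit_row(3, 0.001, alignment = "p1"),   # ref pos 2
    fit_row(5, 0.002, alignment = "p1"),   # ref pos 4
    fit_row(8, 0.003, alignment = "p1"),   # ref pos 7
    fit_row(9, 0.5, alignment = "p1"))     # not selected
  res <- as_scan_result(cols, reference = "ref")
  domains <- tibble::tibble(protein = "p1", start = c(1L, 6L), end = c(5L, 8L),
                            name = c("dom_a", "dom_b"))
  summ <- domain_summary(res, domains, panel, min_positions = 2L)
  expect_equal(summ$name, "dom_a")         # covers ref pos 2 and 4
  expect_equal(summ$n_selected, 2L)
  expect_equal(sort(summ$positions[[1]]$column), c(3L, 5L))
  # dom_b has one position only: excluded at min_positions = 2
  summ1 <- domain_summary(res, domains, panel, min_positions = 1L)
  expect_equal(summ1$name, c("dom_a", "dom_b"))
  # order invariance
  summ_rev <- domain_summary(res, domains[2:1, ], panel, min_positions = 1L)
  expect_equal(summ_rev, summ1)
  # no longevity-selected positions: empty summary
  res0 <- as_scan_result(fit_row(3, 0.9, alignment = "p1"), "ref")
  expect_equal(nrow(domain_summary(res0, domains, panel)), 0L)
  # out-of-range domain errors by name
  bad <- tibble::tibble(protein = "p1", start = 1L, end = 99L, name = "huge")
  expect_error(domain_summary(res, bad, panel), "huge")
})

test_that("rolling medians slide over runs of selected positions only", {
  # 9 selected positions: no window
  res9 <- as_scan_result(fit_row(1:9, rep(0.5, 9)), "ref")
  expect_equal(nrow(rolling_median_p(res9, "a")), 0L)

  # 10 conserved positions, all p = 1: one window with median 1
  cols10 <- fit_row(1:10, rep(1, 10), b_mls = 0, class = "conserved")
  r10 <- rolling_median_p(as_scan_result(cols10, "ref"), "a")
  expect_equal(nrow(r10), 1L)
  expect_equal(r10$median_p, 1)
  expect_equal(c(r10$start_column, r10$end_column), c(1L, 10L))

  # 12 positions with hand-set p values: 3 windows, hand-computed medians
  p12 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.05, 0.15, 0.25)
  r12 <- rolling_median_p(as_scan_result(fit_row(1:12, p12), "ref"), "a")
  expect_equal(nrow(r12), 3L)
  expect_equal(r12$median_p,
               c(median(p12[1:10]), median(p12[2:11]), median(p12[3:12])))

  # an excluded position breaks the run
  cols <- dplyr::bind_rows(
    fit_row(1:11, rep(0.5, 11)),
    tibble::tibble(alignment = "a", column = 12L, class = "excluded",
                   ref_residue = NA_character_, n_chars = 3L, n_diff = 0L,
                   n = NA_integer_, b_mls = NA_real_, p_mls = NA_real_,
                   b_mass = NA_real_, p_mass = NA_real_, degenerate = NA),
    fit_row(13:21, rep(0.5, 9)))
  rbr <- rolling_median_p(as_scan_result(cols, "ref"), "a")
  expect_equal(nrow(rbr), 2L)   # only from the 11-long run before the break
  expect_true(all(rbr$end_column <= 11))
  # windows never span the excluded position
  expect_true(all(rbr$start_column >= 1 & rbr$end_column <= 11))
})

test_that("region residue counts regress on traits with the reference included", {
  n <- 16
  sp <- sprintf("s%02d", 1:n)
  star <- ape::read.tree(text = paste0("(", paste(sp, ":1", collapse = ","), ");"))
  traits <- toy_traits(sp, mls = 10^seq(0.5, 2, length.out = n))
  # counts of C rise linearly with log10 MLS: k cysteines in a 12-column region
  ks <- round(2 + 6 * (log10(traits$mls_years) - 0.5) / 1.5)
  seqs <- vapply(ks, function(k)
    paste(c(rep("C", k), rep("A", 12 - k)), collapse = ""), character(1))
  panel <- toy_panel(setNames(seqs, sp), id = "p1")
  fit <- region_residue_count_pgls(panel, "p1", 1:12, "C", traits, star)
  expect_s3_class(fit, "longscan_gls")
  expect_equal(fit$n, n)                       # reference included
  expect_gt(unname(fit$coefficients["mls"]), 0)
  expect_lt(unname(fit$p.value["mls"]), 0.01)
  expect_equal(unname(fit$coefficients["mls"]), 4, tolerance = 1)

  # identical counts: degenerate
  panel0 <- toy_panel(setNames(rep("ACCA", n), sp), id = "p1")
  f0 <- region_residue_count_pgls(panel0, "p1", 1:4, "C", traits, star)
  expect_true(f0$degenerate)
  # counting itself: "ACCA" has two C over the full range
  expect_equal(unname(rowSums(panel0[["p1"]][, 1:4] == "C")[1]), 2)
  expect_error(region_residue_count_pgls(panel0, "p1", 1:99, "C", traits, star),
               "outside")
})

test_that("secondary-structure composition counts map through reference coordinates", {
  m <- toy_msa(c(ref = paste(c("A", "-", rep("A", 6)), collapse = ""),
                 s1 = strrep("A", 8), s2 = strrep("A", 8)))
  panel <- alignment_panel(list(p1 = m))
  cols <- dplyr::bind_rows(fit_row(3, 0.001, alignment = "p1"),  # ref pos 2
                           fit_row(6, 0.002, alignment = "p1"))  # ref pos 5
  res <- as_scan_result(cols, reference = "ref")
  ss <- tibble::tibble(protein = "p1", position = 1:7,
                       class = c("H", "H", "E", "C", "C", "C", "H"))
  counts <- ss_composition(res, ss, panel)
  expect_equal(counts, c(H = 1L, E = 0L, C = 1L))
})
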