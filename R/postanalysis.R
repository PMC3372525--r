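#' Density histogram of per-column p-values
#'
#' Restricted to fit columns with a positive MLS slope, the population whose
#' p-value density distinguishes a real scan (mass near 0) from a
#' trait-permuted control (flat). Densities integrate to 1 over [0, 1].
#'
#' @param result A [run_scan()] result.
#' @param bins Number of equal-width bins over `[0, 1]`.
#' @return A tibble: `bin_lower`, `bin_upper`, `count`, `density`.
#' @export
pvalue_histogram <- function(result, bins = 20L) {
  stopifnot(inherits(result, "longscan_scan"), bins >= 1L)
  p <- dplyr::filter(as_tibble(result), .data$class == "fit", .data$b_mls > 0)$p_mls
  if (length(p) == 0L) abort("no fit columns with b_mls > 0")
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(p, breaks, rightmost.closed = TRUE), bins),
                     nbins = bins)
  width <- 1 / bins
  tibble(bin_lower = breaks[-(bins + 1L)], bin_upper = breaks[-1],
         count = counts, density = counts / (sum(counts) * width))
}

#' Pearson chi-squared test of secondary-structure composition
#'
#' Default is a goodness-of-fit test of the observed class counts against
#' the class proportions of a reference composition (e.g. the whole
#' proteome, or a randomized control): `E = total(observed) * p_ref`,
#' statistic `sum((O - E)^2 / E)` on `k - 1` degrees of freedom. The
#' `"contingency"` method instead tests independence on the 2 x k table of
#' both sets of counts.
#'
#' @param observed,reference Named counts per class (same names, e.g.
#'   H/E/C); reference counts must all be positive.
#' @param method `"gof"` (default) or `"contingency"`.
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @examples
#' composition_chisq_gof(c(H = 60, E = 40), c(H = 50, E = 50))  # statistic 4
#' @export
composition_chisq_gof <- function(observed, reference,
                                  method = c("gof", "contingency")) {
  method <- match.arg(method)
  stopifnot(length(observed) == length(reference))
  if (!is.null(names(reference)) && !is.null(names(observed))) {
    reference <- reference[names(observed)]
  }
  if (any(reference <= 0)) abort("all reference counts must be positive")
  if (sum(observed) <= 0) abort("observed total must be positive")
  if (method == "gof") {
    expected <- sum(observed) * reference / sum(reference)
    if (any(expected <= 0)) abort("zero expected cell")
    statistic <- sum((observed - expected)^2 / expected)
    df <- length(observed) - 1L
  } else {
    tab <- rbind(observed = observed, reference = reference)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    statistic <- unname(ct$statistic)
    df <- unname(ct$parameter)
  }
  tibble(statistic = statistic, df = df,
         p.value = pchisq(statistic, df, lower.tail = FALSE),
         method = method)
}

#' Secondary-structure composition of longevity-selected positions
#'
#' Maps each longevity-selected column to its ungapped reference coordinate
#' and tallies the H/E/C classes from the annotation track. Columns where
#' the reference has a gap, or proteins absent from the track, are dropped.
#'
#' @param result A [run_scan()] result.
#' @param ss Secondary-structure track ([read_ss_track()] layout).
#' @param panel The scanned [alignment_panel()] (for reference coordinates).
#' @return Named counts for classes H, E, C.
#' @export
ss_composition <- function(result, ss, panel) {
  stopifnot(inherits(result, "longscan_scan"))
  reference <- attr(result, "reference")
  sel <- dplyr::filter(as_tibble(result), .data$longevity_selected)
  counts <- c(H = 0L, E = 0L, C = 0L)
  for (id in unique(sel$alignment)) {
    map <- ref_to_column(panel[[id]], reference)
    pos <- match(sel$column[sel$alignment == id], map)
    pos <- pos[!is.na(pos)]
    cls <- ss$class[ss$protein == id][pos]
    cls <- cls[!is.na(cls)]
    tab <- table(factor(cls, levels = c("H", "E", "C")))
    counts <- counts + as.integer(tab)
  }
  counts
}

#' Aggregate longevity-selected positions by protein domain
#'
#' Counts, for each annotated domain, the longevity-selected positions whose
#' ungapped reference coordinate falls inside the domain, and keeps domains
#' with at least `min_positions` of them, sorted by count (descending) then
#' name.
#'
#' @param result A [run_scan()] result.
#' @param domains Domain table ([read_domain_table()] layout): `protein`
#'   (an alignment id), `start`, `end`, `name`.
#' @param panel The scanned [alignment_panel()].
#' @param min_positions Minimum selected positions per reported domain.
#' @return A tibble: `protein`, `name`, `start`, `end`, `n_selected`,
#'   `positions` (list column of the selected rows).
#' @export
domain_summary <- function(result, domains, panel, min_positions = 2L) {
  stopifnot(inherits(result, "longscan_scan"))
  reference <- attr(result, "reference")
  sel <- dplyr::filter(as_tibble(result), .data$longevity_selected)
  rows <- lapply(seq_len(nrow(domains)), function(i) {
    d <- domains[i, ]
    if (!d$protein %in% names(panel)) {
      abort(sprintf("domain '%s': protein '%s' not in panel", d$name, d$protein))
    }
    map <- ref_to_column(panel[[d$protein]], reference)
    if (d$end > length(map)) {
      abort(sprintf("domain '%s' (%d-%d) exceeds reference length %d",
                    d$name, d$start, d$end, length(map)))
    }
    cols <- map[d$start:d$end]
    hits <- dplyr::filter(sel, .data$alignment == d$protein,
                          .data$column %in% cols)
    tibble(protein = d$protein, name = d$name, start = d$start, end = d$end,
           n_selected = nrow(hits), positions = list(hits))
  })
  out <- bind_rows(rows)
  out <- dplyr::filter(out, .data$n_selected >= min_positions)
  arrange(out, desc(.data$n_selected), .data$name)
}

#' Rolling-window median p-value along an alignment
#'
#' Windows slide one selected position at a time over runs of consecutively
#' selected positions (excluded positions break runs; runs shorter than the
#' window yield nothing). Conserved positions contribute p = 1.
#'
#' @param result A [run_scan()] result.
#' @param alignment Alignment id.
#' @param window Window length in selected positions.
#' @return A tibble: `start_column`, `end_column`, `median_p`.
#' @export
rolling_median_p <- function(result, alignment, window = 10L) {
  cols <- dplyr::filter(as_tibble(result), .data$alignment == !!alignment)
  if (nrow(cols) == 0L) abort(sprintf("alignment '%s' not in result", alignment))
  cols <- arrange(cols, .data$column)
  # runs are maximal stretches of selected positions at consecutive column
  # indices; excluded rows or index gaps (results read back from disk carry
  # only selected positions) both break a run
  stretch <- cumsum(c(TRUE, diff(cols$column) != 1L))
  out <- list()
  for (g in split(seq_len(nrow(cols)), stretch)) {
    runs <- residue_runs(cols$class[g] != "excluded")
    for (r in seq_len(nrow(runs))) {
      if (runs$len[r] < window) next
      idx <- g[runs$from[r]:runs$to[r]]
      for (s in 1:(length(idx) - window + 1L)) {
        w <- idx[s:(s + window - 1L)]
        out[[length(out) + 1L]] <- tibble(
          start_column = cols$column[w[1]],
          end_column = cols$column[w[window]],
          median_p = median(cols$p_mls[w]))
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(start_column = integer(), end_column = integer(),
                  median_p = double()))
  }
  bind_rows(out)
}

#' PGLS of a residue count over a region on lifespan and mass
#'
#' Counts occurrences of one residue per species over a column range (the
#' reference species included: the response is a plain count, not
#' reference-relative) and regresses the counts on transformed MLS and mass
#' under the Brownian covariance.
#'
#' @param panel An [alignment_panel()].
#' @param alignment Alignment id.
#' @param columns Integer vector of alignment columns defining the region.
#' @param residue Single one-letter residue code (e.g. `"C"` for cysteine).
#' @param traits A [trait_table()].
#' @param tree Time-scaled [ape::phylo].
#' @param lambda Pagel's lambda.
#' @param transform Trait transform as in [fit_column()].
#' @return A `longscan_gls` fit (terms `mls`, `mass`).
#' @export
region_residue_count_pgls <- function(panel, alignment, columns, residue,
                                      traits, tree, lambda = 1,
                                      transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  stopifnot(residue %in% AA_STANDARD)
  msa <- panel[[alignment]]
  if (is.null(msa)) abort(sprintf("alignment '%s' not in panel", alignment))
  if (any(columns < 1L | columns > ncol(msa))) abort("column range outside alignment")
  region <- msa[, columns, drop = FALSE]
  has_seq <- rowSums(region != AA_GAP) > 0
  species <- intersect(intersect(rownames(msa)[has_seq], traits$species),
                       tree$tip.label)
  if (length(species) < 4L) abort("need at least 4 species with sequence in the region")
  counts <- rowSums(region[species, , drop = FALSE] == residue)
  Sigma <- brownian_covariance(tree, species, lambda)
  X <- trait_design(traits, species, transform)
  gls_fit(counts, X, Sigma)
}
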