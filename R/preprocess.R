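#' Fraction of a column agreeing with one species' residue
#'
#' For the residue of `species` at `column`, returns the fraction of the
#' other species with a real residue in that column whose residue matches
#' it. Returns 0 when no other species has a real residue. Gaps and masked
#' positions never count.
#'
#' @param msa Character matrix (species x columns).
#' @param species Species id (row name).
#' @param column Column index (1-based).
#' @return A fraction in `[0, 1]`.
#' @export
residue_column_identity <- function(msa, species, column) {
  chars <- msa[, column]
  q <- chars[[species]]
  if (!q %in% AA_STANDARD) {
    abort(sprintf("species '%s' has no real residue at column %d", species, column))
  }
  others <- chars[setdiff(names(chars), species)]
  others <- others[others %in% AA_STANDARD]
  if (length(others) == 0L) return(0)
  mean(others == q)
}

# Identity fraction of every (species, column) cell with a real residue,
# computed in one pass; NA where the species has a gap or mask.
identity_matrix <- function(msa) {
  real <- matrix(msa %in% AA_STANDARD, nrow = nrow(msa),
                 dimnames = dimnames(msa))
  out <- matrix(NA_real_, nrow(msa), ncol(msa), dimnames = dimnames(msa))
  for (j in seq_len(ncol(msa))) {
    rj <- real[, j]
    n_real <- sum(rj)
    if (n_real == 0L) next
    counts <- table(msa[rj, j])
    idj <- if (n_real == 1L) 0 else
      (as.numeric(counts[msa[rj, j]]) - 1) / (n_real - 1)
    out[rj, j] <- idj
  }
  out
}

#' Mask divergent subsequences
#'
#' Per sequence, replaces with `"X"` every maximal run of real residues
#' (gaps skipped) that starts and ends on a divergent residue, spans at
#' least `min_run` residues, and in which every window of `window`
#' consecutive residues contains at least `min_divergent` divergent
#' residues — a residue being divergent when its
#' [residue_column_identity()] falls below `identity_threshold`. Trimming
#' runs to divergent endpoints keeps agreeing flanks, which windows
#' straddling a divergent segment would otherwise drag in (so a segment of
#' only 9 divergent residues is never masked). Identities are computed once
#' on the unmasked input, so masking one sequence never cascades into
#' another.
#'
#' @param panel An [alignment_panel()].
#' @param window Window length in real residues.
#' @param min_divergent Minimum number of low-identity residues per window.
#' @param identity_threshold Identity below which a residue counts as
#'   divergent.
#' @param min_run Minimum masked-run length in residues.
#' @return A list with elements `panel` (the masked panel) and `report`
#'   (a tibble of masked intervals: alignment, species, start, end in
#'   1-based inclusive aligned coordinates, n_residues).
#' @export
mask_divergent_subsequences <- function(panel, window = 10L, min_divergent = 4L,
                                        identity_threshold = 0.30,
                                        min_run = 10L) {
  stopifnot(inherits(panel, "aa_panel"))
  masked <- unclass(panel)
  report <- list()
  for (id in names(panel)) {
    msa <- panel[[id]]
    if (window > ncol(msa)) {
      warn(sprintf("alignment '%s': window (%d) exceeds alignment length (%d); nothing masked",
                   id, window, ncol(msa)))
      next
    }
    idf <- identity_matrix(msa)
    for (sp in rownames(msa)) {
      pos <- which(msa[sp, ] %in% AA_STANDARD)
      k <- length(pos)
      if (k < window) next
      div <- idf[sp, pos] < identity_threshold
      # rolling count of divergent residues in each length-`window` window
      cs <- cumsum(c(0, div))
      qual <- (cs[(window + 1):(k + 1)] - cs[1:(k - window + 1)]) >= min_divergent
      if (!any(qual)) next
      # each maximal run of qualifying windows covers residues
      # [s1, s2 + window - 1]; trim that span to its outermost divergent
      # residues and keep it if at least min_run residues remain
      qruns <- residue_runs(qual)
      runs <- list()
      for (r in seq_len(nrow(qruns))) {
        span <- qruns$from[r]:(qruns$to[r] + window - 1L)
        dspan <- span[div[span]]
        if (length(dspan) == 0L) next
        from <- dspan[1]
        to <- dspan[length(dspan)]
        if (to - from + 1L >= min_run) {
          runs[[length(runs) + 1L]] <- tibble(from = from, to = to,
                                              len = to - from + 1L)
        }
      }
      runs <- if (length(runs)) bind_rows(runs) else
        tibble(from = integer(), to = integer(), len = integer())
      for (r in seq_len(nrow(runs))) {
        res_idx <- runs$from[r]:runs$to[r]
        masked[[id]][sp, pos[res_idx]] <- AA_MASK
        report[[length(report) + 1L]] <- tibble(
          alignment = id, species = sp,
          start = pos[runs$from[r]], end = pos[runs$to[r]],
          n_residues = runs$len[r])
      }
    }
  }
  report <- if (length(report)) bind_rows(report) else
    tibble(alignment = character(), species = character(),
           start = integer(), end = integer(), n_residues = integer())
  list(panel = structure(masked, class = "aa_panel"), report = report)
}

# Maximal runs of TRUE in a logical vector.
residue_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(from = starts[keep], to = ends[keep], len = r$lengths[keep])
}

#' Classify alignment columns as excluded, conserved or fit
#'
#' A column is *selected* when it carries at least `min_chars` real residues
#' including one for the reference species and one for every species in
#' `required_species`. Selected columns with at least `min_diff`
#' non-reference residues differing from the reference residue are *fit*;
#' the remaining selected columns are *conserved*; everything else is
#' *excluded*. Gaps and masked positions never count as characters.
#'
#' @param panel An [alignment_panel()] (typically already masked).
#' @param traits A [trait_table()]; its reference species anchors the
#'   classification.
#' @param required_species Species that must carry a residue for a column to
#'   be selected. Defaults to the shortest-lived species in the trait table,
#'   mirroring the shrew anchor used at proteome scale.
#' @param min_chars Minimum real residues per selected column.
#' @param min_diff Minimum differing non-reference residues for class `fit`.
#' @return A tibble with one row per column: `alignment`, `column`, `class`,
#'   `ref_residue`, `n_chars`, `n_diff`.
#' @export
classify_columns <- function(panel, traits, required_species = NULL,
                             min_chars = 10L, min_diff = 3L) {
  stopifnot(inherits(panel, "aa_panel"), inherits(traits, "trait_table"))
  reference <- trait_reference(traits)
  required_species <- required_species %||% default_required_species(traits)
  missing <- setdiff(c(reference, required_species), traits$species)
  if (length(missing)) {
    abort(sprintf("species not in trait table: %s", paste(missing, collapse = ", ")))
  }
  out <- lapply(names(panel), function(id) {
    msa <- panel[[id]]
    nc <- ncol(msa)
    base <- tibble(alignment = id, column = seq_len(nc),
                   class = "excluded", ref_residue = NA_character_,
                   n_chars = 0L, n_diff = 0L)
    if (!reference %in% rownames(msa)) {
      warn(sprintf("alignment '%s' lacks reference '%s'; all columns excluded",
                   id, reference))
      return(base)
    }
    req_here <- intersect(required_species, rownames(msa))
    real <- matrix(msa %in% AA_STANDARD, nrow = nrow(msa),
                   dimnames = dimnames(msa))
    n_chars <- colSums(real)
    ref_real <- real[reference, ]
    req_ok <- if (length(required_species) == 0L) rep(TRUE, nc) else if
      (length(req_here) < length(required_species)) rep(FALSE, nc) else
      colSums(real[req_here, , drop = FALSE]) == length(req_here)
    selected <- n_chars >= min_chars & ref_real & req_ok
    ref_res <- msa[reference, ]
    nonref <- setdiff(rownames(msa), reference)
    diff_mat <- real[nonref, , drop = FALSE] &
      (msa[nonref, , drop = FALSE] != matrix(ref_res, length(nonref), nc, byrow = TRUE))
    n_diff <- colSums(diff_mat)
    base$n_chars <- unname(n_chars)
    base$n_diff <- unname(as.integer(n_diff))
    base$ref_residue <- ifelse(ref_real, ref_res, NA_character_)
    base$class[selected] <- ifelse(n_diff[selected] >= min_diff, "fit", "conserved")
    base
  })
  bind_rows(out)
}

# The scan's anchor species: shortest-lived in the trait table — the
# analogue of anchoring a mammalian panel on shrew, the shortest-lived
# non-rodent, when no taxonomy is available.
default_required_species <- function(traits) {
  traits$species[which.min(traits$mls_years)]
}
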