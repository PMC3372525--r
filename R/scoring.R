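#' Species mutation-rate corrections from a substitution-scaled tree
#'
#' The rate proxy for species *s* is its root-to-tip path length `m_s` on a
#' tree whose branch lengths are expected amino-acid substitutions. Each
#' species' score correction is `log10(m_s / m_ref)`, so the reference
#' species' correction is exactly 0 and slower-evolving lineages receive
#' negative corrections.
#'
#' @param subst_tree A substitution-scaled [ape::phylo] tree.
#' @param reference Reference species id (must be a tip).
#' @return A `mutation_rates` tibble: `species`, `m`, `correction`, with the
#'   reference in attribute `reference`.
#' @export
mutation_lengths_from_tree <- function(subst_tree, reference) {
  if (!reference %in% subst_tree$tip.label) {
    abort(sprintf("reference '%s' is not a tip of the substitution tree", reference))
  }
  m <- tip_depths(subst_tree)
  if (any(m <= 0)) {
    abort(sprintf("zero root-to-tip substitution path for '%s': correction undefined",
                  names(m)[which(m <= 0)[1]]))
  }
  corr <- log10(unname(m) / m[[reference]])
  out <- tibble(species = names(m), m = unname(m), correction = corr)
  structure(out, reference = reference,
            class = c("mutation_rates", class(out)))
}

#' @rdname mutation_lengths_from_tree
#' @param species Species ids.
#' @description `uniform_rates()` builds the no-correction limit (every
#'   species at the reference rate), under which corrected scores reduce to
#'   raw matrix lookups.
#' @export
uniform_rates <- function(species, reference) {
  stopifnot(reference %in% species)
  out <- tibble(species = species, m = 1, correction = 0)
  structure(out, reference = reference,
            class = c("mutation_rates", class(out)))
}

rate_correction <- function(rates, species) {
  i <- match(species, rates$species)
  if (anyNA(i)) {
    abort(sprintf("species '%s' absent from mutation rates", species[which(is.na(i))[1]]))
  }
  rates$correction[i]
}

#' Estimate a substitution-scaled tree from a panel
#'
#' Branch lengths on the fixed input topology are fitted by non-negative
#' least squares ([phangorn::nnls.tree]) to Poisson-corrected pairwise
#' distances `d_ij = -ln(1 - p_ij)`, where `p_ij` is the mismatch fraction
#' over columns in which both species carry a real residue. A deliberately
#' simple stand-in for full maximum-likelihood branch-length estimation; a
#' user-supplied substitution tree always takes precedence in [run_scan()].
#'
#' @param panel An [alignment_panel()].
#' @param topology A rooted [ape::phylo] covering all panel species.
#' @param columns Optional tibble (`alignment`, `column`) restricting the
#'   distance computation, e.g. to fit columns; default uses every column.
#' @return A substitution-scaled [ape::phylo].
#' @export
estimate_substitution_tree <- function(panel, topology, columns = NULL) {
  stopifnot(inherits(panel, "aa_panel"))
  species <- sort(unique(unlist(lapply(panel, rownames))))
  missing <- setdiff(species, topology$tip.label)
  if (length(missing)) {
    abort(sprintf("topology lacks species: %s", paste(missing, collapse = ", ")))
  }
  # concatenate the (optionally restricted) panel into one species x sites matrix
  mats <- lapply(names(panel), function(id) {
    msa <- panel[[id]]
    if (!is.null(columns)) {
      keep <- columns$column[columns$alignment == id]
      msa <- msa[, keep, drop = FALSE]
    }
    full <- matrix(AA_GAP, length(species), ncol(msa),
                   dimnames = list(species, NULL))
    full[rownames(msa), ] <- msa
    full
  })
  cat_msa <- do.call(cbind, mats)
  real <- matrix(cat_msa %in% AA_STANDARD, nrow = nrow(cat_msa))
  n <- length(species)
  D <- matrix(0, n, n, dimnames = list(species, species))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- real[i, ] & real[j, ]
      if (!any(shared)) {
        abort(sprintf("species '%s' and '%s' share no columns", species[i], species[j]))
      }
      p <- mean(cat_msa[i, shared] != cat_msa[j, shared])
      if (p >= 1) {
        abort(sprintf("saturated distance between '%s' and '%s' (p = 1)",
                      species[i], species[j]))
      }
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  topology <- ape::keep.tip(topology, species)
  if (n == 2L) {
    fitted <- topology
    fitted$edge.length <- rep(D[1, 2] / 2, length(topology$edge.length))
  } else {
    fitted <- phangorn::nnls.tree(stats::as.dist(D), topology, method = "unrooted")
    fitted$edge.length[fitted$edge.length < 0] <- 0
    # nnls.tree returns an unrooted tree and pairwise distances cannot place
    # the root: restore the input topology's basal bipartition and split the
    # basal length evenly so root-to-tip paths are well defined
    if (!ape::is.rooted(fitted)) {
      fitted <- reroot_basal(fitted, topology, n)
    }
    root <- length(fitted$tip.label) + 1L
    basal <- which(fitted$edge[, 1] == root)
    fitted$edge.length[basal] <- sum(fitted$edge.length[basal]) / length(basal)
  }
  attr(fitted, "tree_kind") <- "subst"
  fitted
}

# Restore the input topology's basal bipartition on an unrooted fitted
# tree. After unrooting, only one side of the former root is guaranteed to
# remain a subtree, so try both.
reroot_basal <- function(fitted, topology, n) {
  kids <- topology$edge[topology$edge[, 1] == n + 1L, 2]
  for (ch in kids) {
    clade <- if (ch <= n) topology$tip.label[ch] else
      ape::extract.clade(topology, ch)$tip.label
    out <- tryCatch(ape::root(fitted, outgroup = clade, resolve.root = TRUE),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  abort("could not re-root the fitted substitution tree")
}

#' Mutation-rate-corrected, clamped similarity score
#'
#' The score of `residue` against `ref_residue` plus the species' rate
#' correction, clamped to the range of scores attainable for the reference
#' residue (the min and max of its matrix row over the 20 standard
#' residues).
#'
#' @param residue,ref_residue Standard one-letter residue codes.
#' @param matrix A `subst_matrix`.
#' @param rates A `mutation_rates` table.
#' @param species Species id of `residue`.
#' @return A real score within the reference residue's attainable range.
#' @export
corrected_score <- function(residue, ref_residue, matrix, rates, species) {
  if (!residue %in% AA_STANDARD || !ref_residue %in% AA_STANDARD) {
    abort(sprintf("non-standard residue in pair (%s, %s)", residue, ref_residue))
  }
  raw <- sm_score(matrix, residue, ref_residue) + rate_correction(rates, species)
  rng <- sm_row_range(matrix, ref_residue)
  pmin(pmax(raw, rng[1]), rng[2])
}

#' Score every non-reference residue of a fit column
#'
#' @param msa Character matrix holding the column.
#' @param column Column index.
#' @param ref_residue The reference species' residue in this column.
#' @param reference Reference species id.
#' @inheritParams corrected_score
#' @return A named numeric vector of corrected, clamped scores for exactly
#'   the non-reference species with a real residue in the column.
#' @export
score_column <- function(msa, column, ref_residue, reference, matrix, rates) {
  chars <- msa[, column]
  chars <- chars[setdiff(names(chars), reference)]
  chars <- chars[chars %in% AA_STANDARD]
  if (length(chars) == 0L) return(setNames(numeric(0), character(0)))
  raw <- sm_score(matrix, chars, rep(ref_residue, length(chars))) +
    rate_correction(rates, names(chars))
  rng <- sm_row_range(matrix, ref_residue)
  setNames(pmin(pmax(raw, rng[1]), rng[2]), names(chars))
}
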