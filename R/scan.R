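#' Scan configuration
#'
#' Bundles every tunable of the scan with the defaults used throughout:
#' significance threshold 0.01, at least 10 characters per selected column,
#' at least 3 differing residues for a fit column, Pagel's lambda fixed at
#' 1, log10 trait transform, BLOSUM80 scoring, and the 10-residue masking
#' window with at least 4 residues under 30% column identity.
#'
#' @param alpha Significance threshold on per-column p-values.
#' @param min_chars,min_diff Column classification thresholds
#'   ([classify_columns()]).
#' @param lambda Off-diagonal multiplier of the Brownian covariance.
#' @param trait_transform `"log10"` or `"identity"`.
#' @param required_species Anchor species ([classify_columns()]); `NULL`
#'   picks the shortest-lived species.
#' @param mask Apply [mask_divergent_subsequences()] first?
#' @param window,min_divergent,identity_threshold,min_run Masking
#'   parameters.
#' @param min_fit_species Minimum species for a non-degenerate column fit.
#' @param matrix Substitution matrix name for [blosum_matrix()].
#' @param seed Optional integer recorded in the result provenance.
#' @return A `scan_config` list.
#' @export
scan_config <- function(alpha = 0.01, min_chars = 10L, min_diff = 3L,
                        lambda = 1, trait_transform = c("log10", "identity"),
                        required_species = NULL, mask = TRUE,
                        window = 10L, min_divergent = 4L,
                        identity_threshold = 0.30, min_run = 10L,
                        min_fit_species = 4L, matrix = "BLOSUM80",
                        seed = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, min_chars = min_chars, min_diff = min_diff,
                 lambda = lambda, trait_transform = match.arg(trait_transform),
                 required_species = required_species, mask = mask,
                 window = window, min_divergent = min_divergent,
                 identity_threshold = identity_threshold, min_run = min_run,
                 min_fit_species = min_fit_species, matrix = matrix,
                 seed = seed),
            class = "scan_config")
}

#' Run the full longevity-selection scan
#'
#' Masks divergent subsequences, classifies columns, scores each fit column
#' against the reference residue with mutation-rate correction, and fits
#' each fit column by PGLS on transformed MLS and body mass. Conserved
#' columns receive the fixed convention `b_mls = 0`, `p_mls = 1`. The
#' result is deterministic given inputs and configuration.
#'
#' @param panel An [alignment_panel()].
#' @param traits A [trait_table()]; its reference species defines the
#'   similarity axis.
#' @param tree Time-scaled [ape::phylo] covering the scanned species.
#' @param matrix A `subst_matrix`; default loads `config$matrix`.
#' @param rates A `mutation_rates` table, or `NULL` to estimate one from
#'   the panel's fit columns via [estimate_substitution_tree()]. Use
#'   [uniform_rates()] to disable the correction.
#' @param config A [scan_config()].
#' @return A `longscan_scan` tibble with one row per column (`alignment`,
#'   `column`, `class`, `ref_residue`, `n_chars`, `n_diff`, `n`, `b_mls`,
#'   `p_mls`, `b_mass`, `p_mass`, `degenerate`, `longevity_selected`,
#'   `mass_selected`) and attributes `config`, `counts`, `reference`,
#'   `mask_report`, `rates`, `provenance`.
#' @export
run_scan <- function(panel, traits, tree, matrix = NULL, rates = NULL,
                     config = scan_config()) {
  stopifnot(inherits(panel, "aa_panel"), inherits(traits, "trait_table"),
            inherits(config, "scan_config"))
  tree <- validate_tree(tree, "time")
  matrix <- matrix %||% blosum_matrix(config$matrix)
  reference <- trait_reference(traits)

  mask_report <- NULL
  if (isTRUE(config$mask)) {
    m <- mask_divergent_subsequences(
      panel, window = config$window, min_divergent = config$min_divergent,
      identity_threshold = config$identity_threshold, min_run = config$min_run)
    panel <- m$panel
    mask_report <- m$report
  }
  classes <- classify_columns(panel, traits,
                              required_species = config$required_species,
                              min_chars = config$min_chars,
                              min_diff = config$min_diff)
  fit_cols <- dplyr::filter(classes, .data$class == "fit")
  if (nrow(fit_cols) == 0L) {
    warn("no fit columns in panel; result contains no regression fits")
  }
  if (is.null(rates)) {
    rates <- if (nrow(fit_cols) > 0L) {
      # estimated from every column: at desk scale the fit subset alone is
      # too small to cover all species pairs
      st <- estimate_substitution_tree(panel, tree)
      mutation_lengths_from_tree(st, reference)
    } else {
      uniform_rates(unique(unlist(lapply(panel, rownames))), reference)
    }
  }

  fits <- fit_panel_columns(panel, fit_cols, traits, tree, matrix, rates, config)
  result <- left_join(classes, fits, by = c("alignment", "column"))
  conserved <- result$class == "conserved"
  result$b_mls[conserved] <- 0
  result$p_mls[conserved] <- 1
  result$longevity_selected <- result$class == "fit" &
    !is.na(result$b_mls) & result$b_mls > 0 &
    !is.na(result$p_mls) & result$p_mls < config$alpha
  result$mass_selected <- result$class == "fit" &
    !is.na(result$b_mass) & result$b_mass > 0 &
    !is.na(result$p_mass) & result$p_mass < config$alpha

  counts <- list(
    columns = nrow(result),
    selected = sum(result$class != "excluded"),
    fit = sum(result$class == "fit"),
    conserved = sum(result$class == "conserved"),
    longevity_selected = sum(result$longevity_selected),
    mass_selected = sum(result$mass_selected))
  provenance <- hash(list(panel = unclass(panel), traits = as.data.frame(traits),
                          tree = ape::write.tree(tree),
                          matrix = unclass(matrix), config = unclass(config)))
  structure(result,
            config = config, counts = counts, reference = reference,
            mask_report = mask_report, rates = rates, provenance = provenance,
            class = c("longscan_scan", class(result)))
}

fit_panel_columns <- function(panel, fit_cols, traits, tree, matrix, rates,
                              config) {
  reference <- trait_reference(traits)
  usable <- intersect(intersect(rates$species, traits$species), tree$tip.label)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(fit_cols))
  for (id in unique(fit_cols$alignment)) {
    msa <- panel[[id]]
    keep <- intersect(rownames(msa), union(usable, reference))
    msa <- msa[keep, , drop = FALSE]
    idx <- which(fit_cols$alignment == id)
    for (i in idx) {
      col <- fit_cols$column[i]
      scores <- score_column(msa, col, fit_cols$ref_residue[i], reference,
                             matrix, rates)
      species <- setdiff(intersect(names(scores), usable), reference)
      if (length(species) < config$min_fit_species) {
        rows[[i]] <- tibble(alignment = id, column = col,
                            n = length(species), b_mls = 0, p_mls = 1,
                            b_mass = 0, p_mass = 1, degenerate = TRUE)
        next
      }
      key <- paste(sort(species), collapse = "|")
      ctx <- cache[[key]]
      if (is.null(ctx)) {
        species <- sort(species)
        Sigma <- brownian_covariance(tree, species, config$lambda)
        X <- trait_design(traits, species, config$trait_transform)
        ctx <- make_gls_context(X, Sigma)
        ctx$species <- species
        cache[[key]] <- ctx
      }
      fit <- gls_fit_ctx(ctx, scores[ctx$species])
      rows[[i]] <- tibble(
        alignment = id, column = col, n = length(ctx$species),
        b_mls = if (fit$degenerate) 0 else unname(fit$coefficients["mls"]),
        p_mls = if (fit$degenerate) 1 else unname(fit$p.value["mls"]),
        b_mass = if (fit$degenerate) 0 else unname(fit$coefficients["mass"]),
        p_mass = if (fit$degenerate) 1 else unname(fit$p.value["mass"]),
        degenerate = fit$degenerate)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(alignment = character(), column = integer(), n = integer(),
                  b_mls = double(), p_mls = double(), b_mass = double(),
                  p_mass = double(), degenerate = logical()))
  }
  bind_rows(rows)
}

#' Extract longevity- and mass-selected positions
#'
#' A longevity-selected position is a fit column with `b_mls > 0` and
#' `p_mls < alpha`; a mass-selected position satisfies the analogous
#' condition on the mass coefficient.
#'
#' @param result A [run_scan()] result.
#' @param alpha Threshold; defaults to the scan's configured alpha.
#' @return A list with tibbles `longevity` and `mass`.
#' @export
call_positions <- function(result, alpha = NULL) {
  stopifnot(inherits(result, "longscan_scan"))
  alpha <- alpha %||% attr(result, "config")$alpha
  fit <- dplyr::filter(as_tibble(result), .data$class == "fit")
  list(
    longevity = dplyr::filter(fit, .data$b_mls > 0, .data$p_mls < alpha),
    mass = dplyr::filter(fit, .data$b_mass > 0, .data$p_mass < alpha))
}

#' Permute traits and tip labels for the randomized control
#'
#' Draws a uniformly random permutation of the non-reference species and
#' swaps their (MLS, mass, tip label) triples accordingly; the reference
#' species is a fixed point and alignments are untouched, so the same
#' columns are classified and fit in the control as in the real scan.
#'
#' @param traits A [trait_table()].
#' @param tree Time-scaled [ape::phylo].
#' @param seed Optional integer seed.
#' @return A list: `traits` (permuted), `tree` (tips relabelled by the same
#'   permutation), `permutation` (named vector, species -> donor species).
#' @export
randomize_traits <- function(traits, tree, seed = NULL) {
  stopifnot(inherits(traits, "trait_table"))
  if (!is.null(seed)) set.seed(seed)
  reference <- trait_reference(traits)
  nonref <- setdiff(traits$species, reference)
  if (length(nonref) < 2L) abort("need at least 2 non-reference species")
  donor <- setNames(sample(nonref), nonref)
  i <- match(traits$species, names(donor))
  new_traits <- traits
  swap <- !is.na(i)
  j <- match(donor[i[swap]], traits$species)
  new_traits$mls_years[swap] <- traits$mls_years[j]
  new_traits$mass_g[swap] <- traits$mass_g[j]
  new_tree <- tree
  # the tip that carried the donor's label now carries the recipient's
  relabel <- match(new_tree$tip.label, donor)
  new_tree$tip.label[!is.na(relabel)] <- names(donor)[relabel[!is.na(relabel)]]
  kind <- attr(tree, "tree_kind") %||% "time"
  list(traits = trait_table(as_tibble(new_traits), reference = reference),
       tree = validate_tree(new_tree, kind),
       permutation = donor)
}

#' Map ungapped reference positions to alignment columns
#'
#' @param msa Character matrix.
#' @param reference Reference species id.
#' @return An integer vector: entry `i` is the alignment column holding the
#'   reference's `i`-th non-gap character.
#' @export
ref_to_column <- function(msa, reference) {
  if (!reference %in% rownames(msa)) {
    abort(sprintf("reference '%s' absent from alignment", reference))
  }
  which(msa[reference, ] != AA_GAP)
}

#' Rebuild a scan-result object from a per-column table
#'
#' Used to resume downstream analyses from results written with
#' [write_scan_results()]. Significance calls are recomputed from the
#' stored slopes and p-values.
#'
#' @param columns A tibble in the [read_scan_results()] layout.
#' @param reference Reference species id.
#' @param config A [scan_config()]; its alpha drives the significance
#'   calls.
#' @return A `longscan_scan` object.
#' @export
as_scan_result <- function(columns, reference, config = scan_config()) {
  columns <- as_tibble(columns)
  columns$longevity_selected <- columns$class == "fit" &
    !is.na(columns$b_mls) & columns$b_mls > 0 &
    !is.na(columns$p_mls) & columns$p_mls < config$alpha
  columns$mass_selected <- columns$class == "fit" &
    !is.na(columns$b_mass) & columns$b_mass > 0 &
    !is.na(columns$p_mass) & columns$p_mass < config$alpha
  counts <- list(
    columns = nrow(columns),
    selected = sum(columns$class != "excluded"),
    fit = sum(columns$class == "fit"),
    conserved = sum(columns$class == "conserved"),
    longevity_selected = sum(columns$longevity_selected),
    mass_selected = sum(columns$mass_selected))
  structure(columns, config = config, counts = counts, reference = reference,
            mask_report = NULL, rates = NULL,
            provenance = hash(as.data.frame(columns)),
            class = c("longscan_scan", class(columns)))
}

#' @export
print.longscan_scan <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf(
    "<longscan_scan: %d columns; %d selected (%d fit, %d conserved); %d longevity-selected, %d mass-selected>\n",
    cnt$columns, cnt$selected, cnt$fit, cnt$conserved,
    cnt$longevity_selected, cnt$mass_selected))
  NextMethod()
}
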