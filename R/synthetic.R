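#' Simulation specification
#'
#' Fixes every knob of the synthetic study generator. Defaults emulate a
#' mammal-scale comparative panel: 33 species on an ultrametric coalescent
#' tree of depth 1, correlated Brownian log10 life-history traits whose tip
#' spread matches a 3-90 year lifespan range, and an alignment mixing fully
#' conserved columns, trait-independent "null" columns evolved along the
#' tree, and "planted" columns whose similarity to the reference residue
#' increases with log10 lifespan at a known slope.
#'
#' @param n_species Number of tips.
#' @param depth Tree depth (time units).
#' @param root_log_mls,root_log_mass Root values of log10 MLS (years) and
#'   log10 mass (grams).
#' @param bm_var Brownian variance per unit depth of each log10 trait.
#' @param trait_cor Correlation of the two traits' Brownian increments.
#' @param mls_range_decades If not `NULL`, both log10 traits are rescaled
#'   (jointly, preserving their correlation and the Brownian geometry up to
#'   a common factor) so the realized log10-MLS range across tips equals
#'   this value. The default 1.5 matches a 3-90 year panel; `NULL` keeps
#'   the raw Brownian draw, whose realized spread varies with the deep
#'   splits of the tree.
#' @param n_conserved,n_null,n_planted Column counts per class.
#' @param effect Planted slope, in score units per log10 year of MLS.
#' @param noise_sd Tip standard deviation of the Brownian noise on the
#'   planted score target (score units).
#' @param null_rate Substitution events per unit branch length in null
#'   columns.
#' @param softmax_temp Temperature of the BLOSUM-softmax substitution
#'   kernel.
#' @param rate_multipliers Optional named per-species rate multipliers on
#'   pendant branches (default: all 1).
#' @param seed Integer seed fixing all randomness.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_species = 33L, depth = 1,
                            root_log_mls = 1.1, root_log_mass = 3.5,
                            bm_var = 0.15, trait_cor = 0.8,
                            mls_range_decades = 1.5,
                            n_conserved = 160L, n_null = 36L, n_planted = 4L,
                            effect = 3, noise_sd = 0.5,
                            null_rate = 1, softmax_temp = 2,
                            rate_multipliers = NULL, seed = 1L) {
  stopifnot(n_species >= 3L, depth > 0, bm_var >= 0,
            abs(trait_cor) <= 1, n_conserved >= 0L, n_null >= 0L,
            n_planted >= 0L, is.finite(effect), noise_sd >= 0,
            null_rate >= 0, softmax_temp > 0)
  structure(list(n_species = n_species, depth = depth,
                 root_log_mls = root_log_mls, root_log_mass = root_log_mass,
                 bm_var = bm_var, trait_cor = trait_cor,
                 mls_range_decades = mls_range_decades,
                 n_conserved = n_conserved, n_null = n_null,
                 n_planted = n_planted, effect = effect, noise_sd = noise_sd,
                 null_rate = null_rate, softmax_temp = softmax_temp,
                 rate_multipliers = rate_multipliers, seed = seed),
            class = "simulation_spec")
}

#' Simulate an ultrametric species tree
#'
#' A random coalescent topology whose node heights are spread by a power
#' transform (height -> height^`height_power` on the unit-depth scale)
#' before rescaling to `depth`. The transform pulls the coalescent's pile-up
#' of near-present splits apart so that sister species are separated by a
#' few percent of tree depth, as in dated species-level trees; the raw
#' coalescent would make many tip pairs effectively indistinguishable.
#'
#' @param n_species Number of tips (at least 3).
#' @param depth Root-to-tip depth.
#' @param height_power Exponent applied to relative node heights (1 keeps
#'   raw coalescent times).
#' @param seed Optional integer seed.
#' @return A time-scaled [ape::phylo] with tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_species, depth = 1, height_power = 0.5,
                          seed = NULL) {
  stopifnot(n_species >= 3L, height_power > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rcoal(n_species, tip.label = sprintf("sp%02d", seq_len(n_species)))
  h <- c(rep(0, n_species), ape::branching.times(tree))  # node heights
  h <- depth * (h / max(h))^height_power
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  validate_tree(tree, "time")
}

#' Simulate correlated Brownian life-history traits
#'
#' log10 MLS and log10 mass evolve as correlated Brownian motion along the
#' tree and are exponentiated into the trait table; the longest-lived
#' species becomes the reference.
#'
#' @param tree Time-scaled [ape::phylo].
#' @param spec A [simulation_spec()] (only the trait fields are used).
#' @param seed Optional integer seed.
#' @return A [trait_table()].
#' @export
simulate_traits <- function(tree, spec = simulation_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  C <- ape::vcv.phylo(tree)
  S <- spec$bm_var * matrix(c(1, spec$trait_cor, spec$trait_cor, 1), 2)
  Z <- matrix(rnorm(2 * n), n, 2)
  X <- if (spec$bm_var > 0) t(chol(C)) %*% Z %*% chol(S) else matrix(0, n, 2)
  if (!is.null(spec$mls_range_decades) && spec$bm_var > 0) {
    X <- X * spec$mls_range_decades / diff(range(X[, 1]))
  }
  logs <- cbind(spec$root_log_mls, spec$root_log_mass)[rep(1, n), ] + X
  trait_table(tibble(species = rownames(C),
                     mls_years = 10^logs[, 1],
                     mass_g = 10^logs[, 2]))
}

#' Simulate an alignment panel with known column classes
#'
#' Conserved columns share one residue across all species. Null columns
#' evolve along the tree by a Poisson substitution process whose replacement
#' kernel is a softmax over substitution-matrix similarity to the current
#' residue (so exchanges favour biochemically similar residues), with
#' optional per-species rate multipliers on pendant branches. Planted
#' columns draw each species' residue so its expected similarity to the
#' reference residue increases with log10 MLS at slope `spec$effect`:
#' species' score targets are linear in log10 MLS plus Gaussian noise and
#' each species receives the residue whose score is nearest its target.
#'
#' @param tree Time-scaled [ape::phylo].
#' @param traits A [trait_table()] over the tree's tips.
#' @param spec A [simulation_spec()].
#' @param matrix A `subst_matrix` (defaults to BLOSUM80).
#' @param seed Optional integer seed.
#' @param alignment_id Id of the single generated alignment.
#' @return A list: `panel` ([alignment_panel()]) and `truth`, a tibble with
#'   the generating class (`conserved` / `null` / `planted`) of each column.
#' @export
simulate_panel <- function(tree, traits, spec = simulation_spec(),
                           matrix = NULL, seed = NULL,
                           alignment_id = "sim1", shuffle = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  matrix <- matrix %||% blosum_matrix("BLOSUM80")
  species <- tree$tip.label
  stopifnot(all(species %in% traits$species))
  reference <- trait_reference(traits)
  classes <- rep(c("conserved", "null", "planted"),
                 c(spec$n_conserved, spec$n_null, spec$n_planted))
  n_cols <- length(classes)
  if (n_cols == 0L) abort("spec generates no columns")
  m <- matrix(NA_character_, length(species), n_cols,
              dimnames = list(species, NULL))

  is_con <- classes == "conserved"
  if (any(is_con)) {
    res <- sample(AA_STANDARD, sum(is_con), replace = TRUE)
    m[, is_con] <- matrix(rep(res, each = length(species)),
                          length(species), sum(is_con))
  }
  is_null <- classes == "null"
  if (any(is_null)) {
    m[, is_null] <- evolve_null_columns(tree, sum(is_null), matrix,
                                        spec$null_rate, spec$softmax_temp,
                                        spec$rate_multipliers)[species, ,
                                                               drop = FALSE]
  }
  is_pl <- classes == "planted"
  if (any(is_pl)) {
    m[, is_pl] <- planted_columns(traits, species, sum(is_pl), matrix,
                                  spec$effect, spec$noise_sd, tree)
  }
  if (shuffle) {
    # intersperse variable columns among conserved ones, as in real
    # proteins; a contiguous variable block would read as one divergent
    # subsequence to the masking rule
    perm <- sample(n_cols)
    m <- m[, perm, drop = FALSE]
    classes <- classes[perm]
  }
  truth <- tibble(alignment = alignment_id, column = seq_len(n_cols),
                  truth = classes)
  list(panel = alignment_panel(setNames(list(m), alignment_id)), truth = truth)
}

# Markov substitution along the tree: events ~ Poisson(rate * length), each
# replacing the residue by one drawn from softmax(score(new, current)/temp)
# over the 19 alternatives.
evolve_null_columns <- function(tree, n_cols, matrix, rate, temp,
                                rate_multipliers = NULL) {
  n_tip <- length(tree$tip.label)
  kernel <- softmax_kernel(matrix, temp)
  tree <- stats::reorder(tree)  # cladewise: parents before children
  states <- matrix(NA_character_, n_tip + tree$Nnode, n_cols)
  root <- n_tip + 1L
  states[root, ] <- sample(AA_STANDARD, n_cols, replace = TRUE)
  mult <- setNames(rep(1, n_tip), tree$tip.label)
  if (!is.null(rate_multipliers)) {
    mult[names(rate_multipliers)] <- rate_multipliers
  }
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    r <- rate * if (child <= n_tip) mult[[tree$tip.label[child]]] else 1
    k <- rpois(n_cols, r * tree$edge.length[e])
    st <- states[parent, ]
    for (j in which(k > 0)) {
      cur <- st[j]
      for (s in seq_len(k[j])) {
        cur <- sample(AA_STANDARD, 1L, prob = kernel[cur, ])
      }
      st[j] <- cur
    }
    states[child, ] <- st
  }
  out <- states[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

softmax_kernel <- function(matrix, temp) {
  sc <- matrix[AA_STANDARD, AA_STANDARD]
  k <- exp(sc / temp)
  diag(k) <- 0  # an event always changes the residue
  k / rowSums(k)
}

# Reference residues eligible for planted columns: rows whose attainable
# scores form a wide, dense ladder, so that any clamped linear score target
# can be realized with small rounding error.
planted_eligible <- function(matrix) {
  ok <- vapply(AA_STANDARD, function(r) {
    u <- sort(unique(matrix[r, AA_STANDARD]))
    diff(range(u)) >= 8 && max(diff(u)) <= 4
  }, logical(1))
  AA_STANDARD[ok]
}

planted_columns <- function(traits, species, n_cols, matrix, effect,
                            noise_sd, tree) {
  reference <- trait_reference(traits)
  lm_ref <- log10(traits$mls_years[traits$species == reference])
  dlog <- log10(traits$mls_years[match(species, traits$species)]) - lm_ref
  # target noise evolves as Brownian motion on the tree (tip sd = noise_sd),
  # matching the error model the per-column regression assumes
  C <- ape::vcv.phylo(tree)[species, species]
  Lc <- t(chol(C / max(diag(C))))
  eligible <- planted_eligible(matrix)
  out <- matrix(NA_character_, length(species), n_cols,
                dimnames = list(species, NULL))
  for (j in seq_len(n_cols)) {
    r <- sample(eligible, 1L)
    row <- matrix[r, AA_STANDARD]
    ladder <- sort(unique(row))
    noise <- if (noise_sd > 0) drop(Lc %*% rnorm(length(species))) * noise_sd
             else rep(0, length(species))
    target <- pmin(pmax(matrix[r, r] + effect * dlog + noise,
                        min(ladder)), max(ladder))
    # the rounding draw is itself tree-correlated (probit of a Brownian
    # deviate, hence marginally uniform): close relatives land on the same
    # ladder step, as inherited residues do
    u <- stats::pnorm(drop(Lc %*% rnorm(length(species))))
    out[, j] <- vapply(seq_along(target), function(i)
      sample_score_residue(target[i], u[i], ladder, row), character(1))
    out[species == reference, j] <- r
  }
  out
}

# Draw a residue whose score equals the target in expectation: pick the two
# ladder scores bracketing the target, mix them with linear-interpolation
# weights using the uniform deviate `u`, then draw among residues carrying
# the chosen score.
sample_score_residue <- function(target, u, ladder, row) {
  hi_i <- findInterval(target, ladder, rightmost.closed = TRUE) + 1L
  if (target <= ladder[1]) {
    s <- ladder[1]
  } else if (hi_i > length(ladder)) {
    s <- ladder[length(ladder)]
  } else {
    lo <- ladder[hi_i - 1L]
    hi <- ladder[hi_i]
    s <- if (u < (target - lo) / (hi - lo)) hi else lo
  }
  cand <- names(row)[row == s]
  if (length(cand) > 1L) cand <- sample(cand, 1L)
  cand
}

#' Simulate a complete synthetic study
#'
#' Tree, traits and panel in one deterministic call from a
#' [simulation_spec()].
#'
#' @param spec A [simulation_spec()].
#' @param matrix A `subst_matrix` (defaults to BLOSUM80).
#' @return A list: `tree`, `traits`, `panel`, `truth`, `spec`.
#' @export
simulate_study <- function(spec = simulation_spec(), matrix = NULL) {
  set.seed(spec$seed)
  matrix <- matrix %||% blosum_matrix("BLOSUM80")
  tree <- simulate_tree(spec$n_species, spec$depth)
  traits <- simulate_traits(tree, spec)
  sim <- simulate_panel(tree, traits, spec, matrix = matrix)
  list(tree = tree, traits = traits, panel = sim$panel, truth = sim$truth,
       spec = spec)
}
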