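# Shared fixtures and independent brute-force oracles.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# A small panel where every species carries a residue everywhere.
toy_msa <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

toy_panel <- function(seqs, id = "aln1") {
  alignment_panel(setNames(list(toy_msa(seqs)), id))
}

toy_traits <- function(species, mls = NULL, mass = NULL, reference = NULL) {
  n <- length(species)
  trait_table(tibble::tibble(
    species = species,
    mls_years = mls %||% seq(3, 90, length.out = n),
    mass_g = mass %||% seq(20, 5e5, length.out = n)),
    reference = reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A balanced ultrametric tree over the given species.
toy_tree <- function(species, depth = 1) {
  n <- length(species)
  tree <- ape::compute.brlen(ape::stree(n, type = "balanced", tip.label = species),
                             method = "Grafen")
  tree$edge.length <- tree$edge.length * depth /
    max(ape::node.depth.edgelength(tree)[seq_len(n)])
  validate_tree(tree, "time")
}

# Random toy alignment (no gaps) with a mix of conserved and noisy columns.
random_toy_msa <- function(n_species, n_cols, p_noise = 0.3) {
  species <- sprintf("t%02d", seq_len(n_species))
  m <- matrix(rep(sample(AA20, n_cols, replace = TRUE), each = n_species),
              n_species, n_cols)
  noisy <- matrix(runif(n_species * n_cols) < p_noise, n_species, n_cols)
  m[noisy] <- sample(AA20, sum(noisy), replace = TRUE)
  # sprinkle gaps in a few cells
  gap <- matrix(runif(n_species * n_cols) < 0.05, n_species, n_cols)
  m[gap] <- "-"
  rownames(m) <- species
  m
}

# ---- independent oracles -------------------------------------------------

# Masking oracle: a residue is masked iff it lies in some interval of
# >= min_run consecutive real residues that starts and ends on a divergent
# residue and in which every full window of `window` residues has
# >= min_divergent residues with identity < threshold. Enumerates candidate
# intervals directly (the implementation instead trims maximal runs of
# qualifying windows).
brute_mask <- function(msa, window = 10L, min_divergent = 4L,
                       identity_threshold = 0.30, min_run = 10L) {
  out <- msa
  if (window > ncol(msa)) return(out)
  for (sp in rownames(msa)) {
    pos <- which(msa[sp, ] %in% AA20)
    k <- length(pos)
    if (k < min_run) next
    div <- vapply(pos, function(j)
      residue_column_identity(msa, sp, j) < identity_threshold, logical(1))
    masked <- logical(k)
    for (a in seq_len(k - min_run + 1L)) {
      if (!div[a]) next
      for (b in (a + min_run - 1L):k) {
        if (!div[b]) next
        starts <- a:(b - window + 1L)
        ok <- all(vapply(starts, function(s)
          sum(div[s:(s + window - 1L)]) >= min_divergent, logical(1)))
        if (ok) masked[a:b] <- TRUE
      }
    }
    out[sp, pos[masked]] <- "X"
  }
  out
}

# Classification oracle, straight from the definitions.
brute_classify <- function(msa, reference, required, min_chars = 10L,
                           min_diff = 3L) {
  vapply(seq_len(ncol(msa)), function(j) {
    chars <- msa[, j]
    real <- setNames(chars %in% AA20, names(chars))
    if (sum(real) < min_chars) return("excluded")
    if (!real[[reference]]) return("excluded")
    if (!all(real[required])) return("excluded")
    others <- chars[setdiff(names(chars), reference)]
    n_diff <- sum(others %in% AA20 & others != chars[[reference]])
    if (n_diff >= min_diff) "fit" else "conserved"
  }, character(1))
}

# GLS oracle: explicit Sigma^-1 normal equations.
brute_gls <- function(y, X, Sigma) {
  Xd <- cbind(1, X)
  Si <- solve(Sigma)
  beta <- solve(t(Xd) %*% Si %*% Xd, t(Xd) %*% Si %*% y)
  r <- y - Xd %*% beta
  n <- length(y)
  p <- ncol(Xd)
  s2 <- drop(t(r) %*% Si %*% r) / (n - p)
  se <- sqrt(diag(s2 * solve(t(Xd) %*% Si %*% Xd)))
  tstat <- drop(beta) / se
  list(beta = drop(beta), se = se, statistic = tstat,
       p.value = 2 * pt(abs(tstat), n - p, lower.tail = FALSE), sigma2 = s2)
}

# Pearson chi-squared goodness-of-fit by an explicit loop.
brute_chisq <- function(observed, reference) {
  expected <- sum(observed) * reference / sum(reference)
  stat <- 0
  for (i in seq_along(observed)) {
    stat <- stat + (observed[i] - expected[i])^2 / expected[i]
  }
  unname(stat)
}
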