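#' Alignment panels
#'
#' An alignment panel is a named list of protein multiple sequence alignments
#' (MSAs), each stored as a character matrix with one row per species and one
#' column per alignment position. Characters are uppercase one-letter amino
#' acid codes, `"-"` for a gap and `"X"` for a masked residue.
#'
#' @param alignments Named list; each element is either a character matrix
#'   (rows named by species) or a named character vector of equal-length
#'   aligned sequences.
#' @return An `aa_panel` object.
#' @export
alignment_panel <- function(alignments) {
  if (is.null(names(alignments)) || anyNA(names(alignments)) ||
      any(names(alignments) == "")) {
    abort("every alignment in a panel must be named")
  }
  alignments <- lapply(alignments, as_msa_matrix)
  for (id in names(alignments)) {
    validate_msa(alignments[[id]], id)
  }
  structure(alignments, class = "aa_panel")
}

as_msa_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  lens <- nchar(x)
  if (length(unique(lens)) > 1L) {
    abort(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                  names(x)[which(lens != lens[1])[1]],
                  lens[which(lens != lens[1])[1]], lens[1]))
  }
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

validate_msa <- function(m, id) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    abort(sprintf("alignment '%s': species ids must be present and unique", id))
  }
  ok <- m %in% c(AA_STANDARD, AA_GAP, AA_MASK)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    pos <- arrayInd(bad, dim(m))
    abort(sprintf(
      "alignment '%s': illegal character '%s' (species '%s', column %d)",
      id, m[bad], rownames(m)[pos[1]], pos[2]))
  }
  invisible(m)
}

#' @export
print.aa_panel <- function(x, ...) {
  cat(sprintf("<aa_panel: %d alignment(s)>\n", length(x)))
  for (id in names(x)) {
    cat(sprintf("  %s: %d species x %d columns\n", id, nrow(x[[id]]), ncol(x[[id]])))
  }
  invisible(x)
}

#' Read a panel of FASTA alignments
#'
#' Reads one FASTA file per alignment. Sequences are uppercased; the
#' ambiguity codes B, Z, J, U and O are converted to the mask character
#' `"X"` with a warning. Ragged alignments, duplicated species and illegal
#' characters are hard errors naming the offending file and sequence.
#'
#' @param paths Character vector of FASTA file paths. Alignment ids default
#'   to the file base names without extension.
#' @param id_pattern Optional regular expression with one capture group used
#'   to extract the species id from each FASTA header. The default takes the
#'   first whitespace-delimited token.
#' @param ids Optional character vector of alignment ids, same length as
#'   `paths`.
#' @return An [alignment_panel()].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">Homo_sapiens ENSP0001", "MKLV", ">Mus_musculus", "MRLV"), fa)
#' read_alignment_panel(fa)
#' @export
read_alignment_panel <- function(paths, id_pattern = NULL, ids = NULL) {
  stopifnot(length(paths) >= 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("alignment file not found: %s", missing[1]))
  }
  ids <- ids %||% sub("\\.[^.]*$", "", basename(paths))
  alns <- lapply(seq_along(paths), function(i) {
    read_fasta_msa(paths[i], id_pattern = id_pattern)
  })
  names(alns) <- ids
  alignment_panel(alns)
}

read_fasta_msa <- function(path, id_pattern = NULL) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("failed to parse FASTA '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("FASTA '%s' contains no sequences", path))
  headers <- names(set)
  species <- if (is.null(id_pattern)) {
    stringr::str_split_i(stringr::str_trim(headers), "\\s+", 1)
  } else {
    stringr::str_match(headers, id_pattern)[, 2]
  }
  if (anyNA(species) || any(species == "")) {
    abort(sprintf("FASTA '%s': could not extract a species id from header '%s'",
                  path, headers[which(is.na(species) | species == "")[1]]))
  }
  if (anyDuplicated(species)) {
    abort(sprintf("FASTA '%s': duplicate species '%s'",
                  path, species[duplicated(species)][1]))
  }
  seqs <- toupper(as.character(set))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- which(lens != lens[1])[1]
    abort(sprintf(
      "ragged alignment in '%s': sequence '%s' has length %d, expected %d",
      path, species[off], lens[off], lens[1]))
  }
  n_ambig <- sum(vapply(AA_AMBIGUOUS, function(a)
    sum(stringr::str_count(seqs, stringr::fixed(a))), numeric(1)))
  if (n_ambig > 0) {
    warn(sprintf("'%s': %d ambiguous residue(s) (B/Z/J/U/O) masked as 'X'",
                 path, n_ambig))
    seqs <- chartr(paste(AA_AMBIGUOUS, collapse = ""),
                   strrep(AA_MASK, length(AA_AMBIGUOUS)), seqs)
  }
  names(seqs) <- species
  m <- as_msa_matrix(seqs)
  validate_msa(m, basename(path))
  m
}

#' Write a panel of alignments as FASTA
#'
#' @param panel An [alignment_panel()].
#' @param dir Output directory; one `<alignment-id>.fa` file per alignment.
#' @return Invisibly, the written file paths.
#' @export
write_alignment_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "aa_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(panel), function(id) {
    m <- panel[[id]]
    lines <- as.vector(rbind(paste0(">", rownames(m)),
                             apply(m, 1, paste, collapse = "")))
    path <- file.path(dir, paste0(id, ".fa"))
    writeLines(lines, path)
    path
  }, character(1))
  invisible(paths)
}

#' Species trait tables
#'
#' A trait table records each species' maximum lifespan (MLS, years) and
#' adult body mass (grams), with one species designated the long-lived
#' reference whose residues define the similarity axis of the scan.
#'
#' @param species,mls_years,mass_g Parallel vectors (or `species` may be a
#'   data frame with those three columns).
#' @param reference Species id of the reference; defaults to the
#'   longest-lived species.
#' @return A `trait_table` tibble with a `reference` attribute.
#' @export
trait_table <- function(species, mls_years = NULL, mass_g = NULL,
                        reference = NULL) {
  if (is.data.frame(species)) {
    df <- as_tibble(species)
  } else {
    df <- tibble(species = as.character(species),
                 mls_years = as.numeric(mls_years),
                 mass_g = as.numeric(mass_g))
  }
  need <- c("species", "mls_years", "mass_g")
  if (!all(need %in% names(df))) {
    abort(sprintf("trait table needs columns: %s", paste(need, collapse = ", ")))
  }
  df <- df[need]
  df$species <- as.character(df$species)
  df$mls_years <- as.numeric(df$mls_years)
  df$mass_g <- as.numeric(df$mass_g)
  if (anyDuplicated(df$species)) abort("duplicate species in trait table")
  if (anyNA(df$mls_years) || any(df$mls_years <= 0)) {
    abort("mls_years must be strictly positive")
  }
  if (anyNA(df$mass_g) || any(df$mass_g <= 0)) {
    abort("mass_g must be strictly positive")
  }
  reference <- reference %||% df$species[which.max(df$mls_years)]
  if (!reference %in% df$species) {
    abort(sprintf("reference species '%s' absent from trait table", reference))
  }
  structure(df, reference = reference,
            class = c("trait_table", class(df)))
}

#' @rdname trait_table
#' @param x A trait table.
#' @export
trait_reference <- function(x) attr(x, "reference")

#' Read a tab-separated trait table
#'
#' Expects columns `species`, `mls_years`, `mass_g`.
#'
#' @inheritParams trait_table
#' @param path File path.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, reference = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    mls_years = readr::col_double(),
    mass_g = readr::col_double()))
  trait_table(df, reference = reference)
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(x, path) {
  stopifnot(inherits(x, "trait_table"))
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Read a phylogenetic tree
#'
#' Reads a rooted newick tree with branch lengths. Time-scaled trees must be
#' ultrametric: all root-to-tip path lengths equal within a relative
#' tolerance of 1e-6.
#'
#' @param path Newick file path.
#' @param kind `"time"` for a time-scaled (ultrametric) tree or `"subst"`
#'   for a substitution-scaled tree.
#' @return An [ape::phylo] object with a `tree_kind` attribute.
#' @export
read_tree <- function(path, kind = c("time", "subst")) {
  kind <- match.arg(kind)
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(sprintf("could not parse newick in '%s'", path))
  validate_tree(tree, kind)
}

#' @rdname read_tree
#' @param tree An `ape::phylo` tree to validate and tag.
#' @export
validate_tree <- function(tree, kind = c("time", "subst")) {
  kind <- match.arg(kind)
  if (!inherits(tree, "phylo")) abort("expected an ape 'phylo' tree")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  if (kind == "time") {
    depths <- tip_depths(tree)
    spread <- diff(range(depths))
    if (spread > 1e-6 * max(depths)) {
      abort(sprintf(
        "time-scaled tree is not ultrametric: root-to-tip spread %.3g over depth %.3g",
        spread, max(depths)))
    }
  }
  attr(tree, "tree_kind") <- kind
  tree
}

# Root-to-tip path length for every tip, named by tip label.
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Substitution score matrices
#'
#' `read_substitution_matrix()` parses a matrix in NCBI flat format (comment
#' lines starting with `#`, a header row of residue letters, one labelled row
#' per residue). `blosum_matrix()` returns a built-in BLOSUM matrix.
#' Asymmetric entries and missing standard residues are hard errors; columns
#' beyond the 20 standard residues (B, Z, X, `*`, ...) are parsed but flagged
#' non-standard.
#'
#' @param path NCBI flat matrix file.
#' @return A `subst_matrix`: an integer score matrix with attributes `name`
#'   and `nonstandard` (the non-standard letters present).
#' @examples
#' m <- blosum_matrix("BLOSUM80")
#' sm_score(m, "H", "Y")  # 2
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) abort(sprintf("'%s' is not an NCBI matrix file", path))
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[`, character(1), 1)
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.integer(r[-1]))
    if (anyNA(v) || length(v) != length(header)) {
      abort(sprintf("malformed matrix row '%s' in '%s'", r[1], path))
    }
    v
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labels, header)
  new_subst_matrix(m, name = basename(path))
}

new_subst_matrix <- function(m, name) {
  missing <- setdiff(AA_STANDARD, intersect(rownames(m), colnames(m)))
  if (length(missing)) {
    abort(sprintf("substitution matrix lacks standard residue(s): %s",
                  paste(missing, collapse = ", ")))
  }
  shared <- intersect(rownames(m), colnames(m))
  sq <- m[shared, shared, drop = FALSE]
  if (!isTRUE(all.equal(sq, t(sq), check.attributes = FALSE))) {
    bad <- which(sq != t(sq), arr.ind = TRUE)[1, ]
    abort(sprintf("asymmetric substitution matrix: (%s,%s) != (%s,%s)",
                  shared[bad[1]], shared[bad[2]], shared[bad[2]], shared[bad[1]]))
  }
  structure(m, name = name,
            nonstandard = setdiff(shared, AA_STANDARD),
            class = c("subst_matrix", class(m)))
}

#' @rdname read_substitution_matrix
#' @param name Matrix name, `"BLOSUM80"` (default) or `"BLOSUM62"`.
#' @export
blosum_matrix <- function(name = c("BLOSUM80", "BLOSUM62")) {
  name <- match.arg(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  new_subst_matrix(e[[name]], name = name)
}

#' @rdname read_substitution_matrix
#' @param m A `subst_matrix`.
#' @param a,b One-letter residue codes.
#' @export
sm_score <- function(m, a, b) {
  if (!all(c(a, b) %in% rownames(m))) {
    abort(sprintf("residue pair (%s,%s) not in matrix '%s'", a, b, attr(m, "name")))
  }
  unname(m[cbind(a, b)])
}

# Attainable score range for a reference residue: min/max over the standard
# 20-residue entries of its row.
sm_row_range <- function(m, ref) {
  if (!ref %in% AA_STANDARD) abort(sprintf("non-standard reference residue '%s'", ref))
  range(m[ref, AA_STANDARD])
}

#' @rdname read_substitution_matrix
#' @export
write_substitution_matrix <- function(m, path) {
  letters <- colnames(m)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste0(sprintf("%-2s", rownames(m)[i]),
           paste(sprintf("%3d", m[i, ]), collapse = ""))
  }, character(1))
  writeLines(c(sprintf("# %s", attr(m, "name") %||% "substitution matrix"),
               paste0("  ", paste(sprintf("%2s", letters), collapse = " ")),
               body), path)
  invisible(path)
}

#' Write and read scan results
#'
#' Writes one tab-separated row per selected column (class `conserved` or
#' `fit`): alignment id, 1-based column index, reference residue, class,
#' number of species fit and the four regression summaries. Values
#' round-trip through `read_scan_results()` to at least 12 significant
#' digits.
#'
#' @param result A [run_scan()] result.
#' @param path Output file.
#' @export
write_scan_results <- function(result, path) {
  stopifnot(inherits(result, "longscan_scan"))
  cols <- dplyr::filter(as_tibble(result), .data$class != "excluded")
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))
  out <- tibble(
    alignment = cols$alignment,
    column = cols$column,
    ref_residue = cols$ref_residue,
    class = cols$class,
    n = cols$n,
    b_mls = fmt(cols$b_mls), p_mls = fmt(cols$p_mls),
    b_mass = fmt(cols$b_mass), p_mass = fmt(cols$p_mass))
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    alignment = readr::col_character(),
    column = readr::col_integer(),
    ref_residue = readr::col_character(),
    class = readr::col_character(),
    n = readr::col_integer(),
    b_mls = readr::col_double(), p_mls = readr::col_double(),
    b_mass = readr::col_double(), p_mass = readr::col_double()))
}

#' Read domain annotations
#'
#' Tab-separated columns `protein`, `start`, `end`, `name`; coordinates are
#' 1-based inclusive residue positions in the ungapped reference sequence.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_domain_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    name = readr::col_character()))
  if (any(df$start < 1L) || any(df$start > df$end)) {
    abort("domain table: need 1 <= start <= end")
  }
  df
}

#' Read a secondary-structure track
#'
#' Tab-separated columns `protein`, `position`, `class` with class one of
#' H (helix), E (strand), C (coil) per ungapped reference residue.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_ss_track <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    protein = readr::col_character(),
    position = readr::col_integer(),
    class = readr::col_character()))
  if (!all(df$class %in% c("H", "E", "C"))) {
    abort("secondary-structure classes must be H, E or C")
  }
  df
}
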