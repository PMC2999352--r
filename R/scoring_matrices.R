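#' Count interface residue pairs over a template library
#'
#' Tallies the four 20x20 contact count tables that the knowledge-based
#' scoring matrices are derived from. Every classed contact pair increments
#' the tables matching its classes: sidechain-sidechain counts are
#' symmetrized (both `[i, j]` and `[j, i]`); sidechain-backbone counts are
#' directional with the sidechain residue indexing rows (an `sb` contact of
#' A's sidechain to B's backbone increments row `resA`, a `bs` contact
#' increments row `resB`). Special tables are incremented only for pairs
#' carrying a special bond. Pairs involving a flagged non-standard residue
#' are skipped.
#'
#' @param library list of `TemplateInterface` with annotated contacts.
#' @return A `PairCountTable`: list of integer matrices `ss_vdw`, `sb_vdw`,
#'   `ss_special`, `sb_special` (20x20, rows/cols in the standard residue
#'   order) plus `n_pairs`, the number of contact pairs tallied.
#' @export
count_pairs <- function(library) {
  if (length(library) == 0L) stop("empty template library")
  zero <- matrix(0L, 20, 20, dimnames = list(AA1, AA1))
  tab <- list(ss_vdw = zero, sb_vdw = zero, ss_special = zero, sb_special = zero)
  n <- 0L
  for (t in library) {
    cp <- t$contact_pairs
    for (k in seq_len(nrow(cp))) {
      i <- cp$resA[k]; j <- cp$resB[k]
      if (is.na(i) || is.na(j)) next
      n <- n + 1L
      sp <- cp$special_bond[k] != "none"
      if (cp$ss[k]) {
        tab$ss_vdw[i, j] <- tab$ss_vdw[i, j] + 1L
        tab$ss_vdw[j, i] <- tab$ss_vdw[j, i] + 1L
        if (sp) {
          tab$ss_special[i, j] <- tab$ss_special[i, j] + 1L
          tab$ss_special[j, i] <- tab$ss_special[j, i] + 1L
        }
      }
      if (cp$sb[k]) {
        tab$sb_vdw[i, j] <- tab$sb_vdw[i, j] + 1L
        if (sp) tab$sb_special[i, j] <- tab$sb_special[i, j] + 1L
      }
      if (cp$bs[k]) {
        tab$sb_vdw[j, i] <- tab$sb_vdw[j, i] + 1L
        if (sp) tab$sb_special[j, i] <- tab$sb_special[j, i] + 1L
      }
    }
  }
  structure(c(tab, list(n_pairs = n)), class = "PairCountTable")
}

#' Derive a log-odds contact scoring matrix
#'
#' Computes \eqn{S_{ij} = \ln(q_{ij} / e_{ij})} where \eqn{q_{ij}} is the
#' observed pair probability (counts plus `pseudocount` per cell, normalised
#' over the full 20x20 table) and \eqn{e_{ij} = p_i p_j} the expected
#' probability from the table's own interface marginals
#' \eqn{p_i = \sum_j q_{ij}}. For special-bond classes, cells with zero raw
#' count are reset to 0 after derivation, encoding that chemically
#' impossible bond pairs carry no special-bond energy.
#'
#' @param tab A `PairCountTable` (or any named list of count matrices).
#' @param class One of "ss_vdw", "sb_vdw", "ss_special", "sb_special".
#' @param pseudocount Added to every cell before normalisation.
#' @return A `PairScoringMatrix`: list with `scores` (20x20), `class`,
#'   `symmetric`, `pseudocount`.
#' @export
derive_matrix <- function(tab, class = c("ss_vdw", "sb_vdw", "ss_special", "sb_special"),
                          pseudocount = 0.5) {
  class <- match.arg(class)
  counts <- tab[[class]]
  if (sum(counts) == 0 && pseudocount == 0) stop("all-zero count table for class ", class)
  q <- (counts + pseudocount) / sum(counts + pseudocount)
  p <- rowSums(q)
  e <- outer(p, colSums(q))
  scores <- log(q / e)
  if (grepl("special", class)) scores[counts == 0] <- 0
  structure(list(scores = scores, class = class,
                 symmetric = grepl("^ss", class), pseudocount = pseudocount),
            class = "PairScoringMatrix")
}

#' Derive the full matrix set from a training library
#'
#' Convenience wrapper: counts pairs over `library` and derives the four
#' contact scoring matrices plus the interface residue background (marginal
#' frequencies of the sidechain-sidechain table), which the randomized-
#' interface null model draws substitute residues from.
#'
#' @param library list of annotated `TemplateInterface`.
#' @param pseudocount Per-cell pseudocount for the van der Waals classes;
#'   special classes are derived with the same pseudocount and then zeroed
#'   on raw-zero cells.
#' @return A `MatrixSet`: list with `ss_vdw`, `sb_vdw`, `ss_special`,
#'   `sb_special` (each a `PairScoringMatrix`), `background` (named
#'   20-vector summing to 1) and `counts` (the `PairCountTable`).
#' @export
derive_matrix_set <- function(library, pseudocount = 0.5) {
  tab <- count_pairs(library)
  ms <- lapply(c(ss_vdw = "ss_vdw", sb_vdw = "sb_vdw",
                 ss_special = "ss_special", sb_special = "sb_special"),
               function(cl) derive_matrix(tab, cl, pseudocount))
  q <- (tab$ss_vdw + pseudocount) / sum(tab$ss_vdw + pseudocount)
  structure(c(ms, list(background = rowSums(q), counts = tab)),
            class = "MatrixSet")
}

#' Load a substitution matrix
#'
#' Returns BLOSUM62 (the packaged default, from Biostrings) or parses a
#' matrix in the NCBI text layout (header row of residue codes, one labelled
#' row per residue).
#'
#' @param name "BLOSUM62" for the packaged default, otherwise a path to an
#'   NCBI-format matrix file.
#' @return A `SubstitutionMatrix`: numeric matrix restricted to the 20
#'   standard residues, with symmetric entries and strictly positive
#'   diagonal.
#' @export
load_substitution_matrix <- function(name = "BLOSUM62") {
  if (identical(toupper(name), "BLOSUM62") && !file.exists(name)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    m <- get("BLOSUM62", envir = environment())
  } else {
    lines <- readLines(name)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
    rlab <- vapply(rows, `[`, "", 1)
    vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1])))
    if (any(vapply(vals, anyNA, TRUE)) ||
        any(vapply(vals, length, 1L) != length(header)))
      stop("malformed substitution matrix file: ", name)
    m <- do.call(rbind, vals)
    dimnames(m) <- list(rlab, header)
    bad <- setdiff(rlab, c(AA1, "B", "Z", "X", "*", "J", "U", "O"))
    if (length(bad)) stop("unknown residue code(s) in matrix file: ",
                          paste(bad, collapse = ", "))
  }
  m <- m[AA1, AA1]
  structure(m, class = c("SubstitutionMatrix", "matrix"))
}
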