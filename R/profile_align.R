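# Conditional substitution probabilities P(x | y) implied by BLOSUM62 in
# half-bit units: P(x|y) proportional to p_x * 2^(S_xy / 2), column-normalised.
.blosum_conditional <- function() {
  b <- load_substitution_matrix("BLOSUM62")
  g <- BLOSUM62_BACKGROUND * 2^(b / 2)
  sweep(g, 2, colSums(g), "/")
}

# Henikoff position-based sequence weights for a gapped MSA (rows =
# sequences). Gap characters get no vote; weights normalised to sum 1.
.henikoff_weights <- function(rows) {
  n <- length(rows)
  if (n == 1L) return(1)
  mat <- do.call(rbind, strsplit(rows, ""))
  w <- numeric(n)
  for (p in seq_len(ncol(mat))) {
    col <- mat[, p]
    res <- col[col != "-"]
    if (length(res) == 0L) next
    types <- table(res)
    r <- length(types)
    contrib <- ifelse(col == "-", 0, 1 / (r * as.numeric(types[col])))
    contrib[is.na(contrib)] <- 0
    w <- w + contrib
  }
  if (sum(w) == 0) w <- rep(1, n)
  w / sum(w)
}

#' Build a position-specific scoring profile from a star MSA
#'
#' The first MSA row is the template chain; columns where the template has a
#' gap are dropped so the profile has one score vector per template
#' position. Scores are half-bit log-odds of Henikoff-weighted column
#' frequencies mixed with BLOSUM62-conditional pseudocounts against the
#' BLOSUM62 background: with per-column mixing weight
#' \eqn{\alpha_p = (\mathrm{distinct\ residues\ in\ column}) - 1} and
#' \eqn{\beta = 10},
#' \eqn{M_{xp} = 2\log_2\big((\alpha_p f_{xp} + \beta g_{xp}) /
#' (\alpha_p+\beta) / p_x\big)}. A single-sequence MSA has \eqn{\alpha = 0}
#' and degenerates to (approximately) the BLOSUM62 row of the template
#' residue at each position.
#'
#' @param msa Character vector of equal-length gapped sequences, template
#'   first.
#' @param beta Pseudocount weight.
#' @param chain Chain identifier recorded in the profile.
#' @return A `ChainProfile`: list with `chain`, `length`, `template_seq`,
#'   `M` (20 x length matrix, rows in standard residue order), `source`.
#' @export
build_profile <- function(msa, beta = 10, chain = "A") {
  if (length(msa) < 1L) stop("empty MSA")
  if (length(unique(nchar(msa))) != 1L) stop("MSA rows have unequal lengths")
  tpl_cols <- strsplit(msa[1], "")[[1]] != "-"
  mat <- do.call(rbind, strsplit(msa, ""))[, tpl_cols, drop = FALSE]
  template_seq <- paste(mat[1, ], collapse = "")
  L <- ncol(mat)
  w <- .henikoff_weights(msa)
  cond <- .blosum_conditional()
  M <- matrix(0, 20, L, dimnames = list(AA1, NULL))
  for (p in seq_len(L)) {
    col <- mat[, p]
    ok <- col %in% AA1
    f <- numeric(20); names(f) <- AA1
    if (any(ok)) {
      fw <- tapply(w[ok], factor(col[ok], levels = AA1), sum)
      fw[is.na(fw)] <- 0
      f <- fw / sum(fw)
    }
    g <- as.vector(cond[, AA1] %*% f)   # pseudocount distribution
    alpha <- max(length(unique(col[ok])) - 1L, 0L)
    P <- (alpha * f + beta * g) / (alpha + beta)
    M[, p] <- 2 * log2(pmax(P, 1e-12) / BLOSUM62_BACKGROUND)
  }
  structure(list(chain = chain, length = L, template_seq = template_seq,
                 M = M, source = "in-house"), class = "ChainProfile")
}

#' Import a PSI-BLAST ASCII PSSM
#'
#' Parses the standard PSI-BLAST ASCII PSSM layout (`-out_ascii_pssm`),
#' preserving the integer log-odds scores exactly. Only the first 20 score
#' columns (the PSSM proper) are read; positions are 1-based. Lowercase
#' residue letters are accepted and uppercased.
#'
#' @param text PSSM file content as a single string, a character vector of
#'   lines, or a file path.
#' @return A `ChainProfile` with `source = "imported"`.
#' @export
import_pssm <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text)
           else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D\\s+C", lines)
  if (length(hdr) == 0L) stop("PSSM parse error: residue header row not found")
  order20 <- strsplit(trimws(lines[hdr[1]]), "\\s+")[[1]][1:20]
  body <- grep("^\\s*\\d+\\s+[A-Za-z]\\s+-?\\d", lines, value = TRUE)
  if (length(body) == 0L) stop("PSSM parse error: no position rows")
  rows <- strsplit(trimws(body), "\\s+")
  if (any(vapply(rows, length, 1L) < 22L))
    stop("PSSM parse error: ragged row (fewer than 20 score columns)")
  pos <- as.integer(vapply(rows, `[`, "", 1))
  if (!identical(pos, seq_along(pos)))
    stop("PSSM parse error: positions not consecutive from 1")
  res <- toupper(vapply(rows, `[`, "", 2))
  sc <- vapply(rows, function(r) as.numeric(r[3:22]), numeric(20))
  if (anyNA(sc)) stop("PSSM parse error: non-numeric score")
  rownames(sc) <- toupper(order20)
  structure(list(chain = "imported", length = length(pos),
                 template_seq = paste(res, collapse = ""),
                 M = sc[AA1, , drop = FALSE], source = "imported"),
            class = "ChainProfile")
}

# profile column scores for one candidate residue letter; unknown letters
# (X etc.) get a flat mild penalty
.profile_col <- function(p, letter) {
  if (letter %in% AA1) p$M[letter, ] else rep(-4, p$length)
}

#' Align a candidate sequence to a chain profile
#'
#' Smith-Waterman local alignment of a sequence against the profile scores,
#' with affine gap penalties (a gap of length k costs
#' `gap_open + k * gap_extend`, the BLAST 11/1 convention). Traceback is
#' deterministic: the highest-scoring cell (first in row-major order on
#' ties) is the endpoint, and ties among moves resolve diagonal, then up
#' (template consumed), then left.
#'
#' @param p A `ChainProfile`.
#' @param seq Candidate amino-acid string.
#' @param gap_open,gap_extend Gap penalties.
#' @param id,species Candidate identifiers carried into the result.
#' @return A `ChainAlignment`: list with `chain`, `id`, `species`, `map`
#'   (integer vector over template positions; candidate index or NA),
#'   `cand_seq`, `identity` (over aligned columns), `score`, and `CR`
#'   (NA until [contact_ratio()] is applied).
#' @export
align_profile <- function(p, seq, gap_open = 11, gap_extend = 1,
                          id = "candidate", species = NA_character_) {
  if (!nzchar(seq)) stop("empty candidate sequence")
  L <- p$length
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  colsc <- vapply(s, function(x) .profile_col(p, x), numeric(L))  # L x n
  NEG <- -1e18
  H <- matrix(0, L + 1L, n + 1L)
  E <- matrix(NEG, L + 1L, n + 1L)  # gap in candidate (moving down rows)
  F_ <- matrix(NEG, L + 1L, n + 1L) # gap in template (moving right)
  open <- gap_open + gap_extend
  for (i in seq_len(L)) {
    for (j in seq_len(n)) {
      E[i + 1L, j + 1L] <- max(H[i, j + 1L] - open, E[i, j + 1L] - gap_extend)
      F_[i + 1L, j + 1L] <- max(H[i + 1L, j] - open, F_[i + 1L, j] - gap_extend)
      H[i + 1L, j + 1L] <- max(0, H[i, j] + colsc[i, j],
                               E[i + 1L, j + 1L], F_[i + 1L, j + 1L])
    }
  }
  best <- which(t(H) == max(H))[1]   # row-major order: first best cell
  bi <- (best - 1L) %/% (n + 1L) + 1L
  bj <- best - (bi - 1L) * (n + 1L)
  i <- bi - 1L; j <- bj - 1L
  map <- rep(NA_integer_, L)
  state <- "H"
  while (i > 0L && j > 0L) {
    if (state == "H") {
      h <- H[i + 1L, j + 1L]
      if (h == 0) break
      if (h == H[i, j] + colsc[i, j]) { map[i] <- j; i <- i - 1L; j <- j - 1L }
      else if (h == E[i + 1L, j + 1L]) state <- "E"
      else state <- "F"
    } else if (state == "E") {
      if (E[i + 1L, j + 1L] == H[i, j + 1L] - open) state <- "H"
      i <- i - 1L
    } else {
      if (F_[i + 1L, j + 1L] == H[i + 1L, j] - open) state <- "H"
      j <- j - 1L
    }
  }
  tpl <- strsplit(p$template_seq, "")[[1]]
  aligned <- which(!is.na(map))
  identity <- if (length(aligned)) mean(tpl[aligned] == s[map[aligned]]) else 0
  structure(list(chain = p$chain, id = id, species = species, map = map,
                 cand_seq = seq, identity = identity, score = max(H),
                 CR = NA_real_), class = "ChainAlignment")
}

#' Identity self-alignment of a template chain
#'
#' The alignment of a template chain to itself (identity mapping), the fixed
#' point used by self-consistency checks and the randomized-interface null
#' model.
#'
#' @param t A `TemplateInterface`.
#' @param chain "A" or "B".
#' @return A `ChainAlignment` with identity 1 and a complete map.
#' @export
self_alignment <- function(t, chain = c("A", "B")) {
  chain <- match.arg(chain)
  seq <- if (chain == "A") t$chainA_seq else t$chainB_seq
  structure(list(chain = chain, id = paste0(t$template_id, "_", chain),
                 species = "template", map = seq_len(nchar(seq)),
                 cand_seq = seq, identity = 1, score = NA_real_, CR = 1),
            class = "ChainAlignment")
}

#' Aligned contact residue ratio (CR)
#'
#' Fraction of a template chain's contact residues aligned to a non-gap
#' candidate residue.
#'
#' @param a A `ChainAlignment`.
#' @param contact_positions Integer set of template contact positions.
#' @return The CR fraction in [0, 1].
#' @export
contact_ratio <- function(a, contact_positions) {
  if (length(contact_positions) == 0L) stop("empty contact-position set")
  mean(!is.na(a$map[contact_positions]))
}

#' Candidate filter on identity and contact coverage
#'
#' A candidate pair survives only when sequence identity exceeds
#' `min_identity` and the aligned contact residue ratio exceeds `min_cr` on
#' BOTH chain alignments — strict inequalities on both thresholds.
#'
#' @param aA,aB `ChainAlignment`s for chains A and B, with `CR` set (see
#'   [contact_ratio()]).
#' @param min_identity,min_cr Strict lower thresholds.
#' @return list(pass = logical, reasons = character vector).
#' @export
candidate_filter <- function(aA, aB, min_identity = 0.30, min_cr = 0.5) {
  if (is.na(aA$CR) || is.na(aB$CR))
    stop("alignments must carry CR; apply contact_ratio() first")
  reasons <- character()
  if (aA$identity <= min_identity)
    reasons <- c(reasons, sprintf("chain A identity %.3f not above %.2f", aA$identity, min_identity))
  if (aB$identity <= min_identity)
    reasons <- c(reasons, sprintf("chain B identity %.3f not above %.2f", aB$identity, min_identity))
  if (aA$CR <= min_cr)
    reasons <- c(reasons, sprintf("chain A CR %.3f not above %.2f", aA$CR, min_cr))
  if (aB$CR <= min_cr)
    reasons <- c(reasons, sprintf("chain B CR %.3f not above %.2f", aB$CR, min_cr))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' Converts a local alignment raw score into an expect value
#' \eqn{E = K m n e^{-\lambda S}} with the gapped BLOSUM62 (11/1) constants,
#' the statistic used to gather homolog families (threshold 1e-10 by
#' default elsewhere in the pipeline).
#'
#' @param score Raw alignment score.
#' @param m,n Lengths of the two sequences (profile length and candidate
#'   length).
#' @param lambda,K Karlin-Altschul parameters.
#' @return The E-value.
#' @export
alignment_evalue <- function(score, m, n, lambda = KA_LAMBDA_GAPPED, K = KA_K_GAPPED) {
  K * m * n * exp(-lambda * score)
}

#' Read a FASTA database with species-annotated headers
#'
#' Headers follow `>ID|SPECIES` by default; the pattern is a regex with two
#' capture groups (id, species).
#'
#' @param path FASTA file.
#' @param header_regex Regex with two capture groups applied to the header.
#' @return data.frame with `id`, `species`, `seq`.
#' @export
read_species_fasta <- function(path, header_regex = "^([^|]+)\\|(.+)$") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  hdr <- names(ss)
  m <- regmatches(hdr, regexec(header_regex, hdr))
  id <- vapply(seq_along(m), function(i) if (length(m[[i]]) >= 2) m[[i]][2] else hdr[i], "")
  sp <- vapply(seq_along(m), function(i) if (length(m[[i]]) >= 3) m[[i]][3] else NA_character_, "")
  data.frame(id = id, species = sp, seq = as.character(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}
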