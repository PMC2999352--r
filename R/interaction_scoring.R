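# Precomputed per-contact-pair context for fast repeated scoring: integer
# residue codes of the template pair, class flags, special-bond flag and the
# BLOSUM diagonal denominator shared by the similarity and conservation
# terms. Pairs with a flagged (non-standard) template residue are dropped
# from scoring.
.pair_context <- function(t, matrices, profiles = NULL, blosum = NULL) {
  cp <- t$contact_pairs
  iA <- match(cp$resA, AA1)
  iB <- match(cp$resB, AA1)
  ok <- !is.na(iA) & !is.na(iB)
  blosum <- blosum %||% load_substitution_matrix("BLOSUM62")
  diagK <- diag(unclass(blosum))
  list(posA = cp$posA[ok], posB = cp$posB[ok],
       iA = iA[ok], iB = iB[ok],
       ss = cp$ss[ok], sb = cp$sb[ok], bs = cp$bs[ok],
       special = cp$special_bond[ok] != "none",
       denom = diagK[iA[ok]] + diagK[iB[ok]],
       blosum = unclass(blosum),
       MA = if (!is.null(profiles)) profiles$A$M else NULL,
       MB = if (!is.null(profiles)) profiles$B$M else NULL,
       m = matrices, CP = sum(ok))
}

# sum of matrix lookups at candidate residue codes, NA (gap) contributes 0
.lookup_sum <- function(mat, rows, cols, sel = TRUE) {
  rows <- rows[sel]; cols <- cols[sel]
  v <- !is.na(rows) & !is.na(cols)
  if (!any(v)) return(0)
  sum(mat[cbind(rows[v], cols[v])])
}

# Four-term energy for candidate residue codes jA/jB (integer 1..20 or NA at
# each template position of chains A and B).
.score_letters <- function(ctx, jA, jB, w = 3, normalize = c("sum", "mean")) {
  normalize <- match.arg(normalize)
  cA <- jA[ctx$posA]          # candidate residue aligned to each pair's A position
  cB <- jB[ctx$posB]
  m <- ctx$m
  e_vdw <- .lookup_sum(m$ss_vdw$scores, cA, cB, ctx$ss) +
    .lookup_sum(m$sb_vdw$scores, cA, cB, ctx$sb) +
    .lookup_sum(m$sb_vdw$scores, cB, cA, ctx$bs)
  e_sf <- .lookup_sum(m$ss_special$scores, cA, cB, ctx$ss & ctx$special) +
    .lookup_sum(m$sb_special$scores, cA, cB, ctx$sb & ctx$special) +
    .lookup_sum(m$sb_special$scores, cB, cA, ctx$bs & ctx$special)
  kA <- ifelse(is.na(cA), 0, ctx$blosum[cbind(ctx$iA, cA)])
  kB <- ifelse(is.na(cB), 0, ctx$blosum[cbind(ctx$iB, cB)])
  e_sim <- sum((kA + kB) / ctx$denom)
  e_cons <- 0
  if (!is.null(ctx$MA)) {
    mA <- ifelse(is.na(cA), 0, ctx$MA[cbind(cA, ctx$posA)])
    mB <- ifelse(is.na(cB), 0, ctx$MB[cbind(cB, ctx$posB)])
    e_cons <- sum((mA + mB) / ctx$denom)
  }
  if (normalize == "mean" && ctx$CP > 0) {
    e_sim <- e_sim / ctx$CP
    e_cons <- e_cons / ctx$CP
  }
  total_score(e_vdw, e_sf, e_sim, e_cons, w = w)
}

# candidate residue codes over template positions implied by an alignment
.aligned_codes <- function(a, chain_len) {
  s <- strsplit(a$cand_seq, "")[[1]]
  codes <- rep(NA_integer_, chain_len)
  ok <- !is.na(a$map)
  codes[ok] <- match(s[a$map[ok]], AA1)
  codes
}

.codes_for <- function(t, aA, aB) {
  list(A = .aligned_codes(aA, nchar(t$chainA_seq)),
       B = .aligned_codes(aB, nchar(t$chainB_seq)))
}

#' Van der Waals interface energy of a candidate pair
#'
#' Sum over the template's contact pairs of the sidechain-sidechain and
#' sidechain-backbone van der Waals matrix entries looked up at the
#' candidate residues aligned to the pair's positions, restricted to each
#' pair's contact classes. A pair with either position unaligned (gap)
#' contributes 0.
#'
#' @param t A `TemplateInterface`.
#' @param aA,aB `ChainAlignment`s of the candidate proteins to chains A, B.
#' @param m A `MatrixSet` (see [derive_matrix_set()]).
#' @return The E_vdw score.
#' @export
score_vdw <- function(t, aA, aB, m) {
  if (is.null(m$ss_vdw) || is.null(m$sb_vdw)) stop("matrix set missing vdW class")
  ctx <- .pair_context(t, m)
  cc <- .codes_for(t, aA, aB)
  .score_letters(ctx, cc$A, cc$B, w = 0)$E_vdw
}

#' Special-bond interface energy of a candidate pair
#'
#' As [score_vdw()], but summing the special-bond (T) matrices only over
#' contact pairs that form a special bond (hydrogen bond, salt bridge or
#' disulfide) in the template structure.
#'
#' @inheritParams score_vdw
#' @return The E_SF score.
#' @export
score_special <- function(t, aA, aB, m) {
  if (is.null(m$ss_special) || is.null(m$sb_special)) stop("matrix set missing special class")
  ctx <- .pair_context(t, m)
  cc <- .codes_for(t, aA, aB)
  .score_letters(ctx, cc$A, cc$B, w = 0)$E_SF
}

#' Template-interface similarity score
#'
#' \deqn{E_{sim} = \sum_{(i,j)\in CP} \frac{K_{ii'} + K_{jj'}}{K_{ii}+K_{jj}}}
#' over the template contact pairs, where i', j' are the candidate residues
#' aligned to the template residues i, j and K is BLOSUM62. A gapped
#' position contributes 0 to its K term; because BLOSUM62 diagonals dominate
#' their rows, the self-alignment yields exactly 1 per pair, hence
#' E_sim = CP.
#'
#' @inheritParams score_vdw
#' @param blosum A `SubstitutionMatrix`.
#' @param normalize "sum" (default) or "mean" (divide by CP).
#' @return The E_sim score.
#' @export
score_sim <- function(t, aA, aB, blosum = load_substitution_matrix("BLOSUM62"),
                      normalize = "sum") {
  ctx <- .pair_context(t, matrices = NULL, blosum = blosum)
  cc <- .codes_for(t, aA, aB)
  ctx$m <- .zero_matrix_set()
  .score_letters(ctx, cc$A, cc$B, w = 0, normalize = normalize)$E_sim
}

#' Couple-conserved residue score
#'
#' \deqn{E_{cons} = \sum_{(i,j)\in CP} \frac{M_{i'p} + M_{j'p'}}{K_{ii}+K_{jj}}}
#' where M are the two template chain profiles evaluated at the candidate
#' residues i', j' aligned to template positions p, p'. Gaps contribute 0 to
#' their M term.
#'
#' @inheritParams score_sim
#' @param pA,pB `ChainProfile`s for template chains A and B.
#' @return The E_cons score.
#' @export
score_cons <- function(pA, pB, t, aA, aB,
                       blosum = load_substitution_matrix("BLOSUM62"),
                       normalize = "sum") {
  if (pA$length != nchar(t$chainA_seq) || pB$length != nchar(t$chainB_seq))
    stop("profile length does not match template chain length")
  ctx <- .pair_context(t, matrices = NULL, profiles = list(A = pA, B = pB),
                       blosum = blosum)
  cc <- .codes_for(t, aA, aB)
  ctx$m <- .zero_matrix_set()
  .score_letters(ctx, cc$A, cc$B, w = 1, normalize = normalize)$E_cons
}

.zero_matrix_set <- function() {
  z <- list(scores = matrix(0, 20, 20, dimnames = list(AA1, AA1)))
  list(ss_vdw = z, sb_vdw = z, ss_special = z, sb_special = z)
}

#' Combine the four energy terms
#'
#' \deqn{E_{tot} = E_{vdw} + E_{SF} + E_{sim} + w\,E_{cons}} with weight
#' `w = 3` by default.
#'
#' @param E_vdw,E_SF,E_sim,E_cons The four term values.
#' @param w Weight on the couple-conserved term.
#' @return An `EnergyBreakdown` list with the four terms, `w` and `E_tot`.
#' @export
total_score <- function(E_vdw, E_SF, E_sim, E_cons, w = 3) {
  structure(list(E_vdw = E_vdw, E_SF = E_SF, E_sim = E_sim, E_cons = E_cons,
                 w = w, E_tot = E_vdw + E_SF + E_sim + w * E_cons),
            class = "EnergyBreakdown")
}

#' Score a candidate pair with all four terms
#'
#' Convenience wrapper computing the full `EnergyBreakdown` for a candidate
#' pair on one template.
#'
#' @inheritParams score_vdw
#' @param profiles list(A =, B =) of `ChainProfile`s.
#' @param blosum A `SubstitutionMatrix`.
#' @param w Weight on E_cons.
#' @param normalize Normalisation of E_sim/E_cons ("sum" or "mean").
#' @return An `EnergyBreakdown`.
#' @export
score_candidate <- function(t, aA, aB, m, profiles,
                            blosum = load_substitution_matrix("BLOSUM62"),
                            w = 3, normalize = "sum") {
  ctx <- .pair_context(t, m, profiles, blosum)
  cc <- .codes_for(t, aA, aB)
  .score_letters(ctx, cc$A, cc$B, w = w, normalize = normalize)
}

#' Randomized-interface null model for one template
#'
#' Generates `n` randomized interfaces by mutating a fixed fraction
#' (default 60%) of the template's contact residues, pooled across both
#' chains: each sample draws `ceiling(fraction * n_contact_residues)`
#' positions uniformly without replacement and substitutes each wild-type
#' residue with a different residue drawn from the interface background
#' distribution. Each randomized interface is scored as a candidate with
#' the full four-term E_tot; the sample mean and standard deviation define
#' the normal null used by [z_value()].
#'
#' @inheritParams score_candidate
#' @param background Named 20-vector of residue probabilities (defaults to
#'   the matrix set's interface background).
#' @param n Number of randomized interfaces.
#' @param fraction Fraction of pooled contact residues mutated per sample.
#' @param seed Integer seed; the model is fully reproducible from it.
#' @param keep_samples Keep the per-sample scores (for diagnostics).
#' @return A `NullModel`: list with `template_id`, `n_samples`,
#'   `mutation_fraction`, `mean`, `sd`, `seed` and optionally `samples`.
#' @export
build_null_model <- function(t, m, profiles,
                             blosum = load_substitution_matrix("BLOSUM62"),
                             background = NULL, n = 10000, fraction = 0.6,
                             seed = 1L, w = 3, normalize = "sum",
                             keep_samples = FALSE) {
  background <- background %||% m$background
  if (is.null(background)) stop("no background distribution available")
  bg <- background[AA1]; bg <- bg / sum(bg)
  ctx <- .pair_context(t, m, profiles, blosum)
  jA0 <- match(strsplit(t$chainA_seq, "")[[1]], AA1)
  jB0 <- match(strsplit(t$chainB_seq, "")[[1]], AA1)
  pooled <- rbind(
    data.frame(chain = "A", pos = t$contact_residues_A),
    data.frame(chain = "B", pos = t$contact_residues_B))
  k <- ceiling(fraction * nrow(pooled))
  scores <- numeric(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  for (s in seq_len(n)) {
    jA <- jA0; jB <- jB0
    if (k > 0) {
      sel <- sample.int(nrow(pooled), k)
      for (r in sel) {
        pos <- pooled$pos[r]
        if (pooled$chain[r] == "A") {
          wt <- jA[pos]
          p <- bg; if (!is.na(wt)) p[wt] <- 0
          jA[pos] <- sample.int(20, 1, prob = p / sum(p))
        } else {
          wt <- jB[pos]
          p <- bg; if (!is.na(wt)) p[wt] <- 0
          jB[pos] <- sample.int(20, 1, prob = p / sum(p))
        }
      }
    }
    scores[s] <- .score_letters(ctx, jA, jB, w = w, normalize = normalize)$E_tot
  }
  mu <- mean(scores); sdev <- sd(scores)
  if (!is.finite(sdev) || sdev == 0)
    stop(structure(class = c("degenerate_null_model", "error", "condition"),
                   list(message = sprintf("degenerate null model for template %s (sd = 0)",
                                          t$template_id), call = sys.call())))
  structure(list(template_id = t$template_id, n_samples = n,
                 mutation_fraction = fraction, mean = mu, sd = sdev,
                 seed = seed, samples = if (keep_samples) scores else NULL),
            class = "NullModel")
}

#' Z-value of an interface score under a template's null model
#'
#' @param score An E_tot value.
#' @param nm A `NullModel`.
#' @return `(score - mean) / sd`.
#' @export
z_value <- function(score, nm) {
  if (!is.finite(nm$sd) || nm$sd == 0) stop("degenerate null model: sd is zero")
  (score - nm$mean) / nm$sd
}

#' Per-residue binding contribution (computational alanine scan)
#'
#' The contribution of a contact residue is the drop in total energy when
#' that residue is computationally mutated to alanine in the template's
#' self-alignment, with all four terms recomputed:
#' `E_tot(self) - E_tot(self -> Ala at position)`. Intended to correlate
#' with experimental alanine-scanning ddG values.
#'
#' @inheritParams score_candidate
#' @param chain "A" or "B".
#' @param position Template position (must be a contact residue).
#' @return An `AlaScanRecord`: list with `template_id`, `chain`, `position`,
#'   `wildtype` and `contribution`.
#' @export
residue_contribution <- function(t, chain, position, m, profiles,
                                 blosum = load_substitution_matrix("BLOSUM62"),
                                 w = 3, normalize = "sum") {
  contacts <- if (chain == "A") t$contact_residues_A else t$contact_residues_B
  if (!position %in% contacts)
    stop("position ", position, " is not a contact residue of chain ", chain)
  ctx <- .pair_context(t, m, profiles, blosum)
  jA <- match(strsplit(t$chainA_seq, "")[[1]], AA1)
  jB <- match(strsplit(t$chainB_seq, "")[[1]], AA1)
  self <- .score_letters(ctx, jA, jB, w = w, normalize = normalize)$E_tot
  ala <- match("A", AA1)
  wt <- if (chain == "A") substr(t$chainA_seq, position, position)
        else substr(t$chainB_seq, position, position)
  if (chain == "A") jA[position] <- ala else jB[position] <- ala
  mut <- .score_letters(ctx, jA, jB, w = w, normalize = normalize)$E_tot
  structure(list(template_id = t$template_id, chain = chain,
                 position = position, wildtype = wt,
                 contribution = self - mut), class = "AlaScanRecord")
}

#' Evaluate predicted contributions against an alanine-scan table
#'
#' Reads ASEdb-style records (template, chain, position, ddG), computes the
#' model contribution for each and reports the Pearson correlation.
#'
#' @inheritParams residue_contribution
#' @param scan data.frame with columns `chain`, `position`, `ddG` (a TSV
#'   path is also accepted).
#' @return list with the merged `table` (adds `contribution`) and
#'   `pearson_r`.
#' @export
evaluate_alascan <- function(t, m, profiles, scan,
                             blosum = load_substitution_matrix("BLOSUM62"),
                             w = 3) {
  if (is.character(scan))
    scan <- read.table(scan, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  scan$contribution <- vapply(seq_len(nrow(scan)), function(i) {
    residue_contribution(t, scan$chain[i], scan$position[i], m, profiles,
                         blosum, w)$contribution
  }, 0)
  list(table = scan, pearson_r = cor(scan$contribution, scan$ddG))
}
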