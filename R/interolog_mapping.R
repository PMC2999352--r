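#' Enumerate and score interaction candidates for one template
#'
#' Implements 3D-domain interolog mapping for a single template: every
#' database sequence is aligned to each chain profile; sequences whose
#' alignment E-value is at most `evalue_max` form the homolog families A'
#' and B'. All same-species pairs in A' x B' are candidate interactions
#' (a protein paired with itself is allowed only when it matches both
#' chains); each candidate must pass the identity/CR filter on both
#' alignments, and survivors are scored with the four-term energy and the
#' template's null model.
#'
#' @param t A `TemplateInterface`.
#' @param db data.frame from [read_species_fasta()] (`id`, `species`, `seq`).
#' @param profiles list(A =, B =) of `ChainProfile`s.
#' @param m A `MatrixSet`.
#' @param nm A `NullModel` for the template (built if NULL).
#' @param blosum A `SubstitutionMatrix`.
#' @param config Threshold list, see [default_config()].
#' @return data.frame of unranked `ScoredCandidate` rows: ids, species,
#'   identities, CRs, the four energy terms, `E_tot` and `Z`.
#' @export
enumerate_candidates <- function(t, db, profiles, m, nm = NULL,
                                 blosum = load_substitution_matrix("BLOSUM62"),
                                 config = default_config()) {
  if (is.null(nm))
    nm <- build_null_model(t, m, profiles, blosum,
                           n = config$null_n, fraction = config$null_fraction,
                           seed = config$seed, w = config$w,
                           normalize = config$normalize)
  scan_chain <- function(p, contacts) {
    res <- lapply(seq_len(nrow(db)), function(i) {
      a <- align_profile(p, db$seq[i], config$gap_open, config$gap_extend,
                         id = db$id[i], species = db$species[i])
      a$CR <- contact_ratio(a, contacts)
      a$evalue <- alignment_evalue(a$score, p$length, nchar(db$seq[i]))
      a
    })
    res[vapply(res, function(a) a$evalue <= config$evalue_max, TRUE)]
  }
  famA <- scan_chain(profiles$A, t$contact_residues_A)
  famB <- scan_chain(profiles$B, t$contact_residues_B)
  if (length(famA) == 0L || length(famB) == 0L) {
    message("empty homolog family for template ", t$template_id)
    return(.empty_candidates())
  }
  rows <- list()
  for (aA in famA) for (aB in famB) {
    if (!identical(aA$species, aB$species)) next
    if (identical(aA$id, aB$id)) {
      # self-pairing only when the protein matches both chains (it does, to
      # be in both families), i.e. a homodimer-like candidate; allowed.
    }
    flt <- candidate_filter(aA, aB, config$min_identity, config$min_cr)
    if (!flt$pass) next
    eb <- score_candidate(t, aA, aB, m, profiles, blosum,
                          w = config$w, normalize = config$normalize)
    rows[[length(rows) + 1L]] <- data.frame(
      template_id = t$template_id, idA = aA$id, idB = aB$id,
      species = aA$species, identity_A = aA$identity, identity_B = aB$identity,
      CR_A = aA$CR, CR_B = aB$CR, E_vdw = eb$E_vdw, E_SF = eb$E_SF,
      E_sim = eb$E_sim, E_cons = eb$E_cons, E_tot = eb$E_tot,
      Z = z_value(eb$E_tot, nm), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(.empty_candidates())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_candidates <- function() {
  data.frame(template_id = character(), idA = character(), idB = character(),
             species = character(), identity_A = numeric(),
             identity_B = numeric(), CR_A = numeric(), CR_B = numeric(),
             E_vdw = numeric(), E_SF = numeric(), E_sim = numeric(),
             E_cons = numeric(), E_tot = numeric(), Z = numeric())
}

#' Rank candidates within each template and species
#'
#' Within every (template, species) partition, candidates are sorted by Z
#' descending, ties broken by E_tot descending and then by the lexicographic
#' id pair; ranks are dense 1..n. Per-species ranking suppresses
#' out-paralogs that predate speciation.
#'
#' @param cands Candidate data.frame from [enumerate_candidates()].
#' @return `cands` with a `species_rank` column, sorted by template,
#'   species, rank.
#' @export
rank_within_species <- function(cands) {
  if (nrow(cands) == 0L) { cands$species_rank <- integer(); return(cands) }
  key <- paste(cands$template_id, cands$species, sep = "\r")
  cands$species_rank <- NA_integer_
  for (k in unique(key)) {
    idx <- which(key == k)
    ord <- idx[order(-cands$Z[idx], -cands$E_tot[idx],
                     cands$idA[idx], cands$idB[idx])]
    cands$species_rank[ord] <- seq_along(ord)
  }
  cands <- cands[order(cands$template_id, cands$species, cands$species_rank), ,
                 drop = FALSE]
  rownames(cands) <- NULL
  cands
}

#' Accept candidates by Z-value and per-species rank
#'
#' A ranked candidate is accepted as a predicted interaction when its
#' Z-value reaches `z_min` (default 3.0) and it ranks within the top
#' `rank_max` (default 25) in its species.
#'
#' @param cands Ranked candidates (see [rank_within_species()]).
#' @param z_min Z threshold (`Z >= z_min`).
#' @param rank_max Per-species rank cutoff.
#' @return The accepted subset.
#' @export
apply_acceptance <- function(cands, z_min = 3.0, rank_max = 25) {
  cands[cands$Z >= z_min & cands$species_rank <= rank_max, , drop = FALSE]
}

#' Label candidate pairs using GO-similarity (RSS) scores
#'
#' A pair is labelled `negative` when its cellular-component RSS score is
#' below `cc_threshold` (default 0.4), `positive` when it appears in the
#' gold-standard interaction list, and `unknown` otherwise (including pairs
#' with missing RSS scores).
#'
#' @param pairs data.frame with `idA`, `idB`.
#' @param rss_table data.frame with `idA`, `idB`, `BP_RSS`, `CC_RSS`
#'   (NA allowed).
#' @param positives Optional data.frame/matrix of gold-standard positive id
#'   pairs (columns idA, idB; orientation-insensitive).
#' @param cc_threshold CC RSS below which a pair is negative.
#' @return data.frame `pairs` with `BP_RSS`, `CC_RSS` and `label`.
#' @export
label_by_rss <- function(pairs, rss_table, positives = NULL, cc_threshold = 0.4) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  k <- key(pairs$idA, pairs$idB)
  rk <- key(rss_table$idA, rss_table$idB)
  idx <- match(k, rk)
  pairs$BP_RSS <- rss_table$BP_RSS[idx]
  pairs$CC_RSS <- rss_table$CC_RSS[idx]
  is_pos <- if (!is.null(positives) && nrow(positives) > 0)
    k %in% key(positives$idA, positives$idB) else rep(FALSE, nrow(pairs))
  pairs$label <- ifelse(!is.na(pairs$CC_RSS) & pairs$CC_RSS < cc_threshold,
                        "negative", ifelse(is_pos, "positive", "unknown"))
  pairs
}

#' Precision and recall of accepted predictions
#'
#' Precision is hit positives / (hit positives + hit negatives), with
#' unknown-labelled hits excluded; recall is hit positives / total
#' positives. Optionally sweeps `z_min` and `rank_max` to emit a
#' precision-recall table.
#'
#' @param accepted Accepted candidates with a `label` column (see
#'   [label_by_rss()]).
#' @param total_positives Total number of gold-standard positives.
#' @param sweep Optional list(z_min =, rank_max =) of threshold vectors; the
#'   sweep is applied to `accepted`'s `Z`/`species_rank` columns.
#' @return list(precision, recall) or, when sweeping, a data.frame with one
#'   row per threshold combination.
#' @export
evaluate_precision_recall <- function(accepted, total_positives, sweep = NULL) {
  if (total_positives == 0) stop("recall undefined: zero positives")
  prec_rec <- function(df) {
    ah <- sum(df$label == "positive")
    fh <- sum(df$label == "negative")
    list(precision = if (ah + fh == 0) NaN else ah / (ah + fh),
         recall = ah / total_positives)
  }
  if (is.null(sweep)) return(prec_rec(accepted))
  grid <- expand.grid(z_min = sweep$z_min %||% -Inf,
                      rank_max = sweep$rank_max %||% Inf)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- accepted[accepted$Z >= grid$z_min[i] &
                    accepted$species_rank <= grid$rank_max[i], , drop = FALSE]
    pr <- prec_rec(sub)
    data.frame(z_min = grid$z_min[i], rank_max = grid$rank_max[i],
               n_accepted = nrow(sub), precision = pr$precision,
               recall = pr$recall)
  })
  do.call(rbind, res)
}

#' Write a predictions table
#'
#' Writes the per-candidate TSV (template, ids, species, identities, CRs,
#' energy breakdown, Z, rank), sorted by template, species and rank;
#' byte-stable across runs for identical input.
#'
#' @param cands Ranked candidate data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(cands, path) {
  num <- vapply(cands, is.numeric, TRUE) & names(cands) != "species_rank"
  cands[num] <- lapply(cands[num], function(x) sprintf("%.6g", x))
  write.table(cands, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
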