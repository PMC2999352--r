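# PDB ATOM record writer (fixed columns, element right-justified in 77-78)
.atom_record <- function(serial, name, resid, chain, resno, x, y, z, ele,
                         occ = 1, altloc = " ") {
  name4 <- if (nchar(name) < 4) formatC(paste0(" ", name), width = -4) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, altloc, resid, chain, resno, x, y, z, occ, 0, ele)
}

#' Generate a toy dimer with controlled contacts
#'
#' Places two chains on a lattice so that the planned contacts are the ONLY
#' inter-chain heavy-atom pairs within 4.5 angstrom. The default plan is an
#' all-vs-all sidechain contact block between `n_contact_A` residues of
#' chain A and `n_contact_B` of chain B (sidechain carbon atoms packed so
#' every cross pair sits between 4.0 and 4.13 angstrom apart), plus one
#' isolated contact pair per planned special bond with compliant geometry
#' (Cys SG-SG 2.05 for disulfide, Lys NZ - Glu OE1 3.0 for salt bridge,
#' Ser OG - Asn ND2 3.2 for hydrogen bond). Backbones sit on parallel axes
#' 20 angstrom apart, and non-contact sidechains stay near their own
#' backbone, guaranteeing contact exclusivity without a clash model.
#'
#' @param spec list: `seed`, `len_A`, `len_B` (chain lengths, default 30),
#'   `n_contact_A`, `n_contact_B` (default 6 and 5), `special_bond_plan`
#'   (character vector drawn from "hydrogen_bond", "salt_bridge",
#'   "disulfide"), `contact_types_A`/`_B` (1-letter codes for the vdW
#'   block's residues), `contact_start` (first contact position, default 3).
#' @return list: `pdb` (character vector of PDB lines), `truth` (data.frame
#'   of planned contact pairs: posA, posB, class, special_bond), `seq_A`,
#'   `seq_B`, and the echoed `spec`.
#' @export
make_toy_dimer <- function(spec = list()) {
  seed <- spec$seed %||% 1L
  len_A <- spec$len_A %||% 30L
  len_B <- spec$len_B %||% 30L
  nA <- spec$n_contact_A %||% 6L
  nB <- spec$n_contact_B %||% 5L
  plan <- spec$special_bond_plan %||% character()
  firstA <- spec$contact_start %||% 3L
  if (nA < 1L || nB < 1L) stop("need at least one contact residue per chain")
  typesA <- rep(spec$contact_types_A %||% c("L", "M", "F", "I", "V", "W"),
                length.out = nA)
  typesB <- rep(spec$contact_types_B %||% c("M", "L", "Y", "V", "I"),
                length.out = nB)
  ns <- length(plan)
  if (firstA < 1L) stop("infeasible plan: contact_start below 1")
  if (firstA + nA + ns - 1L > len_A || firstA + nB + ns - 1L > len_B)
    stop("infeasible plan: contact plan does not fit in the chains")
  posA_vdw <- seq(firstA, length.out = nA)
  posB_vdw <- seq(firstA, length.out = nB)
  posA_sp <- seq(firstA + nA, length.out = ns)
  posB_sp <- seq(firstA + nB, length.out = ns)

  sp_res <- list(disulfide = c("C", "C"), salt_bridge = c("K", "E"),
                 hydrogen_bond = c("S", "N"))
  sp_atom <- list(disulfide = list(c("SG", "S"), c("SG", "S")),
                  salt_bridge = list(c("NZ", "N"), c("OE1", "O")),
                  hydrogen_bond = list(c("OG", "O"), c("ND2", "N")))
  sp_gap <- c(disulfide = 2.05, salt_bridge = 3.0, hydrogen_bond = 3.2)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  filler <- c("A", "G", "S", "T", "D", "E", "K", "R", "N", "Q", "P", "H")
  seqA <- sample(filler, len_A, replace = TRUE)
  seqB <- sample(filler, len_B, replace = TRUE)
  seqA[posA_vdw] <- typesA
  seqB[posB_vdw] <- typesB
  for (s in seq_len(ns)) {
    seqA[posA_sp[s]] <- sp_res[[plan[s]]][1]
    seqB[posB_sp[s]] <- sp_res[[plan[s]]][2]
  }

  lines <- character(); serial <- 0L
  emit <- function(name, aa1, chain, resno, x, y, z, ele) {
    serial <<- serial + 1L
    lines[length(lines) + 1L] <<- .atom_record(serial, name, AA3[[aa1]],
                                               chain, resno, x, y, z, ele)
  }
  backbone <- function(aa1, chain, resno, x0, y0, with_cb = TRUE) {
    emit("N", aa1, chain, resno, x0, y0, 0, "N")
    emit("CA", aa1, chain, resno, x0 + 1.2, y0, 0, "C")
    emit("C", aa1, chain, resno, x0 + 2.4, y0, 0, "C")
    emit("O", aa1, chain, resno, x0 + 2.4, y0 + 1.2 * (if (y0 == 0) -1 else 1), 0, "O")
    if (with_cb && aa1 != "G")
      emit("CB", aa1, chain, resno, x0 + 1.2, y0, 1.3, "C")
  }
  ux <- function(i, n) if (n == 1) 0.5 else (i - 1) / (n - 1)
  for (r in seq_len(len_A)) backbone(seqA[r], "A", r, 6 * (r - 1), 0)
  for (r in seq_len(len_B)) backbone(seqB[r], "B", r, 6 * (r - 1), 20)
  for (i in seq_len(nA))
    emit("CG", seqA[posA_vdw[i]], "A", posA_vdw[i], ux(i, nA), 8, 0, "C")
  for (j in seq_len(nB))
    emit("CG", seqB[posB_vdw[j]], "B", posB_vdw[j], ux(j, nB), 12, 0, "C")
  for (s in seq_len(ns)) {
    xs <- 50 + 10 * (s - 1)
    aA <- sp_atom[[plan[s]]][[1]]; aB <- sp_atom[[plan[s]]][[2]]
    emit(aA[1], seqA[posA_sp[s]], "A", posA_sp[s], xs, 9, 0, aA[2])
    emit(aB[1], seqB[posB_sp[s]], "B", posB_sp[s], xs, 9 + sp_gap[[plan[s]]], 0, aB[2])
  }
  lines <- c(lines, "TER", "END")

  truth <- expand.grid(posA = posA_vdw, posB = posB_vdw)
  truth <- truth[order(truth$posA, truth$posB), ]
  truth$class <- "ss"; truth$special_bond <- "none"
  if (ns > 0)
    truth <- rbind(truth, data.frame(posA = posA_sp, posB = posB_sp,
                                     class = "ss", special_bond = plan))
  rownames(truth) <- NULL
  list(pdb = lines, truth = truth,
       seq_A = paste(seqA, collapse = ""), seq_B = paste(seqB, collapse = ""),
       contact_positions_A = sort(c(posA_vdw, posA_sp)),
       contact_positions_B = sort(c(posB_vdw, posB_sp)),
       spec = spec)
}

#' Generate a homolog family with controlled identity
#'
#' Produces mutated copies of a template chain at target sequence
#' identities. The number of substitutions is `round((1 - identity) * L)`,
#' so the realized identity is within 0.5/L of the target. Positions listed
#' in `conserved` or `avoid` are never mutated; positions in `prefer` are
#' mutated first (useful for building decoys whose interface is degraded
#' while overall identity stays high). Substitute residues are drawn from
#' the BLOSUM62-conditional distribution of the wild type (excluding the
#' wild type), which keeps alignments unambiguous.
#'
#' @param template_seq Template chain sequence.
#' @param spec list: `seed`; `members` data.frame with `id`, `species`,
#'   `identity` (one row per family member); optional integer vectors
#'   `conserved`, `avoid`, `prefer`; `substitute` = "blosum" (default,
#'   conservative) or "adversarial" (each mutated residue becomes its
#'   lowest-scoring BLOSUM62 partner, degrading interface scores).
#' @return data.frame `id`, `species`, `seq`, `target_identity`,
#'   `realized_identity`.
#' @export
make_homolog_family <- function(template_seq, spec) {
  members <- spec$members
  stopifnot(is.data.frame(members), all(c("id", "species", "identity") %in% names(members)))
  if (any(members$identity <= 0 | members$identity > 1))
    stop("identity targets must lie in (0, 1]")
  L <- nchar(template_seq)
  tpl <- strsplit(template_seq, "")[[1]]
  protected <- union(spec$conserved %||% integer(), spec$avoid %||% integer())
  prefer <- setdiff(spec$prefer %||% integer(), protected)
  free <- setdiff(seq_len(L), union(protected, prefer))
  cond <- .blosum_conditional()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed %||% 1L)
  out <- members
  out$seq <- NA_character_; out$realized_identity <- NA_real_
  for (i in seq_len(nrow(members))) {
    n_mut <- round((1 - members$identity[i]) * L)
    if (n_mut > length(prefer) + length(free))
      stop("identity target ", members$identity[i],
           " incompatible with the conserved-position plan")
    take <- c(if (length(prefer)) prefer[seq_len(min(n_mut, length(prefer)))],
              if (n_mut > length(prefer))
                sample(free, n_mut - length(prefer)))
    s <- tpl
    adversarial <- identical(spec$substitute, "adversarial")
    if (adversarial) blo <- load_substitution_matrix("BLOSUM62")
    for (p in take) {
      wt <- s[p]
      if (adversarial && wt %in% AA1) {
        s[p] <- AA1[which.min(blo[wt, ])]
      } else {
        pr <- if (wt %in% AA1) cond[, wt] else setNames(rep(1 / 20, 20), AA1)
        pr[wt] <- 0
        s[p] <- sample(AA1, 1, prob = pr / sum(pr))
      }
    }
    out$seq[i] <- paste(s, collapse = "")
    out$realized_identity[i] <- mean(s == tpl)
  }
  names(out)[names(out) == "identity"] <- "target_identity"
  out
}

#' Write a species-annotated FASTA file
#'
#' Headers follow the `>ID|SPECIES` convention read by
#' [read_species_fasta()].
#'
#' @param df data.frame with `id`, `species`, `seq`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_species_fasta <- function(df, path) {
  writeLines(as.vector(rbind(paste0(">", df$id, "|", df$species), df$seq)), path)
  invisible(path)
}

#' Generate a synthetic alanine-scan table
#'
#' Samples `n` contact residues of a template (pooled over both chains),
#' computes their model contributions and adds Gaussian noise to produce an
#' ASEdb-style ddG table — a fully synthetic surrogate for experimental
#' alanine-scanning data, used to exercise the binding-affinity evaluation.
#'
#' @inheritParams residue_contribution
#' @param n Number of scanned residues (at most the pooled contact count).
#' @param noise_sd Gaussian noise standard deviation; `NULL` uses
#'   0.25 x sd(model contributions).
#' @param seed Integer seed.
#' @return data.frame `template_id`, `chain`, `position`, `wildtype`,
#'   `ddG`.
#' @export
make_alascan_set <- function(t, m, profiles, n = 50, noise_sd = NULL,
                             seed = 1L,
                             blosum = load_substitution_matrix("BLOSUM62"),
                             w = 3) {
  pooled <- rbind(data.frame(chain = "A", position = t$contact_residues_A),
                  data.frame(chain = "B", position = t$contact_residues_B))
  if (n > nrow(pooled))
    stop("n exceeds the number of contact residues (", nrow(pooled), ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  pooled <- pooled[sample.int(nrow(pooled), n), , drop = FALSE]
  recs <- lapply(seq_len(n), function(i)
    residue_contribution(t, pooled$chain[i], pooled$position[i], m, profiles,
                         blosum, w))
  contrib <- vapply(recs, function(r) r$contribution, 0)
  if (is.null(noise_sd)) noise_sd <- 0.25 * sd(contrib)
  data.frame(template_id = t$template_id, chain = pooled$chain,
             position = pooled$position,
             wildtype = vapply(recs, function(r) r$wildtype, ""),
             ddG = contrib + rnorm(n, 0, noise_sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a planted-interaction database for a template
#'
#' Builds a species-annotated sequence database containing, per species, a
#' planted true interacting pair (homologs of both template chains at high
#' identity with conserved contact residues) and three decoys on the chain A
#' side: `decoy_low` (remote sequence, fails the identity filter),
#' `decoy_cr` (near-identical but with the whole interface region deleted,
#' fails the contact-coverage filter) and `decoy_z` (interface contact
#' residues adversarially mutated, fails the Z threshold). The ground-truth
#' role of every entry is returned alongside.
#'
#' @param t A `TemplateInterface`.
#' @param spec list: `seed`, `species` (character vector, default Human /
#'   Mouse / Yeast), `true_identity` (default 0.85).
#' @return data.frame `id`, `species`, `seq`, `role` (one of true_A,
#'   true_B, decoy_low, decoy_cr, decoy_z).
#' @export
make_planted_db <- function(t, spec = list()) {
  seed <- spec$seed %||% 1L
  species <- spec$species %||% c("Human", "Mouse", "Yeast")
  tid <- spec$true_identity %||% 0.85
  LA <- nchar(t$chainA_seq)
  ctA <- t$contact_residues_A
  rows <- list()
  for (k in seq_along(species)) {
    sp <- species[k]
    fams <- make_homolog_family(t$chainA_seq, list(
      seed = seed + 13L * k,
      members = data.frame(id = paste0("trueA_", sp), species = sp,
                           identity = tid),
      conserved = ctA))
    famB <- make_homolog_family(t$chainB_seq, list(
      seed = seed + 13L * k + 1L,
      members = data.frame(id = paste0("trueB_", sp), species = sp,
                           identity = tid),
      conserved = t$contact_residues_B))
    low <- make_homolog_family(t$chainA_seq, list(
      seed = seed + 13L * k + 2L,
      members = data.frame(id = paste0("decoyLow_", sp), species = sp,
                           identity = 0.15)))
    # interface deletion: drop everything up to just past the last contact
    cut <- max(ctA) + 2L
    crseq <- substr(t$chainA_seq, min(cut + 1L, LA), LA)
    nz <- make_homolog_family(t$chainA_seq, list(
      seed = seed + 13L * k + 3L,
      members = data.frame(id = paste0("decoyZ_", sp), species = sp,
                           identity = 1 - (length(ctA) + 2) / LA),
      prefer = ctA, substitute = "adversarial"))
    rows[[k]] <- data.frame(
      id = c(fams$id, famB$id, low$id, paste0("decoyCR_", sp), nz$id),
      species = sp,
      seq = c(fams$seq, famB$seq, low$seq, crseq, nz$seq),
      role = c("true_A", "true_B", "decoy_low", "decoy_cr", "decoy_z"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The calcineurin worked-example search results
#'
#' The 19 search-result rows for the human calcineurin heterodimer query
#' (structure 1aui), entered as structured records: interactor ids, species,
#' Z score, per-species rank, the reference positive/negative call, and the
#' biological-process / cellular-component RSS scores (NA where no score is
#' available).
#'
#' @return data.frame with columns `idA`, `idB`, `species`, `Z`,
#'   `species_rank`, `PN`, `BP_RSS`, `CC_RSS`.
#' @export
table3_fixture <- function() {
  data.frame(
    idA = c("P48456", "P23287", "P14747", "Q12705", "P48456", "P48456",
            "P48456", "P48456", "Q8IAM8", "P48456", "P48456", "Q27889",
            "P23287", "P48456", "P48456", "P14747", "P48454", "Q08209",
            "P16298"),
    idB = c("P48451", "P25296", "P25296", "Q9UU93", "P47948", "P47949",
            "P49258", "Q9VQH2", "P62203", "P48593", "A1ZAE1", "P48593",
            "P06787", "Q9VMT2", "Q7K860", "P06787", "Q9NP86", "Q9NP86",
            "Q9NP86"),
    species = c("Fruit fly", "Yeast", "Yeast", "Yeast", "Fruit fly",
                "Fruit fly", "Fruit fly", "Fruit fly",
                "Plasmodium falciparum", "Fruit fly", "Fruit fly",
                "Fruit fly", "Yeast", "Fruit fly", "Fruit fly", "Yeast",
                "Human", "Human", "Human"),
    Z = c(8.98, 8.25, 7.95, 7.94, 4.42, 4.38, 3.99, 3.94, 3.79, 3.72, 3.59,
          3.42, 3.36, 3.03, 2.99, 2.86, 2.33, 2.31, 2.31),
    species_rank = c(1L, 1L, 2L, 1L, 16L, 17L, 23L, 25L, 2L, 31L, 34L, 40L,
                     5L, 50L, 53L, 6L, 90L, 91L, 91L),
    PN = c("P", "P", "P", "P", "N", "N", "P", "N", "P", "P", "N", "P", "P",
           "N", "N", "P", "N", "N", "N"),
    BP_RSS = c(0.89, 0.88, 0.88, NA, 0.41, 0.41, 0.41, 0.49, NA, 0.35, 0.00,
               NA, 0.61, 0.41, 0.41, 0.61, NA, 0.41, NA),
    CC_RSS = c(0.85, 1.00, 1.00, 0.78, 0.30, 0.30, 0.56, 0.33, NA, 0.56,
               0.30, NA, 0.88, 0.30, 0.30, 0.88, 0.00, 0.00, 0.00),
    stringsAsFactors = FALSE)
}
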