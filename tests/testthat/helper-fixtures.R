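# Shared fixtures and independent oracles. Everything is generated in code;
# fixtures are cached per session because several tests reuse them.

.fix_cache <- new.env(parent = emptyenv())

fix <- function(name, builder) {
  if (!exists(name, .fix_cache)) assign(name, builder(), .fix_cache)
  get(name, .fix_cache)
}

# standard toy template with all three special bonds
fix_toy <- function() fix("toy", function() {
  toy <- make_toy_dimer(list(
    seed = 7, special_bond_plan = c("disulfide", "salt_bridge", "hydrogen_bond")))
  s <- parse_structure(toy$pdb, id = "toy")
  t <- build_template(s, "A", "B")
  list(toy = toy, s = s, t = t)
})

fix_matrices <- function() fix("matrices", function()
  derive_matrix_set(list(fix_toy()$t)))

fix_profiles <- function() fix("profiles", function() {
  t <- fix_toy()$t
  list(A = build_profile(t$chainA_seq, chain = "A"),
       B = build_profile(t$chainB_seq, chain = "B"))
})

fix_blosum <- function() fix("blosum", function() load_substitution_matrix("BLOSUM62"))

# a bigger interface (50 pooled contact residues) for alanine-scan work
fix_big <- function() fix("big", function() {
  toy <- make_toy_dimer(list(
    seed = 11, len_A = 40, len_B = 40, n_contact_A = 24, n_contact_B = 24,
    special_bond_plan = c("salt_bridge", "hydrogen_bond"),
    contact_types_A = c("L", "M", "F", "I", "V", "W", "Y", "K", "E", "R", "T", "N"),
    contact_types_B = c("M", "V", "L", "W", "I", "F", "D", "Q", "H", "S", "A", "Y")))
  s <- parse_structure(toy$pdb, id = "big")
  t <- build_template(s, "A", "B")
  list(toy = toy, s = s, t = t,
       m = derive_matrix_set(list(t)),
       profiles = list(A = build_profile(t$chainA_seq, chain = "A"),
                       B = build_profile(t$chainB_seq, chain = "B")))
})

# mid-chain interface used by the planted-recovery pipeline tests
fix_planted_template <- function() fix("planted", function() {
  toy <- make_toy_dimer(list(
    seed = 7, len_A = 60, len_B = 60, contact_start = 25,
    special_bond_plan = c("salt_bridge", "hydrogen_bond")))
  s <- parse_structure(toy$pdb, id = "planted")
  list(toy = toy, s = s, t = build_template(s, "A", "B"))
})

# ---- independent oracles --------------------------------------------------

# brute-force O(N^2) all-atom contact extraction: plain double loops over
# residues and atoms, no vectorisation shared with the implementation
oracle_contacts <- function(s, chainA, chainB, cutoff = 4.5) {
  a <- s$atoms[s$atoms$chain == chainA, ]
  b <- s$atoms[s$atoms$chain == chainB, ]
  res <- list()
  for (pa in unique(a$pos)) for (pb in unique(b$pos)) {
    ra <- a[a$pos == pa, ]; rb <- b[b$pos == pb, ]
    ss <- sb <- bs <- FALSE; mind <- Inf
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
      d <- sqrt((ra$x[i] - rb$x[j])^2 + (ra$y[i] - rb$y[j])^2 +
                (ra$z[i] - rb$z[j])^2)
      if (d <= cutoff) {
        mind <- min(mind, d)
        if (ra$sidechain[i] && rb$sidechain[j]) ss <- TRUE
        if (ra$sidechain[i] && !rb$sidechain[j]) sb <- TRUE
        if (!ra$sidechain[i] && rb$sidechain[j]) bs <- TRUE
      }
    }
    if (is.finite(mind) && (ss || sb || bs))
      res[[length(res) + 1]] <- data.frame(posA = pa, posB = pb, ss = ss,
                                           sb = sb, bs = bs,
                                           min_distance = mind)
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  out[order(out$posA, out$posB), ]
}

# score-only local alignment oracle: O(n^3) formulation scanning explicit
# gap lengths instead of the affine three-state recurrence
oracle_sw_score <- function(M, template_len, seq, gap_open = 11, gap_extend = 1) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  aas <- rownames(M)
  colsc <- function(i, j) {
    x <- s[j]
    if (x %in% aas) M[x, i] else -4
  }
  H <- matrix(0, template_len + 1, n + 1)
  for (i in seq_len(template_len)) for (j in seq_len(n)) {
    best <- max(0, H[i, j] + colsc(i, j))
    for (k in seq_len(i))
      best <- max(best, H[i - k + 1, j + 1] - gap_open - k * gap_extend)
    for (k in seq_len(j))
      best <- max(best, H[i + 1, j - k + 1] - gap_open - k * gap_extend)
    H[i + 1, j + 1] <- best
  }
  max(H)
}

random_aa_string <- function(n) paste(sample(c("A","R","N","D","C","Q","E","G",
  "H","I","L","K","M","F","P","S","T","W","Y","V"), n, replace = TRUE),
  collapse = "")

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# hand-built template interface (no PDB involved)
mk_template <- function(seqA, seqB, pairs, id = "hand") {
  pairs$resA <- strsplit(seqA, "")[[1]][pairs$posA]
  pairs$resB <- strsplit(seqB, "")[[1]][pairs$posB]
  if (is.null(pairs$ss)) pairs$ss <- TRUE
  if (is.null(pairs$sb)) pairs$sb <- FALSE
  if (is.null(pairs$bs)) pairs$bs <- FALSE
  if (is.null(pairs$special_bond)) pairs$special_bond <- "none"
  if (is.null(pairs$min_distance)) pairs$min_distance <- 4.0
  structure(list(template_id = id, chainA = "A", chainB = "B",
                 chainA_seq = seqA, chainB_seq = seqB,
                 contact_residues_A = sort(unique(pairs$posA)),
                 contact_residues_B = sort(unique(pairs$posB)),
                 contact_pairs = pairs, CP = nrow(pairs)),
            class = "TemplateInterface")
}

# alignment of `seq` onto a template chain with an explicit position map
mk_alignment <- function(seq, map, identity = 1, CR = 1) {
  structure(list(chain = "A", id = "cand", species = "Test", map = map,
                 cand_seq = seq, identity = identity, score = NA_real_,
                 CR = CR), class = "ChainAlignment")
}

# zero count table in the shape count_pairs() produces
empty_count_table <- function() {
  zero <- matrix(0L, 20, 20, dimnames = list(AA20, AA20))
  structure(list(ss_vdw = zero, sb_vdw = zero, ss_special = zero,
                 sb_special = zero, n_pairs = 0L), class = "PairCountTable")
}

# PSI-BLAST-style ASCII PSSM fixture text
make_pssm_text <- function(scores, residues) {
  hdr <- paste0("           ", paste(sprintf("%3s", AA20), collapse = ""),
                "   ", paste(sprintf("%3s", AA20), collapse = ""))
  rows <- vapply(seq_along(residues), function(i)
    paste0(sprintf("%5d %s  ", i, residues[i]),
           paste(sprintf("%3d", scores[i, ]), collapse = ""), "  ",
           paste(rep(" 10", 20), collapse = ""), "  0.50 0.10"), "")
  c("", "Last position-specific scoring matrix computed, weighted observed percentages",
    hdr, rows, "", "                      K         Lambda", "Standard Ungapped    0.13     0.31")
}
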