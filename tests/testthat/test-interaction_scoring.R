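test_that("E_vdw is a matrix lookup at candidate residues on the template topology", {
  m <- fix_matrices()
  t1 <- mk_template("LAA", "MAA", data.frame(posA = 1L, posB = 1L))
  self <- list(A = self_alignment(t1, "A"), B = self_alignment(t1, "B"))
  expect_equal(score_vdw(t1, self$A, self$B, m),
               unname(m$ss_vdw$scores["L", "M"]))
  # candidate mutates the pair to Cys-Phe: difference equals the matrix difference,
  # and hydrophobic-packing cells outscore unobserved ones
  cf <- list(A = mk_alignment("CAA", 1:3), B = mk_alignment("FAA", 1:3))
  d <- score_vdw(t1, self$A, self$B, m) - score_vdw(t1, cf$A, cf$B, m)
  expect_equal(d, unname(m$ss_vdw$scores["L", "M"] - m$ss_vdw$scores["C", "F"]))
  expect_gt(d, 0)
  # gap at a contact position contributes exactly 0
  gapped <- mk_alignment("CAA", c(NA, 2:3))
  expect_equal(score_vdw(t1, gapped, cf$B, m), 0)
})

test_that("sb/bs classes look up the directional matrix with sidechain rows", {
  m <- fix_matrices()
  pr <- data.frame(posA = 1L, posB = 1L, ss = FALSE, sb = TRUE, bs = FALSE)
  t1 <- mk_template("WAA", "GAA", pr)
  self <- list(A = self_alignment(t1, "A"), B = self_alignment(t1, "B"))
  expect_equal(score_vdw(t1, self$A, self$B, m),
               unname(m$sb_vdw$scores["W", "G"]))
  pr$sb <- FALSE; pr$bs <- TRUE
  t2 <- mk_template("GAA", "WAA", pr)
  self2 <- list(A = self_alignment(t2, "A"), B = self_alignment(t2, "B"))
  expect_equal(score_vdw(t2, self2$A, self2$B, m),
               unname(m$sb_vdw$scores["W", "G"]))
})

test_that("E_SF sums special matrices only over special-bonded template pairs", {
  # train special scores that include an Arg-Asp salt bridge
  tab <- empty_count_table()
  tab$ss_vdw[] <- 1L
  tab$ss_special["R", "D"] <- tab$ss_special["D", "R"] <- 6L
  tab$ss_special["C", "C"] <- 4L
  m <- list(ss_vdw = derive_matrix(tab, "ss_vdw"),
            sb_vdw = derive_matrix(tab, "sb_vdw", pseudocount = 0.5),
            ss_special = derive_matrix(tab, "ss_special"),
            sb_special = derive_matrix(tab, "sb_special", pseudocount = 0.5))
  salted <- data.frame(posA = 1L, posB = 1L, special_bond = "salt_bridge")
  t1 <- mk_template("RAA", "DAA", salted)
  self <- list(A = self_alignment(t1, "A"), B = self_alignment(t1, "B"))
  expect_equal(score_special(t1, self$A, self$B, m),
               unname(m$ss_special$scores["R", "D"]))
  expect_gt(score_special(t1, self$A, self$B, m), 0)
  # mutating the Asp to Leu hits a chemically impossible cell: exactly 0
  mut <- mk_alignment("LAA", 1:3)
  expect_equal(score_special(t1, self$A, mut, m), 0)
  # a template without special bonds scores 0 for every candidate
  t0 <- mk_template("RAA", "DAA", data.frame(posA = 1L, posB = 1L))
  expect_equal(score_special(t0, self$A, self$B, m), 0)
})

test_that("E_sim normalises BLOSUM similarity by the template diagonal", {
  b <- fix_blosum()
  t1 <- mk_template("WAA", "LAA", data.frame(posA = 1L, posB = 1L))
  self <- list(A = self_alignment(t1, "A"), B = self_alignment(t1, "B"))
  expect_equal(score_sim(t1, self$A, self$B, b), 1)   # (11+4)/(11+4)
  # candidate W,I: (K_WW + K_LI) / (K_WW + K_LL) = 13/15
  wi <- mk_alignment("IAA", 1:3)
  expect_equal(score_sim(t1, self$A, wi, b), 13 / 15)
  # both positions gapped: 0
  g <- mk_alignment("IAA", c(NA, 2:3))
  expect_equal(score_sim(t1, g, g, b), 0)
  # full template: E_sim equals CP at the self fixed point
  t <- fix_toy()$t
  selfT <- list(A = self_alignment(t, "A"), B = self_alignment(t, "B"))
  expect_equal(score_sim(t, selfT$A, selfT$B, b), t$CP)
  # mean normalisation: self fixed point is exactly 1
  expect_equal(score_sim(t, selfT$A, selfT$B, b, normalize = "mean"), 1)
})

test_that("E_cons reads the chain profiles at candidate residues", {
  b <- fix_blosum()
  t <- fix_toy()$t
  pr <- fix_profiles()
  self <- list(A = self_alignment(t, "A"), B = self_alignment(t, "B"))
  got <- score_cons(pr$A, pr$B, t, self$A, self$B, b)
  # independent recomputation from the profile matrices
  cp <- t$contact_pairs
  K <- diag(unclass(b)); names(K) <- rownames(b)
  expected <- sum(vapply(seq_len(nrow(cp)), function(k) {
    (pr$A$M[cp$resA[k], cp$posA[k]] + pr$B$M[cp$resB[k], cp$posB[k]]) /
      (K[cp$resA[k]] + K[cp$resB[k]])
  }, 0))
  expect_equal(got, expected)
  # conserved positions score higher than a low-propensity substitute
  mutA <- strsplit(t$chainA_seq, "")[[1]]
  pos <- t$contact_residues_A[1]
  mutA[pos] <- AA20[which.min(pr$A$M[, pos])]
  worse <- mk_alignment(paste(mutA, collapse = ""), seq_len(nchar(t$chainA_seq)))
  expect_lt(score_cons(pr$A, pr$B, t, worse, self$B, b), got)
  # all contact positions gapped -> 0
  gap <- mk_alignment(t$chainA_seq,
                      replace(seq_len(nchar(t$chainA_seq)),
                              t$contact_residues_A, NA))
  gapB <- mk_alignment(t$chainB_seq,
                       replace(seq_len(nchar(t$chainB_seq)),
                               t$contact_residues_B, NA))
  expect_equal(score_cons(pr$A, pr$B, t, gap, gapB, b), 0)
  # length mismatch guards
  expect_error(score_cons(build_profile("MKW"), pr$B, t, self$A, self$B, b),
               "length")
})

test_that("total_score is the exact weighted sum with configurable w", {
  eb <- total_score(1, 2, 3, 4, w = 3)
  expect_equal(eb$E_tot, 18)
  expect_equal(total_score(1, 2, 3, 4, w = 0)$E_tot, 6)
  expect_equal(total_score(1, 2, 3 + 0.5, 4, w = 3)$E_tot, 18.5)
  # identity holds on a real scored fixture
  t <- fix_toy()$t
  eb2 <- score_candidate(t, self_alignment(t, "A"), self_alignment(t, "B"),
                         fix_matrices(), fix_profiles())
  expect_equal(eb2$E_tot,
               eb2$E_vdw + eb2$E_SF + eb2$E_sim + 3 * eb2$E_cons)
})

test_that("lowering a single contact residue's matrix value never raises E_vdw", {
  m <- fix_matrices()
  t <- fix_toy()$t
  selfB <- self_alignment(t, "B")
  base <- strsplit(t$chainA_seq, "")[[1]]
  pos <- t$contact_residues_A[2]
  partner_pairs <- t$contact_pairs[t$contact_pairs$posA == pos, ]
  val <- function(x) sum(m$ss_vdw$scores[x, partner_pairs$resB])
  scores <- vapply(AA20, function(x) {
    s <- base; s[pos] <- x
    score_vdw(t, mk_alignment(paste(s, collapse = ""), seq_along(base)), selfB, m)
  }, 0)
  expect_equal(order(scores), order(vapply(AA20, val, 0)))
})

test_that("null model is reproducible, calibrated, and degenerate without mutations", {
  t <- fix_toy()$t
  m <- fix_matrices(); pr <- fix_profiles()
  nm1 <- build_null_model(t, m, pr, n = 200, seed = 31, keep_samples = TRUE)
  nm2 <- build_null_model(t, m, pr, n = 200, seed = 31, keep_samples = TRUE)
  expect_identical(nm1$samples, nm2$samples)
  expect_equal(nm1$mean, nm2$mean)
  expect_equal(nm1$sd, nm2$sd)
  nm3 <- build_null_model(t, m, pr, n = 200, seed = 32)
  expect_false(isTRUE(all.equal(nm1$mean, nm3$mean)))
  # z of the null samples themselves: mean ~ 0, sd ~ 1
  z <- vapply(nm1$samples, z_value, 0, nm = nm1)
  expect_lt(abs(mean(z)), 3 / sqrt(nm1$n_samples))
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # z basics
  expect_equal(z_value(nm1$mean, nm1), 0)
  expect_equal(z_value(nm1$mean + 3 * nm1$sd, nm1), 3.0)
  a <- nm1$mean + 1.7; b2 <- nm1$mean - 0.4
  expect_equal(z_value(a, nm1) - z_value(b2, nm1), (a - b2) / nm1$sd)
  # fraction 0: every sample equals the self score -> degenerate
  expect_error(build_null_model(t, m, pr, n = 20, fraction = 0, seed = 1),
               "degenerate")
  expect_error(z_value(1, list(mean = 0, sd = 0)), "degenerate")
})

test_that("null sampling distribution matches exhaustive enumeration on a 2-residue interface", {
  m <- fix_matrices()
  t1 <- mk_template(paste0("L", strrep("A", 29)), paste0("K", strrep("A", 29)),
                    data.frame(posA = 1L, posB = 1L))
  pr <- list(A = build_profile(t1$chainA_seq, chain = "A"),
             B = build_profile(t1$chainB_seq, chain = "B"))
  bg <- setNames(rep(0, 20), AA20)
  bg[c("L", "K", "E")] <- c(0.5, 0.3, 0.2)
  # with 2 pooled contact residues and fraction 0.6, both are always mutated;
  # L mutates to K or E (renormalised background), K to L or E
  outcomes <- expand.grid(a = c("K", "E"), b = c("L", "E"),
                          stringsAsFactors = FALSE)
  pa <- c(K = 0.3 / 0.5, E = 0.2 / 0.5)
  pb <- c(L = 0.5 / 0.7, E = 0.2 / 0.7)
  outcomes$p <- pa[outcomes$a] * pb[outcomes$b]
  outcomes$score <- vapply(seq_len(nrow(outcomes)), function(i) {
    aA <- mk_alignment(paste0(outcomes$a[i], strrep("A", 29)), 1:30)
    aB <- mk_alignment(paste0(outcomes$b[i], strrep("A", 29)), 1:30)
    score_candidate(t1, aA, aB, m, pr)$E_tot
  }, 0)
  mu <- sum(outcomes$p * outcomes$score)
  sdev <- sqrt(sum(outcomes$p * (outcomes$score - mu)^2))
  nm <- build_null_model(t1, m, pr, background = bg, n = 4000, seed = 8,
                         keep_samples = TRUE)
  expect_equal(nm$mean, mu, tolerance = 5 * sdev / sqrt(4000) / abs(mu))
  expect_equal(sort(unique(round(nm$samples, 9))),
               sort(unique(round(outcomes$score, 9))))
})

test_that("residue contributions behave like a computational alanine scan", {
  big <- fix_big()
  t <- big$t; m <- big$m; pr <- big$profiles
  # mutating an alanine to alanine changes nothing
  alaB <- t$contact_residues_B[
    strsplit(t$chainB_seq, "")[[1]][t$contact_residues_B] == "A"][1]
  expect_false(is.na(alaB))
  expect_equal(residue_contribution(t, "B", alaB, m, pr)$contribution, 0)
  expect_error(residue_contribution(t, "A", 2, m, pr), "not a contact residue")
  # single-pair template: contribution equals the hand-computed term difference
  b <- fix_blosum()
  t1 <- mk_template(paste0("L", strrep("A", 29)), paste0("M", strrep("A", 29)),
                    data.frame(posA = 1L, posB = 1L))
  pr1 <- list(A = build_profile(t1$chainA_seq, chain = "A"),
              B = build_profile(t1$chainB_seq, chain = "B"))
  got <- residue_contribution(t1, "A", 1, m, pr1)$contribution
  K <- diag(unclass(b)); names(K) <- rownames(b)
  denom <- K[["L"]] + K[["M"]]
  exp_diff <-
    (m$ss_vdw$scores["L", "M"] - m$ss_vdw$scores["A", "M"]) +
    ((b["L", "L"] - b["L", "A"]) / denom) +
    3 * ((pr1$A$M["L", 1] - pr1$A$M["A", 1]) / denom)
  expect_equal(got, unname(exp_diff))
})

test_that("synthetic alanine-scan recovery: strong correlation under calibrated noise", {
  big <- fix_big()
  t <- big$t; m <- big$m; pr <- big$profiles
  noiseless <- make_alascan_set(t, m, pr, n = 50, noise_sd = 0, seed = 21)
  ev0 <- evaluate_alascan(t, m, pr, noiseless)
  expect_equal(ev0$pearson_r, 1.0)
  scan <- make_alascan_set(t, m, pr, n = 50, noise_sd = NULL, seed = 22)
  ev <- evaluate_alascan(t, m, pr, scan)
  expect_gt(ev$pearson_r, 0.9)
  # permuted ddG destroys the association
  perm <- scan
  set.seed(23)
  perm$ddG <- sample(perm$ddG)
  expect_lt(abs(evaluate_alascan(t, m, pr, perm)$pearson_r), 0.3)
  expect_error(make_alascan_set(t, m, pr, n = 1000), "exceeds")
})
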