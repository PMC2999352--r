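test_that("parse_structure reads chains, drops hydrogens, resolves altlocs", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1       0.500   0.500   0.000  1.00  0.00           H",
    "ATOM      4  CB ASER A   2       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      5  CB BSER A   2       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      6  N   GLY B   1       0.000   4.000   0.000  1.00  0.00           N",
    "TER", "END")
  s <- parse_structure(pdb, id = "mini")
  expect_named(s$chains, c("A", "B"))
  expect_equal(length(s$chains$A$aa), 2)
  expect_equal(length(s$chains$B$aa), 1)
  # hydrogens absent
  expect_false(any(s$atoms$elesy == "H"))
  # altloc: occupancy 0.6 conformer retained
  cb <- s$atoms[s$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 2.0)
})

test_that("parse_structure rejects malformed and non-protein input", {
  bad <- c("ATOM      1  N   ALA A   1       xxx     0.000   0.000  1.00  0.00           N")
  expect_error(parse_structure(bad), "line 1")
  expect_error(parse_structure(c("HEADER    NOTHING", "END")), "ATOM")
})

test_that("selenomethionine maps to Met for scoring", {
  pdb <- c(
    "HETATM    1  N   MSE A   1       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  SE  MSE A   1       1.000   0.000   0.000  1.00  0.00          SE",
    "ATOM      3  N   GLY B   1       0.000   3.000   0.000  1.00  0.00           N",
    "END")
  s <- parse_structure(pdb)
  expect_equal(s$chains$A$aa, "M")
})

test_that("contact cutoff is honoured at the boundary", {
  mk <- function(d) c(
    sprintf("ATOM      1  CB  LEU A   1       0.000   0.000   0.000  1.00  0.00           C"),
    sprintf("ATOM      2  CB  MET B   1       %.3f   0.000   0.000  1.00  0.00           C", d),
    "END")
  s1 <- parse_structure(mk(4.4))
  expect_equal(nrow(extract_contacts(s1, "A", "B")), 1)
  s2 <- parse_structure(mk(4.6))
  expect_equal(nrow(extract_contacts(s2, "A", "B")), 0)
  expect_error(extract_contacts(s1, "A", "Z"), "chain")
})

test_that("extract_contacts equals the brute-force all-pair oracle on random fixtures", {
  set.seed(401)
  for (rep in 1:100) {
    plan <- sample(c("disulfide", "salt_bridge", "hydrogen_bond"),
                   sample(0:2, 1))
    toy <- make_toy_dimer(list(seed = rep, len_A = 12, len_B = 12,
                               n_contact_A = sample(1:3, 1),
                               n_contact_B = sample(1:3, 1),
                               special_bond_plan = plan))
    s <- parse_structure(toy$pdb)
    got <- extract_contacts(s, "A", "B")
    want <- oracle_contacts(s, "A", "B")
    expect_equal(got$posA, want$posA)
    expect_equal(got$posB, want$posB)
    expect_equal(got$ss, want$ss)
    expect_equal(got$sb, want$sb)
    expect_equal(got$bs, want$bs)
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-10)
  }
})

test_that("contact relation is symmetric under chain swap", {
  f <- fix_toy()
  ab <- extract_contacts(f$s, "A", "B")
  ba <- extract_contacts(f$s, "B", "A")
  key_ab <- paste(ab$posA, ab$posB)
  key_ba <- paste(ba$posB, ba$posA)
  expect_setequal(key_ab, key_ba)
  ba <- ba[match(key_ab, key_ba), ]
  expect_equal(ab$ss, ba$ss)
  expect_equal(ab$sb, ba$bs)   # classes transpose
  expect_equal(ab$bs, ba$sb)
  expect_equal(ab$min_distance, ba$min_distance)
})

test_that("special-bond rules fire on constructed geometry with correct precedence", {
  pdb <- c(
    # pair 1: Cys SG-SG at 2.05 -> disulfide
    "ATOM      1  CB  CYS A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  SG  CYS A   1       0.000   1.000   0.000  1.00  0.00           S",
    "ATOM      3  CB  CYS B   1       0.000   4.050   0.000  1.00  0.00           C",
    "ATOM      4  SG  CYS B   1       0.000   3.050   0.000  1.00  0.00           S",
    # pair 2: Lys NZ to Glu OE1 at 3.0 -> salt bridge (not mere H-bond)
    "ATOM      5  NZ  LYS A   2      50.000   0.000   0.000  1.00  0.00           N",
    "ATOM      6  OE1 GLU B   2      50.000   3.000   0.000  1.00  0.00           O",
    # pair 3: Ser OG to backbone O at 2.9 -> hydrogen bond
    "ATOM      7  OG  SER A   3     100.000   0.000   0.000  1.00  0.00           O",
    "ATOM      8  O   GLY B   3     100.000   2.900   0.000  1.00  0.00           O",
    # pair 4: plain carbon contact -> none
    "ATOM      9  CB  LEU A   4     150.000   0.000   0.000  1.00  0.00           C",
    "ATOM     10  CB  MET B   4     150.000   4.000   0.000  1.00  0.00           C",
    "END")
  s <- parse_structure(pdb)
  pairs <- extract_contacts(s, "A", "B")
  pairs <- detect_special_bonds(pairs, s, "A", "B")
  bond <- setNames(pairs$special_bond, pairs$posA)
  expect_equal(bond[["1"]], "disulfide")
  expect_equal(bond[["2"]], "salt_bridge")
  expect_equal(bond[["3"]], "hydrogen_bond")
  expect_equal(bond[["4"]], "none")
  # deterministic and order-independent
  shuf <- pairs[rev(seq_len(nrow(pairs))), ]
  again <- detect_special_bonds(shuf, s, "A", "B")
  expect_equal(setNames(again$special_bond, again$posA), bond[as.character(again$posA)])
})

test_that("generated toy dimers round-trip: planned contacts are exactly recovered", {
  f <- fix_toy()
  got <- f$t$contact_pairs
  expect_equal(paste(got$posA, got$posB),
               paste(f$toy$truth$posA, f$toy$truth$posB))
  expect_equal(got$special_bond, f$toy$truth$special_bond)
  expect_equal(sort(f$t$contact_residues_A), f$toy$contact_positions_A)
})

test_that("validate_template applies the strict extensiveness thresholds", {
  f <- fix_toy()
  expect_true(validate_template(f$t)$accept)
  # boundary: CP = 26 accepted, CP = 25 rejected (strictly more than 25)
  t26 <- f$t; t26$CP <- 26L
  expect_true(validate_template(t26)$accept)
  t25 <- f$t; t25$CP <- 25L
  v <- validate_template(t25)
  expect_false(v$accept)
  expect_match(v$reasons, "not more than 25")
  # contact-residue rule
  t4 <- f$t; t4$contact_residues_B <- t4$contact_residues_B[1:4]
  v4 <- validate_template(t4)
  expect_false(v4$accept)
  expect_match(v4$reasons, "chain B")
  # short chains
  tshort <- f$t; tshort$chainA_seq <- substr(tshort$chainA_seq, 1, 29)
  expect_false(validate_template(tshort)$accept)
  # an accepted template satisfies its own invariants
  ok <- validate_template(f$t)
  expect_true(ok$accept)
  expect_true(f$t$CP > 25 && f$t$CP == nrow(f$t$contact_pairs))
  expect_true(all(f$t$contact_pairs$posA %in% f$t$contact_residues_A))
  expect_true(all(f$t$contact_pairs$posB %in% f$t$contact_residues_B))
})

test_that("deduplicate_library clusters near-identical templates and keeps the larger interface", {
  mk <- function(seed, nA = 6, len = 60) {
    toy <- make_toy_dimer(list(seed = seed, len_A = len, len_B = len,
                               n_contact_A = nA))
    build_template(parse_structure(toy$pdb, id = sprintf("t%d_%d_%d", seed, nA, len)),
                   "A", "B")
  }
  a <- mk(1); b <- mk(1, nA = 5); c <- mk(99)
  # a and b differ at one chain A residue (identity 59/60 > 0.98); c unrelated
  expect_equal(length(deduplicate_library(list(a, a))), 1)
  kept <- deduplicate_library(list(a, b, c))
  expect_equal(length(kept), 2)
  # larger-CP representative retained for the a/b cluster
  expect_true(a$template_id %in% vapply(kept, `[[`, "", "template_id"))
  # identity below threshold: both retained (short chains, 29/30 = 0.967)
  a30 <- mk(1, len = 30); b30 <- mk(1, nA = 5, len = 30)
  expect_equal(length(deduplicate_library(list(a30, b30))), 2)
})

test_that("template library bundle round-trips through JSON", {
  f <- fix_toy()
  path <- tempfile(fileext = ".json")
  write_template_library(list(f$t), path)
  back <- read_template_library(path)
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$chainA_seq, f$t$chainA_seq)
  expect_equal(back[[1]]$CP, f$t$CP)
  expect_equal(as.data.frame(back[[1]]$contact_pairs)$special_bond,
               f$t$contact_pairs$special_bond)
})
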