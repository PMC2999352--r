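#' Parse a PDB-format dimer structure
#'
#' Reads PDB text into a `Structure`: heavy atoms only (hydrogens and
#' deuteriums dropped), alternate locations resolved to the highest-occupancy
#' conformer (ties keep the first listed), residues keyed by
#' (chain, resSeq, iCode) and renumbered 1..n per chain in order of
#' appearance. Selenomethionine and a few other common modified residues are
#' mapped to their standard parents; anything else non-standard is kept in
#' the coordinates but flagged (`aa` is `NA`) and excluded from downstream
#' contact scoring.
#'
#' @param pdb_text Character scalar (or vector of lines) of PDB-format text
#'   containing at least one ATOM record.
#' @param id Structure identifier; defaults to "structure".
#' @return An object of class `Structure`: a list with `id`, `atoms` (one row
#'   per heavy atom: chain, resno, icode, resid, aa, pos, elety, elesy,
#'   x, y, z, sidechain) and `chains` (per chain id: `seq`, `aa`, `resno`).
#' @export
parse_structure <- function(pdb_text, id = "structure") {
  lines <- if (length(pdb_text) == 1L) strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines)))
    stop("no ATOM records found: not a protein structure")
  # fixed-column sanity check so malformed records fail with a line number
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed ATOM record at line %d: shorter than coordinate fields", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("malformed ATOM record at line %d: non-numeric coordinates", i))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  # protein residues only: standard or mapped non-standard 3-letter codes
  known <- at$resid %in% AA3 | at$resid %in% names(NONSTANDARD_PARENT)
  at <- at[at$type == "ATOM" | (at$type == "HETATM" & known), , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein chains in structure")
  # heavy atoms only
  ele <- toupper(ifelse(is.na(at$elesy) | at$elesy == "", NA, trimws(at$elesy)))
  guess_h <- grepl("^[0-9]*H", trimws(at$elety))
  at <- at[!(ele %in% c("H", "D")) & !(is.na(ele) & guess_h), , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms in structure")
  at$icode <- ifelse(is.na(at$insert), "", at$insert)
  # altloc: highest occupancy wins within (chain, resno, icode, atom name)
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$icode, at$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$icode, at$elety, sep = "\r")), , drop = FALSE]

  parent <- ifelse(at$resid %in% names(NONSTANDARD_PARENT),
                   NONSTANDARD_PARENT[at$resid], at$resid)
  aa <- names(AA3)[match(parent, AA3)]
  atoms <- data.frame(chain = at$chain, resno = at$resno, icode = at$icode,
                      resid = at$resid, aa = aa,
                      elety = trimws(at$elety),
                      elesy = toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy))),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms$sidechain <- !(atoms$elety %in% BACKBONE_ATOMS)
  # 1-based residue positions per chain, insertion codes collapsed in order
  atoms$pos <- NA_integer_
  chains <- list()
  for (ch in unique(atoms$chain)) {
    idx <- which(atoms$chain == ch)
    rkey <- paste(atoms$resno[idx], atoms$icode[idx], sep = "\r")
    atoms$pos[idx] <- match(rkey, unique(rkey))
    first <- idx[!duplicated(rkey)]
    chains[[ch]] <- list(
      aa = atoms$aa[first],
      seq = paste(ifelse(is.na(atoms$aa[first]), "X", atoms$aa[first]), collapse = ""),
      resno = atoms$resno[first], icode = atoms$icode[first])
  }
  structure(list(id = id, atoms = atoms, chains = chains), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure", x$id, "-", length(x$chains), "chain(s):",
      paste(sprintf("%s (%d aa)", names(x$chains),
                    vapply(x$chains, function(c) length(c$aa), 1L)),
            collapse = ", "), "\n")
  invisible(x)
}

# all-vs-all inter-chain heavy-atom distance table for two chains
.cross_atoms <- function(s, chainA, chainB) {
  for (ch in c(chainA, chainB))
    if (!ch %in% names(s$chains)) stop("chain '", ch, "' not present in structure")
  list(A = s$atoms[s$atoms$chain == chainA, , drop = FALSE],
       B = s$atoms[s$atoms$chain == chainB, , drop = FALSE])
}

.dist_matrix <- function(a, b) {
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 + outer(a$z, b$z, "-")^2
  sqrt(d2)
}

#' Extract inter-chain residue contact pairs
#'
#' A residue pair is in contact when any heavy-atom pair across the two
#' chains lies within `cutoff` (default 4.5 angstrom). Each pair carries its
#' contact classes, determined by the atom types contributing contacts:
#' `ss` (sidechain-sidechain), `sb` (sidechain of A to backbone of B) and
#' `bs` (backbone of A to sidechain of B). Sidechain atoms are all heavy
#' atoms outside the backbone set N, CA, C, O (and OXT); glycine therefore
#' contributes backbone-only classes. Pairs whose only contacts are
#' backbone-to-backbone carry no scoreable class and are omitted from the
#' pair list (their residues still satisfy the contact-residue definition;
#' see [build_template()]).
#'
#' @param s A `Structure`.
#' @param chainA,chainB Chain identifiers.
#' @param cutoff Heavy-atom distance threshold in angstrom.
#' @return data.frame with one row per contact pair: `posA`, `posB`, `resA`,
#'   `resB` (1-letter), `ss`, `sb`, `bs` (logical class flags),
#'   `special_bond` (initialised "none"), `min_distance`.
#' @export
extract_contacts <- function(s, chainA, chainB, cutoff = 4.5) {
  cx <- .cross_atoms(s, chainA, chainB)
  a <- cx$A; b <- cx$B
  d <- .dist_matrix(a, b)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(.empty_contacts())
  df <- data.frame(posA = a$pos[hit[, 1]], posB = b$pos[hit[, 2]],
                   scA = a$sidechain[hit[, 1]], scB = b$sidechain[hit[, 2]],
                   dist = d[hit])
  keys <- paste(df$posA, df$posB)
  agg <- function(v, f) as.vector(tapply(v, factor(keys, levels = unique(keys)), f))
  out <- data.frame(posA = agg(df$posA, function(v) v[1]),
                    posB = agg(df$posB, function(v) v[1]))
  out$ss <- agg(df$scA & df$scB, any)
  out$sb <- agg(df$scA & !df$scB, any)
  out$bs <- agg(!df$scA & df$scB, any)
  out$min_distance <- agg(df$dist, min)
  out$resA <- cx$A$aa[match(paste(chainA, out$posA), paste(cx$A$chain, cx$A$pos))]
  out$resB <- cx$B$aa[match(paste(chainB, out$posB), paste(cx$B$chain, cx$B$pos))]
  out$special_bond <- "none"
  out <- out[out$ss | out$sb | out$bs, , drop = FALSE]
  out <- out[order(out$posA, out$posB), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("posA", "posB", "resA", "resB", "ss", "sb", "bs",
          "special_bond", "min_distance")]
}

.empty_contacts <- function() {
  data.frame(posA = integer(), posB = integer(), resA = character(),
             resB = character(), ss = logical(), sb = logical(),
             bs = logical(), special_bond = character(),
             min_distance = numeric())
}

#' Annotate special bonds on contact pairs
#'
#' Geometric rules (configurable; the common structural-biology defaults):
#' disulfide when Cys SG-SG <= 2.5 A; salt bridge when a charged-group
#' nitrogen of Arg/Lys/His lies <= 4.0 A from a charged-group oxygen of
#' Asp/Glu; hydrogen bond when any inter-residue N/O atom pair is <= 3.5 A.
#' Precedence: disulfide > salt bridge > hydrogen bond. Annotation only;
#' pairs are returned in the input order with `special_bond` filled.
#'
#' @param pairs Contact pairs from [extract_contacts()].
#' @param s The `Structure` the pairs came from.
#' @param chainA,chainB Chain identifiers used for extraction.
#' @param hbond_max,salt_max,ss_max Distance cutoffs (angstrom).
#' @return `pairs` with the `special_bond` column set.
#' @export
detect_special_bonds <- function(pairs, s, chainA, chainB,
                                 hbond_max = 3.5, salt_max = 4.0, ss_max = 2.5) {
  if (nrow(pairs) == 0L) return(pairs)
  cx <- .cross_atoms(s, chainA, chainB)
  for (k in seq_len(nrow(pairs))) {
    ra <- cx$A[cx$A$pos == pairs$posA[k], , drop = FALSE]
    rb <- cx$B[cx$B$pos == pairs$posB[k], , drop = FALSE]
    d <- .dist_matrix(ra, rb)
    bond <- "none"
    # disulfide
    ia <- ra$elety == "SG" & ra$resid == "CYS"
    ib <- rb$elety == "SG" & rb$resid == "CYS"
    if (any(ia) && any(ib) && min(d[ia, ib, drop = FALSE]) <= ss_max) {
      bond <- "disulfide"
    } else {
      # salt bridge, either orientation
      sbq <- function(rn, ro, dm) {
        ni <- rn$elety %in% (BASIC_N_ATOMS[[rn$resid[1]]] %||% character())
        oi <- ro$elety %in% (ACIDIC_O_ATOMS[[ro$resid[1]]] %||% character())
        any(ni) && any(oi) && min(dm[ni, oi, drop = FALSE]) <= salt_max
      }
      if (sbq(ra, rb, d) || sbq(rb, ra, t(d))) {
        bond <- "salt_bridge"
      } else {
        no_a <- ra$elesy %in% c("N", "O")
        no_b <- rb$elesy %in% c("N", "O")
        if (any(no_a) && any(no_b) &&
            min(d[no_a, no_b, drop = FALSE]) <= hbond_max)
          bond <- "hydrogen_bond"
      }
    }
    pairs$special_bond[k] <- bond
  }
  pairs
}

#' Build a template interface from a parsed dimer
#'
#' Extracts contacts at `cutoff`, annotates special bonds and assembles the
#' `TemplateInterface` used for candidate scoring. Contact-residue sets
#' follow the any-heavy-atom rule (a residue with at least one heavy atom
#' within `cutoff` of the partner chain), so they can be marginally larger
#' than the positions occurring in classed contact pairs.
#'
#' @param s A `Structure`.
#' @param chainA,chainB Chain identifiers.
#' @param cutoff Contact distance threshold (angstrom).
#' @param template_id Identifier; defaults to `<structure id>_<A><B>`.
#' @param ... Passed to [detect_special_bonds()].
#' @return A `TemplateInterface`: list with `template_id`, `chainA`/`chainB`
#'   ids, `chainA_seq`/`chainB_seq`, `contact_residues_A`/`_B` (integer
#'   position sets), `contact_pairs` and `CP`.
#' @export
build_template <- function(s, chainA, chainB, cutoff = 4.5,
                           template_id = NULL, ...) {
  pairs <- extract_contacts(s, chainA, chainB, cutoff)
  pairs <- detect_special_bonds(pairs, s, chainA, chainB, ...)
  cx <- .cross_atoms(s, chainA, chainB)
  d <- .dist_matrix(cx$A, cx$B)
  close <- d <= cutoff
  structure(list(
    template_id = template_id %||% paste0(s$id, "_", chainA, chainB),
    chainA = chainA, chainB = chainB,
    chainA_seq = s$chains[[chainA]]$seq,
    chainB_seq = s$chains[[chainB]]$seq,
    contact_residues_A = sort(unique(cx$A$pos[apply(close, 1, any)])),
    contact_residues_B = sort(unique(cx$B$pos[apply(close, 2, any)])),
    contact_pairs = pairs, CP = nrow(pairs)), class = "TemplateInterface")
}

#' @export
print.TemplateInterface <- function(x, ...) {
  cat(sprintf("TemplateInterface %s: %d+%d aa, %d+%d contact residues, CP=%d (%d special)\n",
              x$template_id, nchar(x$chainA_seq), nchar(x$chainB_seq),
              length(x$contact_residues_A), length(x$contact_residues_B),
              x$CP, sum(x$contact_pairs$special_bond != "none")))
  invisible(x)
}

#' Validate a template interface
#'
#' A template is retained when both chains have at least `min_chain_len`
#' residues, both chains contribute at least `min_contact_res` contact
#' residues, and the interface has strictly more than `min_cp` contact
#' pairs — the extensiveness filters applied when building a dimer template
#' library.
#'
#' @param t A `TemplateInterface`.
#' @param min_chain_len Minimum chain length (residues).
#' @param min_contact_res Minimum contact residues per chain.
#' @param min_cp Contact-pair count must exceed this (strict).
#' @return list(accept = logical, reasons = character vector of violated
#'   rules, empty when accepted).
#' @export
validate_template <- function(t, min_chain_len = 30, min_contact_res = 5,
                              min_cp = 25) {
  reasons <- character()
  if (nchar(t$chainA_seq) < min_chain_len || nchar(t$chainB_seq) < min_chain_len)
    reasons <- c(reasons, sprintf("chain shorter than %d residues", min_chain_len))
  if (length(t$contact_residues_A) < min_contact_res)
    reasons <- c(reasons, sprintf("chain A has fewer than %d contact residues", min_contact_res))
  if (length(t$contact_residues_B) < min_contact_res)
    reasons <- c(reasons, sprintf("chain B has fewer than %d contact residues", min_contact_res))
  if (t$CP <= min_cp)
    reasons <- c(reasons, sprintf("contact pairs (%d) not more than %d", t$CP, min_cp))
  list(accept = length(reasons) == 0L, reasons = reasons)
}

# global percent identity of two sequences, BLOSUM62 11/1
.global_identity <- function(s1, s2) {
  if (s1 == s2) return(1)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2), type = "global",
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 11, gapExtension = 1)
  Biostrings::pid(aln, type = "PID3") / 100
}

#' Remove duplicate templates from a library
#'
#' Two templates are duplicates when the global sequence identities of both
#' matched chains exceed `identity_threshold` (default 0.98). Duplicates are
#' clustered transitively; within a cluster the template with the largest
#' contact-pair count is retained, ties broken by lexicographic template id.
#'
#' @param ts list of `TemplateInterface`.
#' @param identity_threshold Fractional identity above which chains count as
#'   duplicated.
#' @return The retained subset of `ts`, in input order.
#' @export
deduplicate_library <- function(ts, identity_threshold = 0.98) {
  n <- length(ts)
  if (n <= 1L) return(ts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    idA <- .global_identity(ts[[i]]$chainA_seq, ts[[j]]$chainA_seq)
    idB <- .global_identity(ts[[i]]$chainB_seq, ts[[j]]$chainB_seq)
    if (idA > identity_threshold && idB > identity_threshold)
      parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, 1L)
  keep <- logical(n)
  for (r in unique(roots)) {
    members <- which(roots == r)
    cps <- vapply(ts[members], function(t) t$CP, 1)
    ids <- vapply(ts[members], function(t) t$template_id, "")
    keep[members[order(-cps, ids)][1]] <- TRUE
  }
  ts[keep]
}

#' Write / read a template library bundle
#'
#' Serialises templates as a versioned JSON bundle: per-template sequences
#' and the contact-pair table (positions, classes, special bond, minimum
#' distance).
#'
#' @param ts list of `TemplateInterface`.
#' @param path Output JSON file.
#' @return `path`, invisibly (`write_template_library`); list of
#'   `TemplateInterface` (`read_template_library`).
#' @export
write_template_library <- function(ts, path) {
  bundle <- list(format = "interolog3d-templates", version = 1L,
                 templates = lapply(ts, function(t) {
                   t$contact_pairs <- as.list(t$contact_pairs)
                   unclass(t)
                 }))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template_library
#' @export
read_template_library <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(bundle$format, "interolog3d-templates"))
    stop("not a template library bundle: ", path)
  tpls <- bundle$templates
  lapply(seq_len(nrow(tpls)), function(i) {
    t <- lapply(as.list(tpls[i, ]), function(x)
      if (is.list(x) && !is.data.frame(x)) unlist(x) else x)
    cp <- tpls$contact_pairs[i, ]
    t$contact_pairs <- as.data.frame(lapply(cp, function(x) unlist(x)),
                                     stringsAsFactors = FALSE)
    t$CP <- as.integer(t$CP)
    structure(t, class = "TemplateInterface")
  })
}
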