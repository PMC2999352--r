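#' Build cross-species interface alignments (star alignment)
#'
#' For each species, the accepted candidate pair with the highest Z is
#' chosen as the interolog; each of its two chain alignments is projected
#' onto template coordinates (columns = template positions; candidate
#' insertions relative to the template are dropped). The template chain is
#' the center (first) row of each alignment.
#'
#' @param t A `TemplateInterface`.
#' @param accepted Accepted candidate data.frame (needs `idA`, `idB`,
#'   `species`, `Z`).
#' @param alignments Named list of `ChainAlignment`s keyed
#'   `<id>\r<species>\r<chain>` as produced by [run_pipeline()], or a
#'   function(id, species, chain) returning the stored alignment.
#' @return list(A =, B =): each an `InterologMSA` — a character matrix with
#'   one row per species plus the template center row, one column per
#'   template position.
#' @export
build_interolog_msa <- function(t, accepted, alignments) {
  if (nrow(accepted) == 0L) stop("no accepted candidates")
  get_aln <- if (is.function(alignments)) alignments else
    function(id, species, chain) alignments[[paste(id, species, chain, sep = "\r")]]
  best <- accepted[order(accepted$species, -accepted$Z), , drop = FALSE]
  best <- best[!duplicated(best$species), , drop = FALSE]
  project <- function(a, L) {
    s <- strsplit(a$cand_seq, "")[[1]]
    row <- rep("-", L)
    ok <- !is.na(a$map)
    row[ok] <- s[a$map[ok]]
    row
  }
  one_chain <- function(chain) {
    seqs <- if (chain == "A") t$chainA_seq else t$chainB_seq
    L <- nchar(seqs)
    m <- matrix(strsplit(seqs, "")[[1]], nrow = 1,
                dimnames = list("template", NULL))
    for (i in seq_len(nrow(best))) {
      id <- if (chain == "A") best$idA[i] else best$idB[i]
      a <- get_aln(id, best$species[i], chain)
      if (is.null(a)) stop("missing stored alignment for ", id)
      m <- rbind(m, project(a, L))
      rownames(m)[nrow(m)] <- best$species[i]
    }
    structure(m, class = c("InterologMSA", "matrix"))
  }
  list(A = one_chain("A"), B = one_chain("B"))
}

#' Classify interface positions by conservation and special bonds
#'
#' A template contact position is `conserved` when at least
#' `conservation_threshold` of the non-gap interolog rows carry the template
#' residue; it is an `hbond` position when it participates in a template
#' contact pair whose special bond is a hydrogen bond or salt bridge.
#' Categories: `hbond`, `conserved`, `hbond_and_conserved`, `other`.
#'
#' @param msa An `InterologMSA` for one chain.
#' @param t The `TemplateInterface`.
#' @param chain "A" or "B".
#' @param conservation_threshold Fraction of matching rows required.
#' @return data.frame: `position`, `template_res`, `conserved`, `hbond`,
#'   `category`, `groups` (comma-joined physicochemical groups of the
#'   column's residues, one entry per row of the alignment).
#' @export
classify_positions <- function(msa, t, chain = c("A", "B"),
                               conservation_threshold = 0.7) {
  chain <- match.arg(chain)
  contacts <- if (chain == "A") t$contact_residues_A else t$contact_residues_B
  cp <- t$contact_pairs
  hb_pos <- if (chain == "A")
    cp$posA[cp$special_bond %in% c("hydrogen_bond", "salt_bridge")]
  else cp$posB[cp$special_bond %in% c("hydrogen_bond", "salt_bridge")]
  rows <- msa[-1, , drop = FALSE]   # interolog rows, template excluded
  out <- lapply(contacts, function(p) {
    tpl <- msa[1, p]
    col <- rows[, p]
    nong <- col[col != "-"]
    conserved <- length(nong) > 0 && mean(nong == tpl) >= conservation_threshold
    hbond <- p %in% hb_pos
    category <- if (hbond && conserved) "hbond_and_conserved"
      else if (hbond) "hbond" else if (conserved) "conserved" else "other"
    grp <- vapply(msa[, p], function(a)
      if (a == "-") "-" else residue_group(a), "")
    data.frame(position = p, template_res = tpl, conserved = conserved,
               hbond = hbond, category = category,
               groups = paste(grp, collapse = ","), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Physicochemical group of a residue
#'
#' Maps the 20 standard residues onto the 7 groups used to colour the
#' interface-evolution alignment: polar positive (H, R, K), polar negative
#' (D, E), polar neutral (S, T, N, Q), cysteine (C), non-polar aliphatic
#' (A, V, L, I, M), non-polar aromatic (F, Y, W) and others (G, P).
#'
#' @param aa 1-letter residue code (vectorised).
#' @return Group name(s).
#' @export
residue_group <- function(aa) {
  map <- unlist(lapply(names(RESIDUE_GROUPS), function(g)
    setNames(rep(g, length(RESIDUE_GROUPS[[g]])), RESIDUE_GROUPS[[g]])))
  out <- map[aa]
  if (anyNA(out)) stop("non-standard residue: ",
                       paste(aa[is.na(out)], collapse = ", "))
  unname(out)
}

#' Write an interface-evolution report
#'
#' TSV output is byte-stable across runs; HTML output renders the category
#' and physicochemical-group colours of the alignment legend (hydrogen-bond
#' residues green, conserved orange, both yellow, other gray).
#'
#' @param msas list(A =, B =) of `InterologMSA`.
#' @param annotations list(A =, B =) of [classify_positions()] tables.
#' @param path Output file.
#' @param format "tsv" or "html".
#' @return `path`, invisibly.
#' @export
write_report <- function(msas, annotations, path, format = c("tsv", "html")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("chain\tposition\ttemplate_res\tconserved\thbond\tcategory\tgroups", con)
    for (ch in c("A", "B")) {
      ann <- annotations[[ch]]
      for (i in seq_len(NROW(ann)))
        writeLines(paste(ch, ann$position[i], ann$template_res[i],
                         tolower(ann$conserved[i]), tolower(ann$hbond[i]),
                         ann$category[i], ann$groups[i], sep = "\t"), con)
    }
    return(invisible(path))
  }
  cat_col <- c(hbond = "#2e8b57", conserved = "#ff8c00",
               hbond_and_conserved = "#ffd700", other = "#a9a9a9")
  grp_col <- c(polar_positive = "#4169e1", polar_negative = "#dc143c",
               polar_neutral = "#228b22", cysteine = "#ffd700",
               nonpolar_aliphatic = "#808080", nonpolar_aromatic = "#ff69b4",
               others = "#8b4513", "-" = "#ffffff")
  html <- c("<html><head><title>Interface evolution report</title></head><body>")
  for (ch in c("A", "B")) {
    msa <- msas[[ch]]; ann <- annotations[[ch]]
    html <- c(html, sprintf("<h2>Chain %s</h2><table>", ch))
    catmap <- setNames(ann$category, ann$position)
    for (r in seq_len(nrow(msa))) {
      cells <- vapply(seq_len(ncol(msa)), function(p) {
        a <- msa[r, p]
        col <- if (r == 1 && as.character(p) %in% names(catmap))
          cat_col[[catmap[[as.character(p)]]]]
        else if (a != "-") grp_col[[residue_group(a)]] else "#ffffff"
        sprintf("<td style=\"background:%s\">%s</td>", col, a)
      }, "")
      html <- c(html, sprintf("<tr><th>%s</th>%s</tr>", rownames(msa)[r],
                              paste(cells, collapse = "")))
    }
    html <- c(html, "</table>")
  }
  html <- c(html, "</body></html>")
  writeLines(html, path)
  invisible(path)
}
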