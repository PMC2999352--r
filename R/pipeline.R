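#' Default run configuration
#'
#' All thresholds of the method with their standard values: contact cutoff
#' 4.5 angstrom, minimum chain length 30, at least 5 contact residues per
#' chain and more than 25 contact pairs, candidate identity > 0.30 and
#' CR > 0.5, couple-conserved weight w = 3, acceptance at Z >= 3.0 within
#' the per-species top 25, and a null model of 10,000 randomized interfaces
#' mutating 60% of contact residues. Override any entry via `...`.
#'
#' @param ... Named overrides.
#' @return A `RunConfig` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    cutoff = 4.5, min_chain_len = 30, min_contact_res = 5, min_cp = 25,
    min_identity = 0.30, min_cr = 0.5, w = 3, z_min = 3.0, rank_max = 25,
    null_n = 10000, null_fraction = 0.6,
    conservation_threshold = 0.7, cc_threshold = 0.4, evalue_max = 1e-10,
    gap_open = 11, gap_extend = 1, pseudocount = 0.5,
    hbond_max = 3.5, salt_max = 4.0, ss_max = 2.5,
    normalize = "sum", seed = 1L,
    header_regex = "^([^|]+)\\|(.+)$")
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full interolog-mapping pipeline
#'
#' Template build, profile construction, database scan, scoring, per-species
#' ranking, acceptance and interface-evolution reporting, in order. Profiles
#' default to single-sequence profiles of the template chains (MSAs can be
#' supplied). The scoring matrices default to matrices derived from the
#' training library (`training`, a list of annotated templates; the query
#' template itself when omitted).
#'
#' @param config A `RunConfig` (see [default_config()]).
#' @param pdb PDB text (character vector) or a file path.
#' @param chains Length-2 character vector naming chains A and B.
#' @param db FASTA path or a data.frame from [read_species_fasta()].
#' @param training Optional list of `TemplateInterface` for matrix
#'   derivation.
#' @param matrices Optional precomputed `MatrixSet` (overrides `training`).
#' @param msas Optional list(A =, B =) of star MSAs for profile building.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return list: `template`, `matrices`, `profiles`, `null_model`,
#'   `candidates` (ranked), `accepted`, `msa`, `annotations`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), pdb, chains = c("A", "B"),
                         db, training = NULL, matrices = NULL, msas = NULL,
                         out_dir = NULL) {
  s <- .stage("parse-structure", {
    txt <- if (length(pdb) == 1L && file.exists(pdb)) readLines(pdb) else pdb
    parse_structure(txt)
  })
  t <- .stage("build-template",
    build_template(s, chains[1], chains[2], cutoff = config$cutoff,
                   hbond_max = config$hbond_max, salt_max = config$salt_max,
                   ss_max = config$ss_max))
  val <- validate_template(t, config$min_chain_len, config$min_contact_res,
                           config$min_cp)
  if (!val$accept)
    stop("pipeline stage 'validate-template' failed: ",
         paste(val$reasons, collapse = "; "), call. = FALSE)
  m <- matrices %||% .stage("derive-matrices",
    derive_matrix_set(if (is.null(training)) list(t) else training,
                      pseudocount = config$pseudocount))
  blosum <- load_substitution_matrix("BLOSUM62")
  profiles <- .stage("build-profiles", list(
    A = build_profile(msas$A %||% t$chainA_seq, chain = "A"),
    B = build_profile(msas$B %||% t$chainB_seq, chain = "B")))
  dbdf <- .stage("read-database", {
    if (is.character(db)) read_species_fasta(db, config$header_regex) else db
  })
  nm <- .stage("null-model",
    build_null_model(t, m, profiles, blosum, n = config$null_n,
                     fraction = config$null_fraction, seed = config$seed,
                     w = config$w, normalize = config$normalize))
  cands <- .stage("scan-and-score",
    enumerate_candidates(t, dbdf, profiles, m, nm, blosum, config))
  cands <- rank_within_species(cands)
  accepted <- apply_acceptance(cands, config$z_min, config$rank_max)
  msa <- NULL; ann <- NULL
  if (nrow(accepted) > 0) {
    store <- new.env()
    for (i in seq_len(nrow(dbdf))) for (ch in c("A", "B")) {
      p <- profiles[[ch]]
      a <- align_profile(p, dbdf$seq[i], config$gap_open, config$gap_extend,
                         id = dbdf$id[i], species = dbdf$species[i])
      assign(paste(dbdf$id[i], dbdf$species[i], ch, sep = "\r"), a, store)
    }
    msa <- build_interolog_msa(t, accepted, function(id, species, chain)
      get0(paste(id, species, chain, sep = "\r"), store))
    ann <- list(A = classify_positions(msa$A, t, "A", config$conservation_threshold),
                B = classify_positions(msa$B, t, "B", config$conservation_threshold))
  }
  manifest <- version_manifest(config, template_id = t$template_id,
                               n_db = nrow(dbdf), n_candidates = nrow(cands),
                               n_accepted = nrow(accepted))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_template_library(list(t), file.path(out_dir, "template.json"))
    write_predictions(cands, file.path(out_dir, "predictions.tsv"))
    if (!is.null(ann))
      write_report(msa, ann, file.path(out_dir, "evolution.tsv"), "tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(template = t, matrices = m, profiles = profiles, null_model = nm,
       candidates = cands, accepted = accepted, msa = msa,
       annotations = ann, manifest = manifest)
}

#' Provenance manifest for a run
#'
#' Records the package version, R version, configuration (with a stable
#' hash), seeds and any extra fields; two runs with identical configuration
#' produce identical manifests apart from the timestamp.
#'
#' @param config A `RunConfig`.
#' @param ... Extra named fields recorded verbatim.
#' @return list with `package`, `version`, `r_version`, `config`,
#'   `config_hash`, `seed`, `timestamp` and the extras.
#' @export
version_manifest <- function(config = default_config(), ...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), tmp)
  hash <- unname(tools::md5sum(tmp))
  c(list(package = "interolog3d",
         version = as.character(utils::packageVersion("interolog3d")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = unclass(config), config_hash = hash,
         seed = config$seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    list(...))
}
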