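#' Pipeline configuration
#'
#' Collects every path and numeric cutoff of the analysis in one place.
#' Thresholds default to the values the pipeline is built around: average
#' interaction probability 0.9, total spectra 2, peptide length 7, REF
#' member threshold 0.3 and REF report threshold 0.1.
#'
#' @param fasta,counts,design,reference Input file paths (FASTA database,
#'   count-matrix TSV, design TSV, reference-set list). May be `NULL` in
#'   fixture mode, where [make_fixtures()] fills them in.
#' @param peptides Optional long-form peptide evidence TSV.
#' @param out_dir Output directory for reports.
#' @param probability_threshold,min_total_spectra,min_peptide_length
#'   Identification/scoring cutoffs.
#' @param ref_member_threshold,ref_report_threshold REF cutoffs for
#'   candidate nomination.
#' @param pseudocount Background-model pseudocount per control run.
#' @param inclusive_threshold Probability threshold comparison is `>=` when
#'   `TRUE` (default).
#' @param filter_mode See [apply_identification_filters()].
#' @param nsaf_method AP-side replicate handling, see [condition_profile()].
#' @param seed Integer seed used in fixture mode.
#' @param sim A [sim_config()] for fixture mode (built from `seed` when
#'   `NULL`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, counts = NULL, design = NULL,
                            reference = NULL, peptides = NULL,
                            out_dir = "apmsref-out",
                            probability_threshold = 0.9,
                            min_total_spectra = 2L, min_peptide_length = 7L,
                            ref_member_threshold = 0.3,
                            ref_report_threshold = 0.1, pseudocount = 0.1,
                            inclusive_threshold = TRUE,
                            filter_mode = "total", nsaf_method = "mean",
                            seed = 1L, sim = NULL) {
  stopifnot(probability_threshold > 0, probability_threshold <= 1,
            min_total_spectra >= 0, min_peptide_length >= 1,
            ref_member_threshold >= ref_report_threshold,
            ref_report_threshold >= 0, pseudocount > 0)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat-key YAML whose keys mirror the arguments of [pipeline_config()];
#' keys under `sim:` are passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- do.call(pipeline_config, y)
  if (!is.null(sim_args)) {
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cfg$sim <- do.call(sim_config, sim_args)
  }
  cfg
}

#' Write a complete synthetic demo dataset to disk
#'
#' Generates a protein database and AP-MS experiment under the
#' configuration's simulation settings and writes the same formats the
#' readers consume: FASTA database, count-matrix TSV, design TSV, a
#' reference-set list, peptide evidence TSV and a ground-truth TSV.
#'
#' @param config A [pipeline_config()] (its `sim` and `out_dir` are used).
#' @return The updated config with input paths pointing at the fixtures,
#'   invisibly.
#' @export
make_fixtures <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_protein_db(config$sim)
  run <- simulate_apms_counts(sim, config$sim)
  ev <- simulate_peptide_evidence(sim, run$matrix, config$sim)
  paths <- file.path(config$out_dir,
                     c(fasta = "database.fasta", counts = "counts.tsv",
                       design = "design.tsv", reference = "reference.txt",
                       peptides = "peptides.tsv", truth = "truth.tsv"))
  names(paths) <- c("fasta", "counts", "design", "reference", "peptides",
                    "truth")
  write_fasta(sim$db, paths[["fasta"]])
  write_count_matrix(run$matrix, paths[["counts"]])
  write_design(run$design, paths[["design"]])
  writeLines(sim$reference, paths[["reference"]])
  write_tsv(ev, paths[["peptides"]])
  write_tsv(sim$truth, paths[["truth"]])
  config$fasta <- paths[["fasta"]]
  config$counts <- paths[["counts"]]
  config$design <- paths[["design"]]
  config$reference <- paths[["reference"]]
  config$peptides <- paths[["peptides"]]
  invisible(config)
}

log_stage <- function(verbose, ...) if (verbose) message("[apmsref] ", ...)

#' Run the full analysis pipeline
#'
#' Executes identification filtering, background estimation, interaction
#' scoring, NSAF/quotient/REF computation and candidate nomination, writing
#' one TSV per report plus a JSON run manifest (configuration snapshot,
#' seed, package version, per-stage record counts). With `simulate = TRUE`
#' the inputs are first generated by [make_fixtures()].
#'
#' @param config A [pipeline_config()].
#' @param simulate Generate fixture inputs before running.
#' @param verbose Log per-stage record counts.
#' @return A list with `scores`, `qualified`, `ref_tables`, `candidates`,
#'   `isoforms` (or `NULL`), `manifest`, and the paths of the written
#'   reports.
#' @export
run_pipeline <- function(config = pipeline_config(), simulate = FALSE,
                         verbose = FALSE) {
  if (simulate) config <- make_fixtures(config)
  for (p in c("fasta", "counts", "design")) {
    if (is.null(config[[p]])) {
      stop("config error: input path '", p, "' is not set")
    }
  }
  if (is.null(config$reference)) {
    stop("config error: REF analysis requested but no reference-list path set")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  db <- read_fasta(config$fasta)
  design <- read_design(config$design)
  counts <- read_count_matrix(config$counts, design)
  reference <- read_reference_set(config$reference, db)
  peptides <- if (!is.null(config$peptides) && file.exists(config$peptides)) {
    utils::read.delim(config$peptides, sep = "\t", stringsAsFactors = FALSE)
  } else NULL
  log_stage(verbose, "inputs: ", nrow(db), " proteins, ", nrow(design),
            " runs, ", ncol(counts), " quantified accessions")

  filtered <- apply_identification_filters(
    counts, design, peptides = NULL,
    min_peptide_length = config$min_peptide_length,
    min_total_spectra = config$min_total_spectra,
    mode = config$filter_mode, verbose = verbose)
  log_stage(verbose, "identification filters: ",
            sum(colSums(filtered) > 0), " proteins with spectra remain")

  model <- estimate_background(filtered, design, alpha = config$pseudocount)
  scores <- score_interactions(filtered, design, model,
                               threshold = config$probability_threshold,
                               inclusive = config$inclusive_threshold)
  qualified <- filter_interactome(scores,
                                  min_total_spectra = config$min_total_spectra)
  for (b in unique(scores$bait_id)) {
    log_stage(verbose, "bait ", b, ": ",
              sum(scores$bait_id == b & scores$total_spectra > 0),
              " preys detected, ", sum(qualified$bait_id == b), " qualified")
  }

  ref_tables <- enrichment_analysis(filtered, design, db, reference,
                                    method = config$nsaf_method)
  candidates <- nominate_candidates(
    ref_tables, member_threshold = config$ref_member_threshold,
    report_threshold = config$ref_report_threshold)
  log_stage(verbose, "candidates: ", nrow(candidates), " reported, ",
            sum(candidates$member_like), " member-like")

  isoforms <- NULL
  if (!is.null(peptides)) {
    peptides <- peptides[nchar(peptides$peptide) >= config$min_peptide_length,
                         , drop = FALSE]
    groups <- infer_isoform_groups(db)
    isoforms <- isoform_evidence_report(peptides, db, groups)
  }

  paths <- list(
    scores = file.path(config$out_dir, "scores.tsv"),
    qualified = file.path(config$out_dir, "qualified.tsv"),
    enrichment = file.path(config$out_dir, "enrichment.tsv"),
    candidates = file.path(config$out_dir, "candidates.tsv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  write_tsv(round_numeric(scores), paths$scores)
  write_tsv(round_numeric(qualified), paths$qualified)
  enr <- enrichment_table(ref_tables, db)
  write_tsv(enr, paths$enrichment)
  write_tsv(round_numeric(candidates), paths$candidates)
  if (!is.null(isoforms)) {
    paths$isoforms <- file.path(config$out_dir, "isoforms.tsv")
    write_tsv(isoforms, paths$isoforms)
  }

  manifest <- list(
    package = "apmsref",
    version = as.character(utils::packageVersion("apmsref")),
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    sim = unclass(config$sim),
    stage_counts = list(
      proteins = nrow(db), runs = nrow(design),
      scored_pairs = nrow(scores), qualified_pairs = nrow(qualified),
      candidates = nrow(candidates),
      member_like = sum(candidates$member_like))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(scores = scores, qualified = qualified,
                 ref_tables = ref_tables, candidates = candidates,
                 isoforms = isoforms, manifest = manifest, paths = paths))
}

# Round numeric report columns to a fixed precision so reruns are
# byte-identical across platforms' default printing.
round_numeric <- function(df, digits = 6L) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

# Table-style enrichment report: one row per protein, REF per bait at two
# decimals (full precision is kept in the returned ref_tables).
enrichment_table <- function(ref_tables, db) {
  baits <- names(ref_tables)
  ids <- sort(unique(unlist(lapply(ref_tables, `[[`, "protein_id"))))
  out <- data.frame(protein_id = ids,
                    gene_symbol = db$gene_symbol[match(ids, db$protein_id)],
                    stringsAsFactors = FALSE)
  for (b in baits) {
    t <- ref_tables[[b]]
    out[[paste0("ref_", b)]] <- round(t$ref[match(ids, t$protein_id)], 2L)
  }
  in_ref <- ref_tables[[1L]]$in_reference_set[
    match(ids, ref_tables[[1L]]$protein_id)]
  out$in_reference_set <- ifelse(is.na(in_ref), FALSE, in_ref)
  ref_cols <- as.matrix(out[paste0("ref_", baits)])
  ord <- order(-ifelse(out$in_reference_set, 1L, 0L),
               -apply(ref_cols, 1L, function(x) suppressWarnings(
                 max(x, na.rm = TRUE))))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Isoform groups from the synthetic naming convention: a variant accession
# extends its parent accession with a suffix separated by "_".
infer_isoform_groups <- function(db) {
  ids <- db$protein_id
  parents <- ids[vapply(ids, function(i) any(startsWith(ids, paste0(i, "_"))),
                        logical(1))]
  groups <- lapply(parents, function(p) {
    setdiff(ids[startsWith(ids, paste0(p, "_"))], p)
  })
  stats::setNames(groups, parents)
}
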