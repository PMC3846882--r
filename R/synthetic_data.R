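#' Simulation configuration
#'
#' Parameters of the synthetic AP-MS experiment generator. Defaults emulate
#' the study design the pipeline targets: a 12-member core complex (11
#' declared reference members plus one planted, undeclared candidate), three
#' core members used as overexpressed baits with three biological replicates
#' each, a mock-control series capturing sticky contaminants, and one
#' whole-cell-lysate (WCL) run.
#'
#' @param seed Integer RNG seed; every downstream draw is a deterministic
#'   function of it.
#' @param n_core Complex size including the candidate (default 12).
#' @param n_background Contaminant pool size (default 200).
#' @param baits Indices of core members used as baits (default 1:3).
#' @param replicates Biological replicates per bait (default 3).
#' @param control_replicates Mock-control replicates (default 3).
#' @param bait_overexpression Multiplier on the bait's own abundance in its
#'   pull-downs (default 4).
#' @param enrichment_range Range of the per-member pull-down enrichment
#'   factor relative to WCL, drawn uniformly (default c(0.3, 1.7)).
#' @param candidate_enrichment Fixed enrichment of the planted candidate
#'   (default 0.5).
#' @param stickiness Fraction of background proteins that appear in control
#'   (and bait) runs (default 0.3).
#' @param sticky_boost Abundance multiplier for sticky contaminants, making
#'   them abundant as tubulin/ribosome/HSP-class binders are (default 4).
#' @param background_carryover Fraction of its WCL-relative abundance at
#'   which a sticky contaminant carries over into a bait pull-down
#'   (default 0.1): affinity purification depletes nonspecific binders
#'   relative to lysate, so contaminants land an order of magnitude below
#'   the complex on the REF scale.
#' @param run_depth Expected total spectra per AP run (default 20000).
#' @param wcl_depth Expected total spectra for the WCL run (default 1e5).
#' @param replicate_jitter_sd Std. dev. of the per-protein, per-replicate
#'   log-normal abundance jitter modelling biological variability
#'   (default 0.2).
#' @param control_core_frac Fraction of WCL abundance at which core members
#'   leak into the mock control (default 0 = off; set e.g. 0.01 to exercise
#'   non-zero background for true preys).
#' @param seq_length_range Protein length range in residues
#'   (default c(150, 1500)).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_core = 12L, n_background = 200L,
                       baits = 1:3, replicates = 3L, control_replicates = 3L,
                       bait_overexpression = 4, enrichment_range = c(0.3, 1.7),
                       candidate_enrichment = 0.5, stickiness = 0.3,
                       sticky_boost = 4, background_carryover = 0.1,
                       run_depth = 20000,
                       wcl_depth = 1e5, replicate_jitter_sd = 0.2,
                       control_core_frac = 0,
                       seq_length_range = c(150L, 1500L)) {
  stopifnot(n_core >= 2L, n_background >= 0L, length(baits) >= 1L,
            all(baits >= 1L & baits <= n_core), replicates >= 1L,
            control_replicates >= 1L, bait_overexpression > 0,
            all(enrichment_range > 0), candidate_enrichment > 0,
            stickiness >= 0, stickiness <= 1, background_carryover > 0,
            run_depth > 0, wcl_depth > 0,
            replicate_jitter_sd >= 0, control_core_frac >= 0)
  structure(as.list(environment()), class = "sim_config")
}

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Normalize to relative abundance; an all-zero condition stays all-zero.
relativize <- function(w) if (sum(w) > 0) w / sum(w) else w

# Canonical member of the N-extended isoform pair: Met start, excisable
# residue 2, first cut site far enough in for a >=7-residue N-term peptide.
random_nterm_canonical <- function(len) {
  body <- sample(setdiff(AA_ALPHABET, c("K", "R", "P")), 6L, replace = TRUE)
  tail_len <- len - 9L
  paste0("MA", paste(body, collapse = ""), "K", random_sequence(tail_len))
}

# 24-residue N-terminal extension ending in R so that the canonical
# N-terminal peptide becomes an internal tryptic peptide of the variant.
random_extension <- function() {
  mid <- sample(setdiff(AA_ALPHABET, c("P")), 22L, replace = TRUE)
  paste0("M", paste(mid, collapse = ""), "R")
}

# Delete an internal block of `canonical` so that some tryptic peptide of
# the variant spans the new junction and occurs nowhere else in `db_seqs`.
# Returns list(variant, junction_peptide) or NULL after `tries` failures.
plant_junction_variant <- function(canonical, db_seqs, params, tries = 50L) {
  n <- nchar(canonical)
  for (attempt in seq_len(tries)) {
    del_start <- sample(seq(30L, n - 60L), 1L)
    del_len <- sample(20:40, 1L)
    variant <- paste0(substring(canonical, 1L, del_start - 1L),
                      substring(canonical, del_start + del_len, n))
    junction <- del_start - 1L  # variant coordinate of the last kept residue
    pep <- tryptic_digest(variant, params)
    pep <- pep[pep$missed == 0L & pep$start <= junction & pep$end > junction, ]
    if (!nrow(pep)) next
    for (i in seq_len(nrow(pep))) {
      hits <- sum(vapply(c(db_seqs, variant),
                         function(s) lengths(regmatches(
                           s, gregexpr(pep$peptide[i], s, fixed = TRUE))),
                         integer(1)))
      if (hits == 1L) {
        return(list(variant = variant, junction_peptide = pep$peptide[i]))
      }
    }
  }
  NULL
}

#' Generate a synthetic protein database with planted structure
#'
#' Builds random protein sequences for the core complex (the last member is
#' the planted candidate, excluded from the reference set), a background
#' contaminant pool, and two engineered isoform pairs: an N-terminally
#' extended pair (variant = 24 extra residues prepended to the canonical)
#' and a junction pair (variant = canonical with an internal block deleted,
#' such that one tryptic peptide uniquely spans the junction).
#'
#' @param config A [sim_config()] object.
#' @return A list with `db` (protein database `data.frame`), `truth` (a
#'   `data.frame` with per-protein `label`, `wcl_abundance`, `enrichment`,
#'   `sticky`), `reference` (the declared reference-set accessions),
#'   `baits` (bait accessions), `isoform_groups` (named list parent ->
#'   variants) and `junction_peptide`.
#' @export
generate_protein_db <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  params <- digest_params()
  n_core <- config$n_core
  core_ids <- c(sprintf("CORE%02d", seq_len(n_core - 1L)), "CAND01")
  bg_ids <- if (config$n_background > 0) {
    sprintf("BG%03d", seq_len(config$n_background))
  } else character()
  lens <- function(k) sample(seq(config$seq_length_range[1L],
                                 config$seq_length_range[2L]), k,
                             replace = TRUE)
  core_seqs <- vapply(lens(n_core), random_sequence, character(1))
  bg_seqs <- vapply(lens(config$n_background), random_sequence, character(1))

  # isoform pair (a): canonical + N-extended variant
  isoa <- random_nterm_canonical(lens(1L))
  isoa_v <- paste0(random_extension(), isoa)
  # isoform pair (b): canonical + junction-deletion variant
  junction <- NULL
  for (attempt in seq_len(20L)) {
    isob <- random_sequence(max(300L, lens(1L)))
    junction <- plant_junction_variant(
      isob, c(core_seqs, bg_seqs, isoa, isoa_v, isob), params)
    if (!is.null(junction)) break
  }
  if (is.null(junction)) {
    stop("failed to engineer a unique junction peptide; try another seed")
  }
  ids <- c(core_ids, bg_ids, "ISOA", "ISOA_EXT", "ISOB", "ISOB_DX")
  seqs <- c(core_seqs, bg_seqs, isoa, isoa_v, isob, junction$variant)
  db <- data.frame(protein_id = ids, gene_symbol = ids,
                   description = NA_character_, sequence = seqs,
                   length = nchar(seqs), stringsAsFactors = FALSE)
  validate_protein_db(db)

  labels <- c(rep("core", n_core - 1L), "candidate",
              rep("background", config$n_background), rep("isoform", 4L))
  labels[config$baits] <- "bait"
  sticky <- rep(FALSE, nrow(db))
  bg_idx <- which(labels == "background")
  n_sticky <- round(config$stickiness * length(bg_idx))
  if (n_sticky > 0) sticky[sample(bg_idx, n_sticky)] <- TRUE
  abundance <- stats::rlnorm(nrow(db), meanlog = 0, sdlog = 1)
  abundance[sticky] <- abundance[sticky] * config$sticky_boost
  enrichment <- rep(NA_real_, nrow(db))
  complex_idx <- which(labels %in% c("core", "bait", "isoform"))
  enrichment[complex_idx] <- stats::runif(length(complex_idx),
                                          config$enrichment_range[1L],
                                          config$enrichment_range[2L])
  enrichment[labels == "candidate"] <- config$candidate_enrichment
  truth <- data.frame(protein_id = ids, label = labels,
                      wcl_abundance = abundance, enrichment = enrichment,
                      sticky = sticky, stringsAsFactors = FALSE)
  list(db = db, truth = truth,
       reference = core_ids[seq_len(n_core - 1L)],
       baits = core_ids[config$baits],
       isoform_groups = list(ISOA = "ISOA_EXT", ISOB = "ISOB_DX"),
       junction_peptide = junction$junction_peptide)
}

#' Simulate AP-MS spectral counts for a generated database
#'
#' Draws, for every run, independent Poisson spectral counts with expected
#' value `depth * relative abundance` in that run's condition: bait runs
#' contain the overexpressed bait, all complex members (core, candidate,
#' isoform pairs) at their per-member enrichment times WCL abundance, and
#' the sticky contaminants; mock controls contain sticky contaminants only
#' (plus an optional low level of core members); WCL contains everything at
#' base abundance. Per-protein, per-replicate log-normal jitter models
#' biological variability in the AP and control series.
#'
#' @param sim Output of [generate_protein_db()].
#' @param config The same [sim_config()] used to generate it.
#' @return A list with `matrix` (integer run-by-protein counts) and
#'   `design` (experiment design `data.frame`).
#' @export
simulate_apms_counts <- function(sim, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  truth <- sim$truth
  ids <- truth$protein_id
  n <- length(ids)
  complex_members <- truth$label %in% c("core", "bait", "candidate", "isoform")

  design <- list()
  expected <- list()
  jitter <- function() {
    if (config$replicate_jitter_sd > 0) {
      stats::rlnorm(n, meanlog = 0, sdlog = config$replicate_jitter_sd)
    } else rep(1, n)
  }
  for (b in sim$baits) {
    for (r in seq_len(config$replicates)) {
      w <- numeric(n)
      w[complex_members] <- truth$wcl_abundance[complex_members] *
        truth$enrichment[complex_members]
      w[ids == b] <- truth$wcl_abundance[ids == b] * config$bait_overexpression
      w[truth$sticky] <- truth$wcl_abundance[truth$sticky] *
        config$background_carryover
      w <- w * jitter()
      run <- sprintf("%s_rep%d", b, r)
      design[[run]] <- data.frame(run_id = run, condition = "bait",
                                  bait_id = b, replicate = r,
                                  stringsAsFactors = FALSE)
      expected[[run]] <- config$run_depth * relativize(w)
    }
  }
  for (r in seq_len(config$control_replicates)) {
    w <- numeric(n)
    w[truth$sticky] <- truth$wcl_abundance[truth$sticky]
    if (config$control_core_frac > 0) {
      w[complex_members] <- truth$wcl_abundance[complex_members] *
        config$control_core_frac
    }
    w <- w * jitter()
    run <- sprintf("CTRL_rep%d", r)
    design[[run]] <- data.frame(run_id = run, condition = "control",
                                bait_id = NA_character_, replicate = r,
                                stringsAsFactors = FALSE)
    expected[[run]] <- config$run_depth * relativize(w)
  }
  w <- truth$wcl_abundance
  design[["WCL_rep1"]] <- data.frame(run_id = "WCL_rep1", condition = "wcl",
                                     bait_id = NA_character_, replicate = 1L,
                                     stringsAsFactors = FALSE)
  expected[["WCL_rep1"]] <- config$wcl_depth * relativize(w)

  design <- do.call(rbind, design)
  rownames(design) <- NULL
  counts <- t(vapply(design$run_id,
                     function(run) stats::rpois(n, expected[[run]]),
                     integer(n)))
  dimnames(counts) <- list(design$run_id, ids)
  storage.mode(counts) <- "integer"
  list(matrix = counts, design = validate_design(design))
}

#' Simulate peptide-level evidence for the isoform pairs
#'
#' Distributes each isoform protein's per-run spectral count over its
#' tryptic peptides (multinomial, uniform over peptides), substituting the
#' N-terminal processed forms for Met-initiated proteins, to provide
#' peptide evidence for the isoform classification stage.
#'
#' @param sim Output of [generate_protein_db()].
#' @param counts Run-by-protein count matrix from [simulate_apms_counts()].
#' @param config The matching [sim_config()].
#' @param params A [digest_params()] object.
#' @return Long-form evidence `data.frame`: `peptide`, `nterm_mod_delta`,
#'   `protein_id`, `run_id`, `count`.
#' @export
simulate_peptide_evidence <- function(sim, counts, config = sim_config(),
                                      params = digest_params()) {
  set.seed(config$seed + 2L)
  iso_ids <- unlist(c(names(sim$isoform_groups), sim$isoform_groups),
                    use.names = FALSE)
  out <- list()
  for (id in iso_ids) {
    seqn <- sim$db$sequence[sim$db$protein_id == id]
    pep <- tryptic_digest(seqn, params)
    pep <- pep[pep$missed == 0L, , drop = FALSE]
    internal <- pep[pep$start > 1L, , drop = FALSE]
    forms <- data.frame(peptide = internal$peptide, nterm_mod_delta = 0L,
                        stringsAsFactors = FALSE)
    if (startsWith(seqn, "M")) {
      nt <- nterm_processed_forms(seqn, params)
      forms <- rbind(forms, nt[, c("peptide", "nterm_mod_delta")])
    } else if (any(pep$start == 1L)) {
      forms <- rbind(forms, data.frame(peptide = pep$peptide[pep$start == 1L],
                                       nterm_mod_delta = 0L,
                                       stringsAsFactors = FALSE))
    }
    for (run in rownames(counts)) {
      total <- counts[run, id]
      if (total == 0L) next
      alloc <- as.integer(stats::rmultinom(1L, total,
                                           rep(1, nrow(forms))))
      keep <- alloc > 0L
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = forms$peptide[keep],
        nterm_mod_delta = forms$nterm_mod_delta[keep],
        protein_id = id, run_id = run, count = alloc[keep],
        stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}
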