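#' Normalized spectral abundance factor (NSAF) profile
#'
#' NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j), where SpC is the spectral
#' count and L the protein length in residues. The profile sums to 1 over
#' the included proteins; proteins with zero count get NSAF 0.
#'
#' @param counts Named non-negative count vector (names = accessions), or a
#'   single row of a count matrix.
#' @param lengths Named positive residue counts covering every protein in
#'   `counts`.
#' @return Named numeric NSAF vector over the proteins of `counts`.
#' @examples
#' compute_nsaf(c(A = 10, B = 10), c(A = 100, B = 200))  # 2/3, 1/3
#' @export
compute_nsaf <- function(counts, lengths) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  L <- lengths[names(counts)]
  if (anyNA(L)) {
    stop("no length for protein(s): ",
         paste(names(counts)[is.na(L)], collapse = ", "))
  }
  if (any(L <= 0)) stop("protein lengths must be positive")
  if (all(counts == 0)) stop("cannot compute NSAF from an all-zero count vector")
  saf <- counts / L
  saf / sum(saf)
}

# Replicate-level NSAF profiles for a set of runs, as a runs x proteins matrix.
nsaf_by_run <- function(matrix, runs, lengths) {
  t(vapply(runs, function(r) compute_nsaf(matrix[r, ], lengths),
           numeric(ncol(matrix))))
}

#' Condition-level NSAF profile
#'
#' Builds the NSAF profile for one condition of the experiment: for a bait,
#' the arithmetic mean of the per-replicate NSAF profiles (or the NSAF of
#' the pooled counts with `method = "pooled"`); for WCL or control, the mean
#' over that condition's runs.
#'
#' @param matrix Integer run-by-protein count matrix.
#' @param design Experiment design.
#' @param condition `"bait"`, `"control"` or `"wcl"`.
#' @param lengths Named residue-count vector.
#' @param bait_id Required when `condition = "bait"`.
#' @param method `"mean"` (default) averages per-replicate profiles;
#'   `"pooled"` sums counts across replicates first.
#' @return Named NSAF vector (sums to 1).
#' @export
condition_profile <- function(matrix, design, condition, lengths,
                              bait_id = NULL, method = c("mean", "pooled")) {
  method <- match.arg(method)
  sel <- design$condition == condition
  if (condition == "bait") {
    if (is.null(bait_id)) stop("bait_id is required for the bait condition")
    sel <- sel & !is.na(design$bait_id) & design$bait_id == bait_id
  }
  runs <- intersect(design$run_id[sel], rownames(matrix))
  if (!length(runs)) {
    stop("no runs for condition '", condition, "'",
         if (!is.null(bait_id)) paste0(" (bait ", bait_id, ")"))
  }
  if (method == "pooled") {
    compute_nsaf(colSums(matrix[runs, , drop = FALSE]), lengths)
  } else {
    colMeans(nsaf_by_run(matrix, runs, lengths))
  }
}

#' NSAF quotients of an AP profile against whole-cell lysate
#'
#' Divides each protein's NSAF in the affinity-purification profile by its
#' NSAF in the whole-cell-lysate profile. Proteins with zero (or missing)
#' WCL NSAF have no defined quotient; they are flagged and excluded from
#' downstream REF normalization rather than floored, unless `wcl_floor` is
#' enabled, which substitutes half the smallest nonzero WCL NSAF.
#'
#' @param ap_profile Named NSAF vector for the bait condition
#'   ([condition_profile()]).
#' @param wcl_profile Named NSAF vector for whole-cell lysate.
#' @param wcl_floor If `TRUE`, floor zero WCL values instead of flagging.
#' @param verbose Log flagged proteins.
#' @return A `data.frame` with columns `protein_id`, `nsaf_ap`, `nsaf_wcl`,
#'   `quotient`, `defined`. Undefined quotients are `NA`.
#' @export
compute_quotients <- function(ap_profile, wcl_profile, wcl_floor = FALSE,
                              verbose = FALSE) {
  ids <- names(ap_profile)
  wcl <- wcl_profile[ids]
  wcl[is.na(wcl)] <- 0
  if (wcl_floor && any(wcl == 0)) {
    nz <- wcl[wcl > 0]
    if (!length(nz)) stop("WCL profile is all zero")
    wcl[wcl == 0] <- min(nz) / 2
  }
  defined <- wcl > 0 & ap_profile > 0
  q <- ifelse(wcl > 0, ap_profile / wcl, NA_real_)
  q[wcl > 0 & ap_profile == 0] <- NA_real_  # absent from the pull-down
  if (verbose && any(!defined)) {
    message(sum(!defined), " protein(s) without a defined NSAF quotient ",
            "excluded from REF")
  }
  data.frame(protein_id = ids, nsaf_ap = unname(ap_profile),
             nsaf_wcl = unname(wcl), quotient = unname(q),
             defined = unname(defined), stringsAsFactors = FALSE)
}

#' Relative enrichment factor (REF) against a core-complex reference set
#'
#' Normalizes each protein's AP/WCL NSAF quotient by the mean quotient of
#' the known core-complex members, excluding the bait itself. By
#' construction the mean REF over the non-bait reference members is exactly
#' 1, and REF is invariant to rescaling all quotients by a positive
#' constant. The bait's own REF is reported but never enters the
#' normalizing mean.
#'
#' @param quotients Either a named numeric quotient vector or the
#'   `data.frame` from [compute_quotients()].
#' @param reference Character vector of core-complex member accessions (the
#'   reference set).
#' @param bait_id Accession of the bait (excluded from the normalizer).
#' @return A `data.frame` with columns `protein_id`, `quotient`, `ref`,
#'   `in_reference_set`, `is_bait`, sorted by `ref` descending. Proteins
#'   with undefined quotients are dropped.
#' @export
compute_ref <- function(quotients, reference, bait_id) {
  if (is.data.frame(quotients)) {
    q <- stats::setNames(quotients$quotient, quotients$protein_id)
  } else {
    q <- quotients
  }
  stopifnot(!is.null(names(q)))
  q <- q[!is.na(q)]
  if (any(q <= 0)) stop("quotients must be positive where defined")
  norm_ids <- setdiff(intersect(reference, names(q)), bait_id)
  if (!length(norm_ids)) {
    stop("no non-bait reference member has a defined quotient; ",
         "cannot normalize REF")
  }
  norm <- mean(q[norm_ids])
  out <- data.frame(protein_id = names(q), quotient = unname(q),
                    ref = unname(q) / norm,
                    in_reference_set = names(q) %in% reference,
                    is_bait = names(q) == bait_id,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ref, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nominate complex-membership candidates from multi-bait REF tables
#'
#' Combines per-bait REF tables, drops reference-set members, and ranks the
#' remaining preys by their minimum REF across baits. A prey is flagged
#' "member-like" when its REF meets `member_threshold` in every bait; the
#' report retains every prey reaching `report_threshold` in at least one
#' bait.
#'
#' @param ref_tables Named list (bait_id -> [compute_ref()] table).
#' @param member_threshold REF needed in all baits for the member-like flag
#'   (default 0.3).
#' @param report_threshold REF needed in any bait to be reported
#'   (default 0.1).
#' @return A `data.frame` with `protein_id`, one `ref_<bait>` column per
#'   bait, `min_ref`, `member_like`, ranked by `min_ref` descending.
#' @export
nominate_candidates <- function(ref_tables, member_threshold = 0.3,
                                report_threshold = 0.1) {
  stopifnot(length(ref_tables) >= 1L, !is.null(names(ref_tables)))
  baits <- names(ref_tables)
  non_ref <- unique(unlist(lapply(ref_tables, function(t) {
    t$protein_id[!t$in_reference_set]
  })))
  non_ref <- setdiff(non_ref, baits)
  if (!length(non_ref)) {
    return(data.frame(protein_id = character(), min_ref = numeric(),
                      member_like = logical(), stringsAsFactors = FALSE))
  }
  refmat <- sapply(baits, function(b) {
    t <- ref_tables[[b]]
    t$ref[match(non_ref, t$protein_id)]
  })
  refmat <- matrix(refmat, nrow = length(non_ref),
                   dimnames = list(non_ref, paste0("ref_", baits)))
  min_ref <- apply(refmat, 1L, function(x) if (all(is.na(x))) NA_real_
                   else min(x, na.rm = TRUE))
  max_ref <- apply(refmat, 1L, function(x) if (all(is.na(x))) NA_real_
                   else max(x, na.rm = TRUE))
  member_like <- !apply(refmat, 1L, anyNA) &
    apply(refmat >= member_threshold, 1L, all)
  out <- data.frame(protein_id = non_ref, refmat, min_ref = min_ref,
                    member_like = member_like, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out <- out[!is.na(max_ref) & max_ref >= report_threshold, , drop = FALSE]
  out <- out[order(-out$min_ref, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-bait enrichment analysis from a count matrix
#'
#' Convenience wrapper running NSAF, quotient and REF computation for every
#' bait in the design against the whole-cell-lysate profile.
#'
#' @inheritParams condition_profile
#' @param db Protein database (for lengths).
#' @param reference Reference-set accessions.
#' @param method AP-side replicate handling, see [condition_profile()].
#' @param wcl_floor See [compute_quotients()].
#' @return Named list (bait_id -> [compute_ref()] table).
#' @export
enrichment_analysis <- function(matrix, design, db, reference,
                                method = c("mean", "pooled"),
                                wcl_floor = FALSE) {
  method <- match.arg(method)
  lengths <- stats::setNames(db$length, db$protein_id)
  wcl <- condition_profile(matrix, design, "wcl", lengths)
  baits <- unique(design$bait_id[design$condition == "bait"])
  out <- lapply(baits, function(b) {
    ap <- condition_profile(matrix, design, "bait", lengths, bait_id = b,
                            method = method)
    qs <- compute_quotients(ap, wcl, wcl_floor = wcl_floor)
    compute_ref(qs, reference, b)
  })
  stats::setNames(out, baits)
}
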