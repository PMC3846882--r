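#' Estimate the nonspecific background model from mock-control runs
#'
#' Fits, per protein, a background binding rate per unit sequencing depth
#' from the mock-control purifications (affinity tag alone). With R control
#' runs, counts c and run depths d (run totals), the rate is
#' `lambda0_i = (sum(c_i) + alpha * R) / (sum(d) + alpha * R * n_proteins)`:
#' a per-run pseudocount `alpha` keeps every rate strictly positive and
#' makes the estimate from replicated identical runs equal the one-run
#' estimate.
#'
#' @param matrix Integer run-by-protein spectral count matrix.
#' @param design Experiment design; must contain at least one `"control"`
#'   run.
#' @param alpha Pseudocount per control run (default 0.1).
#' @return A list of class `background_model` with `lambda0` (named rate
#'   vector), `control_runs`, `depths` (all run depths) and `alpha`.
#' @export
estimate_background <- function(matrix, design, alpha = 0.1) {
  matrix <- validate_count_matrix(matrix, design)
  control_runs <- intersect(design$run_id[design$condition == "control"],
                            rownames(matrix))
  if (!length(control_runs)) {
    stop("no control runs in the design; interaction scoring requires at ",
         "least one mock-control purification (condition = \"control\")")
  }
  depths <- rowSums(matrix)
  nR <- length(control_runs)
  nprot <- ncol(matrix)
  ctrl_counts <- colSums(matrix[control_runs, , drop = FALSE])
  lambda0 <- (ctrl_counts + alpha * nR) /
    (sum(depths[control_runs]) + alpha * nR * nprot)
  structure(list(lambda0 = lambda0, control_runs = control_runs,
                 depths = depths, alpha = alpha),
            class = "background_model")
}

#' Score one bait-prey pair
#'
#' Two-component Poisson posterior with equal prior odds: for replicate r
#' with count `x_r` and run depth `d_r`, the per-replicate probability of a
#' true interaction is `f1(x_r) / (f1(x_r) + f0(x_r))` where
#' `f0 = Poisson(d_r * lambda0)` models nonspecific background and
#' `f1 = Poisson(d_r * lambda1)` the enriched component. Unless supplied,
#' `lambda1` is the method-of-moments rate over the bait's replicates
#' (`mean(x_r / d_r)`), lower-bounded by `lambda0` so depletion alone never
#' raises the probability above 0.5. The pair probability is the arithmetic
#' mean over replicates.
#'
#' @param bait_counts Integer vector of the prey's counts over the bait's
#'   replicate runs.
#' @param depths Positive run depths (total spectra), same length.
#' @param lambda0 The prey's background rate from [estimate_background()].
#' @param lambda1 Optional enriched rate; estimated from `bait_counts` when
#'   `NULL`.
#' @return A list with `p_rep` (per-replicate probabilities), `avg_prob`,
#'   `lambda1`, `total_spectra`.
#' @export
score_pair <- function(bait_counts, depths, lambda0, lambda1 = NULL) {
  stopifnot(length(bait_counts) == length(depths), lambda0 > 0)
  if (any(depths <= 0)) stop("zero-depth run in bait replicate series")
  if (is.null(lambda1)) lambda1 <- mean(bait_counts / depths)
  lambda1 <- max(lambda1, lambda0)
  log_f1 <- stats::dpois(bait_counts, depths * lambda1, log = TRUE)
  log_f0 <- stats::dpois(bait_counts, depths * lambda0, log = TRUE)
  p_rep <- stats::plogis(log_f1 - log_f0)
  list(p_rep = p_rep, avg_prob = mean(p_rep), lambda1 = lambda1,
       total_spectra = sum(bait_counts))
}

#' Score every bait-prey pair in an experiment
#'
#' Runs [score_pair()] for each prey against each bait's replicate series,
#' using the background model from the mock controls. The bait protein
#' itself is not scored as its own prey.
#'
#' @param matrix Integer run-by-protein count matrix (after
#'   [apply_identification_filters()]).
#' @param design Experiment design.
#' @param model Optional [estimate_background()] fit; computed when `NULL`.
#' @param threshold Average-probability threshold (default 0.9).
#' @param inclusive If `TRUE` (default) the threshold comparison is `>=`,
#'   otherwise strict `>`.
#' @return A `data.frame` with columns `bait_id`, `prey_id`,
#'   `p_rep1..p_repR`, `avg_prob`, `total_spectra`, `passes_threshold`.
#' @export
score_interactions <- function(matrix, design, model = NULL, threshold = 0.9,
                               inclusive = TRUE) {
  matrix <- validate_count_matrix(matrix, design)
  if (is.null(model)) model <- estimate_background(matrix, design)
  baits <- unique(design$bait_id[design$condition == "bait"])
  per_bait <- list()
  for (b in baits) {
    sub <- design[design$condition == "bait" & !is.na(design$bait_id) &
                    design$bait_id == b, ]
    sub <- sub[order(sub$replicate), ]
    runs <- intersect(sub$run_id, rownames(matrix))
    if (!length(runs)) next
    depths <- model$depths[runs]
    preys <- setdiff(colnames(matrix), b)
    p_rep <- matrix(NA_real_, nrow = length(preys), ncol = length(runs))
    avg <- total <- numeric(length(preys))
    for (i in seq_along(preys)) {
      s <- score_pair(matrix[runs, preys[i]], depths,
                      model$lambda0[[preys[i]]])
      p_rep[i, ] <- s$p_rep
      avg[i] <- s$avg_prob
      total[i] <- s$total_spectra
    }
    passes <- if (inclusive) avg >= threshold else avg > threshold
    per_bait[[b]] <- list(df = data.frame(
      bait_id = b, prey_id = preys, avg_prob = avg,
      total_spectra = as.integer(total), passes_threshold = passes,
      stringsAsFactors = FALSE), p_rep = p_rep)
  }
  if (!length(per_bait)) {
    return(data.frame(bait_id = character(), prey_id = character(),
                      avg_prob = numeric(), total_spectra = integer(),
                      passes_threshold = logical(), stringsAsFactors = FALSE))
  }
  max_reps <- max(vapply(per_bait, function(x) ncol(x$p_rep), integer(1)))
  out <- do.call(rbind, lapply(per_bait, function(x) {
    p <- x$p_rep
    if (ncol(p) < max_reps) {
      p <- cbind(p, matrix(NA_real_, nrow(p), max_reps - ncol(p)))
    }
    colnames(p) <- paste0("p_rep", seq_len(max_reps))
    cbind(x$df[, c("bait_id", "prey_id")], p,
          x$df[, c("avg_prob", "total_spectra", "passes_threshold")])
  }))
  rownames(out) <- NULL
  out
}

#' Filter the scored interactome to qualified preys
#'
#' A prey qualifies for a bait when its average probability passes the
#' threshold and it carries at least `min_total_spectra` spectra over the
#' bait's replicate series. The result is sorted by average probability
#' (descending), ties broken by total spectral count (descending), then
#' accession (ascending).
#'
#' @param scores Output of [score_interactions()].
#' @param min_total_spectra Minimum total spectra per bait (default 2).
#' @return The qualified subset of `scores`, re-sorted, with a `qualified`
#'   column set to `TRUE`.
#' @export
filter_interactome <- function(scores, min_total_spectra = 2L) {
  keep <- scores$passes_threshold & scores$total_spectra >= min_total_spectra
  out <- scores[keep, , drop = FALSE]
  if (nrow(out)) {
    out <- out[order(out$bait_id, -out$avg_prob, -out$total_spectra,
                     out$prey_id), , drop = FALSE]
  }
  out$qualified <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
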