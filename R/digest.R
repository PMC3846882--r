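# Residues that permit initiator-Met excision when found at position 2
# (standard methionine aminopeptidase specificity).
MET_EXCISION_SET <- c("A", "C", "G", "P", "S", "T", "V")

# Nominal mass delta tracked for N-terminal acetylation, in Da.
NTERM_ACETYL_DELTA <- 42L

#' Digestion parameters
#'
#' Trypsin-style digestion settings: cleavage C-terminal to K/R, suppressed
#' before proline by default, with up to `max_missed_cleavages` internal
#' uncut sites and a minimum retained peptide length.
#'
#' @param max_missed_cleavages Maximum internal uncut K/R sites per peptide.
#' @param min_length Minimum peptide length in residues.
#' @param cleave_after Residues after which the protease cuts.
#' @param suppress_before_proline If `TRUE`, no cut before a proline.
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 1L, min_length = 7L,
                          cleave_after = c("K", "R"),
                          suppress_before_proline = TRUE) {
  stopifnot(max_missed_cleavages >= 0L, min_length >= 1L,
            length(cleave_after) >= 1L)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 cleave_after = cleave_after,
                 suppress_before_proline = isTRUE(suppress_before_proline)),
            class = "digest_params")
}

# 0-based cut positions (a cut after residue i); sequence boundaries excluded.
cut_sites <- function(res, params) {
  n <- length(res)
  if (n < 2L) return(integer())
  i <- which(res[-n] %in% params$cleave_after)
  if (params$suppress_before_proline) i <- i[res[i + 1L] != "P"]
  i
}

#' In-silico tryptic digestion
#'
#' Cleaves an amino-acid sequence C-terminal to K/R (not before P when
#' suppression is on) and returns every peptide with at most
#' `max_missed_cleavages` internal uncut sites and at least `min_length`
#' residues. Coordinates are 1-based inclusive.
#'
#' @param sequence Amino-acid string.
#' @param params A [digest_params()] object.
#' @return A `data.frame` with columns `peptide`, `start`, `end`, `missed`
#'   ordered by `start` then `missed`.
#' @examples
#' tryptic_digest("MKAAAAAAR", digest_params(max_missed_cleavages = 0))
#' @export
tryptic_digest <- function(sequence, params = digest_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  bounds <- c(0L, cut_sites(res, params), length(res))
  nfrag <- length(bounds) - 1L
  out <- vector("list", nfrag)
  for (i in seq_len(nfrag)) {
    jmax <- min(i + params$max_missed_cleavages, nfrag)
    starts <- bounds[i] + 1L
    ends <- bounds[(i + 1L):(jmax + 1L)]
    out[[i]] <- data.frame(
      peptide = substring(sequence, starts, ends),
      start = starts, end = ends, missed = seq_along(ends) - 1L,
      stringsAsFactors = FALSE
    )
  }
  pep <- do.call(rbind, out)
  pep <- pep[nchar(pep$peptide) >= params$min_length, , drop = FALSE]
  pep <- pep[order(pep$start, pep$missed), , drop = FALSE]
  rownames(pep) <- NULL
  pep
}

#' N-terminally processed peptide forms
#'
#' For a protein whose sequence starts with methionine, enumerates the
#' observable forms of its N-terminal tryptic peptide: the Met-retained
#' form, the Met-excised form (only when residue 2 is in the
#' aminopeptidase-eligible set A/C/G/P/S/T/V), and each with a nominal
#' +42 Da N-terminal acetylation. Internal peptides are unaffected.
#'
#' @param record A one-row protein database entry, or a plain sequence
#'   string starting with `M`.
#' @param params A [digest_params()] object; `min_length` is applied to the
#'   emitted forms.
#' @return A `data.frame` with columns `peptide`, `nterm_mod_delta` (0 or
#'   42), `form` (`"met_retained"`/`"met_excised"`), `start`, `end`.
#' @export
nterm_processed_forms <- function(record, params = digest_params()) {
  sequence <- if (is.data.frame(record)) record$sequence[1L] else record
  stopifnot(is.character(sequence), nzchar(sequence))
  if (substring(sequence, 1L, 1L) != "M") {
    stop("N-terminal processing requires a sequence starting with M")
  }
  res <- strsplit(sequence, "")[[1]]
  first_end <- c(cut_sites(res, params), length(res))[1L]
  base <- substring(sequence, 1L, first_end)
  forms <- data.frame(peptide = base, nterm_mod_delta = 0L,
                      form = "met_retained", start = 1L, end = first_end,
                      stringsAsFactors = FALSE)
  if (length(res) >= 2L && res[2L] %in% MET_EXCISION_SET) {
    forms <- rbind(forms, data.frame(
      peptide = substring(sequence, 2L, first_end), nterm_mod_delta = 0L,
      form = "met_excised", start = 2L, end = first_end,
      stringsAsFactors = FALSE))
  }
  acet <- forms
  acet$nterm_mod_delta <- NTERM_ACETYL_DELTA
  forms <- rbind(forms, acet)
  forms <- forms[nchar(forms$peptide) >= params$min_length, , drop = FALSE]
  rownames(forms) <- NULL
  forms
}

# All digestion-consistent occurrences of a bare peptide in one sequence:
# the match must start at the N-terminus (position 1, or position 2 of a
# Met-initiated sequence when the peptide could be a Met-excised N-terminal
# peptide) or after a cut site, must end at the C-terminus or at a cut site,
# and must contain at most max_missed internal uncut sites.
peptide_occurrences <- function(peptide, sequence, params) {
  hits <- gregexpr(peptide, sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(NULL)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  plen <- nchar(peptide)
  pres <- strsplit(peptide, "")[[1]]
  keep <- vapply(as.integer(hits), function(s) {
    e <- s + plen - 1L
    left_ok <- s == 1L ||
      (s == 2L && res[1L] == "M" && pres[1L] %in% MET_EXCISION_SET) ||
      (res[s - 1L] %in% params$cleave_after &&
         !(params$suppress_before_proline && pres[1L] == "P"))
    right_ok <- e == n ||
      (pres[plen] %in% params$cleave_after &&
         !(params$suppress_before_proline && res[e + 1L] == "P"))
    internal <- which(pres[-plen] %in% params$cleave_after)
    if (params$suppress_before_proline && length(internal)) {
      internal <- internal[pres[internal + 1L] != "P"]
    }
    left_ok && right_ok && length(internal) <= params$max_missed_cleavages
  }, logical(1))
  if (!any(keep)) return(NULL)
  starts <- as.integer(hits)[keep]
  data.frame(start = starts, end = starts + plen - 1L,
             nterminal = starts %in% c(1L, 2L), stringsAsFactors = FALSE)
}

#' Classify a peptide against a protein database
#'
#' Determines whether a peptide is unique to one protein (proteotypic),
#' shared among several, or an ambiguous N-terminal form. A peptide counts
#' as occurring in a protein only where the match honours the digestion
#' boundaries of [tryptic_digest()] (including Met-excised N-termini). A
#' Met-initiated peptide that is both the Met-retained N-terminal peptide of
#' one isoform and an internal peptide of an N-terminally extended isoform
#' in the same group is classified `"ambiguous_nterm"`.
#'
#' @param peptide Peptide string; a `"42+"` prefix (N-terminal acetylation)
#'   is stripped before matching.
#' @param db Protein database `data.frame` ([read_fasta()] layout).
#' @param isoform_groups Optional named list: parent accession ->
#'   character vector of variant accessions.
#' @param params A [digest_params()] object.
#' @return A list with `classification` (one of `"unique"`, `"shared"`,
#'   `"ambiguous_nterm"`), `proteins` (accessions containing the peptide),
#'   `nterm_mod_delta`, and `occurrences` (a `data.frame` of protein_id,
#'   start, end). Errors if the peptide occurs in no sequence.
#' @export
classify_peptide <- function(peptide, db, isoform_groups = NULL,
                             params = digest_params()) {
  stopifnot(nzchar(peptide))
  delta <- 0L
  if (startsWith(peptide, "42+")) {
    delta <- NTERM_ACETYL_DELTA
    peptide <- substring(peptide, 4L)
  }
  occ <- lapply(seq_len(nrow(db)), function(i) {
    o <- peptide_occurrences(peptide, db$sequence[i], params)
    if (is.null(o)) return(NULL)
    cbind(protein_id = db$protein_id[i], o, stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, occ[!vapply(occ, is.null, logical(1))])
  if (is.null(occ) || nrow(occ) == 0L) {
    stop("peptide '", peptide, "' does not occur in any database sequence")
  }
  proteins <- unique(occ$protein_id)
  classification <- if (length(proteins) == 1L) "unique" else "shared"
  if (length(proteins) > 1L && substring(peptide, 1L, 1L) == "M" &&
      !is.null(isoform_groups)) {
    for (parent in names(isoform_groups)) {
      group <- c(parent, isoform_groups[[parent]])
      if (all(proteins %in% group)) {
        has_nterm <- any(occ$start == 1L)
        has_internal <- any(occ$start > 2L)
        if (has_nterm && has_internal) classification <- "ambiguous_nterm"
        break
      }
    }
  }
  list(classification = classification, proteins = proteins,
       nterm_mod_delta = delta,
       occurrences = occ[, c("protein_id", "start", "end")])
}

#' Tally isoform-resolved spectral counts
#'
#' Sums, per isoform, the spectral counts of peptides classified as unique
#' to it. Counts of shared or ambiguous-N-terminal peptides are reported
#' separately and never apportioned between isoforms.
#'
#' @param evidence Long-form peptide evidence: columns `peptide`,
#'   `nterm_mod_delta`, `run_id`, `count` (counts >= 0).
#' @param classifications A `data.frame` with columns `peptide`,
#'   `classification`, `protein_id` (the owning isoform for unique
#'   peptides, `NA` otherwise), e.g. built from [classify_peptide()].
#' @return A list with `unique` (per-isoform `protein_id`, `n_peptides`,
#'   `total_spectra`) and `other` (per non-unique classification,
#'   `total_spectra`).
#' @export
tally_isoform_counts <- function(evidence, classifications) {
  stopifnot(all(evidence$count >= 0))
  cls <- classifications[match(evidence$peptide, classifications$peptide), ]
  if (anyNA(cls$classification)) {
    stop("evidence contains unclassified peptide(s): ",
         paste(unique(evidence$peptide[is.na(cls$classification)]),
               collapse = ", "))
  }
  uniq <- cls$classification == "unique"
  if (any(uniq)) {
    ev <- evidence[uniq, , drop = FALSE]
    owner <- cls$protein_id[uniq]
    totals <- tapply(ev$count, owner, sum)
    npep <- tapply(ev$peptide, owner, function(p) length(unique(p)))
    unique_tab <- data.frame(protein_id = names(totals),
                             n_peptides = as.integer(npep[names(totals)]),
                             total_spectra = as.integer(totals),
                             stringsAsFactors = FALSE, row.names = NULL)
    unique_tab <- unique_tab[order(unique_tab$protein_id), , drop = FALSE]
    rownames(unique_tab) <- NULL
  } else {
    unique_tab <- data.frame(protein_id = character(), n_peptides = integer(),
                             total_spectra = integer(), stringsAsFactors = FALSE)
  }
  if (any(!uniq)) {
    ev <- evidence[!uniq, , drop = FALSE]
    totals <- tapply(ev$count, cls$classification[!uniq], sum)
    other_tab <- data.frame(classification = names(totals),
                            total_spectra = as.integer(totals),
                            stringsAsFactors = FALSE, row.names = NULL)
    other_tab <- other_tab[order(other_tab$classification), , drop = FALSE]
    rownames(other_tab) <- NULL
  } else {
    other_tab <- data.frame(classification = character(),
                            total_spectra = integer(), stringsAsFactors = FALSE)
  }
  list(unique = unique_tab, other = other_tab)
}

#' Isoform evidence report
#'
#' Classifies each observed peptide against the database and writes a
#' per-peptide report: peptide, modification delta, classification, owning
#' protein(s), coordinates and per-run counts.
#'
#' @inheritParams tally_isoform_counts
#' @inheritParams classify_peptide
#' @return A `data.frame` report (one row per peptide).
#' @export
isoform_evidence_report <- function(evidence, db, isoform_groups = NULL,
                                    params = digest_params()) {
  peptides <- unique(evidence[, c("peptide", "nterm_mod_delta")])
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    p <- peptides$peptide[i]
    cl <- classify_peptide(p, db, isoform_groups, params)
    ev <- evidence[evidence$peptide == p &
                     evidence$nterm_mod_delta == peptides$nterm_mod_delta[i], ]
    data.frame(
      peptide = p,
      nterm_mod_delta = peptides$nterm_mod_delta[i],
      classification = cl$classification,
      proteins = paste(sort(cl$proteins), collapse = ";"),
      start = cl$occurrences$start[1L], end = cl$occurrences$end[1L],
      total_spectra = sum(ev$count), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
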