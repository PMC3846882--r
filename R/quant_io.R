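# The 20 standard residues; everything else in a sequence is rejected.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CONDITIONS <- c("bait", "control", "wcl")

#' Read a protein database from FASTA
#'
#' Parses a FASTA file of amino-acid sequences into a protein database table.
#' The first whitespace-delimited token of each header is taken as the
#' accession; the second token, when present, as the gene symbol; the
#' remainder as the description.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `protein_id`, `gene_symbol`,
#'   `description`, `sequence` and `length` (residue count), one row per
#'   entry. An empty file yields a zero-row table with a warning.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 GENE1 demo protein", "MKR"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    warning("FASTA file '", path, "' contains no sequences")
    return(empty_protein_db())
  }
  headers <- names(aa)
  tokens <- strsplit(headers, "[ \t]+")
  ids <- vapply(tokens, `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA parse error: entry ", which(is.na(ids) | !nzchar(ids))[1L],
         " has an empty header")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate protein_id in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  gene <- vapply(tokens, function(t) if (length(t) >= 2L) t[2L] else NA_character_,
                 character(1))
  desc <- vapply(tokens, function(t) {
    if (length(t) >= 3L) paste(t[-(1:2)], collapse = " ") else NA_character_
  }, character(1))
  seqs <- as.character(aa)
  validate_sequences(seqs, ids)
  db <- data.frame(
    protein_id = ids, gene_symbol = gene, description = desc,
    sequence = seqs, length = nchar(seqs),
    stringsAsFactors = FALSE, row.names = NULL
  )
  validate_protein_db(db)
  db
}

empty_protein_db <- function() {
  data.frame(protein_id = character(), gene_symbol = character(),
             description = character(), sequence = character(),
             length = integer(), stringsAsFactors = FALSE)
}

validate_sequences <- function(seqs, ids) {
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% AA_ALPHABET)
  }, logical(1))
  if (any(bad)) {
    offending <- strsplit(seqs[which(bad)[1L]], "")[[1]]
    ch <- offending[!offending %in% AA_ALPHABET][1L]
    stop("FASTA parse error: sequence '", ids[which(bad)[1L]],
         "' contains non-amino-acid character '", ch, "'")
  }
  if (any(!nzchar(seqs))) {
    stop("FASTA parse error: sequence '", ids[which(!nzchar(seqs))[1L]],
         "' is empty")
  }
  invisible(TRUE)
}

#' Validate a protein database table
#'
#' Checks the invariants of the protein database: unique accessions,
#' non-empty uppercase 20-letter sequences, and `length` equal to the residue
#' count.
#'
#' @param db A protein database `data.frame` as returned by [read_fasta()].
#' @return The validated `db`, invisibly. Errors on violation.
#' @export
validate_protein_db <- function(db) {
  stopifnot(is.data.frame(db))
  required <- c("protein_id", "sequence", "length")
  if (!all(required %in% names(db))) {
    stop("protein db must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(db) == 0L) return(invisible(db))
  if (anyDuplicated(db$protein_id)) {
    stop("protein_id values must be unique within a database")
  }
  validate_sequences(db$sequence, db$protein_id)
  if (!all(db$length == nchar(db$sequence)) || any(db$length <= 0L)) {
    stop("length column must equal the residue count of each sequence")
  }
  invisible(db)
}

#' Write a protein database to FASTA
#'
#' @param db A protein database `data.frame` ([read_fasta()] layout).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  validate_protein_db(db)
  aa <- Biostrings::AAStringSet(db$sequence)
  hdr <- db$protein_id
  if ("gene_symbol" %in% names(db)) {
    hdr <- ifelse(is.na(db$gene_symbol), hdr, paste(hdr, db$gene_symbol))
  }
  if ("description" %in% names(db)) {
    hdr <- ifelse(is.na(db$description), hdr, paste(hdr, db$description))
  }
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read or validate an experiment design table
#'
#' The design maps each LC-MS/MS run to its condition: a bait purification
#' (`"bait"`, with `bait_id` naming the tagged protein), a mock-control
#' purification (`"control"`, tag only) or whole-cell lysate (`"wcl"`).
#'
#' @param path Path to a TSV with columns `run_id`, `condition`, `bait_id`,
#'   `replicate`. Empty `bait_id` means none (control/WCL rows).
#' @return A validated `data.frame` with those columns (`bait_id` is
#'   `NA` for control/WCL rows, `replicate` integer).
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", check.names = FALSE)
  required <- c("run_id", "condition", "bait_id", "replicate")
  if (!all(required %in% names(d))) {
    stop("design table must have columns: ", paste(required, collapse = ", "))
  }
  d <- d[, required]
  d$bait_id[!nzchar(d$bait_id)] <- NA_character_
  d$replicate <- suppressWarnings(as.integer(d$replicate))
  validate_design(d)
}

#' @rdname read_design
#' @param design A design `data.frame` to validate in place.
#' @export
validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  if (anyDuplicated(design$run_id)) stop("run_id values must be unique")
  if (!all(design$condition %in% CONDITIONS)) {
    stop("condition must be one of: ", paste(CONDITIONS, collapse = ", "))
  }
  if (anyNA(design$replicate) || any(design$replicate < 1L)) {
    stop("replicate must be a positive integer for every run")
  }
  bait_rows <- design$condition == "bait"
  if (any(is.na(design$bait_id[bait_rows]))) {
    stop("bait runs must carry a bait_id")
  }
  if (any(!is.na(design$bait_id[!bait_rows]))) {
    stop("control/WCL runs must not carry a bait_id")
  }
  key <- paste(design$bait_id[bait_rows], design$replicate[bait_rows])
  if (anyDuplicated(key)) {
    stop("(bait_id, replicate) pairs must be unique among bait runs")
  }
  design
}

#' Write an experiment design table
#' @param design A validated design `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  out <- design
  out$bait_id[is.na(out$bait_id)] <- ""
  write_tsv(out, path)
}

#' Read a spectral count matrix
#'
#' Reads a run-by-protein table of spectral counts. Rows are runs (first
#' column `run_id`), columns are protein accessions. Missing/blank cells are
#' treated as zero; negative or non-integer counts are rejected, as are runs
#' absent from the design.
#'
#' @param path Path to a TSV: first column `run_id`, remaining columns one
#'   per protein accession.
#' @param design An experiment design table covering every run in the file.
#' @return An integer matrix with `run_id` rownames and accession colnames.
#' @export
read_count_matrix <- function(path, design) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("count matrix must have run_id plus >=1 protein column")
  run_ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[is.na(vals) | !nzchar(vals)] <- "0"
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(run_ids, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric count at run '", run_ids[bad[1L]], "', protein '",
         colnames(num)[bad[2L]], "'")
  }
  mat <- matrix(as.integer(round(num)), nrow = nrow(num), dimnames = dimnames(num))
  if (any(abs(num - mat) > 1e-9)) {
    bad <- which(abs(num - mat) > 1e-9, arr.ind = TRUE)[1L, ]
    stop("non-integer count at run '", run_ids[bad[1L]], "', protein '",
         colnames(num)[bad[2L]], "'")
  }
  validate_count_matrix(mat, design)
}

#' @rdname read_count_matrix
#' @param matrix An integer run-by-protein matrix to validate.
#' @export
validate_count_matrix <- function(matrix, design = NULL) {
  if (!is.matrix(matrix) || is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("count matrix must be a matrix with run rownames and protein colnames")
  }
  if (any(matrix < 0L)) stop("spectral counts must be non-negative")
  if (!is.null(design)) {
    missing_runs <- setdiff(rownames(matrix), design$run_id)
    if (length(missing_runs)) {
      stop("run(s) absent from design: ", paste(missing_runs, collapse = ", "))
    }
  }
  storage.mode(matrix) <- "integer"
  matrix
}

#' Write a spectral count matrix
#' @param matrix Integer run-by-protein count matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(matrix, path) {
  df <- data.frame(run_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a reference set of core-complex members
#'
#' @param path Path to a plain-text file with one protein accession (or gene
#'   symbol, see `db`) per line; blank lines and `#` comments are ignored.
#' @param db Optional protein database; when given, members are checked (and,
#'   if they match gene symbols rather than accessions, translated).
#' @return Character vector of member accessions.
#' @export
read_reference_set <- function(path, db = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  members <- unique(lines)
  if (length(members) < 2L) stop("reference set must have at least 2 members")
  if (!is.null(db)) {
    hit_id <- members %in% db$protein_id
    hit_gene <- members %in% db$gene_symbol
    if (any(!hit_id & hit_gene)) {
      idx <- match(members[!hit_id & hit_gene], db$gene_symbol)
      members[!hit_id & hit_gene] <- db$protein_id[idx]
      hit_id <- members %in% db$protein_id
    }
    if (any(!hit_id)) {
      stop("reference members absent from protein database: ",
           paste(members[!hit_id], collapse = ", "))
    }
  }
  members
}

#' Apply spectral-count identification filters
#'
#' Implements the two identification cutoffs applied before quantitation:
#' peptides shorter than `min_peptide_length` residues are discarded (when
#' peptide-level evidence is available, protein counts are re-tallied from
#' the retained peptides), and a protein whose total spectral count across a
#' bait's replicate series is below `min_total_spectra` is removed for that
#' bait (its counts in that bait's runs are zeroed; control and WCL runs are
#' untouched). The operation is idempotent and never increases a count.
#'
#' @param matrix Integer run-by-protein spectral count matrix.
#' @param design Experiment design covering the matrix rows.
#' @param peptides Optional peptide evidence `data.frame` in long form with
#'   columns `peptide`, `protein_id`, `run_id`, `count` (a shared peptide
#'   appears once per assigned protein). When supplied, protein counts are
#'   recomputed from length-filtered peptides.
#' @param min_peptide_length Minimum retained peptide length (residues).
#' @param min_total_spectra Minimum per-bait total spectral count.
#' @param mode `"total"` applies the threshold to the summed count over the
#'   bait's replicates; `"replicates"` instead requires detection (count
#'   >= 1) in at least `min_total_spectra` replicates.
#' @param verbose Log filter decisions via `message()`.
#' @return Filtered integer count matrix with the same dimensions.
#' @export
apply_identification_filters <- function(matrix, design, peptides = NULL,
                                         min_peptide_length = 7L,
                                         min_total_spectra = 2L,
                                         mode = c("total", "replicates"),
                                         verbose = FALSE) {
  mode <- match.arg(mode)
  matrix <- validate_count_matrix(matrix, design)
  if (!is.null(peptides)) {
    keep <- nchar(peptides$peptide) >= min_peptide_length
    if (verbose && any(!keep)) {
      message(sum(!keep), " peptide assignment(s) below ", min_peptide_length,
              " residues removed")
    }
    matrix <- tally_protein_counts(peptides[keep, , drop = FALSE],
                                   rownames(matrix), colnames(matrix))
  }
  baits <- unique(design$bait_id[design$condition == "bait"])
  for (b in baits) {
    runs <- design$run_id[design$condition == "bait" &
                            !is.na(design$bait_id) & design$bait_id == b]
    runs <- intersect(runs, rownames(matrix))
    if (!length(runs)) next
    sub <- matrix[runs, , drop = FALSE]
    stat <- if (mode == "total") colSums(sub) else colSums(sub >= 1L)
    drop <- stat < min_total_spectra & colSums(sub) > 0L
    if (any(drop)) {
      if (verbose) {
        message("bait ", b, ": ", sum(drop), " protein(s) below the ",
                min_total_spectra, "-spectra cutoff removed")
      }
      matrix[runs, drop] <- 0L
    }
  }
  if (all(matrix == 0L)) warning("identification filters left an empty matrix")
  matrix
}

# Rebuild a run-by-protein count matrix from long-form peptide evidence.
tally_protein_counts <- function(peptides, run_ids, protein_ids) {
  mat <- matrix(0L, nrow = length(run_ids), ncol = length(protein_ids),
                dimnames = list(run_ids, protein_ids))
  if (nrow(peptides)) {
    keep <- peptides$run_id %in% run_ids & peptides$protein_id %in% protein_ids
    p <- peptides[keep, , drop = FALSE]
    if (nrow(p)) {
      agg <- stats::aggregate(count ~ run_id + protein_id, data = p, FUN = sum)
      mat[cbind(agg$run_id, agg$protein_id)] <- as.integer(agg$count)
    }
  }
  mat
}

#' Collapse proteins sharing identical peptide sets
#'
#' Greedy parsimony reduction for peptide-level input: accessions whose
#' assigned peptide sets are identical are collapsed to a single group whose
#' representative is the lexicographically smallest accession. A lightweight
#' stand-in for full protein-grouping inference.
#'
#' @param peptides Long-form peptide evidence (`peptide`, `protein_id`,
#'   `run_id`, `count`).
#' @return A list with `peptides` (evidence re-pointed at representatives)
#'   and `groups` (a `data.frame` mapping `protein_id` to `representative`).
#' @export
collapse_protein_groups <- function(peptides) {
  sets <- tapply(peptides$peptide, peptides$protein_id,
                 function(p) paste(sort(unique(p)), collapse = "|"))
  rep_of <- tapply(names(sets), unname(sets), function(ids) min(ids))
  key <- unname(sets[peptides$protein_id])
  out <- peptides
  out$protein_id <- unname(rep_of[key])
  out <- stats::aggregate(count ~ peptide + protein_id + run_id, data = out,
                          FUN = sum)
  groups <- data.frame(protein_id = names(sets),
                       representative = unname(rep_of[unname(sets)]),
                       stringsAsFactors = FALSE)
  list(peptides = out, groups = groups)
}

# Deterministic TSV writer: UTF-8, tab-separated, "." decimals, no quoting.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}
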