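# In-code fixtures shared across test files.

# N-terminally extended isoform pair: the variant prepends a 24-residue
# extension (ending in R) to the canonical, so the canonical's Met-retained
# N-terminal peptide is an internal tryptic peptide of the variant.
make_nterm_pair <- function() {
  canonical <- "MANNDAVLKGGGSSSTTTKWWYYHHAEDKLLLMMMK"
  extension <- paste0("MLPAVAVSEPVVLR", "AAAGGGSSSR")  # 24 residues
  variant <- paste0(extension, canonical)
  data.frame(
    protein_id = c("ISO1", "ISO1_EXT"),
    gene_symbol = c("ISO1", "ISO1_EXT"),
    description = NA_character_,
    sequence = c(canonical, variant),
    length = nchar(c(canonical, variant)),
    stringsAsFactors = FALSE
  )
}

# Junction isoform pair: the variant deletes an internal exon-like block of
# the canonical so one tryptic peptide uniquely spans the new junction.
make_junction_pair <- function() {
  canonical <- paste0("MPMYQVKPYHGGGAPLR",
                      "SYGPAPGAGHVQEESNLSLQALESR",
                      "AAADDDEEEFFFKGGGHHHIIIK")
  variant <- paste0("MPMYQVKPYHGGGAPLR",
                    "SYGPAPGAGHVQDYGALK",
                    "AAADDDEEEFFFKGGGHHHIIIK")
  data.frame(
    protein_id = c("ISO2", "ISO2_DX"),
    gene_symbol = c("ISO2", "ISO2_DX"),
    description = NA_character_,
    sequence = c(canonical, variant),
    length = nchar(c(canonical, variant)),
    stringsAsFactors = FALSE
  )
}

toy_isoform_db <- function() {
  rbind(make_nterm_pair(), make_junction_pair())
}

toy_isoform_groups <- function() {
  list(ISO1 = "ISO1_EXT", ISO2 = "ISO2_DX")
}

# Minimal 2-bait design: b1/b2 x 3 replicates, 2 controls, 1 WCL run.
toy_design <- function(baits = c("B1", "B2"), replicates = 3L,
                       controls = 2L) {
  rows <- list()
  for (b in baits) {
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = sprintf("%s_rep%d", b, r), condition = "bait",
        bait_id = b, replicate = r, stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(controls)) {
    rows[[length(rows) + 1L]] <- data.frame(
      run_id = sprintf("CTRL_rep%d", r), condition = "control",
      bait_id = NA_character_, replicate = r, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    run_id = "WCL_rep1", condition = "wcl", bait_id = NA_character_,
    replicate = 1L, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

toy_matrix <- function(design, proteins, fill = 0L) {
  m <- matrix(as.integer(fill), nrow = nrow(design), ncol = length(proteins),
              dimnames = list(design$run_id, proteins))
  m
}

# Independent digestion oracle: enumerate EVERY substring and keep those
# satisfying the cleavage-boundary rules directly.
brute_force_digest <- function(sequence, max_missed = 1L, min_length = 7L,
                               suppress_kp = TRUE) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_cut_after <- function(i) {
    i >= 1L && i < n && res[i] %in% c("K", "R") &&
      !(suppress_kp && res[i + 1L] == "P")
  }
  out <- character()
  for (s in seq_len(n)) {
    left_ok <- s == 1L || is_cut_after(s - 1L)
    if (!left_ok) next
    for (e in s:n) {
      if (e - s + 1L < min_length) next
      right_ok <- e == n || is_cut_after(e)
      if (!right_ok) next
      internal <- sum(vapply((s:(e - 1L))[seq_len(max(0L, e - s))],
                             is_cut_after, logical(1)))
      if (internal <= max_missed) {
        out <- c(out, paste(res[s:e], collapse = ""))
      }
    }
  }
  sort(unique(out))
}

# Substring-membership oracle for classification: proteins whose sequence
# contains the peptide as a plain substring.
substring_hits <- function(peptide, db) {
  db$protein_id[vapply(db$sequence, function(s) grepl(peptide, s, fixed = TRUE),
                       logical(1))]
}
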