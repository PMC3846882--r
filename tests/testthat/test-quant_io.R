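test_that("FASTA reading parses records, computes lengths and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 G1 a demo protein", "MKR"), fa)
  db <- read_fasta(fa)
  expect_equal(db$protein_id, "P1")
  expect_equal(db$gene_symbol, "G1")
  expect_equal(db$length, 3L)

  writeLines(character(), fa)
  expect_warning(empty <- read_fasta(fa), "no sequences")
  expect_equal(nrow(empty), 0L)

  writeLines(c(">P1 x", "MKR", ">P1 y", "MAR"), fa)
  expect_error(read_fasta(fa), "duplicate")

  writeLines(c(">P1 x", "MKZB"), fa)
  expect_error(read_fasta(fa), "non-amino-acid")
})

test_that("FASTA write/read round-trips a database", {
  set.seed(42)
  db <- data.frame(
    protein_id = c("A1", "B2"), gene_symbol = c("GA", "GB"),
    description = c("first", NA),
    sequence = c("MKARNDCEQGHILFPSTWYV", "MAAAAKRRR"),
    length = c(20L, 9L), stringsAsFactors = FALSE)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db, fa)
  back <- read_fasta(fa)
  expect_equal(back$protein_id, db$protein_id)
  expect_equal(back$sequence, db$sequence)
  expect_equal(back$gene_symbol, db$gene_symbol)
})

test_that("count matrix reader applies missing-as-zero and validates counts", {
  design <- toy_design(baits = "B1", replicates = 2L, controls = 0L)
  design <- design[design$condition == "bait", ]
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("run_id\tP1\tP2\tP3",
               "B1_rep1\t5\t\t2",
               "B1_rep2\t0\t3\t1"), tsv)
  m <- read_count_matrix(tsv, design)
  expect_equal(m["B1_rep1", "P2"], 0L)
  expect_equal(m["B1_rep2", "P2"], 3L)

  writeLines(c("run_id\tP1", "B1_rep1\t-1"), tsv)
  expect_error(read_count_matrix(tsv, design), "non-negative")
  writeLines(c("run_id\tP1", "B1_rep1\t3.5"), tsv)
  expect_error(read_count_matrix(tsv, design), "non-integer")
  writeLines(c("run_id\tP1", "GHOST_run\t3"), tsv)
  expect_error(read_count_matrix(tsv, design), "absent from design")
})

test_that("count matrix write/read round-trips cell-for-cell", {
  design <- toy_design()
  set.seed(7)
  m <- toy_matrix(design, sprintf("P%02d", 1:8))
  m[] <- as.integer(rpois(length(m), 20))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, tsv)
  back <- read_count_matrix(tsv, design)
  expect_identical(back[rownames(m), colnames(m)], m)
})

test_that("design reader enforces condition vocabulary and bait uniqueness", {
  d <- toy_design()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_design(d, tsv)
  back <- read_design(tsv)
  expect_equal(back$run_id, d$run_id)
  expect_true(all(is.na(back$bait_id[back$condition != "bait"])))

  bad <- d
  bad$replicate[2] <- bad$replicate[1]
  bad$bait_id[2] <- bad$bait_id[1]
  expect_error(validate_design(bad), "unique among bait runs")
  bad <- d
  bad$condition[1] <- "pulldown"
  expect_error(validate_design(bad), "condition")
})

test_that("per-bait spectra cutoff removes sparse proteins and keeps the >=2 boundary", {
  design <- toy_design(baits = c("B1", "B2"), replicates = 3L, controls = 1L)
  m <- toy_matrix(design, c("P1", "P2", "P3"))
  # P1: one spectrum total in B1 (below cutoff), 3 in B2 (kept)
  m["B1_rep1", "P1"] <- 1L
  m[c("B1_rep1", "B1_rep2", "B1_rep3"), "P2"] <- c(0L, 1L, 1L)  # total 2: kept
  m[, "P3"] <- 5L
  m["B2_rep1", "P1"] <- 3L
  f <- apply_identification_filters(m, design)
  expect_equal(sum(f[c("B1_rep1", "B1_rep2", "B1_rep3"), "P1"]), 0L)
  expect_equal(f["B2_rep1", "P1"], 3L)
  expect_equal(sum(f[c("B1_rep1", "B1_rep2", "B1_rep3"), "P2"]), 2L)
  # control/WCL rows untouched
  expect_equal(f["CTRL_rep1", "P3"], 5L)

  # idempotent and never increasing
  f2 <- apply_identification_filters(f, design)
  expect_identical(f2, f)
  expect_true(all(f <= m))
  expect_identical(colnames(f), colnames(m))
})

test_that("replicate-presence filter mode is available as the alternative reading", {
  design <- toy_design(baits = "B1", replicates = 3L, controls = 1L)
  m <- toy_matrix(design, c("P1", "P2"))
  m[c("B1_rep1", "B1_rep2", "B1_rep3"), "P1"] <- c(2L, 0L, 0L)  # 1 replicate
  m[c("B1_rep1", "B1_rep2", "B1_rep3"), "P2"] <- c(1L, 1L, 0L)  # 2 replicates
  f <- apply_identification_filters(m, design, mode = "replicates")
  expect_equal(sum(f[1:3, "P1"]), 0L)   # detected once only
  expect_equal(sum(f[1:3, "P2"]), 2L)   # detected in two replicates
  # under the default total-count reading P1 (total 2) survives
  f_tot <- apply_identification_filters(m, design, mode = "total")
  expect_equal(sum(f_tot[1:3, "P1"]), 2L)
})

test_that("peptide length filter drops sub-7-residue peptides before tallying", {
  design <- toy_design(baits = "B1", replicates = 1L, controls = 1L)
  m <- toy_matrix(design, c("P1", "P2"))
  peptides <- data.frame(
    peptide = c("ANNDAVK", "NNDAVK", "ANNDAVK"),
    protein_id = c("P1", "P1", "P2"),
    run_id = "B1_rep1",
    count = c(3L, 5L, 2L), stringsAsFactors = FALSE)
  f <- apply_identification_filters(m, design, peptides = peptides,
                                    min_total_spectra = 0L)
  expect_equal(f["B1_rep1", "P1"], 3L)  # 7-mer retained, 6-mer discarded
  expect_equal(f["B1_rep1", "P2"], 2L)
})

test_that("identical peptide sets collapse to one representative group", {
  peptides <- data.frame(
    peptide = c("AAAAAAK", "CDEFGHK", "AAAAAAK", "CDEFGHK", "YYYYYYK"),
    protein_id = c("P2", "P2", "P1", "P1", "P3"),
    run_id = "r1", count = 1L, stringsAsFactors = FALSE)
  out <- collapse_protein_groups(peptides)
  expect_setequal(unique(out$peptides$protein_id), c("P1", "P3"))
  expect_equal(out$groups$representative[out$groups$protein_id == "P2"], "P1")
  # counts for the collapsed group are summed
  expect_equal(sum(out$peptides$count[out$peptides$protein_id == "P1"]), 4L)
})

test_that("reference set reader resolves gene symbols and enforces membership", {
  db <- toy_isoform_db()
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "ISO1", "ISO2"), f)
  expect_equal(read_reference_set(f, db), c("ISO1", "ISO2"))
  writeLines(c("ISO1", "GHOST"), f)
  expect_error(read_reference_set(f, db), "absent from protein database")
  writeLines("ISO1", f)
  expect_error(read_reference_set(f), "at least 2")
})
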