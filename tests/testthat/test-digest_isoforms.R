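test_that("tryptic digestion cuts after K/R with proline suppression", {
  p0 <- digest_params(max_missed_cleavages = 0L, min_length = 7L)
  d <- tryptic_digest("MKAAAAAAR", p0)
  expect_equal(d$peptide, "AAAAAAR")
  expect_equal(c(d$start, d$end), c(3L, 9L))

  # internal K-P bond stays uncleaved: the whole N-terminal peptide survives
  d <- tryptic_digest("MPMYQVKPYHGGGAPLRSYGPAPK", p0)
  expect_true("MPMYQVKPYHGGGAPLR" %in% d$peptide)
  expect_false("MPMYQVK" %in% d$peptide)

  # suppression off restores the cut
  p_nokp <- digest_params(max_missed_cleavages = 0L, min_length = 7L,
                          suppress_before_proline = FALSE)
  expect_true("MPMYQVK" %in% tryptic_digest("MPMYQVKPYHGGGAPLRSYGPAPK",
                                            p_nokp)$peptide)
})

test_that("missed cleavages concatenate adjacent fragments", {
  p1 <- digest_params(max_missed_cleavages = 1L, min_length = 1L)
  d <- tryptic_digest("AAKCCCRDD", p1)
  expect_setequal(d$peptide, c("AAK", "CCCR", "DD", "AAKCCCR", "CCCRDD"))
  expect_equal(d$missed[d$peptide == "AAKCCCR"], 1L)
})

test_that("0-missed peptides reconstruct the parent sequence in coordinate order", {
  set.seed(11)
  p <- digest_params(max_missed_cleavages = 0L, min_length = 1L)
  for (i in 1:10) {
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 200,
                      replace = TRUE), collapse = "")
    d <- tryptic_digest(s, p)
    expect_identical(paste(d$peptide[order(d$start)], collapse = ""), s)
  }
})

test_that("digestion agrees with a brute-force substring oracle", {
  set.seed(101)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    s <- paste(sample(aas, 150, replace = TRUE), collapse = "")
    got <- sort(unique(tryptic_digest(s, digest_params())$peptide))
    expect_identical(got, brute_force_digest(s))
  }
})

test_that("N-terminal processing emits Met-retained/excised and acetylated forms", {
  f <- nterm_processed_forms("MANNDAVLKGGGGGGR")
  expect_setequal(paste0(ifelse(f$nterm_mod_delta == 42, "42+", ""), f$peptide),
                  c("MANNDAVLK", "ANNDAVLK", "42+MANNDAVLK", "42+ANNDAVLK"))
  expect_true(all(f$nterm_mod_delta %in% c(0L, 42L)))

  # W at position 2 blocks excision
  f <- nterm_processed_forms("MWNNDAVLKGGGGGGR")
  expect_setequal(f$form, "met_retained")
  expect_equal(nrow(f), 2L)

  expect_error(nterm_processed_forms("ANNDAVLKGGGGGGR"), "starting with M")
})

test_that("junction peptides are unique to the deletion variant", {
  db <- toy_isoform_db()
  cl <- classify_peptide("SYGPAPGAGHVQDYGALK", db, toy_isoform_groups())
  expect_equal(cl$classification, "unique")
  expect_equal(cl$proteins, "ISO2_DX")
  cl <- classify_peptide("SYGPAPGAGHVQEESNLSLQALESR", db, toy_isoform_groups())
  expect_equal(cl$classification, "unique")
  expect_equal(cl$proteins, "ISO2")
})

test_that("Met-retained N-terminal peptide of an extended pair is ambiguous", {
  db <- toy_isoform_db()
  groups <- toy_isoform_groups()
  cl <- classify_peptide("MANNDAVLK", db, groups)
  expect_equal(cl$classification, "ambiguous_nterm")
  expect_setequal(cl$proteins, c("ISO1", "ISO1_EXT"))

  # the Met-excised form only matches the canonical N-terminus
  cl <- classify_peptide("ANNDAVLK", db, groups)
  expect_equal(cl$classification, "unique")
  expect_equal(cl$proteins, "ISO1")

  # acetylated notation is accepted and stripped for matching
  cl <- classify_peptide("42+ANNDAVLK", db, groups)
  expect_equal(cl$classification, "unique")
  expect_equal(cl$nterm_mod_delta, 42L)

  # extension-specific peptide marks the variant
  cl <- classify_peptide("MLPAVAVSEPVVLR", db, groups)
  expect_equal(cl$classification, "unique")
  expect_equal(cl$proteins, "ISO1_EXT")

  expect_error(classify_peptide("WWWWWWWK", db, groups), "does not occur")
})

test_that("classification agrees with a substring-membership oracle on random databases", {
  set.seed(202)
  for (rep in 1:5) {
    cfg <- sim_config(seed = 300 + rep, n_core = 4L, n_background = 8L,
                      seq_length_range = c(150L, 250L))
    sim <- generate_protein_db(cfg)
    db <- sim$db
    # sample tryptic peptides from several proteins and classify each
    picks <- sample(nrow(db), 6L)
    for (i in picks) {
      peps <- tryptic_digest(db$sequence[i], digest_params())$peptide
      for (p in sample(peps, min(4L, length(peps)))) {
        cl <- classify_peptide(p, db, sim$isoform_groups)
        expect_setequal(cl$proteins, substring_hits(p, db))
      }
    }
  }
})

test_that("no peptide is unique to two isoforms and tallies are order-invariant", {
  db <- toy_isoform_db()
  groups <- toy_isoform_groups()
  all_peps <- unique(unlist(lapply(db$sequence, function(s)
    tryptic_digest(s, digest_params())$peptide)))
  cls <- lapply(all_peps, classify_peptide, db = db, isoform_groups = groups)
  uniq_owner <- lapply(cls, function(c)
    if (c$classification == "unique") c$proteins else NULL)
  expect_true(all(lengths(uniq_owner) <= 1L))

  classifications <- data.frame(
    peptide = all_peps,
    classification = vapply(cls, `[[`, character(1), "classification"),
    protein_id = vapply(cls, function(c)
      if (c$classification == "unique") c$proteins else NA_character_,
      character(1)),
    stringsAsFactors = FALSE)
  set.seed(5)
  evidence <- data.frame(
    peptide = rep(all_peps, each = 2L), nterm_mod_delta = 0L,
    run_id = rep(c("r1", "r2"), length(all_peps)),
    count = rpois(2L * length(all_peps), 4), stringsAsFactors = FALSE)
  t1 <- tally_isoform_counts(evidence, classifications)
  t2 <- tally_isoform_counts(evidence[sample(nrow(evidence)), ],
                             classifications)
  expect_identical(t1, t2)
  # unique tallies sum only unique peptide counts
  is_uniq <- classifications$classification[
    match(evidence$peptide, classifications$peptide)] == "unique"
  expect_equal(sum(t1$unique$total_spectra), sum(evidence$count[is_uniq]))
  # shared/ambiguous never apportioned: reported separately
  expect_equal(sum(t1$other$total_spectra), sum(evidence$count[!is_uniq]))
})

test_that("tally with no unique peptides reports zero with shared counts", {
  classifications <- data.frame(peptide = "AAAAAAK",
                                classification = "shared",
                                protein_id = NA_character_,
                                stringsAsFactors = FALSE)
  evidence <- data.frame(peptide = "AAAAAAK", nterm_mod_delta = 0L,
                         run_id = "r1", count = 5L, stringsAsFactors = FALSE)
  t <- tally_isoform_counts(evidence, classifications)
  expect_equal(nrow(t$unique), 0L)
  expect_equal(t$other$total_spectra, 5L)
})

test_that("isoform evidence report carries classifications and totals", {
  db <- toy_isoform_db()
  evidence <- data.frame(
    peptide = c("MANNDAVLK", "SYGPAPGAGHVQDYGALK", "SYGPAPGAGHVQDYGALK"),
    nterm_mod_delta = 0L, run_id = c("r1", "r1", "r2"),
    count = c(16L, 20L, 15L), stringsAsFactors = FALSE)
  rep <- isoform_evidence_report(evidence, db, toy_isoform_groups())
  expect_equal(rep$classification[rep$peptide == "MANNDAVLK"],
               "ambiguous_nterm")
  expect_equal(rep$total_spectra[rep$peptide == "SYGPAPGAGHVQDYGALK"], 35L)
})
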