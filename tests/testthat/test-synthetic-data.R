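test_that("cohort config validation names the offending field", {
  expect_error(cohort_config(n_proteins = 0), "n_proteins")
  expect_error(cohort_config(group_sizes = c(normal = 5, tnbc = 5)),
               "group_sizes")
  expect_error(cohort_config(de_fraction = 1.5), "de_fraction")
  expect_error(cohort_config(psm_noise_sd = -1), "psm_noise_sd")
  expect_error(cohort_config(missing_rates = c(0.1, 0.1)), "missing_rates")
  expect_error(cohort_config(missing_rates = c(0.95, 0.1, 0.1)),
               "missing_rates")
})

test_that("a 3-plex cohort has 3 PSM tables, 27 samples and 3 references", {
  b <- generate_cohort(cohort_config(n_proteins = 30, seed = 3))
  expect_length(b$psm_tables, 3)
  expect_equal(sum(!b$design$is_reference), 27)
  expect_equal(sum(b$design$is_reference), 3)
  expect_equal(nrow(b$annotation), 27)
  expect_setequal(b$design$sample_id[!b$design$is_reference],
                  b$annotation$sample_id)
  # every plex hosts samples from several groups (design not confounded)
  per_plex_groups <- tapply(
    b$annotation$group, b$annotation$batch, function(g) length(unique(g)))
  expect_true(all(per_plex_groups >= 3))
})

test_that("zero DE fraction yields a null cohort", {
  b <- generate_cohort(cohort_config(n_proteins = 25, de_fraction = 0,
                                     seed = 4))
  expect_true(all(!b$truth$de_flags$is_de))
  expect_true(all(b$truth$de_flags$effect == 0))
})

test_that("DE flags carry exactly the configured effect size", {
  b <- generate_cohort(cohort_config(n_proteins = 50, de_fraction = 0.2,
                                     effect_size = 1.5, seed = 5))
  fl <- b$truth$de_flags
  expect_equal(sum(fl$is_de), 10)
  expect_true(all(abs(fl$effect[fl$is_de]) == 1.5))
  expect_true(all(fl$effect[!fl$is_de] == 0))
})

test_that("emitted row counts match an independent per-protein re-count", {
  cfg <- cohort_config(n_proteins = 40, psms_per_protein = 5,
                       contaminant_fraction = 0, lowquality_fraction = 0,
                       seed = 6)
  b <- generate_cohort(cfg)
  for (tbl in b$psm_tables) {
    counts <- table(tbl$protein)
    expect_length(counts, 40)          # every protein quantifiable
    expect_true(all(counts >= 1))      # shifted-Poisson floor
    expect_equal(sum(counts), nrow(tbl))
  }
})

test_that("identical seed gives identical cohorts, different seed differs", {
  cfg <- cohort_config(n_proteins = 20, seed = 9)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  b2 <- generate_cohort(cohort_config(n_proteins = 20, seed = 10))
  expect_false(identical(generate_cohort(cfg)$psm_tables, b2$psm_tables))
})

test_that("reference channel is the master mix: pooled mean of all samples", {
  cfg <- cohort_config(n_proteins = 15, psm_noise_sd = 0,
                       batch_shift_sd = 0, missing_rates = rep(0, 3),
                       contaminant_fraction = 0, lowquality_fraction = 0,
                       seed = 11)
  b <- generate_cohort(cfg)
  truth <- b$truth$protein_abundance
  for (k in 1:3) {
    tbl <- b$psm_tables[[k]]
    dk <- b$design[b$design$plex_id == paste0("plex", k), ]
    sam <- dk$sample_id[!dk$is_reference]
    sam_cols <- paste0("channel_", dk$channel[!dk$is_reference])
    # log2(ref) - mean(log2 sample channels): PSM effect cancels, leaving
    # grand mean minus plex mean of the true abundances
    for (r in seq_len(nrow(tbl))) {
      pr <- tbl$protein[r]
      lhs <- log2(tbl$channel_131[r]) -
        mean(log2(unlist(tbl[r, sam_cols])))
      rhs <- mean(truth[pr, ]) - mean(truth[pr, sam])
      expect_equal(lhs, rhs, tolerance = 1e-9)
    }
  }
})

test_that("low-quality injection corrupts exactly the requested fraction", {
  cfg <- cohort_config(n_proteins = 50, psms_per_protein = 2,
                       contaminant_fraction = 0, lowquality_fraction = 0,
                       missing_rates = rep(0, 3), seed = 12)
  b <- generate_cohort(cfg)
  tbl <- b$psm_tables[[1]]
  expect_identical(inject_low_quality(tbl, 0), tbl)
  out <- inject_low_quality(tbl, 0.1, seed = 2)
  n_bad <- sum(!is.na(out$lq_violation))
  expect_equal(n_bad, round(0.1 * nrow(tbl)))
  expect_true(all(c("probability", "purity") %in% out$lq_violation))
  # corrupted probabilities / purities actually violate the thresholds
  expect_true(all(out$peptide_probability[
    out$lq_violation %in% "probability"] < 0.9))
  expect_true(all(out$precursor_purity[out$lq_violation %in% "purity"] < 0.5))
})

test_that("the quality filter later removes exactly the corrupted records", {
  # narrow abundance spread so no clean PSM accidentally trips the
  # intensity filters; the kept set must then equal the unlabeled rows
  cfg <- cohort_config(n_proteins = 60, psms_per_protein = 3,
                       abundance_sd = 0.5, contaminant_fraction = 0,
                       lowquality_fraction = 0.1,
                       missing_rates = rep(0, 3), seed = 13)
  b <- generate_cohort(cfg)
  for (tbl in b$psm_tables) {
    flt <- filter_psms(tbl, filter_criteria(), reference_channel = "131")
    expect_setequal(flt$kept$spectrum_id,
                    tbl$spectrum_id[is.na(tbl$lq_violation)])
  }
})

test_that("realized missingness matches the request within 2% over seeds", {
  cfg <- cohort_config(n_proteins = 40, psms_per_protein = 3,
                       contaminant_fraction = 0, lowquality_fraction = 0,
                       missing_rates = c(0.18, 0.14, 0.12), seed = 1)
  base <- generate_cohort(
    cohort_config(n_proteins = 40, psms_per_protein = 3,
                  contaminant_fraction = 0, lowquality_fraction = 0,
                  missing_rates = rep(0, 3), seed = 1))
  sample_cols <- setdiff(paste0("channel_", tmt10_channels()), "channel_131")
  for (s in 1:10) {
    out <- inject_missingness(base$psm_tables, c(0.18, 0.14, 0.12), seed = s)
    rates <- vapply(out, function(tbl)
      mean(is.na(as.matrix(tbl[, sample_cols]))), numeric(1))
    expect_true(all(abs(rates - c(0.18, 0.14, 0.12)) <= 0.02))
    # reference channel never blanked
    for (tbl in out) expect_false(anyNA(tbl$channel_131))
  }
})

test_that("missingness rate 0 is a no-op and rates >= 0.9 are rejected", {
  b <- generate_cohort(cohort_config(n_proteins = 10,
                                     missing_rates = rep(0, 3),
                                     lowquality_fraction = 0, seed = 2))
  out <- inject_missingness(b$psm_tables, rep(0, 3), seed = 1)
  expect_false(anyNA(as.matrix(out[[1]][, paste0("channel_",
                                                 tmt10_channels())])))
  expect_error(inject_missingness(b$psm_tables, c(0.9, 0.1, 0.1), seed = 1),
               "0.9")
})

test_that("intensity-dependent missingness hits low-abundance cells first", {
  b <- generate_cohort(cohort_config(n_proteins = 60, psms_per_protein = 3,
                                     missing_rates = rep(0, 3),
                                     lowquality_fraction = 0, seed = 21))
  sample_cols <- setdiff(paste0("channel_", tmt10_channels()), "channel_131")
  pre <- as.matrix(b$psm_tables[[1]][, sample_cols])
  out <- inject_missingness(b$psm_tables, rep(0.2, 3), seed = 3,
                            mechanism = "mnar")
  mask <- attr(out, "missing_mask")[[1]]
  expect_lt(mean(log2(pre[mask])), mean(log2(pre[!mask])))
})

test_that("fixture write/read round trip is value-exact with schema headers", {
  b <- generate_cohort(cohort_config(n_proteins = 12, psms_per_protein = 2,
                                     seed = 30))
  dir <- withr::local_tempdir()
  paths <- write_fixture(b, dir)
  for (k in 1:3) {
    back <- read_psm_table(paths[[sprintf("psm_plex%d", k)]])
    expect_identical(names(back), psm_schema())
    orig <- b$psm_tables[[k]][, psm_schema()]
    rownames(orig) <- NULL
    expect_equal(back, orig)
  }
  expect_equal(read_design(paths[["design"]]), b$design,
               ignore_attr = "row.names")
  expect_equal(read_annotation(paths[["annotation"]]), b$annotation,
               ignore_attr = "row.names")
})

test_that("shipped fixture stays small and matches the schema", {
  dir <- system.file("extdata", "fixture", package = "tmtpipe")
  files <- list.files(dir, full.names = TRUE)
  expect_gt(length(files), 0)
  expect_lt(sum(file.size(files)), 2e6)
  psm <- read_psm_table(file.path(dir, "psm_plex1.tsv"))
  expect_identical(names(psm), psm_schema())
})
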