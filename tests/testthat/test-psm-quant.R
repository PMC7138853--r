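test_that("filter keeps only PSMs passing all criteria", {
  psms <- make_psms(5, probability = c(0.99, 0.85, 0.99, 0.99, 0.99),
                    purity = c(0.9, 0.9, 0.4, 0.9, 0.9))
  psms$protein[4] <- "contam_KRT01"
  flt <- filter_psms(psms, filter_criteria(), reference_channel = "131")
  expect_setequal(flt$kept$spectrum_id, psms$spectrum_id[c(1, 5)])
  expect_equal(unname(flt$report[c("probability", "purity", "contaminant")]),
               c(1L, 1L, 1L))
  expect_equal(unname(flt$report["kept"]), 2L)
})

test_that("empty input filters to empty output with an all-zero report", {
  psms <- make_psms(1)[0, ]
  flt <- filter_psms(psms, filter_criteria())
  expect_equal(nrow(flt$kept), 0)
  expect_true(all(flt$report == 0))
  expect_error(filter_psms(make_psms(2), reference_channel = "999"),
               "reference channel")
})

test_that("rejections are attributed to the first failing criterion", {
  psms <- make_psms(3)
  psms$channel_131[1] <- NA          # fails reference AND probability
  psms$peptide_probability[1] <- 0.5
  psms$precursor_purity[2] <- 0.1    # fails purity only
  flt <- filter_psms(psms, filter_criteria())
  expect_equal(unname(flt$report["reference"]), 1L)
  expect_equal(unname(flt$report["probability"]), 0L)
  expect_equal(unname(flt$report["purity"]), 1L)
})

test_that("deduplication keeps the highest-TMT-sum PSM, earliest on ties", {
  rep_mat <- matrix(c(rep(10, 10), rep(20, 10), rep(20, 10)), nrow = 3,
                    byrow = TRUE)
  psms <- make_psms(3, spectrum_id = c("a", "a", "a"), reporters = rep_mat)
  out <- deduplicate_psms(psms)
  expect_equal(nrow(out), 1)
  expect_equal(out$protein, "P02")  # sum 200 beats 100; tie keeps row 2
  psms2 <- make_psms(3)
  expect_identical(deduplicate_psms(psms2), psms2)
})

test_that("log2 ratios follow the reference-subtraction definition", {
  rep_mat <- matrix(100, 2, 10)
  rep_mat[1, 1] <- 100   # equal to reference -> ratio 0
  rep_mat[2, 1] <- 400   # 4x reference -> ratio 2
  psms <- make_psms(2, reporters = rep_mat)
  d <- make_design()
  rr <- to_log_ratios(psms, d)
  expect_equal(rr$s01, c(0, 2))
  bad <- make_psms(1, reporters = matrix(c(-5, rep(100, 9)), 1))
  expect_error(to_log_ratios(bad, d), "sp001")
})

test_that("pooled-reference mode uses the per-PSM mean of all channels", {
  rep_mat <- matrix(2 ^ (1:10), 1, 10)
  psms <- make_psms(1, reporters = rep_mat)
  d <- make_design()
  rr <- to_log_ratios(psms, d, pooled_reference = TRUE)
  expect_equal(unlist(rr[1, d$sample_id[1:9]], use.names = FALSE),
               (1:9) - mean(1:10))
})

test_that("IQR outlier removal matches an independent quantile oracle", {
  expect_equal(remove_outliers_iqr(rep(1, 5)), rep(1, 5))
  expect_equal(remove_outliers_iqr(c(1, 2, 3)), c(1, 2, 3))  # < 4 values
  v <- c(1, 2, 3, 4, 100)
  q1 <- oracle_quantile7(v, 0.25); q3 <- oracle_quantile7(v, 0.75)
  fence <- c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1))
  expect_equal(remove_outliers_iqr(v), v[v >= fence[1] & v <= fence[2]])
  expect_equal(remove_outliers_iqr(v), c(1, 2, 3, 4))
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(4:30, 1))
    q <- c(oracle_quantile7(x, 0.25), oracle_quantile7(x, 0.75))
    iqr <- q[2] - q[1]
    expect_equal(remove_outliers_iqr(x),
                 x[x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr])
  }
})

test_that("roll-up takes per-cell medians and honors the grouping level", {
  rep_mat <- matrix(100, 3, 10)
  rep_mat[, 1] <- 100 * 2 ^ c(1, 2, 9)
  psms <- make_psms(3, protein = c("P1", "P1", "P1"), gene = rep("G1", 3))
  psms[, paste0("channel_", tmt10_channels())] <- rep_mat
  d <- make_design()
  rr <- to_log_ratios(psms, d)
  mat <- rollup(rr, "protein", iqr_k = NULL)
  expect_equal(mat["P1", "s01"], 2)  # median of {1,2,9}
  # gene grouping merges proteins sharing a symbol
  psms2 <- make_psms(2, protein = c("P1", "P2"), gene = c("G", "G"))
  mat2 <- rollup(to_log_ratios(psms2, d), "gene")
  expect_equal(rownames(mat2), "G")
  # single PSM: matrix equals that PSM's ratios
  psms3 <- make_psms(1, reporters = matrix(100 * 2 ^ c(3, rep(0, 9)), 1))
  expect_equal(unname(rollup(to_log_ratios(psms3, d), "protein")[1, 1]), 3)
})

test_that("MAD normalization reproduces the worked two-sample example", {
  mat <- cbind(A = c(1, 2, 3), B = c(2, 4, 6))
  out <- mad_normalize(mat)
  expect_equal(unname(out[, "A"]), c(-1.5, 0, 1.5))
  expect_equal(unname(out[, "B"]), c(-1.5, 0, 1.5))
  expect_equal(attr(out, "MAD0"), 1.5)
  expect_equal(unname(attr(out, "MAD")), c(1, 2))
})

test_that("normalization invariants hold on arbitrary matrices", {
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(rnorm(200), 20, 10)
    m[sample(200, 30)] <- NA
    out <- mad_normalize(m)
    meds <- apply(out, 2, median, na.rm = TRUE)
    expect_true(all(abs(meds) < 1e-9))
    mads <- apply(abs(out), 2, median, na.rm = TRUE)
    expect_true(all(abs(mads - attr(out, "MAD0")) < 1e-9))
    # idempotence
    again <- mad_normalize(out)
    expect_equal(unclass(again)[, ], unclass(out)[, ], tolerance = 1e-9)
    # shift invariance: adding a constant to one sample changes nothing
    shifted <- m
    shifted[, 3] <- shifted[, 3] + 7
    expect_equal(unclass(mad_normalize(shifted))[, ], unclass(out)[, ],
                 tolerance = 1e-9)
  }
})

test_that("single-sample matrix centers without rescaling", {
  m <- matrix(c(1, 2, 4), 3, 1, dimnames = list(NULL, "A"))
  out <- mad_normalize(m)
  expect_equal(unname(out[, 1]), c(-1, 0, 2))
})

test_that("all-equal sample is returned centered with a warning", {
  m <- cbind(A = c(1, 2, 3), B = c(5, 5, 5))
  expect_warning(out <- mad_normalize(m), "zero MAD")
  expect_equal(unname(out[, "B"]), c(0, 0, 0))
})

test_that("reference intensity is the top-3 MS1 sum with global-min fill", {
  p1 <- make_psms(4, protein = rep("P1", 4), ms1 = c(10, 20, 30, 40))
  expect_equal(estimate_reference_intensity(list(p1))["P1", "ref_intensity"],
               90)
  p2 <- make_psms(3, protein = rep("P2", 3), ms1 = c(5, 6, 7))
  expect_equal(estimate_reference_intensity(list(p2))["P2", "ref_intensity"],
               18)
  # P1 absent from plex 2: its term there is the global minimum (18)
  both <- estimate_reference_intensity(list(p1, p2))
  expect_equal(both["P1", "ref_intensity"], (90 + 18) / 2)
  expect_equal(both["P2", "ref_intensity"], (18 + 18) / 2)
})

test_that("abundance back-conversion adds log2 reference intensity", {
  norm <- matrix(0, 1, 2, dimnames = list("P1", c("a", "b")))
  ref <- data.frame(entry = "P1", ref_intensity = 8)
  expect_equal(unname(to_abundance(norm, ref)[1, ]), c(3, 3))
  norm2 <- matrix(c(1, 4), 1, 2, dimnames = list("P1", c("a", "b")))
  ab2 <- to_abundance(norm2, ref)
  expect_equal(unname(ab2[1, "b"] - ab2[1, "a"]),
               unname(norm2[1, "b"] - norm2[1, "a"]))
  expect_error(to_abundance(rbind(norm, P9 = 0), ref), "P9")
})

test_that("plex integration unions proteins and tracks provenance", {
  m1 <- matrix(1, 2, 2, dimnames = list(c("P1", "P2"), c("s1", "s2")))
  m2 <- matrix(2, 2, 2, dimnames = list(c("P2", "P3"), c("s3", "s4")))
  out <- integrate_plexes(list(a = m1, b = m2))
  expect_setequal(rownames(out), c("P1", "P2", "P3"))
  expect_true(is.na(out["P1", "s3"]) && is.na(out["P3", "s1"]))
  expect_equal(out["P2", "s3"], 2)
  expect_equal(unname(attr(out, "plex")), c("a", "a", "b", "b"))
  expect_identical(integrate_plexes(list(only = m1))[, ], m1[, ])
  m_dup <- matrix(3, 1, 1, dimnames = list("P1", "s1"))
  expect_error(integrate_plexes(list(m1, m_dup)), "duplicate sample")
})

test_that("quantification chain equals brute-force recomputation", {
  d <- make_design()
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    reps <- matrix(2 ^ rnorm(n * 10, 10, 2), n, 10)
    psms <- make_psms(n,
                      protein = sprintf("P%d", sample(1:4, n, replace = TRUE)),
                      spectrum_id = sprintf("sp%d", sample(1:n, n, replace = TRUE)),
                      probability = runif(n, 0.7, 1),
                      purity = runif(n, 0.3, 1),
                      ms1 = 10 ^ runif(n, 2, 6),
                      reporters = reps)
    got <- quantify_plex(psms, d)$ratios
    want <- oracle_quantify(psms, d)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got[order(rownames(got)), , drop = FALSE],
                   want[order(rownames(want)), , drop = FALSE],
                   tolerance = 1e-12)
    }
  }
})

test_that("noise-free cohort is recovered exactly up to sample medians", {
  cfg <- cohort_config(n_proteins = 25, psms_per_protein = 3,
                       psm_noise_sd = 0, batch_shift_sd = 0,
                       missing_rates = rep(0, 3), contaminant_fraction = 0,
                       lowquality_fraction = 0, seed = 19)
  b <- generate_cohort(cfg)
  mats <- lapply(1:3, function(k)
    quantify_plex(b$psm_tables[[k]],
                  b$design[b$design$plex_id == paste0("plex", k), ])$ratios)
  comb <- integrate_plexes(mats)
  truth <- b$truth$protein_abundance[rownames(comb), colnames(comb)]
  # without noise, batch shifts or missingness the recovered ratios equal
  # the true abundances relative to the master mix exactly, so abundance
  # differences between any two samples match the truth; normalization
  # only removes each sample's median on top of this
  expect_equal(unclass(comb)[, ], truth - rowMeans(truth), tolerance = 1e-9)
  # sample-to-sample differences of the truth are recoverable from the
  # ratio matrix for every protein
  d_got <- comb[, 5] - comb[, 12]
  d_true <- truth[, 5] - truth[, 12]
  expect_equal(unname(d_got), unname(d_true), tolerance = 1e-9)
})
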