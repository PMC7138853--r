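#' PSM quality-filter criteria
#'
#' Thresholds applied to each PSM before quantification. The defaults are
#' the usual TMT quantification settings: minimum peptide probability 0.9,
#' precursor purity at least 50%, MS1 precursor intensity at least 0.05% of
#' the per-plex maximum, summed reporter (MS2) intensity at least 5% of the
#' per-plex median of that sum, a quantified reference channel required,
#' and contaminant proteins (`contam_` prefix) excluded.
#'
#' The MS1 and MS2 percentage thresholds need a denominator the instrument
#' does not provide; here they are anchored to the per-plex maximum MS1
#' intensity and the per-plex median summed reporter intensity
#' respectively. Both anchors are scale-free and configurable here.
#'
#' @param min_peptide_probability Minimum PeptideProphet-style probability.
#' @param min_precursor_purity Minimum precursor isolation purity.
#' @param min_ms1_intensity_percentile MS1 intensity floor, as a fraction
#'   of the maximum MS1 intensity in the plex.
#' @param min_ms2_fraction Reporter-sum floor, as a fraction of the plex
#'   median reporter sum.
#' @param require_reference_quantified Drop PSMs whose reference reporter
#'   is missing.
#' @param exclude_contaminants Drop PSMs whose protein ID starts with
#'   `contam_`.
#' @return A list of class `"filter_criteria"`.
#' @export
filter_criteria <- function(min_peptide_probability = 0.9,
                            min_precursor_purity = 0.5,
                            min_ms1_intensity_percentile = 0.0005,
                            min_ms2_fraction = 0.05,
                            require_reference_quantified = TRUE,
                            exclude_contaminants = TRUE) {
  crit <- list(min_peptide_probability = min_peptide_probability,
               min_precursor_purity = min_precursor_purity,
               min_ms1_intensity_percentile = min_ms1_intensity_percentile,
               min_ms2_fraction = min_ms2_fraction,
               require_reference_quantified = require_reference_quantified,
               exclude_contaminants = exclude_contaminants)
  num <- c("min_peptide_probability", "min_precursor_purity",
           "min_ms1_intensity_percentile", "min_ms2_fraction")
  for (f in num) {
    if (crit[[f]] < 0 || crit[[f]] > 1)
      stop(sprintf("filter criterion '%s' must be in [0, 1]", f),
           call. = FALSE)
  }
  class(crit) <- "filter_criteria"
  crit
}

#' Filter PSMs by quality criteria
#'
#' A PSM is kept iff it passes all criteria. Rejections are attributed to
#' the first failing criterion in a fixed documented order: missing
#' reference quantification, peptide probability, precursor purity, MS1
#' intensity, summed MS2 (reporter) intensity, contaminant.
#'
#' @param psms PSM data frame ([psm_schema()] columns; extra columns pass
#'   through).
#' @param criteria A [filter_criteria()].
#' @param reference_channel Reference channel name, e.g. `"131"`.
#' @return List with `kept` (the surviving rows, input order preserved) and
#'   `report` (named integer vector of rejection counts per criterion,
#'   plus `kept` and `input`).
#' @export
filter_psms <- function(psms, criteria = filter_criteria(),
                        reference_channel = "131") {
  ref_col <- paste0("channel_", reference_channel)
  if (!ref_col %in% names(psms))
    stop("unknown reference channel: ", reference_channel, call. = FALSE)
  rep_cols <- intersect(reporter_cols(), names(psms))
  n <- nrow(psms)
  report <- c(reference = 0L, probability = 0L, purity = 0L,
              ms1 = 0L, ms2 = 0L, contaminant = 0L)
  if (n == 0) {
    return(list(kept = psms, report = c(report, kept = 0L, input = 0L)))
  }
  ms1_floor <- criteria$min_ms1_intensity_percentile *
    max(psms$ms1_intensity, na.rm = TRUE)
  rep_sum <- rowSums(psms[, rep_cols, drop = FALSE], na.rm = TRUE)
  ms2_floor <- criteria$min_ms2_fraction * stats::median(rep_sum)

  fail_ref <- criteria$require_reference_quantified &
    (is.na(psms[[ref_col]]) | psms[[ref_col]] <= 0)
  fail_prob <- psms$peptide_probability < criteria$min_peptide_probability
  fail_pur <- psms$precursor_purity < criteria$min_precursor_purity
  fail_ms1 <- is.na(psms$ms1_intensity) | psms$ms1_intensity < ms1_floor
  fail_ms2 <- rep_sum < ms2_floor
  fail_contam <- criteria$exclude_contaminants &
    startsWith(psms$protein, "contam_")

  first_fail <- rep(NA_character_, n)
  for (crit in c("contaminant", "ms2", "ms1", "purity", "probability",
                 "reference")) {
    fail <- switch(crit, reference = fail_ref, probability = fail_prob,
                   purity = fail_pur, ms1 = fail_ms1, ms2 = fail_ms2,
                   contaminant = fail_contam)
    first_fail[fail] <- crit
  }
  rejected <- !is.na(first_fail)
  tab <- table(factor(first_fail[rejected], levels = names(report)))
  report[names(tab)] <- as.integer(tab)
  list(kept = psms[!rejected, , drop = FALSE],
       report = c(report, kept = sum(!rejected), input = n))
}

#' Deduplicate PSMs sharing a spectrum
#'
#' Among PSMs with the same `spectrum_id`, keeps the single PSM with the
#' highest summed reporter (TMT) intensity; exact ties keep the earliest
#' record. Input order of the survivors is preserved.
#'
#' @param psms PSM data frame.
#' @return Deduplicated PSM data frame.
#' @export
deduplicate_psms <- function(psms) {
  if (nrow(psms) <= 1) return(psms)
  rep_cols <- intersect(reporter_cols(), names(psms))
  sums <- rowSums(psms[, rep_cols, drop = FALSE], na.rm = TRUE)
  keep <- rep(FALSE, nrow(psms))
  for (idx in split(seq_len(nrow(psms)), psms$spectrum_id)) {
    keep[idx[which.max(sums[idx])]] <- TRUE
  }
  psms[keep, , drop = FALSE]
}

#' Convert PSM reporter intensities to log2 ratios against the reference
#'
#' For each non-reference channel `c` of each PSM:
#' `ratio = log2(reporter_c) - log2(reporter_ref)`. With
#' `pooled_reference = TRUE` (the single-plex design that has no master-mix
#' channel) the reference term is instead the mean of the log2 reporter
#' intensities over all channels of the PSM, and every channel yields a
#' ratio.
#'
#' @param psms Filtered PSM data frame.
#' @param design Plex design data frame (`plex_id, channel, sample_id,
#'   is_reference`) for one plex.
#' @param pooled_reference Use the per-PSM mean over all channels as the
#'   reference instead of a dedicated reference channel.
#' @return Data frame with one row per PSM: `spectrum_id, protein, gene`
#'   and one log2-ratio column per (non-reference) sample.
#' @export
to_log_ratios <- function(psms, design, pooled_reference = FALSE) {
  if (!pooled_reference) {
    ref_rows <- design[design$is_reference, , drop = FALSE]
    if (nrow(ref_rows) != 1)
      stop("design must flag exactly one reference channel", call. = FALSE)
    ref_col <- paste0("channel_", ref_rows$channel)
    sample_rows <- design[!design$is_reference, , drop = FALSE]
  } else {
    sample_rows <- design[!design$is_reference, , drop = FALSE]
    if (nrow(sample_rows) == 0) sample_rows <- design
  }
  cols <- paste0("channel_", sample_rows$channel)
  missing_cols <- setdiff(cols, names(psms))
  if (length(missing_cols) > 0)
    stop("PSM table lacks reporter columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  vals <- as.matrix(psms[, cols, drop = FALSE])
  bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
  if (length(bad) > 0)
    stop("non-positive reporter intensity in record ",
         psms$spectrum_id[bad[1, 1]], call. = FALSE)
  if (!pooled_reference) {
    ref <- psms[[ref_col]]
    if (any(is.na(ref) | ref <= 0))
      stop("non-positive or missing reference reporter in record ",
           psms$spectrum_id[which(is.na(ref) | ref <= 0)[1]], call. = FALSE)
    ratios <- log2(vals) - log2(ref)
  } else {
    all_cols <- intersect(reporter_cols(), names(psms))
    all_vals <- as.matrix(psms[, all_cols, drop = FALSE])
    ref_log <- rowMeans(log2(all_vals), na.rm = TRUE)
    ratios <- log2(vals) - ref_log
  }
  colnames(ratios) <- sample_rows$sample_id
  out <- data.frame(spectrum_id = psms$spectrum_id, protein = psms$protein,
                    gene = psms$gene, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(ratios))
}

#' Remove outliers by the 1.5-IQR fence rule
#'
#' Values outside `[Q1 - k*IQR, Q3 + k*IQR]` are removed, with quartiles by
#' linear interpolation (`stats::quantile` type 7). Groups with fewer than
#' `min_n` values are returned unchanged: quartiles of very few points
#' over-trim. `NA`s pass through untouched.
#'
#' @param values Numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @param min_n Minimum group size for the rule to apply (default 4).
#' @return The values with outliers removed.
#' @export
remove_outliers_iqr <- function(values, k = 1.5, min_n = 4L) {
  obs <- values[!is.na(values)]
  if (length(obs) < min_n) return(values)
  q <- stats::quantile(obs, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  values[is.na(values) | (values >= lo & values <= hi)]
}

#' Roll PSM-level ratios up to a protein (or gene) by sample matrix
#'
#' PSM log2 ratios are grouped by protein (or gene) and, per sample, the
#' 1.5-IQR outlier rule is applied within each group before taking the
#' median. Cells with no surviving PSM are missing.
#'
#' @param ratio_rows Output of [to_log_ratios()].
#' @param grouping `"protein"` or `"gene"`.
#' @param iqr_k Outlier fence multiplier; `NULL` disables outlier removal.
#' @return Numeric matrix (entries x samples) of median log2 ratios.
#' @export
rollup <- function(ratio_rows, grouping = c("protein", "gene"),
                   iqr_k = 1.5) {
  grouping <- match.arg(grouping)
  key <- ratio_rows[[grouping]]
  sample_cols <- setdiff(names(ratio_rows),
                         c("spectrum_id", "protein", "gene"))
  entries <- unique(key)
  mat <- matrix(NA_real_, nrow = length(entries), ncol = length(sample_cols),
                dimnames = list(entries, sample_cols))
  idx_by_entry <- split(seq_len(nrow(ratio_rows)), factor(key, levels = entries))
  for (e in entries) {
    idx <- idx_by_entry[[e]]
    for (s in sample_cols) {
      v <- ratio_rows[[s]][idx]
      if (!is.null(iqr_k)) v <- remove_outliers_iqr(v, k = iqr_k)
      v <- v[!is.na(v)]
      if (length(v) > 0) mat[e, s] <- stats::median(v)
    }
  }
  mat
}

#' Median/MAD normalization of a log2 ratio matrix
#'
#' Per sample `i` over its non-missing entries: the sample median
#' `M_i = median(R_ij)` is subtracted (`R^C_ij = R_ij - M_i`), the sample
#' scale `MAD_i = median(|R^C_ij|)` is computed along with the global scale
#' `MAD_0 = median over samples of MAD_i`, and ratios are rescaled to the
#' common scale: `R^N_ij = (R^C_ij / MAD_i) * MAD_0`. Missing cells stay
#' missing. A sample whose values are all equal has `MAD_i = 0` and is
#' returned centered but unscaled, with a warning.
#'
#' @param mat Numeric matrix, proteins x samples, of log2 ratios.
#' @return Normalized matrix with attributes `M` (per-sample medians),
#'   `MAD` (per-sample MADs) and `MAD0`.
#' @export
mad_normalize <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs == 0))
    stop("sample(s) with no observed value: ",
         paste(colnames(mat)[n_obs == 0], collapse = ", "), call. = FALSE)
  M <- apply(mat, 2, stats::median, na.rm = TRUE)
  centered <- sweep(mat, 2, M)
  MAD <- apply(abs(centered), 2, stats::median, na.rm = TRUE)
  MAD0 <- stats::median(MAD)
  scale <- ifelse(MAD > 0, MAD0 / MAD, 1)
  if (any(MAD == 0))
    warning("sample(s) with zero MAD left unscaled: ",
            paste(colnames(mat)[MAD == 0], collapse = ", "), call. = FALSE)
  out <- sweep(centered, 2, scale, `*`)
  attr(out, "M") <- M
  attr(out, "MAD") <- MAD
  attr(out, "MAD0") <- MAD0
  out
}

#' Estimate per-protein reference intensities from MS1 precursor signal
#'
#' For protein `i` in plex `k`, `REF_ik` is the (by default unweighted) sum
#' of the three largest MS1 precursor intensities among the protein's PSMs
#' in that plex (all of them if fewer than three). `REF_i` is the mean of
#' `REF_ik` over plexes, where a plex in which the protein was not observed
#' contributes the global minimum `REF_ik` over all proteins and plexes.
#'
#' @param psm_tables List of filtered per-plex PSM data frames.
#' @param grouping `"protein"` or `"gene"`.
#' @param top_n Number of top peptide ions summed (default 3).
#' @param weights Optional weights for the top intensities, recycled to
#'   `top_n`; default all 1 (unweighted sum).
#' @return Data frame `entry, ref_intensity` plus per-plex columns; entries
#'   with no PSM in any plex are excluded with a warning.
#' @export
estimate_reference_intensity <- function(psm_tables,
                                         grouping = c("protein", "gene"),
                                         top_n = 3L, weights = NULL) {
  grouping <- match.arg(grouping)
  if (is.null(weights)) weights <- rep(1, top_n)
  weights <- rep_len(weights, top_n)
  if (!is.list(psm_tables) || is.data.frame(psm_tables))
    psm_tables <- list(psm_tables)
  q <- length(psm_tables)
  per_plex <- lapply(psm_tables, function(tbl) {
    vapply(split(tbl$ms1_intensity, tbl[[grouping]]), function(v) {
      v <- sort(v[!is.na(v)], decreasing = TRUE)
      v <- v[seq_len(min(top_n, length(v)))]
      sum(v * weights[seq_along(v)])
    }, numeric(1))
  })
  entries <- sort(unique(unlist(lapply(per_plex, names))))
  if (length(entries) == 0)
    stop("no quantified entries in any plex", call. = FALSE)
  ref_mat <- matrix(NA_real_, nrow = length(entries), ncol = q,
                    dimnames = list(entries, paste0("plex", seq_len(q))))
  for (k in seq_len(q)) ref_mat[names(per_plex[[k]]), k] <- per_plex[[k]]
  global_min <- min(ref_mat, na.rm = TRUE)
  filled <- ref_mat
  filled[is.na(filled)] <- global_min
  out <- data.frame(entry = entries, ref_intensity = rowMeans(filled),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ref_mat))
  rownames(out) <- entries
  out
}

#' Convert normalized log2 ratios back to log2 abundances
#'
#' `A_ij = R^N_ij + log2(REF_i)`: each protein's normalized ratios are
#' shifted by the log2 of its estimated reference intensity, putting all
#' samples on an absolute (log2 intensity) scale.
#'
#' @param norm Normalized ratio matrix from [mad_normalize()].
#' @param ref Reference-intensity table from
#'   [estimate_reference_intensity()].
#' @return Abundance matrix (same shape as `norm`).
#' @export
to_abundance <- function(norm, ref) {
  missing_ref <- setdiff(rownames(norm), ref$entry)
  if (length(missing_ref) > 0)
    stop("no reference intensity for: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  shift <- log2(ref$ref_intensity[match(rownames(norm), ref$entry)])
  out <- norm + shift
  attributes(out)[c("M", "MAD", "MAD0")] <- NULL
  out
}

#' Combine per-plex abundance matrices into one cohort matrix
#'
#' Columns are concatenated over the union of the protein rows; proteins
#' absent from a plex get missing cells for that plex's samples. Column
#' provenance is recorded in the `"plex"` attribute.
#'
#' @param abundances Named list of per-plex abundance matrices.
#' @return Combined matrix with attribute `plex` (per-column plex label).
#' @export
integrate_plexes <- function(abundances) {
  if (is.matrix(abundances)) abundances <- list(plex1 = abundances)
  if (is.null(names(abundances)) || any(!nzchar(names(abundances))))
    names(abundances) <- paste0("plex", seq_along(abundances))
  all_samples <- unlist(lapply(abundances, colnames), use.names = FALSE)
  if (anyDuplicated(all_samples))
    stop("duplicate sample IDs across plexes: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  proteins <- sort(unique(unlist(lapply(abundances, rownames))))
  out <- matrix(NA_real_, nrow = length(proteins), ncol = length(all_samples),
                dimnames = list(proteins, all_samples))
  plex_of <- character(0)
  for (nm in names(abundances)) {
    m <- abundances[[nm]]
    out[rownames(m), colnames(m)] <- m
    plex_of <- c(plex_of, stats::setNames(rep(nm, ncol(m)), colnames(m)))
  }
  attr(out, "plex") <- plex_of[colnames(out)]
  out
}

#' Quantify one TMT plex from a PSM table
#'
#' Convenience wrapper running the full single-plex chain: quality filter,
#' spectrum deduplication, log2 ratio-to-reference conversion, IQR outlier
#' removal within (entry x sample) groups, and median roll-up.
#'
#' @param psms PSM data frame for one plex.
#' @param design Design rows for that plex.
#' @param criteria [filter_criteria()].
#' @param grouping `"protein"` or `"gene"`.
#' @param pooled_reference See [to_log_ratios()].
#' @return List with `ratios` (entries x samples matrix), `kept` (filtered
#'   PSM table) and `filter_report`.
#' @export
quantify_plex <- function(psms, design, criteria = filter_criteria(),
                          grouping = "protein", pooled_reference = FALSE) {
  ref_channel <- design$channel[design$is_reference]
  if (length(ref_channel) != 1 && !pooled_reference)
    stop("design must flag exactly one reference channel", call. = FALSE)
  flt <- filter_psms(psms, criteria,
                     reference_channel = if (length(ref_channel) == 1)
                       ref_channel else "131")
  dedup <- deduplicate_psms(flt$kept)
  ratios <- to_log_ratios(dedup, design, pooled_reference = pooled_reference)
  mat <- rollup(ratios, grouping = grouping)
  list(ratios = mat, kept = dedup, filter_report = flt$report)
}
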