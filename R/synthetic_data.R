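#' Configure a synthetic TMT cohort
#'
#' Builds and validates the configuration of the synthetic PSM-level cohort
#' generator. Defaults emulate a 27-sample breast-tumor cohort measured in
#' three consecutive TMT 10-plexes, each plex carrying nine tissue samples
#' and one pooled-reference ("master mix") channel (131).
#'
#' @param n_plexes Number of 10-plex experiments (batches).
#' @param channels_per_plex Channels per plex; one is the reference.
#' @param n_proteins Number of simulated proteins.
#' @param psms_per_protein Mean PSM count per protein per plex; actual
#'   counts are drawn as `1 + Poisson(psms_per_protein - 1)` so every
#'   protein is quantifiable.
#' @param group_sizes Named integer vector of samples per group. Must sum
#'   to `n_plexes * (channels_per_plex - 1)`.
#' @param de_fraction Fraction of proteins carrying a group effect
#'   (tumor vs normal).
#' @param effect_size Absolute log2 effect added to tumor samples of
#'   differential proteins; sign is drawn at random per protein.
#' @param psm_noise_sd Standard deviation (log2 units) of per-channel
#'   multiplicative measurement noise at the PSM level.
#' @param batch_shift_sd Standard deviation (log2 units) of per-plex,
#'   per-protein batch shifts.
#' @param missing_rates Per-plex fraction of sample-channel reporter cells
#'   blanked; length `n_plexes`, each < 0.9.
#' @param contaminant_fraction Fraction of extra PSM rows assigned to
#'   contaminant proteins (IDs prefixed `contam_`).
#' @param lowquality_fraction Fraction of PSM rows altered to violate one
#'   quality-filter criterion (see [inject_low_quality()]).
#' @param missing_mechanism `"mnar"` (intensity-dependent, logistic in the
#'   observed log2 signal) or `"mcar"` (uniform).
#' @param abundance_sd Standard deviation (log2 units) of the baseline
#'   protein abundances around their grand mean.
#' @param seed Integer seed; the same configuration always generates the
#'   same cohort.
#'
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_plexes = 3L,
                          channels_per_plex = 10L,
                          n_proteins = 200L,
                          psms_per_protein = 5,
                          group_sizes = c(normal = 9L, tnbc = 6L,
                                          spindle = 4L, squamous = 4L,
                                          sarcomatoid = 4L),
                          de_fraction = 0.10,
                          effect_size = 1.5,
                          psm_noise_sd = 0.3,
                          batch_shift_sd = 0.3,
                          missing_rates = c(0.18, 0.14, 0.12),
                          contaminant_fraction = 0.05,
                          lowquality_fraction = 0.05,
                          missing_mechanism = c("mnar", "mcar"),
                          abundance_sd = 1.5,
                          seed = 1L) {
  cfg <- list(n_plexes = as.integer(n_plexes),
              channels_per_plex = as.integer(channels_per_plex),
              n_proteins = as.integer(n_proteins),
              psms_per_protein = psms_per_protein,
              group_sizes = group_sizes,
              de_fraction = de_fraction,
              effect_size = effect_size,
              psm_noise_sd = psm_noise_sd,
              batch_shift_sd = batch_shift_sd,
              missing_rates = missing_rates,
              contaminant_fraction = contaminant_fraction,
              lowquality_fraction = lowquality_fraction,
              missing_mechanism = match.arg(missing_mechanism),
              abundance_sd = abundance_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid cohort config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_plexes < 1L) stop_field("n_plexes", "must be >= 1")
  if (cfg$channels_per_plex < 2L)
    stop_field("channels_per_plex", "must be >= 2 (one reference channel)")
  if (cfg$channels_per_plex > 10L)
    stop_field("channels_per_plex", "must be <= 10 (TMT 10-plex)")
  if (cfg$n_proteins < 1L) stop_field("n_proteins", "must be >= 1")
  if (cfg$psms_per_protein < 1) stop_field("psms_per_protein", "must be >= 1")
  if (is.null(names(cfg$group_sizes)) || any(!nzchar(names(cfg$group_sizes))))
    stop_field("group_sizes", "must be a named vector")
  n_samples <- cfg$n_plexes * (cfg$channels_per_plex - 1L)
  if (sum(cfg$group_sizes) != n_samples)
    stop_field("group_sizes",
               sprintf("must sum to n_plexes * (channels_per_plex - 1) = %d",
                       n_samples))
  for (f in c("de_fraction", "contaminant_fraction", "lowquality_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop_field(f, "must be in [0, 1]")
  }
  for (f in c("psm_noise_sd", "batch_shift_sd", "abundance_sd")) {
    if (cfg[[f]] < 0) stop_field(f, "must be >= 0")
  }
  if (length(cfg$missing_rates) != cfg$n_plexes)
    stop_field("missing_rates", "must have one rate per plex")
  if (any(cfg$missing_rates < 0) || any(cfg$missing_rates >= 0.9))
    stop_field("missing_rates", "must be in [0, 0.9)")
  if (cfg$effect_size < 0) stop_field("effect_size", "must be >= 0")
  invisible(cfg)
}

# Random tryptic-looking peptide sequences ending in K/R.
random_peptides <- function(n, min_len = 7L, max_len = 20L) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) {
    paste0(paste(sample(aa, l - 1L, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1L))
  }, character(1))
}

#' Generate a synthetic multi-plex TMT cohort with known ground truth
#'
#' Simulates PSM-level reporter data for `n_plexes` TMT experiments.
#' Reporter intensities are generated multiplicatively:
#' `reporter = 2 ^ (true log2 abundance + batch shift + PSM effect +
#' N(0, psm_noise_sd))`, where the PSM effect (ionization efficiency) is
#' shared across the channels of a PSM and therefore cancels in
#' ratio-to-reference space. The reference channel of each plex carries the
#' pooled mean (log2 scale) of all samples' true abundances — the "master
#' mix". Samples are assigned to plexes round-robin within the group
#' ordering so that batch is not confounded with group. Contaminant PSMs,
#' low-quality PSMs and intensity-dependent missingness are then injected
#' according to the configuration.
#'
#' @param config A [cohort_config()].
#'
#' @return A list of class `"tmt_cohort"` with elements
#'   * `psm_tables`: list of per-plex PSM data frames ([psm_schema()]
#'     columns plus a hidden `lq_violation` truth column);
#'   * `design`: data frame `plex_id, channel, sample_id, is_reference`;
#'   * `annotation`: data frame `sample_id, group, batch`;
#'   * `truth`: list with `protein_abundance` (proteins x samples true log2
#'     matrix), `de_flags` (per-protein signed effect for the
#'     tumor-vs-normal contrast), `batch_shifts` (proteins x plexes),
#'     `missing_mask` (per-plex logical matrices over PSM reporter cells).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n_prot <- config$n_proteins
  n_plex <- config$n_plexes
  channels <- tmt10_channels()[seq_len(config$channels_per_plex)]
  ref_channel <- channels[length(channels)]
  sample_channels <- channels[-length(channels)]
  n_per_plex <- length(sample_channels)

  proteins <- sprintf("PROT%04d", seq_len(n_prot))
  genes <- sprintf("GENE%04d", seq_len(n_prot))

  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n_samp <- length(groups)
  sample_ids <- unlist(lapply(names(config$group_sizes), function(g) {
    sprintf("%s_%02d", g, seq_len(config$group_sizes[[g]]))
  }), use.names = FALSE)
  # round-robin plex assignment over the group-ordered samples
  plex_of <- rep_len(seq_len(n_plex), n_samp)

  annotation <- data.frame(sample_id = sample_ids, group = groups,
                           batch = sprintf("plex%d", plex_of),
                           stringsAsFactors = FALSE)

  design <- do.call(rbind, lapply(seq_len(n_plex), function(k) {
    ids <- sample_ids[plex_of == k]
    data.frame(plex_id = sprintf("plex%d", k),
               channel = channels,
               sample_id = c(ids, sprintf("plex%d_ref", k)),
               is_reference = c(rep(FALSE, n_per_plex), TRUE),
               stringsAsFactors = FALSE)
  }))

  # true protein abundances: baseline + signed tumor effect for DE proteins
  baseline <- stats::rnorm(n_prot, mean = 25, sd = config$abundance_sd)
  n_de <- round(config$de_fraction * n_prot)
  de_idx <- if (n_de > 0) sample.int(n_prot, n_de) else integer(0)
  effect <- numeric(n_prot)
  if (n_de > 0)
    effect[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$effect_size
  is_tumor <- groups != "normal"
  truth_mat <- matrix(baseline, nrow = n_prot, ncol = n_samp,
                      dimnames = list(proteins, sample_ids))
  truth_mat[, is_tumor] <- truth_mat[, is_tumor] + effect

  batch_shifts <- matrix(stats::rnorm(n_prot * n_plex, 0, config$batch_shift_sd),
                         nrow = n_prot,
                         dimnames = list(proteins, sprintf("plex%d", seq_len(n_plex))))
  ref_true <- rowMeans(truth_mat)  # master mix pools all samples

  lam <- max(config$psms_per_protein - 1, 0)
  psm_tables <- vector("list", n_plex)
  for (k in seq_len(n_plex)) {
    in_plex <- plex_of == k
    ids_k <- sample_ids[in_plex]
    n_psms <- 1L + stats::rpois(n_prot, lam)
    rows_prot <- rep(seq_len(n_prot), n_psms)
    n_rows <- length(rows_prot)
    psm_effect <- stats::rnorm(n_rows, 0, 1)

    # log2 signal per channel: truth + batch + PSM effect + noise
    log_signal <- matrix(NA_real_, nrow = n_rows, ncol = length(channels))
    true_block <- cbind(truth_mat[rows_prot, ids_k, drop = FALSE],
                        ref = ref_true[rows_prot])
    noise <- matrix(stats::rnorm(n_rows * length(channels), 0, config$psm_noise_sd),
                    nrow = n_rows)
    log_signal <- true_block + batch_shifts[rows_prot, k] + psm_effect + noise
    reporters <- 2 ^ log_signal
    colnames(reporters) <- reporter_cols(channels)

    ms1 <- 2 ^ (ref_true[rows_prot] + psm_effect +
                  stats::rnorm(n_rows, 0, config$psm_noise_sd))
    tbl <- data.frame(
      spectrum_id = sprintf("plex%d.%06d", k, seq_len(n_rows)),
      peptide = random_peptides(n_rows),
      protein = proteins[rows_prot],
      gene = genes[rows_prot],
      is_unique = stats::runif(n_rows) < 0.8,
      peptide_probability = stats::runif(n_rows, 0.95, 1),
      precursor_purity = stats::runif(n_rows, 0.7, 1),
      ms1_intensity = ms1,
      ms2_summed_intensity = rowSums(reporters),
      stringsAsFactors = FALSE)
    tbl <- cbind(tbl, as.data.frame(reporters))

    # contaminant PSMs: same signal in every channel (keratins etc.)
    n_contam <- round(config$contaminant_fraction * n_rows)
    if (n_contam > 0) {
      c_base <- stats::rnorm(n_contam, 26, 1)
      c_noise <- matrix(stats::rnorm(n_contam * length(channels), 0,
                                     config$psm_noise_sd), nrow = n_contam)
      c_rep <- 2 ^ (c_base + c_noise)
      colnames(c_rep) <- reporter_cols(channels)
      ctbl <- data.frame(
        spectrum_id = sprintf("plex%d.c%05d", k, seq_len(n_contam)),
        peptide = random_peptides(n_contam),
        protein = sprintf("contam_KRT%02d", sample.int(30, n_contam, replace = TRUE)),
        gene = sprintf("KRT%02d", sample.int(30, n_contam, replace = TRUE)),
        is_unique = TRUE,
        peptide_probability = stats::runif(n_contam, 0.95, 1),
        precursor_purity = stats::runif(n_contam, 0.7, 1),
        ms1_intensity = 2 ^ (c_base + stats::rnorm(n_contam, 0, config$psm_noise_sd)),
        ms2_summed_intensity = rowSums(c_rep),
        stringsAsFactors = FALSE)
      ctbl <- cbind(ctbl, as.data.frame(c_rep))
      tbl <- rbind(tbl, ctbl)
    }
    tbl$ms2_summed_intensity <- rowSums(tbl[, reporter_cols(channels), drop = FALSE])
    psm_tables[[k]] <- tbl
  }
  names(psm_tables) <- sprintf("plex%d", seq_len(n_plex))

  psm_tables <- lapply(seq_len(n_plex), function(k) {
    inject_low_quality(psm_tables[[k]], config$lowquality_fraction,
                       seed = derive_seed(config$seed, 100L + k),
                       reference_channel = ref_channel)
  })
  names(psm_tables) <- sprintf("plex%d", seq_len(n_plex))

  miss <- inject_missingness(psm_tables, config$missing_rates,
                             seed = derive_seed(config$seed, 200L),
                             mechanism = config$missing_mechanism,
                             reference_channel = ref_channel)

  truth <- list(protein_abundance = truth_mat,
                de_flags = data.frame(protein = proteins, gene = genes,
                                      contrast = "tumor_vs_normal",
                                      is_de = effect != 0,
                                      effect = effect,
                                      stringsAsFactors = FALSE),
                batch_shifts = batch_shifts,
                missing_mask = attr(miss, "missing_mask"))
  out <- list(psm_tables = miss, design = design, annotation = annotation,
              truth = truth, config = config)
  class(out) <- "tmt_cohort"
  out
}

#' Corrupt a fraction of PSMs so they violate quality-filter criteria
#'
#' Alters exactly `round(fraction * n)` rows of a PSM table so that each
#' violates one named filter criterion (cycling over low peptide
#' probability, low precursor purity, sub-threshold MS1 intensity, low
#' summed reporter intensity, and a missing reference reporter). Altered
#' rows are labeled in a hidden `lq_violation` column so downstream filter
#' behavior can be checked against the truth.
#'
#' @param psms PSM data frame ([psm_schema()] columns).
#' @param lowquality_fraction Fraction of rows to corrupt, in \[0, 1\].
#' @param seed Integer seed.
#' @param reference_channel Reference channel name (default `"131"`).
#' @return The PSM table with corrupted rows and an `lq_violation` column
#'   (`NA` for untouched rows).
#' @export
inject_low_quality <- function(psms, lowquality_fraction, seed = 1L,
                               reference_channel = "131") {
  if (lowquality_fraction < 0 || lowquality_fraction > 1)
    stop("lowquality_fraction must be in [0, 1]", call. = FALSE)
  if (is.null(psms$lq_violation)) psms$lq_violation <- NA_character_
  n_alter <- round(lowquality_fraction * nrow(psms))
  if (n_alter == 0) return(psms)
  set.seed(seed)
  # corrupt only clean, non-contaminant rows so labels stay unambiguous
  eligible <- which(is.na(psms$lq_violation) &
                      !startsWith(psms$protein, "contam_"))
  n_alter <- min(n_alter, length(eligible))
  rows <- sample(eligible, n_alter)
  kinds <- rep_len(c("probability", "purity", "ms1", "ms2", "reference"), n_alter)
  rep_cols <- intersect(reporter_cols(), names(psms))
  ref_col <- paste0("channel_", reference_channel)
  med_sum <- stats::median(rowSums(psms[, rep_cols], na.rm = TRUE), na.rm = TRUE)
  max_ms1 <- max(psms$ms1_intensity, na.rm = TRUE)
  for (i in seq_len(n_alter)) {
    r <- rows[i]
    switch(kinds[i],
      probability = {
        psms$peptide_probability[r] <- stats::runif(1, 0, 0.89)
      },
      purity = {
        psms$precursor_purity[r] <- stats::runif(1, 0, 0.49)
      },
      ms1 = {
        psms$ms1_intensity[r] <- max_ms1 * 1e-6
      },
      ms2 = {
        cur <- sum(unlist(psms[r, rep_cols]), na.rm = TRUE)
        psms[r, rep_cols] <- psms[r, rep_cols] * (0.01 * med_sum / cur)
        psms$ms2_summed_intensity[r] <- sum(unlist(psms[r, rep_cols]), na.rm = TRUE)
      },
      reference = {
        psms[[ref_col]][r] <- NA_real_
      })
    psms$lq_violation[r] <- kinds[i]
  }
  psms
}

#' Blank reporter intensities to emulate missing values
#'
#' Removes (sets to `NA`) reporter intensities in the sample channels of
#' each plex at the requested per-plex rates. Under the `"mnar"` mechanism
#' cells are drawn with logistic weights decreasing in the observed log2
#' intensity, so low-abundance signals go missing preferentially; `"mcar"`
#' draws uniformly. Exactly `round(rate * n_cells)` cells are blanked per
#' plex, so the realized rate is always within tolerance of the request.
#' The reference channel is never blanked.
#'
#' @param psm_tables List of per-plex PSM data frames.
#' @param missing_rates One rate per plex, each in \[0, 0.9).
#' @param seed Integer seed.
#' @param mechanism `"mnar"` or `"mcar"`.
#' @param reference_channel Reference channel name (never blanked).
#' @return The list of PSM tables with blanked cells; attribute
#'   `missing_mask` holds one logical matrix per plex (PSM rows x sample
#'   channels, `TRUE` = blanked).
#' @export
inject_missingness <- function(psm_tables, missing_rates, seed = 1L,
                               mechanism = c("mnar", "mcar"),
                               reference_channel = "131") {
  mechanism <- match.arg(mechanism)
  if (length(missing_rates) != length(psm_tables))
    stop("need one missing rate per plex", call. = FALSE)
  if (any(missing_rates >= 0.9))
    stop("missing rate >= 0.9 leaves downstream roll-up undefined",
         call. = FALSE)
  if (any(missing_rates < 0))
    stop("missing rates must be >= 0", call. = FALSE)
  set.seed(seed)
  ref_col <- paste0("channel_", reference_channel)
  masks <- vector("list", length(psm_tables))
  for (k in seq_along(psm_tables)) {
    tbl <- psm_tables[[k]]
    cols <- setdiff(intersect(reporter_cols(), names(tbl)), ref_col)
    vals <- as.matrix(tbl[, cols, drop = FALSE])
    n_cells <- length(vals)
    target <- round(missing_rates[k] * n_cells)
    mask <- matrix(FALSE, nrow = nrow(vals), ncol = ncol(vals),
                   dimnames = dimnames(vals))
    if (target > 0) {
      observed <- !is.na(vals)
      idx_pool <- which(observed)
      target <- min(target, length(idx_pool))
      if (mechanism == "mnar") {
        x <- log2(vals[idx_pool])
        s <- max(stats::sd(x) / 2, 1e-6)
        w <- stats::plogis((stats::median(x) - x) / s)
        picked <- sample(idx_pool, target, prob = w)
      } else {
        picked <- sample(idx_pool, target)
      }
      vals[picked] <- NA_real_
      mask[picked] <- TRUE
      tbl[, cols] <- vals
    }
    masks[[k]] <- mask
    psm_tables[[k]] <- tbl
  }
  names(masks) <- names(psm_tables)
  attr(psm_tables, "missing_mask") <- masks
  psm_tables
}

# Format numeric columns at full double precision so a TSV round trip is
# value-exact.
format_full <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
  } else x
}

write_tsv_exact <- function(df, path) {
  out <- as.data.frame(lapply(df, format_full), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic cohort to disk as TSV files
#'
#' Writes one PSM table per plex (schema columns only — hidden truth
#' columns go to `truth_lq_labels.tsv`), the plex design, the sample
#' annotation, and the ground-truth tables. Numeric values are written at
#' full double precision so reading the files back reproduces the cohort
#' exactly.
#'
#' @param bundle A `"tmt_cohort"` from [generate_cohort()].
#' @param directory Output directory (created if absent).
#' @return Named character vector of the paths written.
#' @export
write_fixture <- function(bundle, directory) {
  stopifnot(inherits(bundle, "tmt_cohort"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c()
  for (k in seq_along(bundle$psm_tables)) {
    p <- file.path(directory, sprintf("psm_plex%d.tsv", k))
    write_tsv_exact(bundle$psm_tables[[k]][, psm_schema()], p)
    paths[sprintf("psm_plex%d", k)] <- p
  }
  paths["design"] <- file.path(directory, "design.tsv")
  write_tsv_exact(bundle$design, paths["design"])
  paths["annotation"] <- file.path(directory, "annotation.tsv")
  write_tsv_exact(bundle$annotation, paths["annotation"])

  tr <- bundle$truth
  paths["truth_abundance"] <- file.path(directory, "truth_abundance.tsv")
  ab <- data.frame(protein = rownames(tr$protein_abundance),
                   tr$protein_abundance, check.names = FALSE)
  write_tsv_exact(ab, paths["truth_abundance"])
  paths["truth_de"] <- file.path(directory, "truth_de.tsv")
  write_tsv_exact(tr$de_flags, paths["truth_de"])
  paths["truth_batch"] <- file.path(directory, "truth_batch_shifts.tsv")
  bs <- data.frame(protein = rownames(tr$batch_shifts), tr$batch_shifts,
                   check.names = FALSE)
  write_tsv_exact(bs, paths["truth_batch"])
  lq <- do.call(rbind, lapply(seq_along(bundle$psm_tables), function(k) {
    t <- bundle$psm_tables[[k]]
    data.frame(plex_id = sprintf("plex%d", k), spectrum_id = t$spectrum_id,
               lq_violation = if (is.null(t$lq_violation)) NA_character_ else t$lq_violation,
               stringsAsFactors = FALSE)
  }))
  paths["truth_lq"] <- file.path(directory, "truth_lq_labels.tsv")
  write_tsv_exact(lq, paths["truth_lq"])
  paths
}

#' Read a PSM table written by [write_fixture()]
#'
#' @param path Path to a PSM TSV. Empty reporter fields become `NA`.
#' @return Data frame with [psm_schema()] columns.
#' @export
read_psm_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = c(spectrum_id = "character",
                                         peptide = "character",
                                         protein = "character",
                                         gene = "character"))
  missing_cols <- setdiff(psm_schema(), names(df))
  if (length(missing_cols) > 0)
    stop("PSM table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$is_unique <- as.logical(df$is_unique)
  df
}

#' Read a plex-design table (`plex_id, channel, sample_id, is_reference`)
#' @param path Path to the design TSV.
#' @return Data frame.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("plex_id", "channel", "sample_id", "is_reference")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("design table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$is_reference <- as.logical(df$is_reference)
  df
}

#' Read a sample-annotation table (`sample_id, group, batch`)
#' @param path Path to the annotation TSV.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "group", "batch")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("annotation table missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}
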