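# Fixture builders and independent brute-force oracles used across tests.

# Hand-built PSM table. `reporters` is a numeric matrix (rows = PSMs,
# 10 columns) or NULL for all-100 intensities.
make_psms <- function(n = 4, protein = sprintf("P%02d", seq_len(n)),
                      gene = protein,
                      spectrum_id = sprintf("sp%03d", seq_len(n)),
                      probability = rep(0.99, n), purity = rep(0.9, n),
                      ms1 = rep(1e6, n), reporters = NULL) {
  if (is.null(reporters))
    reporters <- matrix(100, nrow = n, ncol = 10)
  colnames(reporters) <- paste0("channel_", tmt10_channels())
  df <- data.frame(spectrum_id = spectrum_id,
                   peptide = sprintf("PEPTIDE%02dK", seq_len(n)),
                   protein = protein, gene = gene, is_unique = TRUE,
                   peptide_probability = probability,
                   precursor_purity = purity,
                   ms1_intensity = ms1,
                   ms2_summed_intensity = rowSums(reporters, na.rm = TRUE),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(reporters))
}

# Design table for one plex with channel 131 as reference.
make_design <- function(plex = "plex1",
                        samples = sprintf("s%02d", 1:9)) {
  ch <- tmt10_channels()
  data.frame(plex_id = plex, channel = ch,
             sample_id = c(samples, paste0(plex, "_ref")),
             is_reference = c(rep(FALSE, 9), TRUE),
             stringsAsFactors = FALSE)
}

# Independent linear-interpolation quantile (type-7 convention), written
# from the definition rather than calling stats::quantile.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Straight-line brute-force recomputation of the single-plex chain
# filter -> dedup -> log2 ratio -> IQR trim -> median roll-up, written
# with explicit loops and no shared code with the package internals.
oracle_quantify <- function(psms, design, min_prob = 0.9, min_pur = 0.5,
                            ms1_frac = 0.0005, ms2_frac = 0.05) {
  ch_cols <- paste0("channel_", design$channel)
  ref_col <- paste0("channel_", design$channel[design$is_reference])
  sam_cols <- setdiff(ch_cols, ref_col)
  sam_ids <- design$sample_id[!design$is_reference]

  rep_sums <- sapply(seq_len(nrow(psms)), function(r)
    sum(unlist(psms[r, ch_cols]), na.rm = TRUE))
  ms1_floor <- ms1_frac * max(psms$ms1_intensity)
  ms2_floor <- ms2_frac * median(rep_sums)
  keep <- logical(nrow(psms))
  for (r in seq_len(nrow(psms))) {
    ref_ok <- !is.na(psms[[ref_col]][r]) && psms[[ref_col]][r] > 0
    keep[r] <- ref_ok &&
      psms$peptide_probability[r] >= min_prob &&
      psms$precursor_purity[r] >= min_pur &&
      psms$ms1_intensity[r] >= ms1_floor &&
      rep_sums[r] >= ms2_floor &&
      !grepl("^contam_", psms$protein[r])
  }
  kept <- psms[keep, , drop = FALSE]
  kept_sums <- rep_sums[keep]
  # dedup: keep max reporter sum per spectrum, first on ties
  sel <- logical(nrow(kept))
  for (sid in unique(kept$spectrum_id)) {
    idx <- which(kept$spectrum_id == sid)
    sel[idx[which.max(kept_sums[idx])]] <- TRUE
  }
  kept <- kept[sel, , drop = FALSE]

  proteins <- unique(kept$protein)
  out <- matrix(NA_real_, length(proteins), length(sam_ids),
                dimnames = list(proteins, sam_ids))
  for (pr in proteins) {
    rows <- which(kept$protein == pr)
    for (s in seq_along(sam_ids)) {
      vals <- c()
      for (r in rows) {
        v <- kept[[sam_cols[s]]][r]
        ref <- kept[[ref_col]][r]
        if (!is.na(v)) vals <- c(vals, log2(v) - log2(ref))
      }
      if (length(vals) >= 4) {
        q1 <- oracle_quantile7(vals, 0.25)
        q3 <- oracle_quantile7(vals, 0.75)
        iqr <- q3 - q1
        vals <- vals[vals >= q1 - 1.5 * iqr & vals <= q3 + 1.5 * iqr]
      }
      if (length(vals) > 0) out[pr, s] <- median(vals)
    }
  }
  out
}

# Brute-force complete-linkage agglomeration over a distance matrix:
# repeatedly merge the pair of clusters with the smallest maximum
# inter-point distance. Returns merge heights and member sets.
oracle_complete_linkage <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- c()
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Brute-force GSEA running sum on a toy list (explicit walk).
oracle_es <- function(stats_desc, hits, exponent = 1) {
  N <- length(stats_desc)
  w <- abs(stats_desc[hits])^exponent
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (i %in% hits) run <- run + w[match(i, hits)] / sum(w)
    else run <- run - 1 / (N - length(hits))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Mean silhouette width for a 2-group labelling of points (rows), used to
# check PCA group separation.
mean_silhouette <- function(x, labels) {
  d <- as.matrix(dist(x))
  sil <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(tapply(d[i, !own], labels[!own], mean))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}
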