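#' Multiple-imputation settings
#'
#' @param m Number of imputed datasets (default 5).
#' @param maxit Chained-equation sweeps per imputation (default 50).
#' @param donors Donor-pool size for predictive mean matching (default 5).
#' @param seed Integer seed.
#' @return A list of class `"impute_config"`.
#' @export
impute_config <- function(m = 5L, maxit = 50L, donors = 5L, seed = 1L) {
  cfg <- list(m = as.integer(m), maxit = as.integer(maxit),
              donors = as.integer(donors), seed = as.integer(seed))
  if (cfg$m < 1L) stop("m must be >= 1", call. = FALSE)
  if (cfg$maxit < 1L) stop("maxit must be >= 1", call. = FALSE)
  if (cfg$donors < 1L) stop("donors must be >= 1", call. = FALSE)
  class(cfg) <- "impute_config"
  cfg
}

# One chained-equations pass filling the missing cells of `mat` (proteins x
# samples), columns visited in `visit` order. Each column with missingness
# is regressed (OLS) on all other columns over its observed rows, and each
# missing cell takes the observed value of a donor drawn uniformly from the
# `donors` rows with nearest predicted mean (predictive mean matching).
pmm_sweep <- function(completed, mat_obs, visit, donors) {
  for (j in visit) {
    miss <- is.na(mat_obs[, j])
    obs <- !miss
    x_other <- completed[, -j, drop = FALSE]
    y_obs <- mat_obs[obs, j]
    X <- cbind(1, x_other)
    fit <- tryCatch(stats::lm.fit(X[obs, , drop = FALSE], y_obs),
                    error = function(e) NULL)
    rank_ok <- !is.null(fit) && fit$rank == ncol(X)
    if (rank_ok) {
      beta <- fit$coefficients
      pred_all <- drop(X %*% beta)
    } else {
      warning("rank-deficient regression for column '", colnames(mat_obs)[j],
              "'; falling back to column-median prediction", call. = FALSE)
      pred_all <- rep(stats::median(y_obs), nrow(completed))
    }
    pred_obs <- pred_all[obs]
    # donor search over sorted observed predictions: expand a window of
    # the `donors` nearest around each missing cell's prediction
    ord <- order(pred_obs)
    po_sorted <- pred_obs[ord]
    y_sorted <- y_obs[ord]
    n_o <- length(po_sorted)
    k_pool <- min(donors, n_o)
    for (r in which(miss)) {
      p <- pred_all[r]
      lo <- findInterval(p, po_sorted)
      hi <- lo + 1L
      pool <- integer(k_pool)
      for (t in seq_len(k_pool)) {
        d_lo <- if (lo >= 1L) abs(po_sorted[lo] - p) else Inf
        d_hi <- if (hi <= n_o) abs(po_sorted[hi] - p) else Inf
        if (d_lo <= d_hi) { pool[t] <- lo; lo <- lo - 1L }
        else { pool[t] <- hi; hi <- hi + 1L }
      }
      completed[r, j] <- y_sorted[pool[sample.int(k_pool, 1L)]]
    }
  }
  completed
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Missing cells of a proteins-by-samples abundance matrix are imputed by
#' iterating over sample columns (most-missing first): each column is
#' regressed by least squares on the current completions of the other
#' columns, and every missing cell is filled with the observed value of a
#' donor drawn uniformly among the `donors` observed rows whose predicted
#' means are nearest. `m` independent chains of `maxit` sweeps give `m`
#' completed matrices. Every imputed value is an observed value of the same
#' column, and observed cells are never touched.
#'
#' Rows with fewer than `min_observed` observed values are dropped with a
#' warning before imputation.
#'
#' @param mat Numeric matrix, proteins x samples, `NA` = missing.
#' @param config An [impute_config()].
#' @param min_observed Minimum observed values per retained row (default 3).
#' @return List of `m` completed matrices; attribute `dropped` lists
#'   removed rows.
#' @export
pmm_impute <- function(mat, config = impute_config(), min_observed = 3L) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  all_missing <- colSums(!is.na(mat)) == 0
  if (any(all_missing))
    stop("column(s) entirely missing: ",
         paste(colnames(mat)[all_missing], collapse = ", "), call. = FALSE)
  n_obs_row <- rowSums(!is.na(mat))
  dropped <- rownames(mat)[n_obs_row < min_observed]
  if (length(dropped) > 0) {
    warning(length(dropped), " row(s) with < ", min_observed,
            " observed values dropped before imputation", call. = FALSE)
    mat <- mat[n_obs_row >= min_observed, , drop = FALSE]
  }
  n_miss_col <- colSums(is.na(mat))
  visit <- order(n_miss_col, decreasing = TRUE)
  visit <- visit[n_miss_col[visit] > 0]
  out <- vector("list", config$m)
  for (i in seq_len(config$m)) {
    set.seed(derive_seed(config$seed, 300L + i))
    completed <- mat
    # initial fill: random draw from the column's observed values
    for (j in visit) {
      miss <- is.na(mat[, j])
      obs_vals <- mat[!miss, j]
      completed[miss, j] <- sample(obs_vals, sum(miss), replace = TRUE)
    }
    if (length(visit) > 0) {
      for (it in seq_len(config$maxit)) {
        completed <- pmm_sweep(completed, mat, visit, config$donors)
      }
    }
    out[[i]] <- completed
  }
  attr(out, "dropped") <- dropped
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` per-imputation point estimates and their squared standard
#' errors: the pooled point is the mean, within-imputation variance `W` is
#' the mean variance, between-imputation variance `B` is the sample
#' variance of the estimates, and total variance `T = W + (1 + 1/m) B`.
#' Degrees of freedom follow the Barnard-Rubin small-sample formula given a
#' complete-data df (`dfcom`); with `dfcom = Inf` this reduces to the
#' classic Rubin df `(m - 1) / lambda^2`. The two-sided p-value uses the t
#' reference distribution.
#'
#' @param estimates Numeric vector of per-imputation estimates.
#' @param variances Squared standard errors, same length.
#' @param dfcom Complete-data degrees of freedom (default `Inf`).
#' @return List of class `"pooled_estimate"`: `estimate, W, B, T, df,
#'   statistic, p.value, m`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf) {
  if (length(estimates) != length(variances))
    stop("estimates and variances must have equal length", call. = FALSE)
  m <- length(estimates)
  if (m < 1) stop("need at least one estimate", call. = FALSE)
  point <- mean(estimates)
  W <- mean(variances)
  B <- if (m > 1) stats::var(estimates) else 0
  Tv <- W + (1 + 1 / m) * B
  if (B > 0 && m > 1) {
    lambda <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    } else {
      df <- df_old
    }
  } else {
    df <- if (is.finite(dfcom)) dfcom else Inf
  }
  stat <- if (Tv > 0) point / sqrt(Tv) else 0
  p <- if (is.finite(df)) 2 * stats::pt(-abs(stat), df) else
    2 * stats::pnorm(-abs(stat))
  structure(list(estimate = point, W = W, B = B, T = Tv, df = df,
                 statistic = stat, p.value = p, m = m),
            class = "pooled_estimate")
}

#' Median-pooled p-value across imputations
#'
#' A simple, conservative alternative to full Rubin pooling: the median of
#' the per-imputation p-values (even counts average the two central
#' values).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return The median p-value.
#' @export
median_pooled_pvalue <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value list", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::median(pvalues)
}

#' Batch correction by per-protein batch-mean centering
#'
#' For each protein and batch, the batch mean is subtracted and the
#' protein's grand mean (over all observed cells) added back, removing
#' additive batch offsets while preserving within-batch contrasts exactly.
#' Proteins with an entirely missing batch are left uncorrected with a
#' warning.
#'
#' @param mat Numeric matrix, proteins x samples.
#' @param batches Named per-sample batch labels (names = sample IDs), or an
#'   unnamed vector aligned with the columns.
#' @return Corrected matrix.
#' @export
batch_correct <- function(mat, batches) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (!is.null(names(batches))) {
    unknown <- setdiff(colnames(mat), names(batches))
    if (length(unknown) > 0)
      stop("sample(s) missing from batch map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    batches <- batches[colnames(mat)]
  } else if (length(batches) != ncol(mat)) {
    stop("batch labels must match the number of samples", call. = FALSE)
  }
  batches <- as.character(batches)
  levels_b <- unique(batches)
  tab <- table(batches)
  if (any(tab < 2))
    stop("each batch needs >= 2 samples", call. = FALSE)
  out <- mat
  uncorrected <- character(0)
  for (r in seq_len(nrow(mat))) {
    v <- mat[r, ]
    b_means <- tapply(v, batches, mean, na.rm = TRUE)
    if (any(is.nan(b_means))) {
      uncorrected <- c(uncorrected, rownames(mat)[r])
      next
    }
    grand <- mean(v, na.rm = TRUE)
    out[r, ] <- v - b_means[batches] + grand
  }
  if (length(uncorrected) > 0)
    warning(length(uncorrected),
            " protein(s) with an all-missing batch left uncorrected",
            call. = FALSE)
  out
}
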