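#' Differential-expression significance thresholds
#'
#' Defaults follow common proteomics practice on log2 data: absolute log2
#' fold change above 1 at p < 0.05 defines the candidate region, p < 0.01
#' is used for strict volcano highlighting, and q < 0.1 (BH) bounds the
#' false discovery rate.
#'
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @param max_p Nominal p-value cutoff (default 0.05).
#' @param strict_p Strict cutoff for volcano highlighting (default 0.01).
#' @param max_q BH-adjusted cutoff (default 0.1).
#' @return List of class `"de_thresholds"`.
#' @export
de_thresholds <- function(min_abs_log2fc = 1, max_p = 0.05,
                          strict_p = 0.01, max_q = 0.1) {
  th <- list(min_abs_log2fc = min_abs_log2fc, max_p = max_p,
             strict_p = strict_p, max_q = max_q)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (th$max_p > 1) stop("max_p must be <= 1", call. = FALSE)
  class(th) <- "de_thresholds"
  th
}

# Equal-variance two-sample t-test with documented degenerate conventions:
# zero pooled variance with zero difference -> t = 0, p = 1; zero pooled
# variance with nonzero difference -> t = +/-Inf, p = 0.
student_t <- function(a, b, var.equal = TRUE) {
  na <- length(a); nb <- length(b)
  d <- mean(a) - mean(b)
  res <- tryCatch({
    tt <- stats::t.test(a, b, var.equal = var.equal)
    list(t = unname(tt$statistic), p = tt$p.value,
         se = unname(tt$stderr), df = unname(tt$parameter))
  }, error = function(e) NULL)
  if (is.null(res) || is.na(res$p)) {
    df <- if (var.equal) na + nb - 2 else NA_real_
    if (d == 0) res <- list(t = 0, p = 1, se = 0, df = df)
    else res <- list(t = sign(d) * Inf, p = 0, se = 0, df = df)
  }
  c(log2fc = d, t = res$t, p = res$p, se = res$se, df = res$df)
}

#' Two-group differential expression on log2 abundances
#'
#' Per protein: the log2 fold change is the mean difference (group A minus
#' group B) and significance is the equal-variance (Student) two-sample
#' t-test, two-sided; Welch's form is available via `var.equal = FALSE`.
#' BH-adjusted q-values are computed across all tested proteins. Proteins
#' with fewer than two non-missing values in either group are reported as
#' untested (`NA` statistics).
#'
#' @param mat Numeric matrix, proteins x samples, log2 scale.
#' @param group_a,group_b Character vectors of sample IDs (columns).
#' @param var.equal Pooled-variance Student form (default) or Welch.
#' @return Data frame of class `"de_result"`: `protein, log2fc, t, p, q,
#'   se, df, n_a, n_b, tested`.
#' @export
differential_expression <- function(mat, group_a, group_b,
                                    var.equal = TRUE) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty sample group", call. = FALSE)
  missing_s <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(missing_s) > 0)
    stop("sample(s) not in matrix: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  res <- data.frame(protein = rownames(mat), log2fc = NA_real_,
                    t = NA_real_, p = NA_real_, q = NA_real_,
                    se = NA_real_, df = NA_real_,
                    n_a = 0L, n_b = 0L, tested = FALSE,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(mat))) {
    a <- mat[r, group_a]; a <- a[!is.na(a)]
    b <- mat[r, group_b]; b <- b[!is.na(b)]
    res$n_a[r] <- length(a); res$n_b[r] <- length(b)
    if (length(a) < 2 || length(b) < 2) next
    st <- student_t(a, b, var.equal = var.equal)
    res$log2fc[r] <- st["log2fc"]
    res$t[r] <- st["t"]
    res$p[r] <- st["p"]
    res$se[r] <- st["se"]
    res$df[r] <- st["df"]
    res$tested[r] <- TRUE
  }
  res$q[res$tested] <- bh_adjust(res$p[res$tested])
  class(res) <- c("de_result", class(res))
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement, input order preserved
#' (delegates to `stats::p.adjust` after range validation).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' One-way ANOVA across three or more groups, per protein
#'
#' Classical fixed-effects one-way ANOVA F-test on each protein row. The
#' degenerate case of zero between- and within-group variance returns
#' p = 1 with a warning.
#'
#' @param mat Numeric matrix, proteins x samples.
#' @param groups Named per-sample group labels (names = sample IDs) or a
#'   vector aligned with the columns; at least 3 distinct groups.
#' @return Data frame `protein, F, p`.
#' @export
anova_oneway <- function(mat, groups) {
  if (!is.null(names(groups))) groups <- groups[colnames(mat)]
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 3)
    stop("need >= 3 groups (use differential_expression for 2)",
         call. = FALSE)
  if (any(table(groups) < 2))
    stop("each group needs >= 2 samples", call. = FALSE)
  out <- data.frame(protein = rownames(mat), F = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  degenerate <- FALSE
  for (r in seq_len(nrow(mat))) {
    v <- mat[r, ]
    ok <- !is.na(v)
    g <- droplevels(groups[ok])
    if (nlevels(g) < 3 || any(table(g) < 2)) next
    res <- tryCatch(stats::oneway.test(v[ok] ~ g, var.equal = TRUE),
                    error = function(e) NULL)
    if (is.null(res) || is.na(res$p.value)) {
      # zero within-group variance: F undefined; flat data -> p = 1
      if (stats::var(v[ok]) == 0) {
        out$F[r] <- 0; out$p[r] <- 1; degenerate <- TRUE
      } else {
        out$F[r] <- Inf; out$p[r] <- 0
      }
    } else {
      out$F[r] <- unname(res$statistic)
      out$p[r] <- res$p.value
    }
  }
  if (degenerate)
    warning("constant protein(s): ANOVA degenerate, p set to 1",
            call. = FALSE)
  out
}

#' Uncentered-correlation (cosine) distance
#'
#' `d = 1 - sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))` over the
#' pairwise-complete positions, the similarity used by Cluster 3.0's
#' "uncentered correlation" (no mean subtraction); `d` lies in \[0, 2\].
#'
#' @param x,y Numeric vectors of equal length; `NA`s allowed.
#' @return The distance.
#' @export
uncentered_correlation_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no pairwise-complete positions", call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm vector", call. = FALSE)
  1 - sum(x * y) / (nx * ny)
}

# Pairwise uncentered-correlation distance matrix over the rows of `m`.
# Pairs sharing fewer than `min_shared` complete positions get the maximum
# observed distance, with a warning.
uncentered_distance_matrix <- function(m, min_shared = 3L) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  short_pairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (sum(ok) < min_shared) {
        d[i, j] <- d[j, i] <- NA_real_
        short_pairs <- short_pairs + 1L
      } else {
        d[i, j] <- d[j, i] <- uncentered_correlation_distance(m[i, ], m[j, ])
      }
    }
  }
  if (short_pairs > 0) {
    warning(short_pairs, " item pair(s) share < ", min_shared,
            " positions; assigned the maximum observed distance",
            call. = FALSE)
    d[is.na(d)] <- max(d, na.rm = TRUE)
  }
  d
}

#' Hierarchical clustering with uncentered correlation and complete linkage
#'
#' The Cluster 3.0 recipe: optional per-row median centering, pairwise
#' uncentered-correlation distances, agglomerative complete linkage
#' (`stats::hclust`). Items on the clustered axis that are entirely
#' missing are dropped with a warning.
#'
#' @param mat Numeric matrix, proteins x samples.
#' @param axis Cluster `"samples"` (columns) or `"proteins"` (rows).
#' @param median_center Median-center each protein row first (default
#'   TRUE).
#' @param method Linkage passed to `stats::hclust` (default
#'   `"complete"`).
#' @return An object of class `"hclust"`; leaf order in `$order`.
#' @export
hierarchical_cluster <- function(mat, axis = c("samples", "proteins"),
                                 median_center = TRUE,
                                 method = "complete") {
  axis <- match.arg(axis)
  if (median_center) {
    row_med <- apply(mat, 1, stats::median, na.rm = TRUE)
    mat <- sweep(mat, 1, row_med)
  }
  items <- if (axis == "samples") t(mat) else mat
  all_missing <- rowSums(!is.na(items)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing item(s) dropped", call. = FALSE)
    items <- items[!all_missing, , drop = FALSE]
  }
  if (nrow(items) < 2) stop("need >= 2 items to cluster", call. = FALSE)
  d <- stats::as.dist(uncentered_distance_matrix(items))
  stats::hclust(d, method = method)
}

#' PCA scores of the samples
#'
#' Singular value decomposition of the column-centered data with samples
#' as observations (each sample's coordinates are its protein abundances).
#'
#' @param mat Complete numeric matrix, proteins x samples (impute first).
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components) and
#'   `explained_variance` (fractions, sum <= 1).
#' @export
pca_scores <- function(mat, n_components = 2L) {
  if (anyNA(mat))
    stop("matrix contains missing values; impute before PCA",
         call. = FALSE)
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)])
}
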