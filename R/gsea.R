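#' Build a ranked gene list
#'
#' Orders genes by a ranking statistic (typically log2 fold change),
#' descending, with ties broken lexicographically by symbol for
#' reproducibility. Duplicate symbols and non-finite statistics are
#' rejected.
#'
#' @param genes Character vector of gene symbols.
#' @param stats Numeric ranking statistics, same length.
#' @return Data frame `gene, stat` of class `"ranked_list"`, sorted.
#' @export
ranked_list <- function(genes, stats) {
  if (length(genes) != length(stats))
    stop("genes and stats must have equal length", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene symbols in ranked list", call. = FALSE)
  if (any(!is.finite(stats)))
    stop("ranking statistics must be finite", call. = FALSE)
  ord <- order(-stats, genes)
  out <- data.frame(gene = genes[ord], stat = stats[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", class(out))
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT format: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Duplicate members within a line
#' are deduplicated. When a `universe` is supplied, each set is first
#' intersected with it and then size bounds are applied; sets falling
#' outside the bounds are dropped (their names retained in the
#' `"dropped"` attribute).
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector of measured genes.
#' @param min_size,max_size Set-size bounds applied after intersection
#'   (defaults 5 and 500).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path, universe = NULL, min_size = 5L, max_size = 500L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("malformed GMT line %d: expected name, description and members",
                   i), call. = FALSE)
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop(sprintf("malformed GMT line %d: no members", i), call. = FALSE)
    if (parts[1] %in% names(sets))
      stop(sprintf("duplicate set name '%s' at line %d", parts[1], i),
           call. = FALSE)
    sets[[parts[1]]] <- members
  }
  dropped <- character(0)
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, y = universe)
  }
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  dropped <- names(sets)[!keep]
  sets <- sets[keep]
  attr(sets, "dropped") <- dropped
  sets
}

# Weighted Kolmogorov-Smirnov running sum for a set given as positions in
# the ranked list. Returns ES, the extremum index, and the running sum.
running_sum_es <- function(stat_sorted, hit_pos, weight_exponent = 1,
                           keep_running = FALSE) {
  N <- length(stat_sorted)
  n_hit <- length(hit_pos)
  w <- abs(stat_sorted[hit_pos])^weight_exponent
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / n_hit, n_hit) else w <- w / sw
  miss_dec <- if (n_hit < N) 1 / (N - n_hit) else 0
  steps <- rep(-miss_dec, N)
  steps[hit_pos] <- w
  run <- cumsum(steps)
  i_max <- which.max(abs(run))
  es <- run[i_max]
  out <- list(es = es, extremum = i_max)
  if (keep_running) out$running <- run
  out
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Walking the ranked list, set members ("hits") increment the running sum
#' by their statistic's weight `|stat|^exponent / sum over hits`, misses
#' decrement by `1 / (N - N_hit)`. The enrichment score (ES) is the running
#' sum at its maximal absolute deviation from zero; the leading edge is
#' the set members at or before the extremum (at or after it for a
#' negative ES).
#'
#' @param ranked A [ranked_list()] (or data frame `gene, stat`).
#' @param geneset Character vector of member symbols.
#' @param weight_exponent 1 for weighted GSEA (default), 0 for classic.
#' @return List `es`, `running` (the full running sum), `leading_edge`.
#' @export
enrichment_score <- function(ranked, geneset, weight_exponent = 1) {
  hit_pos <- which(ranked$gene %in% geneset)
  if (length(hit_pos) == 0)
    stop("gene set has empty intersection with the ranked universe",
         call. = FALSE)
  r <- running_sum_es(ranked$stat, hit_pos, weight_exponent,
                      keep_running = TRUE)
  le <- if (r$es >= 0) hit_pos[hit_pos <= r$extremum]
        else hit_pos[hit_pos >= r$extremum]
  list(es = r$es, running = r$running,
       leading_edge = ranked$gene[le])
}

#' Preranked gene set enrichment analysis
#'
#' For each set, the null distribution of the enrichment score is built by
#' gene-label permutation: `n_perm` random same-size gene sets drawn from
#' the ranked universe. `NES = ES / mean(|null ES| with matching sign)`;
#' the nominal p-value is the add-one-corrected fraction of same-sign null
#' scores at least as extreme; BH adjustment is applied across sets.
#'
#' @param ranked A [ranked_list()].
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param weight_exponent See [enrichment_score()].
#' @return Data frame of class `"gsea_result"`: `set, size, es, nes, p,
#'   p_adj, leading_edge` (semicolon-joined).
#' @export
preranked_gsea <- function(ranked, collection, n_perm = 1000L, seed = 1L,
                           weight_exponent = 1) {
  if (length(collection) == 0) stop("empty gene set collection", call. = FALSE)
  N <- nrow(ranked)
  universe <- ranked$gene
  sizes <- vapply(collection, function(s) length(intersect(s, universe)),
                  integer(1))
  full_sizes <- lengths(collection)
  if (any(full_sizes > N))
    stop("gene set(s) larger than the universe: ",
         paste(names(collection)[full_sizes > N], collapse = ", "),
         call. = FALSE)
  if (any(sizes == 0))
    stop("gene set(s) with empty intersection: ",
         paste(names(collection)[sizes == 0], collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  out <- data.frame(set = names(collection), size = sizes, es = NA_real_,
                    nes = NA_real_, p = NA_real_, p_adj = NA_real_,
                    leading_edge = NA_character_, stringsAsFactors = FALSE)
  # share one null ensemble per distinct set size
  null_by_size <- new.env(parent = emptyenv())
  for (i in seq_along(collection)) {
    es_obs <- enrichment_score(ranked, collection[[i]], weight_exponent)
    k <- sizes[i]
    key <- as.character(k)
    if (is.null(null_by_size[[key]])) {
      null_es <- vapply(seq_len(n_perm), function(p) {
        pos <- sort(sample.int(N, k))
        running_sum_es(ranked$stat, pos, weight_exponent)$es
      }, numeric(1))
      null_by_size[[key]] <- null_es
    }
    null_es <- null_by_size[[key]]
    same_sign <- if (es_obs$es >= 0) null_es[null_es >= 0] else
      null_es[null_es < 0]
    denom <- mean(abs(same_sign))
    nes <- if (length(same_sign) > 0 && denom > 0) es_obs$es / denom else NA_real_
    p <- (1 + sum(abs(same_sign) >= abs(es_obs$es))) /
      (1 + length(same_sign))
    out$es[i] <- es_obs$es
    out$nes[i] <- nes
    out$p[i] <- p
    out$leading_edge[i] <- paste(es_obs$leading_edge, collapse = ";")
  }
  out$p_adj <- bh_adjust(out$p)
  class(out) <- c("gsea_result", class(out))
  out
}

#' Split significant GSEA results into up- and downregulated tables
#'
#' Partitions results by the sign of the NES, keeps sets with adjusted
#' p below `alpha`, and sorts each table by decreasing `|NES|`.
#'
#' @param results A `"gsea_result"` from [preranked_gsea()].
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return List with data frames `up` and `down`.
#' @export
two_class_report <- function(results, alpha = 0.05) {
  sig <- results[!is.na(results$p_adj) & results$p_adj < alpha, , drop = FALSE]
  up <- sig[sig$nes > 0, , drop = FALSE]
  down <- sig[sig$nes < 0, , drop = FALSE]
  list(up = up[order(-abs(up$nes)), , drop = FALSE],
       down = down[order(-abs(down$nes)), , drop = FALSE])
}
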