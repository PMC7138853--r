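#' Assemble a pipeline configuration
#'
#' Collects the file paths, parameter objects, contrast list and global
#' seed that drive [run_pipeline()]. Contrasts are named two-element lists
#' of group-label vectors; each side may pool several annotation groups
#' (e.g. all tumor subtypes vs normal).
#'
#' @param psm_paths Character vector, one PSM TSV per plex.
#' @param design_path Plex-design TSV.
#' @param annotation_path Sample-annotation TSV.
#' @param gmt_path Optional GMT file for enrichment.
#' @param homolog_path Optional two-column homolog-map TSV.
#' @param mouse_de_path Optional DE TSV of a second species
#'   (`gene, log2fc, p, q`) for signature intersection.
#' @param out_dir Output directory.
#' @param criteria [filter_criteria()].
#' @param impute [impute_config()] (its seed is overridden by the
#'   pipeline's derived stage seed).
#' @param de [de_thresholds()].
#' @param signature [signature_thresholds()].
#' @param contrasts Named list; each element `list(a = groups, b = groups)`.
#' @param grouping Roll-up level, `"protein"` or `"gene"`.
#' @param n_perm GSEA permutations.
#' @param seed Global integer seed; per-stage seeds are derived from it
#'   deterministically so single stages can be rerun in isolation.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(psm_paths, design_path, annotation_path,
                            gmt_path = NULL, homolog_path = NULL,
                            mouse_de_path = NULL,
                            out_dir = "tmtpipe_out",
                            criteria = filter_criteria(),
                            impute = impute_config(),
                            de = de_thresholds(),
                            signature = signature_thresholds(),
                            contrasts = list(
                              tumor_vs_normal = list(
                                a = c("tnbc", "spindle", "squamous",
                                      "sarcomatoid"),
                                b = "normal")),
                            grouping = "protein",
                            n_perm = 1000L,
                            seed = 1L) {
  structure(list(psm_paths = psm_paths, design_path = design_path,
                 annotation_path = annotation_path, gmt_path = gmt_path,
                 homolog_path = homolog_path, mouse_de_path = mouse_de_path,
                 out_dir = out_dir, criteria = criteria, impute = impute,
                 de = de, signature = signature, contrasts = contrasts,
                 grouping = grouping, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema and path checks only; data contents are never touched. Returns
#' the itemized failures instead of stopping, so callers can report all
#' problems at once.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of failure messages (empty when valid).
#' @export
validate_pipeline_config <- function(config) {
  failures <- character(0)
  add <- function(msg) failures <<- c(failures, msg)
  if (length(config$psm_paths) < 1) add("psm_paths: at least one PSM table required")
  for (p in config$psm_paths)
    if (!file.exists(p)) add(sprintf("psm_paths: file not found: %s", p))
  for (f in c("design_path", "annotation_path")) {
    p <- config[[f]]
    if (is.null(p)) add(sprintf("%s: required", f))
    else if (!file.exists(p)) add(sprintf("%s: file not found: %s", f, p))
  }
  for (f in c("gmt_path", "homolog_path", "mouse_de_path")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      add(sprintf("%s: file not found: %s", f, p))
  }
  for (obj in list(config$criteria, config$de, config$signature)) {
    # threshold objects self-validate on construction; re-check ranges in
    # case a field was edited after the fact
    ok <- tryCatch({
      if (inherits(obj, "filter_criteria")) do.call(filter_criteria, unclass(obj))
      else if (inherits(obj, "de_thresholds")) do.call(de_thresholds, unclass(obj))
      else if (inherits(obj, "signature_thresholds"))
        do.call(signature_thresholds, unclass(obj))
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) add(ok)
  }
  if (length(config$contrasts) == 0) add("contrasts: at least one contrast required")
  if (is.null(names(config$contrasts)) ||
      any(!nzchar(names(config$contrasts))))
    add("contrasts: must be named")
  failures
}

write_matrix_tsv <- function(mat, path, key = "protein") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- key
  write_tsv_exact(df, path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# hclust -> Newick string with branch lengths from merge heights,
# deterministic formatting.
hclust_to_newick <- function(hc) {
  height_of <- function(i) if (i < 0) 0 else hc$height[i]
  render <- function(i) {
    if (i < 0) return(hc$labels[-i])
    left <- hc$merge[i, 1]; right <- hc$merge[i, 2]
    h <- hc$height[i]
    sprintf("(%s:%s,%s:%s)",
            render(left), sprintf("%.10g", h - height_of(left)),
            render(right), sprintf("%.10g", h - height_of(right)))
  }
  paste0(render(nrow(hc$merge)), ";")
}

#' Run the full quantification and inference pipeline
#'
#' Executes, in order: per-plex quantification (filter, deduplicate, log2
#' ratio-to-reference, IQR outlier removal, median roll-up), integration
#' of plexes on the ratio scale, global median/MAD normalization,
#' back-conversion to abundances via top-3 MS1 reference intensities,
#' multiple imputation (PMM chained equations), batch correction,
#' differential expression per contrast with Rubin's-rules pooling across
#' imputations, preranked GSEA (when a GMT is supplied), significant-
#' protein signatures with optional cross-species intersection, and
#' hierarchical clustering + PCA. Every output file is recorded in a
#' manifest with its stage, parameters and seed; the same seed always
#' produces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest
#'   data frame (also written to `manifest.tsv`).
#' @export
run_pipeline <- function(config) {
  failures <- validate_pipeline_config(config)
  if (length(failures) > 0)
    stop("invalid pipeline config:\n  ", paste(failures, collapse = "\n  "),
         call. = FALSE)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         parameters = character(0), seed = integer(0),
                         stringsAsFactors = FALSE)
  note <- function(stage, file, parameters = "", seed = NA_integer_) {
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, file = file,
                                  parameters = parameters, seed = seed,
                                  stringsAsFactors = FALSE))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  design <- read_design(config$design_path)
  annotation <- read_annotation(config$annotation_path)
  plex_ids <- unique(design$plex_id)
  if (length(config$psm_paths) != length(plex_ids))
    stop("number of PSM tables (", length(config$psm_paths),
         ") does not match plexes in design (", length(plex_ids), ")",
         call. = FALSE)

  # quantify each plex on the ratio scale
  ratio_mats <- list(); kept_tables <- list(); reports <- list()
  for (k in seq_along(plex_ids)) {
    q <- run_stage(paste0("quantify:", plex_ids[k]), {
      psms <- read_psm_table(config$psm_paths[k])
      dk <- design[design$plex_id == plex_ids[k], , drop = FALSE]
      quantify_plex(psms, dk, criteria = config$criteria,
                    grouping = config$grouping)
    })
    ratio_mats[[plex_ids[k]]] <- q$ratios
    kept_tables[[plex_ids[k]]] <- q$kept
    reports[[plex_ids[k]]] <- q$filter_report
  }
  rep_df <- data.frame(plex_id = names(reports),
                       do.call(rbind, reports), check.names = FALSE)
  utils::write.table(rep_df, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("filter", "filter_report.tsv",
       paste0("min_prob=", config$criteria$min_peptide_probability))

  # integrate ratios, normalize globally, back-convert to abundances
  abundance <- run_stage("normalize", {
    combined <- integrate_plexes(ratio_mats)
    plex_of <- attr(combined, "plex")
    norm <- mad_normalize(combined)
    ref <- estimate_reference_intensity(kept_tables,
                                        grouping = config$grouping)
    missing_ref <- setdiff(rownames(norm), ref$entry)
    ab <- to_abundance(norm[setdiff(rownames(norm), missing_ref), ,
                            drop = FALSE], ref)
    attr(ab, "plex") <- plex_of
    ab
  })
  write_matrix_tsv(abundance, file.path(out_dir, "abundance.tsv"),
                   key = config$grouping)
  note("normalize", "abundance.tsv", paste0("grouping=", config$grouping))

  # impute and batch-correct
  impute_seed <- derive_seed(config$seed, 2L)
  batches <- stats::setNames(annotation$batch, annotation$sample_id)
  completed <- run_stage("impute", {
    cfg <- config$impute
    cfg$seed <- impute_seed
    imps <- pmm_impute(abundance, cfg)
    lapply(imps, batch_correct, batches = batches)
  })
  consensus <- Reduce(`+`, completed) / length(completed)
  write_matrix_tsv(consensus, file.path(out_dir, "abundance_imputed.tsv"),
                   key = config$grouping)
  note("impute", "abundance_imputed.tsv",
       sprintf("m=%d;maxit=%d;donors=%d", config$impute$m,
               config$impute$maxit, config$impute$donors), impute_seed)

  # differential expression per contrast, pooled across imputations
  prot2gene <- unique(do.call(rbind, lapply(kept_tables, function(t)
    t[, c("protein", "gene")])))
  prot2gene <- prot2gene[!duplicated(prot2gene$protein), ]
  group_of <- stats::setNames(annotation$group, annotation$sample_id)
  de_tables <- list()
  for (cname in names(config$contrasts)) {
    ctr <- config$contrasts[[cname]]
    de_tables[[cname]] <- run_stage(paste0("de:", cname), {
      sa <- names(group_of)[group_of %in% ctr$a]
      sb <- names(group_of)[group_of %in% ctr$b]
      d <- pooled_de(completed, sa, sb)
      if (config$grouping == "protein") {
        hit <- match(d$protein, prot2gene$protein)
        d$gene <- ifelse(is.na(hit), d$protein, prot2gene$gene[hit])
      }
      d
    })
    write_tsv_exact(de_tables[[cname]],
                    file.path(out_dir, sprintf("de_%s.tsv", cname)))
    note("de", sprintf("de_%s.tsv", cname),
         sprintf("a=%s;b=%s", paste(ctr$a, collapse = "+"),
                 paste(ctr$b, collapse = "+")))
  }

  # GSEA on the first contrast's fold changes
  gsea_res <- NULL
  if (!is.null(config$gmt_path)) {
    gsea_seed <- derive_seed(config$seed, 3L)
    gsea_res <- run_stage("gsea", {
      de1 <- de_tables[[1]]
      de1 <- de1[de1$tested, ]
      rl <- ranked_list(de1$gene, de1$log2fc)
      sets <- read_gmt(config$gmt_path, universe = rl$gene)
      if (length(sets) == 0) NULL else
        preranked_gsea(rl, sets, n_perm = config$n_perm, seed = gsea_seed)
    })
    if (!is.null(gsea_res)) {
      write_tsv_exact(gsea_res, file.path(out_dir, "gsea.tsv"))
      note("gsea", "gsea.tsv", sprintf("n_perm=%d", config$n_perm),
           gsea_seed)
    }
  }

  # signatures (first contrast), optional cross-species overlap
  signature <- run_stage("signatures", {
    de1 <- de_tables[[1]]
    up <- significant_proteins(de1, config$signature, "up")
    down <- significant_proteins(de1, config$signature, "down")
    res <- list(up = sort(up), down = sort(down), overlap = NULL)
    if (!is.null(config$homolog_path) && !is.null(config$mouse_de_path)) {
      hmap <- read_homolog_map(config$homolog_path)
      mde <- utils::read.delim(config$mouse_de_path, sep = "\t",
                               stringsAsFactors = FALSE)
      m_up <- map_homologs(
        significant_proteins(mde, config$signature, "up"), hmap)
      m_down <- map_homologs(
        significant_proteins(mde, config$signature, "down"), hmap)
      res$overlap <- overlap_signature(up, down, m_up$mapped, m_down$mapped)
    }
    res
  })
  sig_df <- data.frame(
    gene = c(signature$up, signature$down),
    direction = c(rep("up", length(signature$up)),
                  rep("down", length(signature$down))),
    stringsAsFactors = FALSE)
  write_tsv_exact(sig_df, file.path(out_dir, "signature.tsv"))
  note("signatures", "signature.tsv",
       sprintf("p<%g;q<%g;|log2fc|>%g", config$signature$max_p,
               config$signature$max_q, config$signature$min_log2fc))
  if (!is.null(signature$overlap)) {
    ov <- signature$overlap
    ov_df <- data.frame(
      region = c("up_shared", "up_human_only", "up_mouse_only",
                 "down_shared", "down_human_only", "down_mouse_only"),
      count = c(ov$venn$up["shared"], ov$venn$up["human_only"],
                ov$venn$up["mouse_only"], ov$venn$down["shared"],
                ov$venn$down["human_only"], ov$venn$down["mouse_only"]),
      stringsAsFactors = FALSE)
    write_tsv_exact(ov_df, file.path(out_dir, "signature_overlap_venn.tsv"))
    write_tsv_exact(ov$membership,
                    file.path(out_dir, "signature_membership.tsv"))
    note("signatures", "signature_overlap_venn.tsv")
    note("signatures", "signature_membership.tsv")
  }

  # clustering and PCA on the consensus completed matrix
  run_stage("cluster", {
    hc <- hierarchical_cluster(consensus, axis = "samples",
                               median_center = TRUE)
    writeLines(hclust_to_newick(hc), file.path(out_dir, "dendrogram.newick"))
    pca <- pca_scores(consensus, n_components = 3L)
    pca_df <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                         check.names = FALSE)
    write_tsv_exact(pca_df, file.path(out_dir, "pca_scores.tsv"))
    ev <- data.frame(component = seq_along(pca$explained_variance),
                     explained_variance = pca$explained_variance)
    write_tsv_exact(ev, file.path(out_dir, "pca_variance.tsv"))
  })
  note("cluster", "dendrogram.newick",
       "median_center;uncentered_correlation;complete")
  note("cluster", "pca_scores.tsv")
  note("cluster", "pca_variance.tsv")

  note("pipeline", "manifest.tsv", paste0("global_seed=", config$seed),
       config$seed)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(abundance = abundance, completed = completed,
                 consensus = consensus, de = de_tables, gsea = gsea_res,
                 signature = signature, manifest = manifest))
}

#' Differential expression pooled across multiply imputed datasets
#'
#' Runs [differential_expression()] on each completed matrix and combines
#' per-protein fold-change estimates and squared standard errors by
#' Rubin's rules ([pool_rubin()]); q-values are BH-adjusted pooled
#' p-values. The reported `p_median` is the median per-imputation p-value,
#' a simpler pooled summary.
#'
#' @param completed List of completed matrices from [pmm_impute()] (after
#'   any batch correction).
#' @param group_a,group_b Sample-ID vectors.
#' @return A `"de_result"`-style data frame with pooled columns; includes
#'   `gene` (equal to `protein`) for ranked-list construction.
#' @export
pooled_de <- function(completed, group_a, group_b) {
  per_imp <- lapply(completed, differential_expression,
                    group_a = group_a, group_b = group_b)
  base <- per_imp[[1]]
  m <- length(per_imp)
  n <- nrow(base)
  out <- data.frame(protein = base$protein, gene = base$protein,
                    log2fc = NA_real_, t = NA_real_, p = NA_real_,
                    q = NA_real_, p_median = NA_real_,
                    n_a = base$n_a, n_b = base$n_b, tested = base$tested,
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    if (!base$tested[r]) next
    est <- vapply(per_imp, function(d) d$log2fc[r], numeric(1))
    v <- vapply(per_imp, function(d) d$se[r]^2, numeric(1))
    pooled <- pool_rubin(est, v, dfcom = base$df[r])
    out$log2fc[r] <- pooled$estimate
    out$t[r] <- pooled$statistic
    out$p[r] <- pooled$p.value
    out$p_median[r] <- median_pooled_pvalue(
      vapply(per_imp, function(d) d$p[r], numeric(1)))
  }
  out$q[out$tested] <- bh_adjust(out$p[out$tested])
  class(out) <- c("de_result", class(out))
  out
}
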