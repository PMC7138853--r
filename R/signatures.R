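#' Thresholds for significant-protein calling
#'
#' The cutoffs used to call a protein significantly deregulated: nominal
#' p < 0.05, BH q < 0.1 and |log2 fold change| > 1, all strict
#' inequalities.
#'
#' @param max_p Nominal p cutoff (default 0.05).
#' @param max_q BH q cutoff (default 0.1).
#' @param min_log2fc Absolute log2 fold-change cutoff (default 1).
#' @return List of class `"signature_thresholds"`.
#' @export
signature_thresholds <- function(max_p = 0.05, max_q = 0.1,
                                 min_log2fc = 1) {
  th <- list(max_p = max_p, max_q = max_q, min_log2fc = min_log2fc)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (th$max_p > 1) stop("max_p must be <= 1", call. = FALSE)
  class(th) <- "signature_thresholds"
  th
}

#' Call significantly up- or downregulated proteins from a DE table
#'
#' Up: `log2fc > min_log2fc`; down: `log2fc < -min_log2fc`; both
#' additionally require `p < max_p` and `q < max_q` (strict). Returns the
#' gene symbols when the DE table carries a `gene` column, otherwise the
#' protein IDs.
#'
#' @param de A `"de_result"` data frame with `log2fc, p, q` columns.
#' @param thresholds A [signature_thresholds()].
#' @param direction `"up"` or `"down"`.
#' @return Character vector of significant symbols.
#' @export
significant_proteins <- function(de, thresholds = signature_thresholds(),
                                 direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is.null(de$q) || all(is.na(de$q)))
    stop("DE table has no q-values; run bh_adjust first", call. = FALSE)
  fc_ok <- if (direction == "up") de$log2fc > thresholds$min_log2fc
           else de$log2fc < -thresholds$min_log2fc
  sel <- !is.na(de$p) & !is.na(de$q) & !is.na(de$log2fc) &
    fc_ok & de$p < thresholds$max_p & de$q < thresholds$max_q
  key <- if (!is.null(de$gene)) de$gene else de$protein
  unique(key[sel])
}

#' Read a two-column homolog-mapping table
#'
#' @param path TSV with two columns: source symbol, target symbol (header
#'   optional; lines with fewer than two fields are rejected).
#' @param direction Free-text label recorded on the map (e.g.
#'   `"mouse_to_human"`).
#' @return Data frame `source, target` of class `"homolog_map"`.
#' @export
read_homolog_map <- function(path, direction = "mouse_to_human") {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          header = FALSE, colClasses = "character")
  if (ncol(df) < 2)
    stop("homolog map must have two columns", call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("source", "target")
  # tolerate a header row
  if (tolower(df$source[1]) %in% c("source", "mouse", "from", "gene"))
    df <- df[-1, , drop = FALSE]
  df <- df[nzchar(df$source) & nzchar(df$target), , drop = FALSE]
  attr(df, "direction") <- direction
  class(df) <- c("homolog_map", class(df))
  df
}

#' Map gene symbols through a homolog table
#'
#' Symbols are matched case-insensitively. One-to-many mappings expand to
#' all targets; unmapped symbols are reported separately, never silently
#' dropped.
#'
#' @param genes Character vector of symbols to map.
#' @param map A `"homolog_map"` (or data frame `source, target`).
#' @return List with `mapped` (unique target symbols) and `unmapped`
#'   (source symbols without a match).
#' @export
map_homologs <- function(genes, map) {
  if (is.null(map) || nrow(map) == 0) stop("empty homolog map", call. = FALSE)
  src <- toupper(map$source)
  hits <- lapply(genes, function(g) map$target[src == toupper(g)])
  unmapped <- genes[lengths(hits) == 0]
  mapped <- unique(unlist(hits, use.names = FALSE))
  if (is.null(mapped)) mapped <- character(0)
  list(mapped = mapped, unmapped = unmapped)
}

#' Intersect human and (homolog-mapped) mouse significant-protein sets
#'
#' The cross-species signature: up = human up intersect mouse up, down =
#' human down intersect mouse down, with Venn-region counts for every
#' region of each direction's two-set diagram. A warning is issued when a
#' human set contains lower-case (mouse-style) symbols, suggesting
#' unmapped namespaces.
#'
#' @param human_up,human_down Character vectors of human symbols.
#' @param mouse_up_mapped,mouse_down_mapped Mouse sets after
#'   [map_homologs()].
#' @return List of class `"overlap_signature"`: `up`, `down`, `venn`
#'   (region counts), `membership` (per-gene table).
#' @export
overlap_signature <- function(human_up, human_down,
                              mouse_up_mapped, mouse_down_mapped) {
  sets <- list(human_up = unique(human_up), human_down = unique(human_down),
               mouse_up = unique(mouse_up_mapped),
               mouse_down = unique(mouse_down_mapped))
  for (nm in c("human_up", "human_down")) {
    s <- sets[[nm]]
    if (any(s != toupper(s)))
      warning("lower-case symbols in ", nm,
              ": possible unmapped mouse namespace", call. = FALSE)
  }
  up <- sort(intersect(sets$human_up, sets$mouse_up))
  down <- sort(intersect(sets$human_down, sets$mouse_down))
  venn <- list(
    up = c(human_only = length(setdiff(sets$human_up, sets$mouse_up)),
           mouse_only = length(setdiff(sets$mouse_up, sets$human_up)),
           shared = length(up)),
    down = c(human_only = length(setdiff(sets$human_down, sets$mouse_down)),
             mouse_only = length(setdiff(sets$mouse_down, sets$human_down)),
             shared = length(down)))
  all_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- data.frame(
    gene = all_genes,
    human_up = all_genes %in% sets$human_up,
    human_down = all_genes %in% sets$human_down,
    mouse_up = all_genes %in% sets$mouse_up,
    mouse_down = all_genes %in% sets$mouse_down,
    stringsAsFactors = FALSE)
  structure(list(up = up, down = down, venn = venn,
                 membership = membership,
                 provenance = c("human", "mouse_mapped")),
            class = "overlap_signature")
}
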