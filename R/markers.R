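# Marker-gene selection for the nominated malignant cluster, and
# intersection with metabolic gene sets to form the candidate universe for
# pair mining.

#' Select marker genes of one cell cluster
#'
#' Per-gene two-sided Wilcoxon rank-sum test of the target cluster against
#' all other cells, Benjamini-Hochberg adjustment, and a log-fold-change
#' filter.  Expression is assumed to be on a log scale, so the fold change
#' is the difference of class means.
#'
#' @param expression numeric genes x cells matrix (log scale).
#' @param cluster_labels per-cell cluster IDs (length `ncol(expression)`).
#' @param target_cluster cluster whose markers are wanted (>= 3 cells).
#' @param min_lfc minimum log fold change (target minus rest), default 0.25.
#' @param alpha BH-adjusted significance cutoff, default 0.05.
#' @return data.frame with columns `gene`, `log_fold_change`, `p_value`,
#'   `adjusted_p`, `cluster`, sorted by `adjusted_p` then decreasing
#'   `|log_fold_change|`.
#' @export
select_cluster_markers <- function(expression, cluster_labels, target_cluster,
                                   min_lfc = 0.25, alpha = 0.05) {
  check_flag(is.matrix(expression) && ncol(expression) == length(cluster_labels),
             "input error: one cluster label per cell required")
  in_target <- as.character(cluster_labels) == as.character(target_cluster)
  check_flag(any(in_target), "input error: target cluster '%s' absent", target_cluster)
  check_flag(sum(in_target) >= 3L, "input error: target cluster needs >= 3 cells")
  check_flag(any(!in_target), "input error: no cells outside the target cluster")

  lfc <- rowMeans(expression[, in_target, drop = FALSE]) -
    rowMeans(expression[, !in_target, drop = FALSE])
  pvals <- vapply(seq_len(nrow(expression)), function(g) {
    x <- expression[g, in_target]; y <- expression[g, !in_target]
    if (length(unique(c(x, y))) == 1L) return(1)  # constant gene: no evidence
    suppressWarnings(wilcox.test(x, y)$p.value)
  }, numeric(1L))
  adj <- p.adjust(pvals, method = "BH")
  keep <- adj < alpha & lfc > min_lfc
  out <- data.frame(gene = rownames(expression)[keep],
                    log_fold_change = lfc[keep],
                    p_value = pvals[keep],
                    adjusted_p = adj[keep],
                    cluster = rep(as.character(target_cluster), sum(keep)),
                    stringsAsFactors = FALSE)
  out[order(out$adjusted_p, -abs(out$log_fold_change)), , drop = FALSE]
}

#' Intersect marker genes with metabolic gene sets
#'
#' Returns the marker genes present in the union of all sets of the
#' collection, preserving marker order and dropping duplicates.  An empty
#' intersection raises a warning (downstream pair mining then has no
#' candidates).
#'
#' @param markers character vector of gene IDs, or a
#'   [select_cluster_markers()] result.
#' @param collection a [gene_set_collection()].
#' @return character vector of candidate genes.
#' @export
intersect_with_metabolic <- function(markers, collection) {
  if (is.data.frame(markers)) markers <- markers$gene
  check_flag(inherits(collection, "gene_set_collection"),
             "input error: 'collection' must be a gene_set_collection")
  universe <- unique(unlist(collection$sets, use.names = FALSE))
  out <- unique(markers[markers %in% universe])
  if (length(out) == 0)
    warning("empty intersection of markers with metabolic gene sets", call. = FALSE)
  out
}
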