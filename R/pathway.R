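# Per-cell gene-set activity by two rank-based scorers.  Both use only the
# ordering of genes within a cell, so they are invariant to any strictly
# increasing per-cell transform of expression.

#' Dense per-cell gene ranks (1 = highest expression)
#'
#' Ties are broken by one seeded random permutation of the gene order, fixed
#' for the whole call, so repeated runs with the same seed are identical and
#' no gene is systematically favoured.
#'
#' @param expression numeric genes x cells matrix.
#' @param seed integer seed for the tie-breaking permutation.
#' @return integer genes x cells matrix of ranks, each column a permutation
#'   of `1..nrow(expression)`.
#' @export
rank_genes_per_cell <- function(expression, seed = 1L) {
  check_flag(is.matrix(expression) && nrow(expression) >= 1L,
             "input error: 'expression' must be a matrix with >= 1 gene")
  G <- nrow(expression)
  perm <- withr::with_seed(seed, sample.int(G))
  ranks <- apply(expression, 2L, function(v) {
    ord <- order(-v, perm)         # descending value, permuted tie-break
    r <- integer(G); r[ord] <- seq_len(G); r
  })
  dimnames(ranks) <- dimnames(expression)
  ranks
}

#' AUCell-style gene-set activity score for one cell
#'
#' Area under the set-gene recovery curve within the top `top_fraction` of
#' the cell's ranked genes: with `T = ceiling(top_fraction * N)` and
#' `hits(x) = #{set genes with rank <= x}`, the raw AUC is
#' `sum(hits(x), x = 1..T)`, normalized by its maximum
#' `sum(min(x, m), x = 1..T)` for an m-gene effective set.  1 means all set
#' genes occupy the very top ranks; 0 means none enter the top fraction.
#'
#' @param ranks integer rank vector for one cell, names = gene IDs
#'   (1 = highest expression).
#' @param gene_set character gene IDs; genes absent from `ranks` are
#'   dropped, the effective set must be non-empty.
#' @param top_fraction fraction of the ranking that counts, default 0.05.
#' @return score in \[0, 1\].
#' @export
aucell_score <- function(ranks, gene_set, top_fraction = 0.05) {
  check_flag(!is.null(names(ranks)), "input error: 'ranks' must be named by gene")
  N <- length(ranks)
  eff <- intersect(gene_set, names(ranks))
  check_flag(length(eff) > 0, "input error: gene set has no genes in the ranking")
  T <- ceiling(top_fraction * N)
  check_flag(T >= 1L, "input error: top fraction selects zero genes")
  m <- length(eff)
  set_ranks <- ranks[eff]
  hits <- vapply(seq_len(T), function(x) sum(set_ranks <= x), numeric(1L))
  raw <- sum(hits)
  max_auc <- sum(pmin(seq_len(T), m))
  raw / max_auc
}

#' ssGSEA-style enrichment score for one cell
#'
#' Weighted Kolmogorov-Smirnov running sum over the cell's descending gene
#' ranking: stepping down the list, an in-set gene at position k adds
#' `w^alpha / sum(w_set^alpha)` (weight `w = N - k + 1`, i.e. N for the top
#' gene down to 1), an out-of-set gene subtracts `1/(N - m)`.  The score is
#' the integrated (summed) running sum over all N positions, positive when
#' set genes concentrate at the top.
#'
#' @inheritParams aucell_score
#' @param alpha rank-weight exponent, default 0.25.
#' @return enrichment score (unbounded real).
#' @export
ssgsea_score <- function(ranks, gene_set, alpha = 0.25) {
  check_flag(!is.null(names(ranks)), "input error: 'ranks' must be named by gene")
  N <- length(ranks)
  eff <- intersect(gene_set, names(ranks))
  m <- length(eff)
  check_flag(m > 0, "input error: gene set has no genes in the ranking")
  check_flag(m < N, "input error: gene set equals the whole universe")
  in_set <- names(sort(ranks)) %in% eff   # positions 1..N in descending expression
  w <- (N:1)^alpha                        # weight N^alpha at the top position
  pos_w <- ifelse(in_set, w, 0)
  steps <- ifelse(in_set, pos_w / sum(pos_w), -1 / (N - m))
  sum(cumsum(steps))
}

#' Score every cell against every gene set
#'
#' Applies the chosen scorer to each cell x pathway combination.  Genes
#' absent from the expression universe are dropped from each set (count
#' messaged); a set with no overlap is scored `NA` with a warning.
#'
#' @param expression numeric genes x cells matrix.
#' @param collection a [gene_set_collection()].
#' @param method `"ssgsea"` or `"aucell"`.
#' @param top_fraction,alpha scorer parameters (see [aucell_score()],
#'   [ssgsea_score()]).
#' @param seed seed for rank tie-breaking.
#' @return object of class `activity_matrix`: pathways x cells numeric
#'   matrix with attribute `method`.
#' @export
score_all <- function(expression, collection, method = c("ssgsea", "aucell"),
                      top_fraction = 0.05, alpha = 0.25, seed = 1L) {
  method <- match.arg(method)
  check_flag(inherits(collection, "gene_set_collection"),
             "input error: 'collection' must be a gene_set_collection")
  ranks <- rank_genes_per_cell(expression, seed = seed)
  genes <- rownames(expression)
  out <- matrix(NA_real_, nrow = length(collection$sets), ncol = ncol(expression),
                dimnames = list(names(collection$sets), colnames(expression)))
  for (p in names(collection$sets)) {
    set <- collection$sets[[p]]
    eff <- intersect(set, genes)
    dropped <- length(set) - length(eff)
    if (dropped > 0)
      message(sprintf("pathway '%s': dropped %d gene(s) absent from the matrix", p, dropped))
    if (length(eff) == 0) {
      warning(sprintf("pathway '%s' has no genes in the matrix; scored as missing", p),
              call. = FALSE)
      next
    }
    out[p, ] <- apply(ranks, 2L, function(r) {
      names(r) <- genes
      if (method == "aucell") aucell_score(r, eff, top_fraction)
      else ssgsea_score(r, eff, alpha)
    })
  }
  attr(out, "method") <- method
  class(out) <- c("activity_matrix", class(out))
  out
}

#' Per-cluster mean activity summary
#'
#' @param activity an [score_all()] result (pathways x cells).
#' @param assignment per-cell cluster IDs.
#' @return data.frame: pathway, cluster, mean activity.
#' @export
activity_by_cluster <- function(activity, assignment) {
  check_flag(ncol(activity) == length(assignment),
             "input error: one cluster label per cell required")
  ids <- sort(unique(as.character(assignment)))
  do.call(rbind, lapply(ids, function(k) {
    data.frame(pathway = rownames(activity), cluster = k,
               mean_activity = rowMeans(activity[, as.character(assignment) == k, drop = FALSE]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
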