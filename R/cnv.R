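# Post-processing of inferred copy-number profiles: quality control,
# per-cell / per-cluster CNV scores, and k-means secondary clustering with
# elbow-based selection of the number of clusters.

#' Construct a CNV profile matrix
#'
#' Holds inferCNV-style "modified expression" centered at the diploid
#' baseline 1: genes (chromosome-ordered) x cells, positive finite values.
#' Reference cells, when present, are excluded from secondary clustering
#' and scoring summaries.
#'
#' @param values positive finite genes x cells matrix.
#' @param cell_origin per-cell `"tumor"` or `"reference"` (default all
#'   tumor).
#' @return object of class `cnv_matrix`: list with `values`, `cell_origin`.
#' @export
cnv_matrix <- function(values, cell_origin = NULL) {
  check_flag(is.matrix(values) && is.numeric(values), "input error: 'values' must be a numeric matrix")
  check_flag(all(is.finite(values)) && all(values > 0),
             "input error: CNV values must be finite and positive")
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%04d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("c%05d", seq_len(ncol(values)))
  cell_origin <- cell_origin %||% rep("tumor", ncol(values))
  check_flag(length(cell_origin) == ncol(values) && all(cell_origin %in% c("tumor", "reference")),
             "input error: 'cell_origin' must be per-cell 'tumor' or 'reference'")
  new_tag(list(values = values, cell_origin = cell_origin), "cnv_matrix")
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("cnv_matrix: %d genes x %d cells (%d tumor, %d reference)\n",
              nrow(x$values), ncol(x$values),
              sum(x$cell_origin == "tumor"), sum(x$cell_origin == "reference")))
  invisible(x)
}

#' Quality-control filter for single cells
#'
#' Keeps cells with mitochondrial count fraction below `mito_max`,
#' hemoglobin (red-blood-cell) count fraction below `hb_max`, and a
#' detected-gene count inside `[min_genes, max_genes]` (inclusive).  The
#' fraction cutoffs are strict (`<`), the gene-count range inclusive.
#'
#' @param counts genes x cells count matrix.
#' @param mito_genes,hb_genes gene IDs annotated mitochondrial / hemoglobin;
#'   both annotations are required (may be empty character vectors only if
#'   explicitly passed).
#' @param mito_max,hb_max fraction cutoffs (defaults 0.10 and 0.03).
#' @param min_genes,max_genes detected-gene bounds (defaults 200 and 8000).
#' @return data.frame, one row per cell: `cell`, `mito_frac`, `hb_frac`,
#'   `n_genes`, `keep`, `reason` (comma-separated failure reasons, empty if
#'   kept).  Attribute `kept` holds the kept cell IDs.
#' @export
qc_filter <- function(counts, mito_genes, hb_genes, mito_max = 0.10, hb_max = 0.03,
                      min_genes = 200L, max_genes = 8000L) {
  check_flag(is.matrix(counts) && !is.null(rownames(counts)),
             "input error: 'counts' must be a matrix with gene rownames")
  check_flag(!missing(mito_genes) && !missing(hb_genes),
             "input error: mitochondrial and hemoglobin gene annotations required")
  total <- colSums(counts)
  total[total == 0] <- NA_real_
  mito_frac <- colSums(counts[rownames(counts) %in% mito_genes, , drop = FALSE]) / total
  hb_frac <- colSums(counts[rownames(counts) %in% hb_genes, , drop = FALSE]) / total
  mito_frac[is.na(mito_frac)] <- 0; hb_frac[is.na(hb_frac)] <- 0
  n_genes <- colSums(counts > 0)
  fail <- cbind(mito = mito_frac >= mito_max,
                hb = hb_frac >= hb_max,
                min_genes = n_genes < min_genes,
                max_genes = n_genes > max_genes)
  reason <- apply(fail, 1L, function(f) paste(colnames(fail)[f], collapse = ","))
  report <- data.frame(cell = colnames(counts) %||% as.character(seq_len(ncol(counts))),
                       mito_frac = mito_frac, hb_frac = hb_frac, n_genes = n_genes,
                       keep = !apply(fail, 1L, any), reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  attr(report, "kept") <- report$cell[report$keep]
  report
}

#' Per-cell CNV score
#'
#' Mean squared deviation of the inferred copy-number profile from the
#' diploid baseline 1: `mean((value - 1)^2)` over genes.  Zero for a
#' perfectly diploid profile; quadratic in the aberration amplitude.
#'
#' @param profile numeric vector (one cell's gene profile) or genes x cells
#'   matrix (scored column-wise).
#' @return non-negative score (vector of per-cell scores for a matrix).
#' @export
cnv_cell_score <- function(profile) {
  if (inherits(profile, "cnv_matrix")) profile <- profile$values
  check_flag(length(profile) > 0, "input error: empty CNV profile")
  check_flag(all(is.finite(profile)), "input error: non-finite CNV values")
  if (is.matrix(profile)) colMeans((profile - 1)^2) else mean((profile - 1)^2)
}

#' Per-cluster CNV scores and malignant-cluster nomination
#'
#' Cluster score = mean of member cells' [cnv_cell_score()].  The cluster
#' with the highest score is nominated as the most aberrant (malignant)
#' cluster; exact ties break to the lowest cluster ID.
#'
#' @param matrix a [cnv_matrix()] (reference cells are ignored).
#' @param assignment per-tumor-cell cluster IDs.
#' @return list with `scores` (named per-cluster score, ID-sorted) and
#'   `nominated` (cluster ID with the highest score).
#' @export
cnv_cluster_scores <- function(matrix, assignment) {
  check_flag(inherits(matrix, "cnv_matrix"), "input error: 'matrix' must be a cnv_matrix")
  tumor <- matrix$cell_origin == "tumor"
  check_flag(length(assignment) == sum(tumor),
             "input error: 'assignment' must cover all tumor cells")
  assignment <- as.character(assignment)
  cell_scores <- cnv_cell_score(matrix$values[, tumor, drop = FALSE])
  ids <- sort(unique(assignment))
  scores <- vapply(ids, function(k) {
    members <- assignment == k
    check_flag(any(members), "input error: empty cluster '%s'", k)
    mean(cell_scores[members])
  }, numeric(1L))
  list(scores = scores, nominated = ids[which.max(scores)])
}

#' Elbow rule for choosing the number of clusters
#'
#' Given the within-cluster sum-of-squares curve `wss` for k = 1..k_max,
#' picks `k* = argmax` over k in `2..k_max-1` of the second difference
#' `(wss(k-1) - wss(k)) - (wss(k) - wss(k+1))` — the sharpest bend of the
#' elbow.  Exact ties break toward the smallest tied k whose
#' explained-variance ratio `bss(k)/total` is within 0.01 of the next k's
#' (plateau check on the between-cluster sum of squares).  Degenerate input
#' (no between-cell variation, all WSS ~ 0) returns 1 with a warning.
#'
#' @param wss numeric vector, `wss[k]` for k = 1..k_max (k_max >= 3 for a
#'   non-trivial choice).
#' @param total_ss total sum of squares (default `wss[1]`, exact for
#'   k-means); `bss = total_ss - wss`.
#' @return selected number of clusters k*.
#' @export
select_k_elbow <- function(wss, total_ss = wss[1L]) {
  k_max <- length(wss)
  check_flag(k_max >= 3L, "input error: need wss for at least k = 1..3")
  if (total_ss < 1e-12 || all(wss < 1e-12)) {
    warning("degenerate input: no between-cell variation; k* = 1", call. = FALSE)
    return(1L)
  }
  bss <- total_ss - wss
  ks <- 2:(k_max - 1L)
  d2 <- (wss[ks - 1L] - wss[ks]) - (wss[ks] - wss[ks + 1L])
  k_star <- ks[which.max(d2)]
  tied <- ks[abs(d2 - max(d2)) < 1e-12]
  for (k in sort(tied)) {
    if (bss[k] / total_ss >= bss[min(k + 1L, k_max)] / total_ss - 0.01) return(k)
  }
  k_star
}

# k-means++ center initialization (seeded by the caller's RNG state).
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - X[rep(centers[1L], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = probs)
    d2_new <- rowSums((X - X[rep(centers[j + 1L], n), , drop = FALSE])^2)
    d2 <- pmin(d2, d2_new)
  }
  X[centers, , drop = FALSE]
}

#' K-means secondary clustering of CNV profiles with elbow-based k selection
#'
#' Runs Lloyd k-means (k-means++ initialization, `n_restarts` restarts, best
#' total within-cluster sum of squares kept) on the tumor cells' CNV
#' profiles for k = 1..`k_max`, then selects the number of clusters at the
#' elbow of the WSS curve: `k* = argmax` over k in `2..k_max-1` of the
#' second difference `(wss(k-1) - wss(k)) - (wss(k) - wss(k+1))`.  Ties
#' break toward the smaller k whose explained-variance ratio
#' `bss(k)/total` is within 0.01 of the next k's (plateau check).  A
#' degenerate input (all WSS ~ 0) yields k* = 1 with a warning.
#'
#' @param matrix a [cnv_matrix()]; reference cells are excluded.
#' @param k_max largest k explored (>= 2).
#' @param n_restarts k-means restarts per k (default 10).
#' @param seed integer RNG seed.
#' @return object of class `cnv_clustering`: list with `assignment`
#'   (per-tumor-cell cluster ID at k*), `k`, `wss` and `bss` (per-k curves,
#'   k = 1..k_max), `total_ss`, and `scores`/`nominated` from
#'   [cnv_cluster_scores()] at k*.
#' @export
kmeans_select_k <- function(matrix, k_max = 8L, n_restarts = 10L, seed = 1L) {
  check_flag(inherits(matrix, "cnv_matrix"), "input error: 'matrix' must be a cnv_matrix")
  k_max <- check_count(k_max, "k_max", min = 2L)
  X <- t(matrix$values[, matrix$cell_origin == "tumor", drop = FALSE])
  check_flag(nrow(X) >= k_max, "input error: fewer tumor cells than k_max")

  total_ss <- sum(scale(X, scale = FALSE)^2)
  wss <- numeric(k_max); assignments <- vector("list", k_max)
  withr::with_seed(seed, {
    for (k in seq_len(k_max)) {
      if (k == 1L) {
        wss[k] <- total_ss
        assignments[[k]] <- rep(1L, nrow(X))
        next
      }
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- suppressWarnings(
          kmeans(X, centers = kmeanspp_centers(X, k), algorithm = "Lloyd",
                 iter.max = 100L))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      }
      wss[k] <- best$tot.withinss
      assignments[[k]] <- best$cluster
    }
  })
  bss <- total_ss - wss

  k_star <- select_k_elbow(wss, total_ss)
  sc <- cnv_cluster_scores(matrix, assignments[[k_star]])
  new_tag(list(assignment = assignments[[k_star]], k = k_star,
               wss = wss, bss = bss, total_ss = total_ss,
               scores = sc$scores, nominated = sc$nominated),
          "cnv_clustering")
}

#' @export
print.cnv_clustering <- function(x, ...) {
  cat(sprintf("cnv_clustering: k* = %d; cluster scores: %s; nominated: %s\n",
              x$k, paste(sprintf("%s=%.4g", names(x$scores), x$scores), collapse = ", "),
              x$nominated))
  invisible(x)
}
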