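# Relative expression ordering (REO) of gene pairs.  Everything here uses
# only within-sample comparisons of two genes, so results are invariant to
# any strictly increasing per-sample transform of the expression values —
# the property that makes the derived features portable across platforms.

#' Within-class order probabilities for two genes
#'
#' For paired vectors over the same n samples, estimates
#' `p_gt = (1/n) * sum(I[x_z > y_z])` and `p_lt = (1/n) * sum(I[x_z < y_z])`.
#' Ties contribute to neither probability, so `p_gt + p_lt <= 1` with
#' equality exactly when no sample ties.
#'
#' @param x,y numeric vectors of equal positive length, same sample order.
#' @return named numeric vector `c(p_gt, p_lt)`.
#' @export
order_probability <- function(x, y) {
  check_flag(length(x) == length(y), "input error: 'x' and 'y' cover different samples")
  check_flag(length(x) >= 1L, "input error: need at least one sample")
  check_flag(all(is.finite(x)) && all(is.finite(y)), "input error: non-finite expression values")
  n <- length(x)
  c(p_gt = sum(x > y) / n, p_lt = sum(x < y) / n)
}

# Pairwise greater-than counts for a genes x samples block: C[i, j] =
# #samples with expr(i) > expr(j).  One outer comparison per sample; fine up
# to a few hundred candidate genes.
pair_gt_counts <- function(values) {
  G <- nrow(values)
  counts <- matrix(0L, G, G, dimnames = list(rownames(values), rownames(values)))
  for (z in seq_len(ncol(values))) {
    v <- values[, z]
    counts <- counts + outer(v, v, ">")
  }
  counts
}

#' Mine stable gene pairs within one sample class
#'
#' A pair {i, j} is *stable* in a class when its order probability in one
#' direction strictly exceeds `threshold` across that class's samples
#' (`p_gt > threshold` gives direction `"gt"`, `p_lt > threshold` direction
#' `"lt"`).  The inequality is strict: a pair ordered in exactly 90% of
#' samples does not pass the default 0.9 threshold.
#'
#' @param matrix a [labeled_expression()].
#' @param class_label `"tumor"` or `"normal"`.
#' @param candidate_genes genes to consider (default: all); pairs are
#'   enumerated within this set.
#' @param threshold stability cutoff in \[0.5, 1\); default 0.9.
#' @return data.frame with columns `gene_i`, `gene_j` (canonical
#'   lexicographic orientation, `gene_i < gene_j`), `direction` (`"gt"` /
#'   `"lt"`, referring to gene_i vs gene_j), `p_gt`, `p_lt`.
#' @export
find_stable_pairs <- function(matrix, class_label = c("tumor", "normal"),
                              candidate_genes = NULL, threshold = 0.9) {
  check_flag(inherits(matrix, "labeled_expression"),
             "input error: 'matrix' must be a labeled_expression")
  class_label <- match.arg(class_label)
  threshold <- check_prob(threshold, "threshold", lo = 0.5, hi = 1)
  candidate_genes <- candidate_genes %||% rownames(matrix$values)
  missing <- setdiff(candidate_genes, rownames(matrix$values))
  check_flag(length(missing) == 0, "input error: candidate genes absent from matrix: %s",
             paste(head(missing, 3L), collapse = ", "))
  in_class <- matrix$label == class_label
  check_flag(sum(in_class) >= 2L, "input error: need >= 2 samples in class '%s'", class_label)

  genes <- sort(unique(candidate_genes))  # canonical orientation by sorting
  vals <- matrix$values[genes, in_class, drop = FALSE]
  n <- ncol(vals)
  counts <- pair_gt_counts(vals)
  ut <- upper.tri(counts)                 # rows i < cols j lexicographically
  p_gt <- counts[ut] / n
  p_lt <- t(counts)[ut] / n               # counts[j, i] = #{expr(j) > expr(i)}
  idx <- which(ut, arr.ind = TRUE)
  keep <- p_gt > threshold | p_lt > threshold
  data.frame(
    gene_i = genes[idx[keep, 1L]],
    gene_j = genes[idx[keep, 2L]],
    direction = ifelse(p_gt[keep] > threshold, "gt", "lt"),
    p_gt = p_gt[keep],
    p_lt = p_lt[keep],
    stringsAsFactors = FALSE)
}

#' Mine stable reversal gene pairs between tumor and normal
#'
#' A *stable reversal pair* is stable in the tumor class with one direction
#' and stable in the normal class with the opposite direction — the
#' diagnostic feature of the REO approach.  Pairs are reported in canonical
#' orientation with both classes' order probabilities and the per-pair
#' majority binarized value over all training samples (used to impute the
#' feature in validation cohorts that lack one of the genes).
#'
#' @inheritParams find_stable_pairs
#' @return An object of class `reversal_pair_set`: a data.frame with columns
#'   `gene_i`, `gene_j`, `tumor_direction`, `p_gt_tumor`, `p_lt_tumor`,
#'   `p_gt_normal`, `p_lt_normal`, `train_major` (majority 0/1 feature value
#'   across all training samples); attribute `threshold`.
#' @export
find_reversal_pairs <- function(matrix, candidate_genes = NULL, threshold = 0.9) {
  tum <- find_stable_pairs(matrix, "tumor", candidate_genes, threshold)
  nor <- find_stable_pairs(matrix, "normal", candidate_genes, threshold)
  key_t <- paste(tum$gene_i, tum$gene_j)
  key_n <- paste(nor$gene_i, nor$gene_j)
  m <- match(key_t, key_n)
  hit <- !is.na(m) & nor$direction[m] != tum$direction  # opposite direction required
  out <- data.frame(
    gene_i = tum$gene_i[hit],
    gene_j = tum$gene_j[hit],
    tumor_direction = tum$direction[hit],
    p_gt_tumor = tum$p_gt[hit],
    p_lt_tumor = tum$p_lt[hit],
    p_gt_normal = nor$p_gt[m[hit]],
    p_lt_normal = nor$p_lt[m[hit]],
    stringsAsFactors = FALSE)
  # majority binarized value over pooled training samples, for imputation
  out$train_major <- vapply(seq_len(nrow(out)), function(r) {
    frac1 <- mean(matrix$values[out$gene_i[r], ] > matrix$values[out$gene_j[r], ])
    as.integer(frac1 > 0.5)
  }, integer(1L))
  attr(out, "threshold") <- threshold
  class(out) <- c("reversal_pair_set", "data.frame")
  out
}

#' @export
print.reversal_pair_set <- function(x, ...) {
  cat(sprintf("reversal_pair_set: %d stable reversal pairs (threshold > %g)\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 10L), row.names = FALSE)
  invisible(x)
}

#' Binarize an expression matrix over a reversal pair set
#'
#' Produces the pairs x samples binary profile: entry 1 iff
#' `expr(gene_i) > expr(gene_j)` in that sample; ties and `<` map to 0.
#' Pairs whose genes are absent from the matrix (cross-platform validation
#' cohorts) are imputed with the pair's majority training value
#' (`train_major`) and recorded.
#'
#' @param matrix numeric genes x samples matrix, or a [labeled_expression()].
#' @param pairs a [find_reversal_pairs()] result (or any data.frame with
#'   `gene_i`, `gene_j` and, for imputation, `train_major`).
#' @return An object of class `pair_profile`: binary pairs x samples matrix
#'   (rownames `"gene_i|gene_j"`); attribute `imputed` names the imputed
#'   pair features.
#' @export
binarize <- function(matrix, pairs) {
  if (inherits(matrix, "labeled_expression")) matrix <- matrix$values
  check_flag(is.matrix(matrix) && is.numeric(matrix), "input error: 'matrix' must be numeric")
  check_flag(nrow(pairs) >= 1L, "input error: empty pair set")
  pair_id <- paste(pairs$gene_i, pairs$gene_j, sep = "|")
  present <- pairs$gene_i %in% rownames(matrix) & pairs$gene_j %in% rownames(matrix)
  if (!any(present)) stop_input("no usable features: all pair genes absent from matrix")
  prof <- matrix(0L, nrow = nrow(pairs), ncol = ncol(matrix),
                 dimnames = list(pair_id, colnames(matrix)))
  for (r in which(present)) {
    prof[r, ] <- as.integer(matrix[pairs$gene_i[r], ] > matrix[pairs$gene_j[r], ])
  }
  if (any(!present)) {
    fill <- pairs$train_major %||% rep(0L, nrow(pairs))
    for (r in which(!present)) prof[r, ] <- as.integer(fill[r])
    warning(sprintf("imputed %d pair feature(s) with training majority value: %s",
                    sum(!present), paste(pair_id[!present], collapse = ", ")),
            call. = FALSE)
  }
  attr(prof, "imputed") <- pair_id[!present]
  class(prof) <- c("pair_profile", class(prof))
  prof
}

#' Write / read a reversal pair set as TSV
#' @param pairs a `reversal_pair_set`.
#' @param path TSV path.
#' @return [read_pairs()] returns the `reversal_pair_set`.
#' @export
write_pairs <- function(pairs, path) {
  out <- as.data.frame(pairs)
  for (cl in c("p_gt_tumor", "p_lt_tumor", "p_gt_normal", "p_lt_normal"))
    out[[cl]] <- format_num(out[[cl]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  class(df) <- c("reversal_pair_set", "data.frame")
  df
}
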