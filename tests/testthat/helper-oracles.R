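# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from first principles (explicit
# loops over samples / pairs) and share no code with the package internals.

# Enumerate all stable and reversal pairs by recounting indicators per pair.
oracle_reversal_pairs <- function(values, label, threshold = 0.9) {
  genes <- sort(rownames(values))
  out <- NULL
  for (a in seq_along(genes)) for (b in seq_along(genes)) {
    if (a >= b) next
    gi <- genes[a]; gj <- genes[b]
    res <- list()
    for (cls in c("tumor", "normal")) {
      x <- values[gi, label == cls]; y <- values[gj, label == cls]
      res[[cls]] <- c(gt = mean(x > y), lt = mean(x < y))
    }
    dir_t <- if (res$tumor["gt"] > threshold) "gt" else if (res$tumor["lt"] > threshold) "lt" else NA
    dir_n <- if (res$normal["gt"] > threshold) "gt" else if (res$normal["lt"] > threshold) "lt" else NA
    if (!is.na(dir_t) && !is.na(dir_n) && dir_t != dir_n)
      out <- rbind(out, data.frame(gene_i = gi, gene_j = gj, tumor_direction = dir_t,
                                   stringsAsFactors = FALSE))
  }
  out
}

oracle_stable_pairs <- function(values, label, cls, threshold = 0.9) {
  genes <- sort(rownames(values))
  out <- NULL
  for (a in seq_along(genes)) for (b in seq_along(genes)) {
    if (a >= b) next
    x <- values[genes[a], label == cls]; y <- values[genes[b], label == cls]
    p_gt <- mean(x > y); p_lt <- mean(x < y)
    if (p_gt > threshold || p_lt > threshold)
      out <- rbind(out, data.frame(gene_i = genes[a], gene_j = genes[b],
                                   direction = if (p_gt > threshold) "gt" else "lt",
                                   stringsAsFactors = FALSE))
  }
  out
}

# AUC by explicit pairwise concordance count.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# AUCell recovery-curve score by direct summation.
oracle_aucell <- function(ranks, gene_set, top_fraction = 0.05) {
  N <- length(ranks); T <- ceiling(top_fraction * N)
  eff <- intersect(gene_set, names(ranks))
  hits <- sapply(seq_len(T), function(x) sum(ranks[eff] <= x))
  sum(hits) / sum(pmin(seq_len(T), length(eff)))
}

# ssGSEA running sum by explicit walk.
oracle_ssgsea <- function(ranks, gene_set, alpha = 0.25) {
  N <- length(ranks)
  ord <- names(ranks)[order(ranks)]          # descending expression
  eff <- intersect(gene_set, names(ranks))
  denom <- sum((N - ranks[eff] + 1)^alpha)
  rs <- 0; acc <- 0
  for (k in seq_len(N)) {
    g <- ord[k]
    rs <- rs + if (g %in% eff) (N - k + 1)^alpha / denom else -1 / (N - length(eff))
    acc <- acc + rs
  }
  acc
}

# Harrell C-index by explicit pair enumeration (independent of the package's).
oracle_cindex <- function(scores, time, event) {
  n <- length(scores); conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]
    if (ti == tj) {
      if (event[i] + event[j] != 1) next
      a <- if (event[i] == 1) i else j; b <- if (a == i) j else i
    } else {
      a <- if (ti < tj) i else j; b <- if (a == i) j else i
      if (event[a] != 1) next
    }
    usable <- usable + 1
    conc <- conc + (scores[a] > scores[b]) + 0.5 * (scores[a] == scores[b])
  }
  conc / usable
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2)); sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_comb - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Random labeled expression with no planted structure (exchangeable genes).
random_labeled_matrix <- function(n_genes, n_tumor, n_normal, seed) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * (n_tumor + n_normal)), n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_tumor + n_normal))))
  })
  labeled_expression(v, rep(c("tumor", "normal"), c(n_tumor, n_normal)))
}

pair_key <- function(df) paste(df$gene_i, df$gene_j, sep = "|")
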