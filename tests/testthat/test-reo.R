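test_that("order probabilities count strict inequalities and ignore ties", {
  expect_equal(order_probability(c(3, 1, 2), c(1, 2, 0)),
               c(p_gt = 2 / 3, p_lt = 1 / 3))
  expect_equal(order_probability(c(5, 5, 1), c(5, 2, 3)),
               c(p_gt = 1 / 3, p_lt = 1 / 3))
  x <- c(1.5, 2.5, 9)
  expect_equal(order_probability(x, x), c(p_gt = 0, p_lt = 0))
  expect_error(order_probability(1:3, 1:2), "different samples")
  expect_error(order_probability(numeric(), numeric()), "at least one")
})

test_that("order probability is anti-symmetric", {
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- sample(1:6, 12, replace = TRUE); y <- sample(1:6, 12, replace = TRUE)
      p <- order_probability(x, y); q <- order_probability(y, x)
      expect_identical(unname(p), unname(rev(q)))
    }
  })
})

test_that("stable-pair mining applies a strict threshold", {
  # gene A > gene B in 95 of 100 tumor samples -> stable; 90/100 -> not
  two_class <- function(v) {
    m <- cbind(v, v)
    colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
    labeled_expression(m, rep(c("tumor", "normal"), each = ncol(v)))
  }
  v95 <- rbind(A = c(rep(2, 95), rep(0, 5)), B = rep(1, 100))
  colnames(v95) <- sprintf("s%03d", 1:100)
  st <- find_stable_pairs(two_class(v95), "tumor")
  expect_equal(nrow(st), 1L)
  expect_equal(st$direction, "gt")
  expect_equal(st$p_gt, 0.95)

  v90 <- rbind(A = c(rep(2, 90), rep(0, 10)), B = rep(1, 100))
  colnames(v90) <- sprintf("s%03d", 1:100)
  expect_equal(nrow(find_stable_pairs(two_class(v90), "tumor")), 0L)

  # identical columns give no stable pair
  vid <- rbind(A = rep(1, 10), B = rep(1, 10)); colnames(vid) <- sprintf("s%d", 1:10)
  expect_equal(nrow(find_stable_pairs(two_class(vid), "tumor")), 0L)
})

test_that("reversal mining requires opposite directions in the two classes", {
  # A > B in 98% of tumor AND 95% of normal: stable both, same direction -> excluded
  mk <- function(p_tum, p_nor, flip_normal) {
    a_t <- c(rep(2, p_tum), rep(0, 100 - p_tum))
    a_n <- if (flip_normal) c(rep(0, p_nor), rep(2, 100 - p_nor))
           else c(rep(2, p_nor), rep(0, 100 - p_nor))
    v <- rbind(A = c(a_t, a_n), B = rep(1, 200))
    colnames(v) <- sprintf("s%03d", 1:200)
    labeled_expression(v, rep(c("tumor", "normal"), each = 100))
  }
  same_dir <- find_reversal_pairs(mk(98, 95, flip_normal = FALSE))
  expect_equal(nrow(same_dir), 0L)
  reversed <- find_reversal_pairs(mk(98, 97, flip_normal = TRUE))
  expect_equal(nrow(reversed), 1L)
  expect_equal(reversed$tumor_direction, "gt")
  expect_equal(reversed$p_gt_tumor, 0.98)
  expect_equal(reversed$p_lt_normal, 0.97)
})

test_that("reversal mining matches the brute-force oracle on random matrices", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      G <- sample(4:12, 1); nt <- sample(4:15, 1); nn <- sample(4:15, 1)
      # low-resolution integer values provoke plenty of ties
      v <- matrix(sample(1:4, G * (nt + nn), replace = TRUE), G,
                  dimnames = list(sprintf("g%03d", 1:G), sprintf("s%03d", 1:(nt + nn))))
      lab <- rep(c("tumor", "normal"), c(nt, nn))
      m <- labeled_expression(v, lab)
      thr <- sample(c(0.6, 0.75, 0.9), 1)
      got <- find_reversal_pairs(m, threshold = thr)
      want <- oracle_reversal_pairs(v, lab, thr)
      expect_setequal(pair_key(got), if (is.null(want)) character() else pair_key(want))
      got_st <- find_stable_pairs(m, "tumor", threshold = thr)
      want_st <- oracle_stable_pairs(v, lab, "tumor", thr)
      expect_setequal(pair_key(got_st), if (is.null(want_st)) character() else pair_key(want_st))
    }
  })
})

test_that("REO results are invariant to per-sample monotone transforms", {
  m <- gen_labeled_expression(synthetic_expr_config(
    n_genes = 30L, n_tumor = 20L, n_normal = 20L, n_planted_pairs = 5L, seed = 3L))
  ref_pairs <- find_reversal_pairs(m)
  ref_prof <- binarize(m, ref_pairs)
  transforms <- list(function(x) exp(x / 2), function(x) x^3, function(x) rank(x))
  for (i in seq_along(transforms)) {
    v2 <- apply(m$values, 2L, transforms[[i]])
    rownames(v2) <- rownames(m$values)
    m2 <- labeled_expression(v2, as.character(m$label))
    p2 <- find_reversal_pairs(m2)
    expect_identical(pair_key(p2), pair_key(ref_pairs))
    expect_identical(unclass(binarize(m2, p2)), unclass(ref_prof),
                     ignore_attr = TRUE)
  }
})

test_that("raising the threshold never adds pairs", {
  m <- random_labeled_matrix(12, 10, 10, seed = 21)
  prev <- Inf
  for (thr in c(0.6, 0.7, 0.8, 0.9)) {
    n <- nrow(find_reversal_pairs(m, threshold = thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("binarization follows the tie-to-zero convention and imputes missing genes", {
  v <- rbind(A = c(5, 2, 3), B = c(2, 2, 4), C = c(1, 1, 4))
  colnames(v) <- c("s1", "s2", "s3")
  pairs <- data.frame(gene_i = c("A", "A"), gene_j = c("B", "C"),
                      train_major = c(1L, 1L))
  prof <- binarize(v, pairs)
  expect_identical(unname(prof["A|B", ]), c(1L, 0L, 0L))  # gt, tie -> 0, lt -> 0
  expect_identical(unname(prof["A|C", ]), c(1L, 1L, 0L))

  # validation matrix lacking gene B: feature imputed with training majority
  v2 <- v[c("A", "C"), , drop = FALSE]
  expect_warning(prof2 <- binarize(v2, pairs), "imputed")
  expect_identical(unname(prof2["A|B", ]), c(1L, 1L, 1L))
  expect_identical(attr(prof2, "imputed"), "A|B")

  v3 <- v["C", , drop = FALSE]
  expect_error(binarize(v3, pairs), "no usable features")
})
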