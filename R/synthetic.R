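# Seeded synthetic-data generators.  Every signal the pipeline detects is
# planted here with analytically controlled strength, so each downstream
# stage has a recoverable ground truth.  All randomness is scoped with
# withr::with_seed: callers' RNG state is never touched.

#' Configuration for the two-class expression generator
#'
#' Planted reversal pairs are realized by giving gene i a class-dependent
#' mean offset over gene j.  For Gaussian noise with standard deviation
#' `noise_sd`, the difference of the two genes is N(delta, 2 * noise_sd^2),
#' so an offset `delta = sqrt(2) * noise_sd * qnorm(reversal_strength)`
#' makes the within-class order probability exactly `reversal_strength`.
#' The offset flips sign between tumor and normal, producing a reversal.
#' Non-planted genes get one baseline mean each, identical in both classes,
#' so they carry no class signal by construction.
#'
#' @param n_genes number of genes.
#' @param n_tumor,n_normal samples per class.
#' @param n_planted_pairs number of planted reversal pairs; each pair uses
#'   two genes of its own (`n_planted_pairs <= floor(n_genes / 2)`).
#' @param reversal_strength target within-class order probability for the
#'   planted pairs, in (0.9, 1] so planted pairs sit above the mining
#'   threshold.
#' @param noise_sd per-gene Gaussian noise standard deviation (log-intensity
#'   scale).
#' @param baseline_mean_range length-2 interval from which per-gene baseline
#'   means are drawn uniformly.
#' @param seed integer RNG seed for the per-sample sampling noise (the
#'   "patients"); cohorts generated with different seeds but the same
#'   `structure_seed` are independent draws from the same simulated disease.
#' @param structure_seed integer RNG seed for the gene-level structure
#'   (baseline means and which genes carry the planted pairs).  Keep it
#'   fixed across training and validation cohorts of one simulated study.
#' @return validated `synthetic_expr_config` list.
#' @export
synthetic_expr_config <- function(n_genes = 200L, n_tumor = 100L, n_normal = 100L,
                                  n_planted_pairs = 10L, reversal_strength = 0.98,
                                  noise_sd = 1, baseline_mean_range = c(4, 10),
                                  seed = 1L, structure_seed = 20240101L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_tumor = check_count(n_tumor, "n_tumor"),
    n_normal = check_count(n_normal, "n_normal"),
    n_planted_pairs = check_count(n_planted_pairs, "n_planted_pairs", min = 0L),
    reversal_strength = check_prob(reversal_strength, "reversal_strength",
                                   lo = 0.9, hi = 1, lo_open = TRUE),
    noise_sd = check_positive(noise_sd, "noise_sd"),
    baseline_mean_range = baseline_mean_range,
    seed = check_count(seed, "seed", min = -.Machine$integer.max),
    structure_seed = check_count(structure_seed, "structure_seed",
                                 min = -.Machine$integer.max))
  check_flag(length(baseline_mean_range) == 2L && is.numeric(baseline_mean_range) &&
               baseline_mean_range[1L] <= baseline_mean_range[2L],
             "configuration error: 'baseline_mean_range' must be a non-decreasing length-2 interval")
  check_flag(cfg$n_planted_pairs <= floor(cfg$n_genes / 2),
             "configuration error: 'n_planted_pairs' exceeds floor(n_genes/2)")
  new_tag(cfg, "synthetic_expr_config")
}

#' Generate a labeled two-class expression matrix with planted reversal pairs
#'
#' @param config a [synthetic_expr_config()].
#' @return A [labeled_expression()] with attribute `planted`: a data.frame
#'   (`gene_i`, `gene_j`, `tumor_direction`) of the planted pairs in
#'   canonical (lexicographic) orientation.  `tumor_direction = "gt"` means
#'   gene_i exceeds gene_j in tumor samples (and the reverse in normal).
#' @export
gen_labeled_expression <- function(config) {
  check_flag(inherits(config, "synthetic_expr_config"),
             "configuration error: 'config' must come from synthetic_expr_config()")
  G <- config$n_genes
  n <- config$n_tumor + config$n_normal
  genes <- sprintf("g%04d", seq_len(G))
  label <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  delta <- sqrt(2) * config$noise_sd * qnorm(config$reversal_strength)

  # gene-level structure is drawn from structure_seed so that independent
  # cohorts (different 'seed') share the same simulated disease
  withr::with_seed(config$structure_seed, {
    base_mean <- runif(G, config$baseline_mean_range[1L], config$baseline_mean_range[2L])
    picked <- if (config$n_planted_pairs > 0L) sample(G, 2L * config$n_planted_pairs)
              else integer()
  })
  mu <- matrix(base_mean, nrow = G, ncol = n)  # identical in both classes
  planted <- NULL
  if (config$n_planted_pairs > 0L) {
    gi <- picked[seq_len(config$n_planted_pairs)]
    gj <- picked[config$n_planted_pairs + seq_len(config$n_planted_pairs)]
    tum <- label == "tumor"
    for (p in seq_len(config$n_planted_pairs)) {
      m0 <- mean(base_mean[c(gi[p], gj[p])])
      mu[gi[p], tum] <- m0 + delta / 2; mu[gj[p], tum] <- m0 - delta / 2
      mu[gi[p], !tum] <- m0 - delta / 2; mu[gj[p], !tum] <- m0 + delta / 2
    }
    # canonical orientation: gene_i < gene_j lexicographically
    a <- genes[gi]; b <- genes[gj]
    flip <- a > b
    planted <- data.frame(
      gene_i = ifelse(flip, b, a),
      gene_j = ifelse(flip, a, b),
      tumor_direction = ifelse(flip, "lt", "gt"),
      stringsAsFactors = FALSE)
  }
  values <- mu + withr::with_seed(config$seed,
    matrix(rnorm(G * n, sd = config$noise_sd), G, n))
  dimnames(values) <- list(genes, sprintf("s%04d", seq_len(n)))
  out <- labeled_expression(values, label)
  attr(out, "planted") <- planted
  out
}

#' Configuration for the synthetic CNV-profile generator
#'
#' Emulates the output format of reference-based CNV inference from
#' single-cell expression: a genes x cells matrix of modified expression
#' centered at 1, where chromosomal gains/losses appear as contiguous gene
#' blocks shifted above/below 1.
#'
#' @param n_genes number of genes (treated as chromosome-ordered).
#' @param n_cells_per_cluster integer vector, cells in each true tumor
#'   cluster (length = number of clusters).
#' @param amplitudes non-negative aberration magnitude per cluster (0 =
#'   diploid-like); must be distinct so the cluster score ranking is
#'   well-defined.
#' @param segment_length genes per aberrant block.
#' @param noise_sd Gaussian noise standard deviation around the profile.
#' @param n_reference_cells diploid reference cells appended after the tumor
#'   cells (label `"reference"`).
#' @param seed integer RNG seed.
#' @return validated `synthetic_cnv_config` list.
#' @export
synthetic_cnv_config <- function(n_genes = 200L, n_cells_per_cluster = c(50L, 50L, 50L),
                                 amplitudes = c(0.8, 0.9, 1.0), segment_length = 40L,
                                 noise_sd = 0.02, n_reference_cells = 0L, seed = 1L) {
  check_flag(length(n_cells_per_cluster) >= 1L, "configuration error: zero clusters")
  check_flag(length(amplitudes) == length(n_cells_per_cluster),
             "configuration error: 'amplitudes' and 'n_cells_per_cluster' lengths differ")
  check_flag(all(is.finite(amplitudes) & amplitudes >= 0),
             "configuration error: 'amplitudes' must be non-negative")
  check_flag(!anyDuplicated(amplitudes),
             "configuration error: 'amplitudes' must be distinct")
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_cells_per_cluster = vapply(seq_along(n_cells_per_cluster), function(i)
      check_count(n_cells_per_cluster[i], "n_cells_per_cluster"), integer(1L)),
    amplitudes = as.numeric(amplitudes),
    segment_length = check_count(segment_length, "segment_length"),
    noise_sd = check_positive(noise_sd, "noise_sd"),
    n_reference_cells = check_count(n_reference_cells, "n_reference_cells", min = 0L),
    seed = check_count(seed, "seed", min = -.Machine$integer.max))
  check_flag(cfg$segment_length <= cfg$n_genes,
             "configuration error: 'segment_length' exceeds 'n_genes'")
  new_tag(cfg, "synthetic_cnv_config")
}

#' Generate a synthetic CNV profile matrix with planted clusters
#'
#' Each tumor cluster receives one contiguous aberrant gene block (seeded
#' random start, random gain/loss sign) of its own amplitude; cells are that
#' profile plus Gaussian noise.  Reference cells are noise around 1.
#' Cluster blocks are drawn without overlap whenever the gene axis has room
#' (rejection sampling), so the between-cluster separation is governed by
#' the configured amplitudes rather than by accidental block collisions; if
#' the segments cannot all fit disjointly, overlapping draws are kept with
#' a warning.
#'
#' @param config a [synthetic_cnv_config()].
#' @return A [cnv_matrix()] plus attribute `true_labels`: per-cell cluster
#'   IDs (`1..k` for tumor cells, `"reference"` for reference cells).
#' @export
gen_cnv_matrix <- function(config) {
  check_flag(inherits(config, "synthetic_cnv_config"),
             "configuration error: 'config' must come from synthetic_cnv_config()")
  G <- config$n_genes
  k <- length(config$n_cells_per_cluster)
  n_tum <- sum(config$n_cells_per_cluster)
  n_all <- n_tum + config$n_reference_cells
  withr::with_seed(config$seed, {
    profiles <- matrix(1, nrow = G, ncol = k)
    L <- config$segment_length
    taken <- rep(FALSE, G)
    for (c in seq_len(k)) {
      if (config$amplitudes[c] > 0) {
        start <- sample.int(G - L + 1L, 1L)
        for (try in seq_len(200L)) {   # prefer a block disjoint from earlier ones
          if (!any(taken[start:(start + L - 1L)])) break
          start <- sample.int(G - L + 1L, 1L)
        }
        idx <- start:(start + L - 1L)
        if (any(taken[idx]))
          warning("cluster CNV segments overlap: gene axis too short for disjoint blocks",
                  call. = FALSE)
        taken[idx] <- TRUE
        sign <- sample(c(-1, 1), 1L)
        profiles[idx, c] <- 1 + sign * config$amplitudes[c]
      }
    }
    cluster_of <- rep(seq_len(k), config$n_cells_per_cluster)
    vals <- profiles[, cluster_of, drop = FALSE]
    if (config$n_reference_cells > 0L)
      vals <- cbind(vals, matrix(1, G, config$n_reference_cells))
    vals <- vals + matrix(rnorm(G * n_all, sd = config$noise_sd), G, n_all)
  })
  vals <- pmax(vals, .Machine$double.eps)  # inferCNV-style values are positive
  dimnames(vals) <- list(sprintf("g%04d", seq_len(G)), sprintf("c%05d", seq_len(n_all)))
  origin <- rep(c("tumor", "reference"), c(n_tum, config$n_reference_cells))
  out <- cnv_matrix(vals, cell_origin = origin)
  attr(out, "true_labels") <- c(as.character(rep(seq_len(k), config$n_cells_per_cluster)),
                                rep("reference", config$n_reference_cells))
  out
}

#' Generate single cells with planted gene-set activity
#'
#' A fraction `frac_active` of cells has all `gene_set` genes shifted up by
#' `effect` (log-intensity scale, baseline noise sd 1); the remaining cells
#' are null.  Used to calibrate the pathway-activity scorers.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param gene_set character vector of gene IDs, must be a subset of the
#'   generated universe `g0001..g<n_genes>`.
#' @param effect non-negative mean up-shift applied to set genes in active
#'   cells.
#' @param frac_active fraction of cells that are active, in \[0, 1\].
#' @param noise_sd baseline noise standard deviation.
#' @param seed integer RNG seed.
#' @return list with `values` (genes x cells matrix) and `active` (logical
#'   per-cell label).
#' @export
gen_pathway_cells <- function(n_cells, n_genes, gene_set, effect, frac_active = 0.5,
                              noise_sd = 1, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells"); n_genes <- check_count(n_genes, "n_genes")
  check_flag(length(gene_set) > 0, "input error: empty gene_set")
  check_flag(is.numeric(effect) && effect >= 0, "configuration error: 'effect' must be >= 0")
  frac_active <- check_prob(frac_active, "frac_active")
  genes <- sprintf("g%04d", seq_len(n_genes))
  check_flag(all(gene_set %in% genes), "input error: gene_set not contained in gene universe")
  withr::with_seed(seed, {
    base_mean <- runif(n_genes, 4, 8)
    values <- matrix(rnorm(n_genes * n_cells, sd = noise_sd), n_genes, n_cells) + base_mean
    n_active <- round(frac_active * n_cells)
    active <- rep(FALSE, n_cells)
    if (n_active > 0) active[sample.int(n_cells, n_active)] <- TRUE
    values[genes %in% gene_set, active] <- values[genes %in% gene_set, active] + effect
  })
  dimnames(values) <- list(genes, sprintf("c%05d", seq_len(n_cells)))
  list(values = values, active = active)
}

#' Configuration for the survival-time generator
#'
#' Event times are exponential with per-sample rate
#' `baseline_rate * exp(sum(beta_g * z_g))` where `z_g` is the z-scored
#' expression of gene g, i.e. a proportional-hazards model with the planted
#' `betas` as log hazard ratios.  Censoring times are independent
#' exponential with rate `censor_rate` (0 disables censoring).
#'
#' @param n_samples number of samples.
#' @param betas named numeric vector, gene -> planted log-hazard coefficient.
#' @param baseline_rate baseline exponential event rate.
#' @param censor_rate exponential censoring rate (>= 0).
#' @param seed integer RNG seed.
#' @return validated `synthetic_survival_config` list.
#' @export
synthetic_survival_config <- function(n_samples = 300L, betas = c(g0001 = 0.7),
                                      baseline_rate = 0.1, censor_rate = 0.04,
                                      seed = 1L) {
  check_flag(is.numeric(betas) && !is.null(names(betas)) && all(nzchar(names(betas))),
             "configuration error: 'betas' must be a named numeric vector")
  check_flag(is.numeric(censor_rate) && censor_rate >= 0,
             "configuration error: 'censor_rate' must be >= 0")
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples"),
    betas = betas,
    baseline_rate = check_positive(baseline_rate, "baseline_rate"),
    censor_rate = as.numeric(censor_rate),
    seed = check_count(seed, "seed", min = -.Machine$integer.max))
  new_tag(cfg, "synthetic_survival_config")
}

#' Generate survival outcomes driven by expression
#'
#' @param config a [synthetic_survival_config()].
#' @param expression genes x samples numeric matrix containing every gene
#'   named in `config$betas`; `ncol` must equal `config$n_samples`.
#' @return a [survival_table()] (samples in `colnames(expression)` order).
#' @export
gen_survival <- function(config, expression) {
  check_flag(inherits(config, "synthetic_survival_config"),
             "configuration error: 'config' must come from synthetic_survival_config()")
  check_flag(is.matrix(expression) && ncol(expression) == config$n_samples,
             "input error: expression must have n_samples columns")
  missing <- setdiff(names(config$betas), rownames(expression))
  check_flag(length(missing) == 0, "input error: genes missing from expression: %s",
             paste(missing, collapse = ", "))
  X <- expression[names(config$betas), , drop = FALSE]
  Z <- t(scale(t(X)))                      # z-score each gene across samples
  Z[!is.finite(Z)] <- 0                    # constant gene -> no contribution
  lp <- drop(crossprod(Z, config$betas))
  withr::with_seed(config$seed, {
    t_event <- rexp(config$n_samples, rate = config$baseline_rate * exp(lp))
    t_cens <- if (config$censor_rate > 0) rexp(config$n_samples, rate = config$censor_rate)
              else rep(Inf, config$n_samples)
  })
  time <- pmin(t_event, t_cens)
  survival_table(colnames(expression) %||% sprintf("s%04d", seq_len(config$n_samples)),
                 time = time, event = as.integer(t_event <= t_cens))
}
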