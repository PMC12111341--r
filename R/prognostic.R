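# Survival analysis on the genes composing the reversal pairs: Cox
# proportional-hazards fits (via the survival package), median risk
# stratification, Kaplan-Meier / log-rank comparison, Harrell's concordance
# index (implemented here by pair enumeration), and gene co-expression.

#' Univariate or multivariate Cox proportional-hazards fit
#'
#' Covariates are z-scored before fitting, so coefficients are log hazard
#' ratios per standard deviation of expression.  Ties are handled by the
#' Efron approximation.  Constant genes are dropped with a warning.
#' `mode = "univariate"` fits each gene separately (risk scores and C-index
#' then refer to no joint model and are `NULL`); `mode = "multivariate"`
#' fits all genes jointly and reports per-sample risk scores (the linear
#' predictor) and the model's Harrell C-index.
#'
#' @param expression numeric genes x samples matrix (samples must match the
#'   survival table's order, checked by name when both are named).
#' @param surv a [survival_table()].
#' @param mode `"multivariate"` (default) or `"univariate"`.
#' @return object of class `cox_fit`: list with `table` (gene, coef,
#'   hazard_ratio, ci_lower, ci_upper, p_value), `mode`, `c_index`,
#'   `risk_scores` (named per-sample, multivariate only), `n_events`.
#' @export
fit_cox <- function(expression, surv, mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  check_flag(inherits(surv, "survival_table"), "input error: 'surv' must be a survival_table")
  check_flag(is.matrix(expression) && ncol(expression) == nrow(surv),
             "input error: expression samples and survival rows differ")
  if (!is.null(colnames(expression)))
    check_flag(identical(colnames(expression), surv$sample),
               "input error: sample order differs between expression and survival")
  n_events <- sum(surv$event)
  check_flag(n_events > 0, "input error: zero events in survival table")
  if (n_events < 10 && mode == "multivariate")
    warning(sprintf("only %d events; multivariate fit may be unstable", n_events),
            call. = FALSE)

  Z <- t(scale(t(expression)))
  constant <- !is.finite(rowSums(Z))
  if (any(constant)) {
    warning(sprintf("dropped constant gene(s): %s",
                    paste(rownames(expression)[constant], collapse = ", ")), call. = FALSE)
    Z <- Z[!constant, , drop = FALSE]
  }
  check_flag(nrow(Z) > 0, "input error: no usable (non-constant) genes")
  genes <- rownames(Z)
  S <- survival::Surv(surv$time, surv$event)

  fit_one <- function(X) {
    df <- data.frame(t(X), check.names = FALSE)
    survival::coxph(S ~ ., data = df, ties = "efron")
  }
  if (mode == "univariate") {
    rows <- lapply(genes, function(g) {
      fit <- fit_one(Z[g, , drop = FALSE])
      s <- summary(fit)
      data.frame(gene = g, coef = s$coefficients[1L, "coef"],
                 hazard_ratio = s$coefficients[1L, "exp(coef)"],
                 ci_lower = s$conf.int[1L, "lower .95"],
                 ci_upper = s$conf.int[1L, "upper .95"],
                 p_value = s$coefficients[1L, "Pr(>|z|)"],
                 stringsAsFactors = FALSE)
    })
    out <- list(table = do.call(rbind, rows), mode = mode, c_index = NULL,
                risk_scores = NULL, n_events = n_events)
  } else {
    fit <- fit_one(Z)
    check_flag(!is.null(fit$coefficients) && all(is.finite(fit$coefficients)),
               "non-convergence: Cox fit produced non-finite coefficients after %d iterations",
               fit$iter)
    s <- summary(fit)
    lp <- drop(predict(fit, type = "lp"))
    names(lp) <- surv$sample
    out <- list(
      table = data.frame(gene = rownames(s$coefficients),
                         coef = s$coefficients[, "coef"],
                         hazard_ratio = s$coefficients[, "exp(coef)"],
                         ci_lower = s$conf.int[, "lower .95"],
                         ci_upper = s$conf.int[, "upper .95"],
                         p_value = s$coefficients[, "Pr(>|z|)"],
                         stringsAsFactors = FALSE, row.names = NULL),
      mode = mode,
      c_index = concordance_index(lp, surv),
      risk_scores = lp,
      n_events = n_events)
  }
  new_tag(out, "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s), %d events%s\n", x$mode, x$n_events,
              if (!is.null(x$c_index)) sprintf(", C-index = %.3f", x$c_index) else ""))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Median risk stratification
#'
#' Splits samples at the median of the multivariate Cox risk score: strictly
#' above the median is `"high"`, at or below is `"low"` (ties at the median
#' go to the low-risk group, so the high group is never the larger one).
#'
#' @param fit a multivariate [fit_cox()] result (or a named numeric vector
#'   of risk scores).
#' @return named character vector of `"high"` / `"low"` per sample.
#' @export
risk_stratify <- function(fit) {
  scores <- if (inherits(fit, "cox_fit")) {
    check_flag(identical(fit$mode, "multivariate"),
               "input error: risk stratification needs a multivariate fit")
    fit$risk_scores
  } else fit
  check_flag(is.numeric(scores) && length(scores) >= 2L,
             "input error: need >= 2 risk scores")
  if (length(unique(scores)) == 1L)
    stop_input("degenerate stratification: all risk scores identical")
  grp <- ifelse(scores > median(scores), "high", "low")
  setNames(grp, names(scores))
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' Product-limit survival estimates with right censoring per group, and the
#' two-sided log-rank chi-square test with k - 1 degrees of freedom.
#'
#' @param groups per-sample group labels (>= 2 distinct, each non-empty).
#' @param surv a [survival_table()] in the same sample order.
#' @return list with `curves` (data.frame: group, time, n_risk, n_event,
#'   survival), `chisq`, `df`, `p_value`.
#' @export
km_logrank <- function(groups, surv) {
  check_flag(inherits(surv, "survival_table"), "input error: 'surv' must be a survival_table")
  check_flag(length(groups) == nrow(surv), "input error: one group per sample required")
  groups <- as.character(groups)
  tab <- table(groups)
  check_flag(length(tab) >= 2L, "input error: need >= 2 groups")
  check_flag(all(tab >= 1L), "input error: empty group")
  check_flag(sum(surv$event) > 0, "input error: no events observed; log-rank undefined")
  S <- survival::Surv(surv$time, surv$event)
  g <- factor(groups)
  sf <- survival::survfit(S ~ g)
  strata_grp <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = strata_grp, time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, survival = sf$surv,
                       stringsAsFactors = FALSE)
  sd <- survival::survdiff(S ~ g, rho = 0)
  df <- length(tab) - 1L
  list(curves = curves, chisq = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Fraction of usable subject pairs in which the higher risk score belongs
#' to the subject with the earlier event; score ties in a usable pair count
#' 0.5.  A pair is usable when the ordering of its event times is
#' determinable under right censoring: the smaller time must be an event,
#' and tied times are usable only if at least one is an event (event vs
#' censored-at-same-time) — pairs of tied event times are not comparable.
#'
#' @param scores numeric per-sample risk scores (higher = riskier).
#' @param surv a [survival_table()] in the same sample order.
#' @return C-index in \[0, 1\]; 0.5 is uninformative.
#' @export
concordance_index <- function(scores, surv) {
  check_flag(inherits(surv, "survival_table"), "input error: 'surv' must be a survival_table")
  n <- nrow(surv)
  check_flag(length(scores) == n, "input error: one score per sample required")
  time <- surv$time; event <- surv$event
  conc <- 0; tied <- 0; usable <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    # orient so a has the smaller time
    if (time[i] < time[j]) { a <- i; b <- j }
    else if (time[j] < time[i]) { a <- j; b <- i }
    else {
      if (event[i] + event[j] != 1L) next   # tied events or tied censorings: unusable
      a <- if (event[i] == 1L) i else j; b <- if (event[i] == 1L) j else i
    }
    if (event[a] != 1L) next                # earlier time censored: unusable
    usable <- usable + 1
    if (scores[a] > scores[b]) conc <- conc + 1
    else if (scores[a] == scores[b]) tied <- tied + 1
  }
  check_flag(usable > 0, "input error: zero comparable pairs; C-index undefined")
  (conc + 0.5 * tied) / usable
}

#' Gene-gene co-expression matrix
#'
#' Pairwise correlation across samples (Spearman by default, Pearson by
#' flag), symmetric with unit diagonal.  Constant genes get `NA`
#' correlations with a warning.
#'
#' @param expression numeric genes x samples matrix, >= 3 samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return genes x genes correlation matrix.
#' @export
coexpression <- function(expression, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  check_flag(is.matrix(expression) && ncol(expression) >= 3L,
             "input error: need >= 3 samples")
  constant <- apply(expression, 1L, function(v) length(unique(v)) == 1L)
  if (any(constant))
    warning(sprintf("constant gene(s) have undefined correlations: %s",
                    paste(rownames(expression)[constant], collapse = ", ")), call. = FALSE)
  cc <- suppressWarnings(cor(t(expression), method = method))
  diag(cc) <- 1
  cc[constant, ] <- NA_real_; cc[, constant] <- NA_real_
  diag(cc)[constant] <- 1
  cc
}
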