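# Evaluation and inference: AUROC machinery, class-stratified bootstrap
# CIs, paired score permutation tests, KM/logrank/Cox stratification at the
# training-median cutoff, correlations and Benjamini-Hochberg adjustment.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Class-stratified bootstrap confidence interval for the AUROC
#'
#' Resamples within each class with replacement (preserving class counts)
#' and reports the empirical 2.5/97.5 percentile interval.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return An `auroc_result`: `auroc`, `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_auroc_ci <- function(scores, labels, n_boot = 1000L, seed = 1L,
                               conf = 0.95) {
  labels <- as.numeric(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  point <- auroc(scores, labels)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- c(pos[sample.int(length(pos), replace = TRUE)],
             neg[sample.int(length(neg), replace = TRUE)])
    auroc(scores[idx], labels[idx])
  }, 0)
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  structure(list(auroc = point, ci_low = qs[1], ci_high = qs[2],
                 n_boot = as.integer(n_boot)),
            class = "auroc_result")
}

#' Paired score permutation test for an AUROC difference
#'
#' Tests whether two models scored on the same patients differ in AUROC.
#' The observed statistic is `auroc(a) - auroc(b)`; under the null of
#' exchangeable models each patient's pair of scores is swapped
#' independently with probability 1/2 to build the null distribution. The
#' p-value uses the +1 finite-resampling correction.
#'
#' @param scores_a,scores_b Paired score vectors on identical patients.
#' @param labels Binary labels.
#' @param n_perm Number of permutation replicates (default 1000).
#' @param alternative `"two.sided"`, `"greater"` (a better than b) or
#'   `"less"`.
#' @param seed Seed.
#' @return List with `p_value`, `observed`, `n_perm`, `alternative`.
#' @export
permutation_auroc_test <- function(scores_a, scores_b, labels,
                                   n_perm = 1000L,
                                   alternative = c("two.sided", "greater", "less"),
                                   seed = 1L) {
  alternative <- match.arg(alternative)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length", call. = FALSE)
  obs <- auroc(scores_a, labels) - auroc(scores_b, labels)
  set.seed(seed)
  nulls <- vapply(seq_len(n_perm), function(i) {
    sw <- stats::runif(length(labels)) < 0.5
    a <- ifelse(sw, scores_b, scores_a)
    b <- ifelse(sw, scores_a, scores_b)
    auroc(a, labels) - auroc(b, labels)
  }, 0)
  p <- switch(alternative,
              two.sided = (1 + sum(abs(nulls) >= abs(obs))) / (n_perm + 1),
              greater = (1 + sum(nulls >= obs)) / (n_perm + 1),
              less = (1 + sum(nulls <= obs)) / (n_perm + 1))
  list(p_value = p, observed = obs, n_perm = as.integer(n_perm),
       alternative = alternative)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with right censoring.
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A `km_curve`: data frame with `time`, `n_risk`, `n_event`,
#'   `surv`; evaluate with [km_surv()].
#' @export
km_curve <- function(times, events) {
  stopifnot(all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(table = data.frame(time = fit$time, n_risk = fit$n.risk,
                                    n_event = fit$n.event, surv = fit$surv)),
            class = "km_curve")
}

#' Evaluate a KM curve at given times (right-continuous step function)
#' @param km A `km_curve`.
#' @param t Times at which to evaluate the survival function.
#' @return Survival probabilities; `S(t) = 1` before the first event.
#' @export
km_surv <- function(km, t) {
  tab <- km$table[km$table$n_event > 0, , drop = FALSE]
  vapply(t, function(ti) {
    below <- tab$time <= ti
    if (!any(below)) 1 else tab$surv[max(which(below))]
  }, 0)
}

#' Two-group logrank test
#'
#' @param times Follow-up times.
#' @param events Event indicators.
#' @param groups Two-level group labels.
#' @return List with `statistic` (1-df chi-square) and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L)
    stop("logrank test requires exactly two nonempty groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariate Cox hazard ratio between two risk groups
#'
#' Cox partial-likelihood fit (Efron ties) of a high-vs-low-risk indicator.
#' `HR > 1` means the high-risk group has more events. Degenerate when at
#' most one group has events.
#'
#' @param times Follow-up times.
#' @param events Event indicators.
#' @param groups Factor or character with levels `"low"`/`"high"` (or any
#'   two levels; the second sorted level is treated as high-risk unless the
#'   levels are exactly low/high).
#' @return List with `hr`, `ci_low`, `ci_high`, `p_value`,
#'   `degenerate_flag`.
#' @export
cox_hr_binary <- function(times, events, groups) {
  g <- as.character(groups)
  lev <- sort(unique(g))
  high <- if (all(lev %in% c("low", "high"))) "high" else lev[length(lev)]
  x <- as.integer(g == high)
  ev_hi <- sum(events[x == 1]); ev_lo <- sum(events[x == 0])
  if ((ev_hi == 0) + (ev_lo == 0) >= 1L || length(lev) < 2L)
    return(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, degenerate_flag = TRUE))
  fit <- survival::coxph(survival::Surv(times, events) ~ x, ties = "efron")
  sm <- summary(fit)
  list(hr = unname(sm$conf.int[1, "exp(coef)"]),
       ci_low = unname(sm$conf.int[1, "lower .95"]),
       ci_high = unname(sm$conf.int[1, "upper .95"]),
       p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
       degenerate_flag = FALSE)
}

#' Risk stratification at the training-median cutoff
#'
#' The cutoff is the median score of the training cohort; test patients
#' with scores strictly above it form the high-risk group (ties go to
#' low-risk). Reports the Cox HR and logrank p-value of the split, with a
#' degenerate flag when a group is empty or has no events.
#'
#' @param train_scores Scores of the training cohort (defines the cutoff).
#' @param test_scores Scores of the test cohort.
#' @param test_times,test_events Test-cohort survival data aligned with
#'   `test_scores`.
#' @return A `stratification_result`: `cutoff`, `group` (low/high per
#'   patient), `hr`, `hr_ci`, `logrank_p`, `degenerate_flag`.
#' @export
stratify_by_median <- function(train_scores, test_scores, test_times,
                               test_events) {
  stopifnot(length(train_scores) >= 1L)
  cutoff <- stats::median(train_scores)
  group <- ifelse(test_scores > cutoff, "high", "low")
  degenerate <- length(unique(group)) < 2L
  hr <- list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             p_value = NA_real_, degenerate_flag = TRUE)
  lr_p <- NA_real_
  if (!degenerate) {
    hr <- cox_hr_binary(test_times, test_events, group)
    if (!hr$degenerate_flag)
      lr_p <- logrank_test(test_times, test_events, group)$p_value
  }
  structure(list(cutoff = cutoff, group = group, hr = hr$hr,
                 hr_ci = c(hr$ci_low, hr$ci_high), logrank_p = lr_p,
                 degenerate_flag = degenerate || hr$degenerate_flag),
            class = "stratification_result")
}

#' Correlate model scores with clinical variables
#'
#' Ordinal/numeric variables (age, T stage, N stage) use Spearman rho;
#' binary variables (sex, chemo, an HPV-positive indicator) use the
#' point-biserial correlation (Pearson with a binary variable). Constant
#' variables are flagged with an `NA` coefficient.
#'
#' @param scores Numeric model scores.
#' @param clinical_matrix Data frame or matrix of clinical variables
#'   aligned with `scores`.
#' @return Data frame with `variable`, `method`, `estimate`, `p_value`.
#' @export
correlate_scores_clinical <- function(scores, clinical_matrix) {
  cm <- as.data.frame(clinical_matrix)
  rows <- lapply(names(cm), function(v) {
    x <- as.numeric(cm[[v]])
    ok <- !is.na(x) & !is.na(scores)
    if (length(unique(x[ok])) < 2L)
      return(data.frame(variable = v, method = NA_character_,
                        estimate = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    binary <- length(unique(x[ok])) == 2L
    ct <- if (binary)
      stats::cor.test(scores[ok], x[ok], method = "pearson")
    else
      suppressWarnings(stats::cor.test(scores[ok], x[ok],
                                       method = "spearman", exact = FALSE))
    data.frame(variable = v,
               method = if (binary) "point-biserial" else "spearman",
               estimate = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @return Step-up adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}
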