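#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive
#' scores above a random negative, with score ties counting one half.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("undefined metric: only one class present")
  invisible(TRUE)
}

#' Area under the precision-recall curve
#'
#' Step interpolation (average precision): thresholds sweep the sorted
#' scores; each increase in recall contributes that step times the precision
#' reached there. A random scorer's AUPRC equals the prevalence.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate only at the last index of each tied score block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Select a decision threshold on the validation split
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' validation scores plus 0 and 1. `"youden_max"` maximizes
#' J = sensitivity + specificity - 1; `"f1_max"` maximizes the F1 score;
#' `"fixed"` returns 0.5. Ties go to the smallest candidate.
#'
#' @param scores Validation scores.
#' @param labels Validation 0/1 labels.
#' @param policy One of `"fixed"`, `"youden_max"`, `"f1_max"`.
#' @return A `threshold_policy`: list with `mode`, `threshold`, and the
#'   criterion value achieved on the validation split.
#' @export
select_threshold <- function(scores, labels,
                             policy = c("fixed", "youden_max", "f1_max")) {
  policy <- match.arg(policy)
  if (policy == "fixed")
    return(structure(list(mode = policy, threshold = 0.5, value = NA_real_),
                     class = "threshold_policy"))
  check_two_classes(labels)
  u <- sort(unique(scores))
  cand <- unique(c(0, (u[-1] + u[-length(u)]) / 2, 1))
  crit <- vapply(cand, function(th) {
    cm <- confusion_at(scores, labels, th)
    if (policy == "youden_max") cm$sensitivity + cm$specificity - 1 else cm$f1
  }, numeric(1))
  best <- which.max(crit)  # which.max returns the first (smallest) maximizer
  structure(list(mode = policy, threshold = cand[best], value = crit[best]),
            class = "threshold_policy")
}

#' Confusion matrix and threshold-dependent metrics
#'
#' Predicts positive iff `score >= threshold`. Precision and F1 are 0 when
#' nothing is predicted positive; the G-mean is
#' `sqrt(sensitivity * specificity)`.
#'
#' @param scores Risk scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold in `[0, 1]`.
#' @return List with `tp`, `fp`, `fn`, `tn`, `sensitivity` (= recall),
#'   `specificity`, `precision`, `f1`, `g_mean`, `youden`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = sens, specificity = spec, precision = prec,
       f1 = f1, g_mean = sqrt(sens * spec), youden = sens + spec - 1)
}

#' Harrell's concordance index
#'
#' Standard definition: pairs (i, j) with `time_i < time_j` and an observed
#' event for i are comparable (as is j censored exactly at `time_i`; two
#' events at the same time are not); the pair is concordant if
#' `score_i > score_j`, score ties count one half, and pairs censored before
#' the earlier event are excluded.
#'
#' @param scores Risk scores (higher = earlier event expected).
#' @param times Follow-up times in days from the first AF event.
#' @param events 1 = event observed, 0 = censored.
#' @return c-index in `[0, 1]`.
#' @export
harrell_c <- function(scores, times, events) {
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  fit <- survival::concordance(survival::Surv(times, events) ~ scores,
                               reverse = TRUE)
  counts <- fit$count
  if (counts[["concordant"]] + counts[["discordant"]] +
      counts[["tied.x"]] == 0)
    stop("undefined metric: no comparable pairs")
  as.numeric(fit$concordance)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples patients with replacement `B` times (default 1,000, the study
#' protocol) and takes the 2.5/97.5 percentiles of the metric. Resamples on
#' which the metric is undefined (e.g. a single class) are skipped and
#' counted; more than 50% degenerate resamples is an error.
#'
#' @param metric Function of `(idx)` -> scalar, evaluated on resampled row
#'   indices, or one of the built-ins via [evaluate_model()].
#' @param n Number of patients being resampled.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Seed for the resampling.
#' @return List with `lower`, `upper`, `replicates` (number used),
#'   `degenerate` (number skipped).
#' @export
bootstrap_ci <- function(metric, n, B = 1000L, seed = 1L) {
  stopifnot(B >= 1)
  vals <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(metric(idx), error = function(e) NA_real_)
    }, numeric(1))
  })
  bad <- sum(is.na(vals))
  if (bad > B / 2)
    stop("more than half of the bootstrap resamples were degenerate")
  qs <- quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], replicates = B - bad, degenerate = bad)
}

#' Kaplan-Meier curves by risk group
#'
#' Product-limit estimate per group (via the survival package), returned as
#' a tidy table.
#'
#' @param times Follow-up times (days).
#' @param events Event indicators (1 = stroke observed).
#' @param groups Group labels (e.g. `"high"`/`"low"` risk).
#' @return A `survival_result`: list with `curve` (data.frame: group, time,
#'   survival, at_risk, events) and the `survfit` object.
#' @export
km_curve <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  if (sum(events) < 1) stop("need at least one observed event")
  if (any(table(groups) == 0)) stop("a group has zero subjects")
  g <- factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ g)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(g)[1], length(sm$time))
         else sub("^g=", "", as.character(sm$strata))
  curve <- data.frame(group = grp, time = sm$time, survival = sm$surv,
                      at_risk = sm$n.risk, events = sm$n.event)
  structure(list(curve = curve, fit = fit), class = "survival_result")
}

#' Two-group log-rank test
#'
#' @param times Follow-up times.
#' @param events Event indicators.
#' @param groups Exactly two groups.
#' @return List with `chi2` (1 df) and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("log-rank test requires exactly 2 groups")
  if (any(table(g) == 0)) stop("a group has zero subjects")
  fit <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi2 <- as.numeric(fit$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Decision curve analysis
#'
#' Net benefit `NB(p_t) = TP/n - (FP/n) * p_t / (1 - p_t)` of treating
#' patients with `score >= p_t`, against treat-all and treat-none references.
#' Grid points at or above 1 are dropped.
#'
#' @param scores Risk scores.
#' @param labels 0/1 labels.
#' @param grid Threshold probabilities in (0, 1).
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(scores, labels, grid = seq(0.01, 0.5, by = 0.01)) {
  grid <- grid[grid > 0 & grid < 1]
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(grid, function(pt) {
    cm <- confusion_at(scores, labels, pt)
    cm$tp / n - cm$fp / n * pt / (1 - pt)
  }, numeric(1))
  ta <- prev - (1 - prev) * grid / (1 - grid)
  data.frame(threshold = grid, net_benefit = nb, treat_all = ta,
             treat_none = 0)
}

#' Full evaluation report for a scored test set
#'
#' Point estimates and percentile-bootstrap 95% CIs for AUROC, AUPRC,
#' Youden index and F1 (at the validation-selected threshold), recall,
#' precision, G-mean, and Harrell's c when survival data are supplied.
#'
#' @param scores Test-set risk scores.
#' @param labels Test-set 0/1 labels.
#' @param threshold Decision threshold (from [select_threshold()] on the
#'   validation split).
#' @param times,events Optional survival data for the c-index.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @return An `eval_report` data.frame: metric, estimate, lower, upper,
#'   replicates.
#' @export
evaluate_model <- function(scores, labels, threshold = 0.5,
                           times = NULL, events = NULL,
                           B = 1000L, seed = 1L) {
  metrics <- list(
    auroc = function(i) roc_auc(scores[i], labels[i]),
    auprc = function(i) pr_auc(scores[i], labels[i]),
    youden = function(i) confusion_at(scores[i], labels[i], threshold)$youden,
    f1 = function(i) confusion_at(scores[i], labels[i], threshold)$f1,
    recall = function(i) confusion_at(scores[i], labels[i], threshold)$sensitivity,
    precision = function(i) confusion_at(scores[i], labels[i], threshold)$precision,
    g_mean = function(i) confusion_at(scores[i], labels[i], threshold)$g_mean)
  if (!is.null(times))
    metrics$harrell_c <- function(i) harrell_c(scores[i], times[i], events[i])
  n <- length(scores)
  rows <- lapply(seq_along(metrics), function(mi) {
    f <- metrics[[mi]]
    ci <- bootstrap_ci(f, n, B = B, seed = seed + mi)
    data.frame(metric = names(metrics)[mi], estimate = f(seq_len(n)),
               lower = ci$lower, upper = ci$upper, replicates = ci$replicates)
  })
  structure(do.call(rbind, rows), class = c("eval_report", "data.frame"))
}
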