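#' Confusion matrix and classification metrics
#'
#' Standard binary-classification metrics from paired labels and
#' predictions: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' positive predictive value `TP/(TP+FP)`, negative predictive value
#' `TN/(TN+FN)` and accuracy `(TP+TN)/n`. A metric whose denominator is
#' zero is reported as `NA` (undefined), never silently 0; the
#' `undefined` field lists which.
#'
#' @param labels true binary labels (0/1).
#' @param predictions predicted binary labels (0/1).
#' @return An object of class `metrics_report`: list with `tp`, `fp`,
#'   `tn`, `fn`, `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `undefined`.
#' @export
confusion_and_metrics <- function(labels, predictions) {
  stopifnot(length(labels) == length(predictions))
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1))
    stop("labels and predictions must be binary (0/1)")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fn <- sum(labels == 1 & predictions == 0)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(tp = tp, fp = fp, tn = tn, fn = fn,
            accuracy = rate(tp + tn, tp + fp + tn + fn),
            sensitivity = rate(tp, tp + fn),
            specificity = rate(tn, tn + fp),
            ppv = rate(tp, tp + fp),
            npv = rate(tn, tn + fn))
  m$undefined <- names(which(vapply(
    m[c("accuracy", "sensitivity", "specificity", "ppv", "npv")],
    is.na, logical(1))))
  structure(m, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
    cat(sprintf("%-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.3f", x[[nm]])))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps the decision threshold over the unique scores to build the ROC
#' curve and computes the AUC by the rank (Mann-Whitney) statistic, so
#' tied scores contribute 1/2 per tied positive-negative pair — the
#' midpoint convention under which trapezoidal integration of the ROC
#' curve and the pairwise concordance probability coincide.
#'
#' @param labels true binary labels (0/1); both classes must be present.
#' @param scores numeric scores (larger = more positive).
#' @return A list with `roc` (data frame of `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)                       # midpoint ranks for ties
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(th, function(t) {
    c(fpr = sum(labels == 0 & scores >= t) / nn,
      tpr = sum(labels == 1 & scores >= t) / np)
  }, numeric(2))
  roc <- data.frame(threshold = c(Inf, th),
                    fpr = c(0, pts["fpr", ]), tpr = c(0, pts["tpr", ]))
  list(roc = roc, auc = auc)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function, optionally per
#' group, with right censoring respected. The curve starts at 1 and is
#' non-increasing.
#'
#' @param time follow-up times in months (non-negative).
#' @param event event indicator (1 = progressed, 0 = censored).
#' @param group optional group labels.
#' @return data frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time < 0)) stop("negative times")
  if (length(time) < 1) stop("need at least 1 subject")
  event <- as.integer(event)
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = factor(group)))
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(factor(group)), length(s$time))
    else sub("^g=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv)
}

#' Log-rank comparison of survival between groups
#'
#' Standard log-rank test (observed versus expected events under the
#' pooled risk set), with the asymptotic chi-square p-value on
#' `n_groups - 1` degrees of freedom. Symmetric in the group labels;
#' identical event patterns give a statistic of 0.
#'
#' @inheritParams km_estimate
#' @param group group labels (at least 2 groups, at least 1 event).
#' @return A list with `chi_square`, `df`, `p`.
#' @export
logrank <- function(time, event, group) {
  if (any(time < 0)) stop("negative times")
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (sum(event) < 1) stop("need at least 1 event")
  fit <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ g,
                            data = data.frame(time = time, event = event,
                                              g = group))
  df <- nlevels(group) - 1
  list(chi_square = fit$chisq, df = df,
       p = pchisq(fit$chisq, df, lower.tail = FALSE))
}
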