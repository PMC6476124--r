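#' Decision rule on a predicted risk curve
#'
#' The rule mirrors clinical at-risk flagging on the 95% band of the
#' individual failure-probability curve: a subject is flagged
#' `predicted_failure` when the upper band exceeds `failure_threshold` at any
#' time up to the horizon; `predicted_survival` when the median stays below
#' `safe_prob_threshold` and the upper band stays below `failure_threshold`
#' throughout. The two printed conditions do not partition the outcome space,
#' so the gap is reported explicitly as `indeterminate`; `mode = "binary"`
#' collapses the rule to failure iff the upper band ever exceeds
#' `failure_threshold`.
#'
#' @param failure_threshold Upper-band threshold flagging failure (default 0.5).
#' @param safe_prob_threshold Median threshold for predicted survival
#'   (default 0.3).
#' @param horizon Evaluation horizon in years (default 10).
#' @return A `decision_rule` list.
#' @export
decision_rule <- function(failure_threshold = 0.5, safe_prob_threshold = 0.3,
                          horizon = 10) {
  stopifnot(0 < safe_prob_threshold, safe_prob_threshold < failure_threshold,
            failure_threshold < 1)
  structure(list(failure_threshold = failure_threshold,
                 safe_prob_threshold = safe_prob_threshold,
                 horizon = horizon), class = "decision_rule")
}

#' @rdname decision_rule
#' @param curve A `risk_curve` (needs `median` and `upper95` spanning the
#'   horizon; falls back to the plug-in curve when no band is available).
#' @param rule A `decision_rule`.
#' @param mode `"three_level"` (default) or `"binary"`.
#' @return `classify_curve()`: one of `"predicted_failure"`,
#'   `"predicted_survival"`, `"indeterminate"`.
#' @export
classify_curve <- function(curve, rule = decision_rule(),
                           mode = c("three_level", "binary")) {
  mode <- match.arg(mode)
  w <- curve$time <= rule$horizon + 1e-9
  if (!any(w)) stop("curve does not reach the evaluation horizon", call. = FALSE)
  upper <- curve$upper95[w]
  med <- curve$median[w]
  if (all(is.na(upper))) upper <- curve$point[w]
  if (all(is.na(med))) med <- curve$point[w]
  fail <- any(upper > rule$failure_threshold)
  if (mode == "binary") {
    return(if (fail) "predicted_failure" else "predicted_survival")
  }
  if (fail) return("predicted_failure")
  if (all(med < rule$safe_prob_threshold)) return("predicted_survival")
  "indeterminate"
}

#' Confusion metrics as percentages
#'
#' @param tp,fn,tn,fp Nonnegative integer counts (`tp + fn > 0`,
#'   `tn + fp > 0`).
#' @return Tibble with `sensitivity`, `specificity`, `accuracy` (percent).
#' @export
#' @examples
#' confusion_metrics(28, 8, 23, 1)
confusion_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn > 0, tn + fp > 0)
  tibble::tibble(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp)
  )
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times Positive event/censoring times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Tibble with one row per distinct event time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0))
  ord <- order(times)
  t_sorted <- times[ord]
  e_sorted <- as.numeric(events[ord])
  ut <- unique(t_sorted)
  n <- length(t_sorted)
  n_risk <- n - findInterval(ut, t_sorted, left.open = TRUE)
  n_event <- as.numeric(rowsum(e_sorted, t_sorted))
  n_censor <- as.numeric(rowsum(1 - e_sorted, t_sorted))
  surv <- cumprod(1 - n_event / n_risk)
  tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                 n_censor = n_censor, surv = surv)
}

#' K-group log-rank test
#'
#' Standard observed-minus-expected statistic with the hypergeometric
#' variance, chi-square with K-1 degrees of freedom.
#'
#' @param times,events As in [kaplan_meier()].
#' @param group Group labels (>= 2 distinct values).
#' @return List with `chisq`, `df`, `p.value`, and the per-group
#'   observed/expected table.
#' @export
log_rank <- function(times, events, group) {
  group <- as.factor(group)
  K <- nlevels(group)
  stopifnot(K >= 2, sum(events) >= 1)
  ut <- sort(unique(times[events == 1]))
  O <- E <- stats::setNames(numeric(K), levels(group))
  V <- matrix(0, K, K)
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(events == 1 & times == t)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g), 0)
    dg <- vapply(levels(group), function(g) sum(events == 1 & times == t & group == g), 0)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      V <- V + d * (n - d) / (n - 1) * (diag(ng, K) * n - outer(ng, ng)) / n^2
    }
  }
  z <- (O - E)[-K]
  Vk <- V[-K, -K, drop = FALSE]
  chisq <- tryCatch(as.numeric(t(z) %*% solve(Vk, z)), error = function(e) 0)
  df <- K - 1
  list(chisq = chisq, df = df, p.value = stats::pchisq(chisq, df, lower.tail = FALSE),
       table = tibble::tibble(group = levels(group), observed = as.numeric(O),
                              expected = as.numeric(E)))
}

#' Evaluate the decision rule on an external cohort
#'
#' Computes each subject's risk curve with its confidence band, applies the
#' decision rule, and tabulates confusion metrics against the observed
#' outcome (graft failure by the horizon), separately for dnDSA-negative and
#' dnDSA-positive subjects when `split_by_dndsa = TRUE`. Indeterminate
#' classifications count against accuracy and are reported in their own
#' column. An empty subgroup yields an all-`NA` metrics row rather than an
#' error.
#'
#' @param fit A `graft_jlcm`.
#' @param cohort External `graft_cohort` (disjoint from training).
#' @param rule A [decision_rule()].
#' @param landmark Prediction landmark in years.
#' @param n_draws,seed Confidence-band settings per subject.
#' @param split_by_dndsa Report dnDSA subgroups separately.
#' @param mode Classification mode, see [classify_curve()].
#' @return List with `per_subject` (id, subgroup, observed, predicted) and
#'   `metrics` (per subgroup: counts, sensitivity, specificity, accuracy,
#'   indeterminate count).
#' @export
evaluate_external <- function(fit, cohort, rule = decision_rule(), landmark = 1,
                              n_draws = 300, seed = 1L, split_by_dndsa = TRUE,
                              mode = c("three_level", "binary")) {
  mode <- match.arg(mode)
  s <- cohort$subjects
  preds <- vapply(seq_len(nrow(s)), function(i) {
    cur <- predict_risk(fit, s$subject_id[i], cohort, landmark = landmark,
                        horizon = rule$horizon, n_draws = n_draws,
                        seed = seed + i - 1L)
    classify_curve(cur, rule, mode)
  }, "")
  observed <- ifelse(s$event == 1 & s$event_time <= rule$horizon, "failure", "no_failure")
  subgroup <- if (split_by_dndsa) ifelse(s$dndsa == 1, "dndsa_pos", "dndsa_neg") else "all"
  per_subject <- tibble::tibble(subject_id = s$subject_id, subgroup = subgroup,
                                observed = observed, predicted = preds)
  groups <- if (split_by_dndsa) c("dndsa_neg", "dndsa_pos") else "all"
  metrics <- dplyr::bind_rows(lapply(groups, function(g) {
    d <- per_subject[per_subject$subgroup == g, ]
    n <- nrow(d)
    if (n == 0 || !any(d$observed == "failure") || !any(d$observed == "no_failure")) {
      return(tibble::tibble(subgroup = g, n = n, tp = NA_integer_, fn = NA_integer_,
                            tn = NA_integer_, fp = NA_integer_,
                            indeterminate = sum(d$predicted == "indeterminate"),
                            sensitivity = NA_real_, specificity = NA_real_,
                            accuracy = NA_real_))
    }
    tp <- sum(d$observed == "failure" & d$predicted == "predicted_failure")
    fn <- sum(d$observed == "failure" & d$predicted != "predicted_failure")
    tn <- sum(d$observed == "no_failure" & d$predicted == "predicted_survival")
    fp <- sum(d$observed == "no_failure" & d$predicted == "predicted_failure")
    ind <- sum(d$predicted == "indeterminate")
    cm <- confusion_metrics(tp, fn, tn, fp)
    # indeterminates reduce accuracy: correct calls over all subjects
    cm$accuracy <- 100 * (tp + tn) / n
    tibble::tibble(subgroup = g, n = n, tp = tp, fn = fn, tn = tn, fp = fp,
                   indeterminate = ind, sensitivity = cm$sensitivity,
                   specificity = cm$specificity, accuracy = cm$accuracy)
  }))
  list(per_subject = per_subject, metrics = metrics)
}
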