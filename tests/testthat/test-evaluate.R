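make_curve <- function(time, median, upper, lower = pmax(median - 0.05, 0), point = median) {
  structure(tibble::tibble(time = time, point = point, median = median,
                           lower95 = lower, upper95 = upper),
            class = c("risk_curve", class(tibble::tibble())),
            landmark = min(time), n_draws = 100L, seed = 1L, subject_id = "X")
}

test_that("the decision rule reproduces its three printed cases", {
  rule <- decision_rule()
  tt <- seq(1, 10, by = 0.5)
  expect_equal(classify_curve(make_curve(tt, rep(0.05, length(tt)), rep(0.10, length(tt))), rule),
               "predicted_survival")
  up <- rep(0.2, length(tt)); up[tt >= 8] <- 0.6
  expect_equal(classify_curve(make_curve(tt, rep(0.2, length(tt)), up), rule),
               "predicted_failure")
  # the two printed conditions leave a gap: median 0.4, upper 0.45
  expect_equal(classify_curve(make_curve(tt, rep(0.4, length(tt)), rep(0.45, length(tt))), rule),
               "indeterminate")
  # binary reproduction mode collapses the gap
  expect_equal(classify_curve(make_curve(tt, rep(0.4, length(tt)), rep(0.45, length(tt))),
                              rule, mode = "binary"),
               "predicted_survival")
  expect_error(decision_rule(failure_threshold = 0.2, safe_prob_threshold = 0.3))
})

test_that("raising the whole band never downgrades a failure call", {
  rule <- decision_rule()
  tt <- seq(1, 10, by = 1)
  set.seed(5)
  ranks <- c(predicted_survival = 1, indeterminate = 2, predicted_failure = 3)
  for (k in 1:30) {
    med <- sort(runif(length(tt), 0, 0.6))
    up <- pmin(med + runif(1, 0.02, 0.3), 1)
    shift <- runif(1, 0, 0.3)
    c_lo <- classify_curve(make_curve(tt, med, up), rule)
    c_hi <- classify_curve(make_curve(tt, pmin(med + shift, 1), pmin(up + shift, 1)), rule)
    expect_gte(ranks[[c_hi]], ranks[[c_lo]])
  }
})

test_that("confusion metrics match the printed validation arithmetic", {
  m <- confusion_metrics(28, 8, 23, 1)
  expect_equal(m$sensitivity, 100 * 28 / 36)
  expect_gte(m$sensitivity, 77.7)
  expect_lte(m$sensitivity, 77.8)
  expect_equal(round(m$specificity, 1), 95.8)
  expect_equal(m$accuracy, 85)
  expect_equal(unlist(confusion_metrics(1, 0, 1, 0)), c(sensitivity = 100, specificity = 100, accuracy = 100))
  expect_equal(unlist(confusion_metrics(0, 1, 0, 1)), c(sensitivity = 0, specificity = 0, accuracy = 0))
  # swapping (tp<->tn, fn<->fp) swaps sensitivity and specificity
  a <- confusion_metrics(12, 5, 30, 2)
  b <- confusion_metrics(30, 2, 12, 5)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$accuracy, b$accuracy)
  expect_error(confusion_metrics(0, 0, 3, 1))
})

test_that("Kaplan-Meier matches the hand product-limit and the reference", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 1 / 3), tolerance = 1e-15)
  expect_equal(kaplan_meier(c(2, 4, 7), c(0, 0, 0))$surv, rep(1, 3))
  library(survival)
  set.seed(8)
  for (k in 1:200) {
    n <- sample(5:60, 1)
    tt <- round(rexp(n, 0.2), sample(c(0, 1, 3), 1)) + 0.01
    ev <- rbinom(n, 1, 0.6)
    km <- kaplan_meier(tt, ev)
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    expect_lt(max(abs(km$surv - sf$surv[match(km$time, sf$time)])), 1e-12)
  }
})

test_that("log-rank matches the hand calculation and the reference", {
  # two identical groups: no evidence
  lr0 <- log_rank(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1), c(1, 1, 1, 2, 2, 2))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p.value, 1)
  # hand-worked six-subject example (O-E and hypergeometric variance by hand):
  # A: (1,e)(3,c)(5,e); B: (2,e)(4,e)(6,c)
  # t=1: E_A=3/6, v=5/5*9/36;  t=2: E_A=2/5, v=6/25
  # t=4: E_A=1/3, v=2/9;       t=5: E_A=1/2, v=1/4
  lr <- log_rank(c(1, 3, 5, 2, 4, 6), c(1, 0, 1, 1, 1, 0), rep(c("A", "B"), each = 3))
  OA <- 2; EA <- 0.5 + 0.4 + 1 / 3 + 0.5
  V <- 0.25 + 6 / 25 + 2 / 9 + 0.25
  expect_equal(lr$chisq, (OA - EA)^2 / V, tolerance = 1e-12)
  expect_equal(lr$df, 1)
  expect_equal(lr$table$observed[lr$table$group == "A"], 2)
  # reference implementation across random two- and three-group datasets
  library(survival)
  set.seed(12)
  for (k in 1:100) {
    n <- sample(20:80, 1)
    ng <- sample(2:3, 1)
    tt <- round(rexp(n, 0.3), 1) + 0.05
    ev <- rbinom(n, 1, 0.7)
    gr <- sample(seq_len(ng), n, replace = TRUE)
    if (length(unique(gr)) < ng || sum(ev) == 0) next
    lr <- log_rank(tt, ev, gr)
    sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ gr)
    expect_equal(lr$chisq, sd_$chisq, tolerance = 1e-8)
  }
})

test_that("external evaluation splits by dnDSA and tolerates empty subgroups", {
  f <- small_fit()
  v <- generate_validation_split(small_sim_config(30), n_no_dndsa = 24, n_dndsa = 6, seed = 77)
  ev <- evaluate_external(f, v$cohort, decision_rule(), n_draws = 0, mode = "binary")
  expect_equal(nrow(ev$per_subject), n_subjects(v$cohort))
  expect_equal(sum(ev$metrics$n), n_subjects(v$cohort))
  expect_setequal(ev$metrics$subgroup, c("dndsa_neg", "dndsa_pos"))
  expect_equal(ev$metrics$n[ev$metrics$subgroup == "dndsa_pos"],
               sum(v$cohort$subjects$dndsa == 1))
  # all-dnDSA-negative cohort: positive subgroup flagged absent, no crash
  v0 <- generate_validation_split(small_sim_config(20), n_no_dndsa = 20, n_dndsa = 0, seed = 78)
  ev0 <- evaluate_external(f, v0$cohort, decision_rule(), n_draws = 0, mode = "binary")
  expect_true(is.na(ev0$metrics$sensitivity[ev0$metrics$subgroup == "dndsa_pos"]))
})

test_that("a cleanly separated cohort is classified perfectly", {
  f <- small_fit()
  # construct subjects pinned to each class with extreme survival contrast
  fx <- f
  fx$params$B <- diag(1e-4, 2)
  fx$params$zeta <- rbind(c(0.001, 1.5), c(0.5, 2.5))
  fx$vcov_ok <- FALSE
  p <- fx$params
  tv <- c(0.1, 0.25, 0.5, 0.75, 1)
  mk <- function(id, g, event, event_time, dndsa = 0L) {
    list(
      subject = tibble::tibble(
        subject_id = id, donor_age_ge60 = 0L, ndsa_pre = 0L, proteinuria_m12 = 0.05,
        prot_gt_0275 = 0L, acute_rejection = 0L, ar_time = NA_real_, dndsa = dndsa,
        dndsa_time = if (dndsa == 1) 0.5 else NA_real_, entry_time = 0,
        event_time = event_time, event = event, dndsa_x_ar = 0L),
      meas = tibble::tibble(subject_id = id, time_years = tv,
                            scr_umol_l = link_inverse(class_mean_trajectory(p$beta[g, ], tv), p$link))
    )
  }
  rows <- c(lapply(1:6, function(i) mk(paste0("good", i), 1, 0L, 10)),
            lapply(1:6, function(i) mk(paste0("bad", i), 2, 1L, 4)))
  co <- graft_cohort(dplyr::bind_rows(lapply(rows, `[[`, "subject")),
                     dplyr::bind_rows(lapply(rows, `[[`, "meas")))
  ev <- suppressWarnings(
    evaluate_external(fx, co, decision_rule(), n_draws = 0, mode = "binary"))
  m <- ev$metrics[ev$metrics$subgroup == "dndsa_neg", ]
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$accuracy, 100)
})
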