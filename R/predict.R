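# hazard covariate vector for one subject as known at time s:
# dnDSA and acute rejection only count once their onset has occurred
hazard_x_at <- function(profile, hazard_covariates, s = Inf) {
  p <- as.list(profile)
  dndsa <- as.integer(p$dndsa == 1 && (is.na(p$dndsa_time) || p$dndsa_time <= s))
  ar <- as.integer(p$acute_rejection == 1 && (is.na(p$ar_time) || p$ar_time <= s))
  vals <- list(
    ndsa_pre = p$ndsa_pre, prot_gt_0275 = p$prot_gt_0275,
    dndsa = dndsa, acute_rejection = ar, dndsa_x_ar = dndsa * ar
  )
  vapply(hazard_covariates, function(v) {
    as.numeric(if (v %in% names(vals)) vals[[v]] else p[[v]])
  }, 0)
}

#' Posterior class probabilities at a landmark time
#'
#' Conditions on the creatinine history observed up to the landmark `s`, the
#' membership covariates, and survival (event-free) up to `s`:
#' `post_g(s) ~ pi_g(x_c) f(Y(<=s) | g) S_g(s | x_s)`. With no measurement at
#' or before `s` the trajectory term is dropped with a warning.
#'
#' @param fit A `graft_jlcm`.
#' @param measurements Subject's measurement tibble (`time_years`,
#'   `scr_umol_l`); rows after `s` are ignored.
#' @param profile One-row subject tibble (covariates as in the cohort).
#' @param s Landmark time in years.
#' @param params Optional parameter list overriding `fit$params` (used for
#'   uncertainty draws).
#' @return Probability vector over classes.
#' @export
posterior_class_at_landmark <- function(fit, measurements, profile, s,
                                        params = fit$params) {
  G <- params$G
  x_c <- vapply(fit$membership_covariates, function(v) as.numeric(profile[[v]]), 0)
  x_s <- hazard_x_at(profile, fit$hazard_covariates, s)
  meas <- measurements[measurements$time_years <= s, , drop = FALSE]
  entry <- min(as.numeric(profile$entry_time %||% 0), s)
  lg <- log(membership_probs(params$xi, x_c, G))
  for (g in seq_len(G)) {
    surv <- -weibull_cumhaz(s, params$zeta[g, ]) * exp(sum(x_s * params$delta))
    if (entry > 0) surv <- surv + weibull_cumhaz(entry, params$zeta[g, ]) * exp(sum(x_s * params$delta))
    lg[g] <- lg[g] + surv
    if (nrow(meas)) {
      lg[g] <- lg[g] + longitudinal_loglik_given_class(
        meas, params$beta[g, ], params$wg[g] * params$B, params$sigma, params$link)
    }
  }
  if (!nrow(meas)) {
    warning("no measurements at or before the landmark; using covariate-only membership")
  }
  p <- exp(lg - logsumexp(lg))
  p / sum(p)
}

# plug-in conditional failure probability over a grid, given class posterior
failure_curve_point <- function(params, post, x_s, s, grid) {
  elp <- exp(sum(x_s * params$delta))
  sapply(grid, function(t) {
    cond_fail <- vapply(seq_len(params$G), function(g) {
      -expm1(-(weibull_cumhaz(t, params$zeta[g, ]) - weibull_cumhaz(s, params$zeta[g, ])) * elp)
    }, 0)
    sum(post * cond_fail)
  })
}

#' Individual predicted probability of graft failure over time
#'
#' Landmark dynamic prediction: probability of graft failure in `(s, t]`
#' conditional on being event-free at `s` and on the creatinine history and
#' covariates observed up to `s`:
#' `P(s, t) = sum_g post_g(s) * (1 - S_g(t | x) / S_g(s | x))`.
#' With `n_draws > 0` and a valid variance matrix, parameter vectors are drawn
#' from the asymptotic normal on the unconstrained scale and the pointwise
#' 2.5/50/97.5 percentiles of the recomputed curves form the reported median
#' and 95% band (deterministic given `seed`).
#'
#' @param fit A `graft_jlcm`.
#' @param subject_id Subject to predict for.
#' @param cohort Cohort holding the subject (defaults to the training cohort).
#' @param landmark Landmark time `s` in years (default 1, i.e. predictions
#'   from data collected up to 12 months).
#' @param horizon Latest prediction time (default 10 years).
#' @param grid Optional explicit time grid (> landmark).
#' @param n_draws Monte-Carlo draws for the confidence band (0 = plug-in
#'   curve only).
#' @param seed Seed for the draws.
#' @return A `risk_curve` tibble: `time`, `point` (plug-in), `median`,
#'   `lower95`, `upper95`, with the landmark, draws and seed as attributes.
#' @export
predict_risk <- function(fit, subject_id, cohort = NULL, landmark = 1,
                         horizon = 10, grid = NULL, n_draws = 500, seed = 1L) {
  cohort <- cohort %||% fit$cohort
  profile <- cohort$subjects[cohort$subjects$subject_id == subject_id, , drop = FALSE]
  if (nrow(profile) != 1) stop("subject ", subject_id, " not found in cohort", call. = FALSE)
  meas <- cohort$measurements[cohort$measurements$subject_id == subject_id, , drop = FALSE]
  risk_curve(fit, meas, profile, landmark, horizon, grid, n_draws, seed)
}

#' @rdname predict_risk
#' @param measurements,profile Direct data for a subject not in a cohort.
#' @export
risk_curve <- function(fit, measurements, profile, landmark = 1, horizon = 10,
                       grid = NULL, n_draws = 500, seed = 1L) {
  if (is.null(grid)) grid <- seq(landmark, horizon, length.out = 91)
  grid <- sort(unique(pmax(grid, landmark)))
  x_s <- hazard_x_at(profile, fit$hazard_covariates, landmark)

  post0 <- posterior_class_at_landmark(fit, measurements, profile, landmark)
  point <- failure_curve_point(fit$params, post0, x_s, landmark, grid)
  curve_for <- function(params) {
    post <- suppressWarnings(
      posterior_class_at_landmark(fit, measurements, profile, landmark, params))
    failure_curve_point(params, post, x_s, landmark, grid)
  }

  tmpl <- params_template(
    make_model_data(fit$cohort,
                    membership_covariates = fit$membership_covariates,
                    hazard_covariates = fit$hazard_covariates,
                    link = fit$params$link),
    fit$n_classes, fit$control$classwise_re_scale)

  has_ci <- n_draws > 0 && fit$vcov_ok
  if (n_draws > 0 && !fit$vcov_ok) {
    warning("fit has no variance matrix; returning the plug-in curve without a band")
  }
  if (has_ci) {
    Lv <- t(chol(fit$vcov + diag(1e-12, length(fit$theta))))
    draws <- with_seed(seed, {
      z <- matrix(stats::rnorm(n_draws * length(fit$theta)), length(fit$theta), n_draws)
      th <- fit$theta + Lv %*% z
      d <- apply(th, 2L, function(v) curve_for(unpack_params(v, tmpl)))
      matrix(d, nrow = length(grid)) # stays a matrix for length-1 grids
    })
    qs <- apply(draws, 1L, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
    med <- qs[2, ]; lo <- qs[1, ]; hi <- qs[3, ]
  } else {
    med <- point; lo <- rep(NA_real_, length(grid)); hi <- rep(NA_real_, length(grid))
  }
  structure(
    tibble::tibble(time = grid, point = point, median = med,
                   lower95 = lo, upper95 = hi),
    class = c("risk_curve", class(tibble::tibble())),
    landmark = landmark, n_draws = if (has_ci) n_draws else 0L, seed = seed,
    subject_id = as.character(profile$subject_id %||% NA)
  )
}

#' Re-prediction after onset of dnDSA and/or acute rejection
#'
#' Updates the hazard covariates with the newly observed events, moves the
#' landmark to the (latest) onset time, and recomputes the risk curve
#' conditional on being event-free at the new landmark. With no updates the
#' original curve is returned unchanged.
#'
#' @param fit A `graft_jlcm`.
#' @param subject_id,cohort As in [predict_risk()].
#' @param landmark Original landmark (years).
#' @param dndsa_time,ar_time Onset times (years) of dnDSA and acute rejection;
#'   `NULL` leaves the covariate as in the stored profile.
#' @param ... Passed to [risk_curve()] (`horizon`, `grid`, `n_draws`, `seed`).
#' @return A `risk_curve` at the updated landmark.
#' @export
repredict_after_event_update <- function(fit, subject_id, cohort = NULL,
                                         landmark = 1, dndsa_time = NULL,
                                         ar_time = NULL, ...) {
  cohort <- cohort %||% fit$cohort
  profile <- cohort$subjects[cohort$subjects$subject_id == subject_id, , drop = FALSE]
  if (nrow(profile) != 1) stop("subject ", subject_id, " not found in cohort", call. = FALSE)
  meas <- cohort$measurements[cohort$measurements$subject_id == subject_id, , drop = FALSE]
  s_new <- landmark
  if (!is.null(dndsa_time)) {
    profile$dndsa <- 1L
    profile$dndsa_time <- dndsa_time
    s_new <- max(s_new, dndsa_time)
  }
  if (!is.null(ar_time)) {
    profile$acute_rejection <- 1L
    profile$ar_time <- ar_time
    s_new <- max(s_new, ar_time)
  }
  profile$dndsa_x_ar <- as.integer(profile$dndsa == 1 && profile$acute_rejection == 1)
  risk_curve(fit, meas, profile, landmark = s_new, ...)
}
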