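test_that("landmark class posterior is a proper probability vector", {
  f <- small_fit()
  co <- small_sim()$cohort
  ids <- co$subjects$subject_id
  for (id in ids[seq(1, length(ids), by = 2)]) {
    prof <- co$subjects[co$subjects$subject_id == id, ]
    meas <- co$measurements[co$measurements$subject_id == id, ]
    p <- posterior_class_at_landmark(f, meas, prof, s = 1)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p >= 0))
  }
  # without any pre-landmark measurement: covariate-only fallback with warning
  prof <- co$subjects[1, ]
  meas0 <- co$measurements[0, ]
  expect_warning(p0 <- posterior_class_at_landmark(f, meas0, prof, s = 1),
                 "covariate-only")
  expect_lt(abs(sum(p0) - 1), 1e-12)
})

test_that("a history lying on one class mean yields a near-degenerate posterior", {
  f <- small_fit()
  co <- small_sim()$cohort
  p <- f$params
  # shrink the random effects so the trajectory term dominates
  f2 <- f
  f2$params$B <- diag(1e-4, 2)
  tv <- c(0.1, 0.3, 0.6, 0.9)
  lat <- class_mean_trajectory(p$beta[2, ], tv)
  meas <- tibble::tibble(time_years = tv, scr_umol_l = link_inverse(lat, p$link))
  prof <- co$subjects[1, ]
  post <- posterior_class_at_landmark(f2, meas, prof, s = 1)
  expect_gt(post[2], 0.99)
})

test_that("risk curves start at zero, are monotone, and collapse correctly", {
  f <- small_fit()
  co <- small_sim()$cohort
  cur <- predict_risk(f, co$subjects$subject_id[3], landmark = 1, n_draws = 100, seed = 4)
  expect_s3_class(cur, "risk_curve")
  expect_equal(cur$point[1], 0)
  expect_equal(cur$median[1], 0)
  expect_true(all(diff(cur$point) >= -1e-12))
  expect_true(all(diff(cur$median) >= -1e-12))
  expect_true(all(cur$lower95 <= cur$median + 1e-12 & cur$median <= cur$upper95 + 1e-12))
  expect_true(all(cur$point >= 0 & cur$point <= 1))
  # degenerate posterior reproduces the class-conditional failure function
  x_s <- graftjlcm:::hazard_x_at(co$subjects[3, ], f$hazard_covariates, 1)
  grid <- cur$time
  for (g in 1:2) {
    post <- replace(numeric(2), g, 1)
    pg <- graftjlcm:::failure_curve_point(f$params, post, x_s, 1, grid)
    elp <- exp(sum(x_s * f$params$delta))
    ref <- 1 - exp(-(weibull_cumhaz(grid, f$params$zeta[g, ]) -
                       weibull_cumhaz(1, f$params$zeta[g, ])) * elp)
    expect_equal(pg, ref, tolerance = 1e-12)
  }
})

test_that("plug-in curve matches an independent scalar re-implementation", {
  f <- small_fit()
  co <- small_sim()$cohort
  id <- co$subjects$subject_id[7]
  prof <- co$subjects[co$subjects$subject_id == id, ]
  meas <- co$measurements[co$measurements$subject_id == id, ]
  s <- 1
  grid <- c(2, 5, 10)
  cur <- risk_curve(f, meas, prof, landmark = s, grid = grid, n_draws = 0)
  # oracle: explicit Bayes posterior and mixture survival ratio, scalar code
  p <- f$params
  x_c <- as.numeric(prof[[f$membership_covariates]])
  x_s <- c(prof$ndsa_pre, prof$prot_gt_0275,
           as.integer(prof$dndsa == 1 && !is.na(prof$dndsa_time) && prof$dndsa_time <= s),
           as.integer(prof$acute_rejection == 1 && (is.na(prof$ar_time) || prof$ar_time <= s)),
           0)
  x_s[5] <- x_s[3] * x_s[4]
  m <- meas[meas$time_years <= s, ]
  lw <- numeric(p$G)
  for (g in 1:p$G) {
    pi_g <- membership_probs(p$xi, x_c, p$G)[g]
    f_g <- longitudinal_loglik_given_class(m, p$beta[g, ], p$B, p$sigma, p$link)
    s_g <- -(p$zeta[g, 1] * s)^p$zeta[g, 2] * exp(sum(x_s * p$delta))
    lw[g] <- log(pi_g) + f_g + s_g
  }
  w <- exp(lw - max(lw)); w <- w / sum(w)
  oracle <- sapply(grid, function(tt) {
    sum(w * (1 - exp(-((p$zeta[, 1] * tt)^p$zeta[, 2] -
                         (p$zeta[, 1] * s)^p$zeta[, 2]) * exp(sum(x_s * p$delta)))))
  })
  expect_lt(max(abs(cur$point - oracle)), 1e-10)
})

test_that("confidence bands are seeded, degenerate with vanishing vcov", {
  f <- small_fit()
  co <- small_sim()$cohort
  id <- co$subjects$subject_id[2]
  c1 <- predict_risk(f, id, landmark = 1, n_draws = 150, seed = 42)
  c2 <- predict_risk(f, id, landmark = 1, n_draws = 150, seed = 42)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- predict_risk(f, id, landmark = 1, n_draws = 150, seed = 43)
  expect_false(identical(c1$upper95, c3$upper95))
  # vcov -> 0: all three curves coincide with the plug-in curve
  f0 <- f
  f0$vcov <- diag(1e-20, length(f$theta))
  c0 <- predict_risk(f0, id, landmark = 1, n_draws = 100, seed = 1)
  # a 1e-12 ridge keeps the draw covariance PSD, so agreement is ~1e-4
  expect_equal(c0$median, c0$point, tolerance = 1e-4)
  expect_equal(c0$lower95, c0$point, tolerance = 1e-4)
  expect_equal(c0$upper95, c0$point, tolerance = 1e-4)
  # no vcov: plug-in curve returned with a warning, band flagged absent
  fna <- f
  fna$vcov_ok <- FALSE
  expect_warning(cna <- predict_risk(fna, id, landmark = 1, n_draws = 100), "plug-in")
  expect_true(all(is.na(cna$upper95)))
  expect_identical(attr(cna, "n_draws"), 0L)
})

test_that("landmark predictions satisfy the tower identity within class", {
  f <- small_fit()
  p <- f$params
  x_s <- c(1, 0, 0, 1, 0)
  s1 <- 1; s2 <- 3; tt <- 8
  for (g in 1:2) {
    post <- replace(numeric(2), g, 1)
    P_s1_t <- graftjlcm:::failure_curve_point(p, post, x_s, s1, tt)
    P_s1_s2 <- graftjlcm:::failure_curve_point(p, post, x_s, s1, s2)
    P_s2_t <- graftjlcm:::failure_curve_point(p, post, x_s, s2, tt)
    expect_equal(P_s1_t, P_s1_s2 + (1 - P_s1_s2) * P_s2_t, tolerance = 1e-12)
  }
})

test_that("re-prediction after dnDSA/rejection onset updates the curve", {
  f <- small_fit()
  co <- small_sim()$cohort
  no_event <- co$subjects$subject_id[co$subjects$dndsa == 0 &
                                       co$subjects$acute_rejection == 0 &
                                       co$subjects$event_time > 6][1]
  # identity update: same landmark, no covariate change
  base <- predict_risk(f, no_event, landmark = 1, n_draws = 50, seed = 2)
  same <- repredict_after_event_update(f, no_event, landmark = 1,
                                       n_draws = 50, seed = 2)
  expect_equal(as.data.frame(base), as.data.frame(same))
  # force a harmful covariate configuration and re-predict at onset
  fx <- f
  fx$params$delta <- stats::setNames(c(0.5, 0.4, -0.7, -0.25, 2.7), names(f$params$delta))
  fx$vcov_ok <- FALSE
  s2 <- 2.5
  b0 <- suppressWarnings(predict_risk(fx, no_event, landmark = s2, n_draws = 0))
  up <- suppressWarnings(repredict_after_event_update(
    fx, no_event, landmark = s2, dndsa_time = 2.5, ar_time = 2.0, n_draws = 0))
  expect_equal(attr(up, "landmark"), 2.5)
  grid_common <- intersect(b0$time, up$time)
  pb <- b0$point[match(grid_common, b0$time)]
  pu <- up$point[match(grid_common, up$time)]
  expect_true(all(pu[-1] > pb[-1])) # exp(delta_dn + delta_ar + delta_int) > 1
  expect_true(all(diff(up$point) >= -1e-12) && all(up$point >= 0 & up$point <= 1))
})
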