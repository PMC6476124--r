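test_that("packing and unpacking the parameter vector is bijective", {
  g <- small_sim()
  md <- graftjlcm:::make_model_data(g$cohort, "linear")
  for (G in c(1, 3)) {
    tmpl <- graftjlcm:::params_template(md, G)
    for (k in 1:50) {
      p <- random_params(tmpl, seed = 100 * G + k)
      p2 <- graftjlcm:::unpack_params(graftjlcm:::pack_params(p), tmpl)
      expect_equal(p2$xi, p$xi, tolerance = 1e-12)
      expect_equal(p2$beta, p$beta, tolerance = 1e-12)
      expect_equal(p2$B, p$B, tolerance = 1e-10)
      expect_equal(p2$link$eta, p$link$eta, tolerance = 1e-12)
      expect_equal(p2$zeta, p$zeta, tolerance = 1e-12)
      expect_equal(p2$delta, p$delta, tolerance = 1e-12)
      # and theta -> params -> theta
      th <- abs(rnorm(length(graftjlcm:::pack_params(p))))
      th2 <- graftjlcm:::pack_params(graftjlcm:::unpack_params(th, tmpl))
      expect_equal(th2, th, tolerance = 1e-10)
    }
  }
})

test_that("joint likelihood matches a naive scalar enumeration oracle", {
  co <- small_sim()$cohort
  co$subjects <- co$subjects[1:5, ]
  co$measurements <- co$measurements[co$measurements$subject_id %in% co$subjects$subject_id, ]
  md <- graftjlcm:::make_model_data(co, "linear")
  for (G in c(1, 2, 3)) {
    tmpl <- graftjlcm:::params_template(md, G)
    p <- random_params(tmpl, seed = G)
    ll <- joint_loglik(p, co)
    oracle <- sum(vapply(1:5, function(i) {
      rows <- md$first[i] + seq_len(md$ni[i])
      oracle_subject_loglik(p, md$t[rows], md$y[rows],
                            as.numeric(md$Xc[i, ]), as.numeric(md$Xs[i, ]),
                            md$entry[i], md$tev[i], md$dev[i])
    }, 0))
    expect_lt(abs(ll - oracle), 1e-10)
    # compiled and reference paths agree
    expect_lt(abs(ll - joint_loglik(p, co, method = "R")), 1e-10)
  }
})

test_that("one-class likelihood is the sum of its longitudinal and event parts", {
  co <- small_sim()$cohort
  md <- graftjlcm:::make_model_data(co, "linear")
  tmpl <- graftjlcm:::params_template(md, 1)
  p <- random_params(tmpl, seed = 4)
  long_part <- sum(vapply(seq_len(md$n), function(i) {
    rows <- md$first[i] + seq_len(md$ni[i])
    longitudinal_loglik_given_class(
      tibble::tibble(time_years = md$t[rows], scr_umol_l = md$y[rows]),
      p$beta[1, ], p$B, p$sigma, p$link)
  }, 0))
  ev_part <- sum(vapply(seq_len(md$n), function(i) {
    event_loglik_given_class(list(entry_time = md$entry[i], event_time = md$tev[i],
                                  event = md$dev[i]),
                             p$zeta[1, ], p$delta, as.numeric(md$Xs[i, ]))
  }, 0))
  expect_equal(joint_loglik(p, co), long_part + ev_part, tolerance = 1e-9)
})

test_that("duplicating every subject doubles the joint likelihood", {
  co <- small_sim()$cohort
  co$subjects <- co$subjects[1:20, ]
  co$measurements <- co$measurements[co$measurements$subject_id %in% co$subjects$subject_id, ]
  dup <- co
  s2 <- co$subjects
  s2$subject_id <- paste0(s2$subject_id, "_dup")
  m2 <- co$measurements
  m2$subject_id <- paste0(m2$subject_id, "_dup")
  dup$subjects <- dplyr::bind_rows(co$subjects, s2)
  dup$measurements <- dplyr::bind_rows(co$measurements, m2)
  md <- graftjlcm:::make_model_data(co, "linear")
  p <- random_params(graftjlcm:::params_template(md, 2), seed = 8)
  expect_equal(joint_loglik(p, dup), 2 * joint_loglik(p, co), tolerance = 1e-9)
})

test_that("joint likelihood is invariant under class relabeling", {
  co <- small_sim()$cohort
  md <- graftjlcm:::make_model_data(co, "linear")
  tmpl <- graftjlcm:::params_template(md, 2)
  p <- random_params(tmpl, seed = 6)
  p_swapped <- graftjlcm:::permute_params(p, c(2, 1))
  expect_equal(joint_loglik(p, co), joint_loglik(p_swapped, co), tolerance = 1e-8)
  # and for G = 3 under a cyclic permutation
  tmpl3 <- graftjlcm:::params_template(md, 3)
  p3 <- random_params(tmpl3, seed = 7)
  expect_equal(joint_loglik(p3, co), joint_loglik(graftjlcm:::permute_params(p3, c(3, 1, 2)), co),
               tolerance = 1e-8)
})

test_that("the fitted optimum is a fixed point and classes are ordered", {
  f <- small_fit()
  expect_identical(f$convergence$status, "converged")
  # refit warm-started from the optimum moves the likelihood negligibly
  f2 <- fit_jlcm(small_sim()$cohort, 2, link_family = "linear", init = f$theta,
                 control = jlcm_control(n_starts = 1, maxit = 200, hessian = FALSE))
  expect_lt(abs(f2$loglik - f$loglik), 1e-6)
  # ordering convention: class 1 has the lower fitted 18-month creatinine
  m18 <- vapply(1:2, function(g) class_mean_trajectory(f$params$beta[g, ], 1.5), 0)
  expect_true(m18[1] < m18[2])
  # posterior rows normalized
  pc <- posterior_classification(f)
  expect_lt(max(abs(rowSums(as.matrix(pc$posterior[, c("p1", "p2")])) - 1)), 1e-12)
  expect_true(all(pc$summary$mean_posterior > 0.5))
})

test_that("information criteria follow their formulas and G selection works", {
  f <- small_fit()
  expect_equal(f$criteria$BIC, -2 * f$loglik + f$n_params * log(f$n_subjects), tolerance = 1e-12)
  expect_equal(f$criteria$AIC, -2 * f$loglik + 2 * f$n_params, tolerance = 1e-12)
  g <- small_sim()
  sel <- select_n_classes(g$cohort, G_range = 1, link_family = "linear",
                          control = jlcm_control(n_starts = 1, maxit = 150, hessian = FALSE))
  expect_equal(nrow(sel$criteria), 1)
  expect_equal(sel$chosen_G, 1)
  expect_equal(sel$criteria$BIC,
               -2 * sel$criteria$loglik + sel$criteria$n_params * log(n_subjects(g$cohort)))
})

test_that("one-class fits recover the generator parameters within 3 SE", {
  cfg <- generator_config(
    n_subjects = 300,
    xi = matrix(numeric(0), 0, 2),
    beta = matrix(c(130, 5, 1) / 15, 1, 3),
    B = matrix(c(1, 0.15, 0.15, 0.25), 2, 2),
    zeta = matrix(c(0.05, 1.4), 1, 2),
    min_followup = 0.5
  )
  g <- generate_cohort(cfg, seed = 31)
  f <- fit_jlcm(g$cohort, 1, link_family = "linear",
                control = jlcm_control(n_starts = 1, maxit = 400, seed = 2))
  expect_true(f$vcov_ok)
  td <- tidy(f)
  # trajectory fixed effects on the latent scale
  tr <- td[td$submodel == "trajectory", ]
  expect_true(all(abs(tr$estimate - cfg$beta[1, ]) < 3 * tr$std.error))
  # Weibull parameters
  bz <- td[td$submodel == "baseline_risk", ]
  expect_true(all(abs(bz$estimate - cfg$zeta[1, ]) < 3 * bz$std.error))
  # link scale recovers the residual SD (15 umol/L)
  lke <- td[td$submodel == "link", ]
  expect_lt(abs(lke$estimate - 15), 3 * lke$std.error)
})

test_that("reported standard errors track seed-to-seed variation", {
  cfg <- generator_config(
    n_subjects = 400, xi = matrix(numeric(0), 0, 2),
    beta = matrix(c(130, 5, 1) / 15, 1, 3),
    B = matrix(c(1, 0.15, 0.15, 0.25), 2, 2),
    zeta = matrix(c(0.05, 1.4), 1, 2), min_followup = 0.5
  )
  ests <- ses <- matrix(NA_real_, 8, 2)
  for (k in 1:8) {
    g <- generate_cohort(cfg, seed = 200 + k)
    f <- fit_jlcm(g$cohort, 1, link_family = "linear",
                  control = jlcm_control(n_starts = 1, maxit = 300, seed = k))
    td <- tidy(f)
    tr <- td[td$submodel == "trajectory", ]
    ests[k, ] <- tr$estimate[1:2]
    ses[k, ] <- tr$std.error[1:2]
  }
  ratio <- apply(ests, 2, sd) / colMeans(ses)
  expect_true(all(ratio > 0.4 & ratio < 2.5))
})

test_that("tidy and glance expose the fit in broom style", {
  f <- small_fit()
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$submodel),
                  c("membership", "trajectory", "random_effects", "link",
                    "baseline_risk", "hazard"))
  expect_equal(nrow(td), f$n_params)
  if (f$vcov_ok) expect_true(all(is.finite(td$std.error)))
  gl <- glance(f)
  expect_equal(gl$n_classes, 2)
  expect_equal(gl$logLik, f$loglik)
  expect_true(gl$converged)
})

test_that("covariate screening reports univariate and multivariate Wald tables", {
  g <- small_sim()
  sc <- screen_covariates(g$cohort, c("ndsa_pre", "acute_rejection"), n_classes = 1,
                          control = jlcm_control(n_starts = 1, maxit = 150))
  expect_equal(sc$univariate$term, c("ndsa_pre", "acute_rejection"))
  expect_true(all(sc$univariate$p.value >= 0 & sc$univariate$p.value <= 1))
  expect_identical(sc$univariate$entered, sc$univariate$p.value < 0.2)
  expect_setequal(sc$retained, sc$univariate$term[sc$univariate$entered])
  if (length(sc$retained)) {
    expect_s3_class(sc$multivariate, "tbl_df")
    expect_equal(nrow(sc$multivariate), length(sc$retained))
  }
})
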