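# Shared fixtures. Heavy fits are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

# minimal hand-built two-subject cohort (valid by construction)
tiny_cohort <- function() {
  subjects <- tibble::tibble(
    subject_id = c("A", "B"),
    donor_age_ge60 = c(0L, 1L),
    ndsa_pre = c(0L, 1L),
    proteinuria_m12 = c(0.10, 0.30),
    acute_rejection = c(0L, 1L),
    ar_time = c(NA_real_, 0.4),
    dndsa = c(0L, 1L),
    dndsa_time = c(NA_real_, 2.5),
    entry_time = c(0, 0),
    event_time = c(8, 3.2),
    event = c(0L, 1L)
  )
  measurements <- tibble::tibble(
    subject_id = rep(c("A", "B"), each = 5),
    time_years = rep(c(1, 3, 6, 12, 18) / 12, 2),
    scr_umol_l = c(95, 100, 98, 102, 99, 150, 160, 175, 200, 240)
  )
  graft_cohort(subjects, measurements)
}

# small two-class simulated cohort for cheap fitting tests
small_sim_config <- function(n = 120) {
  generator_config(
    n_subjects = n,
    xi = matrix(c(0.4, -1.0), 1, 2),
    beta = rbind(c(100, -10, 3), c(165, 30, 5)) / 15,
    B = matrix(c(1, 0.15, 0.15, 0.25), 2, 2),
    zeta = rbind(c(0.02, 1.5), c(0.12, 1.8)),
    # richer event-covariate mix than the study preset so every hazard
    # coefficient is identified even in small test cohorts
    covariate_probs = c(donor_age_ge60 = 0.25, ndsa_pre = 0.2,
                        acute_rejection = 0.35, dndsa = 0.3),
    min_followup = 0.5
  )
}

small_sim <- function(seed = 5, n = 120) {
  cached(paste0("small_sim_", seed, "_", n), generate_cohort(small_sim_config(n), seed = seed))
}

small_fit <- function() {
  cached("small_fit", {
    g <- small_sim()
    f <- fit_jlcm(g$cohort, 2, link_family = "linear",
                  control = jlcm_control(n_starts = 2, maxit = 300, seed = 1))
    stopifnot(f$vcov_ok) # downstream fixtures rely on the variance matrix
    f
  })
}

# random valid parameter list for a given template
random_params <- function(tmpl, seed = 1) {
  with_seed <- get("with_seed", asNamespace("graftjlcm"))
  with_seed(seed, {
    G <- tmpl$G
    L <- matrix(c(abs(rnorm(1, 1, 0.3)), rnorm(1, 0, 0.2), abs(rnorm(1, 0.5, 0.2))), nrow = 1)
    R <- matrix(c(L[1], 0, L[2], L[3]), 2, 2)
    link <- tmpl$link
    link$eta <- abs(rnorm(tmpl$np_link, 1, 0.3)) + 0.05
    list(
      G = G,
      xi = if (G > 1) matrix(rnorm((G - 1) * (1 + tmpl$pc), 0, 0.7), G - 1, 1 + tmpl$pc)
           else matrix(numeric(0), 0, 1 + tmpl$pc),
      beta = matrix(rnorm(3 * G, c(7, 0, 0), 1), G, 3, byrow = FALSE),
      B = t(R) %*% R, sigma = 1, wg = rep(1, G), link = link,
      zeta = matrix(abs(rnorm(2 * G, c(0.1, 1.2), 0.03)) + 0.01, G, 2),
      delta = stats::setNames(rnorm(tmpl$ps, 0, 0.4), tmpl$hazard_covariates),
      classwise = isTRUE(tmpl$classwise),
      membership_covariates = tmpl$membership_covariates,
      hazard_covariates = tmpl$hazard_covariates
    )
  })
}

# independent scalar oracle for the joint likelihood of one subject:
# base-R formulas only, enumerating classes explicitly
oracle_subject_loglik <- function(params, meas_t, meas_y, x_c, x_s, entry, tev, dev) {
  G <- params$G
  tr <- link_transform(meas_y, params$link) # link map shared; densities re-derived
  contrib <- numeric(G)
  a <- c(if (G > 1) as.numeric(params$xi %*% c(1, x_c)), 0)
  pi_i <- exp(a) / sum(exp(a))
  for (g in seq_len(G)) {
    mu <- params$beta[g, 1] + params$beta[g, 2] * meas_t + params$beta[g, 3] * meas_t^2
    Z <- cbind(1, meas_t)
    V <- params$wg[g] * Z %*% params$B %*% t(Z) + diag(params$sigma^2, length(meas_t))
    r <- tr$h - mu
    ll_long <- -0.5 * (length(meas_t) * log(2 * pi) + determinant(V)$modulus[1] +
                         as.numeric(t(r) %*% solve(V) %*% r)) + sum(tr$log_jacobian)
    z1 <- params$zeta[g, 1]; z2 <- params$zeta[g, 2]
    elp <- exp(sum(x_s * params$delta))
    ll_ev <- -(z1 * tev)^z2 * elp + (if (entry > 0) (z1 * entry)^z2 * elp else 0) +
      dev * (log(z1 * z2) + (z2 - 1) * log(z1 * tev) + sum(x_s * params$delta))
    contrib[g] <- log(pi_i[g]) + ll_long + ll_ev
  }
  m <- max(contrib)
  m + log(sum(exp(contrib - m)))
}
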