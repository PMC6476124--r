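#' Control settings for joint model estimation
#'
#' @param n_starts Number of optimizer initializations (first start is a
#'   structured k-means/least-squares initialization, the rest are jittered).
#' @param maxit Maximum BFGS iterations per start.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param grad_tol Gradient sup-norm below which a start is declared converged.
#' @param fd_step Relative step for central-difference gradients.
#' @param classwise_re_scale If `TRUE`, estimate class-specific proportional
#'   scalings of the random-effect covariance (reference class fixed at 1).
#' @param hessian Compute the observed-information variance matrix at the
#'   optimum.
#' @param start_jitter SD multiplier for the random restarts.
#' @param seed Optional integer seed making the whole fit deterministic.
#' @param trace Passed to [stats::optim()].
#' @return A list of class `jlcm_control`.
#' @export
jlcm_control <- function(n_starts = 10, maxit = 500, reltol = 1e-10, grad_tol = 1e-4,
                         fd_step = 1e-5, classwise_re_scale = FALSE, hessian = TRUE,
                         start_jitter = 0.3, seed = NULL, trace = 0) {
  structure(as.list(environment()), class = "jlcm_control")
}

# deterministic scope for RNG without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' The retained clinical hazard covariate set
#'
#' Pretransplant NDSA, dichotomized month-12 proteinuria, dnDSA, acute
#' rejection, and the dnDSA-by-acute-rejection interaction.
#'
#' @return Character vector of subject-table column names.
#' @export
default_hazard_covariates <- function() {
  c("ndsa_pre", "prot_gt_0275", "dndsa", "acute_rejection", "dndsa_x_ar")
}

# ---- model data ------------------------------------------------------------

make_model_data <- function(cohort, link_family = "ispline_equidistant", n_nodes = 5,
                            membership_covariates = "donor_age_ge60",
                            hazard_covariates = default_hazard_covariates(),
                            link = NULL) {
  s <- cohort$subjects
  m <- cohort$measurements
  ord <- order(match(m$subject_id, s$subject_id), m$time_years)
  m <- m[ord, ]
  ni <- as.integer(table(factor(m$subject_id, levels = s$subject_id)))
  if (any(ni == 0)) stop("every subject needs at least one measurement", call. = FALSE)
  first <- c(0L, cumsum(ni)[-length(ni)])
  if (is.null(link)) {
    link <- make_link(link_family, values = m$scr_umol_l, n_nodes = n_nodes)
  }
  md <- list(
    subjects = s,
    y = m$scr_umol_l, t = m$time_years,
    group = rep(seq_len(nrow(s)), ni),
    first = first, ni = ni, n = nrow(s),
    Xc = as.matrix(s[, membership_covariates, drop = FALSE]),
    Xs = as.matrix(s[, hazard_covariates, drop = FALSE]),
    membership_covariates = membership_covariates,
    hazard_covariates = hazard_covariates,
    entry = s$entry_time, tev = s$event_time, dev = s$event,
    link = link
  )
  if (link$family %in% c("ispline_equidistant", "ispline_quantile")) {
    md$iB <- ispline_basis(md$y, link$nodes, link$degree)
    md$mB <- mspline_basis(md$y, link$nodes, link$degree)
  }
  md
}

# transformed measurements using precomputed spline bases when available
transform_md <- function(md, link) {
  if (!is.null(md$iB) && link$family == md$link$family) {
    list(h = as.numeric(md$iB %*% link$eta),
         log_jacobian = log(as.numeric(md$mB %*% link$eta)))
  } else {
    link_transform(md$y, link)
  }
}

# ---- parameter packing -----------------------------------------------------

params_template <- function(md, G, classwise_re_scale = FALSE) {
  list(G = G, pc = ncol(md$Xc), ps = ncol(md$Xs),
       link = md$link, classwise = classwise_re_scale,
       np_link = n_link_params(md$link),
       membership_covariates = md$membership_covariates,
       hazard_covariates = md$hazard_covariates)
}

#' @keywords internal
pack_params <- function(params) {
  G <- params$G
  R <- tryCatch(chol(params$B), error = function(e) chol(params$B + diag(1e-10, 2)))
  c(
    if (G > 1) as.numeric(t(params$xi)),
    as.numeric(t(params$beta)),
    R[1, 1], R[1, 2], R[2, 2],
    if (isTRUE(params$classwise) && G > 1) sqrt(params$wg[-G]),
    sqrt(params$link$eta),
    as.numeric(t(sqrt(params$zeta))),
    as.numeric(params$delta)
  )
}

#' @keywords internal
unpack_params <- function(theta, tmpl) {
  G <- tmpl$G
  pos <- 0L
  take <- function(k) {
    out <- theta[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  xi <- if (G > 1) matrix(take((G - 1) * (1 + tmpl$pc)), G - 1, 1 + tmpl$pc, byrow = TRUE)
        else matrix(numeric(0), 0, 1 + tmpl$pc)
  beta <- matrix(take(3 * G), G, 3, byrow = TRUE)
  r <- take(3)
  R <- matrix(c(r[1], 0, r[2], r[3]), 2, 2)
  B <- t(R) %*% R
  wg <- rep(1, G)
  if (isTRUE(tmpl$classwise) && G > 1) wg[-G] <- take(G - 1)^2
  link <- tmpl$link
  link$eta <- take(tmpl$np_link)^2
  zeta <- matrix(take(2 * G), G, 2, byrow = TRUE)^2
  delta <- stats::setNames(take(tmpl$ps), tmpl$hazard_covariates)
  if (pos != length(theta)) stop("parameter vector has wrong length", call. = FALSE)
  list(G = G, xi = xi, beta = beta, B = B, sigma = 1, wg = wg,
       link = link, zeta = zeta, delta = delta,
       classwise = isTRUE(tmpl$classwise),
       membership_covariates = tmpl$membership_covariates,
       hazard_covariates = tmpl$hazard_covariates)
}

# ---- joint likelihood ------------------------------------------------------

# n x G matrix of log(pi_ig f_ig [event_ig]); fast compiled path
joint_contrib_matrix <- function(params, md, use_event = TRUE) {
  tr <- transform_md(md, params$link)
  if (any(!is.finite(tr$log_jacobian))) return(NULL)
  logjac <- as.numeric(rowsum(tr$log_jacobian, md$group))
  logpi <- membership_logprobs_matrix(params$xi, md$Xc, params$G)
  lp <- as.numeric(md$Xs %*% params$delta)
  cpp_joint_contrib(md$t, tr$h, md$first, md$ni, logjac,
                    params$beta, params$B, params$wg, params$sigma^2,
                    logpi, md$entry, md$tev, md$dev, lp, params$zeta, use_event)
}

#' Joint log-likelihood of a parameter set on a cohort
#'
#' Mixture over latent classes of the membership probability, the
#' longitudinal density of the transformed creatinine measurements, and the
#' class-specific Weibull event contribution, combined per subject with
#' log-sum-exp stabilization.
#'
#' @param params Parameter list as stored in a fitted model (`fit$params`):
#'   elements `G`, `xi`, `beta`, `B`, `sigma`, `wg`, `link`, `zeta`, `delta`.
#' @param cohort A `graft_cohort`.
#' @param method `"cpp"` (compiled, default) or `"R"` (reference
#'   implementation looping over scalar density routines).
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(params, cohort, method = c("cpp", "R")) {
  method <- match.arg(method)
  md <- make_model_data(cohort,
    membership_covariates = params$membership_covariates %||% "donor_age_ge60",
    hazard_covariates = params$hazard_covariates %||% default_hazard_covariates(),
    link = params$link
  )
  if (method == "cpp") {
    contrib <- joint_contrib_matrix(params, md)
    if (is.null(contrib)) stop("non-finite link Jacobian", call. = FALSE)
    ll_i <- row_logsumexp(contrib)
  } else {
    ll_i <- joint_loglik_r_subjects(params, md)
  }
  if (any(!is.finite(ll_i))) {
    stop("non-finite likelihood contribution for subject(s) ",
         paste(md$subjects$subject_id[!is.finite(ll_i)], collapse = ", "), call. = FALSE)
  }
  sum(ll_i)
}

# reference path: scalar routines, one subject at a time
joint_loglik_r_subjects <- function(params, md) {
  G <- params$G
  vapply(seq_len(md$n), function(i) {
    rows <- md$first[i] + seq_len(md$ni[i])
    meas <- tibble::tibble(time_years = md$t[rows], scr_umol_l = md$y[rows])
    prof <- list(entry_time = md$entry[i], event_time = md$tev[i], event = md$dev[i])
    pi_i <- membership_probs(params$xi, as.numeric(md$Xc[i, ]), G)
    lg <- vapply(seq_len(G), function(g) {
      log(pi_i[g]) +
        longitudinal_loglik_given_class(meas, params$beta[g, ],
                                        params$wg[g] * params$B, params$sigma, params$link) +
        event_loglik_given_class(prof, params$zeta[g, ], params$delta,
                                 as.numeric(md$Xs[i, ]))
    }, 0)
    logsumexp(lg)
  }, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

num_grad <- function(f, x, rel = 1e-5) {
  vapply(seq_along(x), function(j) {
    h <- rel * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# ---- initialization --------------------------------------------------------

init_params <- function(md, G, tmpl) {
  # per-subject least-squares summaries of the crudely transformed outcome
  resid_sd <- {
    r2 <- unlist(lapply(seq_len(md$n), function(i) {
      rows <- md$first[i] + seq_len(md$ni[i])
      if (md$ni[i] < 3) return(numeric(0))
      stats::lm.fit(cbind(1, md$t[rows]), md$y[rows])$residuals
    }))
    s <- stats::sd(r2)
    if (!is.finite(s) || s <= 0) stats::sd(md$y) / 3 else s
  }
  link <- md$link
  link$eta <- switch(link$family,
    linear = resid_sd,
    beta_cdf = c(1, 1, diff(link$y_range) / resid_sd),
    rep(diff(link$y_range) / resid_sd / n_ispline_basis(link$nodes, link$degree),
        n_ispline_basis(link$nodes, link$degree))
  )
  tr <- transform_md(md, link)
  feat <- t(vapply(seq_len(md$n), function(i) {
    rows <- md$first[i] + seq_len(md$ni[i])
    cf <- stats::lm.fit(cbind(1, md$t[rows]), tr$h[rows])$coefficients
    c(cf[1], if (md$ni[i] > 1) cf[2] else 0)
  }, c(0, 0)))
  feat[!is.finite(feat)] <- 0

  if (G > 1) {
    km <- stats::kmeans(scale(feat), centers = G, nstart = 5)
    cl <- km$cluster
  } else {
    cl <- rep(1L, md$n)
  }
  beta <- matrix(0, G, 3)
  zeta <- matrix(0, G, 2)
  for (g in seq_len(G)) {
    rows <- which(md$group %in% which(cl == g))
    X <- cbind(1, md$t[rows], md$t[rows]^2)
    beta[g, ] <- tryCatch(stats::lm.fit(X, tr$h[rows])$coefficients,
                          error = function(e) c(mean(tr$h[rows]), 0, 0))
    beta[g, ][!is.finite(beta[g, ])] <- 0
    sub <- cl == g
    rate <- sum(md$dev[sub]) / sum(md$tev[sub] - md$entry[sub])
    overall <- sum(md$dev) / sum(md$tev - md$entry)
    zeta[g, ] <- c(max(rate, overall / 2, 1e-3), 1)
  }
  pg <- pmax(tabulate(cl, G) / md$n, 1 / (4 * md$n))
  xi <- if (G > 1) cbind(log(pg[-G] / pg[G]), matrix(0, G - 1, ncol(md$Xc)))
        else matrix(numeric(0), 0, 1 + ncol(md$Xc))
  B0 <- diag(c(max(stats::var(feat[, 1]) / 2, 0.05), max(stats::var(feat[, 2]) / 2, 0.02)))
  list(G = G, xi = xi, beta = beta, B = B0, sigma = 1, wg = rep(1, G),
       link = link, zeta = zeta,
       delta = stats::setNames(rep(0, ncol(md$Xs)), colnames(md$Xs)),
       classwise = isTRUE(tmpl$classwise))
}

# ---- class relabeling ------------------------------------------------------

# order classes by fitted mean latent creatinine at 18 months, ascending,
# so class 1 is always the best-function class
class_order <- function(params) {
  order(vapply(seq_len(params$G), function(g)
    class_mean_trajectory(params$beta[g, ], 1.5), 0))
}

permute_params <- function(params, perm) {
  G <- params$G
  if (identical(perm, seq_len(G))) return(params)
  out <- params
  out$beta <- params$beta[perm, , drop = FALSE]
  out$zeta <- params$zeta[perm, , drop = FALSE]
  wref <- params$wg[perm[G]]
  out$wg <- params$wg[perm] / wref
  out$B <- wref * params$B
  if (G > 1) {
    alpha <- rbind(params$xi, 0)
    out$xi <- alpha[perm[-G], , drop = FALSE] -
      matrix(alpha[perm[G], ], G - 1, ncol(alpha), byrow = TRUE)
  }
  out
}

# ---- fitting ---------------------------------------------------------------

#' Fit the joint latent class model
#'
#' Maximizes the joint likelihood (multinomial membership, class-specific
#' latent creatinine trajectories through a monotone link, class-specific
#' Weibull proportional hazards) by BFGS on an unconstrained
#' reparametrization: positive quantities are squares of free parameters and
#' the random-effect covariance is parametrized by its Cholesky factor. The
#' residual SD on the latent scale is fixed at 1 and the link carries no free
#' location, which identifies the latent scale. Classes are relabeled after
#' fitting so that class 1 has the lowest fitted 18-month creatinine.
#'
#' @param cohort A `graft_cohort`.
#' @param n_classes Number of latent classes G (1-5).
#' @param link_family Link family (see [make_link()]).
#' @param n_nodes Number of knots for spline links.
#' @param membership_covariates Subject columns entering the multinomial
#'   submodel.
#' @param hazard_covariates Subject columns entering the proportional-hazards
#'   submodel.
#' @param control A [jlcm_control()].
#' @param init Optional warm start: a parameter list or packed numeric vector.
#' @return A `graft_jlcm` object: estimates (`params`), unconstrained vector
#'   (`theta`), `loglik`, `vcov` (inverse observed information, unconstrained
#'   scale), `criteria` (AIC/BIC), posterior class matrix, modal classes, and
#'   convergence diagnostics.
#' @export
fit_jlcm <- function(cohort, n_classes, link_family = "ispline_equidistant",
                     n_nodes = 5, membership_covariates = "donor_age_ge60",
                     hazard_covariates = default_hazard_covariates(),
                     control = jlcm_control(), init = NULL) {
  stopifnot(inherits(cohort, "graft_cohort"), n_classes >= 1, n_classes <= 5)
  md <- make_model_data(cohort, link_family, n_nodes,
                        membership_covariates, hazard_covariates)
  tmpl <- params_template(md, n_classes, control$classwise_re_scale)

  negll <- function(th) {
    p <- tryCatch(unpack_params(th, tmpl), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    contrib <- joint_contrib_matrix(p, md)
    if (is.null(contrib)) return(1e10)
    ll <- sum(row_logsumexp(contrib))
    if (!is.finite(ll)) 1e10 else -ll
  }
  grad <- function(th) num_grad(negll, th, control$fd_step)

  runs <- with_seed(control$seed, {
    base <- if (is.null(init)) {
      pack_params(init_params(md, n_classes, tmpl))
    } else if (is.numeric(init)) init else pack_params(init)
    lapply(seq_len(control$n_starts), function(s) {
      th0 <- if (s == 1) base else
        base + stats::rnorm(length(base), 0, control$start_jitter * (abs(base) + 0.1))
      o <- tryCatch(
        stats::optim(th0, negll, grad, method = "BFGS",
                     control = list(maxit = control$maxit, reltol = control$reltol,
                                    trace = control$trace)),
        error = function(e) list(value = Inf, convergence = 99L, message = conditionMessage(e))
      )
      o$start <- s
      o
    })
  })
  vals <- vapply(runs, function(o) o$value, 0)
  if (all(!is.finite(vals) | vals >= 1e10)) {
    stop("no start converged to a finite likelihood; per-start values: ",
         paste(format(vals), collapse = ", "), call. = FALSE)
  }
  best <- runs[[which.min(vals)]]

  params <- unpack_params(best$par, tmpl)
  params <- permute_params(params, class_order(params))
  theta <- pack_params(params)
  # repacking after relabeling keeps the optimum (likelihood is label-invariant)
  loglik <- -negll(theta)
  gnorm <- max(abs(grad(theta)))

  vcov <- NULL
  vcov_ok <- FALSE
  if (isTRUE(control$hessian)) {
    H <- tryCatch(pracma::hessian(negll, theta), error = function(e) NULL)
    if (!is.null(H)) {
      H <- (H + t(H)) / 2
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(is.finite(V)) && all(diag(V) > 0)) {
        vcov <- (V + t(V)) / 2
        vcov_ok <- TRUE
      }
    }
    if (!vcov_ok) warning("observed information not invertible; vcov unavailable")
  }

  np <- length(theta)
  N <- md$n
  fit <- structure(list(
    params = params, theta = theta, loglik = loglik,
    vcov = vcov, vcov_ok = vcov_ok, n_params = np,
    criteria = list(AIC = -2 * loglik + 2 * np,
                    BIC = -2 * loglik + np * log(N)),
    n_subjects = N, n_classes = n_classes,
    cohort = cohort,
    membership_covariates = membership_covariates,
    hazard_covariates = hazard_covariates,
    convergence = list(
      status = if (best$convergence == 0 || gnorm <= control$grad_tol) "converged" else "maxit",
      optim_code = best$convergence, n_iter = unname(best$counts["function"]),
      grad_norm = gnorm, starts_tried = control$n_starts,
      start_values = vals, best_start = best$start, seed = control$seed
    ),
    control = control
  ), class = "graft_jlcm")
  pc <- posterior_classification(fit)
  fit$posterior <- pc$posterior
  fit$modal_class <- pc$modal_class
  fit
}

#' @export
print.graft_jlcm <- function(x, ...) {
  cat("<graft_jlcm> G =", x$n_classes, "classes,", x$n_subjects, "subjects, link:",
      x$params$link$family, "\n")
  cat("  logLik:", format(x$loglik, digits = 8),
      " AIC:", format(x$criteria$AIC, digits = 8),
      " BIC:", format(x$criteria$BIC, digits = 8), "\n")
  cat("  class sizes (modal):", paste(tabulate(x$modal_class, x$n_classes), collapse = "/"),
      " convergence:", x$convergence$status, "\n")
  invisible(x)
}

#' Posterior class membership
#'
#' Bayes' rule over prior membership, longitudinal density, and the event
#' contribution; also reports the mean posterior probability within each
#' modally assigned class (the model's discrimination summary).
#'
#' @param fit A `graft_jlcm`.
#' @param cohort Optional cohort (defaults to the training cohort).
#' @return List with `posterior` (tibble `subject_id`, `p1..pG`, `modal`),
#'   `modal_class` (integer vector), and `summary` (per assigned class: size,
#'   proportion, mean posterior probability).
#' @export
posterior_classification <- function(fit, cohort = NULL) {
  cohort <- cohort %||% fit$cohort
  params <- fit$params
  md <- make_model_data(cohort,
                        membership_covariates = fit$membership_covariates,
                        hazard_covariates = fit$hazard_covariates,
                        link = params$link)
  contrib <- joint_contrib_matrix(params, md)
  lse <- row_logsumexp(contrib)
  post <- exp(contrib - lse)
  modal <- max.col(post, ties.method = "first")
  ptib <- tibble::as_tibble(as.data.frame(post, col.names = paste0("p", seq_len(params$G))))
  names(ptib) <- paste0("p", seq_len(params$G))
  ptib <- dplyr::bind_cols(tibble::tibble(subject_id = md$subjects$subject_id), ptib)
  ptib$modal <- modal
  summary <- tibble::tibble(
    class = seq_len(params$G),
    n = tabulate(modal, params$G),
    proportion = tabulate(modal, params$G) / md$n,
    mean_posterior = vapply(seq_len(params$G), function(g) {
      if (any(modal == g)) mean(post[modal == g, g]) else NA_real_
    }, 0)
  )
  list(posterior = ptib, modal_class = modal, summary = summary)
}

#' Fit a range of class counts and select by BIC
#'
#' @param cohort A `graft_cohort`.
#' @param G_range Integer vector of class counts to try.
#' @param ... Passed to [fit_jlcm()].
#' @param keep_fits Keep the fitted models (default `TRUE`).
#' @return List with `criteria` (tibble of G, loglik, n_params, AIC, BIC),
#'   `chosen_G` (minimal BIC), and `fits`.
#' @export
select_n_classes <- function(cohort, G_range = 1:5, ..., keep_fits = TRUE) {
  fits <- lapply(G_range, function(G) fit_jlcm(cohort, G, ...))
  criteria <- tibble::tibble(
    G = as.integer(G_range),
    loglik = vapply(fits, function(f) f$loglik, 0),
    n_params = vapply(fits, function(f) f$n_params, 0L),
    AIC = vapply(fits, function(f) f$criteria$AIC, 0),
    BIC = vapply(fits, function(f) f$criteria$BIC, 0)
  )
  chosen <- G_range[which.min(criteria$BIC)]
  list(criteria = criteria, chosen_G = chosen,
       fits = if (keep_fits) stats::setNames(fits, paste0("G", G_range)))
}

#' Hazard-ratio table of a fitted joint model
#'
#' Wald hazard ratios, confidence intervals and p-values for the
#' proportional-hazards coefficients (common across classes).
#'
#' @param fit A `graft_jlcm` with a valid variance matrix.
#' @param level Confidence level.
#' @return Tibble as in [hazard_ratio_table()].
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  if (!fit$vcov_ok) stop("fit has no variance matrix; refit with hessian = TRUE", call. = FALSE)
  idx <- delta_index(fit)
  hazard_ratio_table(fit$params$delta, fit$vcov[idx, idx, drop = FALSE], level)
}

# positions of delta inside the packed parameter vector
delta_index <- function(fit) {
  np <- fit$n_params
  ps <- length(fit$params$delta)
  (np - ps + 1L):np
}
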