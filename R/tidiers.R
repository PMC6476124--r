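#' Tidy a fitted joint latent class model
#'
#' One row per parameter on the natural scale, grouped by submodel
#' (`membership`, `trajectory`, `random_effects`, `link`, `baseline_risk`,
#' `hazard`). Standard errors are delta-method transforms of the
#' unconstrained-scale variance matrix (diagonal only); they are `NA` when
#' the fit carries no variance matrix.
#'
#' @param x A `graft_jlcm`.
#' @param ... Unused.
#' @return A tibble with `submodel`, `term`, `class`, `estimate`,
#'   `std.error`.
#' @export
tidy.graft_jlcm <- function(x, ...) {
  p <- x$params
  G <- p$G
  th <- x$theta
  se_th <- if (x$vcov_ok) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, length(th))

  rows <- list()
  pos <- 0L
  push <- function(submodel, term, class, est, se) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      submodel = submodel, term = term, class = class, estimate = est, std.error = se)
  }
  if (G > 1) {
    nm <- c("(Intercept)", x$membership_covariates)
    for (g in seq_len(G - 1)) {
      for (j in seq_along(nm)) {
        pos <- pos + 1L
        push("membership", nm[j], g, p$xi[g, j], se_th[pos])
      }
    }
  }
  tn <- c("(Intercept)", "t", "t^2")
  for (g in seq_len(G)) {
    for (j in 1:3) {
      pos <- pos + 1L
      push("trajectory", tn[j], g, p$beta[g, j], se_th[pos])
    }
  }
  # Cholesky entries: report implied variances/covariance, SE on raw entries
  for (nmv in c("chol11", "chol12", "chol22")) {
    pos <- pos + 1L
    push("random_effects", nmv, NA_integer_, th[pos], se_th[pos])
  }
  if (isTRUE(p$classwise) && G > 1) {
    for (g in seq_len(G - 1)) {
      pos <- pos + 1L
      push("random_effects", "re_scale", g, p$wg[g], 2 * abs(th[pos]) * se_th[pos])
    }
  }
  for (j in seq_along(p$link$eta)) {
    pos <- pos + 1L
    push("link", paste0("eta", j), NA_integer_, p$link$eta[j], 2 * abs(th[pos]) * se_th[pos])
  }
  for (g in seq_len(G)) {
    for (j in 1:2) {
      pos <- pos + 1L
      push("baseline_risk", paste0("zeta", j), g, p$zeta[g, j], 2 * abs(th[pos]) * se_th[pos])
    }
  }
  for (j in seq_along(p$delta)) {
    pos <- pos + 1L
    push("hazard", names(p$delta)[j], NA_integer_, p$delta[j], se_th[pos])
  }
  dplyr::bind_rows(rows)
}

#' Glance at a fitted joint latent class model
#'
#' @param x A `graft_jlcm`.
#' @param ... Unused.
#' @return One-row tibble with fit summaries.
#' @export
glance.graft_jlcm <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_classes = x$n_classes,
    logLik = x$loglik,
    AIC = x$criteria$AIC,
    BIC = x$criteria$BIC,
    n_params = x$n_params,
    link = x$params$link$family,
    converged = identical(x$convergence$status, "converged")
  )
}
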