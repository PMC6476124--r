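#' Class-membership probabilities from the multinomial logistic submodel
#'
#' The last class is the reference (its coefficients are fixed at zero).
#'
#' @param xi Coefficient matrix with `G - 1` rows and `1 + p` columns
#'   (intercept first, then one column per membership covariate). May be an
#'   empty matrix when `G = 1`.
#' @param x_c Numeric vector of membership covariate values for one subject
#'   (length `p`, possibly length 0).
#' @param G Number of latent classes.
#' @return Probability vector of length `G`, summing to 1.
#' @export
#' @examples
#' membership_probs(matrix(c(0.5, -0.2), 2, 1), numeric(0), G = 3)
membership_probs <- function(xi, x_c, G) {
  if (G == 1) return(1)
  xi <- as.matrix(xi)
  if (nrow(xi) != G - 1) stop("`xi` must have G - 1 rows", call. = FALSE)
  if (ncol(xi) != 1 + length(x_c)) stop("`xi` must have 1 + length(x_c) columns", call. = FALSE)
  a <- c(as.numeric(xi %*% c(1, x_c)), 0)
  e <- exp(a - max(a))
  e / sum(e)
}

# log membership probabilities for a whole design matrix (n x p, no intercept)
membership_logprobs_matrix <- function(xi, Xc, G) {
  n <- nrow(Xc)
  if (G == 1) return(matrix(0, n, 1))
  A <- cbind(1, Xc) %*% t(as.matrix(xi))
  A <- cbind(A, 0)
  A - apply(A, 1L, logsumexp)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp without per-row apply overhead
row_logsumexp <- function(mat) {
  m <- mat[, 1]
  if (ncol(mat) > 1) for (g in 2:ncol(mat)) m <- pmax(m, mat[, g])
  m + log(rowSums(exp(mat - m)))
}

#' Class-specific mean latent trajectory
#'
#' Quadratic polynomial in time since transplantation:
#' `mu_g(t) = beta0 + beta1 t + beta2 t^2`, on the latent (transformed) scale.
#'
#' @param beta_g Numeric vector `(beta0, beta1, beta2)`.
#' @param t_grid Numeric vector of times (years).
#' @return Numeric vector of latent means.
#' @export
class_mean_trajectory <- function(beta_g, t_grid) {
  stopifnot(length(beta_g) == 3)
  beta_g[1] + beta_g[2] * t_grid + beta_g[3] * t_grid^2
}

#' Longitudinal log-density of one subject's measurements given a class
#'
#' Multivariate-normal log-density of the link-transformed measurements with
#' mean `X beta_g` (quadratic time trend) and covariance
#' `Z B Z' + sigma^2 I` (random intercept and slope), plus the sum of the
#' link's log-Jacobians so the density is on the observed creatinine scale.
#'
#' @param measurements Tibble/data frame with columns `time_years` and
#'   `scr_umol_l` (at least one row).
#' @param beta_g Fixed effects `(intercept, slope, quadratic)` for the class.
#' @param B 2x2 random-effect covariance (intercept, slope); PSD.
#' @param sigma Residual SD on the transformed scale.
#' @param link A [make_link()] specification.
#' @param jitter Ridge added to the covariance diagonal if it is numerically
#'   singular (logged via a message).
#' @return Scalar log-density.
#' @export
longitudinal_loglik_given_class <- function(measurements, beta_g, B, sigma, link,
                                            jitter = 1e-8) {
  t <- measurements$time_years
  if (!length(t)) stop("subject has no measurements", call. = FALSE)
  tr <- link_transform(measurements$scr_umol_l, link)
  Z <- cbind(1, t)
  V <- Z %*% B %*% t(Z) + diag(sigma^2, length(t))
  L <- tryCatch(chol(V), error = function(e) {
    message("longitudinal covariance numerically singular; adding ridge ", jitter)
    chol(V + diag(jitter, length(t)))
  })
  r <- tr$h - class_mean_trajectory(beta_g, t)
  u <- backsolve(L, r, transpose = TRUE)
  -0.5 * length(t) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(u^2) + sum(tr$log_jacobian)
}
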