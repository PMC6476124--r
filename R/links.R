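#' Place knots for a spline link on the creatinine scale
#'
#' Boundary knots always sit at the data minimum and maximum; interior knots
#' are spaced either evenly (`equidistant`) or at equally spaced quantiles of
#' the observed distribution (`quantile`).
#'
#' @param values Numeric vector of observed creatinine values (µmol/L).
#' @param n_nodes Total number of knots including both boundaries (>= 2).
#' @param mode `"equidistant"` or `"quantile"`.
#' @return Numeric vector of strictly increasing knot locations.
#' @export
#' @examples
#' make_nodes(c(50, 120, 550), n_nodes = 5)
make_nodes <- function(values, n_nodes = 5, mode = c("equidistant", "quantile")) {
  mode <- match.arg(mode)
  if (n_nodes < 2) stop("`n_nodes` must be at least 2", call. = FALSE)
  values <- values[is.finite(values)]
  r <- range(values)
  if (diff(r) <= 0) stop("degenerate support: all values are identical", call. = FALSE)
  nodes <- if (mode == "equidistant") {
    seq(r[1], r[2], length.out = n_nodes)
  } else {
    q <- unname(stats::quantile(values, probs = seq(0, 1, length.out = n_nodes), type = 7))
    q[1] <- r[1]
    q[n_nodes] <- r[2]
    q
  }
  if (any(diff(nodes) <= 0)) {
    stop("knots are not strictly increasing (ties in the requested quantiles)", call. = FALSE)
  }
  nodes
}

#' Quadratic I-spline and M-spline bases
#'
#' I-splines are the running integrals of normalized M-splines; a linear
#' combination with positive weights is therefore nondecreasing, which is what
#' makes them suitable as a monotone transformation of the biomarker. Values
#' outside the knot span are clamped to the boundaries, where every I-spline
#' equals 0 (lower) or 1 (upper).
#'
#' @param y Numeric vector of evaluation points (creatinine scale).
#' @param nodes Knot vector from [make_nodes()]; first and last entries are the
#'   support boundaries.
#' @param degree Polynomial degree of the underlying M-splines (2 = quadratic).
#' @return Matrix with `length(y)` rows and `degree + length(nodes) - 1`
#'   columns; each column is one I-spline, nondecreasing in `y` with values in
#'   \[0, 1\].
#' @export
ispline_basis <- function(y, nodes, degree = 2) {
  k <- degree + 1L # spline order
  ymin <- nodes[1]
  ymax <- nodes[length(nodes)]
  y <- pmin(pmax(y, ymin), ymax)
  interior <- nodes[-c(1L, length(nodes))]
  aug <- c(rep(ymin, k + 1L), interior, rep(ymax, k + 1L))
  b <- splines::splineDesign(aug, y, ord = k + 1L)
  nb <- ncol(b) - 1L
  out <- matrix(0, length(y), nb)
  # I_i(y) = sum of order-(k+1) B-splines from index i+1 upward
  acc <- b[, nb + 1L]
  for (i in nb:1L) {
    out[, i] <- acc
    if (i > 1L) acc <- acc + b[, i]
  }
  out
}

#' @rdname ispline_basis
#' @details `mspline_basis()` returns the corresponding M-spline (density-like)
#'   basis, i.e. the derivative of `ispline_basis()` column by column.
#' @export
mspline_basis <- function(y, nodes, degree = 2) {
  k <- degree + 1L
  ymin <- nodes[1]
  ymax <- nodes[length(nodes)]
  y <- pmin(pmax(y, ymin), ymax)
  interior <- nodes[-c(1L, length(nodes))]
  aug <- c(rep(ymin, k), interior, rep(ymax, k))
  b <- splines::splineDesign(aug, y, ord = k)
  denom <- aug[seq_len(ncol(b)) + k] - aug[seq_len(ncol(b))]
  sweep(b, 2L, k / denom, `*`)
}

n_ispline_basis <- function(nodes, degree = 2) degree + length(nodes) - 1L

#' Construct a link specification
#'
#' The link is a strictly increasing map H(y; eta) from observed serum
#' creatinine to the latent Gaussian scale on which the mixed model operates.
#' Four families are supported: `linear` (affine map, one free scale), a
#' rescaled `beta_cdf`, and quadratic I-splines with `equidistant` or
#' `quantile` knots. The residual standard deviation on the latent scale is
#' fixed at 1 for identifiability, and the link carries no free location (its
#' value at the lower support bound is 0); class-specific intercepts of the
#' latent process absorb location.
#'
#' @param family One of `"linear"`, `"beta_cdf"`, `"ispline_equidistant"`,
#'   `"ispline_quantile"`.
#' @param values Observed creatinine values used to place knots and the support
#'   bounds (required unless `nodes` and `y_range` are both given).
#' @param n_nodes Number of knots for the spline families (default 5, the
#'   retained configuration).
#' @param eta Transformation coefficients on the natural scale: `linear` a
#'   single positive scale; `beta_cdf` two positive shapes and a positive
#'   scale; spline families one positive weight per basis function. Defaults
#'   give an identity-like starting link.
#' @param y_range Support bounds `(y_min, y_max)`; defaults to the data range.
#' @param nodes Optional explicit knot vector (spline families).
#' @return A `link_spec` object.
#' @export
make_link <- function(family = c("ispline_equidistant", "ispline_quantile", "linear", "beta_cdf"),
                      values = NULL, n_nodes = 5, eta = NULL, y_range = NULL, nodes = NULL) {
  family <- match.arg(family)
  if (is.null(y_range)) {
    if (is.null(values) && !is.null(nodes)) {
      y_range <- range(nodes)
    } else {
      if (is.null(values)) stop("either `values` or `y_range` must be supplied", call. = FALSE)
      y_range <- range(values, na.rm = TRUE)
    }
  }
  if (diff(y_range) <= 0) stop("`y_range` must have positive width", call. = FALSE)
  if (family %in% c("ispline_equidistant", "ispline_quantile")) {
    if (is.null(nodes)) {
      mode <- if (family == "ispline_equidistant") "equidistant" else "quantile"
      if (is.null(values)) {
        if (mode == "quantile") stop("quantile knots need `values`", call. = FALSE)
        nodes <- seq(y_range[1], y_range[2], length.out = n_nodes)
      } else {
        nodes <- make_nodes(values, n_nodes, mode)
      }
    }
    nodes[1] <- y_range[1]
    nodes[length(nodes)] <- y_range[2]
    nb <- n_ispline_basis(nodes)
    if (is.null(eta)) eta <- rep(diff(y_range) / stats::sd(if (is.null(values)) nodes else values) / nb, nb)
    if (length(eta) != nb) stop("spline link needs ", nb, " positive weights", call. = FALSE)
    if (any(eta <= 0)) stop("spline basis weights must be positive", call. = FALSE)
  } else if (family == "beta_cdf") {
    if (is.null(eta)) eta <- c(1, 1, diff(y_range) / stats::sd(if (is.null(values)) y_range else values))
    if (length(eta) != 3 || any(eta <= 0)) {
      stop("beta_cdf link needs positive (shape1, shape2, scale)", call. = FALSE)
    }
    nodes <- NULL
  } else { # linear
    if (is.null(eta)) eta <- if (is.null(values)) 1 else stats::sd(values)
    if (length(eta) != 1 || eta <= 0) stop("linear link needs one positive scale", call. = FALSE)
    nodes <- NULL
  }
  structure(
    list(family = family, nodes = nodes, eta = as.numeric(eta),
         y_range = as.numeric(y_range), degree = 2L),
    class = "link_spec"
  )
}

#' @export
print.link_spec <- function(x, ...) {
  cat("<link_spec> family:", x$family,
      " support: [", format(x$y_range[1]), ",", format(x$y_range[2]), "]\n")
  if (!is.null(x$nodes)) cat("  nodes:", paste(format(x$nodes, digits = 4), collapse = " "), "\n")
  cat("  eta:", paste(format(x$eta, digits = 4), collapse = " "), "\n")
  invisible(x)
}

n_link_params <- function(link) {
  switch(link$family,
    linear = 1L,
    beta_cdf = 3L,
    n_ispline_basis(link$nodes, link$degree)
  )
}

clamp01 <- function(u, eps = 1e-12) pmin(pmax(u, eps), 1 - eps)

#' Transform creatinine to the latent scale
#'
#' @param y Numeric vector of creatinine values; values outside the link
#'   support are clamped to the boundaries.
#' @param link A [make_link()] specification.
#' @return A list with `h` (transformed values) and `log_jacobian`
#'   (`log dH/dy`, one entry per observation).
#' @export
link_transform <- function(y, link) {
  switch(link$family,
    linear = {
      b <- link$eta[1]
      list(h = y / b, log_jacobian = rep(-log(b), length(y)))
    },
    beta_cdf = {
      a <- link$eta[1]; b <- link$eta[2]; s <- link$eta[3]
      w <- diff(link$y_range)
      u <- clamp01((y - link$y_range[1]) / w)
      list(
        h = s * stats::pbeta(u, a, b),
        log_jacobian = log(s) + stats::dbeta(u, a, b, log = TRUE) - log(w)
      )
    },
    {
      iB <- ispline_basis(y, link$nodes, link$degree)
      mB <- mspline_basis(y, link$nodes, link$degree)
      list(
        h = as.numeric(iB %*% link$eta),
        log_jacobian = log(as.numeric(mB %*% link$eta))
      )
    }
  )
}

#' Map latent values back to the creatinine scale
#'
#' Inverts the monotone link; closed form for the linear and beta-CDF
#' families, bisection (via [stats::uniroot()]) for the spline families.
#' Latent values outside the achievable range are clamped to the support
#' bounds with a warning.
#'
#' @param h Numeric vector on the latent scale.
#' @param link A [make_link()] specification.
#' @return Numeric vector of creatinine values.
#' @export
link_inverse <- function(h, link) {
  switch(link$family,
    linear = h * link$eta[1],
    beta_cdf = {
      a <- link$eta[1]; b <- link$eta[2]; s <- link$eta[3]
      u <- h / s
      if (any(u < -1e-9 | u > 1 + 1e-9)) {
        warning("latent values outside achievable range; clamped to support bounds")
      }
      link$y_range[1] + stats::qbeta(clamp01(u, 0), a, b) * diff(link$y_range)
    },
    {
      lo <- link$y_range[1]; hi <- link$y_range[2]
      hmax <- sum(link$eta)
      out <- numeric(length(h))
      clamped <- FALSE
      for (i in seq_along(h)) {
        if (h[i] <= 0) { out[i] <- lo; clamped <- clamped || h[i] < -1e-9; next }
        if (h[i] >= hmax) { out[i] <- hi; clamped <- clamped || h[i] > hmax + 1e-9; next }
        f <- function(y) as.numeric(ispline_basis(y, link$nodes, link$degree) %*% link$eta) - h[i]
        out[i] <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
      }
      if (clamped) warning("latent values outside achievable range; clamped to support bounds")
      out
    }
  )
}
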