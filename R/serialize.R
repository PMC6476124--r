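JLCM_SCHEMA_VERSION <- "1.0"

#' Serialize a fitted joint model to JSON
#'
#' Versioned JSON document carrying every parameter (natural and
#' unconstrained scale), the variance matrix, link specification, fit
#' criteria and convergence record; numbers are written with 17 significant
#' digits so that `deserialize_model(serialize_model(fit))` restores the
#' parameters bit for bit. The training data are not embedded.
#'
#' @param fit A `graft_jlcm`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
serialize_model <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "graft_jlcm"))
  p <- fit$params
  doc <- list(
    schema = "graftjlcm/model",
    schema_version = JLCM_SCHEMA_VERSION,
    n_classes = fit$n_classes,
    n_subjects = fit$n_subjects,
    params = list(
      xi = unclass_matrix(p$xi), beta = unclass_matrix(p$beta),
      B = unclass_matrix(p$B), sigma = p$sigma, wg = p$wg,
      link = list(family = p$link$family, nodes = p$link$nodes,
                  eta = p$link$eta, y_range = p$link$y_range,
                  degree = p$link$degree),
      zeta = unclass_matrix(p$zeta),
      delta = as.list(p$delta)
    ),
    membership_covariates = fit$membership_covariates,
    hazard_covariates = fit$hazard_covariates,
    theta = fit$theta,
    vcov = if (fit$vcov_ok) unclass_matrix(fit$vcov),
    loglik = fit$loglik, n_params = fit$n_params,
    criteria = fit$criteria,
    convergence = fit$convergence
  )
  js <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

unclass_matrix <- function(m) {
  if (is.null(m) || !length(m)) return(list(nrow = NROW(m), ncol = NCOL(m), data = numeric(0)))
  list(nrow = nrow(m), ncol = ncol(m), data = as.numeric(t(m)))
}

reclass_matrix <- function(x) {
  matrix(as.numeric(unlist(x$data)), x$nrow, x$ncol, byrow = TRUE)
}

#' @rdname serialize_model
#' @param json JSON string or path to a JSON file.
#' @return `deserialize_model()`: a `graft_jlcm` (without the training
#'   cohort attached; supply one to [posterior_classification()] etc.).
#' @export
deserialize_model <- function(json) {
  txt <- if (length(json) == 1 && file.exists(json)) paste(readLines(json), collapse = "\n") else json
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model document: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$schema) || !identical(doc$schema, "graftjlcm/model")) {
    stop("not a graftjlcm model document", call. = FALSE)
  }
  if (!identical(doc$schema_version, JLCM_SCHEMA_VERSION)) {
    stop("model document schema version ", doc$schema_version,
         " is not supported (expected ", JLCM_SCHEMA_VERSION, ")", call. = FALSE)
  }
  lk <- doc$params$link
  link <- structure(list(family = lk$family,
                         nodes = if (!is.null(lk$nodes)) as.numeric(lk$nodes),
                         eta = as.numeric(lk$eta),
                         y_range = as.numeric(lk$y_range),
                         degree = as.integer(lk$degree)), class = "link_spec")
  params <- list(
    G = doc$n_classes,
    xi = reclass_matrix(doc$params$xi), beta = reclass_matrix(doc$params$beta),
    B = reclass_matrix(doc$params$B), sigma = doc$params$sigma,
    wg = as.numeric(doc$params$wg), link = link,
    zeta = reclass_matrix(doc$params$zeta),
    delta = unlist(doc$params$delta),
    membership_covariates = doc$membership_covariates,
    hazard_covariates = doc$hazard_covariates
  )
  structure(list(
    params = params, theta = as.numeric(doc$theta), loglik = doc$loglik,
    vcov = if (!is.null(doc$vcov)) reclass_matrix(doc$vcov),
    vcov_ok = !is.null(doc$vcov), n_params = doc$n_params,
    criteria = doc$criteria, n_subjects = doc$n_subjects,
    n_classes = doc$n_classes, cohort = NULL,
    membership_covariates = doc$membership_covariates,
    hazard_covariates = doc$hazard_covariates,
    convergence = doc$convergence,
    control = jlcm_control()
  ), class = "graft_jlcm")
}
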