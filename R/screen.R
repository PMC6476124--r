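#' Screen candidate hazard covariates
#'
#' Stepwise convenience mirroring classical covariate selection: each
#' candidate is first entered alone in the proportional-hazards submodel
#' (univariate Wald p-value), candidates passing `p_enter` are then fitted
#' jointly (multivariate Wald p-values). Every step refits the full joint
#' model, so this is intended for moderate cohort sizes; the retained
#' clinical covariate set is also available directly as
#' [default_hazard_covariates()] without screening.
#'
#' @param cohort A `graft_cohort`.
#' @param candidates Character vector of subject columns to screen.
#' @param n_classes Number of latent classes during screening.
#' @param p_enter Univariate entry threshold (default 0.2).
#' @param link_family,control Passed to [fit_jlcm()].
#' @return List with `univariate` (term, estimate, p.value, entered),
#'   `multivariate` (Wald table of the joint fit), and `retained`.
#' @export
screen_covariates <- function(cohort, candidates, n_classes = 1, p_enter = 0.2,
                              link_family = "linear",
                              control = jlcm_control(n_starts = 1, maxit = 200)) {
  uni <- dplyr::bind_rows(lapply(candidates, function(v) {
    f <- fit_jlcm(cohort, n_classes, link_family = link_family,
                  hazard_covariates = v, control = control)
    tab <- hazard_ratios(f)
    tibble::tibble(term = v, estimate = tab$estimate, hr = tab$hr, p.value = tab$p.value)
  }))
  uni$entered <- uni$p.value < p_enter
  entered <- uni$term[uni$entered]
  multivariate <- NULL
  if (length(entered)) {
    fm <- fit_jlcm(cohort, n_classes, link_family = link_family,
                   hazard_covariates = entered, control = control)
    multivariate <- hazard_ratios(fm)
  }
  list(univariate = uni, multivariate = multivariate, retained = entered)
}
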