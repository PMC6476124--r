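#' Assemble and validate a transplant cohort
#'
#' A cohort pairs one-row-per-subject covariate/outcome records with
#' long-format serum-creatinine measurements. Times are years since
#' transplantation; creatinine is in µmol/L. Invariants enforced:
#' positive creatinine, finite nonnegative measurement times, unique
#' (subject, time) pairs, `event_time > entry_time`, a dnDSA onset time
#' present exactly when `dndsa == 1`, every measurement attached to a known
#' subject and every subject carrying at least one measurement.
#'
#' @param subjects Tibble with columns `subject_id`, `donor_age_ge60`,
#'   `ndsa_pre`, `proteinuria_m12` (g/L, may be `NA`), `acute_rejection`,
#'   `ar_time`, `dndsa`, `dndsa_time`, `entry_time`, `event_time`, `event`.
#'   A `prot_gt_0275` column is derived if absent.
#' @param measurements Tibble with columns `subject_id`, `time_years`,
#'   `scr_umol_l`.
#' @param proteinuria_threshold Dichotomization cut point for month-12
#'   proteinuria in g/L (default 0.275).
#' @param min_followup Minimum follow-up (years) required for inclusion.
#' @param apply_min_followup If `TRUE` (default), subjects with
#'   `event_time - entry_time < min_followup` are excluded with a message;
#'   if `FALSE` they are kept (e.g. for prediction-only cohorts).
#' @return A `graft_cohort` object: list with tibbles `subjects` and
#'   `measurements`.
#' @export
graft_cohort <- function(subjects, measurements, proteinuria_threshold = 0.275,
                         min_followup = 1, apply_min_followup = TRUE) {
  subjects <- tibble::as_tibble(subjects)
  measurements <- tibble::as_tibble(measurements)

  need_s <- c("subject_id", "donor_age_ge60", "ndsa_pre", "proteinuria_m12",
              "acute_rejection", "dndsa", "entry_time", "event_time", "event")
  need_m <- c("subject_id", "time_years", "scr_umol_l")
  miss_s <- setdiff(need_s, names(subjects))
  miss_m <- setdiff(need_m, names(measurements))
  if (length(miss_s)) stop("subject table is missing column(s): ",
                           paste(miss_s, collapse = ", "), call. = FALSE)
  if (length(miss_m)) stop("measurement table is missing column(s): ",
                           paste(miss_m, collapse = ", "), call. = FALSE)
  if (!"ar_time" %in% names(subjects)) subjects$ar_time <- NA_real_
  if (!"dndsa_time" %in% names(subjects)) subjects$dndsa_time <- NA_real_

  if (!"prot_gt_0275" %in% names(subjects)) {
    n_missing <- sum(is.na(subjects$proteinuria_m12))
    subjects$prot_gt_0275 <- as.integer(
      !is.na(subjects$proteinuria_m12) &
        subjects$proteinuria_m12 > proteinuria_threshold
    )
    if (n_missing > 0) {
      message(n_missing, " subject(s) have missing month-12 proteinuria; ",
              "dichotomized covariate imputed to 0 for them")
    }
  }
  subjects$dndsa_x_ar <- as.integer(subjects$dndsa == 1 & subjects$acute_rejection == 1)

  problems <- validate_graft_cohort(subjects, measurements)
  if (nrow(problems)) {
    stop("cohort validation failed:\n",
         paste(utils::capture.output(print(problems, n = 20)), collapse = "\n"),
         call. = FALSE)
  }

  if (apply_min_followup) {
    short <- subjects$event_time - subjects$entry_time < min_followup
    if (any(short)) {
      message("excluding ", sum(short), " subject(s) with follow-up shorter than ",
              min_followup, " year(s)")
      subjects <- subjects[!short, ]
      measurements <- measurements[measurements$subject_id %in% subjects$subject_id, ]
    }
  }

  structure(
    list(subjects = subjects,
         measurements = dplyr::arrange(measurements, .data$subject_id, .data$time_years)),
    class = "graft_cohort",
    min_followup = min_followup,
    proteinuria_threshold = proteinuria_threshold
  )
}

#' Validate cohort invariants without failing
#'
#' @param subjects,measurements As in [graft_cohort()].
#' @return Tibble of problems (`table`, `subject_id`, `issue`), zero rows when
#'   everything is valid.
#' @export
validate_graft_cohort <- function(subjects, measurements) {
  p <- list()
  bad <- function(tab, id, issue) tibble::tibble(table = tab, subject_id = as.character(id), issue = issue)

  m <- measurements
  if (nrow(m)) {
    i <- !is.finite(m$time_years) | m$time_years < 0
    if (any(i)) p[[length(p) + 1L]] <- bad("measurements", m$subject_id[i], "time_years not finite and >= 0")
    i <- !is.finite(m$scr_umol_l) | m$scr_umol_l <= 0
    if (any(i)) p[[length(p) + 1L]] <- bad("measurements", m$subject_id[i], "scr_umol_l not positive")
    dup <- duplicated(m[, c("subject_id", "time_years")])
    if (any(dup)) p[[length(p) + 1L]] <- bad("measurements", m$subject_id[dup], "duplicate (subject_id, time_years)")
    orphan <- !m$subject_id %in% subjects$subject_id
    if (any(orphan)) p[[length(p) + 1L]] <- bad("measurements", unique(m$subject_id[orphan]), "subject_id not in subject table")
  }

  s <- subjects
  if (nrow(s)) {
    if (anyDuplicated(s$subject_id)) {
      p[[length(p) + 1L]] <- bad("subjects", s$subject_id[duplicated(s$subject_id)], "duplicate subject_id")
    }
    i <- !is.finite(s$entry_time) | s$entry_time < 0
    if (any(i)) p[[length(p) + 1L]] <- bad("subjects", s$subject_id[i], "entry_time not finite and >= 0")
    i <- !is.finite(s$event_time) | s$event_time <= s$entry_time
    if (any(i)) p[[length(p) + 1L]] <- bad("subjects", s$subject_id[i], "event_time must exceed entry_time")
    for (col in c("donor_age_ge60", "ndsa_pre", "acute_rejection", "dndsa", "event")) {
      i <- !s[[col]] %in% c(0, 1)
      if (any(i)) p[[length(p) + 1L]] <- bad("subjects", s$subject_id[i], paste0(col, " must be 0/1"))
    }
    i <- (s$dndsa == 1) != (!is.na(s$dndsa_time))
    if (any(i)) p[[length(p) + 1L]] <- bad("subjects", s$subject_id[i], "dndsa_time must be present iff dndsa == 1")
    i <- !is.na(s$proteinuria_m12) & s$proteinuria_m12 < 0
    if (any(i)) p[[length(p) + 1L]] <- bad("subjects", s$subject_id[i], "proteinuria_m12 must be >= 0")
    nomeas <- !s$subject_id %in% measurements$subject_id
    if (any(nomeas)) p[[length(p) + 1L]] <- bad("subjects", s$subject_id[nomeas], "subject has no measurements")
  }

  if (length(p)) dplyr::bind_rows(p) else
    tibble::tibble(table = character(), subject_id = character(), issue = character())
}

#' Read a cohort from two CSV files
#'
#' Longitudinal CSV columns: `subject_id,time_years,scr_umol_l`. Subject CSV
#' columns: `subject_id,donor_age,ndsa_pre,proteinuria_m12,acute_rejection,`
#' `ar_time,dndsa,dndsa_time,entry_time,event_time,event` (either `donor_age`
#' in years or an already dichotomized `donor_age_ge60` is accepted). When a
#' subject's month-12 proteinuria is missing and `proteinuria_backfill` is
#' `TRUE`, the first creatinine-visit-aligned proteinuria value observed in
#' (12, 18\] months is used if a `proteinuria` column is present in the
#' longitudinal file; any residual missingness dichotomizes to 0 with a
#' message.
#'
#' @param long_csv,subject_csv File paths.
#' @param proteinuria_backfill Backfill missing month-12 proteinuria from the
#'   longitudinal file (default `TRUE`).
#' @inheritParams graft_cohort
#' @return A `graft_cohort`.
#' @export
read_graft_cohort <- function(long_csv, subject_csv, proteinuria_threshold = 0.275,
                              min_followup = 1, apply_min_followup = TRUE,
                              proteinuria_backfill = TRUE) {
  for (f in c(long_csv, subject_csv)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  long <- tibble::as_tibble(utils::read.csv(long_csv))
  subj <- tibble::as_tibble(utils::read.csv(subject_csv))

  if (!"donor_age_ge60" %in% names(subj)) {
    if (!"donor_age" %in% names(subj)) {
      stop("subject table needs `donor_age` (years) or `donor_age_ge60` (0/1)", call. = FALSE)
    }
    subj$donor_age_ge60 <- as.integer(subj$donor_age >= 60)
  }
  for (col in c("ar_time", "dndsa_time")) {
    if (!col %in% names(subj)) subj[[col]] <- NA_real_
  }

  if (proteinuria_backfill && "proteinuria" %in% names(long) &&
      anyNA(subj$proteinuria_m12)) {
    later <- long[!is.na(long$proteinuria) & long$time_years > 1 & long$time_years <= 1.5, ]
    later <- later[order(later$subject_id, later$time_years), ]
    first_later <- later[!duplicated(later$subject_id), c("subject_id", "proteinuria")]
    idx <- match(subj$subject_id, first_later$subject_id)
    fill <- is.na(subj$proteinuria_m12) & !is.na(idx)
    subj$proteinuria_m12[fill] <- first_later$proteinuria[idx[fill]]
    if (any(fill)) message("backfilled month-12 proteinuria for ", sum(fill),
                           " subject(s) from the first value in (12, 18] months")
  }
  long$proteinuria <- NULL

  graft_cohort(subj, long, proteinuria_threshold = proteinuria_threshold,
               min_followup = min_followup, apply_min_followup = apply_min_followup)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_graft_cohort()]; `read -> write -> read` is idempotent on
#' valid data.
#'
#' @param cohort A `graft_cohort`.
#' @param long_csv,subject_csv Output paths.
#' @return `cohort`, invisibly.
#' @export
write_graft_cohort <- function(cohort, long_csv, subject_csv) {
  stopifnot(inherits(cohort, "graft_cohort"))
  utils::write.csv(cohort$measurements, long_csv, row.names = FALSE)
  utils::write.csv(cohort$subjects, subject_csv, row.names = FALSE)
  invisible(cohort)
}

#' @export
print.graft_cohort <- function(x, ...) {
  s <- x$subjects
  cat("<graft_cohort> ", nrow(s), " subjects, ", nrow(x$measurements),
      " creatinine measurements\n", sep = "")
  cat("  events: ", sum(s$event), " (",
      sprintf("%.1f%%", 100 * mean(s$event)), "), dnDSA: ", sum(s$dndsa),
      ", acute rejection: ", sum(s$acute_rejection), "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `graft_cohort`.
#' @return Integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$subjects)
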