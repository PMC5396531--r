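#' Validate a cohort table
#'
#' One row per subject with group membership and baseline covariates. The
#' `group` column distinguishes healthy controls from premanifest Huntington's
#' disease gene carriers (`preHD`); `CAG` (repeat length) and `cognition`
#' (baseline global cognitive composite, standardized units) may be `NA` for
#' controls.
#'
#' @param cohort Data frame with columns `subject_id`, `group` (`"control"` /
#'   `"preHD"`), `age` (years), `sex` (`"M"`/`"F"`), `site`, `education`
#'   (ordinal, treated as numeric in models), and optionally `CAG`,
#'   `cognition`.
#' @return A tibble of class `cohort_table`.
#' @export
cohort_table <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  required <- c("subject_id", "group", "age", "sex", "site", "education")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$subject_id) > 0) {
    stop("cohort table must have one record per subject", call. = FALSE)
  }
  if (!all(cohort$group %in% c("control", "preHD"))) {
    stop("group must be 'control' or 'preHD'", call. = FALSE)
  }
  if (!all(cohort$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  if (!"CAG" %in% names(cohort)) cohort$CAG <- NA_real_
  if (!"cognition" %in% names(cohort)) cohort$cognition <- NA_real_
  class(cohort) <- c("cohort_table", class(cohort))
  cohort
}

#' Read a cohort table from CSV
#'
#' @param path CSV path; see [cohort_table()] for required columns.
#' @return A `cohort_table` tibble.
#' @export
read_cohort <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- cohort_table(tab)
  message("read_cohort: ", nrow(out), " subjects (",
          sum(out$group == "control"), " control, ",
          sum(out$group == "preHD"), " preHD)")
  out
}

#' Bundle atlas, observations and cohort into a longitudinal dataset
#'
#' @param atlas A [region_atlas].
#' @param observations List of [connectome_obs]; per subject, visits must be
#'   strictly increasing. Missing visits are represented by absence, never by
#'   zero-filled matrices.
#' @param cohort A [cohort_table]; every observed subject must appear.
#' @return An object of class `long_dataset`.
#' @export
long_dataset <- function(atlas, observations, cohort) {
  cohort <- cohort_table(cohort)
  subj <- vapply(observations, `[[`, character(1), "subject_id")
  vis <- vapply(observations, `[[`, integer(1), "visit")
  unknown <- setdiff(unique(subj), cohort$subject_id)
  if (length(unknown) > 0) {
    stop("observation subject(s) not in cohort: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  for (s in unique(subj)) {
    v <- vis[subj == s]
    if (anyDuplicated(v) > 0 || is.unsorted(v, strictly = TRUE)) {
      stop("visits for subject ", s, " must be strictly increasing", call. = FALSE)
    }
  }
  bad_dim <- vapply(observations, function(o) nrow(o$W) != nrow(atlas), logical(1))
  if (any(bad_dim)) {
    stop("observation matrix dimension does not match atlas", call. = FALSE)
  }
  structure(list(atlas = atlas, observations = observations, cohort = cohort),
            class = "long_dataset")
}

#' @export
print.long_dataset <- function(x, ...) {
  subj <- vapply(x$observations, `[[`, character(1), "subject_id")
  cat("<long_dataset>", nrow(x$atlas), "regions,",
      length(unique(subj)), "subjects,",
      length(x$observations), "subject-visit observations\n")
  invisible(x)
}

#' Build a long-format modelling table from per-observation strengths
#'
#' Joins per-(subject, visit) connection-strength values with cohort
#' covariates and adds the model time metric `time = visit - 1` (years since
#' baseline). One row per available observation; subjects with missing visits
#' simply contribute fewer rows (the mixed model treats missingness as
#' ignorable).
#'
#' @param dataset A [long_dataset].
#' @param strengths Data frame with columns `subject_id`, `visit` and one or
#'   more value columns (e.g. a `strength` per subtype connection).
#' @return A tibble with `subject_id`, `visit`, `time`, `group`, covariates,
#'   and the value columns from `strengths`.
#' @export
build_long_table <- function(dataset, strengths) {
  strengths <- tibble::as_tibble(strengths)
  stopifnot(all(c("subject_id", "visit") %in% names(strengths)))
  unknown <- setdiff(unique(strengths$subject_id), dataset$cohort$subject_id)
  if (length(unknown) > 0) {
    stop("strengths refer to subject(s) not in cohort: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  strengths |>
    dplyr::mutate(time = .data$visit - 1) |>
    dplyr::left_join(dataset$cohort, by = "subject_id") |>
    dplyr::relocate("subject_id", "visit", "time", "group")
}

#' Reference per-visit enrolment of the emulated observational cohort
#'
#' The two-group, three-visit enrolment schedule (subjects scanned per group
#' per annual visit) that the synthetic cohort generator emulates: 85/87/80
#' controls and 72/82/80 preHD gene carriers at visits 1-3, i.e. 486
#' subject-visit scans in total.
#'
#' @return A tibble with columns `visit`, `group`, `n_scanned`.
#' @export
cohort_visit_counts <- function() {
  tibble::tibble(
    visit = rep(1:3, each = 2),
    group = rep(c("control", "preHD"), times = 3),
    n_scanned = c(85L, 72L, 87L, 82L, 80L, 80L)
  )
}
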