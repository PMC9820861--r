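# Cohort-level diabetes metrics with the exact definitions used in NZO
# cross phenotyping: run-length diabetes classification, prevalence, case
# fatality rate, severe-hyperglycemia fraction and islet-size binning.

#' Classify an animal as diabetic by a run of hyperglycemic weeks
#'
#' An animal is diabetic when its random blood glucose is at or above
#' `threshold` (default 300 mg/dL) for at least `run_weeks` consecutive
#' weeks.  Runs are evaluated over consecutive *observed* weeks: a missing
#' week breaks a run (with weekly measurement, gaps only arise from death).
#'
#' @param glucose numeric vector of weekly glucose values (mg/dL).
#' @param weeks optional integer vector of the age weeks of the
#'   measurements; when omitted the values are taken as consecutive.
#' @param threshold diagnostic glucose threshold, compared with `>=`
#'   ("equal or over"); default 300 mg/dL.
#' @param run_weeks required consecutive weeks at or above threshold
#'   (default 3).
#' @return `TRUE`/`FALSE`; [diabetes_onset_week()] additionally returns the
#'   week completing the first qualifying run (NA if never diabetic).
#' @examples
#' classify_diabetic(c(250, 310, 320, 305, 290))   # TRUE
#' classify_diabetic(c(310, 290, 310, 290, 310))   # FALSE
#' @export
classify_diabetic <- function(glucose, weeks = NULL, threshold = 300,
                              run_weeks = 3L) {
  !is.na(diabetes_onset_week(glucose, weeks, threshold, run_weeks))
}

#' @rdname classify_diabetic
#' @export
diabetes_onset_week <- function(glucose, weeks = NULL, threshold = 300,
                                run_weeks = 3L) {
  .assert(length(glucose) >= 1, "empty glucose series")
  .assert(all(is.finite(glucose)), "glucose values must be finite")
  .assert(.is_count(run_weeks, 1L), "run_weeks must be >= 1")
  if (is.null(weeks)) weeks <- seq_along(glucose)
  .assert(length(weeks) == length(glucose), "weeks must align to glucose")
  ord <- order(weeks)
  weeks <- as.integer(weeks[ord]); glucose <- glucose[ord]
  run <- 0L
  for (i in seq_along(glucose)) {
    consecutive <- i > 1L && weeks[i] == weeks[i - 1L] + 1L
    if (glucose[i] >= threshold) {
      run <- if (consecutive) run + 1L else 1L
    } else {
      run <- 0L
    }
    if (run >= run_weeks) return(weeks[i])
  }
  NA_integer_
}

# per-animal onset weeks for a long-format cohort table
.cohort_onsets <- function(pheno, threshold = 300, run_weeks = 3L) {
  .assert(inherits(pheno, "data.frame") && nrow(pheno) >= 1,
          "empty cohort rejected")
  .assert(all(c("animal", "week", "glucose") %in% names(pheno)),
          "cohort needs animal, week, glucose columns")
  ids <- unique(pheno$animal)
  vapply(ids, function(a) {
    sub <- pheno[pheno$animal == a, ]
    diabetes_onset_week(sub$glucose, sub$week, threshold, run_weeks)
  }, integer(1))
}

#' Diabetes prevalence of a cohort
#'
#' Fraction of animals meeting the run-length diabetes definition, plus the
#' cumulative-by-week onset curve (both readings of a prevalence panel are
#' emitted since either may be wanted).
#'
#' @param pheno long-format cohort table (`animal`, `week`, `glucose`).
#' @inheritParams classify_diabetic
#' @return list with `prevalence` (final fraction), `n`, `n_diabetic`,
#'   `diabetic` (named logical per animal), and `by_week` (data.frame
#'   `week`, `cumulative_prevalence`, non-decreasing).
#' @export
diabetes_prevalence <- function(pheno, threshold = 300, run_weeks = 3L) {
  onset <- .cohort_onsets(pheno, threshold, run_weeks)
  n <- length(onset)
  weeks <- sort(unique(pheno$week))
  curve <- data.frame(
    week = weeks,
    cumulative_prevalence = vapply(weeks, function(w)
      sum(!is.na(onset) & onset <= w) / n, numeric(1)))
  list(prevalence = sum(!is.na(onset)) / n,
       n = n,
       n_diabetic = sum(!is.na(onset)),
       diabetic = !is.na(onset),
       by_week = curve)
}

#' Case fatality rate among diabetic animals
#'
#' Deaths among diabetic animals at or before `study_end_week`, divided by
#' the number of diabetic animals (the denominator is diabetic animals, not
#' the whole cohort).
#'
#' @param pheno long-format cohort table; death weeks are taken from
#'   [death_weeks()] (the `dead` flag / `death_week` attribute).
#' @param study_end_week end of the observation period (default 20 weeks).
#' @inheritParams classify_diabetic
#' @return list with `cfr`, `n_diabetic`, `n_deaths`.  With zero diabetic
#'   animals the CFR is undefined: `NA` with a warning, never 0.
#' @export
case_fatality_rate <- function(pheno, study_end_week = 20L, threshold = 300,
                               run_weeks = 3L) {
  onset <- .cohort_onsets(pheno, threshold, run_weeks)
  diabetic <- names(onset)[!is.na(onset)]
  if (!length(diabetic)) {
    warning("no diabetic animals: case fatality rate undefined")
    return(list(cfr = NA_real_, n_diabetic = 0L, n_deaths = 0L))
  }
  dw <- death_weeks(structure(pheno, class = c("phenotype_table", "data.frame")))
  died <- !is.na(dw[diabetic]) & dw[diabetic] <= study_end_week
  list(cfr = sum(died) / length(diabetic),
       n_diabetic = length(diabetic),
       n_deaths = sum(died))
}

#' Fraction of animals with severe hyperglycemia at a given week
#'
#' Severe hyperglycemia is a blood glucose strictly above `threshold`
#' (default > 500 mg/dL) at the stated age week (default 15).  The
#' denominator is the set of animals with an observation at that week, so
#' animals dead before it are excluded.
#'
#' @inheritParams diabetes_prevalence
#' @param threshold severe glucose cutoff, compared with strict `>`.
#' @param week age week of the measurement.
#' @return list with `fraction`, `n_observed`, `n_severe`.
#' @export
severe_hyperglycemia_fraction <- function(pheno, threshold = 500, week = 15L) {
  .assert(all(c("animal", "week", "glucose") %in% names(pheno)),
          "cohort needs animal, week, glucose columns")
  sub <- pheno[pheno$week == week & !is.na(pheno$glucose), , drop = FALSE]
  .assert(nrow(sub) >= 1, sprintf("no observations at week %d", week))
  list(fraction = sum(sub$glucose > threshold) / nrow(sub),
       n_observed = nrow(sub),
       n_severe = sum(sub$glucose > threshold))
}

#' Histogram of islet cross-sectional areas
#'
#' Bins areas into half-open bins `[k*w, (k+1)*w)`; the first bin captures
#' the cluster of small islets.  The binning is unit-agnostic.
#'
#' @param areas non-negative areas.
#' @param bin_width bin width in the same units (default 10000).
#' @return named integer vector of counts per occupied bin range (all bins
#'   up to the largest observed area; counts sum to `length(areas)`).  An
#'   empty input yields a zero-length histogram.
#' @export
bin_islet_areas <- function(areas, bin_width = 10000) {
  .assert(is.numeric(areas), "areas must be numeric")
  .assert(all(is.finite(areas)) || length(areas) == 0, "areas must be finite")
  .assert(all(areas >= 0), "negative area rejected")
  .assert(.is_number(bin_width) && bin_width > 0, "bin_width must be > 0")
  if (!length(areas)) return(stats::setNames(integer(0), character(0)))
  bin <- floor(areas / bin_width)
  counts <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  lo <- (seq_along(counts) - 1L) * bin_width
  stats::setNames(as.integer(counts),
                  sprintf("[%s,%s)", format(lo, scientific = FALSE, trim = TRUE),
                          format(lo + bin_width, scientific = FALSE, trim = TRUE)))
}

#' Cohort summary per genotype group
#'
#' Convenience wrapper producing the standard panel of diabetes metrics for
#' each genotype group of a cohort.
#'
#' @inheritParams case_fatality_rate
#' @param severe_threshold,severe_week passed to
#'   [severe_hyperglycemia_fraction()].
#' @return data.frame with one row per group: `group`, `n`, `prevalence`,
#'   `cfr`, `severe_fraction`.
#' @export
cohort_summary <- function(pheno, study_end_week = 20L, threshold = 300,
                           run_weeks = 3L, severe_threshold = 500,
                           severe_week = 15L) {
  .assert("group" %in% names(pheno), "cohort needs a group column")
  groups <- sort(unique(pheno$group))
  rows <- lapply(groups, function(grp) {
    sub <- pheno[pheno$group == grp, , drop = FALSE]
    attr(sub, "death_week") <- attr(pheno, "death_week")
    prev <- diabetes_prevalence(sub, threshold, run_weeks)
    cfr <- suppressWarnings(
      case_fatality_rate(sub, study_end_week, threshold, run_weeks))
    sev <- tryCatch(
      severe_hyperglycemia_fraction(sub, severe_threshold, severe_week),
      error = function(e) list(fraction = NA_real_))
    data.frame(group = grp, n = prev$n, prevalence = prev$prevalence,
               cfr = cfr$cfr, severe_fraction = sev$fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
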