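#' Reference demographic table of the emulated CBCT database
#'
#' Per-year-of-age counts of female and male CBCT files in the clinical
#' database whose structure the phantom cohort emulates: 1006 files in
#' total (610 female, 396 male), ages 4-23 years with most mass in the
#' 10-19 range. [generate_cohort()] samples its age/sex cells from this
#' table by default.
#'
#' @return a data.frame with columns `age_years` (lower bound of the
#'   one-year bin), `F` and `M` (file counts).
#' @export
demographic_reference <- function() {
  data.frame(
    age_years = 4:23,
    F = c(0, 5, 2, 7, 11, 22, 50, 61, 61, 65, 56, 52, 57, 68, 65, 17, 9, 1, 1, 0),
    M = c(1, 1, 1, 2, 10, 32, 51, 48, 51, 48, 38, 29, 28, 26, 21, 6, 0, 2, 0, 1)
  )
}

#' Worked-example per-class evaluation table
#'
#' A reference table of per-class one-vs-rest AUC, precision and recall for
#' a five-class age-range classifier evaluated on a 100-image test set
#' (20 per class), used as a worked example for the metrics arithmetic:
#' [f1_score()] applied to each (precision, recall) pair reproduces the
#' published F1 column, and the arithmetic mean of the five AUCs gives the
#' average AUC of 0.7532.
#'
#' @return a data.frame with columns `label`, `age_range`, `auc`,
#'   `precision`, `recall`, `f1`, `n_test`.
#' @export
example_metrics_table <- function() {
  data.frame(
    label = 0:4,
    age_range = c("4-10", "11-12", "13-14", "15-16", "17-23"),
    auc = c(0.9106, 0.6825, 0.6581, 0.7262, 0.7887),
    precision = c(0.5926, 0.4348, 0.6923, 0.6000, 0.5882),
    recall = c(0.8000, 0.5000, 0.4500, 0.6000, 0.5000),
    f1 = c(0.6809, 0.4651, 0.5455, 0.6000, 0.5405),
    n_test = rep(20L, 5)
  )
}
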