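#' Pair baseline and first follow-up tumor fractions per patient
#'
#' For each patient, the baseline is the smallest timepoint and the first
#' follow-up the next smallest. Technical replicates at one (patient,
#' timepoint) are averaged before pairing (reported via a message). Patients
#' with fewer than two distinct timepoints are skipped with a warning.
#'
#' @param estimates data.frame with columns `sample_id` and `tumor_fraction`
#'   (as produced by [predict_fractions()]).
#' @param meta metadata data.frame with `sample_id`, `patient_id`,
#'   `phenotype`, `timepoint` covering every estimate.
#' @return data.frame with columns `patient_id`, `baseline_fraction`,
#'   `followup_fraction`, `delta` (follow-up minus baseline).
#' @export
pair_baseline_followup <- function(estimates, meta) {
  meta <- validate_metadata(meta)
  if (!all(c("sample_id", "tumor_fraction") %in% names(estimates))) {
    stop2("estimates needs sample_id and tumor_fraction columns")
  }
  unknown <- setdiff(estimates$sample_id, meta$sample_id)
  if (length(unknown)) {
    stop2("metadata is missing sample(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  d <- merge(estimates[, c("sample_id", "tumor_fraction")],
             meta[, c("sample_id", "patient_id", "timepoint")], by = "sample_id")
  # average technical replicates per (patient, timepoint)
  key <- interaction(d$patient_id, d$timepoint, drop = TRUE)
  if (anyDuplicated(key)) {
    message("averaging technical replicates at ",
            sum(duplicated(key)), " (patient, timepoint) slot(s)")
  }
  agg <- stats::aggregate(tumor_fraction ~ patient_id + timepoint, data = d, FUN = mean)
  out <- do.call(rbind, lapply(split(agg, agg$patient_id), function(g) {
    g <- g[order(g$timepoint), , drop = FALSE]
    if (nrow(g) < 2) return(NULL)
    data.frame(patient_id = g$patient_id[1],
               baseline_fraction = g$tumor_fraction[1],
               followup_fraction = g$tumor_fraction[2],
               delta = g$tumor_fraction[2] - g$tumor_fraction[1],
               stringsAsFactors = FALSE)
  }))
  n_skipped <- length(unique(agg$patient_id)) - if (is.null(out)) 0 else nrow(out)
  if (n_skipped > 0) {
    warn2(n_skipped, " patient(s) with a single timepoint were skipped")
  }
  if (is.null(out)) {
    stop2("no patient has both a baseline and a follow-up sample")
  }
  rownames(out) <- NULL
  out
}

#' Paired t-test on per-patient tumor-fraction changes
#'
#' One-sample two-sided t-test of the baseline-to-follow-up deltas against
#' zero: `t = mean(delta) / (sd(delta) / sqrt(n))` with `n - 1` degrees of
#' freedom. Also reports the mean and standard deviation of the change in the
#' usual "mean +/- SD" style.
#'
#' @param deltas numeric vector of per-patient changes (or a
#'   [pair_baseline_followup()] result, whose `delta` column is used).
#' @return A list of class `monitor_result` with `n_patients`, `mean_delta`,
#'   `sd_delta`, `t_statistic`, `p_value`.
#' @export
paired_t_test <- function(deltas) {
  if (is.data.frame(deltas)) deltas <- deltas$delta
  if (!is.numeric(deltas) || anyNA(deltas)) stop2("deltas must be numeric without NAs")
  n <- length(deltas)
  if (n < 2) stop2("need at least 2 patients for a paired test")
  m <- mean(deltas)
  s <- stats::sd(deltas)
  if (s == 0) {
    if (m == 0) {
      t_stat <- 0; p <- 1
    } else {
      warn2("all deltas identical and nonzero: sd = 0, p reported as 0")
      t_stat <- sign(m) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(deltas, mu = 0, alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(n_patients = n, mean_delta = m, sd_delta = s,
                 t_statistic = t_stat, p_value = p),
            class = "monitor_result")
}

#' @export
print.monitor_result <- function(x, ...) {
  cat(sprintf("Paired change, n = %d patients\n", x$n_patients))
  cat(sprintf("mean change: %.3f +/- %.3f (SD); paired t-test, t = %.3f, p = %.4g\n",
              x$mean_delta, x$sd_delta, x$t_statistic, x$p_value))
  invisible(x)
}

#' Run the full monitoring step
#'
#' Pairs baselines with first follow-ups and tests the mean change.
#'
#' @inheritParams pair_baseline_followup
#' @return A list with `pairs` (the [pair_baseline_followup()] table) and
#'   `test` (the [paired_t_test()] result).
#' @export
monitor_changes <- function(estimates, meta) {
  pairs <- pair_baseline_followup(estimates, meta)
  list(pairs = pairs, test = paired_t_test(pairs$delta))
}
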