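#' Construct a saliva series
#'
#' Six samples around the stressor with labels (t-30, t-pre, t+00, t+15,
#' t+30, t+50); numeric times come from the labels, with the pre-stressor
#' baseline label "t-pre" mapped to -5 min by default (configurable, since
#' it has no number of its own).
#'
#' @param values six nonnegative concentrations (cortisol nmol/L or
#'   alpha-amylase U/mL).
#' @param labels sample labels.
#' @param t_pre_min numeric time assigned to "t-pre", minutes.
#' @param analyte analyte tag.
#' @return data.frame of class `saliva_series` with `label`, `time_min`,
#'   `value`, `analyte`.
#' @export
saliva_series <- function(values,
                          labels = c("t-30", "t-pre", "t+00", "t+15",
                                     "t+30", "t+50"),
                          t_pre_min = -5, analyte = "cortisol") {
  if (length(values) != 6 || length(labels) != 6) {
    stop("a saliva series has exactly six samples")
  }
  if (any(values < 0)) stop("concentrations must be nonnegative")
  times <- vapply(labels, function(l) {
    if (l == "t-pre") t_pre_min else as.numeric(sub("^t", "", l))
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(times) || any(diff(times) <= 0)) {
    stop("sample times must be strictly increasing")
  }
  structure(
    data.frame(label = labels, time_min = times, value = values,
               analyte = analyte, stringsAsFactors = FALSE),
    class = c("saliva_series", "data.frame")
  )
}

# trapezoidal integral
#' @keywords internal
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Area under the curve with respect to ground
#'
#' Trapezoidal integral of all six samples over time.
#'
#' @param series a [saliva_series()] (or data.frame with `time_min`,
#'   `value`).
#' @return concentration x minutes.
#' @export
aucg <- function(series) {
  trapz(series$time_min, series$value)
}

#' Area under the curve with respect to increment
#'
#' Trapezoidal integral from the second to the sixth sample, minus the
#' rectangle at the pre-stressor baseline (the second sample, by default):
#' the cumulative change relative to baseline. Invariant under adding a
#' constant to all samples.
#'
#' @param series a [saliva_series()].
#' @param baseline_sample index of the baseline sample (default 2, the
#'   pre-stressor baseline; set 1 for the arrival sample).
#' @return concentration x minutes.
#' @export
auci <- function(series, baseline_sample = 2) {
  idx <- baseline_sample:6
  t <- series$time_min[idx]
  v <- series$value[idx]
  trapz(t, v) - v[1] * (t[length(t)] - t[1])
}
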