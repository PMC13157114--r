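#' Component specifications for the passive-viewing task
#'
#' Electrode clusters and scoring windows for the four components: P1
#' (O1/O2/PO7/PO8/P9/P10, 80-120 ms), N170 (PO7/PO8/P9/P10, 130-200 ms),
#' EPN (P7/P8/PO7/PO8/P9/P10, 240-300 ms), and LPP (midline Cz/CPz/Pz/POz,
#' 400-1000 ms).
#'
#' @return named list of specs with fields `cluster`, `window`, `polarity`,
#'   `midline`.
#' @export
component_specs <- function() {
  list(
    P1 = list(cluster = c("O1", "O2", "PO7", "PO8", "P9", "P10"),
              window = c(80, 120), polarity = "positive", midline = FALSE),
    N170 = list(cluster = c("PO7", "PO8", "P9", "P10"),
                window = c(130, 200), polarity = "negative", midline = FALSE),
    EPN = list(cluster = c("P7", "P8", "PO7", "PO8", "P9", "P10"),
               window = c(240, 300), polarity = "negative", midline = FALSE),
    LPP = list(cluster = c("Cz", "CPz", "Pz", "POz"),
               window = c(400, 1000), polarity = "positive", midline = TRUE)
  )
}

# Trials belonging to a condition cell, respecting the rejection mask.
#' @keywords internal
cell_trials <- function(ep, expression) {
  which(!ep$rejected & ep$conditions$expression == expression)
}

# Cluster channels restricted to one hemisphere (odd labels left, even
# right; z-labels are midline and excluded from hemisphere splits).
#' @keywords internal
hemi_cluster <- function(cluster, hemisphere) {
  if (hemisphere == "midline") return(cluster)
  cluster[channel_hemisphere(cluster) == hemisphere]
}

#' Mean component amplitude for one condition cell
#'
#' Mean voltage over the cell's unrejected trials, the (hemisphere-side)
#' cluster channels, and the component window.
#'
#' @param ep an [epoch()] set with an `expression` condition column.
#' @param spec one element of [component_specs()].
#' @param expression condition cell.
#' @param hemisphere "left", "right", or "midline" (the full cluster).
#' @return mean amplitude in uV, or NA (with a warning) for an empty cell.
#' @export
mean_amplitude <- function(ep, spec, expression,
                           hemisphere = c("midline", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  trials <- cell_trials(ep, expression)
  if (length(trials) == 0) {
    warning("no unrejected trials for expression '", expression, "'")
    return(NA_real_)
  }
  chans <- hemi_cluster(spec$cluster, hemisphere)
  if (length(chans) == 0) stop("no cluster channels on that hemisphere")
  ci <- match(chans, ep$channels)
  if (anyNA(ci)) stop("cluster channels missing from the montage")
  sel <- ep$times_ms >= spec$window[1] & ep$times_ms <= spec$window[2]
  if (!any(sel)) stop("component window outside the epoch")
  mean(ep$data[trials, ci, sel])
}

#' Peak-to-peak P1-N170 amplitude
#'
#' On the cell-averaged cluster waveform, finds the P1 peak (maximum in the
#' P1 window) and the N170 trough (minimum in the N170 window) and returns
#' trough minus peak: more negative values mean a larger N170 after
#' discounting P1 carry-over. Invariant under adding a constant to the
#' waveform.
#'
#' @param ep an [epoch()] set with an `expression` condition column.
#' @param expression condition cell.
#' @param hemisphere hemisphere split of the cluster.
#' @param p1_window,n170_window ms windows.
#' @param cluster channel labels.
#' @return trough - peak, uV.
#' @export
peak_to_peak_p1_n170 <- function(ep, expression,
                                 hemisphere = c("midline", "left", "right"),
                                 p1_window = c(80, 120),
                                 n170_window = c(130, 200),
                                 cluster = c("PO7", "PO8", "P9", "P10")) {
  hemisphere <- match.arg(hemisphere)
  trials <- cell_trials(ep, expression)
  if (length(trials) == 0) {
    warning("no unrejected trials for expression '", expression, "'")
    return(NA_real_)
  }
  chans <- hemi_cluster(cluster, hemisphere)
  ci <- match(chans, ep$channels)
  wave <- apply(ep$data[trials, ci, , drop = FALSE], 3, mean)
  p1_sel <- ep$times_ms >= p1_window[1] & ep$times_ms <= p1_window[2]
  n_sel <- ep$times_ms >= n170_window[1] & ep$times_ms <= n170_window[2]
  if (!any(p1_sel) || !any(n_sel)) stop("scoring window outside the epoch")
  min(wave[n_sel]) - max(wave[p1_sel])
}

#' Component amplitude table for one participant
#'
#' Scores P1, N170, and EPN per hemisphere (left/right members of each
#' cluster) and the LPP on the midline cluster, for every expression, plus
#' the peak-to-peak P1-N170 measure per hemisphere.
#'
#' @param ep an [epoch()] set with an `expression` condition column.
#' @param participant,group identifiers copied into the output.
#' @param specs component specifications.
#' @return data.frame `participant`, `group`, `expression`, `component`,
#'   `hemisphere`, `amplitude` (uV); peak-to-peak rows have component
#'   `"P1N170_pp"`.
#' @export
component_table <- function(ep, participant = "p1", group = NA_character_,
                            specs = component_specs()) {
  expressions <- sort(unique(ep$conditions$expression))
  rows <- list()
  for (e in expressions) {
    for (comp in names(specs)) {
      spec <- specs[[comp]]
      hemis <- if (spec$midline) "midline" else c("left", "right")
      for (h in hemis) {
        rows[[length(rows) + 1]] <- data.frame(
          participant = participant, group = group, expression = e,
          component = comp, hemisphere = h,
          amplitude = mean_amplitude(ep, spec, e, h),
          stringsAsFactors = FALSE
        )
      }
    }
    for (h in c("left", "right")) {
      rows[[length(rows) + 1]] <- data.frame(
        participant = participant, group = group, expression = e,
        component = "P1N170_pp", hemisphere = h,
        amplitude = peak_to_peak_p1_n170(ep, e, h),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
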