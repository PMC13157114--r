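#' Standard 10-20 montage used by the simulator and interpolation
#'
#' Approximate unit-sphere positions for the channels the synthetic recordings
#' carry. Positions are derived from the conventional 10-20 angular layout
#' (azimuth measured from the front midline, positive to the right;
#' inclination measured from the vertex). They are used only for
#' distance-weighted neighbour interpolation, which needs relative distances,
#' not a digitized head model.
#'
#' @return A data.frame with columns `label`, `x`, `y`, `z`.
#' @export
standard_montage <- function() {
  ang <- rbind(
    c("Fp1", -18,  90), c("Fpz",   0,  90), c("Fp2",  18,  90),
    c("F7",  -54,  90), c("F3",  -39,  62), c("Fz",    0,  45),
    c("F4",   39,  62), c("F8",   54,  90),
    c("T7",  -90,  90), c("C3",  -90,  45), c("Cz",    0,   0),
    c("C4",   90,  45), c("T8",   90,  90), c("CPz", 180,  22),
    c("P7", -126,  90), c("P3", -141,  62), c("Pz",  180,  45),
    c("P4",  141,  62), c("P8",  126,  90),
    c("P9", -126, 110), c("P10", 126, 110),
    c("PO7", -144, 85), c("POz", 180,  68), c("PO8", 144,  85),
    c("O1", -162,  90), c("Oz",  180,  90), c("O2",  162,  90)
  )
  az <- as.numeric(ang[, 2]) * pi / 180
  incl <- as.numeric(ang[, 3]) * pi / 180
  data.frame(
    label = ang[, 1],
    x = sin(incl) * sin(az),
    y = sin(incl) * cos(az),
    z = cos(incl),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
montage_positions <- function(labels) {
  mon <- standard_montage()
  idx <- match(labels, mon$label)
  if (anyNA(idx)) {
    stop("unknown channel labels: ", paste(labels[is.na(idx)], collapse = ", "))
  }
  as.matrix(mon[idx, c("x", "y", "z")])
}

# Hemisphere from the 10-20 label convention: odd digits left, even right,
# trailing 'z' midline.
#' @keywords internal
channel_hemisphere <- function(labels) {
  num <- sub("^[A-Za-z]+", "", labels)
  ifelse(num == "z" | num == "Z" | num == "", "midline",
         ifelse(as.integer(num) %% 2 == 1, "left", "right"))
}
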