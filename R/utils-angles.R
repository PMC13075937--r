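# Angle helpers. All angles in degrees; wrapping conventions:
#  - wrap360: [0, 360)
#  - wrapDiff: (-180, 180], the shortest signed arc between samples

wrap360 <- function(a) a %% 360

#' Map angular differences to the shortest signed arc
#'
#' @param d numeric, degrees.
#' @return degrees in (-180, 180].
#' @keywords internal
wrapDiff <- function(d) {
  out <- ((d + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi
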