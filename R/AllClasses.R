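#' @import methods
NULL

#' Arena layout: geometry of the tracked regions of interest
#'
#' Describes one or more regions of interest (ROIs) detected in a video
#' frame: circular Buridan platforms or Y-maze chambers arranged in rows
#' and columns, together with the pixel-to-millimetre scale derived from
#' the known physical arena diameter.
#'
#' Image coordinates have their origin at the top-left pixel centre, x
#' increasing rightwards and y downwards. Arena coordinates (used by
#' [toMm()]) have their origin at the ROI centre with y increasing
#' upwards (mathematical convention) and are expressed in mm.
#'
#' @slot rois data.frame with one row per ROI and columns `id` (integer,
#'   unique, row-major), `shape` ("circle" or "ymaze"), `cx_px`, `cy_px`
#'   (centre, pixels), `radius_px` (circle radius or Y-arm length from
#'   centre, pixels), `row`, `col` (grid indices, 1-based) and
#'   `mm_per_px` (scale, mm per pixel, > 0).
#' @slot arenaDiameterMm numeric(1), physical diameter (circle) or twice
#'   the arm length (Y-maze) in mm used to derive `mm_per_px`.
#'
#' @seealso [detectRois()], [arenaLayout()]
#' @exportClass ArenaLayout
setClass("ArenaLayout",
  representation(rois = "data.frame", arenaDiameterMm = "numeric"),
  validity = function(object) {
    r <- object@rois
    need <- c("id", "shape", "cx_px", "cy_px", "radius_px", "row", "col",
              "mm_per_px")
    if (!all(need %in% names(r)))
      return(paste("rois must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(r$id)) return("roi ids must be unique")
    if (any(r$mm_per_px <= 0)) return("mm_per_px must be > 0")
    if (!all(r$shape %in% c("circle", "ymaze")))
      return("shape must be 'circle' or 'ymaze'")
    ord <- order(r$row, r$col)
    if (!identical(ord, seq_len(nrow(r))))
      return("rois must be sorted row-major (row, then col)")
    TRUE
  })

#' Camera calibration model (Brown-Conrady)
#'
#' Pinhole intrinsics plus radial-tangential distortion coefficients, as
#' produced by a standard checkerboard calibration. Estimating the
#' coefficients is out of scope; they are accepted as input.
#'
#' @slot cameraMatrix 3x3 intrinsic matrix; `[1,1]` and `[2,2]` are the
#'   focal terms (pixels) and `[1:2,3]` the principal point.
#' @slot distCoeffs numeric(5): k1, k2, p1, p2, k3.
#'
#' @seealso [undistortFrame()]
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(cameraMatrix = "matrix", distCoeffs = "numeric"),
  validity = function(object) {
    K <- object@cameraMatrix
    if (!all(dim(K) == c(3L, 3L))) return("cameraMatrix must be 3x3")
    if (K[1, 1] <= 0 || K[2, 2] <= 0) return("focal terms must be > 0")
    if (length(object@distCoeffs) != 5L)
      return("distCoeffs must be length 5 (k1,k2,p1,p2,k3)")
    TRUE
  })

#' Raw per-frame tracking result for one ROI
#'
#' Pixel-space centroid trajectory straight out of the tracker, before
#' unit conversion. When the fly is lost (`detected` FALSE) the last
#' known position is carried; frames before the first detection are
#' back-filled with the first detected position.
#'
#' @slot roiId integer(1) ROI this fly belongs to.
#' @slot xPx,yPx numeric per-frame centroid, pixels (image coordinates).
#' @slot detected logical per frame.
#' @slot nCandidates integer per frame: number of above-threshold blobs
#'   seen in the ROI that frame.
#' @exportClass RawTrajectory
setClass("RawTrajectory",
  representation(roiId = "integer", xPx = "numeric", yPx = "numeric",
                 detected = "logical", nCandidates = "integer"),
  validity = function(object) {
    n <- length(object@xPx)
    if (length(object@yPx) != n || length(object@detected) != n ||
        length(object@nCandidates) != n)
      return("per-frame slots must have equal length")
    TRUE
  })

#' Trajectory in real-world units
#'
#' Per-fly time series of planar position in mm, arena coordinates
#' (origin at ROI centre, y up).
#'
#' @slot roiId integer(1).
#' @slot time numeric, seconds, strictly increasing.
#' @slot x,y numeric, mm.
#' @slot detected logical per frame.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(roiId = "integer", time = "numeric", x = "numeric",
                 y = "numeric", detected = "logical"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@x) != n || length(object@y) != n ||
        length(object@detected) != n)
      return("time, x, y, detected must have equal length")
    if (n > 1 && any(diff(object@time) <= 0))
      return("time must be strictly increasing")
    TRUE
  })

#' Walking-threshold filtered trajectory
#'
#' A [Trajectory-class] whose position only advances on frames where the
#' displacement from the last updated position reached the walking
#' threshold; `updated` marks those frames (first frame always TRUE).
#'
#' @slot updated logical per frame.
#' @seealso [walkingFilter()]
#' @exportClass FilteredTrajectory
setClass("FilteredTrajectory", contains = "Trajectory",
  representation(updated = "logical"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@updated) != n)
      return("updated must match trajectory length")
    if (n >= 1 && !object@updated[1]) return("first frame must be updated")
    move <- which(diff(object@x) != 0 | diff(object@y) != 0) + 1L
    if (length(move) && !all(object@updated[move]))
      return("position may only change on updated frames")
    TRUE
  })

#' Tethered-flight heading series
#'
#' Per-frame 0-360 degree heading of a tethered fly, with the underlying
#' 0-180 degree body-axis angle, a flying flag (FALSE during wing-visible
#' stop bouts) and a flag for frames where the axis was degenerate or the
#' head-side test tied and the previous value was carried.
#'
#' @slot time numeric, seconds, strictly increasing.
#' @slot heading numeric degrees in [0, 360).
#' @slot flying logical per frame.
#' @slot axisAngle numeric degrees in [0, 180).
#' @slot flagged logical per frame (carried value).
#' @exportClass HeadingSeries
setClass("HeadingSeries",
  representation(time = "numeric", heading = "numeric", flying = "logical",
                 axisAngle = "numeric", flagged = "logical"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@heading) != n || length(object@flying) != n ||
        length(object@axisAngle) != n || length(object@flagged) != n)
      return("per-frame slots must have equal length")
    if (n > 1 && any(diff(object@time) <= 0))
      return("time must be strictly increasing")
    ok <- is.finite(object@heading)
    if (any(object@heading[ok] < 0 | object@heading[ok] >= 360))
      return("heading must lie in [0, 360)")
    TRUE
  })

#' One fly x one context: named behavioral parameters
#'
#' Walking profiles carry percent_time_walked (%), walking_speed (mm/s),
#' vector_strength ([0,1], axial), angular_velocity (deg/s) and
#' centrophobicity ([0,1]); flight profiles carry n_pauses (count),
#' absolute_angular_velocity (deg/s), vector_strength, angular_velocity
#' (deg/s) and median_heading_axial (deg in [0,180)). Missing values are
#' NA, never zero.
#'
#' @slot flyId character(1).
#' @slot contextId character(1).
#' @slot modality "walk" or "flight".
#' @slot parameters named numeric.
#' @slot moved logical(1): FALSE for non-movers (no updated frame while
#'   walking, or no flying frame in flight), the flies excluded from
#'   analysis.
#' @exportClass BehaviorProfile
setClass("BehaviorProfile",
  representation(flyId = "character", contextId = "character",
                 modality = "character", parameters = "numeric",
                 moved = "logical"),
  prototype(moved = TRUE),
  validity = function(object) {
    if (!object@modality %in% c("walk", "flight"))
      return("modality must be 'walk' or 'flight'")
    p <- object@parameters
    if (is.null(names(p)) || any(!nzchar(names(p))))
      return("parameters must be named")
    chk <- function(nm, lo, hi) {
      v <- p[nm]
      if (!is.na(v) && (v < lo || v > hi))
        sprintf("%s out of [%g, %g]", nm, lo, hi) else NULL
    }
    for (msg in c(chk("percent_time_walked", 0, 100),
                  chk("vector_strength", 0, 1),
                  chk("centrophobicity", 0, 1)))
      if (!is.null(msg)) return(msg)
    if ("n_pauses" %in% names(p) && !is.na(p["n_pauses"]) &&
        (p["n_pauses"] < 0 || p["n_pauses"] != round(p["n_pauses"])))
      return("n_pauses must be a non-negative integer")
    TRUE
  })

# ---- constructors ----------------------------------------------------

#' Construct an ArenaLayout
#'
#' @param rois data.frame; see [ArenaLayout-class]. Rows are re-sorted
#'   row-major and ids reassigned in that order if needed.
#' @param arenaDiameterMm physical arena diameter in mm.
#' @return An [ArenaLayout-class].
#' @export
arenaLayout <- function(rois, arenaDiameterMm) {
  rois <- rois[order(rois$row, rois$col), , drop = FALSE]
  rownames(rois) <- NULL
  new("ArenaLayout", rois = rois, arenaDiameterMm = as.numeric(arenaDiameterMm))
}

#' Construct a CalibrationModel
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels.
#' @param k1,k2,k3 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @return A [CalibrationModel-class].
#' @export
calibrationModel <- function(fx, fy, cx, cy, k1 = 0, k2 = 0, p1 = 0,
                             p2 = 0, k3 = 0) {
  K <- matrix(c(fx, 0, 0, 0, fy, 0, cx, cy, 1), 3, 3)
  new("CalibrationModel", cameraMatrix = K,
      distCoeffs = c(k1 = k1, k2 = k2, p1 = p1, p2 = p2, k3 = k3))
}

#' Construct a Trajectory
#'
#' @param time seconds (strictly increasing).
#' @param x,y positions in mm, arena coordinates.
#' @param detected per-frame detection flag (default all TRUE).
#' @param roiId ROI id (default 1).
#' @return A [Trajectory-class].
#' @export
trajectory <- function(time, x, y, detected = rep(TRUE, length(time)),
                       roiId = 1L) {
  new("Trajectory", roiId = as.integer(roiId), time = as.numeric(time),
      x = as.numeric(x), y = as.numeric(y), detected = detected)
}

#' Construct a HeadingSeries
#'
#' @param time seconds (strictly increasing).
#' @param heading degrees in [0, 360).
#' @param flying logical (default all TRUE).
#' @param axisAngle degrees in [0, 180); default `heading %% 180`.
#' @param flagged logical (default all FALSE).
#' @return A [HeadingSeries-class].
#' @export
headingSeries <- function(time, heading, flying = rep(TRUE, length(time)),
                          axisAngle = heading %% 180,
                          flagged = rep(FALSE, length(time))) {
  new("HeadingSeries", time = as.numeric(time),
      heading = as.numeric(heading), flying = flying,
      axisAngle = as.numeric(axisAngle), flagged = flagged)
}

# ---- accessors and show ----------------------------------------------

#' @describeIn ArenaLayout-class ROI table accessor.
#' @param x an object.
#' @export
rois <- function(x) x@rois

#' Number of frames in a trajectory or heading series
#' @param x a [Trajectory-class], [RawTrajectory-class] or
#'   [HeadingSeries-class].
#' @return integer frame count.
#' @export
nFrames <- function(x) {
  if (is(x, "RawTrajectory")) length(x@xPx) else length(x@time)
}

#' Parameter vector of a BehaviorProfile
#' @param x a [BehaviorProfile-class].
#' @return named numeric.
#' @export
profileParameters <- function(x) x@parameters

setMethod("show", "ArenaLayout", function(object) {
  r <- object@rois
  cat(sprintf("ArenaLayout: %d roi(s), %s, %g mm diameter\n", nrow(r),
              paste(unique(r$shape), collapse = "/"),
              object@arenaDiameterMm))
  cat(sprintf("  grid %d row(s) x %d col(s); mm/px %.4g\n",
              max(r$row), max(r$col), stats::median(r$mm_per_px)))
})

setMethod("show", "Trajectory", function(object) {
  n <- length(object@time)
  cat(sprintf("%s: roi %d, %d frames, %.1f s, %d detected\n",
              class(object), object@roiId, n,
              if (n) object@time[n] - object@time[1] else 0,
              sum(object@detected)))
})

setMethod("show", "HeadingSeries", function(object) {
  n <- length(object@time)
  cat(sprintf("HeadingSeries: %d frames, %.1f s, %.0f%% flying\n",
              n, if (n) object@time[n] - object@time[1] else 0,
              100 * mean(object@flying)))
})

setMethod("show", "BehaviorProfile", function(object) {
  cat(sprintf("BehaviorProfile: fly %s, context %s (%s)\n", object@flyId,
              object@contextId, object@modality))
  print(round(object@parameters, 4))
})
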