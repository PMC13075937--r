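# Arena detection: lens undistortion, background model, ROI discovery.
# Frames are numeric matrices [row = y, col = x] on the 0-255 gray scale,
# origin top-left, pixel centres at integer coordinates.

#' Correct lens distortion in a frame
#'
#' Standard radial-tangential (Brown-Conrady) remap: each output pixel
#' samples the input at its forward-distorted location by bilinear
#' interpolation. Output dimensions equal the input; with all
#' coefficients zero the frame is returned unchanged.
#'
#' @param frame numeric matrix (gray levels).
#' @param calibration a [CalibrationModel-class].
#' @return numeric matrix of the same dimensions.
#' @export
undistortFrame <- function(frame, calibration) {
  if (!is.matrix(frame) || !length(frame)) stop("frame must be a non-empty matrix")
  stopifnot(is(calibration, "CalibrationModel"))
  validObject(calibration)
  dc <- calibration@distCoeffs
  if (all(dc == 0)) return(frame)
  K <- calibration@cameraMatrix
  fx <- K[1, 1]; fy <- K[2, 2]; cx <- K[1, 3]; cy <- K[2, 3]
  h <- nrow(frame); w <- ncol(frame)
  xn <- matrix(rep((seq_len(w) - cx) / fx, each = h), h, w)
  yn <- matrix(rep((seq_len(h) - cy) / fy, w), h, w)
  r2 <- xn^2 + yn^2
  rad <- 1 + dc[1] * r2 + dc[2] * r2^2 + dc[5] * r2^3
  xd <- xn * rad + 2 * dc[3] * xn * yn + dc[4] * (r2 + 2 * xn^2)
  yd <- yn * rad + dc[3] * (r2 + 2 * yn^2) + 2 * dc[4] * xn * yn
  sx <- xd * fx + cx
  sy <- yd * fy + cy
  bilinearSample(frame, sx, sy)
}

# bilinear interpolation of frame at (sx, sy); coordinates clamped to
# the frame border
bilinearSample <- function(frame, sx, sy) {
  h <- nrow(frame); w <- ncol(frame)
  sx <- pmin(pmax(sx, 1), w)
  sy <- pmin(pmax(sy, 1), h)
  x0 <- pmin(floor(sx), w - 1); y0 <- pmin(floor(sy), h - 1)
  tx <- sx - x0; ty <- sy - y0
  i00 <- (x0 - 1) * h + y0
  v <- frame[i00] * (1 - tx) * (1 - ty) + frame[i00 + h] * tx * (1 - ty) +
    frame[i00 + 1] * (1 - tx) * ty + frame[i00 + h + 1] * tx * ty
  matrix(v, h, w)
}

#' Build the background model from the first and last frames
#'
#' Per-pixel maximum intensity of the two frames: any dark fly that
#' moved between the first and last frame disappears from the
#' background-only image.
#'
#' @param first,last numeric matrices of equal dimensions.
#' @return numeric matrix.
#' @export
buildBackground <- function(first, last) {
  if (!identical(dim(first), dim(last)))
    stop("first and last frames must have equal dimensions")
  pmax(first, last)
}

#' Detect and order the arena regions of interest
#'
#' Adaptive thresholding of the bright arenas against the dark surround,
#' hole filling, connected components, area filtering, then a circle (or
#' Y bounding region) fit per component. ROIs are sorted row-major by
#' 1-D clustering of centroid y (tolerance: half the median ROI
#' diameter), then by x within each row; ids are assigned in that order.
#' The mm-per-pixel scale is derived per ROI from the known physical
#' arena diameter.
#'
#' @param frame numeric matrix showing bright arenas on a dark surround.
#' @param expectedCount number of ROIs that must be found; a mismatch is
#'   an error naming both numbers.
#' @param shape "circle" or "ymaze".
#' @param arenaDiameterMm physical diameter (circle) or twice the
#'   centre-to-tip arm length (Y-maze), mm.
#' @param areaBounds length-2 numeric, components outside this area
#'   range (px^2) are discarded; by default components smaller than half
#'   the median component area are dropped.
#' @param offset adaptive-threshold offset, gray levels.
#' @return An [ArenaLayout-class].
#' @export
detectRois <- function(frame, expectedCount, shape = c("circle", "ymaze"),
                       arenaDiameterMm = 49, areaBounds = NULL,
                       offset = 5) {
  shape <- match.arg(shape)
  stopifnot(is.matrix(frame), expectedCount >= 1)
  # neighbourhood defaults to 1/8 of the smaller frame dimension
  win <- max(3L, as.integer(round(min(dim(frame)) / 16)))
  bin <- EBImage::thresh(frame / 255, w = win, h = win, offset = offset / 255)
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  nComp <- max(lab)
  if (nComp < 1)
    stop(sprintf("found 0 rois but expected %d", expectedCount))
  areas <- tabulate(lab[lab > 0], nComp)
  keep <- if (is.null(areaBounds)) {
    # arenas in one array share a size; noise specks are far smaller
    areas >= max(areas) / 4
  } else {
    areas >= areaBounds[1] & areas <= areaBounds[2]
  }
  ids <- which(keep)
  if (length(ids) != expectedCount)
    stop(sprintf("found %d rois but expected %d", length(ids),
                 expectedCount))
  px <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  cxs <- vapply(ids, function(k) mean(px[lv == k, 2]), 0)
  cys <- vapply(ids, function(k) mean(px[lv == k, 1]), 0)
  rads <- vapply(seq_along(ids), function(j) {
    k <- ids[j]
    if (shape == "circle") sqrt(sum(lv == k) / pi)
    else {  # arm length: maximum centroid-to-pixel distance
      p <- px[lv == k, , drop = FALSE]
      sqrt(max((p[, 2] - cxs[j])^2 + (p[, 1] - cys[j])^2))
    }
  }, 0)
  # row clustering on centroid y
  tol <- stats::median(rads)
  o <- order(cys)
  rowIdx <- integer(length(o))
  rowIdx[o[1]] <- 1L
  for (j in seq_along(o)[-1]) {
    rowIdx[o[j]] <- if (cys[o[j]] - cys[o[j - 1]] > tol)
      rowIdx[o[j - 1]] + 1L else rowIdx[o[j - 1]]
  }
  colIdx <- integer(length(o))
  for (rr in unique(rowIdx)) {
    inRow <- which(rowIdx == rr)
    colIdx[inRow[order(cxs[inRow])]] <- seq_along(inRow)
  }
  ord <- order(rowIdx, colIdx)
  roiTab <- data.frame(id = seq_along(ord), shape = shape,
                       cx_px = cxs[ord], cy_px = cys[ord],
                       radius_px = rads[ord], row = rowIdx[ord],
                       col = colIdx[ord],
                       mm_per_px = arenaDiameterMm / (2 * rads[ord]),
                       stringsAsFactors = FALSE)
  arenaLayout(roiTab, arenaDiameterMm)
}

#' Write / read an arena layout as CSV
#'
#' @param layout an [ArenaLayout-class].
#' @param path file path.
#' @return `readArenaLayout` returns an [ArenaLayout-class];
#'   `writeArenaLayout` returns `path` invisibly.
#' @export
writeArenaLayout <- function(layout, path) {
  r <- rois(layout)
  r$arena_diameter_mm <- layout@arenaDiameterMm
  utils::write.csv(r, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeArenaLayout
#' @export
readArenaLayout <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- r$arena_diameter_mm[1]
  r$arena_diameter_mm <- NULL
  arenaLayout(r, d)
}

#' Read / write a calibration model as a YAML config
#'
#' @param calibration a [CalibrationModel-class].
#' @param path file path.
#' @return `readCalibration` returns a [CalibrationModel-class].
#' @export
writeCalibration <- function(calibration, path) {
  K <- calibration@cameraMatrix
  dc <- calibration@distCoeffs
  yaml::write_yaml(list(fx = K[1, 1], fy = K[2, 2], cx = K[1, 3],
                        cy = K[2, 3], k1 = dc[[1]], k2 = dc[[2]],
                        p1 = dc[[3]], p2 = dc[[4]], k3 = dc[[5]]), path)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  v <- yaml::read_yaml(path)
  calibrationModel(v$fx, v$fy, v$cx, v$cy, v$k1, v$k2, v$p1, v$p2, v$k3)
}
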