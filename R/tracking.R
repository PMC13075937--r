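# Walking tracker: background subtraction, thresholding, centroid
# extraction, identity persistence (nearest-previous), hold-on-loss,
# unit conversion and the walking-threshold position filter.

# iterate over a frame source: 3-D array [h, w, n] or a generator
# function(i) -> matrix with attribute nFrames
frameSource <- function(frames) {
  if (is.function(frames)) {
    n <- attr(frames, "nFrames")
    if (is.null(n)) stop("frame generator must carry an nFrames attribute")
    list(n = as.integer(n), get = frames)
  } else {
    stopifnot(is.array(frames), length(dim(frames)) == 3L)
    list(n = dim(frames)[3], get = function(i) frames[, , i])
  }
}

#' Track one fly per ROI across a video
#'
#' Per frame and ROI the absolute difference between the background and
#' the frame is restricted to the ROI and thresholded; blobs of at least
#' `minBlobArea` pixels are kept. A single blob yields its centroid;
#' with several, the blob whose centroid is nearest the previously
#' stored position wins (equidistant tie: lowest blob label); with none,
#' the previous position is held with `detected = FALSE`. Frames before
#' the first detection are back-filled with the first detected position.
#' One fly per ROI is assumed throughout.
#'
#' @param frames 3-D numeric array `height x width x n` (0-255 scale) or
#'   a generator `function(i)` with attribute `nFrames`.
#' @param background numeric matrix from [buildBackground()].
#' @param layout an [ArenaLayout-class].
#' @param detectionThreshold gray-level threshold on the background
#'   difference above which pixels count as foreground (user-set per
#'   run; default 25).
#' @param minBlobArea minimum blob area, px^2.
#' @return list of [RawTrajectory-class], one per ROI, each of length
#'   equal to the frame count.
#' @export
trackWalking <- function(frames, background, layout,
                         detectionThreshold = 25, minBlobArea = 4) {
  src <- frameSource(frames)
  r <- rois(layout)
  if (!nrow(r)) stop("layout has no rois")
  f1 <- src$get(1)
  if (!identical(dim(f1), dim(background)))
    stop("background and frame dimensions differ")
  h <- nrow(background); w <- ncol(background)
  # per-roi bounding boxes and circular masks
  boxes <- lapply(seq_len(nrow(r)), function(k) {
    rad <- r$radius_px[k]
    x0 <- max(1L, floor(r$cx_px[k] - rad)); x1 <- min(w, ceiling(r$cx_px[k] + rad))
    y0 <- max(1L, floor(r$cy_px[k] - rad)); y1 <- min(h, ceiling(r$cy_px[k] + rad))
    xs <- x0:x1; ys <- y0:y1
    mask <- outer(ys - r$cy_px[k], xs - r$cx_px[k],
                  function(a, b) a^2 + b^2 <= rad^2)
    list(x0 = x0, y0 = y0, xs = xs, ys = ys, mask = mask)
  })
  n <- src$n
  nR <- nrow(r)
  X <- Y <- matrix(NA_real_, n, nR)
  DET <- matrix(FALSE, n, nR)
  NC <- matrix(0L, n, nR)
  last <- matrix(NA_real_, 2, nR)
  for (i in seq_len(n)) {
    fr <- if (i == 1) f1 else src$get(i)
    dif <- abs(background - fr)
    for (k in seq_len(nR)) {
      b <- boxes[[k]]
      sub <- dif[b$ys, b$xs, drop = FALSE]
      bin <- (sub >= detectionThreshold) & b$mask
      cand <- blobCentroids(bin, minBlobArea)
      NC[i, k] <- nrow(cand)
      if (nrow(cand) == 0) {
        if (!is.na(last[1, k])) { X[i, k] <- last[1, k]; Y[i, k] <- last[2, k] }
        next
      }
      cx <- cand$x + b$x0 - 1; cy <- cand$y + b$y0 - 1
      j <- if (nrow(cand) == 1 || is.na(last[1, k])) 1L else
        which.min((cx - last[1, k])^2 + (cy - last[2, k])^2)
      X[i, k] <- cx[j]; Y[i, k] <- cy[j]
      DET[i, k] <- TRUE
      last[, k] <- c(cx[j], cy[j])
    }
  }
  lapply(seq_len(nR), function(k) {
    xk <- X[, k]; yk <- Y[, k]
    first <- which(DET[, k])[1]
    if (is.na(first))
      stop(sprintf("roi %d: fly never detected", r$id[k]))
    if (first > 1) {  # back-fill frames before the first detection
      xk[seq_len(first - 1)] <- xk[first]
      yk[seq_len(first - 1)] <- yk[first]
    }
    new("RawTrajectory", roiId = as.integer(r$id[k]), xPx = xk, yPx = yk,
        detected = DET[, k], nCandidates = NC[, k])
  })
}

# centroids of connected components with area >= minArea in a logical
# matrix; returns data.frame(label, x, y, area) in local (col=x, row=y)
# coordinates, ordered by label
blobCentroids <- function(bin, minArea) {
  if (!any(bin)) return(data.frame(label = integer(0), x = numeric(0),
                                   y = numeric(0), area = integer(0)))
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  areas <- tabulate(lab[lab > 0], max(lab))
  keep <- which(areas >= minArea)
  if (!length(keep)) return(data.frame(label = integer(0), x = numeric(0),
                                       y = numeric(0), area = integer(0)))
  px <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  data.frame(label = keep,
             x = vapply(keep, function(k) mean(px[lv == k, 2]), 0),
             y = vapply(keep, function(k) mean(px[lv == k, 1]), 0),
             area = areas[keep])
}

#' Convert a raw pixel trajectory to real-world units
#'
#' Positions are re-expressed in arena coordinates: origin at the ROI
#' centre, x to the right, y upwards, in mm; time is the 0-based frame
#' index divided by the frame rate.
#'
#' @param raw a [RawTrajectory-class].
#' @param layout an [ArenaLayout-class] containing `raw`'s ROI.
#' @param rate frame rate, frames/s.
#' @return A [Trajectory-class].
#' @export
toMm <- function(raw, layout, rate) {
  r <- rois(layout)
  k <- match(raw@roiId, r$id)
  if (is.na(k)) stop(sprintf("roi id %d not found in layout", raw@roiId))
  s <- r$mm_per_px[k]
  n <- length(raw@xPx)
  new("Trajectory", roiId = raw@roiId, time = (seq_len(n) - 1) / rate,
      x = (raw@xPx - r$cx_px[k]) * s, y = -(raw@yPx - r$cy_px[k]) * s,
      detected = raw@detected)
}

#' Apply the walking-threshold position filter
#'
#' Minimal movements are filtered out by only updating the fly's
#' position when its displacement from the last updated position (the
#' anchor) reaches the walking threshold `tau` (default 0.8 mm/frame,
#' inclusive). Because the anchor, not the previous raw frame, is the
#' reference, sub-threshold jitter around a spot never registers, while
#' genuine slow locomotion still updates once the fly is `tau` away.
#' The filter is idempotent.
#'
#' @param traj a [Trajectory-class] (mm).
#' @param tau walking threshold, mm per frame (> 0).
#' @return A [FilteredTrajectory-class].
#' @export
walkingFilter <- function(traj, tau = 0.8) {
  stopifnot(is(traj, "Trajectory"))
  if (tau <= 0) stop("tau must be > 0")
  n <- length(traj@time)
  x <- traj@x; y <- traj@y
  fx <- fy <- numeric(n)
  upd <- logical(n)
  fx[1] <- x[1]; fy[1] <- y[1]; upd[1] <- TRUE
  ax <- x[1]; ay <- y[1]
  for (i in seq_len(n)[-1]) {
    if (sqrt((x[i] - ax)^2 + (y[i] - ay)^2) >= tau) {
      ax <- x[i]; ay <- y[i]
      upd[i] <- TRUE
    }
    fx[i] <- ax; fy[i] <- ay
  }
  new("FilteredTrajectory", roiId = traj@roiId, time = traj@time,
      x = fx, y = fy, detected = traj@detected, updated = upd)
}

#' Write a trajectory as CSV
#'
#' Columns: frame, time_s, x_mm, y_mm, detected and (for filtered
#' trajectories) updated.
#'
#' @param traj a [Trajectory-class] or [FilteredTrajectory-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  d <- data.frame(frame = seq_along(traj@time), time_s = traj@time,
                  x_mm = traj@x, y_mm = traj@y, detected = traj@detected)
  if (is(traj, "FilteredTrajectory")) d$updated <- traj@updated
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Legacy paired .TXT/.DAT export of a raw trajectory
#'
#' Writes the per-frame pixel coordinates as a tab-separated .DAT file
#' (columns x_px, y_px, one row per frame, no header) and a .TXT
#' metadata header (format version, ROI id, frame count, frame rate,
#' scale). The column dialect is versioned (`flyIndiv-dat-1`) rather
#' than asserted bit-compatible with earlier Buridan analysis software.
#'
#' @param raw a [RawTrajectory-class].
#' @param basePath path without extension; `.TXT` and `.DAT` are added.
#' @param rate frame rate, frames/s.
#' @param mmPerPx scale, mm per pixel.
#' @return character(2): the two paths written, invisibly.
#' @export
writeLegacyTxtDat <- function(raw, basePath, rate, mmPerPx) {
  datPath <- paste0(basePath, ".DAT")
  txtPath <- paste0(basePath, ".TXT")
  utils::write.table(data.frame(x_px = raw@xPx, y_px = raw@yPx),
                     datPath, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  writeLines(c("format: flyIndiv-dat-1",
               sprintf("roi_id: %d", raw@roiId),
               sprintf("n_frames: %d", length(raw@xPx)),
               sprintf("frame_rate_hz: %g", rate),
               sprintf("mm_per_px: %g", mmPerPx),
               "columns: x_px\ty_px"), txtPath)
  invisible(c(txtPath, datPath))
}
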