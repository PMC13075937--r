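# Tethered-flight heading tracker: dual-scale Gaussian segmentation,
# ellipse-fit body axis from second central moments, head-end
# disambiguation by quadrant pixel sums, and wing (flight-stop)
# detection.

# separable Gaussian blur with edge renormalization (truncated at 3
# sigma); frames are small close-ups, so dense convolution matrices are
# cheapest and exact at the borders
gaussianBlur <- function(frame, sigma) {
  if (sigma <= 0) return(frame)
  mk <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    K <- stats::dnorm(d, sd = sigma)
    K[d > 3 * sigma] <- 0
    K / rowSums(K)
  }
  mk(nrow(frame)) %*% frame %*% t(mk(ncol(frame)))
}

#' Default flight-tracker configuration
#'
#' Sigmas are tuned to the renderer's default fly size (about 60 px body
#' length) and should be scaled linearly with the configured fly size.
#'
#' @param strongSigma Gaussian sigma (px) that blurs out legs and wings,
#'   leaving only the body above threshold.
#' @param weakSigma weaker sigma (px) that preserves appendages.
#' @param threshold gray level below which blurred pixels count as fly
#'   (the fly is dark on a bright backlight).
#' @param wingFraction flying is declared over when the appendage pixel
#'   count within the lateral sectors exceeds this fraction of the body
#'   pixel count.
#' @param wingGuardPx appendage pixels closer than this to the body mask
#'   are ignored by the wing criterion: the two blur scales disagree by
#'   a thin rim along the body outline, which must not count as wings.
#' @param minBodyPx minimum body-mask size for a valid frame.
#' @return named list.
#' @export
flightConfig <- function(strongSigma = 5, weakSigma = 2, threshold = 120,
                         wingFraction = 0.05, wingGuardPx = 6,
                         minBodyPx = 5) {
  stopifnot(strongSigma > weakSigma, weakSigma >= 0, threshold > 0,
            wingFraction > 0, wingGuardPx >= 0)
  list(strongSigma = strongSigma, weakSigma = weakSigma,
       threshold = threshold, wingFraction = wingFraction,
       wingGuardPx = wingGuardPx, minBodyPx = minBodyPx)
}

#' Segment a tethered fly at two blur scales
#'
#' The strongly blurred frame thresholds only the fly's body (legs and
#' wings are smoothed away); subtracting the body pixels from the
#' weak-blur mask leaves the appendages (limbs, and the wings that
#' become visible when the fly stops flying). Because the two blur
#' scales disagree by a thin rim along the body outline, the body mask
#' is grown by `wingGuardPx` before the subtraction, so the appendage
#' mask holds genuine appendages only.
#'
#' @param frame numeric matrix, 0-255 gray levels, dark fly on bright
#'   background.
#' @param config a [flightConfig()].
#' @return list of class `FlightSegmentation` with logical matrices
#'   `bodyMask` and `appendageMask` (disjoint), or `NULL` if no body
#'   pixels are found (fly not found).
#' @export
segmentFly <- function(frame, config = flightConfig()) {
  body <- gaussianBlur(frame, config$strongSigma) <= config$threshold
  # no body pixels, or "body" covering most of the frame (e.g. an
  # all-dark image), cannot be a fly silhouette
  if (sum(body) < config$minBodyPx || mean(body) > 0.5) return(NULL)
  weak <- gaussianBlur(frame, config$weakSigma) <= config$threshold
  grown <- body
  if (config$wingGuardPx > 0) {
    brush <- EBImage::makeBrush(2 * config$wingGuardPx + 1, "disc")
    grown <- EBImage::imageData(EBImage::dilate(
      EBImage::Image(body * 1), brush)) > 0
  }
  structure(list(bodyMask = body, appendageMask = weak & !grown),
            class = "FlightSegmentation")
}

#' Body-axis angle of a segmented fly
#'
#' Orientation of the best-fit ellipse via second central moments,
#' mapped to [0, 180) degrees, measured counter-clockwise from image +x
#' (mathematical convention, image y pointing down).
#'
#' @param bodyMask logical matrix with at least 5 pixels.
#' @param minElongation minimum relative difference of the two moment
#'   eigenvalues below which the mask is considered isotropic.
#' @return degrees in [0, 180).
#' @export
bodyAxis <- function(bodyMask, minElongation = 0.05) {
  px <- which(bodyMask, arr.ind = TRUE)
  if (nrow(px) < 5) stop("body mask has fewer than 5 pixels")
  dx <- px[, 2] - mean(px[, 2])
  dy <- -(px[, 1] - mean(px[, 1]))  # flip image y so angles are CCW
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  spread <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  if (spread < minElongation * (mu20 + mu02))
    stop("degenerate (isotropic) body mask: no defined axis")
  (rad2deg(0.5 * atan2(2 * mu11, mu20 - mu02))) %% 180
}

#' Resolve the 0-360 degree heading from the body axis
#'
#' The mask centroid is set to (0, 0) and the body axis aligned with the
#' x axis of a fictive coordinate system; the head is assigned to
#' whichever half (quadrants I+IV, x > 0, versus II+III, x < 0) holds
#' the smaller pixel sum, since head plus thorax are narrower than the
#' abdomen. The heading is `axis` or `axis + 180` accordingly.
#'
#' @param bodyMask logical matrix.
#' @param axis degrees in [0, 180) from [bodyAxis()].
#' @return degrees in [0, 360), or `NA_real_` when the two half sums are
#'   exactly equal (caller retains the previous side and flags the
#'   frame).
#' @export
resolveHeading <- function(bodyMask, axis) {
  px <- which(bodyMask, arr.ind = TRUE)
  dx <- px[, 2] - mean(px[, 2])
  dy <- px[, 1] - mean(px[, 1])  # image y (down)
  th <- deg2rad(axis)
  u <- dx * cos(th) - dy * sin(th)  # along-axis coordinate
  headPos <- sum(u > 0); headNeg <- sum(u < 0)
  if (headPos == headNeg) return(NA_real_)
  if (headPos < headNeg) axis %% 360 else (axis + 180) %% 360
}

#' Track a tethered fly's heading across a frame stack
#'
#' Per frame: dual-scale segmentation, moment-based axis fit and
#' head-end disambiguation. Degenerate frames (no fly, isotropic mask,
#' or an exactly tied head test) carry the previous value and are
#' flagged, never interpolated. `flying` turns FALSE on frames whose
#' lateral appendage pixel count (wings) exceeds
#' `wingFraction x body pixels`.
#'
#' @param frames 3-D array `h x w x n` (0-255) or generator
#'   `function(i)` with attribute `nFrames`.
#' @param config a [flightConfig()].
#' @param rate frame rate, frames/s.
#' @return A [HeadingSeries-class]; attribute `failed` is TRUE when more
#'   than half the frames had no detectable fly.
#' @export
trackFlight <- function(frames, config = flightConfig(), rate = 90) {
  src <- frameSource(frames)
  n <- src$n
  heading <- axisA <- numeric(n)
  flying <- rep(TRUE, n)
  flagged <- logical(n)
  lost <- 0L
  prevHeading <- NA_real_
  prevAxis <- NA_real_
  for (i in seq_len(n)) {
    seg <- segmentFly(src$get(i), config)
    if (is.null(seg)) {
      lost <- lost + 1L
      flagged[i] <- TRUE
      heading[i] <- if (is.na(prevHeading)) 0 else prevHeading
      axisA[i] <- if (is.na(prevAxis)) 0 else prevAxis
      next
    }
    ax <- tryCatch(bodyAxis(seg$bodyMask), error = function(e) NA_real_)
    if (is.na(ax)) {
      flagged[i] <- TRUE
      heading[i] <- if (is.na(prevHeading)) 0 else prevHeading
      axisA[i] <- if (is.na(prevAxis)) 0 else prevAxis
      next
    }
    hd <- resolveHeading(seg$bodyMask, ax)
    if (is.na(hd)) {  # tied halves: keep the previous heading's side
      flagged[i] <- TRUE
      hd <- if (is.na(prevHeading)) ax else {
        cand <- c(ax, (ax + 180)) %% 360
        cand[which.min(abs(wrapDiff(cand - prevHeading)))]
      }
    }
    # wing detection in the lateral sectors around the axis
    if (any(seg$appendageMask)) {
      ap <- which(seg$appendageMask, arr.ind = TRUE)
      px <- which(seg$bodyMask, arr.ind = TRUE)
      cx <- mean(px[, 2]); cy <- mean(px[, 1])
      th <- deg2rad(ax)
      au <- (ap[, 2] - cx) * cos(th) - (ap[, 1] - cy) * sin(th)
      av <- (ap[, 2] - cx) * sin(th) + (ap[, 1] - cy) * cos(th)
      # lateral sectors: bearings more than ~22 deg off the body axis,
      # where folded wings flare out beyond the body outline
      if (sum(abs(av) > 0.4 * abs(au)) > config$wingFraction * nrow(px))
        flying[i] <- FALSE
    }
    heading[i] <- hd
    axisA[i] <- ax
    prevHeading <- hd
    prevAxis <- ax
  }
  out <- headingSeries(time = (seq_len(n) - 1) / rate, heading = heading,
                       flying = flying, axisAngle = axisA,
                       flagged = flagged)
  if (lost > n / 2) {
    warning(sprintf("fly not found in %d of %d frames: run flagged as failed",
                    lost, n))
    attr(out, "failed") <- TRUE
  }
  out
}

#' Unwrap a heading series to a continuous angle
#'
#' Successive differences are mapped to the shortest signed arc
#' (-180, 180] and cumulatively summed from the first heading, giving an
#' unbounded rotation angle suitable for rotational-velocity estimates.
#'
#' @param series a [HeadingSeries-class] or numeric vector of degrees.
#' @return numeric vector, degrees (unbounded).
#' @export
unwrapHeadings <- function(series) {
  h <- if (is(series, "HeadingSeries")) series@heading else series
  if (!length(h)) stop("empty heading series")
  h[1] + c(0, cumsum(wrapDiff(diff(h))))
}

#' Write a heading series as CSV
#'
#' Columns: frame, time_s, heading_deg, axis_deg, flying, flagged.
#'
#' @param series a [HeadingSeries-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeHeadingSeries <- function(series, path) {
  utils::write.csv(data.frame(frame = seq_along(series@time),
                              time_s = series@time,
                              heading_deg = series@heading,
                              axis_deg = series@axisAngle,
                              flying = series@flying,
                              flagged = series@flagged),
                   path, row.names = FALSE)
  invisible(path)
}
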