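# Configuration, frame I/O and the command-line pipeline tying the
# stages together: simulate -> detect -> track -> params -> stats.
# All tabular outputs are UTF-8 CSV with headers; angles in degrees,
# times in seconds, positions in mm. Videos are handled as 8-bit
# grayscale PNG frame sequences (one file per frame) or in-memory
# arrays.

#' Default run configuration
#'
#' Nested list of every tunable of the pipeline with its default:
#' simulation sizes, arena geometry, tracker thresholds (detection gray
#' levels, minimum blob area, walking threshold 0.8 mm/frame, frame
#' rate), flight-tracker settings and statistics settings (lambda grid
#' size, CV folds, bootstrap iterations, seed).
#'
#' @return named nested list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    simulate = list(nFlies = 4L, arenaRadiusMm = 24.5, durationS = 20,
                    rateHz = 15, grid = c(2L, 2L), frameWidth = 240L,
                    frameHeight = 240L, noiseSd = 2),
    arena = list(shape = "circle", expectedCount = 4L, diameterMm = 49),
    tracker = list(detectionThreshold = 25, minBlobArea = 4,
                   walkingTauMm = 0.8, rateHz = 15),
    flight = list(strongSigma = 5, weakSigma = 2, threshold = 120,
                  wingFraction = 0.05, pauseMinDuration = 0.2,
                  rateHz = 90),
    stats = list(folds = 5L, nLambda = 25L, B = 1000L))
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read and validate a run configuration
#'
#' Reads a YAML file, merges it over [defaultRunConfig()] and validates
#' field by field; an invalid value raises an error naming the field.
#'
#' @param path YAML file, or NULL for the defaults.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  }
  chk <- function(ok, field) if (!ok) stop("invalid config field: ", field)
  chk(cfg$tracker$detectionThreshold > 0, "tracker.detectionThreshold")
  chk(cfg$tracker$minBlobArea > 0, "tracker.minBlobArea")
  chk(cfg$tracker$walkingTauMm > 0, "tracker.walkingTauMm")
  chk(cfg$tracker$rateHz > 0, "tracker.rateHz")
  chk(cfg$flight$strongSigma > cfg$flight$weakSigma, "flight.strongSigma")
  chk(cfg$flight$threshold > 0, "flight.threshold")
  chk(cfg$simulate$nFlies >= 1, "simulate.nFlies")
  chk(cfg$stats$folds >= 2, "stats.folds")
  chk(cfg$stats$B >= 2, "stats.B")
  cfg
}

#' Write / read a video as a PNG frame sequence
#'
#' Frames are written as 8-bit grayscale PNGs named `frame_000001.png`,
#' ... so a directory round-trips through `readFrameDir` as a frame
#' generator usable by the trackers.
#'
#' @param frames 3-D array `h x w x n`, 0-255 scale, or generator.
#' @param dir directory (created if missing).
#' @return `writeFrameDir`: the directory, invisibly; `readFrameDir`: a
#'   generator `function(i)` with attribute `nFrames`.
#' @export
writeFrameDir <- function(frames, dir) {
  src <- frameSource(frames)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(src$n)) {
    m <- src$get(i)
    png::writePNG(matrix(pmin(1, pmax(0, m / 255)), nrow(m), ncol(m)),
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}

#' @rdname writeFrameDir
#' @export
readFrameDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir)
  gen <- function(i) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3L) {
      warning("color frame converted to luma")
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    }
    img * 255
  }
  attr(gen, "nFrames") <- length(files)
  gen
}

# run log: config hash, seed, package version, timestamp
writeRunLog <- function(outDir, step, cfg, configPath = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- if (!is.null(configPath) && file.exists(configPath))
    unname(tools::md5sum(configPath)) else "defaults"
  writeLines(c(sprintf("step: %s", step),
               sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               sprintf("config_md5: %s", hash),
               sprintf("seed: %d", as.integer(cfg$seed)),
               sprintf("flyIndiv_version: %s",
                       as.character(utils::packageVersion("flyIndiv")))),
             file.path(outDir, sprintf("log_%s.txt", step)))
}

# simulate a small multi-arena cohort video plus ground truth
runSimulate <- function(cfg, outDir) {
  s <- cfg$simulate
  nR <- prod(s$grid)
  margin <- 10
  cellW <- (s$frameWidth - 2 * margin) / s$grid[2]
  cellH <- (s$frameHeight - 2 * margin) / s$grid[1]
  radPx <- 0.45 * min(cellW, cellH)
  roiTab <- do.call(rbind, lapply(seq_len(nR), function(k) {
    rr <- (k - 1) %/% s$grid[2] + 1; cc <- (k - 1) %% s$grid[2] + 1
    data.frame(id = k, shape = "circle",
               cx_px = margin + (cc - 0.5) * cellW,
               cy_px = margin + (rr - 0.5) * cellH,
               radius_px = radPx, row = rr, col = cc,
               mm_per_px = (2 * s$arenaRadiusMm) / (2 * radPx))
  }))
  layout <- arenaLayout(roiTab, 2 * s$arenaRadiusMm)
  ctx <- contextModifier("sim")
  walks <- lapply(seq_len(nR), function(k) {
    prof <- latentFlyProfile(sprintf("fly%02d", k),
                             baseSpeed = 8 + 4 * ((k - 1) %% 3),
                             activity = 0.4 + 0.12 * ((k - 1) %% 4),
                             stripeAttraction = 0.15, edgeBias = 0.2)
    simulateWalk(prof, ctx, arenaRadius = 0.8 * s$arenaRadiusMm,
                 duration = s$durationS, rate = s$rateHz,
                 seed = cfg$seed + k)
  })
  frames <- renderArenaFrames(lapply(walks, `[[`, "trajectory"), layout,
                              width = s$frameWidth, height = s$frameHeight,
                              noiseSd = s$noiseSd, seed = cfg$seed,
                              asFunction = TRUE)
  writeFrameDir(frames, file.path(outDir, "video"))
  utils::write.csv(attr(frames, "groundTruthPx"),
                   file.path(outDir, "ground_truth_px.csv"),
                   row.names = FALSE)
  writeArenaLayout(layout, file.path(outDir, "layout.csv"))
  invisible(layout)
}

runTrackWalk <- function(cfg, videoDir, outDir) {
  gen <- readFrameDir(videoDir)
  n <- attr(gen, "nFrames")
  background <- buildBackground(gen(1), gen(n))
  layout <- detectRois(background, expectedCount = cfg$arena$expectedCount,
                       shape = cfg$arena$shape,
                       arenaDiameterMm = cfg$arena$diameterMm)
  raws <- trackWalking(gen, background, layout,
                       detectionThreshold = cfg$tracker$detectionThreshold,
                       minBlobArea = cfg$tracker$minBlobArea)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeArenaLayout(layout, file.path(outDir, "layout.csv"))
  for (k in seq_along(raws)) {
    tr <- toMm(raws[[k]], layout, cfg$tracker$rateHz)
    ft <- walkingFilter(tr, cfg$tracker$walkingTauMm)
    writeTrajectory(ft, file.path(outDir, sprintf("traj_roi%02d.csv", k)))
    writeLegacyTxtDat(raws[[k]], file.path(outDir, sprintf("raw_roi%02d", k)),
                      cfg$tracker$rateHz, rois(layout)$mm_per_px[k])
  }
  invisible(raws)
}

runParamsWalk <- function(cfg, trackDir, outDir) {
  files <- sort(list.files(trackDir, pattern = "^traj_roi.*\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no trajectory CSVs found in ", trackDir)
  profiles <- lapply(seq_along(files), function(k) {
    d <- utils::read.csv(files[k])
    ft <- new("FilteredTrajectory", roiId = k, time = d$time_s,
              x = d$x_mm, y = d$y_mm, detected = as.logical(d$detected),
              updated = as.logical(d$updated))
    computeProfile(ft, flyId = sprintf("fly%02d", k), contextId = "run",
                   rate = cfg$tracker$rateHz,
                   arenaRadius = cfg$arena$diameterMm / 2)
  })
  sp <- excludeNonmovers(profiles)
  if (length(sp$excluded))
    message(sprintf("excluded %d non-mover(s)", length(sp$excluded)))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeProfiles(sp$kept, file.path(outDir, "profiles.csv"))
  invisible(sp)
}

runStats <- function(cfg, tableCsv, outDir) {
  tab <- utils::read.csv(tableCsv, stringsAsFactors = FALSE)
  checkBehaviorTable(tab)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- list(seed = cfg$seed)
  for (tr in unique(tab$trait)) {
    ctxs <- unique(tab$context)
    cors <- list()
    if (length(ctxs) >= 2) {
      prs <- utils::combn(ctxs, 2, simplify = FALSE)
      cors <- lapply(prs, function(p) {
        r <- tryCatch(pearsonAcrossContexts(tab, tr, p[1], p[2]),
                      error = function(e) list(r = NA, p = NA, n = NA))
        c(list(contextA = p[1], contextB = p[2]), r)
      })
    }
    lmm <- tryCatch({
      f <- fitTraitLMM(tab, tr)
      list(icc = f$icc, sigma2_between = f$sigma2Between,
           sigma2_within = f$sigma2Within, singular = f$singular,
           fixed = f$fixed)
    }, error = function(e) list(error = conditionMessage(e)))
    out[[tr]] <- list(correlations = cors, lmm = lmm)
  }
  jsonlite::write_json(out, file.path(outDir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out)
}

#' Command-line entry point
#'
#' Thin dispatcher over the pipeline stages, used by the
#' `inst/scripts/flyindiv.R` wrapper:
#' \describe{
#'   \item{simulate}{render a synthetic multi-arena video plus ground
#'     truth into `--out`.}
#'   \item{track-walk}{track a PNG frame-sequence video (`--video`) and
#'     write trajectory CSVs and legacy .TXT/.DAT exports.}
#'   \item{track-flight}{track a tethered-fly close-up video and write
#'     the heading CSV.}
#'   \item{params}{compute behavior profiles from tracked trajectories
#'     (`--track`).}
#'   \item{stats}{correlation / mixed-model report from a long-format
#'     behavior table (`--table`).}
#' }
#' Every stage writes a log with the config hash, seed and package
#' version. Invalid configs and missing inputs exit non-zero with a
#' field-level message.
#'
#' @param args character vector: subcommand followed by `--config
#'   <yaml>`, `--out <dir>` and the stage's input flag.
#' @return exit status, invisibly (0 on success).
#' @export
flyIndivCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: flyindiv.R <simulate|track-walk|track-flight|",
                 "params|stats> [--config cfg.yaml] --out DIR",
                 "[--video DIR] [--track DIR] [--table CSV]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  sub <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  status <- tryCatch({
    cfg <- readRunConfig(opt("--config"))
    outDir <- opt("--out")
    if (is.null(outDir)) stop("--out is required")
    switch(sub,
      "simulate" = runSimulate(cfg, outDir),
      "track-walk" = {
        v <- opt("--video")
        if (is.null(v) || !dir.exists(v)) stop("missing input video dir")
        runTrackWalk(cfg, v, outDir)
      },
      "track-flight" = {
        v <- opt("--video")
        if (is.null(v) || !dir.exists(v)) stop("missing input video dir")
        hs <- trackFlight(readFrameDir(v),
                          flightConfig(cfg$flight$strongSigma,
                                       cfg$flight$weakSigma,
                                       cfg$flight$threshold,
                                       cfg$flight$wingFraction),
                          rate = cfg$flight$rateHz)
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeHeadingSeries(hs, file.path(outDir, "headings.csv"))
      },
      "params" = {
        v <- opt("--track")
        if (is.null(v) || !dir.exists(v)) stop("missing tracking dir")
        runParamsWalk(cfg, v, outDir)
      },
      "stats" = {
        v <- opt("--table")
        if (is.null(v) || !file.exists(v)) stop("missing behavior table")
        runStats(cfg, v, outDir)
      },
      stop("unknown subcommand: ", sub))
    writeRunLog(outDir, sub, cfg, opt("--config"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
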