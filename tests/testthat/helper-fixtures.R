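# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

# single circular arena layout: centre (60, 60), radius 50 px, 49 mm
singleArenaLayout <- function() {
  arenaLayout(data.frame(id = 1L, shape = "circle", cx_px = 60,
                         cy_px = 60, radius_px = 50, row = 1L, col = 1L,
                         mm_per_px = 0.49),
              arenaDiameterMm = 49)
}

# grid of circular arenas, centres spaced regularly
gridArenaLayout <- function(nrow = 5, ncol = 5, pitch = 80, radius = 35,
                            margin = 40, mmPerPx = 0.7) {
  tab <- do.call(rbind, lapply(seq_len(nrow * ncol), function(k) {
    rr <- (k - 1) %/% ncol + 1; cc <- (k - 1) %% ncol + 1
    data.frame(id = k, shape = "circle",
               cx_px = margin + (cc - 1) * pitch,
               cy_px = margin + (rr - 1) * pitch,
               radius_px = radius, row = rr, col = cc,
               mm_per_px = mmPerPx)
  }))
  arenaLayout(tab, arenaDiameterMm = 2 * radius * mmPerPx)
}

# fly-free background for a layout: bright disks on a dark surround
layoutBackground <- function(layout, width, height, arenaIntensity = 200,
                             bgIntensity = 30) {
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  bg <- matrix(bgIntensity, height, width)
  r <- rois(layout)
  for (k in seq_len(nrow(r)))
    bg[(xs - r$cx_px[k])^2 + (ys - r$cy_px[k])^2 <= r$radius_px[k]^2] <-
      arenaIntensity
  bg
}

# fly-free background matching singleArenaLayout()
singleArenaBackground <- function() layoutBackground(singleArenaLayout(),
                                                     120, 120)

# short simulated walk in the single arena
fixtureWalk <- function(seed = 3, duration = 10, rate = 15,
                        activity = 0.8) {
  simulateWalk(latentFlyProfile(baseSpeed = 12, activity = activity,
                                stripeAttraction = 0.2, edgeBias = 0.2),
               contextModifier("fix"), arenaRadius = 18,
               duration = duration, rate = rate, seed = seed)
}

# straight-line trajectory along +x with the given per-frame steps (mm)
stepTrajectory <- function(steps, rate = 15) {
  x <- cumsum(c(0, steps))
  trajectory(time = (seq_along(x) - 1) / rate, x = x, y = rep(0, length(x)))
}

wrapDiff180 <- function(d) {
  o <- ((d + 180) %% 360) - 180
  o[o == -180] <- 180
  o
}

# contexts used by the statistics fixtures
fourContexts <- function() {
  list(contextModifier("c1", day = 1, temperature = 25),
       contextModifier("c2", day = 2, temperature = 32),
       contextModifier("c3", day = 3, light = 0),
       contextModifier("c4", day = 3, arena = 1))
}
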