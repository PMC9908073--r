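# Synthetic miniscope sessions: place-cell populations on a linear track,
# category-modulated populations for an instrumental task, scripted rigid
# image motion, smooth background, sensor noise -- with full ground truth.

#' Generate a back-and-forth linear-track trajectory
#'
#' Simulates constant-speed runs between the ends of a linear track with a
#' configurable dwell at each end. The path is circularized: the rightward
#' leg occupies bins `1..K/2` and the leftward leg bins `K/2+1..K`, so the
#' bin index is a deterministic function of position and running direction.
#'
#' @param nFrames number of frames to simulate.
#' @param trackLength_cm track length L in cm (default 250).
#' @param fps frame rate (default 20).
#' @param speed_cm_s running speed in cm/s (default 50, capped at
#'   `vMax_cm_s`).
#' @param pause_s dwell time at each end of the track, seconds.
#' @param K number of circularized position bins (even, default 24).
#' @param vMax_cm_s maximum permissible running speed (default 150 cm/s).
#' @param speedSd_cm_s per-run random speed perturbation (sd, cm/s); 0 gives
#'   a fully deterministic trajectory.
#' @param seed integer seed.
#' @return data.frame with per-frame `position_cm`, `direction`
#'   ("rightward"/"leftward"), and `bin` in 1..K; attributes `fps`,
#'   `trackLength_cm`, `K`.
#' @export
generateTrajectory <- function(nFrames, trackLength_cm = 250, fps = 20,
                               speed_cm_s = 50, pause_s = 0.5, K = 24L,
                               vMax_cm_s = 150, speedSd_cm_s = 0, seed = 1L) {
  if (trackLength_cm <= 0 || fps <= 0 || nFrames < 1 || speed_cm_s <= 0)
    stop("trackLength_cm, fps, nFrames and speed_cm_s must be positive")
  if (K %% 2L != 0L) stop("K must be even")
  set.seed(seed)
  L <- trackLength_cm
  baseSpeed <- min(speed_cm_s, vMax_cm_s)
  pauseFrames <- round(pause_s * fps)
  pos <- numeric(nFrames); dirn <- character(nFrames)
  x <- 0; dr <- 1L; pauseLeft <- 0L
  runSpeed <- function() {
    s <- baseSpeed + if (speedSd_cm_s > 0) rnorm(1, 0, speedSd_cm_s) else 0
    min(max(s, 1), vMax_cm_s)
  }
  sp <- runSpeed()
  for (f in seq_len(nFrames)) {
    if (pauseLeft > 0L) {
      pauseLeft <- pauseLeft - 1L
    } else {
      x <- x + dr * sp / fps
      if (x >= L) { x <- L; dr <- -1L; pauseLeft <- pauseFrames; sp <- runSpeed() }
      if (x <= 0) { x <- 0; dr <- 1L; pauseLeft <- pauseFrames; sp <- runSpeed() }
    }
    pos[f] <- x
    dirn[f] <- if (dr > 0L) "rightward" else "leftward"
  }
  out <- data.frame(position_cm = pos, direction = dirn,
                    bin = positionToBin(pos, dirn, trackLength_cm = L, K = K))
  attr(out, "fps") <- fps
  attr(out, "trackLength_cm") <- L
  attr(out, "K") <- K
  out
}

#' Map track position and direction to a circularized bin index
#'
#' The two running directions are unwrapped onto a loop of length 2L; the
#' rightward leg maps to bins `1..K/2` and the leftward leg to `K/2+1..K`,
#' each bin spanning `2L/K` cm of path.
#'
#' @param position_cm position(s) in `[0, L]`.
#' @param direction "rightward" or "leftward", recycled.
#' @param trackLength_cm track length L.
#' @param K total bin count (even).
#' @return integer bin indices in 1..K.
#' @export
positionToBin <- function(position_cm, direction, trackLength_cm = 250,
                          K = 24L) {
  half <- K %/% 2L
  w <- trackLength_cm / half
  right <- direction == "rightward"
  b <- integer(length(position_cm))
  b[right] <- pmin(half, floor(position_cm[right] / w) + 1L)
  b[!right] <- half +
    pmin(half, floor((trackLength_cm - position_cm[!right]) / w) + 1L)
  as.integer(b)
}

# Gaussian footprint patch with circular truncation, peak 1
.footprintPatch <- function(radius_px, sigma_px) {
  d <- seq(-radius_px, radius_px)
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma_px^2))
  g[outer(d^2, d^2, "+") > radius_px^2] <- 0
  g
}

# scatter footprint centers over the frame interior on a jittered grid
.placeFootprints <- function(nCells, frameDim, radius_px, jitter_px, seed) {
  margin <- radius_px + 1L
  lo <- margin + 1L
  hiR <- frameDim[1] - margin; hiC <- frameDim[2] - margin
  if (hiR <= lo || hiC <= lo)
    stop("footprints of radius ", radius_px,
         " do not fit inside a ", frameDim[1], " x ", frameDim[2], " frame")
  g <- ceiling(sqrt(nCells))
  rows <- round(seq(lo, hiR, length.out = g))
  cols <- round(seq(lo, hiC, length.out = g))
  grid <- expand.grid(row = rows, col = cols)[seq_len(nCells), ]
  set.seed(seed)
  grid$row <- pmin(hiR, pmax(lo, grid$row +
    sample(seq(-jitter_px, jitter_px), nCells, replace = TRUE)))
  grid$col <- pmin(hiC, pmax(lo, grid$col +
    sample(seq(-jitter_px, jitter_px), nCells, replace = TRUE)))
  grid
}

#' Generate a spatially tuned (place-cell) ground-truth population
#'
#' Field centers tile the track; direction preference alternates between
#' cells; footprints are truncated 2D Gaussians scattered over the frame
#' interior (disjointness is not enforced).
#'
#' @param nCells number of cells.
#' @param frameDim integer c(height, width) of the working frame.
#' @param trackLength_cm track length L.
#' @param fieldWidth_cm place-field width (FWHM of the Gaussian spatial
#'   tuning), cm.
#' @param amplitude peak fluorescence drive per cell (8-bit units).
#' @param decayHalftime_s indicator half decay time, seconds (GCaMP7s-like
#'   default 0.7).
#' @param footprintRadius_px truncation radius of the footprint.
#' @param footprintSigma_px Gaussian width of the footprint.
#' @param jitter_px random placement jitter applied to the footprint grid.
#' @param seed integer seed.
#' @return list of cells; each has `footprint` (patch matrix, peak 1),
#'   `center` (row, col), `field_center_cm`, `field_width_cm`,
#'   `direction_pref`, `amplitude`, `decay_halftime_s`.
#' @export
generatePlaceCells <- function(nCells, frameDim = c(512L, 512L),
                               trackLength_cm = 250, fieldWidth_cm = 20,
                               amplitude = 70, decayHalftime_s = 0.7,
                               footprintRadius_px = 6L,
                               footprintSigma_px = 2.5, jitter_px = 2L,
                               seed = 1L) {
  if (nCells < 1) stop("nCells must be >= 1")
  if (fieldWidth_cm <= 0 || decayHalftime_s <= 0)
    stop("field widths and decay half-times must be positive")
  centers_cm <- seq(trackLength_cm / (2 * nCells),
                    trackLength_cm * (1 - 1 / (2 * nCells)),
                    length.out = nCells)
  pos <- .placeFootprints(nCells, frameDim, footprintRadius_px, jitter_px,
                          seed)
  patch <- .footprintPatch(footprintRadius_px, footprintSigma_px)
  lapply(seq_len(nCells), function(i) list(
    footprint = patch,
    center = c(pos$row[i], pos$col[i]),
    field_center_cm = centers_cm[i],
    field_width_cm = fieldWidth_cm,
    direction_pref = if (i %% 2L) "rightward" else "leftward",
    amplitude = amplitude,
    decay_halftime_s = decayHalftime_s))
}

#' Noiseless per-cell activation traces for a trajectory
#'
#' The instantaneous drive is a Gaussian function of position (peak at the
#' field center, FWHM = field width), gated by running direction. Indicator
#' dynamics follow a peak-hold exponential decay with per-cell half-time:
#' `a(f) = max(drive(f), a(f-1) * 2^(-1/(halftime*fps)))`, so an isolated
#' impulse falls to 50% after `halftime * fps` frames.
#'
#' @param cells list of ground-truth cells.
#' @param trajectory data.frame from [generateTrajectory()].
#' @param fps frame rate; defaults to the trajectory's.
#' @return matrix cells x frames of noiseless activations.
#' @export
cellActivations <- function(cells, trajectory, fps = attr(trajectory, "fps")) {
  n <- nrow(trajectory)
  act <- matrix(0, length(cells), n)
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    sig <- cl$field_width_cm / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    drive <- cl$amplitude *
      exp(-(trajectory$position_cm - cl$field_center_cm)^2 / (2 * sig^2)) *
      (trajectory$direction == cl$direction_pref)
    dec <- 2^(-1 / (cl$decay_halftime_s * fps))
    a <- numeric(n); prev <- 0
    for (f in seq_len(n)) {
      prev <- max(drive[f], prev * dec)
      a[f] <- prev
    }
    act[i, ] <- a
  }
  act
}

#' Build a per-frame rigid motion script
#'
#' Jitter events displace the image transiently and return to the pre-event
#' offset; shift events persist to the end of the session.
#'
#' @param nFrames frames in the session.
#' @param events list of events, each
#'   `list(frame=, dx=, dy=, kind="jitter"|"shift", duration=)` (duration is
#'   ignored for shifts).
#' @return data.frame with per-frame integer `dx`, `dy` and `kind`
#'   ("none" where no jitter is active; "shift" from a shift onset onward).
#' @export
motionScript <- function(nFrames, events = list()) {
  dx <- integer(nFrames); dy <- integer(nFrames)
  kind <- rep("none", nFrames)
  for (ev in events) {
    stopifnot(ev$frame >= 1, ev$frame <= nFrames)
    if (identical(ev$kind, "shift")) {
      idx <- ev$frame:nFrames
      kind[idx][kind[idx] == "none"] <- "shift"
    } else {
      dur <- if (is.null(ev$duration)) 1L else ev$duration
      idx <- ev$frame:min(nFrames, ev$frame + dur - 1L)
      kind[idx] <- "jitter"
    }
    dx[idx] <- dx[idx] + as.integer(ev$dx)
    dy[idx] <- dy[idx] + as.integer(ev$dy)
  }
  data.frame(dx = dx, dy = dy, kind = kind)
}

# default low-order polynomial background
.backgroundMatrix <- function(frameDim, bg) {
  H <- frameDim[1]; W <- frameDim[2]
  xs <- matrix(seq(0, 1, length.out = W), H, W, byrow = TRUE)
  ys <- matrix(seq(0, 1, length.out = H), H, W)
  bg$base + bg$slopeX * xs + bg$slopeY * ys + bg$cross * xs * ys
}

#' Render a synthetic miniscope session
#'
#' Each frame is `clip(background(f) + sum_c activation_c(f) * footprint_c,
#' 0..255)`, rigidly translated by the motion-script offset, with optional
#' i.i.d. additive sensor noise. The noiseless activations, trajectory,
#' motion script, and all parameters are stored as ground truth.
#'
#' @param cells ground-truth cell list.
#' @param trajectory trajectory from [generateTrajectory()], or NULL for
#'   behavior-only sessions.
#' @param activations optional precomputed cells x frames activation matrix;
#'   computed from the trajectory when NULL.
#' @param motion motion script from [motionScript()]; NULL for a static
#'   session.
#' @param frameDim working-frame dimensions c(height, width).
#' @param fps frame rate.
#' @param nFrames frame count (required when no trajectory is given).
#' @param background list(base, slopeX, slopeY, cross, driftAmp,
#'   driftPeriod_frames, textureAmp, textureScale_px): low-order 2D
#'   polynomial plus optional slow sinusoidal temporal drift, plus a
#'   static anatomical texture (seeded smooth random field, sd
#'   `textureAmp`, correlation length `textureScale_px`) that moves with
#'   the brain and gives the stabilization stage stationary features to
#'   track.
#' @param noiseSd additive Gaussian sensor noise sd (8-bit units).
#' @param behaviorLabels optional per-frame category labels.
#' @param saturationLimit warn if the mean fraction of saturated pixels
#'   exceeds this value.
#' @param seed integer seed (noise reproducibility).
#' @return a \linkS4class{MiniscopeSession}.
#' @export
renderSession <- function(cells, trajectory = NULL, activations = NULL,
                          motion = NULL, frameDim = c(512L, 512L),
                          fps = 20, nFrames = NULL,
                          background = list(base = 20, slopeX = 10,
                                            slopeY = 10, cross = 0,
                                            driftAmp = 0,
                                            driftPeriod_frames = 1000),
                          noiseSd = 0, behaviorLabels = character(),
                          saturationLimit = 0.1, seed = 1L) {
  if (is.null(activations)) {
    if (!is.null(trajectory))
      activations <- cellActivations(cells, trajectory, fps)
    else if (!is.null(nFrames))
      activations <- matrix(0, length(cells), nFrames)
    else
      stop("a trajectory, an activation matrix, or nFrames is required")
  }
  n <- ncol(activations)
  if (!is.null(trajectory) && nrow(trajectory) != n)
    stop("trajectory and activations disagree on the frame count")
  if (is.null(motion)) motion <- motionScript(n)
  if (nrow(motion) != n) stop("motion script must cover every frame")

  bgDefaults <- list(base = 20, slopeX = 10, slopeY = 10, cross = 0,
                     driftAmp = 0, driftPeriod_frames = 1000,
                     textureAmp = 8, textureScale_px = 3)
  background <- modifyList(bgDefaults, background)
  bg <- .backgroundMatrix(frameDim, background)
  if (background$textureAmp > 0) {
    set.seed(.childSeed(seed, 9901L))
    tex <- matrix(rnorm(prod(frameDim)), frameDim[1], frameDim[2])
    sc <- background$textureScale_px
    g <- EBImage::makeBrush(2L * ceiling(2 * sc) + 1L, "Gaussian",
                            sigma = sc)
    tex <- EBImage::filter2(tex, g, boundary = "circular")
    bg <- bg + background$textureAmp * tex / sd(tex)
    bg <- pmax(bg, 0)
  }
  H <- frameDim[1]; W <- frameDim[2]
  frames <- array(0L, c(H, W, n))
  set.seed(seed)
  satFrac <- numeric(n)
  patchIdx <- lapply(cells, function(cl) {
    r <- (nrow(cl$footprint) - 1L) %/% 2L
    list(rows = (cl$center[1] - r):(cl$center[1] + r),
         cols = (cl$center[2] - r):(cl$center[2] + r))
  })
  for (cl in seq_along(cells)) {
    pi <- patchIdx[[cl]]
    if (min(pi$rows) < 1L || max(pi$rows) > H ||
        min(pi$cols) < 1L || max(pi$cols) > W)
      stop("cell ", cl, " footprint exceeds the frame bounds")
  }
  for (f in seq_len(n)) {
    scene <- bg
    if (background$driftAmp > 0)
      scene <- scene + background$driftAmp *
        sin(2 * pi * f / background$driftPeriod_frames)
    for (cl in seq_along(cells)) {
      a <- activations[cl, f]
      if (a > 1e-3) {
        pi <- patchIdx[[cl]]
        scene[pi$rows, pi$cols] <-
          scene[pi$rows, pi$cols] + a * cells[[cl]]$footprint
      }
    }
    if (motion$dx[f] != 0L || motion$dy[f] != 0L)
      scene <- translateMatrix(scene, motion$dx[f], motion$dy[f], fill = 0)
    if (noiseSd > 0)
      scene <- scene + matrix(rnorm(H * W, 0, noiseSd), H, W)
    scene <- round(.clip8(scene))
    satFrac[f] <- mean(scene == 255)
    frames[, , f] <- as.integer(scene)
  }
  if (mean(satFrac) > saturationLimit)
    warning(sprintf("saturation fraction %.1f%% exceeds the %.1f%% limit",
                    100 * mean(satFrac), 100 * saturationLimit))
  new("MiniscopeSession",
      frames = frames,
      trajectory = if (is.null(trajectory)) data.frame() else trajectory,
      cells = cells,
      motion = motion,
      trueTraces = activations,
      behaviorLabels = as.character(behaviorLabels),
      fps = fps,
      trackLength = if (is.null(trajectory)) NA_real_
                    else attr(trajectory, "trackLength_cm"),
      nBins = if (is.null(trajectory)) NA_integer_
              else as.integer(attr(trajectory, "K")),
      seed = as.integer(seed),
      params = list(frameDim = frameDim, background = background,
                    noiseSd = noiseSd, saturationLimit = saturationLimit))
}

#' Behavior category labels
#' @export
behaviorCategories <- function() {
  c("pre-trial", "correct choice", "incorrect choice", "reward retrieval",
    "intertrial")
}

#' Generate an instrumental-task behavior session
#'
#' Builds a per-frame label series over the five mutually exclusive
#' categories (pre-trial frames fill a 1-s window before trial initiation;
#' reward-retrieval frames fill a 2-s window after magazine entry;
#' incorrect choices are followed by a timeout spent in the intertrial
#' category), renders a population of category-modulated cells, and
#' optionally locks transient image jitter to reward-retrieval onsets to
#' emulate consumption-locked brain motion.
#'
#' @param nTrials number of trials.
#' @param fps frame rate.
#' @param timing list(pre_s, choice_s, reward_s, iti_s, timeout_s) in
#'   seconds; defaults follow the task description (1-s pre-trial window,
#'   2-s reward window, 10-s intertrial interval, 5-s timeout).
#' @param pCorrect probability a trial is correct.
#' @param nCells number of category-modulated cells.
#' @param frameDim working-frame dimensions.
#' @param amplitude peak fluorescence drive.
#' @param decayHalftime_s indicator half decay time.
#' @param rewardJitter NULL, or list(dx, dy, duration, prob): jitter locked
#'   to reward-retrieval onsets, emulating oscillatory brain motion during
#'   food consumption (the image wobbles between the offset and rest in
#'   2-frame bouts). `duration` defaults to the full reward window; `prob`
#'   (default 1) is the per-event probability that retrieval actually
#'   moves the brain.
#' @param rewardSignal multiplier on the amplitude of reward-preferring
#'   cells (default 1); values < 1 emulate a weakly encoded category.
#' @param responseProb per-event probability that a cell responds to an
#'   occurrence of its preferred category (default 1 = fully reliable;
#'   real neurons respond probabilistically across trials).
#' @param randomJitterRate if > 0, behavior-independent jitter events are
#'   scattered at this per-frame rate instead of (or on top of) none.
#' @param noiseSd sensor noise sd.
#' @param background background parameter list (see [renderSession()]).
#' @param seed integer seed.
#' @return list(session = MiniscopeSession, labels = character per-frame
#'   labels).
#' @export
generateBehaviorSession <- function(nTrials, fps = 20,
                                    timing = list(pre_s = 1, choice_s = 1.5,
                                                  reward_s = 2, iti_s = 10,
                                                  timeout_s = 5),
                                    pCorrect = 0.95, nCells = 20,
                                    frameDim = c(128L, 128L), amplitude = 70,
                                    decayHalftime_s = 0.7,
                                    rewardJitter = NULL,
                                    rewardSignal = 1,
                                    responseProb = 1,
                                    randomJitterRate = 0,
                                    noiseSd = 1,
                                    background = list(base = 20),
                                    seed = 1L) {
  if (nTrials < 1) stop("nTrials must be >= 1")
  tdef <- list(pre_s = 1, choice_s = 1.5, reward_s = 2, iti_s = 10,
               timeout_s = 5)
  timing <- modifyList(tdef, timing)
  fr <- function(s) max(1L, round(s * fps))
  set.seed(.childSeed(seed, 1L))
  correct <- runif(nTrials) < pCorrect

  labels <- character(0)
  rewardOnsets <- integer(0)
  for (t in seq_len(nTrials)) {
    labels <- c(labels, rep("intertrial", fr(timing$iti_s)),
                rep("pre-trial", fr(timing$pre_s)))
    if (correct[t]) {
      labels <- c(labels, rep("correct choice", fr(timing$choice_s)))
      rewardOnsets <- c(rewardOnsets, length(labels) + 1L)
      labels <- c(labels, rep("reward retrieval", fr(timing$reward_s)))
    } else {
      labels <- c(labels, rep("incorrect choice", fr(timing$choice_s)),
                  rep("intertrial", fr(timing$timeout_s)))
    }
  }
  n <- length(labels)

  # category-modulated population: cells cycle over the four event
  # categories so every event type has dedicated signal sources
  prefs <- rep(c("pre-trial", "correct choice", "reward retrieval",
                 "incorrect choice"), length.out = nCells)
  patch <- .footprintPatch(5L, 2.2)
  pos <- .placeFootprints(nCells, frameDim, 5L, 2L, .childSeed(seed, 2L))
  cells <- lapply(seq_len(nCells), function(i) list(
    footprint = patch, center = c(pos$row[i], pos$col[i]),
    field_center_cm = NA_real_, field_width_cm = NA_real_,
    direction_pref = prefs[i], amplitude = amplitude,
    decay_halftime_s = decayHalftime_s))

  dec <- 2^(-1 / (decayHalftime_s * fps))
  act <- matrix(0, nCells, n)
  runs <- rle(labels)
  runEnd <- cumsum(runs$lengths)
  runStart <- runEnd - runs$lengths + 1L
  set.seed(.childSeed(seed, 5L))
  for (i in seq_len(nCells)) {
    amp <- amplitude *
      if (prefs[i] == "reward retrieval") rewardSignal else 1
    drive <- numeric(n)
    for (j in which(runs$values == prefs[i]))
      if (runif(1) <= responseProb)
        drive[runStart[j]:runEnd[j]] <- amp
    prev <- 0
    for (f in seq_len(n)) {
      prev <- max(drive[f], prev * dec)
      act[i, f] <- prev
    }
  }

  events <- list()
  set.seed(.childSeed(seed, 3L))
  if (!is.null(rewardJitter)) {
    jdef <- list(dx = 3L, dy = 0L, duration = fr(timing$reward_s), prob = 1)
    rewardJitter <- modifyList(jdef, rewardJitter)
    for (on in rewardOnsets) {
      if (runif(1) > rewardJitter$prob) next
      sgn <- sample(c(-1L, 1L), 1L)
      # 2-frame wobble bouts spaced every 4 frames across the window
      for (o in seq(on, on + rewardJitter$duration - 1L, by = 4L))
        events[[length(events) + 1L]] <- list(
          frame = o, dx = sgn * rewardJitter$dx,
          dy = rewardJitter$dy, kind = "jitter", duration = 2L)
    }
  }
  if (randomJitterRate > 0) {
    onsets <- which(runif(n) < randomJitterRate)
    for (on in onsets)
      events[[length(events) + 1L]] <- list(
        frame = on, dx = sample(c(-3L, 3L), 1L), dy = 0L,
        kind = "jitter", duration = 3L)
  }
  motion <- motionScript(n, events)

  session <- renderSession(cells, trajectory = NULL, activations = act,
                           motion = motion, frameDim = frameDim, fps = fps,
                           background = background, noiseSd = noiseSd,
                           behaviorLabels = labels,
                           seed = .childSeed(seed, 4L))
  list(session = session, labels = labels)
}

# ------------------------------ session I/O --------------------------------

#' Write a session to disk
#'
#' Frames go to a multi-page 8-bit grayscale TIFF; trajectory, labels, true
#' displacements and true traces to CSV; the manifest (seed and all
#' parameters) to JSON.
#'
#' @param session a MiniscopeSession.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- sessionFrames(session)
  pages <- lapply(seq_len(dim(fr)[3]), function(f) fr[, , f] / 255)
  paths <- list(frames = file.path(dir, "frames.tif"),
                trajectory = file.path(dir, "trajectory.csv"),
                motion = file.path(dir, "motion.csv"),
                traces = file.path(dir, "true_traces.csv"),
                labels = file.path(dir, "labels.csv"),
                manifest = file.path(dir, "manifest.json"))
  tiff::writeTIFF(pages, paths$frames, bits.per.sample = 8L)
  if (nrow(trajectory(session)))
    write.csv(trajectory(session), paths$trajectory, row.names = FALSE)
  write.csv(motionScriptOf(session), paths$motion, row.names = FALSE)
  write.csv(as.data.frame(t(trueTraces(session))), paths$traces,
            row.names = FALSE)
  if (length(behaviorLabels(session)))
    write.csv(data.frame(frame_index = seq_along(behaviorLabels(session)),
                         value = behaviorLabels(session)),
              paths$labels, row.names = FALSE)
  jsonlite::write_json(
    list(seed = session@seed, fps = session@fps,
         trackLength_cm = session@trackLength, nBins = session@nBins,
         nFrames = dim(fr)[3], params = session@params),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a frame stack from a multi-page TIFF
#'
#' @param path TIFF path (8-bit grayscale pages).
#' @return integer array height x width x frames, values 0..255.
#' @export
readFrameStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  arr <- array(0L, c(H, W, length(pages)))
  for (f in seq_along(pages))
    arr[, , f] <- as.integer(round(pages[[f]] * 255))
  arr
}
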