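test_that("trajectory runs end to end at the configured speed", {
  # 250 cm at 50 cm/s and 20 fps: a full one-way run takes 100 frames
  tr <- generateTrajectory(400, trackLength_cm = 250, fps = 20,
                           speed_cm_s = 50, pause_s = 0, seed = 1)
  expect_equal(which(tr$position_cm == 250)[1], 100)
  # per-frame step never exceeds v_max/fps
  expect_true(all(abs(diff(tr$position_cm)) <= 150 / 20 + 1e-9))
  expect_true(all(tr$position_cm >= 0 & tr$position_cm <= 250))
})

test_that("circularized bins span ~20.8 cm of path and partition the loop", {
  tr <- generateTrajectory(2000, fps = 20, pause_s = 0, seed = 2)
  expect_setequal(unique(tr$bin), 1:24)
  # brute-force bin widths from the positions at which the bin changes
  w <- 2 * 250 / 24
  for (b in 1:12) {
    pos <- tr$position_cm[tr$bin == b & tr$direction == "rightward"]
    expect_true(max(pos) - min(pos) <= w)
  }
  # bin is a deterministic function of (position, direction)
  expect_equal(tr$bin,
               positionToBin(tr$position_cm, tr$direction, 250, 24L))
  # leftward leg occupies the upper half of the bin range
  expect_true(all(tr$bin[tr$direction == "leftward"] > 12))
})

test_that("trajectory generation is deterministic and validates inputs", {
  a <- generateTrajectory(300, seed = 9, speedSd_cm_s = 4)
  b <- generateTrajectory(300, seed = 9, speedSd_cm_s = 4)
  expect_identical(a, b)
  expect_error(generateTrajectory(0), "positive")
  expect_error(generateTrajectory(10, trackLength_cm = -5), "positive")
  expect_error(generateTrajectory(10, K = 23L), "even")
})

test_that("place-cell population tiles the track with alternating prefs", {
  cells <- generatePlaceCells(50, frameDim = c(160, 160), seed = 3)
  ctr <- vapply(cells, function(c) c$field_center_cm, numeric(1))
  expect_true(all(diff(ctr) > 0))
  expect_true(all(ctr > 0 & ctr < 250))
  prefs <- vapply(cells, function(c) c$direction_pref, character(1))
  expect_setequal(unique(prefs), c("rightward", "leftward"))
  # footprints non-negative, fit the frame
  for (cl in cells) expect_true(all(cl$footprint >= 0))
  expect_error(generatePlaceCells(4, frameDim = c(10, 10),
                                  footprintRadius_px = 6L), "fit")
})

test_that("a single cell is maximally active in its field's central bin", {
  traj <- generateTrajectory(1200, fps = 20, seed = 4)
  cells <- generatePlaceCells(1, frameDim = c(96, 96), seed = 4)
  cells[[1]]$field_center_cm <- 125
  act <- cellActivations(cells, traj)
  tc <- tuningCurve(act[1, ], traj$bin, K = 24L)
  # field at 125 cm, rightward pref: central bin of the rightward leg
  expect_equal(which.max(tc$curve), positionToBin(125, "rightward"))
})

test_that("tuning-curve peaks of the rendered population follow field order", {
  traj <- generateTrajectory(2400, fps = 20, seed = 6)
  cells <- generatePlaceCells(50, frameDim = c(160, 160), seed = 6)
  act <- cellActivations(cells, traj)
  right <- which(vapply(cells, function(c) c$direction_pref, character(1))
                 == "rightward")
  peaks <- vapply(right, function(i)
    which.max(tuningCurve(act[i, ], traj$bin)$curve), integer(1))
  # rightward cells ordered by field center decode to non-decreasing peaks
  expect_true(all(diff(peaks) >= 0))
  expect_true(all(peaks <= 12))
})

test_that("indicator dynamics halve after one half-time", {
  # one-frame impulse, 0.7 s half time at 20 fps: 50% after 14 frames
  traj <- data.frame(position_cm = c(125, rep(0, 40)),
                     direction = "rightward",
                     bin = 1L)
  attr(traj, "fps") <- 20
  cells <- list(list(footprint = matrix(1), center = c(5, 5),
                     field_center_cm = 125, field_width_cm = 1e-6,
                     direction_pref = "rightward", amplitude = 100,
                     decay_halftime_s = 0.7))
  act <- cellActivations(cells, traj, fps = 20)
  expect_equal(act[1, 1], 100)
  expect_equal(act[1, 15], 50, tolerance = 1e-9)  # 14 frames later
})

test_that("zero-amplitude cells contribute nothing to any frame", {
  traj <- generateTrajectory(200, seed = 8)
  cells <- generatePlaceCells(3, frameDim = c(96, 96), amplitude = 0,
                              seed = 8)
  bg <- list(base = 30, slopeX = 0, slopeY = 0, textureAmp = 0)
  sess <- renderSession(cells, traj, frameDim = c(96, 96), noiseSd = 0,
                        background = bg, seed = 8)
  fr <- sessionFrames(sess)
  expect_true(all(fr == 30L))
})

test_that("rendering with no cells, flat background and no noise is static", {
  sess <- renderSession(list(), nFrames = 6, frameDim = c(48, 48),
                        noiseSd = 0,
                        background = list(base = 40, slopeX = 0,
                                          slopeY = 0, textureAmp = 0),
                        seed = 1)
  fr <- sessionFrames(sess)
  for (f in 2:6) expect_identical(fr[, , f], fr[, , 1])
})

test_that("scripted jitter translates frames exactly and then returns", {
  motion <- motionScript(6, list(list(frame = 3, dx = 3, dy = 0,
                                      kind = "jitter", duration = 2)))
  expect_equal(motion$dx, c(0, 0, 3, 3, 0, 0))
  traj <- generateTrajectory(6, seed = 2)
  cells <- generatePlaceCells(2, frameDim = c(64, 64), seed = 2)
  s0 <- renderSession(cells, traj, frameDim = c(64, 64), noiseSd = 0,
                      seed = 3)
  s1 <- renderSession(cells, traj, motion = motion, frameDim = c(64, 64),
                      noiseSd = 0, seed = 3)
  f0 <- sessionFrames(s0); f1 <- sessionFrames(s1)
  expect_identical(f1[, , 1], f0[, , 1])
  expect_equal(f1[, , 3], translateMatrix(f0[, , 3], 3, 0),
               ignore_attr = TRUE)
  expect_identical(f1[, , 5], f0[, , 5])
})

test_that("shift events persist while jitter events return to baseline", {
  m <- motionScript(10, list(
    list(frame = 2, dx = 1, dy = 0, kind = "jitter", duration = 2),
    list(frame = 6, dx = 0, dy = 2, kind = "shift")))
  expect_equal(m$dx, c(0, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(m$dy, c(0, 0, 0, 0, 0, 2, 2, 2, 2, 2))
})

test_that("noiseless motion-free rendering reproduces true traces", {
  traj <- generateTrajectory(300, seed = 5)
  cells <- generatePlaceCells(4, frameDim = c(96, 96), amplitude = 40,
                              seed = 5)
  bg <- list(base = 0, slopeX = 0, slopeY = 0, textureAmp = 0)
  sess <- renderSession(cells, traj, frameDim = c(96, 96), noiseSd = 0,
                        background = bg, seed = 5)
  fr <- sessionFrames(sess)
  act <- trueTraces(sess)
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    r <- (nrow(cl$footprint) - 1L) %/% 2L
    rows <- (cl$center[1] - r):(cl$center[1] + r)
    cols <- (cl$center[2] - r):(cl$center[2] + r)
    sums <- vapply(seq_len(dim(fr)[3]), function(f)
      sum(fr[rows, cols, f]), numeric(1))
    # footprint-weighted sums match up to 8-bit rounding of each pixel
    npx <- length(rows) * length(cols)
    expect_lt(max(abs(sums - act[i, ] * sum(cl$footprint))),
              0.5 * npx + 1)
  }
})

test_that("session regeneration with the same seed is bit-identical", {
  mk <- function() {
    traj <- generateTrajectory(120, seed = 11)
    cells <- generatePlaceCells(3, frameDim = c(64, 64), seed = 11)
    renderSession(cells, traj, frameDim = c(64, 64), noiseSd = 2,
                  seed = 11)
  }
  expect_identical(sessionFrames(mk()), sessionFrames(mk()))
})

test_that("behavior labels partition every frame into the five categories", {
  bs <- generateBehaviorSession(5, timing = list(iti_s = 2, timeout_s = 1),
                                pCorrect = 0.6, nCells = 4,
                                frameDim = c(64, 64), seed = 3)
  expect_equal(length(bs$labels), nFrames(bs$session))
  expect_true(all(bs$labels %in% behaviorCategories()))
  # reward-retrieval windows last 2 s x 20 fps = 40 frames
  r <- rle(bs$labels)
  expect_equal(unique(r$lengths[r$values == "reward retrieval"]), 40)
})

test_that("an all-correct single-trial session has one choice segment", {
  bs <- generateBehaviorSession(1, pCorrect = 1, nCells = 4,
                                frameDim = c(64, 64), seed = 2)
  r <- rle(bs$labels)
  expect_equal(sum(r$values == "correct choice"), 1)
  expect_equal(sum(r$values == "incorrect choice"), 0)
  expect_equal(sum(r$values == "reward retrieval"), 1)
})

test_that("behavior-locked jitter elevates |dd| during reward frames", {
  bs <- generateBehaviorSession(8, timing = list(iti_s = 2, timeout_s = 1),
                                nCells = 4, frameDim = c(64, 64),
                                rewardJitter = list(dx = 3), seed = 7)
  mot <- motionFeatures(motionScriptOf(bs$session))
  rew <- bs$labels == "reward retrieval"
  iti <- bs$labels == "intertrial"
  expect_gt(mean(mot[rew, "abs_dd"]), mean(mot[iti, "abs_dd"]))
  expect_gt(mean(mot[rew, "d"]), mean(mot[iti, "d"]))
})

test_that("sessions round-trip through TIFF and CSV on disk", {
  traj <- generateTrajectory(40, seed = 13)
  cells <- generatePlaceCells(2, frameDim = c(48, 48), seed = 13)
  sess <- renderSession(cells, traj, frameDim = c(48, 48), noiseSd = 1,
                        seed = 13)
  dir <- withr::local_tempdir()
  paths <- writeSession(sess, dir)
  expect_true(file.exists(paths$frames))
  back <- readFrameStack(paths$frames)
  expect_identical(back, sessionFrames(sess))
  tr <- read.csv(paths$trajectory)
  expect_equal(tr$bin, trajectory(sess)$bin)
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$seed, 13)
})
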