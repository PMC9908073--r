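# Shared fixture builders. Everything is generated in code at test time;
# expensive sessions live in the test files that use them.

# small textured frame stack with scripted integer motion, suitable for
# displacement-recovery checks
makeTexturedStack <- function(nFrames, dim = 64L, motion = NULL,
                              seed = 42L) {
  set.seed(seed)
  base <- matrix(runif(dim * dim, 0, 255), dim, dim)
  frames <- array(0L, c(dim, dim, nFrames))
  if (is.null(motion))
    motion <- data.frame(dx = integer(nFrames), dy = integer(nFrames))
  for (f in seq_len(nFrames))
    frames[, , f] <- as.integer(round(translateMatrix(base, motion$dx[f],
                                                      motion$dy[f])))
  list(frames = frames, base = base, motion = motion)
}

# brute-force exhaustive-shift argmax: for every candidate lag, the score
# is the Pearson correlation between the overlapping parts of the window
# and the lag-shifted template (same definition as the estimator, computed
# here by direct submatrix extraction); package tie-break applied
bruteForceDisplacement <- function(w, template, radius) {
  n <- nrow(w)
  grid <- expand.grid(u = -radius:radius, v = -radius:radius)
  grid$val <- vapply(seq_len(nrow(grid)), function(i) {
    u <- grid$u[i]; v <- grid$v[i]
    rows <- max(1, 1 + v):min(n, n + v)
    cols <- max(1, 1 + u):min(n, n + u)
    cor(as.vector(w[rows, cols]),
        as.vector(template[rows - v, cols - u]))
  }, numeric(1))
  top <- grid[grid$val >= max(grid$val) - 1e-9, ]
  top <- top[order(abs(top$u) + abs(top$v), top$v, top$u), ]
  list(dx = top$u[1], dy = top$v[1])
}

# naive double-loop kernel correlation at interior pixels only
naiveFilterInterior <- function(w, k) {
  r <- (nrow(k) - 1L) %/% 2L
  out <- matrix(NA_real_, nrow(w), ncol(w))
  for (y in (r + 1L):(nrow(w) - r))
    for (x in (r + 1L):(ncol(w) - r))
      out[y, x] <- sum(k * w[(y - r):(y + r), (x - r):(x + r)])
  out
}

# tiny linear-track session shared by a few decoding tests
makeTinyPlaceSession <- function(nFrames = 600L, nCells = 12L, dim = 96L,
                                 noiseSd = 1, seed = 5L) {
  traj <- generateTrajectory(nFrames, fps = 20, seed = seed)
  cells <- generatePlaceCells(nCells, frameDim = c(dim, dim),
                              seed = seed + 1L)
  sess <- renderSession(cells, traj, frameDim = c(dim, dim),
                        noiseSd = noiseSd, seed = seed + 2L)
  list(session = sess, trajectory = traj, cells = cells)
}
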