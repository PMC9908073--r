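test_that("position metrics use circular distance on the 2L loop", {
  pm <- positionMetrics(1:24, 1:24)
  expect_equal(pm$lambdaBar, 0)
  expect_equal(pm$rho, 100)
  # diametrically opposite predictions sit half the loop away: 250 cm
  true <- rep(1L, 10)
  opposite <- rep(13L, 10)
  pm2 <- positionMetrics(true, opposite)
  expect_equal(unique(pm2$lambda), 250)
  expect_equal(pm2$rho, 0)
})

test_that("position metrics equal a per-frame enumeration oracle", {
  set.seed(41)
  true <- sample(1:24, 10, replace = TRUE)
  pred <- sample(1:24, 10, replace = TRUE)
  pm <- positionMetrics(true, pred)
  ctr <- (seq_len(24) - 0.5) * (500 / 24)
  lam <- numeric(10)
  for (f in 1:10) {
    d <- abs(ctr[true[f]] - ctr[pred[f]])
    lam[f] <- min(d, 500 - d)
  }
  expect_equal(pm$lambda, lam)
  expect_equal(pm$lambdaBar, mean(lam))
  expect_equal(pm$rho, 100 * mean(lam <= 30))
})

test_that("hit rate is monotone in the tolerance", {
  set.seed(42)
  true <- sample(1:24, 200, replace = TRUE)
  pred <- sample(1:24, 200, replace = TRUE)
  tols <- c(60, 30, 20, 10, 5)
  rhos <- vapply(tols, function(t)
    positionMetrics(true, pred, tolerance_cm = t)$rho, numeric(1))
  expect_true(all(diff(rhos) <= 0))
})

test_that("tuning curves normalize bin-averaged zero-referenced activity", {
  # activity confined to bin 5 gives a one-hot normalized curve
  bins <- rep(1:24, each = 4)
  tr <- as.numeric(bins == 5) * 80 + 7
  tc <- tuningCurve(tr, bins)
  expect_equal(tc$curve[5], 1)
  expect_equal(tc$curve[-5], rep(0, 23))
  expect_false(tc$flagged)
  # constant trace: Z = 0 everywhere, flagged all-zero curve
  tc0 <- tuningCurve(rep(3, length(bins)), bins)
  expect_true(tc0$flagged)
  expect_true(all(tc0$curve == 0))
  # random series equals a double-loop binning oracle
  set.seed(43)
  tr2 <- runif(length(bins), 0, 50)
  tc2 <- tuningCurve(tr2, bins)
  Z <- tr2 - min(tr2)
  for (b in 1:24) {
    visits <- which(bins == b)
    expect_equal(tc2$A[b], sum(Z[visits]) / length(visits))
  }
  expect_equal(tc2$curve, tc2$A / max(tc2$A))
})

test_that("the signed log-significance transform hits its anchor points", {
  expect_equal(signedLogP(1, 0.5), 0)
  expect_equal(signedLogP(0.1, 0.5), 1)
  expect_equal(signedLogP(0.01, 0.5), 2)
  expect_equal(signedLogP(0.01, -0.5), -2)
})

test_that("similarity scores behave at the significance boundary", {
  set.seed(44)
  a <- runif(24)
  s <- similarityScore(a, a + rnorm(24, 0, 0.05))
  expect_gt(s$S, 2)
  expect_equal(sign(s$R), 1)
  # degenerate curves are reported missing
  expect_true(is.na(similarityScore(rep(1, 24), a)$S))
  expect_true(is.na(similarityScore(a[1:2], a[1:2])$S))
})

test_that("independent random curves exceed |S| = 2 about 1% of the time", {
  set.seed(45)
  hits <- 0; n <- 2000
  for (i in seq_len(n)) {
    s <- similarityScore(runif(24), runif(24))
    if (abs(s$S) > 2) hits <- hits + 1
  }
  expect_gt(hits / n, 0.002)
  expect_lt(hits / n, 0.03)
})

test_that("motion-artifact scores detect constructed correlations", {
  set.seed(46)
  bins <- rep(1:24, each = 30)
  n <- length(bins)
  d <- runif(n, 0, 10)               # displacement above threshold in bins
  lambda <- 5 * d + rnorm(n, 0, 3)   # error proportional to displacement
  ms <- motionArtifactScore(lambda, d, bins)
  expect_gt(ms$Omega, 2)
  expect_gt(ms$R, 0)
  # displacement below threshold everywhere: missing
  ms0 <- motionArtifactScore(lambda, rep(1, n), bins)
  expect_true(is.na(ms0$Omega))
  expect_equal(ms0$framesUsed, 0L)
})

test_that("only frames from qualifying bins enter the correlation", {
  bins <- rep(c(1L, 2L), each = 50)
  d <- c(runif(50, 5, 10), runif(50, 0, 1))  # only bin 1 exceeds 4 px
  lambda <- c(3 * d[1:50], runif(50, 0, 100))
  ms <- motionArtifactScore(lambda, d, bins)
  expect_equal(ms$binsUsed, 1L)
  expect_equal(ms$framesUsed, 50L)
  oracle <- cor.test(lambda[1:50], d[1:50])
  expect_equal(ms$R, unname(oracle$estimate))
  expect_equal(ms$Omega, -log10(oracle$p.value) * sign(oracle$estimate))
})

test_that("independent displacement rarely scores |Omega| > 2", {
  set.seed(47)
  hits <- 0; n <- 300
  for (i in seq_len(n)) {
    bins <- rep(1:6, each = 40)
    d <- runif(240, 0, 10)
    lambda <- runif(240, 0, 100)
    if (abs(motionArtifactScore(lambda, d, bins)$Omega) > 2)
      hits <- hits + 1
  }
  expect_lt(hits / n, 0.05)
})

test_that("event metrics count window hits and compose the F-score", {
  # perfect prediction
  lab <- c(rep("intertrial", 5), rep("reward retrieval", 4),
           rep("intertrial", 5), rep("reward retrieval", 4),
           rep("intertrial", 2))
  em <- eventMetrics(lab, lab, "reward retrieval", nShuffles = 50, seed = 1)
  expect_equal(em$sensitivity, 100)
  expect_equal(em$precision, 100)
  expect_equal(em$F, 100)
  # sensitivity = precision = p implies F = p
  expect_equal(2 * 60 * 60 / (60 + 60), 60)
  # hand-enumerated 20-frame session: two true events, one hit by a
  # single frame, one missed; one spurious predicted episode
  truth <- c(rep("intertrial", 4), rep("reward retrieval", 4),
             rep("intertrial", 4), rep("reward retrieval", 4),
             rep("intertrial", 4))
  pred <- rep("intertrial", 20)
  pred[6] <- "reward retrieval"     # hits event 1
  pred[18] <- "reward retrieval"    # outside both events
  em2 <- eventMetrics(truth, pred, "reward retrieval", nShuffles = 50,
                      seed = 2)
  expect_equal(em2$sensitivity, 50)        # 1 of 2 events hit
  expect_equal(em2$precision, 50)          # 1 of 2 episodes inside an event
  expect_equal(em2$F, 50)
  expect_equal(em2$frameSensitivity, 100 * 1 / 8)
  # no events of the requested type: metrics missing
  em3 <- eventMetrics(rep("intertrial", 10), rep("intertrial", 10),
                      "reward retrieval", nShuffles = 10, seed = 3)
  expect_true(is.na(em3$F))
})

test_that("the shuffle null covers chance-level predictions", {
  set.seed(48)
  lab <- rep(rep(c("intertrial", "reward retrieval"), 10),
             times = c(rbind(sample(5:9, 10, TRUE), sample(3:5, 10, TRUE))))
  # a prediction built by shuffling window labels should sit inside its
  # own null distribution most of the time
  r <- rle(lab)
  rs <- r; rs$values <- sample(r$values)
  pred <- inverse.rle(rs)
  em <- eventMetrics(lab, pred, "reward retrieval", nShuffles = 400,
                     seed = 4)
  expect_gt(em$pValue, 0.01)
})
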