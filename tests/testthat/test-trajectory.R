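circleTraj <- function(r = 1, n = 30, phase = 0, m = 3) {
  t <- 2 * pi * (0:(n - 1)) / n + phase
  cbind(r * cos(t), r * sin(t), matrix(0, n, m - 2))
}

test_that("trajectory size: zero, homogeneity, circle value, translation", {
  pts <- circleTraj(r = 2.5)
  expect_equal(trajectorySize(pts), 2.5 * sqrt(30))
  expect_equal(trajectorySize(2 * pts), 2 * trajectorySize(pts))
  expect_equal(trajectorySize(matrix(1, 30, 3)), 0)
  shifted <- sweep(pts, 2, c(5, -3, 2), "+")
  expect_equal(trajectorySize(shifted), trajectorySize(pts))
})

test_that("trajectory angle: quadrants, equivariance, translation invariance", {
  pts <- matrix(0, 30, 3)
  pts[11, ] <- c(1, 1, 0)
  expect_equal(trajectoryAngle(pts, "12"), 45)
  pts[11, ] <- c(-1, 0, 0)
  expect_equal(trajectoryAngle(pts, "12"), 180)
  pts[11, ] <- c(0, 2, -2)
  expect_equal(trajectoryAngle(pts, "12"), 90)
  expect_equal(trajectoryAngle(pts, "13"), 270)

  set.seed(41)
  traj <- matrix(rnorm(90), 30, 3)
  a0 <- trajectoryAngle(traj, "12")
  th <- 30 * pi / 180
  rot <- traj
  rot[, 1:2] <- traj[, 1:2] %*% rbind(c(cos(th), sin(th)),
                                      c(-sin(th), cos(th)))
  expect_equal(trajectoryAngle(rot, "12"), (a0 + 30) %% 360,
               tolerance = 1e-9)
  expect_equal(trajectoryAngle(sweep(traj, 2, c(3, 4, 5), "+"), "12"), a0)

  degenerate <- matrix(0, 30, 3)
  expect_error(trajectoryAngle(degenerate, "12"), "undefined")
})

mkTrajSet <- function(trajs, groups) {
  structure(list(trajectories = trajs,
                 caseIds = sprintf("c%02d", seq_along(trajs)),
                 groups = groups, nFrames = nrow(trajs[[1]]),
                 surface = "endo", mode = "SSS"),
            class = "lvTrajectorySet")
}

test_that("trajectory shape analysis removes rotation and scale", {
  # identical ellipses differing only by in-plane rotation and scale:
  # no shape variation left, so no group difference
  set.seed(42)
  ell <- circleTraj(); ell[, 2] <- 0.5 * ell[, 2]
  trajs <- lapply(1:10, function(i) {
    th <- runif(1, 0, 2 * pi)
    s <- runif(1, 0.5, 2)
    out <- ell
    out[, 1:2] <- s * ell[, 1:2] %*% rbind(c(cos(th), sin(th)),
                                           c(-sin(th), cos(th)))
    out
  })
  res <- suppressWarnings(
    trajectoryShapeAnalysis(mkTrajSet(trajs, rep(c("Control", "MI"), 5))))
  expect_equal(res$manova$statistic, 1, tolerance = 1e-6)
  expect_gte(res$manova$pValue, 0.999)

  # circles vs 2:1 ellipses: constructed perfect separation
  mkNoisy <- function(ratio) {
    out <- circleTraj()
    out[, 2] <- ratio * out[, 2]
    out[, 1:2] <- out[, 1:2] + matrix(rnorm(60, sd = 0.01), 30, 2)
    out
  }
  trajs2 <- c(lapply(1:8, function(i) mkNoisy(1)),
              lapply(1:8, function(i) mkNoisy(0.5)))
  res2 <- suppressWarnings(
    trajectoryShapeAnalysis(mkTrajSet(trajs2, rep(c("Control", "MI"),
                                                  each = 8)), nPCs = 5))
  expect_lt(res2$manova$statistic, 0.05)
  expect_lt(res2$manova$pValue, 1e-6)

  # explained fractions non-increasing
  expect_true(all(diff(res2$model@explainedFraction) <= 1e-12))
})

test_that("trajectory shape result is invariant to common rotation/scaling", {
  set.seed(43)
  trajs <- lapply(1:12, function(i) matrix(rnorm(90), 30, 3))
  groups <- rep(c("Control", "MI"), 6)
  lam0 <- suppressWarnings(
    trajectoryShapeAnalysis(mkTrajSet(trajs, groups),
                            nPCs = 5))$manova$statistic
  r <- randomRotation()
  moved <- lapply(trajs, function(t) 3.1 * t %*% r)
  lam1 <- suppressWarnings(
    trajectoryShapeAnalysis(mkTrajSet(moved, groups),
                            nPCs = 5))$manova$statistic
  expect_equal(lam1, lam0, tolerance = 1e-8)
})

test_that("adjusted-R2 ANOVA matches hand-computed sums of squares", {
  res <- anovaAdjusted(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$rSquaredAdj, 1 - (1 - 13.5 / 17.5) * 5 / 4,
               tolerance = 1e-6)

  same <- anovaAdjusted(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_lte(same$rSquaredAdj, 0)

  const <- anovaAdjusted(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_equal(const$statistic, 0)
  expect_equal(const$pValue, 1)

  set.seed(44)
  for (i in 1:100) {
    v <- rnorm(20)
    g <- sample(rep(c("a", "b", "c"), length.out = 20))
    got <- anovaAdjusted(v, g)
    want <- manualANOVA(v, g)
    expect_equal(got$statistic, want$F, tolerance = 1e-8)
    expect_equal(got$pValue, want$p, tolerance = 1e-8)
    expect_equal(got$rSquaredAdj, want$adjR2, tolerance = 1e-8)
  }
})

test_that("ANOVA p-values are uniform under a permutation null", {
  set.seed(45)
  v <- rnorm(40)
  p <- vapply(1:1000, function(i)
    anovaAdjusted(v, sample(rep(c("a", "b"), 20)))$pValue, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("dispersion test detects spread differences and matches vegan", {
  set.seed(46)
  a <- matrix(rnorm(15 * 5), 15, 5)
  bSame <- matrix(rnorm(15 * 5), 15, 5)
  bWide <- sweep(bSame, 2, colMeans(bSame)) * 3
  groups <- rep(c("Control", "MI"), each = 15)

  null <- dispersionTest(rbind(a, bSame), groups, nPerm = 499, seed = 2)
  expect_gt(null$pValue, 0.05)
  eff <- dispersionTest(rbind(a, bWide), groups, nPerm = 499, seed = 2)
  expect_lt(eff$pValue, 0.01)

  # independent cross-check of the F statistic against vegan::betadisper
  skip_if_not_installed("vegan")
  x <- rbind(a, bWide)
  bd <- vegan::betadisper(dist(x), factor(groups), type = "centroid")
  fVegan <- anova(bd)$`F value`[1]
  expect_equal(eff$statistic, fVegan, tolerance = 1e-8)

  expect_error(dispersionTest(rbind(a, bSame), groups, nPerm = 0), "nPerm")
})

test_that("per-time tests flag the frames where groups separate", {
  fix <- effectCohortRegistered()
  tds <- cachedFixture("effectTDS_sss", runLSPCA(fix$endo, mode = "SSS"))
  pt <- perTimeTests(tds, axis = 1)
  expect_equal(nrow(pt), 30L)
  expect_true(all(pt$pValue >= 0 & pt$pValue <= 1))
  # the amplitude effect concentrates around end-systole
  expect_true(all(pt$significantRaw[9:13]))
  expect_error(perTimeTests(tds, axis = 10000), "out of range")
})

test_that("attribute tables carry sizes, angles and shape scores", {
  fix <- effectCohortRegistered()
  tds <- cachedFixture("effectTDS_sss", runLSPCA(fix$endo, mode = "SSS"))
  at <- trajectoryAttributes(tds)
  expect_equal(nrow(at), 20L)
  expect_true(all(c("trajSize", "angle12", "angle13", "shapePC1",
                    "shapePC15") %in% names(at)))
  expect_true(all(at$trajSize > 0))
  expect_true(all(at$angle12 >= 0 & at$angle12 < 360, na.rm = TRUE))
  # circular variance diagnostic is defined and bounded
  cv <- circularVariance(at$angle12)
  expect_gte(cv, 0); expect_lte(cv, 1)
})
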