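test_that("phase warp pins the endpoints and the ES point", {
  expect_equal(warpPhase(0, 0.5), 0)
  expect_equal(warpPhase(1, 0.5), 1)
  expect_equal(warpPhase(0.25, 0.5, 0.35), 0.175)
  expect_equal(warpPhase(0.4, 0.4, 0.35), 0.35)
  expect_equal(warpPhase(0.7, 0.4, 0.35), 0.35 + 0.3 * (0.65 / 0.6))
  expect_error(warpPhase(0.5, 0), "inside")
  expect_error(warpPhase(0.5, 1), "inside")
})

test_that("phase warp is a continuous strictly increasing bijection", {
  phi <- seq(0, 1, by = 1e-3)
  for (esRaw in c(0.3, 0.45, 0.6)) {
    w <- warpPhase(phi, esRaw, 0.35)
    expect_true(all(diff(w) > 0))
    expect_equal(range(w), c(0, 1))
    expect_lt(max(abs(diff(w))), 3e-3)  # no jumps
  }
})

test_that("Fourier fit is exact for band-limited signals and periodic", {
  ph <- (0:11) / 12
  expect_equal(unname(fourierFit(ph, rep(7, 12))$a0), 7)
  expect_lt(max(abs(unlist(fourierFit(ph, rep(7, 12))[c("a", "b")]))), 1e-8)

  f <- function(p) cos(2 * pi * p) + 0.5 * sin(4 * pi * p)
  fit <- fourierFit(ph, f(ph), nHarmonics = 5)
  grid <- seq(0, 1, by = 0.007)
  expect_lt(max(abs(evalFourier(fit, grid) - f(grid))), 1e-6)
  # exact 1-periodicity
  expect_equal(evalFourier(fit, grid), evalFourier(fit, grid + 1),
               tolerance = 1e-12)
  expect_error(fourierFit((0:5) / 6, rnorm(6), nHarmonics = 5),
               "at least")
})

test_that("Fourier coefficients match a normal-equations oracle on noise", {
  set.seed(21)
  ph <- sort(runif(30))
  v <- rnorm(30)
  fit <- fourierFit(ph, v, nHarmonics = 5)
  # independent oracle: explicit normal equations
  h <- 1:5
  x <- cbind(1, cos(2 * pi * outer(ph, h)), sin(2 * pi * outer(ph, h)))
  beta <- solve(t(x) %*% x, t(x) %*% v)
  expect_equal(c(fit$a0, fit$a, fit$b), drop(beta), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("periodic spline interpolates the samples and wraps", {
  set.seed(22)
  ph <- (0:14) / 15
  v <- rnorm(15)
  f <- periodicSplineFun(ph, v)
  expect_equal(f(ph), v, tolerance = 1e-9)
  expect_equal(f(0.3), f(1.3), tolerance = 1e-12)
})

test_that("registration is the identity on band-limited registered input", {
  set.seed(23)
  spec <- registrationSpec()
  k <- 12
  base <- matrix(rnorm(k * 3, sd = 5), k, 3)
  coefsA <- matrix(rnorm(k * 3, sd = 0.3), k, 3)
  coefsB <- matrix(rnorm(k * 3, sd = 0.2), k, 3)
  phases <- (0:29) / 30
  frames <- lapply(phases, function(p)
    base + coefsA * cos(2 * pi * p) + coefsB * sin(2 * 2 * pi * p))
  seq35 <- new("LVMotionSequence", caseId = "bl", group = "Control",
               surface = "endo", frames = frames, esPhaseRaw = 0.35,
               registered = FALSE)
  out <- registerSequence(seq35, spec)
  expect_equal(unlist(out@frames), unlist(frames), tolerance = 1e-6)
})

test_that("registration leaves a static heart static", {
  spec <- registrationSpec()
  f <- matrix(rnorm(36), 12, 3)
  static <- new("LVMotionSequence", caseId = "st", group = "Control",
                surface = "endo", frames = rep(list(f), 17),
                esPhaseRaw = 0.5, registered = FALSE)
  out <- registerSequence(static, spec)
  expect_equal(length(out@frames), 30L)
  for (fr in out@frames) expect_equal(fr, f, tolerance = 1e-8)
})

test_that("registration moves the volume minimum to the target phase", {
  # contracting shell with raw ES at 0.5 -> registered minimum near 0.35
  mesh <- buildLVMesh(6, 8)
  s0 <- cardiomorph:::.lvSurface(25, 75, 6, 8)
  tRaw <- 24
  frames <- lapply(seq_len(tRaw), function(j) {
    g <- cardiomorph:::.contractionProfile((j - 1) / tRaw)  # min at 0.5
    cardiomorph:::.contract(s0, g, 0.4, 0.2)
  })
  raw <- new("LVMotionSequence", caseId = "c", group = "Control",
             surface = "endo", frames = frames, esPhaseRaw = 0.5,
             registered = FALSE)
  reg <- registerSequence(raw, registrationSpec())
  vols <- frameVolumes(reg, mesh)
  minPhase <- (which.min(vols) - 1) / 30
  expect_lt(abs(minPhase - 0.35), 1 / 30 + 1e-9)
  expect_equal(detectESFrame(reg, mesh), 11L)
})

test_that("cavity volume: cube, analytic shell limit, rigid invariance", {
  v <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1), ncol = 3,
              byrow = TRUE) * 10
  tri <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
               c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
               c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  cube <- lvMesh(tri)
  expect_equal(cavityVolume(v, cube), 1)
  expect_equal(cavityVolume(v + 10, cube), 1, tolerance = 1e-12)

  # fine discretization approaches the analytic solid-of-revolution volume
  thetaMax <- 2 * pi / 3
  a <- 25; len <- 75
  cc <- len / (1 - cos(thetaMax))
  analytic <- integrate(function(t) pi * (a * sin(t))^2 * cc * sin(t),
                        0, thetaMax)$value / 1000
  sF <- cardiomorph:::.lvSurface(a, len, 60, 80)
  expect_equal(cavityVolume(sF, buildLVMesh(60, 80)), analytic,
               tolerance = 0.01 * analytic)

  s <- cardiomorph:::.lvSurface(a, len, 6, 8)
  m <- buildLVMesh(6, 8)
  base <- cavityVolume(s, m)
  r <- randomRotation()
  expect_equal(cavityVolume(sweep(s %*% r, 2, c(10, 10, 10), "+"), m),
               base, tolerance = 1e-9)

  open <- lvMesh(tri[-1, ])  # remove one face -> not closed
  expect_error(cavityVolume(v, open), "not closed")
})

test_that("ES detection: parabolic curve, ties, and the floor convention", {
  mesh <- buildLVMesh(4, 6)
  s0 <- cardiomorph:::.lvSurface(20, 60, 4, 6)
  v0 <- cavityVolume(s0, mesh)
  mkSeq <- function(vols) {
    frames <- lapply(vols, function(v) s0 * (v / v0)^(1 / 3))
    new("LVMotionSequence", caseId = "p", group = "Control",
        surface = "endo", frames = frames, esPhaseRaw = 0.35,
        registered = TRUE)
  }
  # noise-free parabola minimized at phase 12/30 -> frame 13 (both paths)
  ph <- (0:29) / 30
  par <- mkSeq(100 + 400 * (ph - 0.4)^2)
  expect_equal(detectESFrame(par, mesh), 13L)
  expect_equal(detectESFrame(par, mesh, refine = FALSE), 13L)
  # minimum exactly at phase 0.35 (between frames 11 and 12) -> frame 11
  par35 <- mkSeq(100 + 400 * (ph - 0.35)^2)
  expect_equal(detectESFrame(par35, mesh), 11L)
  # static sequence -> frame 1
  expect_equal(detectESFrame(mkSeq(rep(80, 30)), mesh), 1L)
})

test_that("registration specs validate their invariants", {
  expect_error(registrationSpec(nFrames = 10, nHarmonics = 5), "Nyquist")
  expect_error(registrationSpec(esTargetPhase = 1.2), "0,1")
  expect_equal(nominalESFrame(registrationSpec()), 11L)
})
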