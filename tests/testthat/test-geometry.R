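test_that("centroid size: analytic value, homogeneity, degenerate zero", {
  sq <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0)
  expect_equal(centroidSize(sq), sqrt(8))
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(centroidSize(3 * x), 3 * centroidSize(x))
  expect_equal(centroidSize(matrix(2, 5, 3)), 0)
  expect_error(centroidSize(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)),
               "non-finite")
})

test_that("OPA recovers exact congruences with a proper rotation", {
  set.seed(2)
  x <- matrix(rnorm(15), 5, 3)
  same <- opaAlign(x, x)
  expect_equal(same$rotation, diag(3), tolerance = 1e-12)
  expect_equal(same$scale, 1)
  expect_lt(same$residual, 1e-20)

  moved <- sweep(x %*% rotZ(pi / 2), 2, c(2, 3, 0), "+")
  fit <- opaAlign(moved, x)
  expect_lt(fit$residual, 1e-20)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  expect_error(opaAlign(x, matrix(rnorm(12), 4, 3)), "mismatched")
})

test_that("OPA on mirrored shapes stays proper and matches brute force", {
  set.seed(3)
  x <- matrix(rnorm(15), 5, 3)
  mirrored <- x %*% diag(c(-1, 1, 1))
  fit <- opaAlign(mirrored, x)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$residual, 1e-4)
  oracle <- bruteForceOPAResidual(mirrored, x)
  expect_equal(fit$residual, oracle, tolerance = 1e-6)
})

test_that("OPA residual matches brute-force rotation search (both modes)", {
  set.seed(4)
  for (mode in c("SSS", "SS")) {
    for (rep in 1:3) {
      a <- matrix(rnorm(15), 5, 3)
      b <- matrix(rnorm(15), 5, 3)
      fit <- opaAlign(a, b, mode = mode)
      oracle <- bruteForceOPAResidual(a, b, mode = mode)
      expect_equal(fit$residual, oracle, tolerance = 1e-6)
    }
  }
})

test_that("OPA residual is invariant under common rigid motion of both inputs", {
  set.seed(5)
  a <- matrix(rnorm(24), 8, 3)
  b <- matrix(rnorm(24), 8, 3)
  base <- opaAlign(a, b)$residual
  for (rep in 1:5) {
    r <- randomRotation()
    shift <- rnorm(3)
    moved <- opaAlign(sweep(a %*% r, 2, shift, "+"),
                      sweep(b %*% r, 2, shift, "+"))$residual
    expect_equal(moved, base, tolerance = 1e-8)
  }
  baseSS <- opaAlign(a, b, mode = "SS")$residual
  s <- 2.7
  expect_equal(opaAlign(s * a, s * b, mode = "SS")$residual, baseSS,
               tolerance = 1e-8)
})

test_that("GPA: congruent sets collapse to zero objective", {
  set.seed(6)
  x <- matrix(rnorm(18), 6, 3)
  two <- gpa(list(x, x))
  expect_lt(tail(two$objectiveTrace, 1), 1e-20)
  expect_equal(two$consensus, centerConfig(x), tolerance = 1e-10)

  copies <- lapply(1:3, function(i)
    sweep(x %*% randomRotation(), 2, rnorm(3), "+"))
  expect_lt(tail(gpa(copies)$objectiveTrace, 1), 1e-18)

  scaled <- lapply(1:3, function(i)
    runif(1, 0.5, 2) * sweep(x %*% randomRotation(), 2, rnorm(3), "+"))
  expect_lt(tail(gpa(scaled, mode = "SS")$objectiveTrace, 1), 1e-18)
})

test_that("GPA objective is monotone and matches an independent implementation", {
  set.seed(7)
  for (mode in c("SSS", "SS")) {
    base <- matrix(rnorm(21), 7, 3)
    configs <- lapply(1:10, function(i)
      sweep((base + matrix(rnorm(21, sd = 0.2), 7, 3)) %*% randomRotation(),
            2, rnorm(3), "+"))
    fit <- gpa(configs, mode = mode)
    expect_true(all(diff(fit$objectiveTrace) <= 1e-12))
    expect_lte(tail(fit$objectiveTrace, 1), fit$objectiveTrace[1])
    oracle <- naiveGPA(configs, mode = mode, tol = 1e-15)
    expect_equal(tail(fit$objectiveTrace, 1), oracle$objective,
                 tolerance = 1e-6)
    # consensus equals mean of aligned shapes; aligned shapes are centered
    consensus <- Reduce(`+`, fit$aligned) / length(fit$aligned)
    expect_equal(fit$consensus, consensus, tolerance = 1e-10)
    expect_true(all(vapply(fit$aligned, function(a)
      max(abs(colMeans(a))) < 1e-10, logical(1))))
    if (mode == "SS") {
      cs <- vapply(fit$aligned, centroidSize, numeric(1))
      expect_equal(cs, rep(1, 10), tolerance = 1e-10)
    } else {
      csIn <- vapply(configs, centroidSize, numeric(1))
      csOut <- vapply(fit$aligned, centroidSize, numeric(1))
      expect_equal(csOut, csIn, tolerance = 1e-10)
    }
  }
})

test_that("GPA requires compatible inputs", {
  expect_error(gpa(list(matrix(0, 4, 3))), "at least 2")
  expect_error(gpa(list(matrix(rnorm(12), 4, 3), matrix(rnorm(15), 5, 3))),
               "same dimensions")
})

test_that("PCA: rank-1 data, completeness, orthonormality, sign convention", {
  set.seed(8)
  direction <- rnorm(12)
  line <- outer(rnorm(20), direction) +
    matrix(rep(rnorm(12), each = 20), 20, 12)
  m <- fitPCA(line)
  expect_equal(m@explainedFraction[1], 1, tolerance = 1e-10)

  x <- matrix(rnorm(240), 20, 12)
  m2 <- fitPCA(x)
  gram <- tcrossprod(m2@components)
  expect_equal(gram, diag(nrow(m2@components)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(m2@variances) <= 1e-12))
  expect_equal(sum(m2@explainedFraction), 1, tolerance = 1e-10)
  # reconstruction from all components reproduces the data
  scores <- pcProject(m2, x)
  recon <- sweep(scores %*% m2@components, 2, m2@center, "+")
  expect_equal(recon, x, tolerance = 1e-8, ignore_attr = TRUE)
  # score variances match model variances; scores are mean-zero
  expect_equal(apply(scores, 2, var), m2@variances, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(scores))), 1e-10)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(nrow(m2@components)))
    expect_gt(m2@components[j, which.max(abs(m2@components[j, ]))], 0)

  expect_error(fitPCA(matrix(1, 1, 5)), "at least 2")
})

test_that("shape reconstruction along a PC axis is linear about the mean", {
  set.seed(9)
  x <- matrix(rnorm(300), 10, 30)
  m <- fitPCA(x)
  mu <- unflattenConfig(m@center, d = 3)
  expect_equal(reconstructShapeAtScore(m, 1, 0), mu, tolerance = 1e-12)
  plus <- reconstructShapeAtScore(m, 2, 1.3)
  minus <- reconstructShapeAtScore(m, 2, -1.3)
  expect_equal((plus + minus) / 2, mu, tolerance = 1e-12)
  # full-score reconstruction of case rows
  scores <- pcProject(m, x)
  rec <- Reduce(`+`, lapply(seq_len(ncol(scores)), function(j)
    scores[3, j] * m@components[j, ])) + m@center
  expect_equal(unflattenConfig(rec, 3), unflattenConfig(x[3, ], 3),
               tolerance = 1e-8)
  expect_error(reconstructShapeAtScore(m, 99, 0), "out of range")
})

test_that("displacement magnitude equals the per-landmark loop", {
  set.seed(10)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(displacementMagnitude(a, a), rep(0, 10))
  expect_equal(displacementMagnitude(a, sweep(a, 2, c(0, 0, 1), "+")),
               rep(1, 10))
  b <- matrix(rnorm(30), 10, 3)
  loop <- vapply(1:10, function(i) sqrt(sum((a[i, ] - b[i, ])^2)), numeric(1))
  expect_equal(displacementMagnitude(a, b), loop)
  expect_error(displacementMagnitude(a, b[1:5, ]), "mismatched")
})
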