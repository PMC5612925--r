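# Independent oracles and shared fixtures for the test suite.

rotZ <- function(th) rbind(c(cos(th), sin(th), 0),
                           c(-sin(th), cos(th), 0),
                           c(0, 0, 1))

randomRotation <- function() {
  qrres <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qrres)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

eulerRotation <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

# Brute-force OPA oracle: numeric minimization of the residual over proper
# rotations (Euler-angle parametrization, many random restarts), independent
# of the SVD route.
bruteForceOPAResidual <- function(target, source, mode = "SSS",
                                  nStarts = 40L) {
  tc <- sweep(target, 2, colMeans(target))
  sc <- sweep(source, 2, colMeans(source))
  if (mode == "SS") {
    tc <- tc / sqrt(sum(tc^2))
    sc <- sc / sqrt(sum(sc^2))
  }
  obj <- function(ang) {
    r <- eulerRotation(ang)
    tr <- tc %*% r
    beta <- if (mode == "SS") max(0, sum(tr * sc) / sum(tr^2)) else 1
    sum((beta * tr - sc)^2)
  }
  best <- Inf
  for (s in seq_len(nStarts)) {
    start <- runif(3, -pi, pi)
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Second, straightforward GPA implementation (kept deliberately plain).
naiveGPA <- function(configs, mode = "SSS", tol = 1e-12, maxIter = 500L) {
  work <- lapply(configs, function(x) {
    xc <- sweep(x, 2, colMeans(x))
    if (mode == "SS") xc <- xc / sqrt(sum(xc^2))
    xc
  })
  rotTo <- function(x, y) {
    m <- t(x) %*% y
    sv <- svd(m)
    s <- sign(det(sv$u %*% t(sv$v))); if (s == 0) s <- 1
    d <- diag(c(rep(1, ncol(m) - 1), s))
    sv$u %*% d %*% t(sv$v)
  }
  cons <- work[[1]]
  prev <- Inf
  for (it in seq_len(maxIter)) {
    tgt <- if (mode == "SS") cons / sqrt(sum(cons^2)) else cons
    work <- lapply(work, function(x) x %*% rotTo(x, tgt))
    cons <- Reduce(`+`, work) / length(work)
    obj <- sum(vapply(work, function(w) sum((w - cons)^2), numeric(1)))
    if (is.finite(prev) && abs(prev - obj) <= tol * max(prev, 1e-300)) break
    prev <- obj
  }
  list(aligned = work, consensus = cons, objective = obj)
}

# Hand-computed one-way ANOVA from sums of squares (oracle for
# anovaAdjusted).
manualANOVA <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values); g <- nlevels(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  sst <- sum((values - gm)^2)
  ssw <- sst - ssb
  fstat <- (ssb / (g - 1)) / (ssw / (n - g))
  r2 <- ssb / sst
  list(F = fstat, p = pf(fstat, g - 1, n - g, lower.tail = FALSE),
       r2 = r2, adjR2 = 1 - (1 - r2) * (n - 1) / (n - g))
}

# Session-level cache so expensive cohorts/pipelines are built once.
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# Small registered two-group cohort with the default group effect.
effectCohortRegistered <- function() {
  cachedFixture("effectCohort", {
    sp <- simulationSpec(nPerGroup = 10L, seed = 42L)
    cases <- generateCohort(sp)
    rs <- registrationSpec()
    list(
      cases = cases,
      endo = lapply(cases, function(cs) registerSequence(cs@endo, rs)),
      mesh = cases[[1]]@mesh
    )
  })
}
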