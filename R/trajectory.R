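#' @include linear_shift.R
NULL

#' Per-case motion trajectories in PC space
#'
#' Splits the joint PC scores of a transported dataset into one ordered
#' nFrames x m path per case — the case's motion trajectory through the
#' space of the first `nPCs` principal components, which downstream
#' attribute analysis treats as a geometric shape whose "landmarks" are the
#' per-frame scores.
#'
#' @param tds an [LVTransportedDataset].
#' @param nPCs number of PC axes retained (default 3).
#' @return Object of class `"lvTrajectorySet"`: list with `trajectories`
#'   (list of nFrames x nPCs matrices, ordered as `caseTable`), `caseIds`,
#'   `groups`, `nFrames`, `surface`, `mode`.
#' @export
buildTrajectories <- function(tds, nPCs = 3L) {
  stopifnot(is(tds, "LVTransportedDataset"))
  nPCs <- min(nPCs, ncol(tds@scores))
  ct <- tds@caseTable
  nT <- max(tds@rowFrame)
  trajs <- lapply(ct$caseId, function(id) {
    sel <- tds@rowCase == id
    pts <- tds@scores[sel, seq_len(nPCs), drop = FALSE]
    pts[order(tds@rowFrame[sel]), , drop = FALSE]
  })
  structure(list(trajectories = trajs, caseIds = ct$caseId,
                 groups = ct$group, nFrames = nT,
                 surface = tds@surface, mode = tds@mode),
            class = "lvTrajectorySet")
}

#' Trajectory size
#'
#' Centroid size of the trajectory's point set — the same scale measure used
#' for landmark configurations, applied to the nFrames x m path of PC
#' scores. Invariant to translating the whole path; homogeneous of degree
#' one under scaling.
#'
#' @param points nFrames x m matrix of PC scores.
#' @return Non-negative scalar.
#' @export
trajectorySize <- function(points) {
  if (nrow(points) < 2L) stop("a trajectory needs at least 2 points",
                              call. = FALSE)
  centroidSize(points)
}

#' Trajectory orientation: the ED -> ES angle in a PC plane
#'
#' Four-quadrant angle (degrees in `[0, 360)`) of the vector connecting the
#' end-diastolic score (row 1) to the end-systolic score (row `esIndex`) in
#' the PC1/PC2 or PC1/PC3 plane — the morphological direction connecting the
#' two cardiac states.
#'
#' @param points nFrames x m matrix of PC scores (m >= 3 for plane "13").
#' @param plane `"12"` (PC1/PC2) or `"13"` (PC1/PC3).
#' @param esIndex row index of end-systole (default 11, the nominal ES frame
#'   of the default 30-frame registration).
#' @return Angle in degrees, `[0, 360)`.
#' @export
trajectoryAngle <- function(points, plane = c("12", "13"), esIndex = 11L) {
  plane <- match.arg(plane)
  axes <- if (plane == "12") c(1L, 2L) else c(1L, 3L)
  if (max(axes) > ncol(points))
    stop("trajectory has fewer PC axes than the requested plane",
         call. = FALSE)
  if (esIndex > nrow(points) || esIndex < 2L)
    stop("esIndex out of range", call. = FALSE)
  v <- points[esIndex, axes] - points[1L, axes]
  if (sqrt(sum(v^2)) < .Machine$double.eps * max(1, max(abs(points))))
    stop("ED and ES coincide in this plane: angle undefined", call. = FALSE)
  (atan2(v[2L], v[1L]) * 180 / pi) %% 360
}

#' Group test result container
#' @noRd
.groupTest <- function(statistic, pValue, rSquaredAdj = NA_real_, testKind) {
  list(statistic = unname(statistic), pValue = unname(pValue),
       rSquaredAdj = unname(rSquaredAdj), testKind = testKind)
}

#' One-way ANOVA with adjusted R-squared
#'
#' Standard one-way F test of `values` across groups, reporting the adjusted
#' coefficient of determination `1 - (1 - R^2) (n-1)/(n-g)` as the effect
#' size (adjusted R-squared can be negative for null effects). Degenerate
#' constant data return F = 0, p = 1.
#'
#' @param values numeric per-case measurements.
#' @param groups group labels (>= 2 groups, >= 2 cases per group).
#' @return A group-test result list: `statistic` (F), `pValue`,
#'   `rSquaredAdj`, `testKind = "anova"`.
#' @export
anovaAdjusted <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("need >= 2 cases per group", call. = FALSE)
  n <- length(values)
  g <- nlevels(groups)
  sst <- sum((values - mean(values))^2)
  if (sst <= .Machine$double.eps * max(1, mean(values)^2) * n)
    return(.groupTest(0, 1, 1 - (n - 1) / (n - g), "anova"))
  fit <- lm(values ~ groups)
  an <- anova(fit)
  s <- summary(fit)
  .groupTest(an$`F value`[1L], an$`Pr(>F)`[1L], s$adj.r.squared, "anova")
}

#' Trajectory shape analysis with MANOVA
#'
#' Treats each case's trajectory as a configuration of nFrames "landmarks"
#' in m dimensions, removes trajectory position, orientation and size by a
#' GPA with scaling (size is analyzed separately as its own attribute),
#' ordinates the aligned trajectories by PCA, and tests group differences in
#' the first `nPCs` trajectory-shape scores with a MANOVA (Wilks' lambda,
#' Rao's F approximation).
#'
#' @param trajSet an `"lvTrajectorySet"` from [buildTrajectories()].
#' @param nPCs number of trajectory-shape PCs entering the MANOVA (default
#'   15); clipped with a warning when fewer informative components exist.
#' @return List: `shapeScores` (n x p matrix), `model` (the [PCModel]),
#'   `nPCsUsed`, `manova` (group-test list with `statistic` = Wilks'
#'   lambda, `approxF`, `pValue`, `testKind = "manova_wilks"`).
#' @export
trajectoryShapeAnalysis <- function(trajSet, nPCs = 15L) {
  stopifnot(inherits(trajSet, "lvTrajectorySet"))
  groups <- factor(trajSet$groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  fit <- gpa(trajSet$trajectories, mode = "SS")
  m <- ncol(trajSet$trajectories[[1L]])
  vecs <- t(vapply(fit$aligned, flattenConfig,
                   numeric(trajSet$nFrames * m)))
  pcm <- fitPCA(vecs)
  scores <- pcProject(pcm, vecs)

  informative <- sum(pcm@variances > 1e-12 * max(pcm@variances, 1e-300))
  nUse <- min(nPCs, informative, nrow(vecs) - nlevels(groups))
  if (nUse < nPCs)
    warning(sprintf("only %d informative trajectory-shape PCs available; using %d",
                    informative, max(nUse, 0L)))

  totalVar <- sum(apply(scores, 2L, var))
  refScale <- mean(vapply(trajSet$trajectories, function(t) sum(t^2),
                          numeric(1)))
  if (nUse < 1L || totalVar <= 1e-18 * max(refScale, .Machine$double.xmin)) {
    ## no detectable shape variation among aligned trajectories
    test <- .groupTest(1, 1, NA_real_, "manova_wilks")
    test$approxF <- 0
    return(list(shapeScores = scores, model = pcm, nPCsUsed = 0L,
                manova = test))
  }

  y <- scores[, seq_len(nUse), drop = FALSE]
  mv <- summary(manova(y ~ groups), test = "Wilks")$stats
  test <- .groupTest(mv["groups", "Wilks"], mv["groups", "Pr(>F)"],
                     NA_real_, "manova_wilks")
  test$approxF <- unname(mv["groups", "approx F"])
  list(shapeScores = scores, model = pcm, nPCsUsed = as.integer(nUse),
       manova = test)
}

#' Permutation test of multivariate dispersion differences
#'
#' Tests whether groups differ in multivariate spread: each case's Euclidean
#' distance to its own group centroid in score space is computed, an ANOVA F
#' statistic compares those distances across groups, and significance comes
#' from permuting group labels (centroids and distances recomputed per
#' permutation).
#'
#' @param scores n x p matrix of (trajectory-shape) scores.
#' @param groups group labels (>= 2 groups, >= 3 cases per group).
#' @param nPerm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return Group-test list: `statistic` (F on centroid distances), `pValue`
#'   (permutation), `testKind = "dispersion_perm"`.
#' @export
dispersionTest <- function(scores, groups, nPerm = 999L, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 3L)) stop("need >= 3 cases per group", call. = FALSE)
  if (nPerm < 1L) stop("nPerm must be >= 1", call. = FALSE)
  scores <- as.matrix(scores)
  n <- nrow(scores)

  distStat <- function(g) {
    dists <- numeric(n)
    for (lev in levels(g)) {
      sel <- g == lev
      ctr <- colMeans(scores[sel, , drop = FALSE])
      dists[sel] <- sqrt(rowSums(sweep(scores[sel, , drop = FALSE], 2L,
                                       ctr, "-")^2))
    }
    gm <- mean(dists)
    ssb <- sum(tapply(dists, g, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(dists, g, function(v) sum((v - mean(v))^2)))
    dfb <- nlevels(g) - 1L
    dfw <- n - nlevels(g)
    if (ssw <= 0) return(if (ssb <= 0) 0 else Inf)
    (ssb / dfb) / (ssw / dfw)
  }

  fObs <- distStat(groups)
  set.seed(seed)
  fPerm <- vapply(seq_len(nPerm),
                  function(i) distStat(sample(groups)), numeric(1))
  p <- (1 + sum(fPerm >= fObs)) / (nPerm + 1)
  .groupTest(fObs, p, NA_real_, "dispersion_perm")
}

#' Per-timepoint group ANOVA along the cycle
#'
#' At each of the nFrames homologous times, a one-way ANOVA compares the
#' chosen PC score between groups — the per-frame significance track drawn
#' as asterisks along the temporal course of a PC. Raw p-values are reported
#' together with Benjamini-Hochberg-adjusted significance flags.
#'
#' @param tds an [LVTransportedDataset].
#' @param axis PC axis to test (default 1).
#' @param alpha significance level for the flags (default 0.05).
#' @return data.frame with one row per frame: `frame`, `statistic`,
#'   `pValue`, `rSquaredAdj`, `pBH`, `significantRaw`, `significantBH`.
#' @export
perTimeTests <- function(tds, axis = 1L, alpha = 0.05) {
  stopifnot(is(tds, "LVTransportedDataset"))
  if (axis < 1L || axis > ncol(tds@scores))
    stop("PC axis index out of range", call. = FALSE)
  groupOfCase <- setNames(tds@caseTable$group, tds@caseTable$caseId)
  nT <- max(tds@rowFrame)
  res <- lapply(seq_len(nT), function(t) {
    sel <- tds@rowFrame == t
    vals <- tds@scores[sel, axis]
    grp <- groupOfCase[tds@rowCase[sel]]
    tst <- anovaAdjusted(vals, grp)
    data.frame(frame = t, statistic = tst$statistic, pValue = tst$pValue,
               rSquaredAdj = tst$rSquaredAdj)
  })
  out <- do.call(rbind, res)
  out$pBH <- p.adjust(out$pValue, method = "BH")
  out$significantRaw <- out$pValue < alpha
  out$significantBH <- out$pBH < alpha
  out
}

#' Per-case trajectory attribute table
#'
#' Tidy per-case summary of the three trajectory attributes — size
#' ([trajectorySize()]), orientation in the PC1/PC2 and PC1/PC3 planes
#' ([trajectoryAngle()]) and shape scores ([trajectoryShapeAnalysis()]) —
#' for one transported dataset. Cases with an undefined angle (ED and ES
#' coincide in a plane) get `NA` there, with a warning naming the case.
#'
#' @param tds an [LVTransportedDataset].
#' @param nPCs trajectory dimension (default 3).
#' @param nShapePCs trajectory-shape scores kept in the table (default 15).
#' @param esIndex ES row used for angles (default the nominal ES frame 11).
#' @return data.frame: `caseId`, `group`, `surface`, `space`, `trajSize`,
#'   `angle12`, `angle13`, `shapePC1..nShapePCs`; the shape-analysis result
#'   is attached as attribute `"shapeAnalysis"`.
#' @export
trajectoryAttributes <- function(tds, nPCs = 3L, nShapePCs = 15L,
                                 esIndex = 11L) {
  trajSet <- buildTrajectories(tds, nPCs = nPCs)
  n <- length(trajSet$trajectories)
  sizes <- vapply(trajSet$trajectories, trajectorySize, numeric(1))
  ang <- function(pts, plane, id) {
    tryCatch(trajectoryAngle(pts, plane, esIndex = esIndex),
             error = function(e) {
               warning("angle undefined for case '", id, "' (", plane, "): ",
                       conditionMessage(e))
               NA_real_
             })
  }
  a12 <- mapply(function(p, id) ang(p, "12", id),
                trajSet$trajectories, trajSet$caseIds)
  a13 <- mapply(function(p, id) ang(p, "13", id),
                trajSet$trajectories, trajSet$caseIds)
  shp <- trajectoryShapeAnalysis(trajSet, nPCs = nShapePCs)
  nKeep <- min(nShapePCs, ncol(shp$shapeScores))
  shpScores <- shp$shapeScores[, seq_len(nKeep), drop = FALSE]
  colnames(shpScores) <- paste0("shapePC", seq_len(nKeep))
  out <- data.frame(caseId = trajSet$caseIds, group = trajSet$groups,
                    surface = trajSet$surface, space = trajSet$mode,
                    trajSize = sizes, angle12 = a12, angle13 = a13,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(shpScores))
  attr(out, "shapeAnalysis") <- shp
  out
}

#' Circular variance of a set of angles
#'
#' Diagnostic accompanying the plain ANOVA on ED->ES angles: angles live on
#' the circle, so the linear ANOVA is reported with this wrap-around-aware
#' spread measure alongside (`1 - |mean resultant vector|`, in `[0, 1]`).
#'
#' @param anglesDeg angles in degrees.
#' @return Circular variance in `[0, 1]`.
#' @export
circularVariance <- function(anglesDeg) {
  a <- anglesDeg[is.finite(anglesDeg)] * pi / 180
  if (!length(a)) return(NA_real_)
  1 - sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}
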