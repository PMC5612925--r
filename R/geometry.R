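#' @include AllClasses.R
NULL

## ---- basic configuration helpers -------------------------------------------

.checkConfig <- function(x, name = "configuration") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop(name, " contains non-finite coordinates", call. = FALSE)
  invisible(x)
}

#' Center a configuration at the origin
#'
#' @param x k x d numeric landmark matrix.
#' @return The matrix with its centroid translated to the origin.
#' @export
centerConfig <- function(x) {
  .checkConfig(x)
  sweep(x, 2L, colMeans(x), "-")
}

#' Centroid size of a configuration
#'
#' The standard geometric-morphometric scale measure: the square root of the
#' summed squared distances of all landmarks from their centroid. Homogeneous
#' of degree one (scaling a configuration by c scales its centroid size by c)
#' and zero only when all landmarks coincide.
#'
#' @param x k x d numeric landmark matrix.
#' @return A non-negative scalar.
#' @examples
#' sq <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0)
#' centroidSize(sq)  # sqrt(8)
#' @export
centroidSize <- function(x) {
  .checkConfig(x)
  sqrt(sum(centerConfig(x)^2))
}

## Row-major landmark-by-coordinate flattening (x1, y1, z1, x2, ...).
flattenConfig <- function(x) as.vector(t(x))
unflattenConfig <- function(v, d = 3L) matrix(v, ncol = d, byrow = TRUE)

#' Per-landmark displacement magnitude between two configurations
#'
#' Euclidean distance of each landmark in `a` from its homologue in `b`;
#' the quantity rendered as displacement colormaps over a surface.
#'
#' @param a,b k x d landmark matrices with matching dimensions.
#' @return Length-k non-negative vector.
#' @export
displacementMagnitude <- function(a, b) {
  .checkConfig(a); .checkConfig(b)
  if (!all(dim(a) == dim(b)))
    stop("configurations have mismatched dimensions", call. = FALSE)
  sqrt(rowSums((a - b)^2))
}

## ---- ordinary Procrustes alignment -----------------------------------------

## Optimal proper rotation R (applied as X %*% R) minimizing ||X R - Y||_F,
## for centered X, Y. Kabsch solution with smallest-singular-value sign
## correction so that det(R) = +1 always (no reflections: anatomical
## homology must not mirror). When the cross-covariance is (nearly) rank
## deficient the optimum can be non-unique; the fully degenerate case
## returns the identity (the rotation closest to identity) with a warning.
.optimalRotation <- function(x, y) {
  m <- crossprod(x, y)
  d <- ncol(m)
  sv <- svd(m)
  sgn <- sign(det(sv$u %*% t(sv$v)))
  if (sgn == 0) sgn <- 1
  if (max(sv$d) <= .Machine$double.eps * max(1, sum(abs(m)))) {
    warning("degenerate cross-covariance: rotation is arbitrary, using identity")
    return(list(rotation = diag(d), traceD = 0))
  }
  if (sv$d[d] < 1e-10 * sv$d[1L])
    warning("near rank-deficient cross-covariance: optimal rotation may not be unique")
  corr <- c(rep(1, d - 1L), sgn)
  rotation <- sv$u %*% (corr * t(sv$v))
  list(rotation = rotation, traceD = sum(sv$d * corr))
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Centers both configurations and finds the proper rotation (and, in shape
#' space, the scale) of `target` minimizing the sum of squared landmark
#' distances to the centered `source`. Reflections are excluded: the returned
#' rotation always has determinant +1.
#'
#' In `"SSS"` (size-and-shape space) mode only translation and rotation are
#' removed. In `"SS"` (shape space) mode shapes are scale-free: both
#' configurations are first normalized to unit centroid size and the
#' least-squares optimal (non-negative) scale is then applied to the target,
#' so the SS residual is the squared partial Procrustes distance and is
#' invariant under common scaling of both inputs.
#'
#' @param target,source k x d landmark matrices with equal dimensions.
#' @param mode `"SSS"` or `"SS"`.
#' @return A list with elements `aligned` (the transformed target),
#'   `rotation` (d x d, det +1), `scale` (the total factor applied to the
#'   centered target; 1 in SSS mode) and `residual` (the minimized sum of
#'   squares; against the unit-size source in SS mode).
#' @examples
#' x <- matrix(rnorm(15), 5, 3)
#' th <- pi / 3
#' rz <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
#' fit <- opaAlign(x %*% rz, x)
#' fit$residual  # ~ 0
#' @export
opaAlign <- function(target, source, mode = c("SSS", "SS")) {
  mode <- match.arg(mode)
  .checkConfig(target, "target"); .checkConfig(source, "source")
  if (!all(dim(target) == dim(source)))
    stop("target and source have mismatched dimensions", call. = FALSE)
  tc <- centerConfig(target)
  sc <- centerConfig(source)
  if (sum(sc^2) == 0)
    stop("source configuration is fully degenerate", call. = FALSE)
  scale <- 1
  if (mode == "SS") {
    csT <- sqrt(sum(tc^2))
    if (csT == 0) stop("cannot scale a fully degenerate target", call. = FALSE)
    csS <- sqrt(sum(sc^2))
    tc <- tc / csT
    sc <- sc / csS
    opt <- .optimalRotation(tc, sc)
    beta <- opt$traceD   # = cos of the Procrustes angle for unit shapes
    if (beta <= 0) {
      warning("non-positive optimal scale; shapes are nearly antipodal")
      beta <- 0
    }
    scale <- beta / csT
    aligned <- beta * (tc %*% opt$rotation)
  } else {
    opt <- .optimalRotation(tc, sc)
    aligned <- tc %*% opt$rotation
  }
  list(aligned = aligned, rotation = opt$rotation, scale = scale,
       residual = sum((aligned - sc)^2))
}

## ---- generalized Procrustes alignment --------------------------------------

#' Generalized Procrustes alignment of a set of configurations
#'
#' Iterative least-squares superimposition: all configurations are centered
#' (and scaled to unit centroid size in `"SS"` mode), then repeatedly rotated
#' to the current consensus, which is re-estimated as the arithmetic mean of
#' the aligned configurations. Iteration stops when the relative change of
#' the Procrustes objective (the summed squared distances of the aligned
#' configurations from their mean) falls below `tol`.
#'
#' In `"SS"` mode the configurations stay at unit centroid size throughout
#' (partial Procrustes superimposition in shape space) and the alignment
#' target is the consensus renormalized to unit size each iteration; the
#' returned `consensus` is the plain mean of the aligned configurations.
#' In `"SSS"` mode no scaling is applied anywhere and aligned configurations
#' keep the centroid sizes of the centered inputs.
#'
#' @param configs list of k x d landmark matrices (>= 2, equal dimensions).
#' @param mode `"SSS"` or `"SS"`.
#' @param tol relative objective-change convergence threshold.
#' @param maxIter iteration cap; non-convergence returns the current state
#'   with a warning and `converged = FALSE`.
#' @return An object of class `"gpaAlignment"`: list with `aligned` (list of
#'   aligned matrices), `consensus` (mean of aligned), `rotations` (list of
#'   d x d proper rotations), `scales`, `objectiveTrace` (non-increasing),
#'   `converged`, `iterations`, `mode`.
#' @export
gpa <- function(configs, mode = c("SSS", "SS"), tol = 1e-10, maxIter = 100L) {
  mode <- match.arg(mode)
  if (!is.list(configs) || length(configs) < 2L)
    stop("gpa needs a list of at least 2 configurations", call. = FALSE)
  dims <- vapply(configs, dim, integer(2))
  if (length(unique(dims[1L, ])) != 1L || length(unique(dims[2L, ])) != 1L)
    stop("all configurations must share the same dimensions", call. = FALSE)
  n <- length(configs)
  d <- ncol(configs[[1L]])

  scales <- rep(1, n)
  work <- vector("list", n)
  for (i in seq_len(n)) {
    .checkConfig(configs[[i]], sprintf("configuration %d", i))
    xc <- centerConfig(configs[[i]])
    if (mode == "SS") {
      cs <- sqrt(sum(xc^2))
      if (cs == 0)
        stop("configuration ", i, " is fully degenerate", call. = FALSE)
      scales[i] <- 1 / cs
      xc <- xc / cs
    }
    work[[i]] <- xc
  }

  rotations <- rep(list(diag(d)), n)
  consensusTarget <- work[[1L]]
  if (mode == "SS") consensusTarget <- consensusTarget / sqrt(sum(consensusTarget^2))
  objective <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  while (iter < maxIter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      opt <- .optimalRotation(work[[i]], consensusTarget)
      work[[i]] <- work[[i]] %*% opt$rotation
      rotations[[i]] <- rotations[[i]] %*% opt$rotation
    }
    consensus <- Reduce(`+`, work) / n
    newObjective <- sum(vapply(work, function(w) sum((w - consensus)^2),
                               numeric(1)))
    trace <- c(trace, newObjective)
    if (is.finite(objective)) {
      denom <- max(objective, .Machine$double.eps)
      if ((objective - newObjective) / denom < tol) {
        converged <- TRUE
        objective <- newObjective
        break
      }
    }
    objective <- newObjective
    consensusTarget <- consensus
    if (mode == "SS") {
      cs <- sqrt(sum(consensusTarget^2))
      if (cs > 0) consensusTarget <- consensusTarget / cs
    }
  }
  if (!converged)
    warning(sprintf("GPA did not converge in %d iterations", maxIter))

  consensus <- Reduce(`+`, work) / n
  structure(
    list(aligned = work, consensus = consensus, rotations = rotations,
         scales = scales, objectiveTrace = trace, converged = converged,
         iterations = iter, mode = mode),
    class = "gpaAlignment")
}

#' @export
print.gpaAlignment <- function(x, ...) {
  cat(sprintf(
    "GPA (%s): %d configurations, objective %.4g after %d iterations (%s)\n",
    x$mode, length(x$aligned), utils::tail(x$objectiveTrace, 1L),
    x$iterations, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

## Rotation angle (radians) of a d x d proper rotation; used as a GPA
## diagnostic. For d = 3 this is acos((tr R - 1)/2).
rotationAngle <- function(r) {
  d <- ncol(r)
  ct <- (sum(diag(r)) - (d - 3L) - 1) / 2
  if (d == 2L) ct <- sum(diag(r)) / 2
  acos(pmin(1, pmax(-1, ct)))
}

## ---- PCA over vectorized configurations ------------------------------------

#' Fit a PCA model to vectorized configurations
#'
#' Mean-centered eigendecomposition of the sample covariance of the rows.
#' Components are returned one per row, orthonormal, ordered by decreasing
#' variance; each component's sign is fixed so that its entry of largest
#' absolute value is positive, making score signs reproducible across
#' platforms.
#'
#' @param x n x p numeric matrix (n >= 2), one vectorized configuration per
#'   row.
#' @return A [PCModel].
#' @export
fitPCA <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2L)
    stop("fitPCA needs a matrix with at least 2 rows", call. = FALSE)
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  comps <- t(pr$rotation)
  for (j in seq_len(nrow(comps))) {
    i <- which.max(abs(comps[j, ]))
    if (comps[j, i] < 0) comps[j, ] <- -comps[j, ]
  }
  variances <- pr$sdev^2
  total <- sum(variances)
  new("PCModel", center = pr$center, components = comps,
      variances = variances,
      explainedFraction = if (total > 0) variances / total
                          else rep(0, length(variances)))
}

#' Project vectorized configurations onto a PC model
#'
#' @param model a [PCModel].
#' @param x n x p matrix in the model's coordinate space.
#' @return n x nComponents score matrix.
#' @export
pcProject <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sweep(x, 2L, model@center, "-") %*% t(model@components)
}

#' Reconstruct a configuration at a position along one PC axis
#'
#' Returns `center + magnification * score * component[axis]`, reshaped to a
#' k x d landmark matrix — the shape predicted at a chosen score along one
#' axis of variation (magnification > 1 exaggerates the deformation for
#' visualization).
#'
#' @param model a [PCModel].
#' @param axis 1-based component index.
#' @param score position along the axis.
#' @param magnification positive multiplier (default 1).
#' @param d coordinate dimension used to reshape (default 3).
#' @return k x d landmark matrix.
#' @export
reconstructShapeAtScore <- function(model, axis, score, magnification = 1,
                                    d = 3L) {
  if (axis < 1L || axis > nrow(model@components))
    stop("PC axis index out of range", call. = FALSE)
  if (magnification <= 0) stop("magnification must be positive", call. = FALSE)
  v <- model@center + magnification * score * model@components[axis, ]
  unflattenConfig(v, d = d)
}
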