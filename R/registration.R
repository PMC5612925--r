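#' @include geometry.R
NULL

#' Construct temporal registration settings
#'
#' Defaults follow the standard cardiac protocol: 30 output frames per
#' normalized cycle, end-systole pinned at 35% of the cycle, five Fourier
#' harmonics.
#'
#' @param nFrames number of uniformly spaced output frames.
#' @param esTargetPhase normalized phase at which ES is pinned.
#' @param nHarmonics number of harmonics of the cyclic representation.
#' @return A [RegistrationSpec].
#' @export
registrationSpec <- function(nFrames = 30L, esTargetPhase = 0.35,
                             nHarmonics = 5L) {
  new("RegistrationSpec", nFrames = as.integer(nFrames),
      esTargetPhase = esTargetPhase, nHarmonics = as.integer(nHarmonics))
}

#' Nominal end-systolic frame of a registration spec
#'
#' Frame t covers phases `[(t-1)/n, t/n)`; the frame containing the ES target
#' phase is `floor(phase * n) + 1` (floor convention), frame 11 for the
#' default 30-frame / 35% settings.
#'
#' @param spec a [RegistrationSpec].
#' @return Integer frame index.
#' @export
nominalESFrame <- function(spec) {
  as.integer(floor(spec@esTargetPhase * spec@nFrames) + 1L)
}

#' Piecewise-linear cyclic time warp pinning end-systole
#'
#' Maps raw cycle phase to normalized phase so that 0 -> 0, the raw ES phase
#' -> the target ES phase, and 1 -> 1, linearly on each of the two segments
#' (systole and diastole are stretched independently; ED stays continuous at
#' 0/100% of the cycle). A continuous, strictly increasing bijection of
#' [0, 1].
#'
#' @param phi raw phase(s) in `[0, 1]` (vectorized).
#' @param esRaw raw ES phase, strictly inside (0,1).
#' @param esTarget target ES phase, strictly inside (0,1) (default 0.35).
#' @return Warped phase(s) in `[0, 1]`.
#' @examples
#' warpPhase(0.25, esRaw = 0.5)          # 0.175
#' warpPhase(0.7, esRaw = 0.4)           # 0.675
#' @export
warpPhase <- function(phi, esRaw, esTarget = 0.35) {
  if (esRaw <= 0 || esRaw >= 1)
    stop("esRaw must lie strictly inside (0,1)", call. = FALSE)
  if (esTarget <= 0 || esTarget >= 1)
    stop("esTarget must lie strictly inside (0,1)", call. = FALSE)
  ifelse(phi <= esRaw,
         phi * esTarget / esRaw,
         esTarget + (phi - esRaw) * (1 - esTarget) / (1 - esRaw))
}

## ---- cyclic Fourier representation -----------------------------------------

.trigDesign <- function(phases, nHarmonics) {
  h <- seq_len(nHarmonics)
  ang <- outer(2 * pi * phases, h)
  cbind(1, cos(ang), sin(ang))
}

#' Fit a truncated Fourier series to cyclic samples
#'
#' Least-squares projection of `(phase, value)` samples onto the 1-periodic
#' trigonometric basis `{1, cos(2*pi*h*phi), sin(2*pi*h*phi)}`, h = 1..H
#' (harmonic regression / Fourier interpolation). With at least `2H + 1`
#' samples at distinct phases the fit reproduces any signal band-limited to H
#' harmonics exactly; phases need not be uniform, so warped sample times are
#' handled directly. The returned representation is exactly 1-periodic.
#'
#' A periodic cubic spline through the same samples, the classical supporting
#' interpolant for visualizing the continuous cycle, is available via
#' [periodicSplineFun()].
#'
#' @param phases sample phases in `[0, 1)`.
#' @param values sample values (same length).
#' @param nHarmonics number of harmonics H.
#' @return Object of class `"fourierFit"`: list with `a0`, `a` (cosine
#'   coefficients), `b` (sine coefficients), `nHarmonics`.
#' @seealso [evalFourier()]
#' @export
fourierFit <- function(phases, values, nHarmonics = 5L) {
  if (length(phases) != length(values))
    stop("phases and values must have equal length", call. = FALSE)
  if (length(phases) < 2L * nHarmonics + 1L)
    stop("need at least 2*nHarmonics + 1 samples", call. = FALSE)
  if (anyDuplicated(round(phases %% 1, 12L)))
    stop("sample phases must be distinct on the cycle", call. = FALSE)
  x <- .trigDesign(phases, nHarmonics)
  coefs <- qr.coef(qr(x), values)
  h <- nHarmonics
  structure(list(a0 = coefs[1L], a = coefs[2L:(h + 1L)],
                 b = coefs[(h + 2L):(2L * h + 1L)], nHarmonics = h),
            class = "fourierFit")
}

#' Evaluate a fitted Fourier series
#'
#' @param fit a `"fourierFit"` object.
#' @param phi phase(s); any real value, evaluated 1-periodically.
#' @return Numeric vector of values.
#' @export
evalFourier <- function(fit, phi) {
  h <- seq_len(fit$nHarmonics)
  ang <- outer(2 * pi * phi, h)
  drop(fit$a0 + cos(ang) %*% fit$a + sin(ang) %*% fit$b)
}

#' Periodic cubic spline through cyclic samples
#'
#' Supporting interpolant for a cyclic signal: a cubic spline with periodic
#' boundary conditions through the `(phase, value)` samples, period 1.
#'
#' @param phases sample phases in `[0, 1)`, need not be sorted.
#' @param values sample values.
#' @return A function of phase (vectorized, 1-periodic).
#' @export
periodicSplineFun <- function(phases, values) {
  ord <- order(phases)
  x <- c(phases[ord], phases[ord][1L] + 1)
  y <- c(values[ord], values[ord][1L])
  f <- stats::splinefun(x, y, method = "periodic")
  function(phi) f(phases[ord][1L] + (phi - phases[ord][1L]) %% 1)
}

## ---- sequence registration -------------------------------------------------

#' Temporally register a raw motion sequence
#'
#' Normalizes one case's cardiac cycle to `nFrames` homologous frames:
#' each raw frame's phase is warped so ES lands at the target phase
#' ([warpPhase()]), every landmark coordinate is fitted as a cyclic signal
#' with `nHarmonics` Fourier harmonics at the warped phases, and the fits are
#' resampled at uniform phases `(t-1)/nFrames`. Registration is idempotent on
#' already-registered band-limited sequences.
#'
#' @param raw an unregistered [LVMotionSequence] (raw cycle ED -> ED, frame j
#'   at phase (j-1)/T).
#' @param spec a [RegistrationSpec].
#' @return A registered [LVMotionSequence] with `nFrames` frames.
#' @export
registerSequence <- function(raw, spec = registrationSpec()) {
  stopifnot(is(raw, "LVMotionSequence"), is(spec, "RegistrationSpec"))
  if (raw@registered)
    warning("sequence '", raw@caseId, "' is already registered; re-registering")
  tRaw <- length(raw@frames)
  if (tRaw < 2L * spec@nHarmonics + 1L)
    stop(sprintf("case '%s': %d raw frames; need at least %d for %d harmonics",
                 raw@caseId, tRaw, 2L * spec@nHarmonics + 1L, spec@nHarmonics),
         call. = FALSE)
  k <- nrow(raw@frames[[1L]])
  d <- ncol(raw@frames[[1L]])

  rawPhases <- (seq_len(tRaw) - 1) / tRaw
  warped <- warpPhase(rawPhases, raw@esPhaseRaw, spec@esTargetPhase)

  ## one QR solve for all k*d coordinate signals at once
  y <- t(vapply(raw@frames, flattenConfig, numeric(k * d)))
  x <- .trigDesign(warped, spec@nHarmonics)
  coefs <- qr.coef(qr(x), y)

  outPhases <- (seq_len(spec@nFrames) - 1) / spec@nFrames
  resampled <- .trigDesign(outPhases, spec@nHarmonics) %*% coefs

  outFrames <- lapply(seq_len(spec@nFrames),
                      function(t) unflattenConfig(resampled[t, ], d = d))
  new("LVMotionSequence", caseId = raw@caseId, group = raw@group,
      surface = raw@surface, frames = outFrames,
      esPhaseRaw = spec@esTargetPhase, registered = TRUE)
}

## ---- end-systole detection -------------------------------------------------

#' Cavity volumes of every frame of a sequence
#'
#' @param seq an [LVMotionSequence].
#' @param mesh an [LVMesh] over the sequence's landmarks.
#' @return Numeric vector of volumes (ml), one per frame.
#' @export
frameVolumes <- function(seq, mesh) {
  vapply(seq@frames, cavityVolume, numeric(1), mesh = mesh)
}

#' Detect the end-systolic frame of a registered sequence
#'
#' End-systole is the time of minimal cavity volume. With `refine = TRUE`
#' (default) a circular parabola is fitted through the discrete volume
#' minimum and its two neighbours to estimate the continuous minimum phase,
#' and the frame containing that phase under the floor convention is
#' returned; this makes the detection robust to which side of an off-grid
#' minimum samples marginally lower (a volume minimum at exactly the 35%
#' target phase reports frame 11 of 30) and to isovolumetric noise. With
#' `refine = FALSE` the plain discrete argmin is returned, ties broken toward
#' the earlier frame.
#'
#' @param seq a registered endocardial [LVMotionSequence].
#' @param mesh an [LVMesh] over the sequence's landmarks.
#' @param refine logical; sub-frame parabolic refinement (default TRUE).
#' @return Integer frame index in `1..nFrames`.
#' @export
detectESFrame <- function(seq, mesh, refine = TRUE) {
  vols <- frameVolumes(seq, mesh)
  n <- length(vols)
  iMin <- which.min(vols)  # earliest index on exact ties
  if (!refine || n < 3L) return(iMin)
  if (diff(range(vols)) == 0) return(1L)

  iPrev <- if (iMin == 1L) n else iMin - 1L
  iNext <- if (iMin == n) 1L else iMin + 1L
  ## unwrap neighbour phases around the minimum
  p0 <- (iMin - 1) / n
  pPrev <- p0 - 1 / n
  pNext <- p0 + 1 / n
  v <- c(vols[iPrev], vols[iMin], vols[iNext])
  denom <- v[1L] - 2 * v[2L] + v[3L]
  if (denom <= 0) return(iMin)  # flat or non-convex neighbourhood
  vertex <- p0 + (1 / n) * (v[1L] - v[3L]) / (2 * denom)
  vertex <- min(max(vertex, pPrev), pNext) %% 1
  as.integer(floor(vertex * n) + 1L)
}
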