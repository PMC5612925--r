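#' @include mesh.R registration.R
NULL

#' Solve the radial contraction amplitude for a programmed ejection fraction
#'
#' Under the generator's anisotropic contraction map the cavity volume at
#' peak contraction scales exactly by `(1-a)^2 * (1 - a*longRatio*(1-sph))`
#' relative to end-diastole, so the radial amplitude `a` realizing a target
#' EF solves `(1-a)^2 (1 - a r (1-s)) = 1 - EF`.
#'
#' @param ef target ejection fraction in (0,1).
#' @param longRatio longitudinal/radial amplitude ratio.
#' @param sphericity sphericity-change coefficient (fractional loss of
#'   longitudinal shortening).
#' @return Radial amplitude in (0,1).
#' @export
amplitudeForEF <- function(ef, longRatio = 0.5, sphericity = 0) {
  stopifnot(ef > 0, ef < 1)
  f <- function(a) (1 - a)^2 * (1 - a * longRatio * (1 - sphericity)) -
    (1 - ef)
  uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}

#' Construct synthetic cohort settings
#'
#' The generator emulates the structure of population cardiac MR shape data:
#' per case, two nested truncated-ellipsoid surfaces (endocardium inside
#' epicardium, open base) sampled on a rings x meridians grid plus an apex
#' landmark; a smooth cyclic contraction ED -> ES -> ED whose volume minimum
#' sits at a case-specific raw ES phase; group-specific contraction
#' amplitude (Controls contract more than MI) and sphericity change (MI
#' loses more long-axis shortening); inter-individual baseline size and
#' orientation variation; per-frame rigid-motion jitter; i.i.d. landmark
#' noise; and per-case volume ground truth.
#'
#' @param nPerGroup cases per group.
#' @param rings,meridians surface grid (k = rings*meridians + 1 landmarks
#'   per surface; default 9 x 12 -> 109, configurable up to the full-study
#'   33 x 33 -> 1,090).
#' @param nRawFramesRange inclusive range the per-case raw frame count is
#'   drawn from.
#' @param esPhaseRawRange range of the raw ES phase.
#' @param ampControl,ampMI endocardial fractional radial contraction per
#'   group.
#' @param efTarget optional length-2 vector `c(Control, MI)` of programmed
#'   ejection fractions; when given, radial amplitudes are solved from it
#'   via [amplitudeForEF()] and override `ampControl`/`ampMI`.
#' @param epiAmpRatio epicardial/endocardial amplitude ratio.
#' @param epiEffectRatio fraction of the endocardial group amplitude
#'   difference expressed at the epicardium (default 0.5): infarct motion
#'   abnormalities are more accentuated at the endocardium, so the
#'   epicardial disease separation is compressed relative to the
#'   endocardial one.
#' @param longRatio longitudinal/radial amplitude ratio.
#' @param sphericityControl,sphericityMI fractional loss of longitudinal
#'   shortening per group (MI default larger: contraction becomes more
#'   spherical).
#' @param septalAkinesia logical; damp contraction in a septal angular
#'   sector (off by default).
#' @param septalDamping fractional damping inside the septal sector.
#' @param endoRadius,endoLength,wallThickness baseline endocardial
#'   equatorial radius, apex-to-base depth and wall thickness (mm).
#' @param baselineJitterSD lognormal SD of per-case size factors.
#' @param orientationJitterSD per-case orientation jitter (degrees).
#' @param frameJitterTransSD,frameJitterRotSD per-frame rigid jitter
#'   (mm / degrees).
#' @param noiseSD i.i.d. landmark noise SD (mm).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return An [LVSimulationSpec].
#' @export
simulationSpec <- function(nPerGroup = 20L, rings = 9L, meridians = 12L,
                           nRawFramesRange = c(20L, 35L),
                           esPhaseRawRange = c(0.4, 0.6),
                           ampControl = 0.55, ampMI = 0.30,
                           efTarget = numeric(0),
                           epiAmpRatio = 0.45, epiEffectRatio = 0.5,
                           longRatio = 0.5,
                           sphericityControl = 0, sphericityMI = 0.4,
                           septalAkinesia = FALSE, septalDamping = 0.7,
                           endoRadius = 25, endoLength = 75,
                           wallThickness = 8,
                           baselineJitterSD = 0.06,
                           orientationJitterSD = 4,
                           frameJitterTransSD = 0.3, frameJitterRotSD = 0.3,
                           noiseSD = 0.5, seed = 1L) {
  new("LVSimulationSpec",
      nPerGroup = as.integer(nPerGroup), rings = as.integer(rings),
      meridians = as.integer(meridians),
      nRawFramesRange = as.integer(nRawFramesRange),
      esPhaseRawRange = esPhaseRawRange,
      ampControl = ampControl, ampMI = ampMI, efTarget = efTarget,
      epiAmpRatio = epiAmpRatio, epiEffectRatio = epiEffectRatio,
      longRatio = longRatio,
      sphericityControl = sphericityControl, sphericityMI = sphericityMI,
      septalAkinesia = septalAkinesia, septalDamping = septalDamping,
      endoRadius = endoRadius, endoLength = endoLength,
      wallThickness = wallThickness,
      baselineJitterSD = baselineJitterSD,
      orientationJitterSD = orientationJitterSD,
      frameJitterTransSD = frameJitterTransSD,
      frameJitterRotSD = frameJitterRotSD,
      noiseSD = noiseSD, seed = as.integer(seed))
}

## Truncated-ellipsoid LV surface on the rings x meridians grid.
## Base plane at z = 0, apex at z = -length. Row 1 is the apex landmark.
.lvSurface <- function(radius, length, rings, meridians,
                       thetaMax = 2 * pi / 3) {
  cc <- length / (1 - cos(thetaMax))
  theta <- seq_len(rings) / rings * thetaMax
  phi <- (seq_len(meridians) - 1) / meridians * 2 * pi
  pts <- matrix(0, nrow = rings * meridians + 1L, ncol = 3L)
  pts[1L, ] <- c(0, 0, -length)                       # apex
  row <- 2L
  for (i in seq_len(rings)) {
    r <- radius * sin(theta[i])
    z <- -cc * (cos(theta[i]) - cos(thetaMax))
    for (j in seq_len(meridians)) {
      pts[row, ] <- c(r * cos(phi[j]), r * sin(phi[j]), z)
      row <- row + 1L
    }
  }
  pts
}

## Smooth cyclic contraction profile on the contraction clock:
## u in [0,1] with peak contraction at u = 0.5; g(0) = 0 (ED), g(0.5) = 1.
.contractionProfile <- function(u) (1 - cos(2 * pi * u)) / 2

## Anisotropic contraction of a surface about the base plane (z = 0):
## x,y scaled by rho, z by lambda. Cavity volume scales exactly by
## rho^2 * lambda.
.contract <- function(surface, g, ampR, ampL, septalMask = NULL,
                      septalDamping = 0) {
  gLocal <- rep(g, nrow(surface))
  if (!is.null(septalMask)) gLocal[septalMask] <- g * (1 - septalDamping)
  rho <- 1 - ampR * gLocal
  lambda <- 1 - ampL * gLocal
  cbind(surface[, 1L] * rho, surface[, 2L] * rho, surface[, 3L] * lambda)
}

.smallRotation <- function(sdDeg) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- rnorm(1, sd = sdDeg * pi / 180)
  kx <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(ang) * kx + (1 - cos(ang)) * (kx %*% kx)
}

#' Generate a synthetic two-surface LV motion cohort
#'
#' See [simulationSpec()] for what the generator emulates. Per case a
#' baseline geometry is drawn (size and orientation jitter around the
#' template), a raw frame count and raw ES phase are sampled, and frames at
#' raw phases (j-1)/T are produced by the cyclic contraction, rigid-motion
#' jitter and landmark noise. Ground truth per case: true EDV/ESV/EF by mesh
#' volume integration of the noise-free geometry at ED and peak contraction,
#' the programmed (analytic) EF, the raw ES phase and the applied
#' amplitudes.
#'
#' @param spec an [LVSimulationSpec].
#' @return List of [LVSyntheticCase] objects (Controls first, then MI).
#' @export
generateCohort <- function(spec = simulationSpec()) {
  stopifnot(is(spec, "LVSimulationSpec"))
  validObject(spec)
  set.seed(spec@seed)
  mesh <- buildLVMesh(spec@rings, spec@meridians)
  k <- spec@rings * spec@meridians + 1L

  amps <- c(Control = spec@ampControl, MI = spec@ampMI)
  sphs <- c(Control = spec@sphericityControl, MI = spec@sphericityMI)
  if (length(spec@efTarget) == 2L) {
    amps <- c(Control = amplitudeForEF(spec@efTarget[1L], spec@longRatio,
                                       sphs[["Control"]]),
              MI = amplitudeForEF(spec@efTarget[2L], spec@longRatio,
                                  sphs[["MI"]]))
  }

  cases <- list()
  for (grp in c("Control", "MI")) {
    for (i in seq_len(spec@nPerGroup)) {
      id <- sprintf("%s_%03d", grp, i)
      sizeJitR <- exp(rnorm(1, sd = spec@baselineJitterSD))
      sizeJitL <- exp(rnorm(1, sd = spec@baselineJitterSD))
      aEndo <- spec@endoRadius * sizeJitR
      lEndo <- spec@endoLength * sizeJitL
      aEpi <- aEndo + spec@wallThickness
      lEpi <- lEndo + spec@wallThickness
      endo0 <- .lvSurface(aEndo, lEndo, spec@rings, spec@meridians)
      epi0 <- .lvSurface(aEpi, lEpi, spec@rings, spec@meridians)
      caseRot <- .smallRotation(spec@orientationJitterSD)
      caseShift <- rnorm(3, sd = 2)

      ampR <- amps[[grp]]
      ampL <- ampR * spec@longRatio * (1 - sphs[[grp]])
      ## epicardial amplitude: compressed disease separation (endocardial
      ## dominance of MI motion abnormality)
      ampMean <- mean(amps)
      ampRepi <- spec@epiAmpRatio *
        (ampMean + spec@epiEffectRatio * (ampR - ampMean))
      ampLepi <- ampRepi * spec@longRatio * (1 - sphs[[grp]])

      septalMask <- NULL
      if (spec@septalAkinesia) {
        az <- atan2(endo0[, 2L], endo0[, 1L])
        septalMask <- which(abs(az) < pi / 4)
      }

      frameChoices <- seq(spec@nRawFramesRange[1L], spec@nRawFramesRange[2L])
      tRaw <- frameChoices[sample.int(length(frameChoices), 1L)]
      esRaw <- runif(1, spec@esPhaseRawRange[1L], spec@esPhaseRawRange[2L])

      endoFrames <- vector("list", tRaw)
      epiFrames <- vector("list", tRaw)
      for (j in seq_len(tRaw)) {
        u <- warpPhase((j - 1) / tRaw, esRaw, 0.5)
        g <- .contractionProfile(u)
        en <- .contract(endo0, g, ampR, ampL, septalMask, spec@septalDamping)
        ep <- .contract(epi0, g, ampRepi, ampLepi, septalMask,
                        spec@septalDamping)
        frameRot <- .smallRotation(spec@frameJitterRotSD)
        frameShift <- rnorm(3, sd = spec@frameJitterTransSD)
        rig <- function(x) {
          x <- x %*% caseRot %*% frameRot
          x <- sweep(x, 2L, caseShift + frameShift, "+")
          x + matrix(rnorm(length(x), sd = spec@noiseSD), ncol = 3L)
        }
        endoFrames[[j]] <- rig(en)
        epiFrames[[j]] <- rig(ep)
      }

      ## ground truth from noise-free geometry at ED (g = 0) and peak ES
      ## (g = 1); for the default affine contraction this equals the
      ## programmed analytic EF exactly.
      edv <- cavityVolume(endo0, mesh)
      esFrameTrue <- .contract(endo0, 1, ampR, ampL, septalMask,
                               spec@septalDamping)
      esv <- cavityVolume(esFrameTrue, mesh)
      stopifnot(edv > 0, esv > 0)
      truth <- list(edv = edv, esv = esv, ef = (edv - esv) / edv,
                    efProgrammed = 1 - (1 - ampR)^2 * (1 - ampL),
                    esPhaseRaw = esRaw, ampRadial = ampR,
                    ampLongitudinal = ampL, group = grp)

      cases[[id]] <- new("LVSyntheticCase",
        endo = new("LVMotionSequence", caseId = id, group = grp,
                   surface = "endo", frames = endoFrames,
                   esPhaseRaw = esRaw, registered = FALSE),
        epi = new("LVMotionSequence", caseId = id, group = grp,
                  surface = "epi", frames = epiFrames,
                  esPhaseRaw = esRaw, registered = FALSE),
        mesh = mesh, truth = truth)
    }
  }
  cases
}

## Project each column-space constraint out of a k x 3 matrix; constraints
## are given as a list of k x 3 matrices treated as vectors.
.projectOut <- function(x, constraints) {
  if (!length(constraints)) return(x)
  basis <- qr.Q(qr(vapply(constraints, as.vector,
                          numeric(length(x)))))
  v <- as.vector(x)
  matrix(v - basis %*% crossprod(basis, v), ncol = 3L)
}

## Constraint directions whose removal makes the cross-covariance of delta
## with template t symmetric (t A for a skew basis A), plus t itself
## (scale direction).
.symConstraints <- function(tmpl) {
  a1 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0))
  a2 <- rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0))
  a3 <- rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0))
  list(tmpl %*% a1, tmpl %*% a2, tmpl %*% a3, tmpl)
}

.centeringConstraints <- function(k) {
  lapply(1:3, function(j) {
    m <- matrix(0, k, 3L); m[, j] <- 1; m
  })
}

#' Canonical fixture for the transport-nulling property
#'
#' Two cases with genuinely different baseline shapes that share, by
#' construction, the identical within-cycle displacement field applied after
#' alignment — the situation Linear-Shift transport is designed to collapse:
#' after transport the two trajectories must coincide, while the raw
#' trajectories differ by the baseline shape difference.
#'
#' The displacement fields are constructed so that every optimal Procrustes
#' rotation in the pipeline is exactly the identity (each field is centered,
#' has symmetric cross-covariance with both templates and with every other
#' field, and is orthogonal to both scale directions; the templates are
#' size-matched and have symmetric cross-covariance), so the post-transport
#' trajectories coincide to machine precision in both SSS and SS.
#'
#' @param rings,meridians surface grid of the underlying shapes.
#' @param nFrames frames per cycle (default 30).
#' @param templateDiff relative size of the baseline-shape difference.
#' @param displacementScale relative size of the shared cyclic displacement.
#' @param seed RNG seed.
#' @return List of two registered endocardial [LVMotionSequence] objects
#'   (`caseA` in group Control, `caseB` in group MI).
#' @export
generateNullTransportPair <- function(rings = 7L, meridians = 10L,
                                      nFrames = 30L, templateDiff = 0.1,
                                      displacementScale = 0.03, seed = 1L) {
  set.seed(seed)
  k <- rings * meridians + 1L
  tA <- centerConfig(.lvSurface(25, 75, rings, meridians))
  csA <- centroidSize(tA)

  centerCons <- .centeringConstraints(k)
  dd <- matrix(rnorm(k * 3), k, 3L) * templateDiff * csA / sqrt(3 * k)
  dd <- .projectOut(dd, c(centerCons, .symConstraints(tA)))
  tB <- tA + dd
  tB <- tB * (csA / centroidSize(tB))   # size-match (keeps symmetry)

  cons <- c(centerCons, .symConstraints(tA), .symConstraints(tB))
  deltas <- vector("list", nFrames)
  targetNorm <- displacementScale * csA
  for (t in seq_len(nFrames)) {
    d <- matrix(rnorm(k * 3), k, 3L)
    d <- .projectOut(d, cons)
    d <- d * (targetNorm / sqrt(sum(d^2)))
    deltas[[t]] <- d
    cons <- c(cons, .symConstraints(d)[1:3])  # keep pairwise symmetry
  }

  mkSeq <- function(tmpl, id, grp) {
    new("LVMotionSequence", caseId = id, group = grp, surface = "endo",
        frames = lapply(deltas, function(d) tmpl + d),
        esPhaseRaw = 0.35, registered = TRUE)
  }
  list(caseA = mkSeq(tA, "nullA", "Control"),
       caseB = mkSeq(tB, "nullB", "MI"))
}
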