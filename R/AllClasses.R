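#' @include cardiomorph-package.R
NULL

.SPACE_MODES <- c("SSS", "SS")
.SURFACES <- c("endo", "epi")
.GROUPS <- c("Control", "MI")

#' Motion sequence of one surface of one case
#'
#' Ordered landmark configurations (k x 3 matrices, mm) through one cardiac
#' cycle, ED -> ED, frame 1 at phase 0 (end-diastole). Raw sequences carry the
#' expert-marked end-systolic phase `esPhaseRaw` in (0,1); registered
#' sequences have exactly `nFrames` frames at uniform phases (t-1)/nFrames.
#'
#' @slot caseId character case identifier.
#' @slot group character, `"Control"` or `"MI"`.
#' @slot surface character, `"endo"` or `"epi"`.
#' @slot frames list of k x 3 numeric matrices, shared k >= 4.
#' @slot esPhaseRaw numeric in (0,1): raw ES phase for unregistered
#'   sequences; the registration target phase after registration.
#' @slot registered logical flag.
#' @export
setClass("LVMotionSequence",
  representation(
    caseId = "character",
    group = "character",
    surface = "character",
    frames = "list",
    esPhaseRaw = "numeric",
    registered = "logical"
  ),
  prototype(registered = FALSE)
)

setValidity("LVMotionSequence", function(object) {
  msg <- character()
  if (length(object@frames) < 1L) msg <- c(msg, "sequence has no frames")
  dims <- vapply(object@frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) return(c(NA_integer_, NA_integer_))
    dim(f)
  }, integer(2))
  if (anyNA(dims)) {
    msg <- c(msg, "all frames must be numeric matrices")
  } else {
    if (length(unique(dims[1L, ])) != 1L || length(unique(dims[2L, ])) != 1L)
      msg <- c(msg, "all frames must share the same dimensions")
    if (dims[1L, 1L] < 4L) msg <- c(msg, "at least 4 landmarks required")
    if (!all(vapply(object@frames, function(f) all(is.finite(f)), logical(1))))
      msg <- c(msg, sprintf("non-finite coordinates in case '%s'", object@caseId))
  }
  if (!object@surface %in% .SURFACES)
    msg <- c(msg, "surface must be 'endo' or 'epi'")
  if (length(object@esPhaseRaw) != 1L || !is.finite(object@esPhaseRaw) ||
      object@esPhaseRaw <= 0 || object@esPhaseRaw >= 1)
    msg <- c(msg, "esPhaseRaw must lie strictly inside (0,1)")
  if (length(msg)) msg else TRUE
})

#' Temporal registration settings
#'
#' @slot nFrames integer number of output frames (default 30).
#' @slot esTargetPhase numeric phase at which end-systole is pinned
#'   (default 0.35).
#' @slot nHarmonics integer count of Fourier harmonics (default 5).
#' @export
setClass("RegistrationSpec",
  representation(nFrames = "integer", esTargetPhase = "numeric",
                 nHarmonics = "integer"))

setValidity("RegistrationSpec", function(object) {
  msg <- character()
  if (object@esTargetPhase <= 0 || object@esTargetPhase >= 1)
    msg <- c(msg, "esTargetPhase must be in (0,1)")
  if (object@nHarmonics < 1L) msg <- c(msg, "nHarmonics must be >= 1")
  if (object@nFrames <= 2L * object@nHarmonics)
    msg <- c(msg, "nFrames must exceed 2*nHarmonics (Nyquist)")
  if (length(msg)) msg else TRUE
})

#' Principal component model of vectorized configurations
#'
#' @slot center numeric mean vector (length k*d).
#' @slot components p x (k*d) matrix, orthonormal rows, one component per row.
#' @slot variances non-increasing component variances.
#' @slot explainedFraction per-component fraction of total variance.
#' @export
setClass("PCModel",
  representation(center = "numeric", components = "matrix",
                 variances = "numeric", explainedFraction = "numeric"))

setValidity("PCModel", function(object) {
  msg <- character()
  if (ncol(object@components) != length(object@center))
    msg <- c(msg, "component length must match center length")
  if (nrow(object@components) != length(object@variances))
    msg <- c(msg, "one variance per component required")
  if (is.unsorted(rev(object@variances), strictly = FALSE))
    msg <- c(msg, "variances must be sorted in decreasing order")
  if (any(object@variances < -1e-12))
    msg <- c(msg, "variances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Linear-Shift-transported dataset with its PC model
#'
#' Output of the full transport composition: common GPA for the grand mean
#' (common template, CT), per-case GPAs for local templates, OPA alignment of
#' each LT to the CT, Linear-Shift transport of within-cycle deformations to
#' the CT, a final common GPA, and PCA. Rows of `transported` and `scores`
#' are case-frame observations in row-major landmark flattening.
#'
#' @slot mode `"SSS"` (size retained) or `"SS"` (unit centroid size).
#' @slot surface `"endo"` or `"epi"`.
#' @slot ct k x d grand-mean configuration (unit size in SS).
#' @slot transported (n*nFrames) x (k*d) matrix of GPA-aligned transported
#'   shapes.
#' @slot pcModel [PCModel] fitted on `transported`.
#' @slot scores (n*nFrames) x p PC score matrix.
#' @slot rowCase,rowFrame per-row case id and frame index.
#' @slot caseTable data.frame with columns `caseId`, `group`.
#' @slot k,d landmark count and coordinate dimension.
#' @slot maxRotationAngle largest rotation (radians) applied by the final
#'   common GPA (diagnostic; expected near zero).
#' @slot ctDrift relative Procrustes distance between the CT and the final
#'   GPA consensus (diagnostic).
#' @export
setClass("LVTransportedDataset",
  representation(
    mode = "character", surface = "character",
    ct = "matrix", transported = "matrix",
    pcModel = "PCModel", scores = "matrix",
    rowCase = "character", rowFrame = "integer",
    caseTable = "data.frame",
    k = "integer", d = "integer",
    maxRotationAngle = "numeric", ctDrift = "numeric"
  ))

setValidity("LVTransportedDataset", function(object) {
  msg <- character()
  if (!object@mode %in% .SPACE_MODES) msg <- c(msg, "mode must be SSS or SS")
  n <- nrow(object@transported)
  if (nrow(object@scores) != n || length(object@rowCase) != n ||
      length(object@rowFrame) != n)
    msg <- c(msg, "row index vectors must match the transported matrix")
  if (ncol(object@transported) != object@k * object@d)
    msg <- c(msg, "transported width must equal k*d")
  if (n > 0 && max(abs(colMeans(object@scores))) > 1e-6)
    msg <- c(msg, "PC scores must have (near) zero column means")
  if (length(msg)) msg else TRUE
})

#' Repeated random-split SVM evaluation report
#'
#' @slot summary one-row data.frame of mean accuracy, specificity,
#'   sensitivity and AUC over all runs.
#' @slot perRun nRuns x 4 matrix of the raw per-run metrics.
#' @slot nRuns number of random splits.
#' @slot seed RNG seed the report is reproducible from.
#' @slot featureName label of the evaluated feature set.
#' @export
setClass("ClassificationReport",
  representation(summary = "data.frame", perRun = "matrix",
                 nRuns = "integer", seed = "integer",
                 featureName = "character"))

setValidity("ClassificationReport", function(object) {
  msg <- character()
  m <- as.numeric(object@perRun)
  if (length(m) && (any(m < -1e-12) || any(m > 1 + 1e-12)))
    msg <- c(msg, "all metrics must lie in [0,1]")
  if (nrow(object@perRun) != object@nRuns)
    msg <- c(msg, "perRun must have nRuns rows")
  if (length(msg)) msg else TRUE
})

#' Triangulated surface connectivity for cavity volumes
#'
#' Triangle list over the landmark indices of one surface, plus the ordered
#' basal ring whose centroid caps the open base so the surface closes.
#'
#' @slot triangles integer nT x 3 matrix of 1-based landmark indices, wound
#'   so that normals point outward.
#' @slot capRing ordered integer indices of the basal ring (may be empty for
#'   an already-closed mesh).
#' @export
setClass("LVMesh",
  representation(triangles = "matrix", capRing = "integer"))

setValidity("LVMesh", function(object) {
  msg <- character()
  if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must have 3 columns")
  if (any(object@triangles < 1L)) msg <- c(msg, "triangle indices are 1-based")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort settings
#'
#' Defaults encode the study conditions the generator emulates: two nested
#' tube-like LV surfaces, cyclic contraction with end-systole at a variable
#' raw phase, group-specific contraction amplitude (Control stronger than
#' MI), inter-individual baseline variation, rigid per-frame jitter and
#' landmark noise. See [simulationSpec()].
#'
#' @export
setClass("LVSimulationSpec",
  representation(
    nPerGroup = "integer", rings = "integer", meridians = "integer",
    nRawFramesRange = "integer", esPhaseRawRange = "numeric",
    ampControl = "numeric", ampMI = "numeric", efTarget = "numeric",
    epiAmpRatio = "numeric", epiEffectRatio = "numeric",
    longRatio = "numeric",
    sphericityControl = "numeric", sphericityMI = "numeric",
    septalAkinesia = "logical", septalDamping = "numeric",
    endoRadius = "numeric", endoLength = "numeric", wallThickness = "numeric",
    baselineJitterSD = "numeric", orientationJitterSD = "numeric",
    frameJitterTransSD = "numeric", frameJitterRotSD = "numeric",
    noiseSD = "numeric", seed = "integer"
  ))

setValidity("LVSimulationSpec", function(object) {
  msg <- character()
  amps <- c(object@ampControl, object@ampMI)
  if (any(amps <= 0) || any(amps >= 1))
    msg <- c(msg, "contraction amplitudes must lie in (0,1)")
  sds <- c(object@baselineJitterSD, object@orientationJitterSD,
           object@frameJitterTransSD, object@frameJitterRotSD, object@noiseSD)
  if (any(sds < 0)) msg <- c(msg, "all jitter/noise SDs must be >= 0")
  if (object@wallThickness <= 0) msg <- c(msg, "wallThickness must be > 0")
  if (diff(object@nRawFramesRange) < 0 || object@nRawFramesRange[1L] < 11L)
    msg <- c(msg, "raw frame counts must be >= 11 (2*harmonics + 1)")
  if (any(object@esPhaseRawRange <= 0) || any(object@esPhaseRawRange >= 1))
    msg <- c(msg, "esPhaseRawRange must lie inside (0,1)")
  if (length(object@efTarget) && (any(object@efTarget <= 0) ||
                                  any(object@efTarget >= 1)))
    msg <- c(msg, "efTarget values must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' One synthetic case: both surfaces, mesh and ground truth
#'
#' @slot endo,epi raw [LVMotionSequence] objects.
#' @slot mesh [LVMesh] connectivity shared by both surfaces.
#' @slot truth list of ground-truth values (true EDV/ESV/EF from noise-free
#'   geometry, programmed EF, raw ES phase, applied amplitudes).
#' @export
setClass("LVSyntheticCase",
  representation(endo = "LVMotionSequence", epi = "LVMotionSequence",
                 mesh = "LVMesh", truth = "list"))
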