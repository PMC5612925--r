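#' @include geometry.R
NULL

#' Per-case local templates (individual mean shapes)
#'
#' Runs a separate GPA over each case's registered frames; the local template
#' (LT) is that GPA's consensus — the individual's mean shape over its cycle.
#' In `"SS"` mode the LT is renormalized to unit centroid size.
#'
#' @param seqs list of registered [LVMotionSequence] objects (one surface).
#' @param mode `"SSS"` or `"SS"`.
#' @return List with one element per case: `caseId`, `group`, `shape`
#'   (the LT configuration), `alignedFrames` (the case's GPA-aligned frames)
#'   and `objective` (final within-case Procrustes objective).
#' @export
computeLocalTemplates <- function(seqs, mode = c("SSS", "SS")) {
  mode <- match.arg(mode)
  lapply(seqs, function(s) {
    stopifnot(is(s, "LVMotionSequence"))
    fit <- tryCatch(gpa(s@frames, mode = mode),
                    error = function(e)
                      stop("GPA failed for case '", s@caseId, "': ",
                           conditionMessage(e), call. = FALSE))
    lt <- fit$consensus
    if (mode == "SS") lt <- lt / sqrt(sum(lt^2))
    list(caseId = s@caseId, group = s@group, shape = lt,
         alignedFrames = fit$aligned,
         objective = utils::tail(fit$objectiveTrace, 1L))
  })
}

#' Linear-Shift parallel transport of within-cycle deformations
#'
#' Euclidean parallel transport of each case's within-cycle deformations to
#' the common template (CT, the grand mean): the case's local template (LT)
#' is OPA-aligned to the CT; every frame is OPA-aligned to the CT-aligned
#' LT; the deformation is the difference `aligned frame - aligned LT`; and
#' the transported shape is `CT + deformation`. Transporting the LT itself
#' therefore returns the CT exactly, and the deformation norm is preserved
#' by construction. What remains after transport is pure within-cycle
#' deformation: inter-individual baseline shape differences are filtered
#' out.
#'
#' @param seqs list of registered [LVMotionSequence] objects (one surface).
#' @param lts output of [computeLocalTemplates()] for the same cases.
#' @param ct k x d common-template configuration (centered; unit size in SS).
#' @param mode `"SSS"` or `"SS"`.
#' @return List: `transported` ((n*nFrames) x (k*d) matrix, row-major
#'   flattened), `rowCase`, `rowFrame`, `ct`, `mode`.
#' @export
linearShiftTransport <- function(seqs, lts, ct, mode = c("SSS", "SS")) {
  mode <- match.arg(mode)
  stopifnot(length(seqs) == length(lts))
  k <- nrow(ct); d <- ncol(ct)
  nT <- length(seqs[[1L]]@frames)
  rows <- vector("list", length(seqs))
  rowCase <- character(0); rowFrame <- integer(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]; lt <- lts[[i]]
    if (!identical(s@caseId, lt$caseId))
      stop("sequence/template case order mismatch at position ", i,
           call. = FALSE)
    ltAligned <- opaAlign(lt$shape, ct, mode = mode)$aligned
    if (mode == "SS") ltAligned <- ltAligned / sqrt(sum(ltAligned^2))
    def <- t(vapply(s@frames, function(f) {
      fa <- opaAlign(f, ltAligned, mode = mode)$aligned
      flattenConfig(fa - ltAligned)
    }, numeric(k * d)))
    rows[[i]] <- sweep(def, 2L, flattenConfig(ct), "+")
    rowCase <- c(rowCase, rep(s@caseId, nT))
    rowFrame <- c(rowFrame, seq_len(nT))
  }
  list(transported = do.call(rbind, rows), rowCase = rowCase,
       rowFrame = rowFrame, ct = ct, mode = mode)
}

#' Full Linear-Shift + GPA + PCA composition
#'
#' The complete deformation-analysis pipeline for one surface in one space:
#' a common GPA over all case-frames whose consensus defines the common
#' template (this GPA serves only to find the CT); separate per-case GPAs
#' for the local templates; OPA alignment of each LT to the CT; Linear-Shift
#' transport of all frames; a final common GPA over the transported shapes;
#' and PCA fitted jointly on all case-frame rows, so per-frame scores share
#' axes across the cycle.
#'
#' The final GPA re-estimates its consensus; since transported shapes are
#' all deformations of the one CT its rotations are expected to be tiny, and
#' the largest rotation angle plus the CT drift are kept as diagnostics.
#'
#' @param seqs list of registered [LVMotionSequence] objects, one surface,
#'   equal frame counts.
#' @param mode `"SSS"` or `"SS"`.
#' @return An [LVTransportedDataset].
#' @export
runLSPCA <- function(seqs, mode = c("SSS", "SS")) {
  mode <- match.arg(mode)
  stopifnot(length(seqs) >= 2L)
  if (!all(vapply(seqs, isRegistered, logical(1))))
    stop("all sequences must be registered first", call. = FALSE)
  surf <- unique(vapply(seqs, surfaceTag, character(1)))
  if (length(surf) != 1L)
    stop("all sequences must come from the same surface", call. = FALSE)
  nT <- unique(vapply(seqs, nFrames, integer(1)))
  if (length(nT) != 1L)
    stop("all sequences must share the frame count", call. = FALSE)

  allFrames <- unlist(lapply(seqs, frames), recursive = FALSE)
  ctFit <- gpa(allFrames, mode = mode)         # only serves to find the CT
  ct <- ctFit$consensus
  if (mode == "SS") ct <- ct / sqrt(sum(ct^2))

  lts <- computeLocalTemplates(seqs, mode = mode)
  tr <- linearShiftTransport(seqs, lts, ct, mode = mode)

  k <- nrow(ct); d <- ncol(ct)
  trConfigs <- lapply(seq_len(nrow(tr$transported)),
                      function(i) unflattenConfig(tr$transported[i, ], d = d))
  finalFit <- gpa(trConfigs, mode = mode)
  maxAngle <- max(vapply(finalFit$rotations, rotationAngle, numeric(1)))
  cons <- finalFit$consensus
  ctDrift <- {
    consN <- if (mode == "SS") cons / sqrt(sum(cons^2)) else cons
    sqrt(sum((consN - ct)^2)) / sqrt(sum(ct^2))
  }

  aligned <- t(vapply(finalFit$aligned, flattenConfig, numeric(k * d)))
  pcm <- fitPCA(aligned)
  scores <- pcProject(pcm, aligned)

  groupsByCase <- vapply(seqs, groupLabel, character(1))
  caseIds <- vapply(seqs, caseId, character(1))
  if (anyDuplicated(caseIds))
    stop("duplicated case ids in dataset", call. = FALSE)
  new("LVTransportedDataset", mode = mode, surface = surf,
      ct = ct, transported = aligned, pcModel = pcm, scores = scores,
      rowCase = tr$rowCase, rowFrame = tr$rowFrame,
      caseTable = data.frame(caseId = caseIds, group = groupsByCase,
                             stringsAsFactors = FALSE),
      k = as.integer(k), d = as.integer(d),
      maxRotationAngle = maxAngle, ctDrift = ctDrift)
}
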