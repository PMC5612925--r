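#' @include AllClasses.R
NULL

#' Accessors for cardiomorph containers
#'
#' Small generic accessors so user code never touches slots directly.
#'
#' @param x a cardiomorph S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("surfaceTag", function(x) standardGeneric("surfaceTag"))
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("esPhaseRaw", function(x) standardGeneric("esPhaseRaw"))
#' @rdname accessors
#' @export
setGeneric("isRegistered", function(x) standardGeneric("isRegistered"))
#' @rdname accessors
#' @export
setGeneric("spaceMode", function(x) standardGeneric("spaceMode"))
#' @rdname accessors
#' @export
setGeneric("commonTemplate", function(x) standardGeneric("commonTemplate"))
#' @rdname accessors
#' @export
setGeneric("pcModel", function(x) standardGeneric("pcModel"))
#' @rdname accessors
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))
#' @rdname accessors
#' @export
setGeneric("caseTable", function(x) standardGeneric("caseTable"))
#' @rdname accessors
#' @export
setGeneric("explainedFraction", function(x) standardGeneric("explainedFraction"))
#' @rdname accessors
#' @export
setGeneric("reportSummary", function(x) standardGeneric("reportSummary"))

#' @rdname accessors
setMethod("caseId", "LVMotionSequence", function(x) x@caseId)
#' @rdname accessors
setMethod("groupLabel", "LVMotionSequence", function(x) x@group)
#' @rdname accessors
setMethod("surfaceTag", "LVMotionSequence", function(x) x@surface)
#' @rdname accessors
setMethod("frames", "LVMotionSequence", function(x) x@frames)
#' @rdname accessors
setMethod("nFrames", "LVMotionSequence", function(x) length(x@frames))
#' @rdname accessors
setMethod("esPhaseRaw", "LVMotionSequence", function(x) x@esPhaseRaw)
#' @rdname accessors
setMethod("isRegistered", "LVMotionSequence", function(x) x@registered)

#' @rdname accessors
setMethod("spaceMode", "LVTransportedDataset", function(x) x@mode)
#' @rdname accessors
setMethod("surfaceTag", "LVTransportedDataset", function(x) x@surface)
#' @rdname accessors
setMethod("commonTemplate", "LVTransportedDataset", function(x) x@ct)
#' @rdname accessors
setMethod("pcModel", "LVTransportedDataset", function(x) x@pcModel)
#' @rdname accessors
setMethod("pcScores", "LVTransportedDataset", function(x) x@scores)
#' @rdname accessors
setMethod("caseTable", "LVTransportedDataset", function(x) x@caseTable)
#' @rdname accessors
setMethod("explainedFraction", "PCModel", function(x) x@explainedFraction)
#' @rdname accessors
setMethod("explainedFraction", "LVTransportedDataset",
          function(x) x@pcModel@explainedFraction)
#' @rdname accessors
setMethod("reportSummary", "ClassificationReport", function(x) x@summary)

setMethod("show", "LVMotionSequence", function(object) {
  k <- nrow(object@frames[[1L]])
  cat(sprintf("LVMotionSequence '%s' (%s, %s): %d frames, %d landmarks, %s\n",
              object@caseId, object@group, object@surface,
              length(object@frames), k,
              if (object@registered) "registered"
              else sprintf("raw (ES phase %.3f)", object@esPhaseRaw)))
})

setMethod("show", "PCModel", function(object) {
  p <- length(object@variances)
  cat(sprintf("PCModel: %d components over %d coordinates\n",
              p, length(object@center)))
  shown <- min(p, 5L)
  cat("  explained fraction:",
      paste(sprintf("%.3f", object@explainedFraction[seq_len(shown)]),
            collapse = " "),
      if (p > shown) "..." else "", "\n")
})

setMethod("show", "LVTransportedDataset", function(object) {
  cat(sprintf(
    "LVTransportedDataset (%s, %s): %d cases x %d frames, %d landmarks\n",
    object@surface, object@mode, nrow(object@caseTable),
    max(object@rowFrame), object@k))
  cat(sprintf("  PC1..3 variance fractions: %s\n",
              paste(sprintf("%.3f",
                            head(object@pcModel@explainedFraction, 3L)),
                    collapse = " ")))
  cat(sprintf("  final-GPA diagnostics: max rotation %.2e rad, CT drift %.2e\n",
              object@maxRotationAngle, object@ctDrift))
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport '%s' (%d runs, seed %d)\n",
              object@featureName, object@nRuns, object@seed))
  print(round(object@summary, 4L))
})

setMethod("show", "LVSyntheticCase", function(object) {
  cat(sprintf("LVSyntheticCase '%s' (%s): EF %.3f, EDV %.1f ml, ESV %.1f ml\n",
              object@endo@caseId, object@endo@group,
              object@truth$ef, object@truth$edv, object@truth$esv))
})
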