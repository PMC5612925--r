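#' @include io.R classification.R
NULL

#' Pipeline configuration
#'
#' Validated bundle of every stage's settings, with the standard defaults:
#' 30-frame registration with ES pinned at 35% and five harmonics, both
#' spaces and both surfaces, 3 trajectory PCs, 15 trajectory-shape PCs, and
#' the repeated-split SVM protocol.
#'
#' @param regSpec a [RegistrationSpec].
#' @param spaces subset of `c("SSS", "SS")`.
#' @param surfaces subset of `c("endo", "epi")`.
#' @param nPCs trajectory dimension.
#' @param nShapePCs trajectory-shape score count.
#' @param svmRuns random splits per feature set.
#' @param nTrainPerClass,nTestPerClass per-class split sizes.
#' @param seed root seed; stage seeds are derived from it.
#' @return A list of class `"lvPipelineConfig"`.
#' @export
pipelineConfig <- function(regSpec = registrationSpec(),
                           spaces = c("SSS", "SS"),
                           surfaces = c("endo", "epi"),
                           nPCs = 3L, nShapePCs = 15L,
                           svmRuns = 1000L, nTrainPerClass = 200L,
                           nTestPerClass = 100L, seed = 1L) {
  if (!all(spaces %in% .SPACE_MODES))
    stop("unknown space label: ", paste(setdiff(spaces, .SPACE_MODES),
                                        collapse = ", "), call. = FALSE)
  if (!all(surfaces %in% .SURFACES))
    stop("unknown surface label: ", paste(setdiff(surfaces, .SURFACES),
                                          collapse = ", "), call. = FALSE)
  stopifnot(is(regSpec, "RegistrationSpec"), nPCs >= 2L, nShapePCs >= 1L,
            svmRuns >= 1L)
  structure(list(regSpec = regSpec, spaces = spaces, surfaces = surfaces,
                 nPCs = as.integer(nPCs), nShapePCs = as.integer(nShapePCs),
                 svmRuns = as.integer(svmRuns),
                 nTrainPerClass = as.integer(nTrainPerClass),
                 nTestPerClass = as.integer(nTestPerClass),
                 seed = as.integer(seed)),
            class = "lvPipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.writeStamped <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash %s", hash), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full trajectory-analysis pipeline on a cohort
#'
#' register -> Linear-Shift transport + PCA (per surface x space) ->
#' trajectory attributes and group tests -> traditional indicators ->
#' repeated-split SVM classification, with all result tables written under
#' `outDir` (attribute tables, test tables, per-time significance tracks, a
#' classification summary, and a provenance record with the seed and
#' configuration). Fully reproducible from the configuration seed.
#'
#' @param cases list of [LVSyntheticCase] objects (or any list whose
#'   elements carry `endo`/`epi` raw [LVMotionSequence]s and a shared mesh),
#'   e.g. from [generateCohort()] or [readDataset()].
#' @param config an `"lvPipelineConfig"`.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list: `registered`, `transported` (named by
#'   `surface_space`), `attributes`, `tests`, `perTime`, `indicators`,
#'   `classification`.
#' @export
runPipeline <- function(cases, config = pipelineConfig(), outDir) {
  stopifnot(inherits(config, "lvPipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)
  esIdx <- nominalESFrame(config$regSpec)

  mesh <- if (is(cases[[1L]], "LVSyntheticCase")) cases[[1L]]@mesh else
    attr(cases, "mesh")

  pick <- function(cs, surf)
    if (is(cs, "LVSyntheticCase")) slot(cs, surf) else cs[[surf]]
  registered <- .stage("register", {
    lapply(cases, function(cs) {
      lapply(setNames(config$surfaces, config$surfaces), function(surf)
        registerSequence(pick(cs, surf), config$regSpec))
    })
  })

  indicators <- NULL
  if ("endo" %in% config$surfaces && !is.null(mesh)) {
    indicators <- .stage("indicators", {
      computeTraditionalIndicators(lapply(registered, `[[`, "endo"), mesh)
    })
    .writeStamped(indicators, file.path(outDir, "indicators.csv"), hash)
  }

  transported <- list(); attributes <- list(); tests <- list()
  perTime <- list()
  for (surf in config$surfaces) {
    seqs <- lapply(registered, `[[`, surf)
    for (space in config$spaces) {
      tag <- paste(surf, tolower(space), sep = "_")
      tds <- .stage(paste0("transport_", tag), runLSPCA(seqs, mode = space))
      transported[[tag]] <- tds

      at <- .stage(paste0("attributes_", tag),
                   trajectoryAttributes(tds, nPCs = config$nPCs,
                                        nShapePCs = config$nShapePCs,
                                        esIndex = esIdx))
      attributes[[tag]] <- at
      .writeStamped(at, file.path(outDir, sprintf("attributes_%s.csv", tag)),
                    hash)

      shp <- attr(at, "shapeAnalysis")
      tst <- .stage(paste0("tests_", tag), {
        size <- anovaAdjusted(at$trajSize, at$group)
        ok12 <- is.finite(at$angle12); ok13 <- is.finite(at$angle13)
        a12 <- anovaAdjusted(at$angle12[ok12], at$group[ok12])
        a13 <- anovaAdjusted(at$angle13[ok13], at$group[ok13])
        nUse <- max(shp$nPCsUsed, 1L)
        disp <- dispersionTest(
          shp$shapeScores[, seq_len(nUse), drop = FALSE],
          at$group, nPerm = 999L, seed = config$seed)
        data.frame(
          test = c("traj_size_anova", "angle12_anova", "angle13_anova",
                   "traj_shape_manova", "traj_shape_dispersion"),
          statistic = c(size$statistic, a12$statistic, a13$statistic,
                        shp$manova$statistic, disp$statistic),
          pValue = c(size$pValue, a12$pValue, a13$pValue,
                     shp$manova$pValue, disp$pValue),
          rSquaredAdj = c(size$rSquaredAdj, a12$rSquaredAdj,
                          a13$rSquaredAdj, NA, NA))
      })
      tests[[tag]] <- tst
      .writeStamped(tst, file.path(outDir, sprintf("tests_%s.csv", tag)),
                    hash)

      pt <- .stage(paste0("per_time_", tag), perTimeTests(tds, axis = 1L))
      perTime[[tag]] <- pt
      .writeStamped(pt, file.path(outDir, sprintf("per_time_%s.csv", tag)),
                    hash)
    }
  }

  classification <- .stage("classify", {
    fs <- buildFeatureSets(transported, clinical = indicators,
                           nPCs = config$nPCs, nShapePCs = config$nShapePCs,
                           esIndex = esIdx)
    classifyFeatureSets(fs, nRuns = config$svmRuns, seed = config$seed,
                        nTrainPerClass = config$nTrainPerClass,
                        nTestPerClass = config$nTestPerClass)
  })
  .writeStamped(classification, file.path(outDir, "classification.csv"), hash)

  provenance <- list(config_hash = hash, seed = config$seed,
                     n_cases = length(cases),
                     spaces = config$spaces, surfaces = config$surfaces,
                     n_frames = config$regSpec@nFrames,
                     es_target_phase = config$regSpec@esTargetPhase,
                     n_harmonics = config$regSpec@nHarmonics,
                     svm_runs = config$svmRuns,
                     package_version =
                       as.character(utils::packageVersion("cardiomorph")))
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(registered = registered, transported = transported,
                 attributes = attributes, tests = tests, perTime = perTime,
                 indicators = indicators, classification = classification))
}
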