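#' @include trajectory.R
NULL

#' Traditional volumetric indicators per case
#'
#' EDV (cavity volume at frame 1, end-diastole), ESV (minimum frame volume)
#' and ejection fraction EF = (EDV - ESV)/EDV from registered endocardial
#' sequences and their triangulation.
#'
#' @param seqs list of registered endocardial [LVMotionSequence] objects.
#' @param mesh an [LVMesh] shared by the sequences.
#' @return data.frame: `caseId`, `group`, `edv`, `esv`, `ef` (volumes in ml).
#' @export
computeTraditionalIndicators <- function(seqs, mesh) {
  rows <- lapply(seqs, function(s) {
    vols <- frameVolumes(s, mesh)
    edv <- vols[1L]
    esv <- min(vols)
    data.frame(caseId = s@caseId, group = s@group, edv = edv, esv = esv,
               ef = (edv - esv) / edv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Fast exact AUC of a continuous score for the positive class, by the
## rank-sum (Mann-Whitney) identity; ties handled by midranks.
.rankAUC <- function(score, positive) {
  r <- rank(score)
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Repeated stratified random-split SVM evaluation
#'
#' The evaluation protocol for one feature set: `nRuns` times, the cohort is
#' split per class into disjoint stratified train and test sets (defaults
#' 200 train + 100 test per class; cohorts smaller than that are split 2/3
#' train, 1/3 test per class with a warning), features are z-scored on the
#' training set only, an SVM is fitted on the training set, and accuracy,
#' specificity, sensitivity (Control = negative, MI = positive) and the AUC
#' of the ROC of the continuous decision values are recorded on the test
#' set. Means over all runs summarize performance; the whole procedure is
#' reproducible from `seed`.
#'
#' @param x n x d numeric feature matrix (rows = cases; no missing values).
#' @param labels per-case labels, `"Control"`/`"MI"`.
#' @param nRuns number of random splits (default 1000).
#' @param nTrainPerClass,nTestPerClass per-class split sizes (defaults
#'   200/100).
#' @param seed RNG seed.
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost SVM regularization constant (default 1).
#' @param featureName label stored in the report.
#' @return A [ClassificationReport].
#' @export
runRepeatedSVM <- function(x, labels, nRuns = 1000L, nTrainPerClass = 200L,
                           nTestPerClass = 100L, seed = 1L,
                           kernel = "linear", cost = 1,
                           featureName = "features") {
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  labels <- factor(labels, levels = c("Control", "MI"))
  if (anyNA(labels)) stop("labels must be 'Control' or 'MI'", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L)) stop("each class needs at least 2 cases", call. = FALSE)
  nTrain <- setNames(rep(as.integer(nTrainPerClass), 2L), levels(labels))
  nTest <- setNames(rep(as.integer(nTestPerClass), 2L), levels(labels))
  if (any(counts < nTrainPerClass + nTestPerClass)) {
    nTrain <- setNames(pmax(1L, floor(2 / 3 * as.integer(counts))),
                       names(counts))
    nTest <- as.integer(counts) - nTrain
    names(nTest) <- names(counts)
    warning(sprintf(
      "cohort smaller than %d+%d per class; using 2/3-1/3 splits (%s train / %s test)",
      nTrainPerClass, nTestPerClass,
      paste(nTrain, collapse = "+"), paste(nTest, collapse = "+")))
    if (any(nTest < 1L))
      stop("classes too small for a train/test split", call. = FALSE)
  }

  idxByClass <- split(seq_along(labels), labels)
  set.seed(seed)
  perRun <- matrix(NA_real_, nrow = nRuns, ncol = 4L,
                   dimnames = list(NULL, c("accuracy", "specificity",
                                           "sensitivity", "auc")))
  for (run in seq_len(nRuns)) {
    trainIdx <- integer(0); testIdx <- integer(0)
    for (cl in levels(labels)) {
      pool <- idxByClass[[cl]]
      tr <- sample(pool, nTrain[[cl]])
      remaining <- setdiff(pool, tr)
      te <- if (length(remaining) > nTest[[cl]])
        sample(remaining, nTest[[cl]]) else remaining
      trainIdx <- c(trainIdx, tr); testIdx <- c(testIdx, te)
    }
    stopifnot(length(intersect(trainIdx, testIdx)) == 0L)

    mu <- colMeans(x[trainIdx, , drop = FALSE])
    sig <- apply(x[trainIdx, , drop = FALSE], 2L, sd)
    sig[sig == 0 | !is.finite(sig)] <- 1
    z <- sweep(sweep(x, 2L, mu, "-"), 2L, sig, "/")

    fit <- e1071::svm(z[trainIdx, , drop = FALSE], labels[trainIdx],
                      kernel = kernel, cost = cost, scale = FALSE)
    pred <- predict(fit, z[testIdx, , drop = FALSE], decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    ## e1071 decision values are positive for the class named first in the
    ## column label; orient so larger = more MI-like.
    miScore <- if (grepl("^MI/", colnames(attr(pred, "decision.values"))[1L]))
      dv else -dv
    truth <- labels[testIdx]
    isMI <- truth == "MI"
    perRun[run, "accuracy"] <- mean(pred == truth)
    perRun[run, "sensitivity"] <- mean(pred[isMI] == "MI")
    perRun[run, "specificity"] <- mean(pred[!isMI] == "Control")
    perRun[run, "auc"] <- .rankAUC(miScore, isMI)
  }

  new("ClassificationReport",
      summary = as.data.frame(t(colMeans(perRun))),
      perRun = perRun, nRuns = as.integer(nRuns), seed = as.integer(seed),
      featureName = featureName)
}

#' Assemble the full menu of classifier feature sets
#'
#' For each transported dataset (surface x space) the morphometric feature
#' sets evaluated in the classification exercise: the two ED->ES angles, the
#' trajectory size, the first `nShapePCs` trajectory-shape scores, PC1, PC2
#' and PC3 evaluated at all homologous times (d = nFrames each), and
#' PC1-PC10 at all times (d = 10*nFrames); plus, when a clinical table is
#' given, the traditional indicators EF, ESV and EDV (d = 1 each).
#' Cases with an undefined angle are dropped from that angle's feature set.
#'
#' @param tdsList list of [LVTransportedDataset] objects (any surfaces and
#'   spaces; all over the same cases).
#' @param clinical optional data.frame from
#'   [computeTraditionalIndicators()].
#' @param nPCs trajectory dimension for angles (default 3).
#' @param nShapePCs trajectory-shape score count (default 15).
#' @param esIndex ES frame for angles (default 11).
#' @return Named list; each element has `name`, `matrix` (cases x d),
#'   `labels`, `surface`, `space`.
#' @export
buildFeatureSets <- function(tdsList, clinical = NULL, nPCs = 3L,
                             nShapePCs = 15L, esIndex = 11L) {
  out <- list()
  add <- function(name, mat, labels, surface, space) {
    keep <- stats::complete.cases(mat)
    out[[name]] <<- list(name = name,
                         matrix = as.matrix(mat)[keep, , drop = FALSE],
                         labels = labels[keep],
                         surface = surface, space = space)
  }
  for (tds in tdsList) {
    stopifnot(is(tds, "LVTransportedDataset"))
    tag <- paste(tds@surface, tolower(tds@mode), sep = "_")
    attrs <- trajectoryAttributes(tds, nPCs = nPCs, nShapePCs = nShapePCs,
                                  esIndex = esIndex)
    labels <- attrs$group
    add(paste0(tag, "_angle12"), attrs[, "angle12", drop = FALSE],
        labels, tds@surface, tds@mode)
    add(paste0(tag, "_angle13"), attrs[, "angle13", drop = FALSE],
        labels, tds@surface, tds@mode)
    add(paste0(tag, "_traj_size"), attrs[, "trajSize", drop = FALSE],
        labels, tds@surface, tds@mode)
    shapeCols <- grep("^shapePC", names(attrs), value = TRUE)
    add(paste0(tag, "_traj_shape_", length(shapeCols), "pc"),
        attrs[, shapeCols, drop = FALSE], labels, tds@surface, tds@mode)

    ## per-time score features: case rows, frame columns
    nT <- max(tds@rowFrame)
    perTime <- function(axes) {
      mats <- lapply(tds@caseTable$caseId, function(id) {
        sel <- tds@rowCase == id
        sc <- tds@scores[sel, axes, drop = FALSE]
        as.vector(sc[order(tds@rowFrame[sel]), , drop = FALSE])
      })
      do.call(rbind, mats)
    }
    for (kk in 1:3)
      if (kk <= ncol(tds@scores))
        add(paste0(tag, "_pc", kk, "_all_times"), perTime(kk),
            tds@caseTable$group, tds@surface, tds@mode)
    nTop <- min(10L, ncol(tds@scores))
    add(paste0(tag, "_pc1_", nTop, "_all_times"), perTime(seq_len(nTop)),
        tds@caseTable$group, tds@surface, tds@mode)
  }
  if (!is.null(clinical)) {
    for (v in c("ef", "esv", "edv"))
      add(v, clinical[, v, drop = FALSE], clinical$group, "none", "none")
  }
  out
}

#' Evaluate every feature set with the repeated-split SVM protocol
#'
#' @param featureSets output of [buildFeatureSets()].
#' @param nRuns,seed,... passed to [runRepeatedSVM()]; each feature set gets
#'   its own derived seed so reports are independent but reproducible.
#' @return data.frame, one row per feature set, with the mean metrics; the
#'   full [ClassificationReport] objects are attached as attribute
#'   `"reports"`.
#' @export
classifyFeatureSets <- function(featureSets, nRuns = 1000L, seed = 1L, ...) {
  reports <- list()
  rows <- list()
  for (i in seq_along(featureSets)) {
    fs <- featureSets[[i]]
    rep <- runRepeatedSVM(fs$matrix, fs$labels, nRuns = nRuns,
                          seed = seed + i, featureName = fs$name, ...)
    reports[[fs$name]] <- rep
    rows[[fs$name]] <- cbind(data.frame(feature = fs$name,
                                        surface = fs$surface,
                                        space = fs$space,
                                        d = ncol(fs$matrix),
                                        stringsAsFactors = FALSE),
                             rep@summary)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
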