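#' @include simulate.R
NULL

.fmt17 <- function(x) sprintf("%.17g", x)

## Small deterministic string hash used to stamp outputs with their
## configuration (FNV-1a style folded to 31 bits).
.configHash <- function(obj) {
  s <- paste(deparse(obj), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.writeMesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("LVMESH", con)
  writeLines(sprintf("triangles %d", nrow(mesh@triangles)), con)
  apply(mesh@triangles - 1L, 1L, function(tr)
    writeLines(paste(tr, collapse = " "), con))
  writeLines(paste(c("cap", mesh@capRing - 1L), collapse = " "), con)
  invisible(path)
}

.readMesh <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "LVMESH")
    stop("bad mesh header in ", path, call. = FALSE)
  nT <- as.integer(sub("^triangles ", "", lines[2L]))
  tri <- do.call(rbind, lapply(lines[3:(2 + nT)], function(l)
    as.integer(strsplit(l, " ")[[1L]])))
  capLine <- strsplit(lines[3L + nT], " ")[[1L]]
  stopifnot(capLine[1L] == "cap")
  lvMesh(tri + 1L, capRing = as.integer(capLine[-1L]) + 1L)
}

#' Write a cohort to a plain-text dataset directory
#'
#' Layout: `manifest.json` (cases, groups, frame counts, raw ES phases,
#' landmark counts), one tidy CSV per case and surface
#' (`<caseId>_<surface>.csv` with columns frame, landmark, x, y, z; 1-based
#' indices, mm, full double precision), a shared `mesh.txt` (0-based
#' triangle list plus basal cap ring) and `clinical.csv` with the
#' ground-truth EDV/ESV/EF when available.
#'
#' @param cases list of [LVSyntheticCase] objects.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeDataset <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(cases = lapply(cases, function(cs) {
    list(case_id = cs@endo@caseId, group = cs@endo@group,
         surfaces = c("endo", "epi"),
         n_frames = length(cs@endo@frames),
         es_phase_raw = cs@endo@esPhaseRaw,
         k = nrow(cs@endo@frames[[1L]]))
  }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (cs in cases) {
    for (surf in c("endo", "epi")) {
      s <- slot(cs, surf)
      k <- nrow(s@frames[[1L]])
      nT <- length(s@frames)
      co <- do.call(rbind, s@frames)
      df <- data.frame(frame = rep(seq_len(nT), each = k),
                       landmark = rep(seq_len(k), nT),
                       x = .fmt17(co[, 1L]), y = .fmt17(co[, 2L]),
                       z = .fmt17(co[, 3L]))
      write.csv(df, file.path(dir, paste0(s@caseId, "_", surf, ".csv")),
                row.names = FALSE, quote = FALSE)
    }
  }
  .writeMesh(cases[[1L]]@mesh, file.path(dir, "mesh.txt"))
  clin <- do.call(rbind, lapply(cases, function(cs)
    data.frame(caseId = cs@endo@caseId, group = cs@endo@group,
               edv = .fmt17(cs@truth$edv), esv = .fmt17(cs@truth$esv),
               ef = .fmt17(cs@truth$ef))))
  write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' Read a plain-text dataset directory
#'
#' Inverse of [writeDataset()], with validation: every case file listed in
#' the manifest must exist, landmark counts must be consistent, and any
#' non-finite coordinate aborts with the offending case and row.
#'
#' @param dir dataset directory.
#' @return List: `sequences` (list per case with `endo`/`epi` raw
#'   [LVMotionSequence]s), `mesh` ([LVMesh]), `clinical` (data.frame or
#'   NULL).
#' @export
readDataset <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath))
    stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(manifestPath)
  mesh <- .readMesh(file.path(dir, "mesh.txt"))
  sequences <- list()
  kSeen <- NULL
  for (entry in manifest$cases) {
    id <- entry$case_id
    caseSeqs <- list()
    for (surf in unlist(entry$surfaces)) {
      path <- file.path(dir, paste0(id, "_", surf, ".csv"))
      if (!file.exists(path))
        stop(sprintf("missing landmark file for case '%s' surface '%s'",
                     id, surf), call. = FALSE)
      df <- read.csv(path)
      bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
      if (length(bad))
        stop(sprintf("non-finite coordinate in case '%s' (%s), row %d",
                     id, surf, bad[1L]), call. = FALSE)
      k <- max(df$landmark)
      if (is.null(kSeen)) kSeen <- k
      else if (k != kSeen)
        stop(sprintf("inconsistent landmark count in case '%s' (%s): %d vs %d",
                     id, surf, k, kSeen), call. = FALSE)
      frames <- lapply(split(df, df$frame), function(fr)
        as.matrix(fr[order(fr$landmark), c("x", "y", "z")]))
      frames <- unname(frames[order(as.integer(names(frames)))])
      frames <- lapply(frames, function(f) {
        dimnames(f) <- NULL; f
      })
      caseSeqs[[surf]] <- new("LVMotionSequence", caseId = id,
                              group = entry$group, surface = surf,
                              frames = frames,
                              esPhaseRaw = entry$es_phase_raw,
                              registered = FALSE)
    }
    sequences[[id]] <- caseSeqs
  }
  clinPath <- file.path(dir, "clinical.csv")
  clinical <- if (file.exists(clinPath)) read.csv(clinPath) else NULL
  list(sequences = sequences, mesh = mesh, clinical = clinical)
}
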