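#' @include AllClasses.R
NULL

#' Construct an LV surface mesh
#'
#' @param triangles integer nT x 3 matrix of 1-based landmark indices, wound
#'   counter-clockwise seen from outside (outward normals).
#' @param capRing ordered 1-based indices of the open basal ring; the cavity
#'   volume routine caps it with a fan to the ring centroid.
#' @return An [LVMesh].
#' @export
lvMesh <- function(triangles, capRing = integer(0)) {
  storage.mode(triangles) <- "integer"
  new("LVMesh", triangles = triangles, capRing = as.integer(capRing))
}

#' Triangulation of the generator's rings x meridians LV surface grid
#'
#' Vertex layout: index 1 is the apex; ring i (1 = nearest the apex, `rings`
#' = basal), meridian j has index `1 + (i-1)*meridians + j`. Triangles: an
#' apex fan to ring 1, two triangles per quad between consecutive rings, and
#' the basal ring returned as `capRing` so the open base is capped at its
#' centroid when integrating volumes.
#'
#' @param rings,meridians grid dimensions (rings >= 2, meridians >= 3).
#' @return An [LVMesh] over `rings*meridians + 1` vertices.
#' @export
buildLVMesh <- function(rings, meridians) {
  stopifnot(rings >= 2L, meridians >= 3L)
  rings <- as.integer(rings); meridians <- as.integer(meridians)
  idx <- function(i, j) 1L + (i - 1L) * meridians + ((j - 1L) %% meridians) + 1L
  tris <- list()
  for (j in seq_len(meridians))               # apex fan
    tris[[length(tris) + 1L]] <- c(1L, idx(1L, j + 1L), idx(1L, j))
  for (i in seq_len(rings - 1L)) {            # ring-to-ring quads
    for (j in seq_len(meridians)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      cc <- idx(i + 1L, j + 1L); dd <- idx(i + 1L, j)
      tris[[length(tris) + 1L]] <- c(a, b, cc)
      tris[[length(tris) + 1L]] <- c(a, cc, dd)
    }
  }
  lvMesh(do.call(rbind, tris),
         capRing = vapply(seq_len(meridians), function(j) idx(rings, j),
                          integer(1)))
}

## Full closed triangle list: mesh triangles plus the basal cap fan to an
## appended centroid vertex (index k+1). The cap winding is chosen so the
## closed mesh is consistently oriented (each directed edge used once),
## i.e. opposite to the wall's basal edges.
.closedTriangles <- function(mesh, k) {
  tris <- mesh@triangles
  ring <- mesh@capRing
  if (length(ring)) {
    m <- length(ring)
    capIdx <- k + 1L
    wallDirected <- paste(tris[, c(1L, 2L, 3L)],
                          tris[, c(2L, 3L, 1L)])
    ringFwd <- paste(ring, ring[c(2:m, 1L)])
    cap <- if (any(ringFwd %in% wallDirected))
      cbind(capIdx, ring[c(2:m, 1L)], ring)
    else cbind(capIdx, ring, ring[c(2:m, 1L)])
    tris <- rbind(tris, cap)
  }
  tris
}

.checkClosedMesh <- function(tris) {
  e <- rbind(tris[, c(1L, 2L)], tris[, c(2L, 3L)], tris[, c(3L, 1L)])
  keys <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(keys)
  if (any(cnt != 2L))
    stop("mesh is not closed: some edges are not shared by exactly 2 triangles",
         call. = FALSE)
  ## orientability: each undirected edge must appear once per direction
  dirKeys <- paste(e[, 1L], e[, 2L])
  if (anyDuplicated(dirKeys))
    stop("mesh is not consistently oriented", call. = FALSE)
  invisible(TRUE)
}

#' Cavity volume enclosed by a triangulated surface
#'
#' Signed volume by the divergence theorem: the sum of signed tetrahedron
#' volumes from the origin over all triangles of the closed surface (the
#' open base is capped with a fan to the basal-ring centroid first).
#' Positive for outward-oriented triangles, and invariant under rotation and
#' translation of the configuration. Coordinates are millimetres; the result
#' is millilitres.
#'
#' @param config k x 3 landmark matrix (mm).
#' @param mesh an [LVMesh] over the configuration's landmarks.
#' @return Volume in ml.
#' @export
cavityVolume <- function(config, mesh) {
  .checkConfig(config)
  if (ncol(config) != 3L)
    stop("cavity volumes require 3-D configurations", call. = FALSE)
  k <- nrow(config)
  if (max(mesh@triangles) > k || (length(mesh@capRing) && max(mesh@capRing) > k))
    stop("mesh indices exceed the number of landmarks", call. = FALSE)
  tris <- .closedTriangles(mesh, k)
  .checkClosedMesh(tris)
  verts <- config
  if (length(mesh@capRing))
    verts <- rbind(verts, colMeans(config[mesh@capRing, , drop = FALSE]))
  v1 <- verts[tris[, 1L], , drop = FALSE]
  v2 <- verts[tris[, 2L], , drop = FALSE]
  v3 <- verts[tris[, 3L], , drop = FALSE]
  cross <- cbind(v2[, 2L] * v3[, 3L] - v2[, 3L] * v3[, 2L],
                 v2[, 3L] * v3[, 1L] - v2[, 1L] * v3[, 3L],
                 v2[, 1L] * v3[, 2L] - v2[, 2L] * v3[, 1L])
  sum(rowSums(v1 * cross)) / 6 / 1000
}
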