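#' Tetrahedral claw mesh
#'
#' `tet_mesh()` constructs the package's central geometric container: node
#' coordinates in millimetres (claw local frame: +x proximodistal with distal
#' positive, +z dorsoventral with dorsal positive, +y mediolateral),
#' tetrahedral connectivity, oriented boundary facets, and named anatomical
#' region sets ("articular", "ventral", "tip").
#'
#' Invariants enforced on construction:
#' * every tetrahedron has strictly positive signed volume under the stored
#'   node ordering (degenerate tets are an error, not repaired);
#' * boundary facets exactly tile the topological boundary (each triangle
#'   belongs to exactly one tet); when `boundary` is `NULL` it is derived
#'   from the tets with outward orientation;
#' * region sets reference only existing nodes/facets.
#'
#' Surface-only meshes (from STL/PLY/OFF) have zero tets and a populated
#' boundary; they support measurement but not finite-element solves.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z (mm).
#' @param tets integer matrix, one row per tetrahedron, four 1-based node
#'   indices.
#' @param boundary integer matrix of outward-oriented boundary triangles
#'   (1-based node indices), or `NULL` to derive from `tets`.
#' @param regions list with optional elements `nodes` (named list of node
#'   index vectors) and `facets` (named list of row indices into `boundary`).
#' @param node_params optional data frame of per-node parametric coordinates
#'   (columns such as `u` along the claw axis), carried by generated meshes.
#' @param provenance free-text origin of the mesh.
#'
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets = NULL, boundary = NULL, regions = list(),
                     node_params = NULL, provenance = "unknown") {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("`nodes` must have three columns (x, y, z)")
  if (is.null(tets)) tets <- matrix(integer(), 0L, 4L)
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(tets) != 4L && nrow(tets) > 0L) stop("`tets` must have four columns")
  n_nodes <- nrow(nodes)
  if (nrow(tets) > 0L) {
    if (min(tets) < 1L || max(tets) > n_nodes)
      stop("tet connectivity references nodes outside 1..", n_nodes)
    v <- tet_volumes(nodes, tets)
    bad <- which(v <= 0)
    if (length(bad) > 0L)
      stop("mesh contains ", length(bad),
           " non-positively oriented (degenerate or inverted) tets; ",
           "first offender is tet ", bad[1L])
  }
  if (is.null(boundary)) {
    boundary <- derive_boundary(tets)
  } else {
    boundary <- as.matrix(boundary)
    storage.mode(boundary) <- "integer"
    if (nrow(boundary) > 0L && (min(boundary) < 1L || max(boundary) > n_nodes))
      stop("boundary facets reference nodes outside 1..", n_nodes)
  }
  regions <- validate_regions(regions, n_nodes, nrow(boundary))
  structure(
    list(nodes = nodes, tets = tets, boundary = boundary,
         regions = regions, node_params = node_params,
         provenance = provenance),
    class = "tet_mesh")
}

validate_regions <- function(regions, n_nodes, n_facets) {
  if (is.null(regions)) regions <- list()
  regions$nodes <- lapply(regions$nodes %||% list(), function(idx) {
    idx <- as.integer(idx)
    if (length(idx) && (min(idx) < 1L || max(idx) > n_nodes))
      stop("node region set references missing nodes")
    sort(unique(idx))
  })
  regions$facets <- lapply(regions$facets %||% list(), function(idx) {
    idx <- as.integer(idx)
    if (length(idx) && (min(idx) < 1L || max(idx) > n_facets))
      stop("facet region set references missing facets")
    sort(unique(idx))
  })
  regions
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tet_mesh <- function(x, ...) {
  cat("<tet_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tets), " tets, ",
      nrow(x$boundary), " boundary facets\n", sep = "")
  rn <- names(x$regions$nodes); rf <- names(x$regions$facets)
  if (length(rn)) cat("  node sets:  ", paste(rn, collapse = ", "), "\n", sep = "")
  if (length(rf)) cat("  facet sets: ", paste(rf, collapse = ", "), "\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Signed volumes of tetrahedra
#'
#' @param nodes node coordinate matrix.
#' @param tets tet connectivity matrix.
#' @return numeric vector of signed volumes (mm^3), positive for correctly
#'   oriented tets.
#' @keywords internal
tet_volumes <- function(nodes, tets) {
  if (nrow(tets) == 0L) return(numeric())
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE] - a
  c_ <- nodes[tets[, 3L], , drop = FALSE] - a
  d <- nodes[tets[, 4L], , drop = FALSE] - a
  # scalar triple product (b x c) . d / 6, vectorised over rows
  cx <- b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]
  cy <- b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]
  cz <- b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L]
  (cx * d[, 1L] + cy * d[, 2L] + cz * d[, 3L]) / 6
}

# Outward-oriented faces of each tet (a,b,c,d): (a,c,b) (a,b,d) (a,d,c) (b,c,d)
tet_faces <- function(tets) {
  if (nrow(tets) == 0L) return(matrix(integer(), 0L, 3L))
  a <- tets[, 1L]; b <- tets[, 2L]; c_ <- tets[, 3L]; d <- tets[, 4L]
  rbind(cbind(a, c_, b), cbind(a, b, d), cbind(a, d, c_), cbind(b, c_, d))
}

# Boundary = faces appearing in exactly one tet, outward orientation kept.
derive_boundary <- function(tets) {
  faces <- tet_faces(tets)
  if (nrow(faces) == 0L) return(matrix(integer(), 0L, 3L))
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

facet_normals_areas <- function(nodes, facets) {
  a <- nodes[facets[, 1L], , drop = FALSE]
  b <- nodes[facets[, 2L], , drop = FALSE] - a
  c_ <- nodes[facets[, 3L], , drop = FALSE] - a
  nx <- b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]
  ny <- b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]
  nz <- b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L]
  nrm <- cbind(nx, ny, nz)
  area <- sqrt(rowSums(nrm^2)) / 2
  unit <- nrm / pmax(2 * area, .Machine$double.eps)
  list(normal = unit, area = area)
}

#' Total surface area of a mesh boundary
#' @param mesh a [tet_mesh()].
#' @return surface area in mm^2.
#' @export
surface_area <- function(mesh) {
  if (nrow(mesh$boundary) == 0L) return(0)
  sum(facet_normals_areas(mesh$nodes, mesh$boundary)$area)
}

#' Enclosed volume of a closed oriented boundary (divergence theorem)
#' @param mesh a [tet_mesh()].
#' @return volume in mm^3, or `NA` with a warning for an open surface.
#' @export
enclosed_volume <- function(mesh) {
  fac <- mesh$boundary
  if (nrow(fac) == 0L) return(NA_real_)
  if (!is_closed_surface(fac)) {
    warning("boundary surface is not closed; volume unavailable")
    return(NA_real_)
  }
  a <- mesh$nodes[fac[, 1L], , drop = FALSE]
  b <- mesh$nodes[fac[, 2L], , drop = FALSE]
  c_ <- mesh$nodes[fac[, 3L], , drop = FALSE]
  # sum of signed tet volumes to the origin over outward facets
  cx <- b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]
  cy <- b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]
  cz <- b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L]
  sum(a[, 1L] * cx + a[, 2L] * cy + a[, 3L] * cz) / 6
}

# every undirected edge of a closed triangle surface is shared by exactly
# two facets, once in each direction
is_closed_surface <- function(facets) {
  if (nrow(facets) == 0L) return(FALSE)
  e <- rbind(facets[, c(1L, 2L)], facets[, c(2L, 3L)], facets[, c(3L, 1L)])
  fwd <- paste(e[, 1L], e[, 2L])
  rev <- paste(e[, 2L], e[, 1L])
  all(fwd %in% rev) && !anyDuplicated(fwd)
}
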