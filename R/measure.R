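#' Measure a claw mesh
#'
#' Computes the morphometric summary used throughout the total-evidence
#' assessment: claw length L, depth D and width W (mm), their ratios L/W,
#' L/D and D/W, surface area (mm^2) and enclosed volume (mm^3).
#'
#' L, D and W are extents along the principal axes of the node scatter:
#' L is the extent along the first principal axis (the proximodistal claw
#' axis); of the remaining two axes, D is the one whose unit vector has the
#' larger absolute z-component in the claw local frame (the dorsoventral
#' axis), W the other. For curved claws L is therefore a chord-like extent,
#' not an arc length. Volume is computed by the divergence theorem over the
#' oriented boundary facets; for an open surface it is reported `NA` with a
#' warning while the extents and ratios are still returned.
#'
#' @param mesh a [tet_mesh()] (tetrahedral or surface-only).
#' @return a one-row tibble of class `claw_measurements` with columns
#'   `length_mm`, `depth_mm`, `width_mm`, `ratio_LW`, `ratio_LD`,
#'   `ratio_DW`, `surface_area_mm2`, `volume_mm3`.
#' @export
measure_claw <- function(mesh) {
  nodes <- mesh$nodes
  if (nrow(nodes) < 4L) stop("mesh has too few nodes to measure")
  ctr <- colMeans(nodes)
  x <- sweep(nodes, 2L, ctr)
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  axes <- ev$vectors                       # columns, decreasing variance
  proj <- x %*% axes
  ext <- apply(proj, 2L, function(p) diff(range(p)))
  L <- ext[1L]
  # D = remaining axis closest to local +z; ties toward +z
  zc <- abs(axes[3L, 2:3])
  d_idx <- if (zc[1L] >= zc[2L]) 2L else 3L
  w_idx <- if (d_idx == 2L) 3L else 2L
  D <- ext[d_idx]; W <- ext[w_idx]
  area <- surface_area(mesh)
  vol <- if (nrow(mesh$boundary)) suppressWarnings(enclosed_volume(mesh)) else NA_real_
  if (is.na(vol)) warning("open or missing boundary surface; volume unavailable")
  out <- tibble::tibble(
    length_mm = L, depth_mm = D, width_mm = W,
    ratio_LW = L / W, ratio_LD = L / D, ratio_DW = D / W,
    surface_area_mm2 = area, volume_mm3 = vol)
  class(out) <- c("claw_measurements", class(out))
  out
}

#' Scale a mesh uniformly to a target surface area
#'
#' Standardises specimens for comparison: applies the uniform scale factor
#' `s = sqrt(target / current)` about the node centroid, so the post-scale
#' surface area equals the target (volume scales by `s^3`). Idempotent at
#' the target.
#'
#' @param mesh a [tet_mesh()].
#' @param target_area_mm2 target surface area (mm^2, > 0).
#' @return the scaled [tet_mesh()].
#' @export
scale_to_surface_area <- function(mesh, target_area_mm2) {
  if (!is.numeric(target_area_mm2) || target_area_mm2 <= 0)
    stop("`target_area_mm2` must be a positive number")
  cur <- surface_area(mesh)
  if (cur <= 0) stop("mesh has no boundary surface to scale")
  s <- sqrt(target_area_mm2 / cur)
  ctr <- colMeans(mesh$nodes)
  mesh$nodes <- sweep(sweep(mesh$nodes, 2L, ctr) * s, 2L, ctr, `+`)
  mesh
}
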