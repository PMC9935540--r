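#' Structured tetrahedral bar mesh
#'
#' A rectangular bar meshed as an nx x ny x nz hexahedral lattice, each hex
#' split into six positively oriented tets sharing the main diagonal (a
#' conforming template: shared hex faces receive matching triangle
#' diagonals). Used for solver verification against closed-form beam and
#' patch-test solutions.
#'
#' The bar spans `[0, length]` x `[-width/2, width/2]` x
#' `[-depth/2, depth/2]` so bending about y is symmetric in z.
#'
#' @param length_mm,width_mm,depth_mm bar dimensions along x, y, z (mm).
#' @param nx,ny,nz hex subdivisions along x, y, z.
#' @return a [tet_mesh()] with node sets `root` (x = 0 face), `far`
#'   (x = length face) and a matching facet set `far`.
#' @export
generate_bar_mesh <- function(length_mm, width_mm, depth_mm, nx, ny, nz) {
  stopifnot(length_mm > 0, width_mm > 0, depth_mm > 0,
            nx >= 1, ny >= 1, nz >= 1)
  xs <- seq(0, length_mm, length.out = nx + 1L)
  ys <- seq(-width_mm / 2, width_mm / 2, length.out = ny + 1L)
  zs <- seq(-depth_mm / 2, depth_mm / 2, length.out = nz + 1L)
  nid <- function(i, j, k) ((k - 1L) * (ny + 1L) + (j - 1L)) * (nx + 1L) + i
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL

  hexes <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  v <- cbind(
    nid(hexes$i,      hexes$j,      hexes$k),       # local 0
    nid(hexes$i + 1L, hexes$j,      hexes$k),       # 1
    nid(hexes$i + 1L, hexes$j + 1L, hexes$k),       # 2
    nid(hexes$i,      hexes$j + 1L, hexes$k),       # 3
    nid(hexes$i,      hexes$j,      hexes$k + 1L),  # 4
    nid(hexes$i + 1L, hexes$j,      hexes$k + 1L),  # 5
    nid(hexes$i + 1L, hexes$j + 1L, hexes$k + 1L),  # 6
    nid(hexes$i,      hexes$j + 1L, hexes$k + 1L))  # 7
  tets <- hex_to_tets(v)

  mesh <- tet_mesh(nodes, tets, provenance = "generate_bar_mesh")
  root <- which(nodes[, 1L] <= 0 + 1e-12)
  far <- which(nodes[, 1L] >= length_mm - 1e-9 * length_mm)
  far_fac <- which(apply(matrix(mesh$boundary %in% far,
                                nrow(mesh$boundary)), 1L, all))
  mesh$regions <- validate_regions(
    list(nodes = list(root = root, far = far),
         facets = list(far = far_fac)),
    nrow(nodes), nrow(mesh$boundary))
  mesh
}

# six-tet split of hex rows (columns = local vertices 0..7), all tets share
# the 0-6 diagonal; positive orientation for a right-handed hex
hex_to_tets <- function(v) {
  rbind(
    v[, c(1L, 2L, 3L, 7L), drop = FALSE],
    v[, c(1L, 3L, 4L, 7L), drop = FALSE],
    v[, c(1L, 4L, 8L, 7L), drop = FALSE],
    v[, c(1L, 8L, 5L, 7L), drop = FALSE],
    v[, c(1L, 5L, 6L, 7L), drop = FALSE],
    v[, c(1L, 6L, 2L, 7L), drop = FALSE])
}

#' Consistent nodal forces for a uniform traction on a facet set
#'
#' Distributes a total force as a uniform traction over the given boundary
#' facets: each facet carries force proportional to its area, split equally
#' among its three nodes, all along `direction`.
#'
#' @param mesh a [tet_mesh()].
#' @param facet_rows row indices into `mesh$boundary`.
#' @param total_force_n total force magnitude (N).
#' @param direction length-3 force direction (normalised internally).
#' @return n x 3 nodal force matrix.
#' @export
traction_loads <- function(mesh, facet_rows, total_force_n, direction) {
  direction <- direction / sqrt(sum(direction^2))
  fac <- mesh$boundary[facet_rows, , drop = FALSE]
  na <- facet_normals_areas(mesh$nodes, fac)
  per_facet <- total_force_n * na$area / sum(na$area)
  forces <- matrix(0, nrow(mesh$nodes), 3L)
  for (corner in 1:3) {
    idx <- fac[, corner]
    w <- per_facet / 3
    for (d in 1:3) {
      add <- rowsum(w * direction[d], idx)
      forces[as.integer(rownames(add)), d] <-
        forces[as.integer(rownames(add)), d] + add[, 1L]
    }
  }
  forces
}
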