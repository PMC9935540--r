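# fixtures are built in code: tiny text meshes, a unit icosphere, and a
# reference claw-ratio table emulating a broad comparative sample

single_tet_inp <- function(path = tempfile(fileext = ".inp")) {
  writeLines(c(
    "*NODE",
    "1, 0, 0, 0",
    "2, 1, 0, 0",
    "3, 0, 1, 0",
    "4, 0, 0, 1",
    "*ELEMENT, TYPE=C3D4",
    "1, 1, 2, 3, 4",
    "*NSET, NSET=ARTICULAR",
    "1, 2, 3"), path)
  path
}

unit_cube_stl <- function(path = tempfile(fileext = ".stl")) {
  # 12 outward-oriented facets of the unit cube
  v <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
             c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  quads <- list(c(1,4,3,2),     # z = 0, outward -z
                c(5,6,7,8),     # z = 1
                c(1,2,6,5),     # y = 0
                c(3,4,8,7),     # y = 1
                c(2,3,7,6),     # x = 1
                c(1,5,8,4))     # x = 0
  lines <- "solid cube"
  for (q in quads) for (tri in list(q[c(1,2,3)], q[c(1,3,4)])) {
    a <- v[tri[1],]; b <- v[tri[2],]; c_ <- v[tri[3],]
    n <- c((b-a)[2]*(c_-a)[3]-(b-a)[3]*(c_-a)[2],
           (b-a)[3]*(c_-a)[1]-(b-a)[1]*(c_-a)[3],
           (b-a)[1]*(c_-a)[2]-(b-a)[2]*(c_-a)[1])
    n <- n / sqrt(sum(n^2))
    lines <- c(lines,
               sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
               "    outer loop",
               sprintf("      vertex %g %g %g", v[tri, 1], v[tri, 2], v[tri, 3]),
               "    endloop", "  endfacet")
  }
  writeLines(c(lines, "endsolid cube"), path)
  path
}

# axis-aligned box as a solid tet mesh centred so extents are exact
box_mesh <- function(lx, ly, lz, n = 2L) {
  generate_bar_mesh(lx, ly, lz, n, n, n)
}

# geodesic sphere: subdivided icosahedron projected onto radius r
icosphere <- function(r = 5, subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1,12,6), c(1,6,2), c(1,2,8), c(1,8,11), c(1,11,12),
    c(2,6,10), c(6,12,5), c(12,11,3), c(11,8,7), c(8,2,9),
    c(4,10,5), c(4,5,3), c(4,3,7), c(4,7,9), c(4,9,10),
    c(5,10,6), c(3,5,12), c(7,3,11), c(9,7,8), c(10,9,2))
  for (s in seq_len(subdivisions)) {
    mids <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mids[[key]]
      if (is.null(id)) {
        m <- (v[i, ] + v[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        id <- nrow(v)
        mids[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, 0L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  tet_mesh(v * r, NULL, boundary = f, provenance = "icosphere")
}

# synthetic reference claw-ratio table spanning claw morphologies from
# broad flat claws to narrow sickle-shaped ones
reference_ratio_table <- function(n = 20, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    specimen_id = sprintf("ref%02d", seq_len(n)),
    ratio_LW = exp(stats::runif(n, log(1.5), log(8))),
    ratio_LD = exp(stats::runif(n, log(1.2), log(4))),
    ratio_DW = exp(stats::runif(n, log(0.8), log(3))))
}

rotation_matrix <- function(axis = c(1, 2, 1), angle = 0.7) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  ca * diag(3) + sa * rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]),
                            c(-a[2], a[1], 0)) +
    (1 - ca) * outer(a, a)
}

rotate_mesh <- function(mesh, R) {
  mesh$nodes <- mesh$nodes %*% t(R)
  mesh
}

small_claw <- function(seed = 1L, arc = 60, dw = 2) {
  generate_claw_mesh(claw_params(
    arc_deg = arc, base_depth_mm = 10 * dw, base_width_mm = 10,
    axial_segments = 8, circumferential_segments = 8,
    radial_segments = 1L, seed = seed))
}

# interval vector with hand-set attributes, for ordination tests
fake_interval_vector <- function(pct, edges, id, scenario = "piercing",
                                 mean_stress = sum(pct * seq_along(pct))) {
  n <- length(pct)
  v <- tibble::tibble(interval = seq_len(n), lower_mpa = edges[-(n + 1)],
                      upper_mpa = edges[-1], pct = pct)
  attr(v, "edges") <- edges
  attr(v, "specimen_id") <- id
  attr(v, "scenario") <- scenario
  attr(v, "trimmed_volume_pct") <- 100 - sum(pct)
  attr(v, "mean_stress_mpa") <- mean_stress
  class(v) <- c("interval_vector", class(v))
  v
}
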