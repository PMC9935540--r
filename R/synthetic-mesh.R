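#' Parameters of a synthetic claw mesh
#'
#' The generator sweeps an elliptical cross-section along a circular-arc
#' centerline that curves ventrally (tip down), tapering to a point at the
#' tip. It stands in for CT-derived ungual meshes in tests and benchmarks.
#'
#' Defaults describe a robust, moderately curved digging-type ungual
#' (deep relative to length, as in alvarezsauroid claws): 50 mm long,
#' 20 mm deep and 10 mm wide at the base (D/W = 2), arced through 60
#' degrees.
#'
#' @param length_mm centerline arc length (mm).
#' @param arc_deg total centerline arc in degrees, in \[0, 180); 0 gives a
#'   straight claw. The arc radius is `length_mm / arc` (radians) and is
#'   reported by the generator, not supplied.
#' @param base_depth_mm,base_width_mm dorsoventral and mediolateral
#'   diameters of the elliptical base cross-section (mm).
#' @param taper_exponent radius scale along the axis is
#'   `(1 - u)^taper_exponent`; 1 is a straight-sided cone.
#' @param axial_segments,circumferential_segments,radial_segments mesh
#'   resolution (axial >= 4, circumferential >= 4, radial >= 1).
#' @param noise_amplitude_mm standard deviation of seeded radial surface
#'   noise (mm); 0 (default) gives a deterministic smooth claw.
#' @param seed integer seed for the noise.
#' @return a validated `claw_params` list.
#' @export
claw_params <- function(length_mm = 50, arc_deg = 60,
                        base_depth_mm = 20, base_width_mm = 10,
                        taper_exponent = 1.2,
                        axial_segments = 16, circumferential_segments = 12,
                        radial_segments = 2,
                        noise_amplitude_mm = 0, seed = 1L) {
  stopifnot(length_mm > 0, base_depth_mm > 0, base_width_mm > 0,
            taper_exponent > 0, noise_amplitude_mm >= 0)
  if (arc_deg < 0 || arc_deg >= 180)
    stop("`arc_deg` must lie in [0, 180)")
  if (axial_segments < 4 || circumferential_segments < 4)
    stop("axial and circumferential segments must both be >= 4")
  if (radial_segments < 1) stop("`radial_segments` must be >= 1")
  structure(list(
    length_mm = length_mm, arc_deg = arc_deg,
    base_depth_mm = base_depth_mm, base_width_mm = base_width_mm,
    taper_exponent = taper_exponent,
    axial_segments = as.integer(axial_segments),
    circumferential_segments = as.integer(circumferential_segments),
    radial_segments = as.integer(radial_segments),
    noise_amplitude_mm = noise_amplitude_mm, seed = as.integer(seed)),
    class = "claw_params")
}

#' Generate a parametric tetrahedral claw mesh
#'
#' Builds the swept, tapered claw described by [claw_params()]: disk
#' cross-sections (a centre node plus concentric polygon rings) are swept
#' along the arc, the resulting prismatic and hexahedral lattice cells are
#' tetrahedralised through shared face-centre and cell-centre nodes (which
#' makes the mesh watertight by construction for any cell shape, including
#' the collapsed apex slab), and anatomical regions are labelled from the
#' parametric coordinates: `articular` is the proximal cap (u = 0),
#' `ventral` the boundary facets on the concave (local -z) side, `tip`
#' everything with u >= 0.95.
#'
#' Ring vertices are placed at an area-preserving radius (the inscribed
#' polygon has exactly the ellipse's area), so discretised volumes agree
#' closely with closed forms for straight claws.
#'
#' @param params a [claw_params()].
#' @return a [tet_mesh()] with `node_params` columns `u` (axial parametric
#'   coordinate) and `d_loc` (normalised local dorsoventral coordinate).
#' @export
generate_claw_mesh <- function(params) {
  stopifnot(inherits(params, "claw_params"))
  L <- params$length_mm
  phi_tot <- params$arc_deg * pi / 180
  na_ <- params$axial_segments
  nc <- params$circumferential_segments
  nr <- params$radial_segments
  p <- params$taper_exponent
  if (phi_tot > 0) {
    R <- L / phi_tot
    if (params$base_depth_mm / 2 >= R)
      stop("arc too tight: base depth/2 (", params$base_depth_mm / 2,
           " mm) must be below the centerline arc radius (",
           signif(R, 6), " mm)")
  } else R <- Inf

  centerline <- function(u) {
    if (phi_tot == 0) return(cbind(L * u, 0, 0))
    phi <- u * phi_tot
    cbind(R * sin(phi), 0, R * (cos(phi) - 1))
  }
  dorsal_dir <- function(u) {
    if (phi_tot == 0) return(cbind(0, 0, 1))
    phi <- u * phi_tot
    cbind(sin(phi), 0, cos(phi))
  }
  kappa <- sqrt(2 * pi / (nc * sin(2 * pi / nc)))  # area-preserving radius

  # --- lay down section nodes -------------------------------------------
  n_max <- (na_) * (1L + nr * nc) + 1L + 4096L
  coords <- matrix(NA_real_, n_max * 4L, 3L)
  uu <- dd <- numeric(n_max * 4L)
  n_nodes <- 0L
  new_node <- function(xyz, u, d) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > nrow(coords)) {
      coords <<- rbind(coords, matrix(NA_real_, nrow(coords), 3L))
      uu <<- c(uu, numeric(length(uu))); dd <<- c(dd, numeric(length(dd)))
    }
    coords[n_nodes, ] <<- xyz; uu[n_nodes] <<- u; dd[n_nodes] <<- d
    n_nodes
  }

  set.seed(params$seed)
  theta <- 2 * pi * (seq_len(nc) - 1L) / nc
  centers <- integer(na_)           # sections 0 .. na_-1  (u < 1)
  rings <- vector("list", na_)      # [[i]][r, j]
  for (i in seq_len(na_)) {
    u <- (i - 1L) / na_
    taper <- (1 - u)^p
    cl <- centerline(u)[1L, ]
    dhat <- dorsal_dir(u)[1L, ]
    what <- c(0, 1, 0)
    aw <- params$base_width_mm / 2 * taper * kappa
    ad <- params$base_depth_mm / 2 * taper * kappa
    centers[i] <- new_node(cl, u, 0)
    ring <- matrix(0L, nr, nc)
    for (r in seq_len(nr)) {
      rho <- r / nr
      for (j in seq_len(nc)) {
        w_off <- aw * rho * cos(theta[j])
        d_off <- ad * rho * sin(theta[j])
        if (params$noise_amplitude_mm > 0) {
          # radial noise expressed at the claw base so the absolute
          # perturbation tapers with the cross-section (keeps the tip
          # region from folding at high taper exponents)
          nz <- stats::rnorm(1L, 0, params$noise_amplitude_mm)
          base_semi <- (params$base_width_mm + params$base_depth_mm) / 4
          scl <- max(1 + nz / max(base_semi * rho, 1e-9), 0.2)
          w_off <- w_off * scl; d_off <- d_off * scl
        }
        ring[r, j] <- new_node(cl + w_off * what + d_off * dhat,
                               u, rho * sin(theta[j]))
      }
    }
    rings[[i]] <- ring
  }
  apex <- new_node(centerline(1)[1L, ], 1, 0)

  # --- tetrahedralise lattice cells -------------------------------------
  tets <- matrix(0L, 64L * na_ * nc * nr, 4L)
  n_tets <- 0L
  add_tet <- function(a, b, c_, d) {
    n_tets <<- n_tets + 1L
    if (n_tets > nrow(tets)) tets <<- rbind(tets, tets * 0L)
    tets[n_tets, ] <<- c(a, b, c_, d)
  }
  face_centers <- new.env(hash = TRUE, parent = emptyenv())
  face_center <- function(face) {
    key <- paste(sort(face), collapse = "-")
    id <- face_centers[[key]]
    if (is.null(id)) {
      id <- new_node(colMeans(coords[face, , drop = FALSE]),
                     mean(uu[face]), mean(dd[face]))
      face_centers[[key]] <- id
    }
    id
  }
  signed6 <- function(a, b, c_, d) {
    u1 <- coords[b, ] - coords[a, ]; u2 <- coords[c_, ] - coords[a, ]
    u3 <- coords[d, ] - coords[a, ]
    (u1[2] * u2[3] - u1[3] * u2[2]) * u3[1] +
      (u1[3] * u2[1] - u1[1] * u2[3]) * u3[2] +
      (u1[1] * u2[2] - u1[2] * u2[1]) * u3[3]
  }
  emit_tet <- function(a, b, c_, d) {
    s <- signed6(a, b, c_, d)
    if (abs(s) < 1e-12) stop("degenerate cell produced; refine parameters")
    if (s > 0) add_tet(a, b, c_, d) else add_tet(a, c_, b, d)
  }
  add_cell <- function(faces) {
    verts <- unique(unlist(faces))
    if (length(verts) == 4L) {          # already a tet
      emit_tet(verts[1L], verts[2L], verts[3L], verts[4L])
      return(invisible())
    }
    ctr <- new_node(colMeans(coords[verts, , drop = FALSE]),
                    mean(uu[verts]), mean(dd[verts]))
    for (f in faces) {
      if (length(f) == 3L) {
        emit_tet(f[1L], f[2L], f[3L], ctr)
      } else {
        fc <- face_center(f)
        for (k in seq_len(4L)) {
          k2 <- if (k == 4L) 1L else k + 1L
          emit_tet(f[k], f[k2], fc, ctr)
        }
      }
    }
  }

  for (i in seq_len(na_)) {
    lastslab <- i == na_
    c0 <- centers[i]; r0 <- rings[[i]]
    if (!lastslab) { c1 <- centers[i + 1L]; r1 <- rings[[i + 1L]] }
    for (j in seq_len(nc)) {
      j2 <- if (j == nc) 1L else j + 1L
      if (lastslab) {
        # collapse onto the apex: inner triangle -> tet, ring quads -> pyramids
        add_cell(list(c(c0, r0[1L, j], r0[1L, j2], apex)))
        if (nr > 1L) for (r in seq_len(nr - 1L)) {
          q <- c(r0[r, j], r0[r + 1L, j], r0[r + 1L, j2], r0[r, j2])
          add_cell(list(q, c(q[1L], q[2L], apex), c(q[2L], q[3L], apex),
                        c(q[3L], q[4L], apex), c(q[4L], q[1L], apex)))
        }
      } else {
        # wedge prism between the inner triangles
        t0 <- c(c0, r0[1L, j], r0[1L, j2])
        t1 <- c(c1, r1[1L, j], r1[1L, j2])
        add_cell(list(t0, t1,
                      c(t0[1L], t0[2L], t1[2L], t1[1L]),
                      c(t0[2L], t0[3L], t1[3L], t1[2L]),
                      c(t0[3L], t0[1L], t1[1L], t1[3L])))
        if (nr > 1L) for (r in seq_len(nr - 1L)) {
          q0 <- c(r0[r, j], r0[r + 1L, j], r0[r + 1L, j2], r0[r, j2])
          q1 <- c(r1[r, j], r1[r + 1L, j], r1[r + 1L, j2], r1[r, j2])
          add_cell(list(q0, q1,
                        c(q0[1L], q0[2L], q1[2L], q1[1L]),
                        c(q0[2L], q0[3L], q1[3L], q1[2L]),
                        c(q0[3L], q0[4L], q1[4L], q1[3L]),
                        c(q0[4L], q0[1L], q1[1L], q1[4L])))
        }
      }
    }
  }

  nodes <- coords[seq_len(n_nodes), , drop = FALSE]
  tets <- tets[seq_len(n_tets), , drop = FALSE]
  uu <- uu[seq_len(n_nodes)]; dd <- dd[seq_len(n_nodes)]
  boundary_check <- derive_boundary(tets)
  if (!is_closed_surface(boundary_check))
    stop("generation error: parameters produce a self-intersecting or ",
         "folded mesh (arc too tight, taper too sharp, or noise too large)")
  mesh <- tet_mesh(nodes, tets,
                   node_params = data.frame(u = uu, d_loc = dd),
                   provenance = sprintf(
                     "generate_claw_mesh(L=%g, arc=%g, D=%g, W=%g, taper=%g, seed=%d)",
                     L, params$arc_deg, params$base_depth_mm,
                     params$base_width_mm, p, params$seed))
  mesh$regions <- claw_regions(mesh)
  attr(mesh, "claw_params") <- params
  attr(mesh, "arc_radius_mm") <- R
  mesh
}

# label articular / ventral / tip regions from parametric node coordinates
claw_regions <- function(mesh, tip_u = 0.95) {
  u <- mesh$node_params$u; d <- mesh$node_params$d_loc
  fac <- mesh$boundary
  fu <- pmax(u[fac[, 1L]], u[fac[, 2L]], u[fac[, 3L]])
  fd <- (d[fac[, 1L]] + d[fac[, 2L]] + d[fac[, 3L]]) / 3
  art_fac <- which(u[fac[, 1L]] < 1e-9 & u[fac[, 2L]] < 1e-9 &
                     u[fac[, 3L]] < 1e-9)
  validate_regions(list(
    nodes = list(articular = which(u < 1e-9),
                 tip = which(u >= tip_u)),
    facets = list(articular = art_fac,
                  ventral = setdiff(which(fd < 0), art_fac),
                  tip = which(fu >= tip_u))),
    nrow(mesh$nodes), nrow(fac))
}
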