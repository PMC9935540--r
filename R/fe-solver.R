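#' Material specification for the linear-elastic solver
#'
#' Elastic, isotropic, homogeneous bone. The default values (E = 20.49 GPa,
#' nu = 0.40) are the standard properties used for theropod ungual bone in
#' comparative FE work. Units are mm / N / MPa throughout the package, so
#' the modulus is converted from GPa to MPa (x1000) internally.
#'
#' @param youngs_modulus_gpa Young's modulus in GPa (> 0).
#' @param poisson_ratio Poisson's ratio in [0, 0.5).
#' @return a `material_spec` list with `E_mpa` and `nu`.
#' @export
material_spec <- function(youngs_modulus_gpa = 20.49, poisson_ratio = 0.40) {
  if (youngs_modulus_gpa <= 0) stop("Young's modulus must be positive")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("Poisson's ratio must lie in [0, 0.5)")
  structure(list(E_mpa = youngs_modulus_gpa * 1000,
                 youngs_modulus_gpa = youngs_modulus_gpa,
                 nu = poisson_ratio),
            class = "material_spec")
}

# 6x6 isotropic elasticity matrix, Voigt order (xx,yy,zz,xy,yz,zx),
# engineering shear strain
elasticity_matrix <- function(material) {
  E <- material$E_mpa; nu <- material$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# Shape-function gradients of all tets, vectorised.
# Returns list g1..g4, each an m x 3 matrix, plus volumes.
tet_gradients <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  r1 <- nodes[tets[, 2L], , drop = FALSE] - a
  r2 <- nodes[tets[, 3L], , drop = FALSE] - a
  r3 <- nodes[tets[, 4L], , drop = FALSE] - a
  cross3 <- function(u, v) cbind(
    u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
    u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
    u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  c23 <- cross3(r2, r3)
  det6 <- rowSums(r1 * c23)               # 6 * volume
  g2 <- c23 / det6
  g3 <- cross3(r3, r1) / det6
  g4 <- cross3(r1, r2) / det6
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), volume = det6 / 6)
}

# Sparse strain operator S (6q x 3n) plus quadrature weights w (q), such
# that K = t(S) %*% (D (x) diag(w)) %*% S. Dof ordering is stacked:
# (ux_1..ux_n, uy_1..uy_n, uz_1..uz_n); strain rows are stacked the same
# way per Voigt component.
#
# formulation "cst": one strain sample per element (classical constant-
# strain tets). "smoothed": one strain sample per node, the volume-weighted
# average of adjacent element strains (node-based smoothed FEM); linear
# 4-node tets throughout, but far better bending accuracy at coarse
# resolutions.
strain_operator <- function(mesh, formulation = c("smoothed", "cst")) {
  formulation <- match.arg(formulation)
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  gr <- tet_gradients(mesh$nodes, mesh$tets)
  g <- gr$g; V <- gr$volume

  if (formulation == "cst") {
    ii <- rep(seq_len(m), 4L)
    jj <- as.vector(mesh$tets)
    gx <- c(g[[1L]][, 1L], g[[2L]][, 1L], g[[3L]][, 1L], g[[4L]][, 1L])
    gy <- c(g[[1L]][, 2L], g[[2L]][, 2L], g[[3L]][, 2L], g[[4L]][, 2L])
    gz <- c(g[[1L]][, 3L], g[[2L]][, 3L], g[[3L]][, 3L], g[[4L]][, 3L])
    q <- m
    w <- V
  } else {
    Vn <- as.numeric(rowsum(rep(V / 4, 4L), as.vector(mesh$tets),
                            reorder = TRUE))
    if (length(Vn) != n || any(Vn <= 0))
      stop("smoothed formulation requires every node to belong to a tet")
    ii <- jj <- integer(16L * m)
    gx <- gy <- gz <- numeric(16L * m)
    pos <- 0L
    for (cn in 1:4) {
      nn <- mesh$tets[, cn]
      wgt <- (V / 4) / Vn[nn]
      for (cj in 1:4) {
        idx <- pos + seq_len(m)
        ii[idx] <- nn
        jj[idx] <- mesh$tets[, cj]
        gx[idx] <- wgt * g[[cj]][, 1L]
        gy[idx] <- wgt * g[[cj]][, 2L]
        gz[idx] <- wgt * g[[cj]][, 3L]
        pos <- pos + m
      }
    }
    q <- n
    w <- Vn
  }
  Gx <- Matrix::sparseMatrix(i = ii, j = jj, x = gx, dims = c(q, n))
  Gy <- Matrix::sparseMatrix(i = ii, j = jj, x = gy, dims = c(q, n))
  Gz <- Matrix::sparseMatrix(i = ii, j = jj, x = gz, dims = c(q, n))
  Z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(q, n))
  S <- rbind(cbind(Gx, Z, Z), cbind(Z, Gy, Z), cbind(Z, Z, Gz),
             cbind(Gy, Gx, Z), cbind(Z, Gz, Gy), cbind(Gz, Z, Gx))
  list(S = S, w = w, q = q, element_volume = V, gradients = g)
}

#' Solve the linear elastic problem on a tetrahedral mesh
#'
#' Small-strain linear elasticity on 4-node tetrahedra. The default
#' `"smoothed"` formulation uses node-based strain smoothing (strains
#' averaged over nodal volumes before integration), which passes the
#' uniform-strain patch test exactly and removes most of the bending
#' over-stiffness of plain constant-strain tets at coarse resolutions; the
#' classical `"cst"` formulation is available for comparison. The global
#' stiffness matrix is assembled sparsely and factorised with a sparse
#' Cholesky decomposition; element stresses follow from isotropic Hooke's
#' law, with the von Mises scalar
#' `vm = sqrt(((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2) / 2)` in terms of
#' principal stresses.
#'
#' @param mesh a [tet_mesh()] with at least one tet.
#' @param material a [material_spec()].
#' @param loads nodal force matrix (n_nodes x 3, N), e.g. the output of
#'   [assign_scenario_loads()] (which may be passed directly as a list).
#' @param fixed_nodes integer node indices fixed in all translations;
#'   taken from `loads$fixed_nodes` when `loads` is a scenario load set.
#' @param fixed_dofs optional two-column matrix (node index, direction 1-3)
#'   of single constrained translations, for roller supports in
#'   verification problems. Claw scenarios only use `fixed_nodes`.
#' @param formulation `"smoothed"` (default) or `"cst"`.
#' @param scenario,specimen_id metadata attached to the result.
#'
#' @return a [stress_field()] with one row per tet. Attributes:
#'   `displacements` (n x 3 nodal displacements, mm), `tensors` (m x 6
#'   element stress in Voigt order xx,yy,zz,xy,yz,zx, MPa),
#'   `nodal_tensors` (n x 6 nodal stress), `centroids` (m x 3 element
#'   centroids, mm).
#' @export
solve_linear_elastic <- function(mesh, material, loads, fixed_nodes = NULL,
                                 fixed_dofs = NULL,
                                 formulation = c("smoothed", "cst"),
                                 scenario = NA_character_,
                                 specimen_id = NA_character_) {
  formulation <- match.arg(formulation)
  if (nrow(mesh$tets) == 0L) stop("mesh has no tetrahedra; cannot solve")
  if (is.list(loads) && !is.matrix(loads)) {
    fixed_nodes <- fixed_nodes %||% loads$fixed_nodes
    if (is.na(scenario)) scenario <- loads$scenario %||% NA_character_
    loads <- loads$forces
  }
  if ((is.null(fixed_nodes) || length(fixed_nodes) == 0L) &&
      (is.null(fixed_dofs) || nrow(fixed_dofs) == 0L))
    stop("no fixed nodes: constrain the articular surface before solving")
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  op <- strain_operator(mesh, formulation)
  D <- elasticity_matrix(material)
  WD <- Matrix::kronecker(D, Matrix::Diagonal(x = op$w))
  K <- Matrix::t(op$S) %*% WD %*% op$S

  f <- c(loads[, 1L], loads[, 2L], loads[, 3L])
  fixed <- integer()
  if (length(fixed_nodes)) {
    fn <- as.integer(fixed_nodes)
    fixed <- c(fn, fn + n, fn + 2L * n)
  }
  if (!is.null(fixed_dofs) && nrow(fixed_dofs))
    fixed <- union(fixed, (as.integer(fixed_dofs[, 2L]) - 1L) * n +
                     as.integer(fixed_dofs[, 1L]))
  free <- setdiff(seq_len(3L * n), fixed)
  u <- numeric(3L * n)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  sol <- tryCatch(Matrix::solve(Kff, f[free]),
                  error = function(e) stop(
                    "stiffness system is singular; check that the articular ",
                    "(fixed) node set removes all rigid-body motion: ",
                    conditionMessage(e)))
  u[free] <- as.numeric(sol)
  U <- cbind(u[seq_len(n)], u[n + seq_len(n)], u[2L * n + seq_len(n)])

  strains <- matrix(as.numeric(op$S %*% u), ncol = 6L)
  stresses <- strains %*% D
  if (formulation == "cst") {
    elem_sig <- stresses
    nodal_sig <- nodal_average(mesh, stresses, op$element_volume)
  } else {
    nodal_sig <- stresses
    elem_sig <- (stresses[mesh$tets[, 1L], , drop = FALSE] +
                   stresses[mesh$tets[, 2L], , drop = FALSE] +
                   stresses[mesh$tets[, 3L], , drop = FALSE] +
                   stresses[mesh$tets[, 4L], , drop = FALSE]) / 4
  }
  vm <- vm_from_voigt(elem_sig)
  cent <- (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
             mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
             mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
             mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4

  out <- stress_field(vm, op$element_volume, scenario = scenario,
                      specimen_id = specimen_id)
  attr(out, "displacements") <- U
  attr(out, "tensors") <- elem_sig
  attr(out, "nodal_tensors") <- nodal_sig
  attr(out, "centroids") <- cent
  out
}

vm_from_voigt <- function(sig) {
  sqrt(pmax(0.5 * ((sig[, 1L] - sig[, 2L])^2 + (sig[, 2L] - sig[, 3L])^2 +
                     (sig[, 3L] - sig[, 1L])^2) +
              3 * (sig[, 4L]^2 + sig[, 5L]^2 + sig[, 6L]^2), 0))
}

# volume-weighted average of per-element Voigt tensors onto nodes
nodal_average <- function(mesh, elem_sig, V) {
  n <- nrow(mesh$nodes)
  idx <- as.vector(mesh$tets)
  wv <- rep(V / 4, 4L)
  num <- rowsum(elem_sig[rep(seq_len(nrow(elem_sig)), 4L), , drop = FALSE] * wv,
                idx, reorder = TRUE)
  den <- as.numeric(rowsum(wv, idx, reorder = TRUE))
  out <- matrix(0, n, 6L)
  out[sort(unique(idx)), ] <- num / den
  out
}

#' Von Mises equivalent stress of a symmetric stress tensor
#'
#' Rotation-invariant scalar used as the ductile-failure criterion: zero
#' for hydrostatic states, equal to sigma for uniaxial stress sigma, and
#' sqrt(3) tau for pure shear tau.
#'
#' @param stress 3x3 symmetric stress tensor (MPa).
#' @return non-negative scalar (MPa).
#' @export
von_mises <- function(stress) {
  stress <- as.matrix(stress)
  if (!isTRUE(all.equal(stress, t(stress), tolerance = 1e-8)))
    stop("stress tensor must be symmetric")
  s <- stress - diag(sum(diag(stress)) / 3, 3L)
  sqrt(pmax(1.5 * sum(s * s), 0))
}
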