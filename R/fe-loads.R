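#' Standardized claw load scenario
#'
#' The three canonical ungual functions simulated for every specimen:
#' * `scratch_digging` — total force centred on the ventral surface of the
#'   claw tip (substrate reaction while digging), directed along the inward
#'   (dorsal-pointing) facet normals;
#' * `hook_and_pull` — force spread evenly (per unit area) along the whole
#'   ventral surface (pulling down vegetation), inward normals;
#' * `piercing` — force on the tip nodes directed proximally along the
#'   claw axis (a strike driving the tip into prey).
#'
#' A total force of 200 N is applied in every scenario by default.
#'
#' @param kind `"scratch_digging"`, `"hook_and_pull"` or `"piercing"`.
#' @param total_force_n total applied force magnitude (N, > 0).
#' @param tip_fraction distal fraction of the axial parametric coordinate
#'   treated as "the tip" (default 0.05, i.e. u >= 0.95).
#' @return a `load_scenario` list.
#' @export
load_scenario <- function(kind = c("scratch_digging", "hook_and_pull",
                                   "piercing"),
                          total_force_n = 200, tip_fraction = 0.05) {
  kind <- match.arg(kind)
  if (!is.numeric(total_force_n) || total_force_n <= 0)
    stop("`total_force_n` must be positive")
  if (tip_fraction <= 0 || tip_fraction >= 1)
    stop("`tip_fraction` must lie in (0, 1)")
  structure(list(kind = kind, total_force_n = total_force_n,
                 tip_fraction = tip_fraction),
            class = "load_scenario")
}

#' Build the nodal force set and fixed node set for a load scenario
#'
#' The articular node set is fully fixed (all translations). Forces are
#' assembled so the vector resultant has exactly the scenario's total
#' magnitude: ventral-surface scenarios distribute force over the selected
#' facets proportional to facet area along each facet's inward normal and
#' then rescale to the requested resultant; piercing splits the force
#' equally over the tip nodes along the proximally directed claw-axis
#' tangent.
#'
#' The tip region is resolved from, in order of preference: the nodal
#' parametric coordinate `u` (generated meshes; `u >= 1 - tip_fraction`),
#' the mesh's named `tip` region set, or (with a message) the distal
#' fraction of the extent along the first principal axis.
#'
#' @param mesh a [tet_mesh()] with non-empty `articular` and `ventral`
#'   region sets (and a resolvable tip).
#' @param scenario a [load_scenario()].
#' @return list with `forces` (n x 3 nodal force matrix, N), `fixed_nodes`
#'   (articular node indices) and `scenario` (the kind string).
#' @export
assign_scenario_loads <- function(mesh, scenario) {
  stopifnot(inherits(scenario, "load_scenario"))
  art <- mesh$regions$nodes$articular
  if (is.null(art) || length(art) == 0L)
    stop("configuration error: region set 'articular' is empty or missing")
  n <- nrow(mesh$nodes)
  forces <- matrix(0, n, 3L)

  if (scenario$kind %in% c("scratch_digging", "hook_and_pull")) {
    ven <- mesh$regions$facets$ventral
    if (is.null(ven) || length(ven) == 0L)
      stop("configuration error: region set 'ventral' is empty or missing")
    rows <- if (scenario$kind == "hook_and_pull") ven else {
      tipf <- tip_facets(mesh, scenario$tip_fraction)
      sel <- intersect(ven, tipf)
      if (length(sel) == 0L)
        stop("configuration error: no ventral facets inside the tip region")
      sel
    }
    fac <- mesh$boundary[rows, , drop = FALSE]
    na <- facet_normals_areas(mesh$nodes, fac)
    # per-facet magnitude ~ area, direction = inward (dorsal-pointing) normal
    mag <- scenario$total_force_n * na$area / sum(na$area)
    fvec <- -na$normal * mag
    for (corner in 1:3) {
      add <- rowsum(fvec / 3, fac[, corner], reorder = TRUE)
      ids <- as.integer(rownames(add))
      forces[ids, ] <- forces[ids, ] + add
    }
    res <- sqrt(sum(colSums(forces)^2))
    if (res < 1e-9 * scenario$total_force_n)
      stop("ventral facet normals cancel; cannot normalise the resultant")
    forces <- forces * (scenario$total_force_n / res)
  } else {
    tipn <- tip_nodes(mesh, scenario$tip_fraction)
    if (length(tipn) == 0L)
      stop("configuration error: region set 'tip' is empty or missing")
    tangent <- distal_tangent(mesh, scenario$tip_fraction)
    dir <- -tangent                      # proximally directed
    per_node <- scenario$total_force_n / length(tipn)
    forces[tipn, ] <- matrix(dir * per_node, length(tipn), 3L, byrow = TRUE)
  }
  list(forces = forces, fixed_nodes = art, scenario = scenario$kind)
}

tip_nodes <- function(mesh, tip_fraction = 0.05) {
  u <- mesh$node_params$u
  if (!is.null(u)) return(which(u >= 1 - tip_fraction))
  tn <- mesh$regions$nodes$tip
  if (!is.null(tn) && length(tn)) return(tn)
  message("no parametric coordinates or 'tip' set; using the distal ",
          tip_fraction, " fraction of the principal-axis extent")
  ax <- principal_axis(mesh)
  proj <- mesh$nodes %*% ax
  which(proj >= max(proj) - tip_fraction * diff(range(proj)))
}

tip_facets <- function(mesh, tip_fraction = 0.05) {
  u <- mesh$node_params$u
  if (!is.null(u)) {
    fac <- mesh$boundary
    # a facet belongs to the tip when it reaches into the tip region
    # (max node u), which stays non-empty at coarse axial resolutions
    fu <- pmax(u[fac[, 1L]], u[fac[, 2L]], u[fac[, 3L]])
    return(which(fu >= 1 - tip_fraction))
  }
  tf <- mesh$regions$facets$tip
  if (!is.null(tf) && length(tf)) return(tf)
  tipn <- tip_nodes(mesh, tip_fraction)
  which(rowSums(matrix(mesh$boundary %in% tipn,
                       nrow(mesh$boundary))) == 3L)
}

# distal unit tangent of the claw axis (pointing out of the tip)
distal_tangent <- function(mesh, tip_fraction = 0.05) {
  u <- mesh$node_params$u
  if (!is.null(u)) {
    near <- u >= 1 - 4 * tip_fraction & u < 1 - tip_fraction
    tip <- u >= 1 - tip_fraction
    if (any(near) && any(tip)) {
      t_ <- colMeans(mesh$nodes[tip, , drop = FALSE]) -
        colMeans(mesh$nodes[near, , drop = FALSE])
      return(t_ / sqrt(sum(t_^2)))
    }
  }
  tipn <- tip_nodes(mesh, tip_fraction)
  t_ <- colMeans(mesh$nodes[tipn, , drop = FALSE]) - colMeans(mesh$nodes)
  t_ / sqrt(sum(t_^2))
}

principal_axis <- function(mesh) {
  x <- sweep(mesh$nodes, 2L, colMeans(mesh$nodes))
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  ax <- ev$vectors[, 1L]
  # orient distally (+x-ish) for determinism
  if (ax[1L] < 0) ax <- -ax
  ax
}
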