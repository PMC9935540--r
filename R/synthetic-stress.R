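#' Parameters for simulated stress fields
#'
#' Simulated fields draw per-element von Mises stress i.i.d. from a named
#' distribution family, with element volumes taken from a mesh. Because
#' the distribution parameters are known exactly, these fields provide
#' ground truth for recovery tests of the intervals-method pipeline (the
#' FE solver supplies spatially structured fields when realism is needed
#' instead).
#'
#' For the lognormal family the target volume-weighted mean is
#' `exp(meanlog + sdlog^2 / 2)`; `stress_sim_params()` accepts either
#' `meanlog` or a target `mean_mpa` (converted internally).
#'
#' @param family `"lognormal"`, `"gamma"` or `"constant"`.
#' @param mean_mpa target mean stress (MPa); mutually exclusive with
#'   `meanlog` for the lognormal family. For `"constant"` this is the
#'   constant value; for `"gamma"` the mean `shape * scale`.
#' @param sdlog lognormal log-scale standard deviation (default 0.4).
#' @param shape gamma shape parameter (default 4).
#' @param meanlog lognormal log-scale location (overrides `mean_mpa`).
#' @param seed integer seed.
#' @return a `stress_sim_params` list.
#' @export
stress_sim_params <- function(family = c("lognormal", "gamma", "constant"),
                              mean_mpa = 10, sdlog = 0.4, shape = 4,
                              meanlog = NULL, seed = 1L) {
  family <- match.arg(family)
  if (family == "lognormal") {
    if (sdlog <= 0) stop("`sdlog` must be positive")
    if (is.null(meanlog)) {
      if (mean_mpa <= 0) stop("`mean_mpa` must be positive")
      meanlog <- log(mean_mpa) - sdlog^2 / 2
    }
  } else if (family == "gamma") {
    if (shape <= 0 || mean_mpa <= 0) stop("gamma needs positive shape and mean")
  } else if (mean_mpa < 0) stop("constant stress must be non-negative")
  structure(list(family = family, mean_mpa = mean_mpa, sdlog = sdlog,
                 shape = shape, meanlog = meanlog, seed = as.integer(seed)),
            class = "stress_sim_params")
}

#' Draw a simulated stress field on a mesh
#'
#' @param mesh a [tet_mesh()] with positive-volume tets.
#' @param params a [stress_sim_params()].
#' @param scenario scenario label to attach.
#' @param specimen_id specimen label to attach.
#' @return a [stress_field()] with one element per tet.
#' @export
generate_stress_field <- function(mesh, params,
                                  scenario = NA_character_,
                                  specimen_id = NA_character_) {
  stopifnot(inherits(params, "stress_sim_params"))
  vol <- tet_volumes(mesh$nodes, mesh$tets)
  if (length(vol) == 0L) stop("mesh has no tets; cannot simulate a field")
  m <- length(vol)
  set.seed(params$seed)
  vm <- switch(params$family,
    lognormal = stats::rlnorm(m, params$meanlog, params$sdlog),
    gamma = stats::rgamma(m, shape = params$shape,
                          scale = params$mean_mpa / params$shape),
    constant = rep(params$mean_mpa, m))
  stress_field(vm, vol, scenario = scenario, specimen_id = specimen_id)
}

#' Generate a benchmark cohort with known ground truth
#'
#' Builds `n_specimens` synthetic claws spanning stated depth/width (D/W)
#' and curvature gradients, and for each claw three scenario stress
#' fields whose target mean stresses follow stated rules: a per-specimen
#' base (piercing) stress that increases linearly with the specimen's
#' position along the D/W gradient by `stress_gradient`, multiplied by
#' `dig_multiplier` for scratch-digging and `pull_multiplier` for
#' hook-and-pull. The manifest records all ground truth for recovery
#' tests.
#'
#' @param n_specimens number of claws (>= 3).
#' @param dw_range range of base depth/width ratios spanned (low, high).
#' @param arc_range range of centerline arcs spanned (degrees).
#' @param base_mean_mpa piercing-scenario mean stress of the first
#'   specimen (MPa).
#' @param stress_gradient multiplicative increase of the base stress from
#'   the first to the last specimen (1 = flat).
#' @param dig_multiplier,pull_multiplier scenario mean-stress multipliers
#'   relative to piercing.
#' @param sdlog lognormal spread of the simulated fields.
#' @param mesh_resolution axial segments of the generated meshes
#'   (circumferential and radial resolution scale with it).
#' @param seed master seed; every specimen/scenario derives its own
#'   sub-seed deterministically.
#' @return a `benchmark_cohort` list: `manifest` tibble (ground truth and
#'   measurements per specimen), `meshes` (named list of [tet_mesh()]),
#'   `fields` (named list, one list of three [stress_field()]s per
#'   specimen).
#' @export
make_benchmark_cohort <- function(n_specimens = 12,
                                  dw_range = c(1.2, 3),
                                  arc_range = c(30, 90),
                                  base_mean_mpa = 10,
                                  stress_gradient = 1,
                                  dig_multiplier = 1,
                                  pull_multiplier = 1,
                                  sdlog = 0.4,
                                  mesh_resolution = 10,
                                  seed = 1L) {
  if (n_specimens < 3L) stop("a cohort needs at least 3 specimens")
  g <- if (n_specimens == 1L) 0 else
    (seq_len(n_specimens) - 1) / (n_specimens - 1)
  dw <- dw_range[1L] + g * diff(dw_range)
  arc <- arc_range[1L] + g * diff(arc_range)
  base_mean <- base_mean_mpa * (1 + g * (stress_gradient - 1))
  mult <- c(scratch_digging = dig_multiplier, hook_and_pull = pull_multiplier,
            piercing = 1)
  ids <- sprintf("claw%02d", seq_len(n_specimens))

  meshes <- list(); fields <- list(); rows <- list()
  for (i in seq_len(n_specimens)) {
    cp <- claw_params(length_mm = 50, arc_deg = arc[i],
                      base_depth_mm = 10 * dw[i], base_width_mm = 10,
                      axial_segments = mesh_resolution,
                      circumferential_segments = max(8L, mesh_resolution %/% 2 * 2L),
                      radial_segments = 1L,
                      seed = seed + i)
    mesh <- generate_claw_mesh(cp)
    meshes[[ids[i]]] <- mesh
    meas <- suppressWarnings(measure_claw(mesh))
    sf <- list()
    for (s in names(mult)) {
      sub_seed <- (seed * 1000L + i * 10L +
                     match(s, names(mult))) %% .Machine$integer.max
      sp <- stress_sim_params("lognormal", mean_mpa = base_mean[i] * mult[[s]],
                              sdlog = sdlog, seed = sub_seed)
      sf[[s]] <- generate_stress_field(mesh, sp, scenario = s,
                                       specimen_id = ids[i])
    }
    fields[[ids[i]]] <- sf
    rows[[i]] <- tibble::tibble(
      specimen_id = ids[i], dw_param = dw[i], arc_deg = arc[i],
      true_mean_piercing = base_mean[i],
      true_mean_digging = base_mean[i] * dig_multiplier,
      true_mean_pulling = base_mean[i] * pull_multiplier,
      ratio_LW = meas$ratio_LW, ratio_LD = meas$ratio_LD,
      ratio_DW = meas$ratio_DW,
      surface_area_mm2 = meas$surface_area_mm2,
      volume_mm3 = meas$volume_mm3)
  }
  structure(list(manifest = dplyr::bind_rows(rows), meshes = meshes,
                 fields = fields,
                 params = list(n_specimens = n_specimens, dw_range = dw_range,
                               arc_range = arc_range,
                               base_mean_mpa = base_mean_mpa,
                               stress_gradient = stress_gradient,
                               dig_multiplier = dig_multiplier,
                               pull_multiplier = pull_multiplier,
                               sdlog = sdlog, seed = seed)),
            class = "benchmark_cohort")
}

#' Run the full intervals/FSA pipeline on a benchmark cohort
#'
#' Trims, bins (shared bound), ordinates all 3 x n simulations jointly,
#' builds the per-specimen functional triangles and returns the report
#' joined with the cohort manifest.
#'
#' @param cohort a [make_benchmark_cohort()] result.
#' @param config an [interval_config()].
#' @return list with `space` (the `functional_space`), `triangles`, and
#'   `report` (triangle report joined to the manifest).
#' @export
run_cohort_pipeline <- function(cohort, config = interval_config()) {
  stopifnot(inherits(cohort, "benchmark_cohort"))
  all_fields <- unlist(cohort$fields, recursive = FALSE, use.names = FALSE)
  vecs <- compute_interval_vectors(all_fields, config)
  space <- ordinate(vecs, log_offset = config$log_offset)
  tris <- functional_triangles(space)
  report <- dplyr::left_join(triangle_report(tris), cohort$manifest,
                             by = "specimen_id")
  list(space = space, triangles = tris, report = report)
}

#' Write a benchmark cohort to disk
#'
#' Writes each mesh as an INP file, each stress field as an exchange CSV
#' (see [write_stress_export()]) and the manifest as
#' `manifest.csv`, producing a fully text-based, re-readable cohort
#' directory.
#'
#' @param cohort a [make_benchmark_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$meshes))
    write_mesh(cohort$meshes[[id]], file.path(dir, paste0(id, ".inp")))
  for (id in names(cohort$fields))
    for (s in names(cohort$fields[[id]]))
      write_stress_export(cohort$fields[[id]][[s]],
                          file.path(dir, paste0(id, "_", s, ".csv")))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
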