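test_that("straight cone volume matches the closed form", {
  cp <- claw_params(length_mm = 50, arc_deg = 0, base_depth_mm = 10,
                    base_width_mm = 10, taper_exponent = 1,
                    axial_segments = 32, circumferential_segments = 16)
  mesh <- generate_claw_mesh(cp)
  exact <- pi * 25 * 50 / 3
  expect_lt(abs(enclosed_volume(mesh) - exact) / exact, 0.02)
})

test_that("generation is bit-identical for equal parameters and seed", {
  a <- generate_claw_mesh(claw_params(noise_amplitude_mm = 0.2, seed = 4))
  b <- generate_claw_mesh(claw_params(noise_amplitude_mm = 0.2, seed = 4))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$tets, b$tets)
  c_ <- generate_claw_mesh(claw_params(noise_amplitude_mm = 0.2, seed = 5))
  expect_false(identical(a$nodes, c_$nodes))
})

test_that("the D/W parameter is recovered by measurement", {
  mesh <- generate_claw_mesh(claw_params())   # base D/W = 2, 60 degree arc
  meas <- measure_claw(mesh)
  expect_lt(abs(meas$ratio_DW - 2) / 2, 0.05)
})

test_that("generated meshes satisfy the mesh invariants over a parameter sweep", {
  set.seed(55)
  for (i in 1:40) {
    cp <- claw_params(
      length_mm = runif(1, 20, 80),
      arc_deg = runif(1, 0, 100),
      base_depth_mm = runif(1, 5, 15),
      base_width_mm = runif(1, 4, 12),
      taper_exponent = runif(1, 0.6, 2),
      axial_segments = sample(4:10, 1),
      circumferential_segments = sample(c(4, 6, 8), 1),
      radial_segments = sample(1:2, 1),
      noise_amplitude_mm = runif(1, 0, 0.1),
      seed = i)
    mesh <- generate_claw_mesh(cp)
    expect_true(all(tet_volumes(mesh$nodes, mesh$tets) > 0))
    expect_true(clawfsa:::is_closed_surface(mesh$boundary))
    expect_gt(length(mesh$regions$nodes$articular), 0L)
    expect_gt(length(mesh$regions$facets$ventral), 0L)
  }
})

test_that("volume and area converge as axial resolution doubles", {
  ref <- generate_claw_mesh(claw_params(axial_segments = 96,
                                        circumferential_segments = 12))
  v_ref <- enclosed_volume(ref)
  errs <- vapply(c(8, 16, 32, 64), function(na) {
    m <- generate_claw_mesh(claw_params(axial_segments = na,
                                        circumferential_segments = 12))
    abs(enclosed_volume(m) - v_ref) / v_ref
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("overly tight arcs are rejected with the violated bound", {
  expect_error(generate_claw_mesh(
    claw_params(length_mm = 20, arc_deg = 170, base_depth_mm = 18)),
    "arc too tight")
})

test_that("simulated stress families behave as declared", {
  mesh <- small_claw(31)
  const <- generate_stress_field(
    mesh, stress_sim_params("constant", mean_mpa = 7), "piercing", "c1")
  expect_true(all(const$vm_mpa == 7))
  expect_equal(const$volume_mm3, tet_volumes(mesh$nodes, mesh$tets))

  p <- stress_sim_params("lognormal", meanlog = 1, sdlog = 0.5, seed = 77)
  f1 <- generate_stress_field(mesh, p)
  f2 <- generate_stress_field(mesh, p)
  expect_identical(f1$vm_mpa, f2$vm_mpa)
})

test_that("lognormal fields hit the moment-formula mean within sampling error", {
  cp <- claw_params(axial_segments = 24, circumferential_segments = 16,
                    radial_segments = 2)
  mesh <- generate_claw_mesh(cp)
  expect_gt(nrow(mesh$tets), 1e4)
  p <- stress_sim_params("lognormal", meanlog = 1, sdlog = 0.5, seed = 13)
  f <- generate_stress_field(mesh, p)
  target <- exp(1 + 0.5^2 / 2)
  # volume weighting is independent of the stress draw, so the weighted
  # mean is unbiased with standard error ~ sd * sqrt(sum(w^2)) / sum(w)
  w <- f$volume_mm3
  se <- sqrt(exp(2 * 1 + 0.5^2) * (exp(0.5^2) - 1)) *
    sqrt(sum(w^2)) / sum(w)
  expect_lt(abs(mean_stress_summary(f) - target), 3 * se)
})

test_that("cohort manifests record ground truth matching the emitted fields", {
  co <- make_benchmark_cohort(n_specimens = 4, dig_multiplier = 2,
                              pull_multiplier = 0.5, mesh_resolution = 10,
                              seed = 3)
  expect_equal(nrow(co$manifest), 4L)
  for (i in seq_len(4)) {
    f <- co$fields[[i]]
    man <- co$manifest[i, ]
    for (pair in list(c("scratch_digging", "true_mean_digging"),
                      c("hook_and_pull", "true_mean_pulling"),
                      c("piercing", "true_mean_piercing"))) {
      got <- mean_stress_summary(f[[pair[1]]])
      truth <- man[[pair[2]]]
      expect_lt(abs(got - truth) / truth, 0.1)
    }
  }
})

test_that("an all-identical cohort produces identical records", {
  co <- make_benchmark_cohort(n_specimens = 3, dw_range = c(2, 2),
                              arc_range = c(60, 60), stress_gradient = 1,
                              mesh_resolution = 8, seed = 9)
  m <- co$manifest
  expect_equal(length(unique(m$ratio_DW)), 1L)
  expect_equal(length(unique(m$true_mean_piercing)), 1L)
  expect_equal(length(unique(m$surface_area_mm2)), 1L)
})

test_that("cohort output directories are reproducible byte for byte", {
  d1 <- tempfile("cohort1"); d2 <- tempfile("cohort2")
  co1 <- make_benchmark_cohort(n_specimens = 3, mesh_resolution = 8,
                               seed = 42)
  co2 <- make_benchmark_cohort(n_specimens = 3, mesh_resolution = 8,
                               seed = 42)
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})
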