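test_that("exact linear data recover slope, intercept and R-squared of 1", {
  df <- tibble::tibble(x = 1:5, y = 2 * (1:5) + 1)
  r <- regress_ols(df, "x", "y")
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
})

test_that("regression matches an explicit normal-equations oracle", {
  df <- tibble::tibble(x = c(1, 2, 3, 4, 5),
                       y = c(2.1, 3.9, 6.2, 7.8, 10.1))
  r <- regress_ols(df, "x", "y")
  X <- cbind(1, df$x)
  beta <- solve(t(X) %*% X, t(X) %*% df$y)     # independent matrix oracle
  expect_equal(r$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r$slope, beta[2], tolerance = 1e-10)
  res <- df$y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((df$y - mean(df$y))^2)
  expect_equal(r$r_squared, r2, tolerance = 1e-10)
  # slope t-test oracle on n - 2 df
  se <- sqrt(sum(res^2) / 3 / sum((df$x - mean(df$x))^2))
  expect_equal(r$p_value, 2 * pt(abs(beta[2] / se), 3, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("independent noise yields near-zero R-squared at large n", {
  set.seed(99)
  df <- tibble::tibble(x = rnorm(1e4), y = rnorm(1e4))
  expect_lt(regress_ols(df, "x", "y")$r_squared, 0.01)
})

test_that("fit quality is invariant under affine rescaling of x", {
  set.seed(3)
  df <- tibble::tibble(x = runif(30), y = runif(30) + 0.5 * runif(30))
  r1 <- regress_ols(df, "x", "y")
  df$x2 <- 3.7 * df$x + 11
  r2 <- regress_ols(df, "x2", "y")
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("degenerate regressions are handled explicitly", {
  expect_error(regress_ols(tibble::tibble(x = rep(2, 5), y = 1:5), "x", "y"),
               "variance")
  r <- regress_ols(tibble::tibble(x = c(1, 2), y = c(3, 5)), "x", "y")
  expect_equal(r$r_squared, 1)
  expect_true(is.na(r$p_value))
  expect_error(regress_ols(tibble::tibble(x = c(-1, 2, 3), y = 1:3),
                           "x", "y", log_x = TRUE), "positive")
})

test_that("log-log regression recovers a power law", {
  set.seed(12)
  x <- exp(runif(40, 0, 4))
  y <- 3 * x^0.75
  r <- regress_ols(tibble::tibble(x = x, y = y), "x", "y",
                   log_x = TRUE, log_y = TRUE)
  expect_equal(r$slope, 0.75, tolerance = 1e-9)
  expect_equal(r$intercept, log10(3), tolerance = 1e-9)
})

test_that("reference rows project onto their own morphospace scores", {
  ref <- reference_ratio_table(12)
  ms <- morphospace_project(ref[3, ], ref)
  expect_equal(as.numeric(ms$record_scores[1, -1]),
               as.numeric(ms$reference_scores[3, -1]), tolerance = 1e-10)
})

test_that("morphospace projection matches a centre-and-rotate oracle", {
  ref <- reference_ratio_table(5, seed = 8)
  rec <- reference_ratio_table(3, seed = 9)
  ms <- morphospace_project(rec, ref)
  L <- log10(as.matrix(ref[, c("ratio_LW", "ratio_LD", "ratio_DW")]))
  ctr <- colMeans(L)
  C <- crossprod(sweep(L, 2, ctr)) / (nrow(L) - 1)
  ev <- eigen(C, symmetric = TRUE)
  rot <- ev$vectors
  for (k in 1:3) if (rot[which.max(abs(rot[, k])), k] < 0)
    rot[, k] <- -rot[, k]
  Lr <- log10(as.matrix(rec[, c("ratio_LW", "ratio_LD", "ratio_DW")]))
  oracle <- sweep(Lr, 2, ctr) %*% rot
  expect_equal(unname(as.matrix(ms$record_scores[, -1])), unname(oracle),
               tolerance = 1e-10)
  expect_equal(ms$explained_variance,
               ev$values / sum(ev$values), tolerance = 1e-10)
})

test_that("non-positive ratios and missing columns are rejected", {
  ref <- reference_ratio_table(5)
  bad <- tibble::tibble(specimen_id = "x", ratio_LW = -1, ratio_LD = 2,
                        ratio_DW = 1)
  expect_error(morphospace_project(bad, ref), "positive")
  expect_error(morphospace_project(bad[, -2], ref), "ratio_LW")
})

test_that("divergence metrics are zero at the baseline and symmetric", {
  rec <- tibble::tibble(
    specimen_id = c("base", "left", "right"),
    mpc1 = c(0, -2, 2), mpc2 = c(0, 1, -1),
    area = c(1, 2, 3),
    side_digpierce = c(0.5, -1, 1))
  d <- divergence_metrics(rec, "base")
  expect_equal(d$morphological_divergence, c(0, sqrt(5), sqrt(5)))
  expect_equal(d$functional_divergence, rec$area)
  d2 <- divergence_metrics(rec, "base", functional_metric = "side_digpierce")
  expect_equal(d2$functional_divergence, rec$side_digpierce)
  expect_error(divergence_metrics(rec, "nope"), "baseline")
})

test_that("imposed stress-morphology coupling is recovered as a significant slope", {
  co <- make_benchmark_cohort(n_specimens = 12, stress_gradient = 2,
                              mesh_resolution = 8, seed = 21)
  measured <- vapply(co$fields,
                     function(f) mean_stress_summary(f$piercing), numeric(1))
  df <- tibble::tibble(dw = co$manifest$ratio_DW, stress = measured)
  r <- regress_ols(df, "dw", "stress")
  expect_gt(r$slope, 0)
  expect_lt(r$p_value, 0.05)
})
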