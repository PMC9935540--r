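test_that("upper-tail trimming is greedy by volume and never exceeds the fraction", {
  f <- stress_field(vm_mpa = 1:10, volume_mm3 = rep(1, 10))
  expect_identical(trim_upper_tail(f, 0)$vm_mpa, f$vm_mpa)
  t1 <- trim_upper_tail(f, 0.1)
  expect_equal(sort(t1$vm_mpa), 1:9)
  expect_equal(attr(t1, "trimmed_volume_mm3"), 1)

  f5 <- stress_field(vm_mpa = c(3, 1, 5, 2, 4), volume_mm3 = rep(2, 5))
  t2 <- trim_upper_tail(f5, 0.25)   # second removal would hit 40% > 25%
  expect_equal(nrow(t2), 4L)
  expect_equal(max(t2$vm_mpa), 4)
})

test_that("interval vectors match closed-form and degenerate cases", {
  f <- stress_field(vm_mpa = c(1, 3, 5, 7), volume_mm3 = rep(1, 4))
  v <- compute_interval_vector(f, interval_config(
    n_intervals = 4, trim_fraction = 0, lower_bound_mpa = 0,
    upper_bound_mpa = 8))
  expect_equal(v$pct, rep(25, 4))
  expect_equal(attr(v, "edges"), seq(0, 8, 2))

  fz <- stress_field(vm_mpa = rep(0, 6), volume_mm3 = rep(1, 6))
  vz <- compute_interval_vector(fz, interval_config(
    n_intervals = 10, upper_bound_mpa = 5))
  expect_equal(vz$pct, c(100, rep(0, 9)))
})

test_that("interval accumulation equals a brute-force element-by-element oracle", {
  set.seed(101)
  f <- stress_field(vm_mpa = rlnorm(1000, 1, 0.6),
                    volume_mm3 = runif(1000, 0.5, 2))
  cfg <- interval_config(n_intervals = 50, trim_fraction = 0.02)
  v <- compute_interval_vectors(list(f), cfg)[[1]]
  edges <- attr(v, "edges")
  trimmed <- trim_upper_tail(f, 0.02)
  oracle <- numeric(50)
  for (i in seq_len(nrow(trimmed))) {     # independent per-element scan
    s <- trimmed$vm_mpa[i]
    for (k in 1:50) {
      if ((s >= edges[k] && s < edges[k + 1]) || (k == 50 && s == edges[51])) {
        oracle[k] <- oracle[k] + trimmed$volume_mm3[i]
        break
      }
    }
  }
  oracle <- 100 * oracle / sum(f$volume_mm3)
  expect_equal(v$pct, oracle, tolerance = 1e-12)
  # conservation: percentages plus trimmed volume account for the model
  expect_equal(sum(v$pct) + attr(v, "trimmed_volume_pct"), 100,
               tolerance = 1e-9)
})

test_that("untrimmed percentages sum to exactly 100", {
  set.seed(7)
  f <- stress_field(vm_mpa = rgamma(300, 3), volume_mm3 = runif(300))
  v <- compute_interval_vectors(list(f),
                                interval_config(trim_fraction = 0))[[1]]
  expect_equal(sum(v$pct), 100, tolerance = 1e-9)
})

test_that("nested refinement collapses exactly onto the coarse binning", {
  set.seed(11)
  f <- stress_field(vm_mpa = rlnorm(400, 0.5, 0.7), volume_mm3 = runif(400))
  up <- max(f$vm_mpa)
  coarse <- compute_interval_vector(f, interval_config(
    n_intervals = 25, trim_fraction = 0, upper_bound_mpa = up))
  fine <- compute_interval_vector(f, interval_config(
    n_intervals = 50, trim_fraction = 0, upper_bound_mpa = up))
  folded <- colSums(matrix(fine$pct, nrow = 2))
  expect_equal(folded, coarse$pct, tolerance = 1e-12)
})

test_that("stress above a fixed shared bound lands in the last interval with a warning", {
  f <- stress_field(vm_mpa = c(1, 2, 9), volume_mm3 = rep(1, 3))
  expect_warning(
    v <- compute_interval_vector(f, interval_config(
      n_intervals = 4, upper_bound_mpa = 4)),
    "last interval")
  expect_equal(v$pct[4], 100 / 3, tolerance = 1e-9)
})

test_that("volume-weighted mean stress matches direct computation", {
  expect_equal(mean_stress_summary(
    stress_field(c(2, 4), c(1, 1))), 3)
  expect_equal(mean_stress_summary(
    stress_field(c(4, 0), c(1, 3))), 1)
  set.seed(5)
  f <- stress_field(rlnorm(500), runif(500))
  expect_equal(mean_stress_summary(f),
               sum(f$vm_mpa * f$volume_mm3) / sum(f$volume_mm3),
               tolerance = 1e-12)
})

test_that("ordination is deterministic and drops constant columns gracefully", {
  edges <- seq(0, 10, length.out = 11)
  base <- c(30, 25, 20, 10, 5, 5, 3, 2, 0, 0)
  vs <- list(
    fake_interval_vector(base, edges, "a", mean_stress = 2),
    fake_interval_vector(base, edges, "b", mean_stress = 2),
    fake_interval_vector(c(20, 30, 25, 10, 5, 5, 3, 2, 0, 0), edges, "c",
                         mean_stress = 7),
    fake_interval_vector(c(28, 24, 22, 11, 6, 4, 3, 2, 0, 0), edges, "d",
                         mean_stress = 3))
  sp <- ordinate(vs)
  # identical inputs get identical coordinates
  expect_equal(as.numeric(sp$scores[1, -(1:3)]),
               as.numeric(sp$scores[2, -(1:3)]), tolerance = 1e-10)
  # the shared empty top intervals were dropped, not propagated as NaN
  expect_true(all(is.finite(as.matrix(sp$scores[, -(1:2)]))))
  expect_lt(length(sp$kept_columns), 10L)
  # scores are centred and variance shares are sorted
  expect_lt(max(abs(colMeans(as.matrix(sp$scores[, -(1:3)])))), 1e-9)
  expect_true(all(diff(sp$explained_variance) < 1e-12))
})

test_that("ordination refuses unusable batches", {
  edges <- seq(0, 10, length.out = 11)
  v1 <- fake_interval_vector(c(50, 50, rep(0, 8)), edges, "a")
  v2 <- fake_interval_vector(c(40, 60, rep(0, 8)), edges, "b")
  expect_error(ordinate(list(v1, v2)), "at least 3")
  v3 <- fake_interval_vector(c(40, 60, rep(0, 8)),
                             seq(0, 20, length.out = 11), "c")
  expect_error(ordinate(list(v1, v2, v3)), "shared upper bound")
})

test_that("full-space score distances match an independent standardise+SVD oracle", {
  set.seed(23)
  edges <- seq(0, 12, length.out = 13)
  vs <- lapply(1:10, function(i) {
    p <- runif(12); p <- 100 * p / sum(p)
    fake_interval_vector(p, edges, paste0("s", i),
                         mean_stress = runif(1, 1, 9))
  })
  sp <- ordinate(vs)
  P <- do.call(rbind, lapply(vs, function(v) v$pct))
  X <- scale(log(P + 0.01))
  sv <- svd(X)
  oracle_scores <- sv$u %*% diag(sv$d)
  d_pkg <- as.matrix(dist(as.matrix(sp$scores[, -(1:3)])))
  d_orc <- as.matrix(dist(oracle_scores))
  expect_lt(max(abs(d_pkg - d_orc)), 1e-8)
})

test_that("PC1 is oriented along increasing mean stress", {
  set.seed(31)
  edges <- seq(0, 10, length.out = 21)
  centres <- (edges[-21] + edges[-1]) / 2
  make_v <- function(mu, id) {
    w <- dnorm(centres, mu, 1.2)
    fake_interval_vector(100 * w / sum(w), edges, id,
                         mean_stress = mu)
  }
  vs <- c(lapply(1:4, function(i) make_v(2 + 0.1 * i, paste0("lo", i))),
          lapply(1:4, function(i) make_v(7 + 0.1 * i, paste0("hi", i))))
  sp <- ordinate(vs)
  expect_gte(cor(sp$scores$pc1, sp$scores$mean_stress_mpa), 0)
  expect_gt(mean(sp$scores$pc1[5:8]), mean(sp$scores$pc1[1:4]))
})
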