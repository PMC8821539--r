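# Grid chosen so the probe CV values fall exactly on primitive grid points:
# end kernels at 4 and 5.975 give spacing 0.025 over 80 points, putting
# 5.0 and 5.05 on the grid while contributing ~exp(-200) there themselves.
probe_kernels <- function(centers) {
  make_kernels(c(4, centers, 5.975))
}

g_at <- function(fes, x) {
  i <- which.min(abs(fes$D_A - x))
  stopifnot(abs(fes$D_A[i] - x) < 1e-9)
  fes$g_kcal[i]
}

test_that("primitive FES is the negated kernel sum on an 80-point grid", {
  fes <- primitive_fes(probe_kernels(5))
  expect_equal(nrow(fes), 80)
  expect_equal(fes$D_A[1], 4)
  expect_equal(fes$D_A[80], 5.975)
  expect_equal(g_at(fes, 5), -0.01, tolerance = 1e-9)

  # additivity: two identical kernels double the well
  fes2 <- primitive_fes(probe_kernels(c(5, 5)))
  expect_equal(g_at(fes2, 5), -0.02, tolerance = 1e-9)

  # one sigma from the center: -h exp(-1/2)
  expect_equal(g_at(fes, 5.05), -0.01 * exp(-0.5), tolerance = 1e-9)
})

test_that("primitive FES matches the brute-force oracle everywhere", {
  for (s in c(101, 202)) {
    set.seed(s)
    ks <- make_kernels(runif(1000, 2, 9), heights = runif(1000, 0.005, 0.02),
                       widths = runif(1000, 0.03, 0.1))
    fes <- primitive_fes(ks)
    oracle <- -sum_gaussians_oracle(fes$D_A, ks$center_A, ks$width_A,
                                    ks$height_kcal)
    expect_lt(max(abs(fes$g_kcal - oracle)), 1e-10)
  }
})

test_that("interpolate_linear follows the two-point formula", {
  expect_equal(interpolate_linear(1.5, 1, -1, 2, -3), -2)
  expect_equal(interpolate_linear(1, 1, -1, 2, -3), -1)
  expect_equal(interpolate_linear(2, 1, -1, 2, -3), -3)
  expect_error(interpolate_linear(2.5, 1, -1, 2, -3), "within")
  expect_error(interpolate_linear(1.5, 2, -1, 1, -3), "D1 < D2")

  # exact on affine data at many random query points
  set.seed(1)
  D <- sort(runif(1000, 3, 7))
  got <- interpolate_linear(D, 3, 2 - 0.7 * 3, 7, 2 - 0.7 * 7)
  expect_equal(got, 2 - 0.7 * D, tolerance = 1e-12)
})

test_that("averaging identical or constant members behaves exactly", {
  m <- make_well_primitive()
  avg <- average_fes(list(m, m, m))
  expect_s3_class(avg, "ensemble_fes")
  expect_equal(attr(avg, "n_members"), 3)
  # idempotence: the average of identical members reproduces the member
  expect_equal(approx(avg$D_A, avg$g_kcal, xout = m$D_A)$y, m$g_kcal,
               tolerance = 1e-9)

  f1 <- fes_profile(seq(0, 1, length.out = 11), rep(-1, 11), "averaged")
  f2 <- fes_profile(seq(0, 1, length.out = 11), rep(-3, 11), "averaged")
  avg2 <- average_fes(list(f1, f2))
  expect_equal(unique(avg2$g_kcal), -2)
  expect_error(average_fes(list()), "at least one")
})

test_that("the common grid honours union range and smallest spacing", {
  f1 <- fes_profile(seq(0, 2, length.out = 21), rep(-1, 21), "averaged")
  f2 <- fes_profile(seq(1, 4, length.out = 16), rep(-3, 16), "averaged")
  avg <- average_fes(list(f1, f2))
  expect_equal(range(avg$D_A), c(0, 4))
  expect_lte(diff(avg$D_A)[1], min(0.1, 0.2) + 1e-12)
  # members contribute zero outside their own sampled range
  expect_equal(avg$g_kcal[avg$D_A > 2.05], rep(-1.5, sum(avg$D_A > 2.05)))
  expect_equal(avg$g_kcal[avg$D_A < 0.95], rep(-0.5, sum(avg$D_A < 0.95)))
})

test_that("averaging is permutation-invariant and bounded by its members", {
  reps <- bench_replicas(6)
  members <- lapply(reps, `[[`, "fes")
  a1 <- average_fes(members)
  a2 <- average_fes(rev(members))
  expect_identical(a1$g_kcal, a2$g_kcal)

  # bounds: between the member-wise min and max of resampled contributions
  resampled <- vapply(members, function(m) {
    y <- approx(m$D_A, m$g_kcal, xout = a1$D_A, rule = 1)$y
    y[is.na(y)] <- 0
    y
  }, numeric(nrow(a1)))
  expect_true(all(a1$g_kcal >= apply(resampled, 1, min) - 1e-9))
  expect_true(all(a1$g_kcal <= apply(resampled, 1, max) + 1e-9))
})

test_that("ensemble average matches the direct kernel re-evaluation oracle", {
  pot <- default_test_potential()
  runs <- lapply(1:10, function(s)
    simulate_run(pot, sim_config(seed = 400 + s, duration_ns = 0.09,
                                 wall_A = 12)))
  members <- lapply(runs, function(r) primitive_fes(r$kernels))
  avg <- average_fes(members)

  # oracle: re-evaluate every kernel of every replica on the common grid,
  # zero outside the member's own sampled range, then average
  oracle <- rowMeans(vapply(seq_along(runs), function(i) {
    ks <- runs[[i]]$kernels
    lo <- min(ks$center_A)
    hi <- max(ks$center_A)
    y <- -sum_gaussians_oracle(avg$D_A, ks$center_A, ks$width_A,
                               ks$height_kcal)
    y[avg$D_A < lo | avg$D_A > hi] <- 0
    y
  }, numeric(nrow(avg))))

  # member-wise linear interpolation error bound: curvature * spacing^2 / 8
  h <- diff(avg$D_A)[1]
  curv <- max(vapply(members, function(m) {
    max(abs(diff(diff(m$g_kcal)))) / diff(m$D_A)[1]^2
  }, 0))
  bound <- curv * max(vapply(members, function(m) diff(m$D_A)[1], 0))^2 / 8
  expect_lt(max(abs(avg$g_kcal - oracle)), bound + 1e-9)
})

test_that("long biased sampling flattens the well onto the model potential", {
  # closed box (wall just past the rim) so deposition keeps recycling;
  # -bias converges to U plus a growing constant, so g - U is constant
  # within the well up to the deposition ripple
  pot <- model_potential("piecewise_well_flat", r_w = 3, U0 = 3, kappa = 50)
  members <- lapply(1:8, function(s) {
    run <- simulate_run(pot, sim_config(seed = s, duration_ns = 1.5,
                                        wall_A = 4.5))
    primitive_fes(run$kernels)
  })
  avg <- average_fes(members)
  U <- potential_energy(pot, avg$D_A)
  well <- U < -0.5
  dev <- avg$g_kcal[well] - U[well]
  dev <- dev - mean(dev)
  expect_lt(max(abs(dev)), 3 * 0.01 * sqrt(8))
})
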