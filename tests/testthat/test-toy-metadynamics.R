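test_that("kernel count equals floor(duration / deposit interval)", {
  run <- simulate_run(model_potential("flat"),
                      sim_config(seed = 1, duration_ns = 9))
  expect_equal(nrow(run$kernels), 100000)
  expect_equal(run$kernels$time_ps[1], 0.09)
  # each kernel center is the CV value at its deposition time
  tr <- run$trajectory
  idx <- match(run$kernels$time_ps, tr$time_ps)
  expect_identical(run$kernels$center_A, tr$D_A[idx])
})

test_that("identical seed and configuration reproduce a run bit for bit", {
  cfg <- sim_config(seed = 5, duration_ns = 0.05, wall_A = 12)
  pot <- default_test_potential()
  r1 <- simulate_run(pot, cfg)
  r2 <- simulate_run(pot, cfg)
  expect_identical(as.data.frame(r1$kernels), as.data.frame(r2$kernels))
  expect_identical(as.data.frame(r1$trajectory), as.data.frame(r2$trajectory))
  r3 <- simulate_run(pot, sim_config(seed = 6, duration_ns = 0.05,
                                     wall_A = 12))
  expect_false(identical(r1$kernels$center_A, r3$kernels$center_A))
})

test_that("unbiased dynamics in a harmonic well satisfies equipartition", {
  # var(D) = kT / kappa for overdamped Langevin at equilibrium
  kappa <- 10
  run <- simulate_run(
    model_potential("harmonic_well", r_w = 5, U0 = 5, kappa = kappa),
    sim_config(seed = 9, duration_ns = 2, record_stride = 5L),
    deposit = FALSE
  )
  v <- var(run$trajectory$D_A[run$trajectory$time_ps > 100])
  expect_lt(abs(v - kB() * 310 / kappa) / (kB() * 310 / kappa), 0.05)
})

test_that("unbiased dynamics on a flat potential samples uniformly", {
  run <- simulate_run(
    model_potential("flat"),
    sim_config(seed = 11, duration_ns = 20, diffusion = 1, wall_A = 10,
               record_stride = 45L),
    deposit = FALSE
  )
  # thin to roughly one relaxation time so counts are nearly independent
  tr <- run$trajectory[seq(1, nrow(run$trajectory), by = 500), ]
  d <- tr$D_A[tr$D_A >= 0 & tr$D_A <= 10]
  counts <- table(cut(d, breaks = seq(0, 10, 2.5)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("extension is exact continuation", {
  pot <- default_test_potential()
  cfg <- sim_config(seed = 42, duration_ns = 0.1, wall_A = 12)
  leg <- simulate_run(pot, cfg)

  # extend by 0 is the identity
  same <- extend_run(leg$kernels, leg$trajectory, pot, cfg, 0)
  expect_identical(same$kernels, leg$kernels)

  # two 0.1 ns legs equal one 0.2 ns run, bitwise
  full <- extend_run(leg$kernels, leg$trajectory, pot, cfg, 0.1)
  ref <- simulate_run(pot, sim_config(seed = 42, duration_ns = 0.2,
                                      wall_A = 12))
  expect_identical(as.data.frame(full$kernels), as.data.frame(ref$kernels))
  expect_identical(as.data.frame(full$trajectory),
                   as.data.frame(ref$trajectory))
  expect_identical(attr(full$kernels, "final_cv"),
                   attr(ref$kernels, "final_cv"))

  # continuation survives a file round trip (state is in the headers)
  fk <- withr::local_tempfile()
  ft <- withr::local_tempfile()
  write_kernel_sequence(leg$kernels, fk)
  write_cv_trajectory(leg$trajectory, ft)
  full2 <- extend_run(read_kernel_sequence(fk), read_cv_trajectory(ft),
                      pot, cfg, 0.1)
  expect_identical(as.data.frame(full2$kernels), as.data.frame(ref$kernels))
})

test_that("extending a run that already exited deposits in the free region only", {
  pot <- default_test_potential() # well at 3 A, rim ~3.4 A
  cfg <- sim_config(seed = 20, duration_ns = 0.6)
  leg <- simulate_run(pot, cfg)
  expect_gt(attr(leg$kernels, "final_cv"), 8) # far out in the free region
  ext <- extend_run(leg$kernels, leg$trajectory, pot, cfg, 0.02)
  new_centers <- tail(ext$kernels$center_A, nrow(ext$kernels) -
                        nrow(leg$kernels))
  expect_gt(min(new_centers), 5) # no new deposition back in the well
})

test_that("state mismatch between sequence and trajectory is rejected", {
  pot <- default_test_potential()
  cfg <- sim_config(seed = 3, duration_ns = 0.05, wall_A = 12)
  a <- simulate_run(pot, cfg)
  b <- simulate_run(pot, sim_config(seed = 4, duration_ns = 0.05,
                                    wall_A = 12), run_id = "seed3")
  expect_error(extend_run(a$kernels, b$trajectory, pot, cfg, 0.1),
               "state mismatch")
  expect_error(
    extend_run(a$kernels, b$trajectory, pot,
               sim_config(seed = 9, duration_ns = 0.05, wall_A = 12), 0.1),
    "mismatch|seed")
})

test_that("a divergent integration step raises an informative error", {
  expect_error(
    simulate_run(model_potential("harmonic_well", r_w = 5, U0 = 5,
                                 kappa = 50),
                 sim_config(seed = 2, duration_ns = 0.01, dt = 0.09,
                            initial_cv = 0.5, wall_A = 12)),
    "divergent")
})

test_that("every biased replica exits the well across 30 seeds", {
  pot <- default_test_potential()
  rim <- 3 + sqrt(2 * 4 / 50)
  exits <- vapply(1:30, function(s) {
    run <- simulate_run(pot, sim_config(seed = s, duration_ns = 0.5,
                                        wall_A = 12))
    max(run$trajectory$D_A) > rim + 1
  }, TRUE)
  expect_true(all(exits))
})

test_that("deeper wells take longer to escape on seed average", {
  mean_exit <- function(U0) {
    rim <- 3 + sqrt(2 * U0 / 50)
    mean(vapply(1:8, function(s) {
      run <- simulate_run(
        model_potential("piecewise_well_flat", r_w = 3, U0 = U0, kappa = 50),
        sim_config(seed = 100 + s, duration_ns = 0.8, wall_A = 12))
      t <- run$trajectory$time_ps[run$trajectory$D_A > rim + 0.5][1]
      if (is.na(t)) 800 else t
    }, 0))
  }
  exits <- vapply(c(2, 4, 6), mean_exit, 0)
  expect_true(all(diff(exits) > 0))
})
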