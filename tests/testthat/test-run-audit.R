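# analytic averaged profile: harmonic well opening onto a plateau
well_plateau <- function(r0 = 5, U0 = 12, kappa = 50, plateau = -0.5,
                         from = 3.5, to = 10, n = 301) {
  D <- seq(from, to, length.out = n)
  g <- pmax(pmin(0.5 * kappa * (D - r0)^2 - U0, plateau), -U0)
  fes_profile(D, g, "averaged")
}

test_that("landmarks sit at the well minimum and the first plateau point", {
  prof <- well_plateau()
  lmk <- locate_landmarks(prof, smooth_window = 1L)
  expect_s3_class(lmk, "dfe_landmarks")
  expect_equal(lmk$r0_A, 5, tolerance = 0.02)
  expect_equal(lmk$g_min_kcal, -12, tolerance = 0.02)
  # rb: first point where the rise onto the plateau stops
  rim <- 5 + sqrt(2 * 11.5 / 50)
  expect_gte(lmk$rb_A, rim - 0.05)
  expect_lt(lmk$rb_A, rim + 0.2)
  # inner wall: 4 kcal/mol above the minimum, left of r0
  expect_lt(lmk$inner_wall_A, 5)
  expect_equal(0.5 * 50 * (lmk$inner_wall_A - 5)^2, 4, tolerance = 0.3)
})

test_that("with two interior maxima the smaller-CV one is the boundary", {
  D <- seq(0, 10, length.out = 501)
  g <- -12 * exp(-(D - 3)^2 / 0.5) - 3 * exp(-(D - 6.5)^2 / 0.5) - 0.3
  prof <- fes_profile(D, g, "averaged")
  lmk <- locate_landmarks(prof, smooth_window = 1L)
  expect_equal(lmk$r0_A, 3, tolerance = 0.02)
  # first maximum (between the wells, ~4.8 A), not the one past 8 A
  expect_gt(lmk$rb_A, 4)
  expect_lt(lmk$rb_A, 5.5)
})

test_that("a monotone profile has no bound state", {
  D <- seq(0, 10, length.out = 101)
  expect_error(locate_landmarks(fes_profile(D, -D, "averaged")),
               "no bound state")
  expect_error(locate_landmarks(fes_profile(D, D - 10, "averaged")),
               "no bound state")
})

lmk_fix <- tibble::tibble(r0_A = 5, rb_A = 6, g_min_kcal = -12,
                          inner_wall_A = 4.6)

test_that("the four trajectory categories are recognised", {
  # monotone dissociation: one-way, keep
  t1 <- cv_trajectory(1:100, seq(5, 15, length.out = 100), "a")
  v1 <- classify_run(t1, lmk_fix)
  expect_equal(v1$category, "one_way")
  expect_equal(v1$action, "keep")
  expect_equal(v1$return_events, 0L)
  expect_equal(v1$first_crossing_ps, t1$time_ps[t1$D_A > 6][1])

  # exits at 4 ns, returns to the bound level at 7 ns: multi-trip, reject
  tm <- c(seq(0, 3999, 100), seq(4000, 6999, 100), seq(7000, 10000, 100))
  Dm <- c(rep(5, 40), rep(8, 30), rep(5, 31))
  v2 <- classify_run(cv_trajectory(tm, Dm, "b"), lmk_fix)
  expect_equal(v2$category, "multi_trip")
  expect_equal(v2$action, "reject")
  expect_gte(v2$return_events, 1L)

  # drifts 5 A below r0 without exiting: invasion, reject
  t3 <- cv_trajectory(1:100, seq(5, 0, length.out = 100) + 0.001, "c")
  v3 <- classify_run(t3, lmk_fix)
  expect_equal(v3$category, "invasion")
  expect_equal(v3$action, "reject")

  # oscillates inside [r0 - 1, rb - 1] the whole run: incomplete, extend
  t4 <- cv_trajectory(1:200, 4.5 + 0.5 * sin(1:200 / 5), "d")
  v4 <- classify_run(t4, lmk_fix)
  expect_equal(v4$category, "incomplete")
  expect_equal(v4$action, "extend")
})

test_that("classification ignores uniform time rescaling", {
  D <- c(seq(5, 8, length.out = 50), seq(8, 5.2, length.out = 50),
         seq(5.2, 12, length.out = 50))
  for (scale in c(1, 3.7, 0.01)) {
    v <- classify_run(cv_trajectory(seq_along(D) * scale, D, "x"), lmk_fix)
    expect_equal(v$category, "multi_trip")
  }
})

test_that("hysteresis suppresses boundary jitter", {
  # dips to rb - 0.3 only: inside the default 0.5 A hysteresis band
  D <- c(seq(5, 6.5, length.out = 30), 5.7, seq(6.5, 12, length.out = 30))
  v <- classify_run(cv_trajectory(seq_along(D), D, "j"), lmk_fix)
  expect_equal(v$category, "one_way")
  v2 <- classify_run(cv_trajectory(seq_along(D), D, "j"), lmk_fix,
                     hysteresis = 0.1)
  expect_equal(v2$category, "multi_trip")
})

test_that("the inner-invasion diagnostic reports deposited bias left of the inner wall", {
  D <- seq(3, 7, length.out = 80)
  g <- -exp(-(D - 4)^2 / 0.02) # bias concentrated near 4 A, left of 4.6
  prim <- fes_profile(D, g, "primitive")
  v <- classify_run(cv_trajectory(1:10, rep(5, 10) + 0.01 * (1:10), "r"),
                    lmk_fix, primitive = prim)
  expect_gt(v$inner_bias_frac, 0.9)
})

test_that("audit keeps a clean ensemble intact and rejects injected deviants", {
  reps <- bench_replicas(12)
  audit <- audit_ensemble(reps)
  expect_s3_class(audit, "dfe_audit")
  expect_equal(nrow(audit$verdicts), 12)

  # inject two multi-trip and one invasion replica built from a kept run
  keep_idx <- match(audit$keep_ids, audit$verdicts$run_id)
  base <- reps[[keep_idx[1]]]
  rb <- audit$landmarks$rb_A
  r0 <- audit$landmarks$r0_A
  mk_traj <- function(D, id) cv_trajectory(seq_along(D) * 0.09, D, id)
  bad <- list(
    list(trajectory = mk_traj(c(seq(r0, rb + 3, length.out = 60),
                                seq(rb + 3, r0, length.out = 60)), "mt1"),
         fes = base$fes),
    list(trajectory = mk_traj(c(seq(r0, rb + 2, length.out = 40),
                                seq(rb + 2, r0 - 1, length.out = 40),
                                seq(r0 - 1, rb + 4, length.out = 40)), "mt2"),
         fes = base$fes),
    list(trajectory = mk_traj(seq(r0, max(0.01, r0 - 4.5),
                                  length.out = 80), "inv1"),
         fes = base$fes)
  )
  audit2 <- audit_ensemble(c(reps, bad))
  v <- audit2$verdicts
  expect_equal(v$category[v$run_id == "mt1"], "multi_trip")
  expect_equal(v$category[v$run_id == "mt2"], "multi_trip")
  expect_equal(v$category[v$run_id == "inv1"], "invasion")
  expect_false(any(c("mt1", "mt2", "inv1") %in% audit2$keep_ids))
  # the verdicts of the original replicas are unchanged by the injection
  expect_equal(v$category[match(audit$verdicts$run_id, v$run_id)],
               audit$verdicts$category)
})

test_that("landmarks are stable across disjoint half-ensembles", {
  reps <- bench_replicas(12)
  avg_a <- average_fes(lapply(reps[1:6], `[[`, "fes"))
  avg_b <- average_fes(lapply(reps[7:12], `[[`, "fes"))
  la <- locate_landmarks(avg_a)
  lb <- locate_landmarks(avg_b)
  spacing <- diff(avg_a$D_A)[1]
  expect_lte(abs(la$r0_A - lb$r0_A), 2 * spacing)
})
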