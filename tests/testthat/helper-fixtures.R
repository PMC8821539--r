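# Shared fixtures, built in code.

# quick kernel-sequence constructor for hand-made deposition histories
make_kernels <- function(centers, heights = 0.01, widths = 0.05,
                         run_id = "test", seed = 1L, wall_A = 40,
                         duration_ns = 1) {
  n <- length(centers)
  kernel_sequence(
    tibble::tibble(time_ps = 0.09 * seq_len(n), center_A = centers,
                   width_A = rep_len(widths, n),
                   height_kcal = rep_len(heights, n)),
    run_id = run_id, seed = seed, wall_A = wall_A, duration_ns = duration_ns
  )
}

# an analytic 80-point primitive-style profile: capped harmonic well
make_well_primitive <- function(r_w = 5, U0 = 12, kappa = 50,
                                from = 4, to = 10, run_id = "synthetic") {
  D <- seq(from, to, length.out = 80)
  g <- pmin(0.5 * kappa * (D - r_w)^2 - U0, 0)
  fes_profile(D, g, kind = "primitive", run_id = run_id)
}

# fast-dissociating shallow well for simulator behaviour tests
default_test_potential <- function() {
  model_potential("piecewise_well_flat", r_w = 3, U0 = 4, kappa = 50)
}

# R-side brute-force kernel sum: the independent oracle for primitive_fes
sum_gaussians_oracle <- function(x, centers, widths, heights) {
  vapply(x, function(xi)
    sum(heights * exp(-(xi - centers)^2 / (2 * widths^2))), 0)
}

# benchmark replica cache: several tests share a small ensemble of the
# default 12 kcal/mol campaign conditions
.bench_env <- new.env(parent = emptyenv())
bench_replicas <- function(n = 12) {
  key <- paste0("n", n)
  if (is.null(.bench_env[[key]])) {
    pot <- model_potential("piecewise_well_flat", r_w = 5, U0 = 12,
                           kappa = 50)
    .bench_env[[key]] <- lapply(seq_len(n) + 2006L, function(s) {
      run <- simulate_run(pot, sim_config(seed = s))
      list(kernels = run$kernels, trajectory = run$trajectory,
           fes = primitive_fes(run$kernels))
    })
  }
  .bench_env[[key]]
}
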