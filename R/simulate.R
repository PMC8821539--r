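#' Simulator configuration
#'
#' Parameters of one toy metadynamics replica: overdamped Langevin dynamics
#' on the CV with history-dependent Gaussian bias deposition, a reflective
#' boundary at D = 0 and a half-harmonic wall at `wall_A`. The deposition
#' defaults (height 0.01 kcal/mol, width 0.05 A, one Gaussian every 0.09 ps,
#' 310 K) are the production metadynamics settings the method was developed
#' with; the integration defaults (dt = 0.002 ps, D_c = 0.1 A^2/ps, wall
#' spring 100 kcal mol-1 A-2) are chosen for stable desk-scale integration.
#'
#' @param seed Integer random seed (one per replica). The per-step noise is a
#'   counter-based function of `(seed, step index)`, so runs are exactly
#'   reproducible and extendable.
#' @param duration_ns Simulated chemical time (ns).
#' @param dt Integration timestep (ps).
#' @param diffusion CV diffusion coefficient D_c (A^2 / ps).
#' @param temperature Temperature (K).
#' @param deposit_interval Time between Gaussian depositions tau_G (ps); must
#'   be an integer multiple of `dt`.
#' @param height,width Deposited Gaussian height h (kcal/mol) and width sigma (A).
#' @param wall_A Half-harmonic wall position (A).
#' @param wall_spring Wall spring constant (kcal mol-1 A-2).
#' @param initial_cv Starting CV value (A); defaults to the potential's well
#'   position (half the wall distance for a flat potential).
#' @param record_stride Trajectory recording interval in steps; defaults to
#'   one record per deposition interval. The initial and final states are
#'   always recorded.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 2007, duration_ns = 0.01)
#' cfg$deposit_interval / cfg$dt  # integration steps per deposition
#' @export
sim_config <- function(seed, duration_ns = 1.2, dt = 0.002, diffusion = 0.1,
                       temperature = 310, deposit_interval = 0.09,
                       height = 0.01, width = 0.05, wall_A = 35,
                       wall_spring = 100, initial_cv = NULL,
                       record_stride = NULL) {
  stopifnot(dt > 0, duration_ns > 0, diffusion > 0, temperature > 0,
            height > 0, width > 0, wall_A > 0, wall_spring >= 0)
  tau_steps <- deposit_interval / dt
  if (abs(tau_steps - round(tau_steps)) > 1e-9)
    abort("deposit_interval must be an integer multiple of dt")
  tau_steps <- as.integer(round(tau_steps))
  if (!is.null(initial_cv) && (initial_cv < 0 || initial_cv >= wall_A))
    abort("initial_cv must lie in [0, wall_A)")
  record_stride <- as.integer(record_stride %||% tau_steps)
  stopifnot(record_stride >= 1)
  structure(
    list(seed = as.integer(seed), duration_ns = duration_ns, dt = dt,
         diffusion = diffusion, temperature = temperature,
         deposit_interval = deposit_interval, tau_steps = tau_steps,
         height = height, width = width, wall_A = wall_A,
         wall_spring = wall_spring, initial_cv = initial_cv,
         record_stride = record_stride),
    class = "sim_config"
  )
}

bias_grid_spec <- function(config) {
  dx <- config$width / 10
  x0 <- -1
  n <- as.integer(ceiling((config$wall_A + 2 - x0) / dx)) + 1L
  list(x0 = x0, dx = dx, n = n)
}

default_initial_cv <- function(potential, config) {
  config$initial_cv %||%
    (if (potential$form == "flat") config$wall_A / 2 else potential$r_w)
}

#' Run one toy metadynamics replica
#'
#' Integrates overdamped Langevin dynamics on the CV,
#' \deqn{D \leftarrow D + (D_c/kT)\,F(D)\,dt + \sqrt{2 D_c dt}\,\xi,}
#' where F is minus the derivative of (model potential + accumulated Gaussian
#' bias + wall term) and \eqn{\xi} a standard normal deviate, depositing a
#' repulsive Gaussian at the running CV value every `deposit_interval`.
#' Identical `(potential, config)` always produce bit-identical output.
#'
#' @param potential A [model_potential()].
#' @param config A [sim_config()].
#' @param run_id Replica identifier; defaults to `"seed<seed>"`.
#' @param deposit If `FALSE`, plain Langevin dynamics with no bias (useful for
#'   sampling checks).
#' @return A list with elements `kernels` (a [kernel_sequence()] with
#'   `floor(duration / deposit_interval)` rows) and `trajectory`
#'   (a [cv_trajectory()]).
#' @examples
#' run <- simulate_run(model_potential("flat"),
#'                     sim_config(seed = 1, duration_ns = 0.002, wall_A = 10))
#' nrow(run$kernels)  # floor(2 ps / 0.09 ps)
#' @export
simulate_run <- function(potential, config, run_id = NULL, deposit = TRUE) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(config, "sim_config"))
  run_id <- run_id %||% paste0("seed", config$seed)
  n_steps <- round(config$duration_ns * 1000 / config$dt)
  gs <- bias_grid_spec(config)
  res <- metad_core(
    form = pot_code(potential), pot_params = pot_params(potential),
    dt = config$dt, Dc = config$diffusion, temperature = config$temperature,
    tau_steps = config$tau_steps, height = config$height,
    sigma = config$width, wall = config$wall_A,
    wall_spring = config$wall_spring, grid_x0 = gs$x0, grid_dx = gs$dx,
    n_grid = gs$n, fgrid_init = numeric(0),
    D0 = default_initial_cv(potential, config), start_step = 0,
    n_steps = n_steps, seed = config$seed, deposit = deposit,
    record_stride = config$record_stride
  )
  ks <- kernel_sequence(
    tibble(time_ps = res$kernel_time, center_A = res$kernel_center,
           width_A = rep(config$width, length(res$kernel_time)),
           height_kcal = rep(config$height, length(res$kernel_time))),
    run_id = run_id, seed = config$seed, wall_A = config$wall_A,
    duration_ns = config$duration_ns,
    final_cv = res$final_D, final_step = res$final_step
  )
  tr <- cv_trajectory(res$traj_time, res$traj_D, run_id = run_id,
                      wall_A = config$wall_A, final_step = res$final_step)
  list(kernels = ks, trajectory = tr)
}

#' Extend a replica run in place
#'
#' Continues a run produced by [simulate_run()] for `extra_duration_ns` more
#' simulated time. The integrator state is reconstructed exactly: the final
#' CV and global step index are read from the recorded metadata, the bias
#' grid is rebuilt by re-depositing the recorded kernels in order, and the
#' counter-based noise stream resumes at the stored step index — so the
#' result is bit-identical to a single run of the combined duration with the
#' same seed.
#'
#' @param sequence,trajectory The `kernels` / `trajectory` pair from
#'   [simulate_run()] (or read back from files).
#' @inheritParams simulate_run
#' @param extra_duration_ns Additional simulated time (ns); 0 is the identity.
#' @return As [simulate_run()], covering the combined duration.
#' @examples
#' pot <- model_potential("flat")
#' cfg <- sim_config(seed = 3, duration_ns = 0.001, wall_A = 10)
#' leg <- simulate_run(pot, cfg)
#' full <- extend_run(leg$kernels, leg$trajectory, pot, cfg, 0.001)
#' attr(full$kernels, "duration_ns")
#' @export
extend_run <- function(sequence, trajectory, potential, config,
                       extra_duration_ns) {
  stopifnot(inherits(sequence, "kernel_seq"), inherits(trajectory, "cv_traj"),
            extra_duration_ns >= 0)
  if (extra_duration_ns == 0)
    return(list(kernels = sequence, trajectory = trajectory))
  if (!identical(attr(sequence, "run_id"), attr(trajectory, "run_id")))
    abort("sequence and trajectory come from different runs")
  fcv <- attr(sequence, "final_cv")
  fstep <- attr(sequence, "final_step")
  if (is.null(fcv) || is.null(fstep))
    abort("sequence lacks recoverable integrator state (final_cv / final_step)")
  tfin <- attr(trajectory, "final_step")
  if (!is.null(tfin) && !identical(as.numeric(tfin), as.numeric(fstep)))
    abort("sequence and trajectory disagree on the final step: state mismatch")
  if (abs(trajectory$D_A[nrow(trajectory)] - fcv) > 1e-12)
    abort("trajectory endpoint does not match the recorded final CV: state mismatch")
  if (attr(sequence, "seed") != config$seed)
    abort("config seed differs from the seed the run was generated with")

  gs <- bias_grid_spec(config)
  fgrid <- rebuild_bias_grid(sequence$center_A, sequence$width_A,
                             sequence$height_kcal, gs$x0, gs$dx, gs$n)
  n_steps <- round(extra_duration_ns * 1000 / config$dt)
  res <- metad_core(
    form = pot_code(potential), pot_params = pot_params(potential),
    dt = config$dt, Dc = config$diffusion, temperature = config$temperature,
    tau_steps = config$tau_steps, height = config$height,
    sigma = config$width, wall = config$wall_A,
    wall_spring = config$wall_spring, grid_x0 = gs$x0, grid_dx = gs$dx,
    n_grid = gs$n, fgrid_init = fgrid, D0 = fcv, start_step = fstep,
    n_steps = n_steps, seed = config$seed, deposit = TRUE,
    record_stride = config$record_stride
  )
  new_duration <- attr(sequence, "duration_ns") + extra_duration_ns
  ks <- kernel_sequence(
    tibble(
      time_ps = c(sequence$time_ps, res$kernel_time),
      center_A = c(sequence$center_A, res$kernel_center),
      width_A = c(sequence$width_A, rep(config$width, length(res$kernel_time))),
      height_kcal = c(sequence$height_kcal,
                      rep(config$height, length(res$kernel_time)))
    ),
    run_id = attr(sequence, "run_id"), seed = attr(sequence, "seed"),
    wall_A = attr(sequence, "wall_A"), duration_ns = new_duration,
    final_cv = res$final_D, final_step = res$final_step
  )
  # drop the previous leg's final record if it was off-stride: a single long
  # run would not contain it
  old <- trajectory
  if (fstep %% config$record_stride != 0) old <- old[-nrow(old), ]
  tr <- cv_trajectory(c(old$time_ps, res$traj_time),
                      c(old$D_A, res$traj_D),
                      run_id = attr(trajectory, "run_id"),
                      wall_A = attr(trajectory, "wall_A") %||% config$wall_A,
                      final_step = res$final_step)
  list(kernels = ks, trajectory = tr)
}
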