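#' Campaign configuration
#'
#' Bundles every knob of a multi-replica DFE campaign. Accepts a YAML file
#' path or a named list; unspecified keys take the defaults below, which are
#' the package's toy benchmark: 50 replicas on a single 12 kcal/mol well with
#' the production deposition settings.
#'
#' @param config A named list of overrides, or a path to a YAML file of them.
#'   Recognised keys: `campaign_id`, `potential` (list with `form` and its
#'   parameters), `n_replicas`, `seed_start` (replica seeds are
#'   `seed_start, seed_start + 1, ...`) or an explicit `seeds` vector
#'   (must be unique), `duration_ns`, `sim` (list of [sim_config()]
#'   overrides), `temperature`, `a`, `b`, `hysteresis`, `invasion_margin`,
#'   `extend_by_ns`, `max_extensions`, `max_batches`, `out_dir`.
#' @return A list of class `campaign_config`.
#' @examples
#' cfg <- campaign_config(list(n_replicas = 5, duration_ns = 0.05))
#' cfg$seeds
#' @export
campaign_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    campaign_id = "campaign",
    potential = list(form = "piecewise_well_flat", r_w = 5, U0 = 12,
                     kappa = 50),
    n_replicas = 50L, seed_start = 2007L, seeds = NULL, duration_ns = 1.2,
    sim = list(), temperature = 310, a = NULL, b = NULL,
    hysteresis = 0.5, invasion_margin = 4,
    extend_by_ns = NULL, max_extensions = 2L, max_batches = 3L,
    out_dir = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    abort(paste("unknown campaign keys:", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  cfg$seeds <- as.integer(cfg$seeds %||%
    seq.int(cfg$seed_start, length.out = cfg$n_replicas))
  if (anyDuplicated(cfg$seeds))
    abort("replica seeds must be unique")
  cfg$n_replicas <- length(cfg$seeds)
  cfg$extend_by_ns <- cfg$extend_by_ns %||% cfg$duration_ns
  class(cfg) <- "campaign_config"
  cfg
}

campaign_potential <- function(cfg) {
  p <- cfg$potential
  do.call(model_potential, p)
}

campaign_sim_config <- function(cfg, seed, duration_ns) {
  do.call(sim_config, modifyList(
    list(seed = seed, duration_ns = duration_ns), cfg$sim))
}

new_replica <- function(cfg, pot, seed) {
  scfg <- campaign_sim_config(cfg, seed, cfg$duration_ns)
  run <- simulate_run(pot, scfg)
  list(seed = seed, run_id = attr(run$kernels, "run_id"),
       kernels = run$kernels, trajectory = run$trajectory,
       fes = primitive_fes(run$kernels),
       fes_nc = NULL, extensions = 0L, config = scfg)
}

extend_replica <- function(cfg, pot, rep) {
  # keep the pre-correction surface from the first pass
  if (is.null(rep$fes_nc)) rep$fes_nc <- rep$fes
  ext <- extend_run(rep$kernels, rep$trajectory, pot, rep$config,
                    cfg$extend_by_ns)
  rep$kernels <- ext$kernels
  rep$trajectory <- ext$trajectory
  rep$fes <- primitive_fes(ext$kernels)
  rep$extensions <- rep$extensions + 1L
  rep$config <- campaign_sim_config(cfg, rep$seed,
                                    attr(ext$kernels, "duration_ns"))
  rep
}

#' Run a full DFE campaign on the toy simulator
#'
#' Executes the staged procedure end to end: simulate the replica batch,
#' reconstruct each primitive FES, audit the ensemble against the
#' one-way-trip criteria (extending `incomplete` runs by `extend_by_ns` up
#' to `max_extensions` times, then rejecting them; rejecting multi-trip and
#' invasion runs outright), average the filtered ensemble, compute DFE with
#' its jackknife uncertainty and the DFE-versus-N convergence trace, and —
#' if the last-five rule is not yet satisfied — launch a further batch of
#' the same size and repeat, up to `max_batches` batches.
#'
#' Both the corrected DFE (filtered, post-extension ensemble) and the
#' uncorrected DFE (all replicas, pre-extension surfaces) are reported.
#' Identical configurations reproduce the manifest bit for bit apart from
#' the timestamp.
#'
#' @param config A [campaign_config()], or anything it accepts.
#' @return A `dfe_campaign` manifest: seeds and per-replica bookkeeping,
#'   audit verdicts, DFE with uncertainty, the uncorrected DFE, the
#'   convergence trace and flag, batch/extension counts, tool version and a
#'   config hash. If `out_dir` is set, all per-replica files, the averaged
#'   surface, a verdict TSV and a JSON manifest are written there. Has
#'   [glance()] and [autoplot()] methods.
#' @examples
#' \donttest{
#' man <- run_campaign(list(n_replicas = 3, duration_ns = 0.2,
#'                          potential = list(form = "piecewise_well_flat",
#'                                           r_w = 3, U0 = 2, kappa = 50),
#'                          sim = list(wall_A = 6)))
#' glance(man)
#' }
#' @export
run_campaign <- function(config = list()) {
  cfg <- if (inherits(config, "campaign_config")) config
         else campaign_config(config)
  pot <- campaign_potential(cfg)
  replicas <- list()
  next_seeds <- cfg$seeds
  batch <- 0L
  audit <- NULL
  repeat {
    batch <- batch + 1L
    replicas <- c(replicas, purrr::map(next_seeds,
                                       function(s) new_replica(cfg, pot, s)))
    # audit/extend loop: extend incomplete runs, re-audit, until none left
    repeat {
      audit <- audit_ensemble(
        purrr::map(replicas, function(r) list(trajectory = r$trajectory,
                                              fes = r$fes)),
        hysteresis = cfg$hysteresis, invasion_margin = cfg$invasion_margin)
      extendable <- which(audit$verdicts$action == "extend" &
                            purrr::map_int(replicas, "extensions") <
                              cfg$max_extensions)
      if (length(extendable) == 0) break
      for (i in extendable) replicas[[i]] <- extend_replica(cfg, pot,
                                                            replicas[[i]])
    }
    verdicts <- audit$verdicts
    # an extended run that still has not exited is discarded
    verdicts$action[verdicts$action == "extend"] <- "reject"
    keep <- which(verdicts$action == "keep")
    if (length(keep) == 0)
      abort(paste("every replica failed the one-way-trip audit;",
                  "increase duration_ns or the replica count"))
    kept_members <- purrr::map(replicas[keep], "fes")
    nc_members <- purrr::map(replicas, function(r) r$fes_nc %||% r$fes)
    dfe <- dfe_from_fes(average_fes(kept_members),
                        temperature = cfg$temperature, a = cfg$a, b = cfg$b,
                        members = if (length(kept_members) >= 2) kept_members)
    dfe_nc <- dfe_from_fes(average_fes(nc_members),
                           temperature = cfg$temperature, a = cfg$a,
                           b = cfg$b)
    trace <- convergence_trace(kept_members, temperature = cfg$temperature,
                               a = cfg$a, b = cfg$b)
    if (attr(trace, "converged") || batch >= cfg$max_batches) break
    next_seeds <- seq.int(max(purrr::map_int(replicas, "seed")) + 1L,
                          length.out = length(cfg$seeds))
  }
  manifest <- structure(
    list(
      campaign_id = cfg$campaign_id,
      seeds = purrr::map_int(replicas, "seed"),
      run_ids = purrr::map_chr(replicas, "run_id"),
      extensions = purrr::map_int(replicas, "extensions"),
      durations_ns = purrr::map_dbl(replicas, function(r)
        attr(r$kernels, "duration_ns")),
      verdicts = verdicts,
      landmarks = audit$landmarks,
      audit_iterations = audit$iterations,
      n_batches = batch,
      dfe = dfe, dfe_nc = dfe_nc,
      convergence = trace,
      converged = attr(trace, "converged"),
      status = if (attr(trace, "converged")) "converged" else "unconverged",
      tool_version = as.character(utils::packageVersion("dfekit")),
      config_hash = rlang::hash(unclass(cfg)),
      timestamp = format(Sys.time(), tz = "UTC"),
      averaged = average_fes(purrr::map(replicas[keep], "fes")),
      replicas = replicas
    ),
    class = "dfe_campaign"
  )
  if (!is.null(cfg$out_dir)) write_campaign(manifest, cfg$out_dir)
  manifest
}

write_campaign <- function(man, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (r in man$replicas) {
    kf <- file.path(out_dir, paste0(r$run_id, ".kerseq.tsv"))
    cf <- file.path(out_dir, paste0(r$run_id, ".cv.tsv"))
    ff <- file.path(out_dir, paste0(r$run_id, ".fes.tsv"))
    write_kernel_sequence(r$kernels, kf)
    write_cv_trajectory(r$trajectory, cf)
    write_fes(r$fes, ff)
    files <- c(files, kf, cf, ff)
  }
  af <- file.path(out_dir, "averaged.fes.tsv")
  write_fes(man$averaged, af)
  vf <- file.path(out_dir, "verdicts.tsv")
  utils::write.table(man$verdicts, vf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mf <- file.path(out_dir, "manifest.json")
  slim <- man[setdiff(names(man), c("replicas", "averaged", "convergence"))]
  slim$dfe <- unclass(man$dfe)
  slim$dfe_nc <- unclass(man$dfe_nc)
  slim$dfe_by_n <- man$convergence$dfe
  slim$files <- c(files, af, vf)
  jsonlite::write_json(slim, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(mf)
}

#' @export
print.dfe_campaign <- function(x, ...) {
  counts <- table(x$verdicts$category)
  cat(sprintf("DFE campaign '%s': %d replicas, %d batch(es), %s\n",
              x$campaign_id, length(x$seeds), x$n_batches, x$status))
  cat("  verdicts:", paste(names(counts), counts, sep = "=", collapse = ", "),
      "\n")
  cat(sprintf("  DFE = %.2f ± %.2f kcal/mol (uncorrected %.2f)\n",
              x$dfe$dfe, x$dfe$uncertainty, x$dfe_nc$dfe))
  invisible(x)
}
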