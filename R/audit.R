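rolling_mean <- function(x, w) {
  if (w <= 1) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)] # keep raw values at the edges
  sm
}

#' Locate the bound-state landmarks on an averaged FES
#'
#' Finds `r0`, the CV of the bound-state minimum (global minimum of the
#' lightly smoothed profile), and `rb`, the bound/free boundary: the first
#' local maximum of the profile right of `r0`, or — when the surface rises
#' monotonically onto a plateau with no interior maximum — the first point
#' that has risen to within `plateau_tol` of the plateau level (mean of the
#' rightmost tenth of the grid). Ties are broken toward smaller CV. The inner
#' wall (first point left of `r0` where the surface has risen `inner_rise`
#' above the minimum) is also reported; it feeds the invasion diagnostic.
#'
#' @param averaged A `fes_profile`/`ensemble_fes` with at least 3 points.
#' @param smooth_window Width (points) of the centered rolling mean applied
#'   before landmark detection; 1 disables smoothing.
#' @param plateau_tol Rise tolerance (kcal/mol) for the plateau fallback.
#' @param inner_rise Energy rise (kcal/mol) defining the inner wall.
#' @return A one-row tibble of class `dfe_landmarks`: `r0_A`, `rb_A`,
#'   `g_min_kcal`, `inner_wall_A`.
#' @examples
#' D <- seq(0, 10, 0.05)
#' g <- pmin(0.5 * 50 * (D - 5)^2 - 12, 0)
#' lm <- locate_landmarks(fes_profile(D, g, "averaged"))
#' lm$r0_A
#' @export
locate_landmarks <- function(averaged, smooth_window = 5L, plateau_tol = 0.1,
                             inner_rise = 4) {
  stopifnot(inherits(averaged, "fes_profile"))
  n <- nrow(averaged)
  if (n < 3) abort("averaged profile too short to locate landmarks")
  D <- averaged$D_A
  g <- rolling_mean(averaged$g_kcal, smooth_window)
  imin <- which.min(g) # which.min breaks ties toward smaller CV
  if (imin == 1L || imin == n)
    abort("no bound state detected: profile minimum lies on the grid edge")
  # boundary: the first point right of the minimum where the (smoothed)
  # profile stops rising — a local maximum / saddle, or the first point of
  # the free-region plateau — after it has recovered at least half of the
  # total rise. The half-rise guard skips noise bumps on the well slope;
  # taking the *first* qualifying point breaks ties toward smaller CV.
  rise_target <- g[imin] + 0.5 * (max(g[(imin + 1L):n]) - g[imin])
  irb <- NA_integer_
  for (i in seq(imin + 1L, n - 1L)) {
    if (g[i] >= g[i + 1L] && g[i] >= rise_target) { irb <- i; break }
  }
  if (is.na(irb)) {
    # profile rises monotonically to the grid edge
    cand <- which(seq_len(n) > imin & g >= max(g) - plateau_tol)
    if (length(cand) == 0)
      abort("no bound/free boundary found right of the minimum")
    irb <- cand[1]
  }
  iw <- which(seq_len(n) < imin & g >= g[imin] + inner_rise)
  inner <- if (length(iw)) D[max(iw)] else NA_real_
  out <- tibble(r0_A = D[imin], rb_A = D[irb], g_min_kcal = averaged$g_kcal[imin],
                inner_wall_A = inner)
  class(out) <- c("dfe_landmarks", class(tibble()))
  out
}

#' Classify one replica against the one-way-trip criteria
#'
#' A replica whose CV crosses the boundary `rb` and never afterwards drops
#' back below `rb - hysteresis` is a completed one-way trip (keep). Crossing
#' and returning is a multi-trip (reject). A run that never crosses `rb` is
#' an invasion (reject) if its CV dropped more than `invasion_margin` below
#' `r0` — drift opposite to dissociation — and otherwise incomplete (extend:
#' the run simply needs more time). When the replica's primitive FES and the
#' inner wall are available, the fraction of its deposited bias lying left of
#' the inner wall is reported as a diagnostic (it is not used for rejection).
#'
#' @param trajectory A [cv_trajectory()].
#' @param landmarks A [locate_landmarks()] result.
#' @param primitive Optional primitive `fes_profile` of the same run, for the
#'   inner-invasion diagnostic.
#' @param hysteresis Return margin below `rb` (A) that counts as re-entering
#'   the bound state; suppresses boundary jitter.
#' @param invasion_margin Distance below `r0` (A) that defines an invasion.
#' @return A one-row tibble: `run_id`, `category` (one of `one_way`,
#'   `multi_trip`, `invasion`, `incomplete`), `action` (`keep`, `reject`,
#'   `extend`), `first_crossing_ps`, `min_cv_A`, `return_events`,
#'   `inner_bias_frac`.
#' @examples
#' lmk <- tibble::tibble(r0_A = 5, rb_A = 6, g_min_kcal = -12,
#'                       inner_wall_A = 4.4)
#' tr <- cv_trajectory(1:10, c(5, 5, 5.5, 6.5, 8, 9, 10, 10, 11, 11.5), "r1")
#' classify_run(tr, lmk)$category  # one_way
#' @export
classify_run <- function(trajectory, landmarks, primitive = NULL,
                         hysteresis = 0.5, invasion_margin = 4) {
  stopifnot(inherits(trajectory, "cv_traj"), nrow(trajectory) > 0)
  r0 <- landmarks$r0_A
  rb <- landmarks$rb_A
  D <- trajectory$D_A
  min_cv <- min(D)
  above <- which(D > rb)
  frac <- inner_bias_fraction(primitive, landmarks$inner_wall_A)
  if (length(above) > 0) {
    icross <- above[1]
    after <- D[icross:length(D)]
    # count distinct re-entries below the hysteresis line after first exit
    below <- after < rb - hysteresis
    runs <- rle(below)
    returns <- sum(runs$values)
    category <- if (returns == 0) "one_way" else "multi_trip"
    first_cross <- trajectory$time_ps[icross]
  } else {
    returns <- 0L
    first_cross <- NA_real_
    category <- if (min_cv < r0 - invasion_margin) "invasion" else "incomplete"
  }
  action <- c(one_way = "keep", multi_trip = "reject", invasion = "reject",
              incomplete = "extend")[[category]]
  tibble(run_id = attr(trajectory, "run_id") %||% NA_character_,
         category = category, action = action,
         first_crossing_ps = first_cross, min_cv_A = min_cv,
         return_events = as.integer(returns), inner_bias_frac = frac)
}

inner_bias_fraction <- function(primitive, inner_wall) {
  if (is.null(primitive) || is.na(inner_wall)) return(NA_real_)
  D <- primitive$D_A
  w <- -primitive$g_kcal # deposited bias is the negated FES
  tot <- integrand_trapz(D, w)
  if (tot <= 0) return(0)
  left <- D <= inner_wall
  if (sum(left) < 2) return(0)
  integrand_trapz(D[left], w[left]) / tot
}

#' Audit a replica ensemble and build the filtered member set
#'
#' Runs the correction process over a full ensemble: average all members,
#' locate the landmarks, classify every replica, then iterate — re-averaging
#' over the keepers only and re-locating the landmarks — until the verdict
#' set is stable (at most `max_iter` passes). Replicas flagged `extend`
#' remain outside the averaged set until they are extended and re-audited
#' (the campaign driver [run_campaign()] does this automatically).
#'
#' @param replicas A list; each element a list with `$trajectory` (a
#'   [cv_trajectory()]) and `$fes` (the replica's primitive `fes_profile`).
#' @inheritParams classify_run
#' @param max_iter Maximum filter/re-average passes.
#' @return A `dfe_audit` list: `verdicts` (tibble, one row per replica),
#'   `keep_ids`, `landmarks`, `averaged` (ensemble average over keepers),
#'   `iterations`, `stable`. Has [tidy()] and [glance()] methods.
#' @export
audit_ensemble <- function(replicas, hysteresis = 0.5, invasion_margin = 4,
                           max_iter = 5L) {
  stopifnot(length(replicas) >= 1)
  profiles <- purrr::map(replicas, "fes")
  trajs <- purrr::map(replicas, "trajectory")
  ids <- vapply(seq_along(replicas), function(i)
    attr(trajs[[i]], "run_id") %||% paste0("run", i), "")
  keep <- seq_along(replicas)
  verdicts <- NULL
  landmarks <- NULL
  iterations <- 0L
  stable <- FALSE
  repeat {
    iterations <- iterations + 1L
    avg <- average_fes(profiles[keep])
    landmarks <- locate_landmarks(avg)
    new_verdicts <- purrr::map_dfr(seq_along(replicas), function(i)
      classify_run(trajs[[i]], landmarks, primitive = profiles[[i]],
                   hysteresis = hysteresis,
                   invasion_margin = invasion_margin))
    new_verdicts$run_id <- ids
    new_keep <- which(new_verdicts$action == "keep")
    if (length(new_keep) == 0) {
      warn("audit rejected every replica; landmarks kept from the full ensemble")
      verdicts <- new_verdicts
      keep <- integer(0)
      break
    }
    if (!is.null(verdicts) && identical(new_verdicts$category,
                                        verdicts$category)) {
      verdicts <- new_verdicts
      stable <- TRUE
      break
    }
    verdicts <- new_verdicts
    keep <- new_keep
    if (iterations >= max_iter) break
  }
  keep <- which(verdicts$action == "keep")
  structure(
    list(verdicts = verdicts, keep_ids = ids[keep],
         landmarks = landmarks,
         averaged = average_fes(profiles[if (length(keep)) keep
                                         else seq_along(profiles)]),
         iterations = iterations, stable = stable),
    class = "dfe_audit"
  )
}

#' @export
print.dfe_audit <- function(x, ...) {
  counts <- table(x$verdicts$category)
  cat("Replica audit:", nrow(x$verdicts), "runs;",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  cat(sprintf("landmarks: r0 = %.2f A, rb = %.2f A, g_min = %.2f kcal/mol\n",
              x$landmarks$r0_A, x$landmarks$rb_A, x$landmarks$g_min_kcal))
  invisible(x)
}
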