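#' Tidiers for dfekit result objects
#'
#' broom-style accessors. `tidy()` returns one row per estimated term or per
#' replica; `glance()` returns a one-row model summary.
#'
#' @param x A `dfe_calibration`, `dfe_audit`, `dfe_result`, `dfe_convergence`
#'   or `dfe_campaign` object.
#' @param ... Unused; for generic consistency.
#' @return A tibble.
#' @name dfekit-tidiers
#' @examples
#' glance(fit_calibration(ppc_affinity_table(), exclude = "3SGB"))
NULL

#' @rdname dfekit-tidiers
#' @export
tidy.dfe_calibration <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(sm[, "Std. Error"]),
         statistic = unname(sm[, "t value"]),
         p.value = unname(sm[, "Pr(>|t|)"]))
}

#' @rdname dfekit-tidiers
#' @export
glance.dfe_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, r = unname(x$r), sigma = x$se,
         slope = x$slope, intercept = x$intercept, nobs = x$n,
         n.excluded = length(x$excluded_ids))
}

#' @rdname dfekit-tidiers
#' @export
tidy.dfe_audit <- function(x, ...) x$verdicts

#' @rdname dfekit-tidiers
#' @export
glance.dfe_audit <- function(x, ...) {
  v <- x$verdicts
  tibble(n_runs = nrow(v),
         n_one_way = sum(v$category == "one_way"),
         n_multi_trip = sum(v$category == "multi_trip"),
         n_invasion = sum(v$category == "invasion"),
         n_incomplete = sum(v$category == "incomplete"),
         r0_A = x$landmarks$r0_A, rb_A = x$landmarks$rb_A,
         iterations = x$iterations, stable = x$stable)
}

#' @rdname dfekit-tidiers
#' @export
glance.dfe_result <- function(x, ...) {
  tibble(dfe = x$dfe, uncertainty = x$uncertainty, Q = x$Q,
         temperature = x$temperature, a = x$a, b = x$b)
}

#' @rdname dfekit-tidiers
#' @export
tidy.dfe_convergence <- function(x, ...) {
  tibble(n = x$n, dfe = x$dfe)
}

#' @rdname dfekit-tidiers
#' @export
glance.dfe_convergence <- function(x, ...) {
  w <- attr(x, "window")
  last <- tail(x$dfe, w)
  tibble(n = nrow(x), converged = attr(x, "converged"),
         n_at_convergence = attr(x, "n_at_convergence"),
         window_spread = max(last) - min(last),
         dfe_final = x$dfe[nrow(x)])
}

#' @rdname dfekit-tidiers
#' @export
glance.dfe_campaign <- function(x, ...) {
  tibble(campaign_id = x$campaign_id, n_replicas = length(x$seeds),
         n_kept = sum(x$verdicts$action == "keep"),
         n_batches = x$n_batches,
         dfe = x$dfe$dfe, uncertainty = x$dfe$uncertainty,
         dfe_nc = x$dfe_nc$dfe, converged = x$converged)
}
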