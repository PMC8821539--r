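integrand_trapz <- function(D, y) pracma::trapz(D, y)

clip_profile <- function(profile, a, b) {
  D <- profile$D_A
  g <- profile$g_kcal
  lo <- D[1]
  hi <- D[length(D)]
  tol <- 1e-9 * (hi - lo)
  if (a < lo - tol || b > hi + tol)
    abort("[a, b] must lie inside the averaged grid range")
  a <- max(a, lo)
  b <- min(b, hi)
  if (b <= a) abort("requires a < b")
  inside <- D > a & D < b
  ga <- approx(D, g, xout = a, rule = 2)$y
  gb <- approx(D, g, xout = b, rule = 2)$y
  list(D = c(a, D[inside], b), g = c(ga, g[inside], gb), a = a, b = b)
}

#' Nominal partition function of an averaged FES
#'
#' \deqn{Q = (b-a)^{-1} \int_a^b \exp\{-g(D)/kT\}\, dD,}
#' evaluated by composite trapezoidal quadrature on the profile's own grid,
#' with linearly interpolated endpoint values when `a` or `b` falls between
#' grid points. `[a, b]` is the integration window over the bound-state
#' region; because the Boltzmann factor is narrowly concentrated around the
#' FES minimum, the defaults take the whole tabulated range (a = grid start,
#' b = grid end, i.e. out to the wall) without materially changing Q.
#'
#' @param averaged A `fes_profile` (normally kind `"averaged"`).
#' @param a,b Integration bounds (A); default to the grid range.
#' @param temperature Temperature (K).
#' @return The dimensionless nominal partition function (positive scalar).
#' @examples
#' flat <- fes_profile(seq(0, 10, 0.1), rep(0, 101), "averaged")
#' nominal_partition_function(flat)  # exactly 1
#' @export
nominal_partition_function <- function(averaged, a = NULL, b = NULL,
                                       temperature = 310) {
  stopifnot(inherits(averaged, "fes_profile"), temperature > 0)
  a <- a %||% averaged$D_A[1]
  b <- b %||% averaged$D_A[nrow(averaged)]
  cp <- clip_profile(averaged, a, b)
  kT <- kB() * temperature
  integrand_trapz(cp$D, exp(-cp$g / kT)) / (cp$b - cp$a)
}

#' Dissociation free energy from an averaged FES
#'
#' DFE = -kT ln Q, with Q the nominal partition function of the averaged
#' surface over `[a, b]`. DFE measures the work needed to push the system
#' out of the bound-state well; it is calibrated against experimental
#' binding free energies with [fit_calibration()].
#'
#' When the minimum is a few kcal/mol deep the Boltzmann integral is carried
#' entirely by the bottom of the well, so the bounds can be left at their
#' defaults (the full tabulated range, out to the wall) without locating the
#' bound/free boundary first. Narrowing the window then changes DFE only
#' through the explicit `kT ln(b - a)` normalization term of Q — a fixed
#' convention that the linear calibration absorbs.
#'
#' @inheritParams nominal_partition_function
#' @param members Optional list of member profiles; when supplied, a
#'   delete-one jackknife standard error over replicas is attached (see
#'   [dfe_uncertainty()]).
#' @return A `dfe_result` list: `Q`, `dfe` (kcal/mol), `temperature`, `a`,
#'   `b`, `uncertainty` (NA unless `members` given). Has a [glance()] method.
#' @examples
#' const <- fes_profile(seq(0, 10, 0.1), rep(-3, 101), "averaged")
#' dfe_from_fes(const)$dfe  # exactly -3
#' @export
dfe_from_fes <- function(averaged, temperature = 310, a = NULL, b = NULL,
                         members = NULL) {
  Q <- nominal_partition_function(averaged, a = a, b = b,
                                  temperature = temperature)
  kT <- kB() * temperature
  unc <- if (!is.null(members))
    dfe_uncertainty(members, temperature = temperature, a = a, b = b)
  else NA_real_
  structure(
    list(Q = Q, dfe = -kT * log(Q), temperature = temperature,
         a = a %||% averaged$D_A[1], b = b %||% averaged$D_A[nrow(averaged)],
         uncertainty = unc),
    class = "dfe_result"
  )
}

#' @export
print.dfe_result <- function(x, ...) {
  cat(sprintf("DFE = %.2f %s kcal/mol  (Q = %.4g, T = %g K, window [%.3g, %.3g] A)\n",
              x$dfe,
              if (is.na(x$uncertainty)) "" else sprintf("± %.2f", x$uncertainty),
              x$Q, x$temperature, x$a, x$b))
  invisible(x)
}

#' DFE convergence trace over replica count
#'
#' Recomputes DFE from the running ensemble average: entry N is the DFE of
#' the average of the first N member surfaces in launch order. Sampling is
#' declared converged when the spread (max - min) of the last five entries
#' is below 1 kcal/mol; at least five members are required before the flag
#' can be set.
#'
#' @param members Ordered list of `fes_profile` members (launch order).
#' @inheritParams nominal_partition_function
#' @param window Number of trailing entries in the convergence window.
#' @param tol_kcal Convergence threshold on the window spread (kcal/mol).
#' @return A `dfe_convergence` tibble with columns `n`, `dfe`, and attributes
#'   `converged` (logical) and `n_at_convergence` (first N at which the
#'   trailing window satisfies the rule, or NA).
#' @examples
#' m <- fes_profile(seq(0, 1, 0.01), rep(-2, 101), "averaged")
#' tr <- convergence_trace(rep(list(m), 5))
#' attr(tr, "converged")
#' @export
convergence_trace <- function(members, temperature = 310, a = NULL, b = NULL,
                              window = 5L, tol_kcal = 1) {
  if (length(members) < 1) abort("need at least one member")
  dfe_n <- vapply(seq_along(members), function(n) {
    dfe_from_fes(average_fes(members[seq_len(n)]), temperature = temperature,
                 a = a, b = b)$dfe
  }, 0)
  n_conv <- NA_integer_
  if (length(dfe_n) >= window) {
    for (n in seq(window, length(dfe_n))) {
      w <- dfe_n[(n - window + 1):n]
      if (max(w) - min(w) < tol_kcal) { n_conv <- n; break }
    }
  }
  last <- tail(dfe_n, window)
  converged <- length(dfe_n) >= window && (max(last) - min(last) < tol_kcal)
  out <- tibble(n = seq_along(dfe_n), dfe = dfe_n)
  attr(out, "converged") <- converged
  attr(out, "n_at_convergence") <- n_conv
  attr(out, "window") <- as.integer(window)
  attr(out, "tol_kcal") <- tol_kcal
  class(out) <- c("dfe_convergence", class(tibble()))
  out
}

#' Jackknife standard error of DFE over replicas
#'
#' Delete-one jackknife across member surfaces: DFE is recomputed on each
#' leave-one-out ensemble average and the jackknife standard error
#' \eqn{\sqrt{(n-1)/n \sum_i (\theta_{(i)} - \bar\theta)^2}} is returned.
#' This quantifies sampling completeness of the replica ensemble.
#'
#' @inheritParams convergence_trace
#' @return Standard error of DFE (kcal/mol).
#' @examples
#' m1 <- fes_profile(seq(0, 1, 0.01), rep(-2, 101), "averaged")
#' m2 <- fes_profile(seq(0, 1, 0.01), rep(-3, 101), "averaged")
#' dfe_uncertainty(list(m1, m2))  # half the DFE gap: 0.5
#' @export
dfe_uncertainty <- function(members, temperature = 310, a = NULL, b = NULL) {
  n <- length(members)
  if (n < 2) abort("jackknife needs at least 2 members")
  loo <- vapply(seq_len(n), function(i) {
    dfe_from_fes(average_fes(members[-i]), temperature = temperature,
                 a = a, b = b)$dfe
  }, 0)
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}
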