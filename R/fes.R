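#' Primitive free energy surface of one replica
#'
#' The FES estimate of a single metadynamics run is the negative image of its
#' accumulated bias: at CV value D,
#' \deqn{g(D) = -\sum_i h_i \exp\{-(D - d_i)^2 / 2\sigma_i^2\},}
#' summed over every kernel in the deposition record. The sampled CV region
#' — from the smallest to the largest kernel center — is divided into a
#' uniform grid of 80 points (79 equal intervals) and g is evaluated exactly
#' (no kernel truncation) at each point.
#'
#' @param sequence A [kernel_sequence()] with at least one kernel and a
#'   nondegenerate center range.
#' @return A `fes_profile` of kind `"primitive"` carrying the replica's
#'   `run_id`.
#' @examples
#' ks <- kernel_sequence(
#'   tibble::tibble(time_ps = c(0.09, 0.18, 0.27),
#'                  center_A = c(4, 5, 6), width_A = 0.05, height_kcal = 0.01),
#'   run_id = "r1", seed = 1L, wall_A = 12, duration_ns = 1
#' )
#' fes <- primitive_fes(ks)
#' range(fes$D_A)  # spans the kernel centers
#' @export
primitive_fes <- function(sequence) {
  stopifnot(inherits(sequence, "kernel_seq"))
  if (nrow(sequence) == 0) abort("empty deposition history")
  lo <- min(sequence$center_A)
  hi <- max(sequence$center_A)
  if (hi - lo <= 0)
    abort("degenerate deposition history: all kernel centers coincide")
  grid <- seq(lo, hi, length.out = 80L)
  g <- -sum_gaussians(grid, sequence$center_A, sequence$width_A,
                      sequence$height_kcal)
  fes_profile(grid, g, kind = "primitive", run_id = attr(sequence, "run_id"))
}

#' Linear interpolation between two FES points
#'
#' The one-segment interpolation primitive used when member surfaces are
#' resampled onto the common ensemble grid:
#' \deqn{g = g_1 + (D - D_1)\,(g_2 - g_1)/(D_2 - D_1).}
#'
#' @param D Query CV value(s), each inside `[D1, D2]`.
#' @param D1,D2 Bracketing CV values, `D1 < D2`.
#' @param g1,g2 Free energy values at `D1` and `D2`.
#' @return Interpolated free energy value(s).
#' @examples
#' interpolate_linear(1.5, 1, -1, 2, -3)  # -2
#' @export
interpolate_linear <- function(D, D1, g1, D2, g2) {
  if (D2 <= D1) abort("requires D1 < D2")
  if (any(D < D1) || any(D > D2)) abort("D must lie within [D1, D2]")
  g1 + (D - D1) * (g2 - g1) / (D2 - D1)
}

#' Average an ensemble of primitive surfaces onto a common grid
#'
#' The common grid spans the union of the member ranges (the lowest and
#' highest CV values visited by any member), with uniform spacing no larger
#' than the smallest member spacing (the union range is divided into
#' `ceiling(range / h_min)` equal intervals). Each member is resampled onto
#' this grid by linear interpolation inside its own sampled range and
#' contributes zero outside it (an unvisited region holds no accumulated
#' bias); the ensemble value at each grid point is the arithmetic mean over
#' all members, zeros included.
#'
#' @param members A list of `fes_profile` objects (normally primitive).
#' @return A `fes_profile` of kind `"averaged"` and class `ensemble_fes`,
#'   with attributes `member_ids` and `n_members`.
#' @examples
#' f1 <- fes_profile(seq(0, 1, length.out = 11), rep(-1, 11), "averaged")
#' f2 <- fes_profile(seq(0, 1, length.out = 11), rep(-3, 11), "averaged")
#' avg <- average_fes(list(f1, f2))
#' unique(avg$g_kcal)  # -2
#' @export
average_fes <- function(members) {
  if (is.null(members) || length(members) == 0)
    abort("need at least one member profile")
  stopifnot(all(vapply(members, inherits, TRUE, "fes_profile")))
  lows <- vapply(members, function(m) m$D_A[1], 0)
  highs <- vapply(members, function(m) m$D_A[nrow(m)], 0)
  h_min <- min(vapply(members, fes_spacing, 0))
  lo <- min(lows)
  hi <- max(highs)
  n_int <- max(1L, as.integer(ceiling((hi - lo) / h_min - 1e-9)))
  grid <- seq(lo, hi, length.out = n_int + 1L)
  eps <- 1e-9 * (hi - lo)
  vals <- vapply(members, function(m) {
    y <- approx(m$D_A, m$g_kcal, xout = grid, rule = 1)$y
    # grid points within round-off of a member endpoint belong to the member
    edge <- is.na(y) & grid >= m$D_A[1] - eps & grid <= m$D_A[nrow(m)] + eps
    if (any(edge))
      y[edge] <- approx(m$D_A, m$g_kcal, xout = grid[edge], rule = 2)$y
    y[is.na(y)] <- 0
    y
  }, numeric(length(grid)))
  avg <- rowMeans(vals)
  ids <- vapply(seq_along(members), function(i)
    attr(members[[i]], "run_id") %||% paste0("member", i), "")
  out <- fes_profile(grid, avg, kind = "averaged")
  attr(out, "member_ids") <- ids
  attr(out, "n_members") <- length(members)
  class(out) <- c("ensemble_fes", class(out))
  out
}
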