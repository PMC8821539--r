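#' Model potentials for the toy dissociation simulator
#'
#' One-dimensional stand-ins for the free-energy landscape a bound complex
#' presents along its dissociation coordinate. All forms share an inner
#' repulsive harmonic branch below the well position (the molecular "cannot
#' interpenetrate" wall) so the CV cannot drift to zero for free:
#'
#' * `harmonic_well`: \eqn{U(D) = \kappa (D - r_w)^2 / 2 - U_0} everywhere
#'   (confining on both sides; used for equipartition checks).
#' * `piecewise_well_flat`: the same parabola, truncated at zero where it
#'   crosses it on the dissociation side, flat (U = 0) beyond — a single
#'   bound well opening onto a free region. This is the default benchmark
#'   landscape.
#' * `double_well`: a second truncated well at `r_w2` (depth `U0_2`,
#'   curvature `kappa2`), flat elsewhere; the wells must not overlap.
#' * `flat`: U = 0 everywhere (free diffusion; histogram checks).
#'
#' @param form Potential form name.
#' @param r_w Well position (A).
#' @param U0 Well depth (kcal/mol, > 0 for welled forms).
#' @param kappa Curvature (kcal mol-1 A-2).
#' @param r_w2,U0_2,kappa2 Second-well parameters (`double_well` only).
#' @return An object of class `model_potential`.
#' @examples
#' pot <- model_potential("piecewise_well_flat", r_w = 5, U0 = 12, kappa = 50)
#' potential_energy(pot, c(4, 5, 6, 8))
#' @export
model_potential <- function(form = c("piecewise_well_flat", "harmonic_well",
                                     "double_well", "flat"),
                            r_w = 5, U0 = 12, kappa = 50,
                            r_w2 = NULL, U0_2 = NULL, kappa2 = NULL) {
  form <- match.arg(form)
  if (form != "flat") {
    stopifnot(U0 > 0, kappa > 0, r_w >= 0)
  }
  if (form == "double_well") {
    if (is.null(r_w2) || is.null(U0_2) || is.null(kappa2))
      abort("double_well needs r_w2, U0_2 and kappa2")
    stopifnot(U0_2 > 0, kappa2 > 0)
    rim1 <- r_w + sqrt(2 * U0 / kappa)
    if (r_w2 - sqrt(2 * U0_2 / kappa2) <= rim1)
      abort("double_well wells overlap; move r_w2 further out")
  }
  structure(
    list(form = form, r_w = r_w, U0 = U0, kappa = kappa,
         r_w2 = r_w2, U0_2 = U0_2, kappa2 = kappa2),
    class = "model_potential"
  )
}

# numeric encoding shared with the compiled integrator
pot_code <- function(pot) {
  switch(pot$form, flat = 0L, harmonic_well = 1L,
         piecewise_well_flat = 2L, double_well = 3L)
}

pot_params <- function(pot) {
  c(pot$r_w %||% 0, pot$U0 %||% 0, pot$kappa %||% 1,
    pot$r_w2 %||% 0, pot$U0_2 %||% 0, pot$kappa2 %||% 1)
}

#' @rdname model_potential
#' @param pot A `model_potential`.
#' @param D Numeric vector of CV values (A).
#' @export
potential_energy <- function(pot, D) {
  w1 <- 0.5 * pot$kappa * (D - pot$r_w)^2 - pot$U0
  switch(pot$form,
    flat = rep(0, length(D)),
    harmonic_well = w1,
    piecewise_well_flat = {
      rim <- pot$r_w + sqrt(2 * pot$U0 / pot$kappa)
      ifelse(D < rim, w1, 0)
    },
    double_well = {
      rim1 <- pot$r_w + sqrt(2 * pot$U0 / pot$kappa)
      half2 <- sqrt(2 * pot$U0_2 / pot$kappa2)
      w2 <- 0.5 * pot$kappa2 * (D - pot$r_w2)^2 - pot$U0_2
      ifelse(D < rim1, w1, ifelse(abs(D - pot$r_w2) < half2, w2, 0))
    }
  )
}

#' @rdname model_potential
#' @export
potential_force <- function(pot, D) {
  f1 <- -pot$kappa * (D - pot$r_w)
  switch(pot$form,
    flat = rep(0, length(D)),
    harmonic_well = f1,
    piecewise_well_flat = {
      rim <- pot$r_w + sqrt(2 * pot$U0 / pot$kappa)
      ifelse(D < rim, f1, 0)
    },
    double_well = {
      rim1 <- pot$r_w + sqrt(2 * pot$U0 / pot$kappa)
      half2 <- sqrt(2 * pot$U0_2 / pot$kappa2)
      f2 <- -pot$kappa2 * (D - pot$r_w2)
      ifelse(D < rim1, f1, ifelse(abs(D - pot$r_w2) < half2, f2, 0))
    }
  )
}

#' Analytic reference FES of a model potential
#'
#' Tabulates the model potential on a uniform grid as an `"averaged"`-kind
#' FES profile, so it can be pushed through the same partition-function
#' machinery as a simulated ensemble surface (the bias-free reference the
#' simulated campaigns are benchmarked against).
#'
#' @param pot A [model_potential()].
#' @param from,to Grid range (A).
#' @param n Number of grid points.
#' @return A `fes_profile` of kind `"averaged"`.
#' @examples
#' ref <- reference_fes(model_potential("piecewise_well_flat"), 3, 12, 1801)
#' @export
reference_fes <- function(pot, from, to, n = 1001) {
  D <- seq(from, to, length.out = n)
  fes_profile(D, potential_energy(pot, D), kind = "averaged",
              run_id = "analytic_reference")
}
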