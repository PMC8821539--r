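#' Plot methods for dfekit objects
#'
#' ggplot2 `autoplot()` methods: a free energy surface (with optional
#' bound-state landmarks), a CV-versus-time trajectory, the DFE-versus-N
#' convergence trace, and the calibration scatter with its fitted line
#' (excluded outliers drawn as open circles).
#'
#' @param object The object to plot.
#' @param landmarks Optional [locate_landmarks()] result; adds r0/rb guides.
#' @param ... Unused.
#' @return A ggplot object.
#' @name dfekit-autoplot
NULL

#' @rdname dfekit-autoplot
#' @export
autoplot.fes_profile <- function(object, landmarks = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$D_A, y = .data$g_kcal)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "CV distance D (Å)", y = "g(D) (kcal/mol)",
                  title = paste0(attr(object, "kind"), " FES",
                                 if (!is.null(attr(object, "run_id")))
                                   paste0(" — ", attr(object, "run_id"))))
  if (!is.null(landmarks))
    p <- p + ggplot2::geom_vline(xintercept = c(landmarks$r0_A,
                                                landmarks$rb_A),
                                 linetype = "dashed", color = "firebrick")
  p
}

#' @rdname dfekit-autoplot
#' @export
autoplot.cv_traj <- function(object, landmarks = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time_ps, y = .data$D_A)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::labs(x = "time (ps)", y = "D (Å)",
                  title = attr(object, "run_id"))
  if (!is.null(landmarks))
    p <- p + ggplot2::geom_hline(yintercept = c(landmarks$r0_A,
                                                landmarks$rb_A),
                                 linetype = "dashed", color = "firebrick")
  p
}

#' @rdname dfekit-autoplot
#' @export
autoplot.dfe_convergence <- function(object, ...) {
  df <- tibble(n = object$n, dfe = object$dfe)
  w <- attr(object, "window")
  last <- tail(df, w)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$dfe)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::annotate("rect", xmin = min(last$n), xmax = max(last$n),
                      ymin = min(last$dfe), ymax = max(last$dfe),
                      alpha = 0.2, fill = "steelblue") +
    ggplot2::labs(x = "replicas averaged (N)", y = "DFE (kcal/mol)",
                  subtitle = if (attr(object, "converged"))
                    "converged (last-five spread < 1 kcal/mol)"
                  else "not converged")
}

#' @rdname dfekit-autoplot
#' @export
autoplot.dfe_calibration <- function(object, ...) {
  used <- object$data
  ggplot2::ggplot(used, ggplot2::aes(x = .data$dfe, y = .data$dg_exp)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "DFE (kcal/mol)", y = expression(Delta * G[e] ~ "(kcal/mol)"),
      subtitle = sprintf("R² = %.2f, SE = %.2f kcal/mol, n = %d",
                         object$r_squared, object$se, object$n))
}

#' @rdname dfekit-autoplot
#' @export
autoplot.dfe_campaign <- function(object, ...) {
  autoplot(object$convergence) +
    ggplot2::ggtitle(paste0("campaign '", object$campaign_id, "'"))
}

#' Overlay member surfaces on the ensemble average
#'
#' @param members List of primitive `fes_profile` objects.
#' @param averaged The ensemble average (optional; computed if missing).
#' @return A ggplot object.
#' @export
plot_fes_ensemble <- function(members, averaged = NULL) {
  averaged <- averaged %||% average_fes(members)
  mem <- purrr::map_dfr(seq_along(members), function(i) {
    tibble(member = attr(members[[i]], "run_id") %||% paste0("member", i),
           D_A = members[[i]]$D_A, g_kcal = members[[i]]$g_kcal)
  })
  ggplot2::ggplot(mem, ggplot2::aes(x = .data$D_A, y = .data$g_kcal,
                                    group = .data$member)) +
    ggplot2::geom_line(alpha = 0.25, color = "grey40") +
    ggplot2::geom_line(data = as_tibble(averaged),
                       ggplot2::aes(group = NULL), color = "firebrick",
                       linewidth = 0.8) +
    ggplot2::labs(x = "CV distance D (Å)", y = "g(D) (kcal/mol)")
}
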