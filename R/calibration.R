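#' Convert a dissociation constant to an experimental binding free energy
#'
#' \eqn{\Delta G_e = kT \ln K_d}, with `kd` in molar (1 M standard state
#' implicit) and the temperature fixed at the simulation temperature of
#' 310 K by default.
#'
#' @param kd Dissociation constant(s), molar; must be positive.
#' @param temperature Temperature (K).
#' @return Binding free energy (kcal/mol). `dg_to_kd()` is the exact inverse.
#' @examples
#' kd_to_dg(2.4e-14)  # -19.32 kcal/mol at 310 K
#' dg_to_kd(kd_to_dg(1e-9))
#' @export
kd_to_dg <- function(kd, temperature = 310) {
  if (any(kd <= 0)) abort("kd must be > 0 (molar)")
  stopifnot(temperature > 0)
  kB() * temperature * log(kd)
}

#' @rdname kd_to_dg
#' @param dg Binding free energy (kcal/mol).
#' @export
dg_to_kd <- function(dg, temperature = 310) {
  stopifnot(temperature > 0)
  exp(dg / (kB() * temperature))
}

#' Fit the linear DFE-to-binding-free-energy calibration
#'
#' Ordinary least squares of the experimental binding free energy
#' \eqn{\Delta G_e} on the calculated DFE, optionally excluding named
#' outliers. The residual standard error uses n - 2 degrees of freedom.
#'
#' @param records A data frame with columns `complex_id`, `dfe` (kcal/mol)
#'   and `dg_exp` (kcal/mol); e.g. [ppc_affinity_table()].
#' @param exclude Character vector of `complex_id` values to drop before
#'   fitting (explicit, by identifier only — no automatic outlier hunting).
#' @return A `dfe_calibration` object: `slope`, `intercept` (kcal/mol),
#'   `r_squared`, `r` (signed correlation), `se` (residual standard error,
#'   kcal/mol), `n`, `excluded_ids`, plus the underlying `lm` fit and data.
#'   Has [tidy()], [glance()], [autoplot()] and [predict_dg()] methods.
#' @examples
#' fit <- fit_calibration(ppc_affinity_table(), exclude = "3SGB")
#' round(c(fit$slope, fit$intercept, fit$r_squared), 3)
#' @export
fit_calibration <- function(records, exclude = character()) {
  records <- as_tibble(records)
  need <- c("complex_id", "dfe", "dg_exp")
  if (!all(need %in% names(records)))
    abort(paste("records must have columns:", paste(need, collapse = ", ")))
  used <- records[!records$complex_id %in% exclude, ]
  if (nrow(used) < 3) abort("need at least 3 records after exclusion")
  if (anyNA(used$dfe) || anyNA(used$dg_exp))
    abort("records contain missing dfe or dg_exp values")
  if (var(used$dfe) == 0) abort("degenerate fit: all dfe values identical")
  fit <- lm(dg_exp ~ dfe, data = used)
  sm <- summary(fit)
  structure(
    list(slope = unname(coef(fit)["dfe"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         r_squared = sm$r.squared,
         r = unname(sign(coef(fit)["dfe"])) * sqrt(sm$r.squared),
         se = sm$sigma, n = nrow(used),
         excluded_ids = intersect(exclude, records$complex_id),
         model = fit, data = used),
    class = "dfe_calibration"
  )
}

#' Predict a calibrated binding free energy from DFE
#'
#' Applies the fitted affine map: \eqn{\Delta G_c =} `slope` * dfe +
#' `intercept`.
#'
#' @param fit A [fit_calibration()] result, or a list with `slope` and
#'   `intercept`.
#' @param dfe DFE value(s), kcal/mol.
#' @return Calculated binding free energy \eqn{\Delta G_c} (kcal/mol).
#' @examples
#' predict_dg(list(slope = 0.4512, intercept = -1.02), -32.42)  # ~ -15.65
#' @export
predict_dg <- function(fit, dfe) {
  fit$slope * dfe + fit$intercept
}

#' @export
print.dfe_calibration <- function(x, ...) {
  cat(sprintf("dG_e = %.4f DFE %+.2f   (R^2 = %.2f, R = %.2f, SE = %.2f kcal/mol, n = %d%s)\n",
              x$slope, x$intercept, x$r_squared, x$r, x$se, x$n,
              if (length(x$excluded_ids))
                paste0("; excluded: ", paste(x$excluded_ids, collapse = ", "))
              else ""))
  invisible(x)
}

#' Aggregate per-target correlation statistics into a panel summary
#'
#' Unweighted arithmetic means of the per-target R-squared and standard
#' error, with an optional substitution map for outlier-excluded variants
#' (e.g. replacing a target's all-points R-squared with its value after
#' excluding named outliers).
#'
#' @param panel A data frame with columns `target`, `r_squared` and
#'   (optionally) `se`; e.g. [plc_panel_table()].
#' @param r_squared_sub,se_sub Named numeric vectors (names = targets) whose
#'   values replace the corresponding entries before averaging.
#' @return A one-row tibble: `n_targets`, `mean_r_squared`, `mean_se`.
#' @examples
#' aggregate_panel(plc_panel_table())$mean_r_squared          # 0.45
#' aggregate_panel(plc_panel_table(),
#'                 r_squared_sub = c(Thrombin = 0.62))$mean_r_squared
#' @export
aggregate_panel <- function(panel, r_squared_sub = NULL, se_sub = NULL) {
  panel <- as_tibble(panel)
  if (nrow(panel) == 0) abort("panel must be nonempty")
  if (!all(c("target", "r_squared") %in% names(panel)))
    abort("panel must have columns target and r_squared")
  sub_into <- function(x, subs) {
    if (is.null(subs)) return(x)
    miss <- setdiff(names(subs), panel$target)
    if (length(miss)) abort(paste("unknown targets:", paste(miss, collapse = ", ")))
    x[match(names(subs), panel$target)] <- subs
    x
  }
  r2 <- sub_into(panel$r_squared, r_squared_sub)
  se <- if ("se" %in% names(panel)) sub_into(panel$se, se_sub) else NA_real_
  tibble(n_targets = nrow(panel), mean_r_squared = mean(r2),
         mean_se = mean(se))
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "dfekit", mustWork = TRUE)
  as_tibble(utils::read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE))
}

#' Published reference tables
#'
#' The printed benchmark tables shipped as plain-text fixtures, at printed
#' precision.
#'
#' * `ppc_affinity_table()`: 19 non-congeneric protein-protein complexes —
#'   complex id (PDB code), interaction type, CV definition, calculated DFE
#'   with its sampling standard error, calibrated \eqn{\Delta G_c},
#'   experimental \eqn{\Delta G_e} and dissociation constant `kd` (M).
#'   The 3SGB complex is the documented calibration outlier.
#' * `ppc_corrections_table()`: the same panel before/after the one-way-trip
#'   correction process — run count, per-run chemical time, the applied
#'   corrections, and the corrected (`dfe`, `dg_calc`) versus uncorrected
#'   (`dfe_nc`, `dg_calc_nc`) values.
#' * `plc_panel_table()`: per-target summaries for eight protein-ligand
#'   panels — ligand count, run settings, `r_squared` and `se` of the
#'   per-target DFE calibration and its printed slope/intercept. For
#'   Thrombin the columns `r_squared_excl`, `se_excl` hold the values after
#'   excluding its two outlier ligands, and the printed slope/intercept
#'   correspond to that outlier-excluded fit.
#'
#' @return A tibble.
#' @examples
#' ppc_affinity_table()[1, c("complex_id", "dfe", "dg_exp")]
#' @export
ppc_affinity_table <- function() {
  tb <- read_fixture("ppc_affinity.tsv")
  tb$kd <- as.numeric(tb$kd)
  tb
}

#' @rdname ppc_affinity_table
#' @export
ppc_corrections_table <- function() read_fixture("ppc_corrections.tsv")

#' @rdname ppc_affinity_table
#' @export
plc_panel_table <- function() read_fixture("plc_panels.tsv")
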