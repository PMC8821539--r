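#' Deposition-record containers
#'
#' Constructors and validators for the three tabular objects the pipeline
#' passes around: a kernel sequence (the time-ordered record of every Gaussian
#' deposited in one metadynamics replica), a CV-versus-time trajectory, and a
#' tabulated free energy surface. All are tibbles carrying their run metadata
#' as attributes, so they pipe through dplyr verbs; the validators enforce the
#' physical invariants (positive widths and heights, strictly increasing
#' times, centers inside the walled region, uniform FES grids).
#'
#' Units are fixed package-wide: angstrom for the CV, picoseconds for chemical
#' time (nanoseconds for run durations in headers), kcal/mol for energies.
#'
#' @param kernels A data frame with columns `time_ps`, `center_A`, `width_A`,
#'   `height_kcal`, one row per deposition event in time order.
#' @param run_id Character identifier of the replica.
#' @param seed Integer random seed the replica was generated with.
#' @param wall_A Position of the restraining wall (angstrom). Deposition
#'   centers may exceed it by at most 0.5 A (the wall is half-harmonic, so
#'   small excursions beyond it are legal).
#' @param duration_ns Total simulated chemical time (ns).
#' @param final_cv,final_step Integrator state at the end of the run (CV value
#'   and global step index); required by [extend_run()].
#' @return `kernel_sequence()` a `kernel_seq` tibble; `cv_trajectory()` a
#'   `cv_traj` tibble; `fes_profile()` a `fes_profile` tibble.
#' @seealso [read_kernel_sequence()], [simulate_run()], [primitive_fes()]
#' @examples
#' ks <- kernel_sequence(
#'   tibble::tibble(time_ps = 0.09, center_A = 5, width_A = 0.05,
#'                  height_kcal = 0.01),
#'   run_id = "r1", seed = 1L, wall_A = 12, duration_ns = 0.001
#' )
#' attr(ks, "wall_A")
#' @export
kernel_sequence <- function(kernels, run_id, seed, wall_A, duration_ns,
                            final_cv = NULL, final_step = NULL) {
  kernels <- as_tibble(kernels)
  need <- c("time_ps", "center_A", "width_A", "height_kcal")
  if (!all(need %in% names(kernels)))
    abort(paste("kernel table must have columns:", paste(need, collapse = ", ")))
  ks <- kernels[need]
  attr(ks, "run_id") <- as.character(run_id)
  attr(ks, "seed") <- as.integer(seed)
  attr(ks, "wall_A") <- as.numeric(wall_A)
  attr(ks, "duration_ns") <- as.numeric(duration_ns)
  attr(ks, "final_cv") <- if (is.null(final_cv)) NULL else as.numeric(final_cv)
  attr(ks, "final_step") <- if (is.null(final_step)) NULL else as.numeric(final_step)
  class(ks) <- c("kernel_seq", class(tibble()))
  validate_kernel_seq(ks)
}

validate_kernel_seq <- function(ks) {
  if (nrow(ks) > 0) {
    if (any(ks$width_A <= 0)) abort("kernel widths must be > 0")
    if (any(ks$height_kcal <= 0)) abort("kernel heights must be > 0")
    if (any(ks$time_ps < 0)) abort("kernel times must be >= 0")
    if (nrow(ks) > 1 && any(diff(ks$time_ps) <= 0))
      abort("kernel times must be strictly increasing")
    wall <- attr(ks, "wall_A")
    if (any(ks$center_A < 0) || any(ks$center_A > wall + 0.5))
      abort("kernel centers must lie in [0, wall_A] (+0.5 A wall-excursion tolerance)")
  }
  ks
}

#' @rdname kernel_sequence
#' @param times,values Numeric vectors of chemical time (ps) and CV value (A),
#'   equal length, times strictly increasing.
#' @export
cv_trajectory <- function(times, values, run_id, wall_A = NULL,
                          final_step = NULL) {
  if (length(times) != length(values))
    abort("times and values must have the same length")
  if (length(times) == 0) abort("trajectory must be nonempty")
  if (length(times) > 1 && any(diff(times) <= 0))
    abort("trajectory times must be strictly increasing")
  if (any(values < 0)) abort("CV values must be >= 0")
  if (!is.null(wall_A) && any(values > wall_A + 1))
    abort("CV values exceed wall_A beyond tolerance")
  tr <- tibble(time_ps = as.numeric(times), D_A = as.numeric(values))
  attr(tr, "run_id") <- as.character(run_id)
  attr(tr, "wall_A") <- if (is.null(wall_A)) NULL else as.numeric(wall_A)
  attr(tr, "final_step") <- if (is.null(final_step)) NULL else as.numeric(final_step)
  class(tr) <- c("cv_traj", class(tibble()))
  tr
}

#' @rdname kernel_sequence
#' @param D,g Numeric vectors: uniformly spaced ascending CV grid (A) and the
#'   free energy values on it (kcal/mol).
#' @param kind `"primitive"` (a single replica's surface; exactly 80 points,
#'   energies <= 0) or `"averaged"` (an ensemble mean; any length).
#' @export
fes_profile <- function(D, g, kind = c("primitive", "averaged"),
                        run_id = NULL) {
  kind <- match.arg(kind)
  if (length(D) != length(g)) abort("grid and energies must have equal length")
  if (length(D) < 2) abort("FES needs at least 2 grid points")
  dd <- diff(D)
  if (any(dd <= 0)) abort("FES grid must be strictly ascending")
  if (max(dd) - min(dd) > 1e-9 * max(abs(dd)))
    abort("FES grid must be uniformly spaced (1e-9 relative tolerance)")
  if (kind == "primitive") {
    if (length(D) != 80) abort("a primitive FES has exactly 80 grid points")
    if (any(g > 1e-12))
      abort("primitive FES energies must be <= 0 (negated accumulated bias)")
  }
  fp <- tibble(D_A = as.numeric(D), g_kcal = as.numeric(g))
  attr(fp, "kind") <- kind
  attr(fp, "run_id") <- if (is.null(run_id)) NULL else as.character(run_id)
  class(fp) <- c("fes_profile", class(tibble()))
  fp
}

fes_spacing <- function(fp) (fp$D_A[nrow(fp)] - fp$D_A[1]) / (nrow(fp) - 1)

UNITS_LINE <- "A ps kcal/mol"

fmt_full <- function(x) sprintf("%.17g", x)

parse_header <- function(lines, path) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", hdr))
  kv <- kv[lengths(kv) == 3]
  as.list(setNames(vapply(kv, `[`, "", 3), vapply(kv, `[`, "", 2)))
}

check_units <- function(hdr, path) {
  u <- hdr[["units"]]
  if (is.null(u))
    abort(paste0(path, ": missing '# units=' header line"))
  ok <- gsub("Å", "A", u) # accept the angstrom glyph
  if (!identical(ok, UNITS_LINE))
    abort(paste0(path, ": units must be '", UNITS_LINE, "', found '", u, "'"))
}

read_numeric_rows <- function(lines, n_cols, path) {
  is_data <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[is_data]
  if (length(data_lines) == 0)
    return(matrix(numeric(0), ncol = n_cols))
  vals <- tryCatch(
    suppressWarnings(scan(text = paste(data_lines, collapse = "\n"),
                          quiet = TRUE, what = numeric())),
    error = function(e) NA_real_
  )
  if (anyNA(vals) || length(vals) %% n_cols != 0) {
    # slow path: locate the offending physical line
    lineno <- which(is_data)
    for (j in seq_along(data_lines)) {
      fields <- strsplit(trimws(data_lines[j]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(fields))
      if (length(fields) != n_cols || anyNA(v))
        abort(paste0(path, ": malformed row at line ", lineno[j],
                     " (expected ", n_cols, " numeric fields)"))
    }
    abort(paste0(path, ": malformed numeric data"))
  }
  matrix(vals, ncol = n_cols, byrow = TRUE)
}

hdr_num <- function(hdr, key, path) {
  v <- hdr[[key]]
  if (is.null(v)) abort(paste0(path, ": missing '# ", key, "=' header line"))
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) abort(paste0(path, ": header key '", key, "' is not numeric"))
  out
}

#' Read and write kernel-sequence, trajectory and FES files
#'
#' Plain-text, diff-friendly dialects with `#`-prefixed `key=value` headers
#' followed by whitespace-separated numeric rows, written at full double
#' precision so a write/read round trip is bit-exact. Every file must declare
#' its units (`# units=A ps kcal/mol`); readers reject anything else.
#' File extensions by convention: `.kerseq.tsv`, `.cv.tsv`, `.fes.tsv`.
#'
#' @param path File path.
#' @param ks,traj,profile The object to write.
#' @return Readers return the corresponding container (see
#'   [kernel_sequence()]); writers return `path` invisibly.
#' @examples
#' ks <- kernel_sequence(
#'   tibble::tibble(time_ps = c(0.09, 0.18), center_A = c(5, 5.1),
#'                  width_A = 0.05, height_kcal = 0.01),
#'   run_id = "r1", seed = 7L, wall_A = 12, duration_ns = 0.00018
#' )
#' f <- tempfile(fileext = ".kerseq.tsv")
#' write_kernel_sequence(ks, f)
#' identical(read_kernel_sequence(f)$center_A, ks$center_A)
#' @export
read_kernel_sequence <- function(path) {
  if (!file.exists(path)) abort(paste0(path, ": no such file"))
  lines <- readLines(path)
  hdr <- parse_header(lines, path)
  check_units(hdr, path)
  m <- read_numeric_rows(lines, 4L, path)
  kernel_sequence(
    tibble(time_ps = m[, 1], center_A = m[, 2], width_A = m[, 3],
           height_kcal = m[, 4]),
    run_id = hdr[["run_id"]] %||% abort(paste0(path, ": missing run_id header")),
    seed = hdr_num(hdr, "seed", path),
    wall_A = hdr_num(hdr, "wall_A", path),
    duration_ns = hdr_num(hdr, "duration_ns", path),
    final_cv = if (!is.null(hdr[["final_cv_A"]])) hdr_num(hdr, "final_cv_A", path),
    final_step = if (!is.null(hdr[["final_step"]])) hdr_num(hdr, "final_step", path)
  )
}

#' @rdname read_kernel_sequence
#' @export
write_kernel_sequence <- function(ks, path) {
  validate_kernel_seq(ks)
  hdr <- c(
    paste0("# run_id=", attr(ks, "run_id")),
    paste0("# seed=", attr(ks, "seed")),
    paste0("# wall_A=", fmt_full(attr(ks, "wall_A"))),
    paste0("# duration_ns=", fmt_full(attr(ks, "duration_ns"))),
    if (!is.null(attr(ks, "final_cv")))
      paste0("# final_cv_A=", fmt_full(attr(ks, "final_cv"))),
    if (!is.null(attr(ks, "final_step")))
      paste0("# final_step=", fmt_full(attr(ks, "final_step"))),
    paste0("# units=", UNITS_LINE),
    "# columns=time_ps center_A width_A height_kcal"
  )
  rows <- paste(fmt_full(ks$time_ps), fmt_full(ks$center_A),
                fmt_full(ks$width_A), fmt_full(ks$height_kcal), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname read_kernel_sequence
#' @export
read_cv_trajectory <- function(path) {
  if (!file.exists(path)) abort(paste0(path, ": no such file"))
  lines <- readLines(path)
  hdr <- parse_header(lines, path)
  check_units(hdr, path)
  m <- read_numeric_rows(lines, 2L, path)
  cv_trajectory(
    m[, 1], m[, 2],
    run_id = hdr[["run_id"]] %||% abort(paste0(path, ": missing run_id header")),
    wall_A = if (!is.null(hdr[["wall_A"]])) hdr_num(hdr, "wall_A", path),
    final_step = if (!is.null(hdr[["final_step"]])) hdr_num(hdr, "final_step", path)
  )
}

#' @rdname read_kernel_sequence
#' @export
write_cv_trajectory <- function(traj, path) {
  hdr <- c(
    paste0("# run_id=", attr(traj, "run_id")),
    if (!is.null(attr(traj, "wall_A")))
      paste0("# wall_A=", fmt_full(attr(traj, "wall_A"))),
    if (!is.null(attr(traj, "final_step")))
      paste0("# final_step=", fmt_full(attr(traj, "final_step"))),
    paste0("# units=", UNITS_LINE),
    "# columns=time_ps D_A"
  )
  writeLines(c(hdr, paste(fmt_full(traj$time_ps), fmt_full(traj$D_A),
                          sep = "\t")), path)
  invisible(path)
}

#' @rdname read_kernel_sequence
#' @export
read_fes <- function(path) {
  if (!file.exists(path)) abort(paste0(path, ": no such file"))
  lines <- readLines(path)
  hdr <- parse_header(lines, path)
  check_units(hdr, path)
  kind <- hdr[["kind"]]
  if (is.null(kind) || !kind %in% c("primitive", "averaged"))
    abort(paste0(path, ": missing or invalid '# kind=' header (primitive|averaged)"))
  m <- read_numeric_rows(lines, 2L, path)
  fes_profile(m[, 1], m[, 2], kind = kind, run_id = hdr[["run_id"]])
}

#' @rdname read_kernel_sequence
#' @export
write_fes <- function(profile, path) {
  # re-validate: constructor invariants must still hold at write time
  profile <- fes_profile(profile$D_A, profile$g_kcal, attr(profile, "kind"),
                         run_id = attr(profile, "run_id"))
  hdr <- c(
    paste0("# kind=", attr(profile, "kind")),
    if (!is.null(attr(profile, "run_id")))
      paste0("# run_id=", attr(profile, "run_id")),
    paste0("# units=", UNITS_LINE),
    "# columns=D_A g_kcal_per_mol"
  )
  writeLines(c(hdr, paste(fmt_full(profile$D_A), fmt_full(profile$g_kcal),
                          sep = "\t")), path)
  invisible(path)
}
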