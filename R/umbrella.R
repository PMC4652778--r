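# Harmonic umbrella-window model on the (CPDb, chi) plane. The bias at a
# rectangular grid point is U = k_cpdb * dCPDb^2 + k_chi * dchi^2 with no 1/2
# prefactor (the printed convention); each displacement is the minimal-image
# wrapped difference, in radians by default.

#' A single harmonic umbrella window
#'
#' @param id Integer identifier (1-based position in its grid).
#' @param cpdb0,chi0 Window centre in degrees (wrapped on construction).
#' @param k_cpdb,k_chi Non-negative force constants; kcal/mol/rad^2 under
#'   the default unit convention.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(id, cpdb0, chi0, k_cpdb = 100, k_chi = 50) {
  if (k_cpdb < 0 || k_chi < 0) stop("umbrella_window: force constants must be >= 0")
  structure(list(id = as.integer(id), cpdb0 = wrap_angle(cpdb0), chi0 = wrap_angle(chi0),
                 k_cpdb = k_cpdb, k_chi = k_chi),
            class = "umbrella_window")
}

#' Rectangular grid of umbrella windows
#'
#' CPDb centres include both range endpoints (spacing `(max - min)/(n - 1)`).
#' chi is periodic: when the requested range spans a full turn the centres
#' are spaced `360/n_chi` starting at the lower bound, so -180 and +180 are
#' one wrapped point and the whole circle is covered without duplication.
#' Windows are enumerated row-major, CPDb outer and chi inner.
#'
#' @param n_cpdb,n_chi Number of centres per axis (>= 1).
#' @param cpdb_range,chi_range Length-2 numeric ranges in degrees.
#' @param k_cpdb,k_chi Force constants applied to every window.
#' @return An object of class `window_grid` with elements `windows`
#'   (list of [umbrella_window()]), `n_cpdb`, `n_chi`, `cpdb_centers`,
#'   `chi_centers`, `cpdb_range`, `chi_range`.
#' @examples
#' g <- build_window_grid(13, c(-100, 100), 24, c(-180, 180))
#' length(g$windows)  # 312
#' @export
build_window_grid <- function(n_cpdb = 13, cpdb_range = c(-100, 100),
                              n_chi = 24, chi_range = c(-180, 180),
                              k_cpdb = 100, k_chi = 50) {
  stopifnot(n_cpdb >= 1, n_chi >= 1, length(cpdb_range) == 2, length(chi_range) == 2)
  if (diff(cpdb_range) <= 0 || diff(chi_range) <= 0) {
    stop("build_window_grid: degenerate range")
  }
  cpdb_centers <- if (n_cpdb == 1L) cpdb_range[1L] else
    seq(cpdb_range[1L], cpdb_range[2L], length.out = n_cpdb)
  periodic_chi <- isTRUE(all.equal(diff(chi_range), 360))
  chi_centers <- if (n_chi == 1L) chi_range[1L] else if (periodic_chi)
    chi_range[1L] + (seq_len(n_chi) - 1L) * 360 / n_chi else
    seq(chi_range[1L], chi_range[2L], length.out = n_chi)
  centers <- expand.grid(chi0 = chi_centers, cpdb0 = cpdb_centers)  # chi inner
  key <- paste(round(wrap_angle(centers$cpdb0), 9), round(wrap_angle(centers$chi0), 9))
  if (anyDuplicated(key)) stop("build_window_grid: duplicate wrapped window centres")
  windows <- lapply(seq_len(nrow(centers)), function(i) {
    umbrella_window(i, centers$cpdb0[i], centers$chi0[i], k_cpdb, k_chi)
  })
  structure(list(windows = windows, n_cpdb = as.integer(n_cpdb), n_chi = as.integer(n_chi),
                 cpdb_centers = cpdb_centers, chi_centers = wrap_angle(chi_centers),
                 cpdb_range = cpdb_range, chi_range = chi_range,
                 k_cpdb = k_cpdb, k_chi = k_chi),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat("window_grid:", x$n_cpdb, "x", x$n_chi, "=", length(x$windows), "windows\n")
  cat("  CPDb centres:", format(min(x$cpdb_centers)), "..", format(max(x$cpdb_centers)),
      " chi spacing:", format(if (x$n_chi > 1) diff(x$chi_centers[1:2]) else NA), "deg\n")
  cat("  k_cpdb =", x$k_cpdb, " k_chi =", x$k_chi, "(kcal/mol/rad^2)\n")
  invisible(x)
}

#' Harmonic bias energy of a window
#'
#' Evaluates `k_cpdb * dCPDb^2 + k_chi * dchi^2` (no 1/2 prefactor) with
#' each displacement the minimal-image wrapped difference from the window
#' centre. Under the default convention the force constants are
#' kcal/mol/rad^2 and displacements are converted to radians;
#' `k_unit = "deg"` treats them as kcal/mol/deg^2. `half_k = TRUE`
#' switches to the `k/2 * d^2` convention used by some bias engines.
#'
#' @param w An [umbrella_window()].
#' @param cpdb,chi Numeric vectors of coordinates in degrees (recycled).
#' @param half_k Apply a 1/2 prefactor.
#' @param k_unit `"rad"` (default) or `"deg"`.
#' @return Bias energies in kcal/mol.
#' @export
bias_energy <- function(w, cpdb, chi, half_k = FALSE, k_unit = c("rad", "deg")) {
  k_unit <- match.arg(k_unit)
  d1 <- angle_diff(cpdb, w$cpdb0)
  d2 <- angle_diff(chi, w$chi0)
  if (k_unit == "rad") {
    d1 <- d1 * pi / 180
    d2 <- d2 * pi / 180
  }
  u <- w$k_cpdb * d1^2 + w$k_chi * d2^2
  if (half_k) u <- u / 2
  u
}
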