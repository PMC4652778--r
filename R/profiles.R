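# Effective 1D profiles derived from the 2D surface: the Boltzmann marginal
# F(chi) = -RT log integral P(chi, CPDb) dCPDb (and its CPDb analogue), a
# fixed-CPDb slice, and the lowest-free-energy path profile (pointwise
# minimum over the other axis).

axis_data <- function(fes, axis = c("chi", "cpdb")) {
  axis <- match.arg(axis)
  if (axis == "chi") {
    list(centers = fes$chi_centers, F = t(fes$F), sampled = t(fes$sampled),
         other_width = diff(fes$cpdb_edges))
  } else {
    list(centers = fes$cpdb_centers, F = fes$F, sampled = fes$sampled,
         other_width = diff(fes$chi_edges))
  }
}

marginal_1d <- function(axis, centers, F) {
  keep <- is.finite(F)
  out <- list(axis = axis, centers = centers, F = F - min(F[keep]))
  class(out) <- "marginal_1d"
  out
}

#' @export
print.marginal_1d <- function(x, ...) {
  cat(sprintf("marginal_1d over %s: %d centres, max F = %.2f kcal/mol\n",
              x$axis, length(x$centers), max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Effective 1D potential of mean force by Boltzmann marginalisation
#'
#' For each centre on the chosen axis, integrates the 2D probability
#' `P = exp(-F/RT)` over the other axis by bin-width quadrature (masked
#' bins contribute zero probability) and returns `-RT log` of the result,
#' minimum-referenced to zero. Rows/columns with no sampled bin are
#' masked (`NA`) in the output.
#'
#' @param fes A [fes_grid()].
#' @param axis `"chi"` or `"cpdb"`: the axis the profile runs along.
#' @return A `marginal_1d` with `centers` (degrees) and `F` (kcal/mol).
#' @export
marginal <- function(fes, axis = c("chi", "cpdb")) {
  axis <- match.arg(axis)
  ad <- axis_data(fes, axis)
  kT <- KCAL_R * fes$temperature
  F1 <- vapply(seq_along(ad$centers), function(i) {
    ok <- ad$sampled[i, ]
    if (!any(ok)) return(NA_real_)
    -kT * log(sum(exp(-ad$F[i, ok] / kT) * ad$other_width[ok]))
  }, numeric(1))
  marginal_1d(axis, ad$centers, F1)
}

#' 1D profile along chi at fixed CPDb (a surface slice)
#'
#' Extracts the row of the surface nearest the requested CPDb value,
#' minimum-referenced to zero; the CPDb = 0 slice is the rotation profile
#' in the absence of base flipping.
#'
#' @param fes A [fes_grid()].
#' @param cpdb Requested CPDb, degrees (nearest bin centre is used).
#' @return A `marginal_1d` along chi.
#' @export
slice_profile <- function(fes, cpdb = 0) {
  i <- which.min(abs(fes$cpdb_centers - cpdb))
  if (!any(fes$sampled[i, ])) {
    stop("slice_profile: row at CPDb = ", fes$cpdb_centers[i], " deg is fully masked")
  }
  F1 <- ifelse(fes$sampled[i, ], fes$F[i, ], NA_real_)
  marginal_1d("chi", fes$chi_centers, F1)
}

#' Lowest-free-energy path profile
#'
#' For each centre on the chosen axis, the minimum of F over the sampled
#' bins of the other axis; pointwise it can only lie at or below both the
#' Boltzmann marginal and any fixed slice.
#'
#' @param fes A [fes_grid()].
#' @param axis `"chi"` or `"cpdb"`.
#' @return A `marginal_1d`.
#' @export
min_path_profile <- function(fes, axis = c("chi", "cpdb")) {
  axis <- match.arg(axis)
  ad <- axis_data(fes, axis)
  F1 <- vapply(seq_along(ad$centers), function(i) {
    ok <- ad$sampled[i, ]
    if (!any(ok)) return(NA_real_)
    min(ad$F[i, ok])
  }, numeric(1))
  marginal_1d(axis, ad$centers, F1)
}
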