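# File formats and the end-to-end pipeline driver. Collective-variable time
# series use the COLVAR-style whitespace text format with a `#! FIELDS ...`
# header; surfaces are written as a TSV of bin centres with a JSON sidecar
# carrying temperature and binning metadata.

#' Read a COLVAR-style collective-variable time series
#'
#' Parses the `#! FIELDS time cpdb chi` header, skips comment lines,
#' ignores extra columns, and wraps angles into `[-180, 180)`.
#'
#' @param path File path.
#' @param window Optional [umbrella_window()]; when given, the series is
#'   returned as a [biased_ensemble()] for that window instead of a
#'   torsion series.
#' @return A `torsion_series` data frame (`time`, `cpdb`, `chi`) or a
#'   [biased_ensemble()].
#' @export
read_colvar <- function(path, window = NULL) {
  lines <- readLines(path)
  head_i <- grep("^#!\\s*FIELDS", lines)
  if (!length(head_i)) stop("read_colvar: ", path, ": missing '#! FIELDS' header")
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[head_i[1L]]), "\\s+")[[1L]]
  for (need in c("time", "cpdb", "chi")) {
    if (!need %in% fields) {
      stop("read_colvar: ", path, ": required field '", need, "' missing from header")
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("read_colvar: ", path, ": no data rows")
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (ncol(mat) < length(fields)) stop("read_colvar: ", path, ": rows shorter than header")
  out <- data.frame(time = mat[, match("time", fields)],
                    cpdb = wrap_angle(mat[, match("cpdb", fields)]),
                    chi = wrap_angle(mat[, match("chi", fields)]))
  if (!is.null(window)) {
    return(biased_ensemble(window, as.matrix(out[, c("cpdb", "chi")])))
  }
  class(out) <- c("torsion_series", "data.frame")
  out
}

#' Write a collective-variable time series in COLVAR-style text
#'
#' @param series A `torsion_series` (or data frame with `time`, `cpdb`,
#'   `chi`).
#' @param path Output path.
#' @export
write_colvar <- function(series, path) {
  stopifnot(all(c("time", "cpdb", "chi") %in% names(series)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cpdb chi", con)
  utils::write.table(series[, c("time", "cpdb", "chi")], con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a free-energy surface to TSV with a JSON sidecar
#'
#' The TSV holds one row per bin (cpdb_center, chi_center, F, sampled);
#' `<path>.json` records temperature and bin edges so the surface
#' round-trips exactly.
#'
#' @param fes A [fes_grid()].
#' @param path Output TSV path.
#' @export
write_fes <- function(fes, path) {
  grid <- expand.grid(i = seq_along(fes$cpdb_centers), j = seq_along(fes$chi_centers))
  df <- data.frame(cpdb_center = fes$cpdb_centers[grid$i],
                   chi_center = fes$chi_centers[grid$j],
                   F = fes$F[cbind(grid$i, grid$j)],
                   sampled = fes$sampled[cbind(grid$i, grid$j)])
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(temperature = fes$temperature,
                            cpdb_edges = fes$cpdb_edges, chi_edges = fes$chi_edges),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a surface written by [write_fes()]
#'
#' @param path TSV path (the `.json` sidecar must sit alongside).
#' @return A [fes_grid()].
#' @export
read_fes <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  nx <- length(meta$cpdb_edges) - 1L
  ny <- length(meta$chi_edges) - 1L
  F <- matrix(NA_real_, nx, ny)
  S <- matrix(FALSE, nx, ny)
  xc <- (meta$cpdb_edges[-1L] + meta$cpdb_edges[-(nx + 1L)]) / 2
  yc <- (meta$chi_edges[-1L] + meta$chi_edges[-(ny + 1L)]) / 2
  i <- vapply(df$cpdb_center, function(v) which.min(abs(xc - v)), integer(1))
  j <- vapply(df$chi_center, function(v) which.min(abs(yc - v)), integer(1))
  F[cbind(i, j)] <- df$F
  S[cbind(i, j)] <- as.logical(df$sampled)
  fes_grid(meta$cpdb_edges, meta$chi_edges, F, S, temperature = meta$temperature)
}

#' Default run configuration
#'
#' The conventional study conditions: a 13 x 24 window grid over
#' CPDb in [-100, 100] and the full chi turn, force constants 100 and 50
#' kcal/mol/rad^2, 300 K, 5-degree estimator bins, and the 20/60 degree
#' route cutoffs.
#'
#' @param ... Named overrides of any default element.
#' @return A list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    temperature = 300,
    n_cpdb = 13, cpdb_range = c(-100, 100),
    n_chi = 24, chi_range = c(-180, 180),
    k_cpdb = 100, k_chi = 50, k_unit = "rad", half_k = FALSE,
    bin_width = 5, wham_tol = 1e-7, wham_max_iter = 1e5,
    route_small = 20, route_large = 60,
    mc = list(n_steps = 1000, n_equil = 400, thin = 2, n_chains = 4,
              step_sizes = c(6, 7)),
    fractions = c(0.25, 0.5, 0.75, 1),
    seed = 1
  )
  override <- list(...)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  structure(cfg, class = "run_config")
}

#' Run the full synthetic umbrella-sampling analysis
#'
#' Simulate the biased window suite on the model surface, reweight with
#' WHAM, derive 1D profiles, locate and label basins, extract the
#' six-route pathways, and (optionally) run the cumulative-time
#' convergence diagnostic; returns a structured report.
#'
#' @param config A [default_config()] (possibly with overrides).
#' @param surface A [model_surface()]; the default builds the standard
#'   calibrated surface.
#' @param convergence Run the cumulative-time diagnostic (re-estimates
#'   the surface once per fraction).
#' @param json_path Optional path to write the report as JSON.
#' @return A list of class `pipeline_report` with the fitted surface,
#'   basins, routes, profiles, convergence and headline numbers.
#' @export
run_pipeline <- function(config = default_config(), surface = model_surface(),
                         convergence = TRUE, json_path = NULL) {
  grid <- build_window_grid(config$n_cpdb, config$cpdb_range,
                            config$n_chi, config$chi_range,
                            config$k_cpdb, config$k_chi)
  params <- mc_params(temperature = config$temperature,
                      step_sizes = config$mc$step_sizes,
                      n_steps = config$mc$n_steps, n_equil = config$mc$n_equil,
                      thin = config$mc$thin, n_chains = config$mc$n_chains,
                      seed = config$seed)
  ens <- make_window_suite(surface, grid, params,
                           half_k = config$half_k, k_unit = config$k_unit)
  fit <- wham2d(ens, bin_width = config$bin_width, temperature = config$temperature,
                tol = config$wham_tol, max_iter = config$wham_max_iter,
                half_k = config$half_k, k_unit = config$k_unit)
  fes <- fit$fes
  minima <- find_minima(fes)
  basins <- label_basins(minima, flip_small = config$route_small)
  labels <- vapply(basins, function(b) b$label, character(1))
  wc <- if ("WC" %in% labels) basins[[which(labels == "WC")]] else NULL
  hg <- if ("HG" %in% labels) basins[[which(labels == "HG")]] else NULL
  ls <- if ("LS" %in% labels) basins[[which(labels == "LS")]] else NULL
  routes <- if (!is.null(wc) && !is.null(hg)) {
    extract_paths(fes, wc, hg, ls,
                  small_cut = config$route_small, large_cut = config$route_large)
  } else NULL
  conv <- if (convergence) {
    convergence_report(ens, fractions = config$fractions,
                       bin_width = config$bin_width, temperature = config$temperature,
                       tol = config$wham_tol, max_iter = config$wham_max_iter,
                       half_k = config$half_k, k_unit = config$k_unit)
  } else NULL

  barriers <- if (!is.null(routes)) {
    vapply(routes, function(p) if (is.null(p)) NA_real_ else p$forward_barrier, numeric(1))
  } else NULL
  report <- structure(list(
    n_windows = length(grid$windows),
    fes = fes, wham = fit$wham, ensembles = ens, grid = grid,
    basins = basins, routes = routes, convergence = conv,
    marginal_chi = marginal(fes, "chi"), marginal_cpdb = marginal(fes, "cpdb"),
    slice_chi_at_0 = slice_profile(fes, 0),
    delta_g_wc_hg = if (!is.null(wc) && !is.null(hg)) delta_g(fes, wc, hg) else NA_real_,
    route_barriers = barriers,
    ls_location = if (!is.null(ls)) c(cpdb = ls$point$cpdb, chi = ls$point$chi) else NULL
  ), class = "pipeline_report")
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n_windows = report$n_windows,
      delta_g_wc_hg = report$delta_g_wc_hg,
      route_barriers = as.list(barriers),
      ls_location = as.list(report$ls_location),
      convergence_rms = if (!is.null(conv)) conv$rms else NULL,
      kbt = KCAL_R * config$temperature,
      wham_converged = fit$wham$converged,
      seed = config$seed
    ), json_path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("WC -> HG umbrella-sampling analysis\n")
  cat("  windows:", x$n_windows, " WHAM converged:", x$wham$converged, "\n")
  cat(sprintf("  dG(WC -> HG) = %.2f kcal/mol\n", x$delta_g_wc_hg))
  if (!is.null(x$route_barriers)) {
    cat("  forward barriers (kcal/mol):\n")
    for (nm in names(x$route_barriers)) {
      cat(sprintf("    %-3s %s\n", nm,
                  ifelse(is.na(x$route_barriers[nm]), "absent",
                         sprintf("%.2f", x$route_barriers[nm]))))
    }
  }
  if (!is.null(x$ls_location)) {
    cat(sprintf("  LS intermediate at (%.1f, %.1f)\n",
                x$ls_location["cpdb"], x$ls_location["chi"]))
  }
  if (!is.null(x$convergence)) print(x$convergence)
  invisible(x)
}
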