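# Self-consistent WHAM reweighting of the biased window ensembles into the
# unbiased 2D free-energy surface. Bias energies are evaluated at bin
# centres; chi is periodic. The fixed point solved is
#   p_m = n_m / sum_i N_i exp((f_i - U_i(m)) / kT)
#   f_i = -kT log sum_m p_m exp(-U_i(m) / kT)
# iterated on the window shifts f_i, with optional Aitken extrapolation.

#' Binned 2D free-energy surface
#'
#' @param cpdb_edges,chi_edges Bin edges, degrees (chi edges must span a
#'   full wrapped turn for periodic analyses).
#' @param F Matrix of free energies, kcal/mol, `length(cpdb_edges)-1` rows
#'   by `length(chi_edges)-1` columns; `NA` on unsampled bins.
#' @param sampled Logical matrix marking bins with data.
#' @param temperature Kelvin.
#' @return An object of class `fes_grid`. The minimum over sampled bins
#'   is shifted to zero.
#' @export
fes_grid <- function(cpdb_edges, chi_edges, F, sampled, temperature = 300) {
  F <- as.matrix(F)
  sampled <- as.matrix(sampled)
  stopifnot(nrow(F) == length(cpdb_edges) - 1L, ncol(F) == length(chi_edges) - 1L,
            all(dim(F) == dim(sampled)))
  if (!any(sampled)) stop("fes_grid: no sampled bins")
  if (any(!is.finite(F[sampled]))) stop("fes_grid: non-finite F on sampled bins")
  F[!sampled] <- NA_real_
  F <- F - min(F[sampled])
  structure(list(cpdb_edges = cpdb_edges, chi_edges = chi_edges,
                 cpdb_centers = (cpdb_edges[-1L] + cpdb_edges[-length(cpdb_edges)]) / 2,
                 chi_centers = (chi_edges[-1L] + chi_edges[-length(chi_edges)]) / 2,
                 F = F, sampled = sampled, temperature = temperature),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat(sprintf("fes_grid: %d x %d bins, %d sampled, T = %g K, max F = %.2f kcal/mol\n",
              nrow(x$F), ncol(x$F), sum(x$sampled), x$temperature,
              max(x$F[x$sampled])))
  invisible(x)
}

bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

# Core WHAM fixed point on histogram totals. n_m: counts per bin (vector);
# N_i: samples per window; B: windows x bins bias matrix (kcal/mol).
wham_core <- function(n_m, N_i, B, kT, tol = 1e-7, max_iter = 1e5, accelerate = TRUE,
                      init_f = NULL) {
  logQ <- -B / kT                         # windows x bins
  # per-bin offset keeps the denominator sums in floating-point range even
  # for stiff biases (logQ can reach -2000 at distant bins)
  c_m <- apply(logQ, 2L, max)
  Qc <- exp(sweep(logQ, 2L, c_m))         # in (0, 1], max 1 per column
  logN <- log(N_i)
  g <- if (is.null(init_f)) rep(0, length(N_i)) else init_f / kT  # f_i / kT
  occupied <- n_m > 0
  step_p <- function(g) {
    z <- exp(logN + g)
    denom <- as.vector(crossprod(Qc, z))  # scaled by exp(-c_m)
    logp <- ifelse(occupied, log(n_m) - c_m - log(denom), -Inf)
    logp - max(logp)
  }
  Qe <- exp(logQ)
  step_g <- function(logp) {
    gn <- -log(as.vector(Qe %*% exp(logp)))
    gn - gn[1L]
  }
  hist_g <- list()
  iters <- 0L
  residual <- Inf
  repeat {
    iters <- iters + 1L
    logp <- step_p(g)
    g_new <- step_g(logp)
    if (any(!is.finite(g_new))) stop("wham_core: a window has no overlap with any sampled bin")
    residual <- kT * max(abs(g_new - g))
    g <- g_new
    if (residual < tol || iters >= max_iter) break
    if (accelerate && iters %% 25L == 0L) {
      hist_g[[length(hist_g) + 1L]] <- g
      if (length(hist_g) >= 3L) {
        g1 <- hist_g[[1L]]; g2 <- hist_g[[2L]]; g3 <- hist_g[[3L]]
        d <- g3 - 2 * g2 + g1
        ok <- abs(d) > 1e-12
        g_acc <- g3
        g_acc[ok] <- g3[ok] - (g3[ok] - g2[ok])^2 / d[ok]
        # reject wild extrapolations (Aitken diverges near non-scalar modes)
        if (all(is.finite(g_acc)) &&
            max(abs(g_acc - g3)) <= 10 * max(abs(g3 - g2)) + 1e-12) {
          g <- g_acc - g_acc[1L]
        }
        hist_g <- list()
      }
    }
  }
  logp <- step_p(g)
  list(f = kT * g, p = exp(logp), iterations = iters, residual = residual,
       converged = residual < tol)
}

#' Reweight biased ensembles into a 2D free-energy surface (WHAM)
#'
#' Combines the per-window biased samples by the self-consistent weighted
#' histogram equations on a shared (CPDb, chi) binning, evaluating each
#' window's bias at the bin centres with periodic chi, and returns the
#' minimum-referenced surface together with the converged window shifts.
#'
#' @param ensembles List of [biased_ensemble()] objects.
#' @param bin_width Bin width, degrees (applied to both axes).
#' @param cpdb_range Optional CPDb span; defaults to the sample range
#'   expanded to whole bins. Default binning places bin centres on the
#'   multiples-of-`bin_width` lattice that carries the umbrella window
#'   centres (edges offset by half a bin), so basin and window positions
#'   fall on bin centres rather than edges.
#' @param chi_range chi span covering one full turn; the default
#'   `c(-182.5, 177.5)` centres bins on the same lattice. Samples are
#'   wrapped into the edge frame.
#' @param temperature Kelvin.
#' @param tol Convergence tolerance on the maximum change of the window
#'   shifts per iteration, kcal/mol.
#' @param max_iter Iteration cap; exceeding it flags the result as not
#'   converged rather than failing.
#' @param accelerate Apply periodic Aitken extrapolation to the shifts.
#' @param init_f Optional starting window shifts (kcal/mol), e.g. from a
#'   previous fit on related data (warm start).
#' @param half_k,k_unit Bias conventions, see [bias_energy()].
#' @return A list with `fes` (a [fes_grid()]) and `wham` (window shifts
#'   `f`, `iterations`, `converged`, `residual`).
#' @export
wham2d <- function(ensembles, bin_width = 5, cpdb_range = NULL,
                   chi_range = c(-182.5, 177.5), temperature = 300,
                   tol = 1e-7, max_iter = 1e5, accelerate = TRUE,
                   half_k = FALSE, k_unit = "rad", init_f = NULL) {
  stopifnot(length(ensembles) >= 1L)
  for (e in ensembles) {
    if (!inherits(e, "biased_ensemble")) stop("wham2d: inputs must be biased_ensemble objects")
  }
  all_cpdb <- unlist(lapply(ensembles, function(e) e$samples[, "cpdb"]))
  all_chi <- unlist(lapply(ensembles, function(e) e$samples[, "chi"]))
  if (is.null(cpdb_range)) {
    cpdb_range <- c((floor(min(all_cpdb) / bin_width - 0.5) + 0.5) * bin_width,
                    (ceiling(max(all_cpdb) / bin_width + 0.5) - 0.5) * bin_width)
    if (diff(cpdb_range) <= 0) cpdb_range <- cpdb_range + c(-bin_width, bin_width)
  }
  cpdb_edges <- seq(cpdb_range[1L], cpdb_range[2L], by = bin_width)
  chi_edges <- seq(chi_range[1L], chi_range[2L], by = bin_width)
  if (!isTRUE(all.equal(diff(range(chi_edges)), 360))) {
    stop("wham2d: chi_range must span one full 360-degree turn")
  }
  nx <- length(cpdb_edges) - 1L
  ny <- length(chi_edges) - 1L
  if (any(all_cpdb < cpdb_range[1L] | all_cpdb > cpdb_range[2L])) {
    stop("wham2d: bins do not cover all CPDb samples")
  }

  ix <- bin_index(all_cpdb, cpdb_edges)
  chi_lo <- chi_edges[1L]
  iy <- bin_index(chi_lo + (all_chi - chi_lo) %% 360, chi_edges)
  if (any(is.na(ix)) || any(is.na(iy))) stop("wham2d: bins do not cover all samples")
  flat <- (iy - 1L) * nx + ix
  n_m <- tabulate(flat, nbins = nx * ny)
  if (all(n_m == 0L)) stop("wham2d: degenerate input, every bin empty")
  N_i <- vapply(ensembles, function(e) e$n, numeric(1))

  xc <- (cpdb_edges[-1L] + cpdb_edges[-(nx + 1L)]) / 2
  yc <- (chi_edges[-1L] + chi_edges[-(ny + 1L)]) / 2
  centers_x <- rep(xc, times = ny)
  centers_y <- rep(yc, each = nx)
  B <- t(vapply(ensembles, function(e) {
    bias_energy(e$window, centers_x, centers_y, half_k = half_k, k_unit = k_unit)
  }, numeric(nx * ny)))

  kT <- KCAL_R * temperature
  sol <- wham_core(n_m, N_i, B, kT, tol = tol, max_iter = max_iter,
                   accelerate = accelerate, init_f = init_f)

  sampled <- matrix(n_m > 0L, nx, ny)
  Fm <- matrix(NA_real_, nx, ny)
  p <- sol$p
  pos <- p > 0
  Fm[matrix(pos, nx, ny)] <- -kT * log(p[pos])
  sampled <- sampled & matrix(pos, nx, ny)
  fes <- fes_grid(cpdb_edges, chi_edges, Fm, sampled, temperature = temperature)
  list(fes = fes,
       wham = list(window_shifts = sol$f, iterations = sol$iterations,
                   converged = sol$converged, residual = sol$residual))
}
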