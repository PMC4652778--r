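# Synthetic biased sampling in collective-variable space. Each umbrella
# window is emulated by Metropolis Monte Carlo on F_true + U_bias — exactly
# the statistical object the reweighting stage consumes — with a documented
# deterministic per-window seed split. A toy well-tempered metadynamics
# walker provides the coverage-study trajectory.

KCAL_R <- 1.9872041e-3  # gas constant, kcal/mol/K

#' Monte Carlo sampling parameters for one umbrella window
#'
#' @param temperature Kelvin.
#' @param step_sizes Gaussian proposal standard deviations, degrees, for
#'   (CPDb, chi).
#' @param n_steps Post-equilibration steps per chain.
#' @param n_equil Discarded equilibration steps per chain.
#' @param thin Keep every `thin`-th post-equilibration state.
#' @param n_chains Independent chains per window (pooled, interleaved in
#'   time order); defaults give `n_chains * n_steps / thin` samples.
#' @param seed Master seed; each window derives its own stream from it.
#' @return A list of class `mc_params`.
#' @export
mc_params <- function(temperature = 300, step_sizes = c(5, 6),
                      n_steps = 1000, n_equil = 400, thin = 2,
                      n_chains = 4, seed = 1) {
  stopifnot(n_steps > 0, n_equil >= 0, thin >= 1, n_chains >= 1,
            all(step_sizes > 0), temperature > 0)
  structure(list(temperature = temperature, step_sizes = step_sizes,
                 n_steps = as.integer(n_steps), n_equil = as.integer(n_equil),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed)),
            class = "mc_params")
}

#' Deterministic per-window seed split
#'
#' Maps (master seed, window id) to a 31-bit seed by a fixed integer hash,
#' identical across platforms, so that every window's chain is reproducible
#' in isolation and the full suite is reproducible as a whole.
#'
#' @param master Master seed (integer).
#' @param id Window id (integer).
#' @return A positive integer seed below 2^31.
#' @export
window_seed <- function(master, id) {
  as.integer((abs(as.numeric(master)) %% 65536) * 20011 +
             (as.numeric(id) %% 65536) * 7919 + 12345) %% 2147483647L
}

#' A biased ensemble: samples drawn under one umbrella window
#'
#' @param window The [umbrella_window()] that generated the bias.
#' @param samples Numeric matrix with columns `cpdb`, `chi` (degrees,
#'   wrapped), one row per retained sample in time order.
#' @param acceptance Optional realised Metropolis acceptance rate.
#' @return An object of class `biased_ensemble` with `n` samples.
#' @export
biased_ensemble <- function(window, samples, acceptance = NA_real_) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("biased_ensemble: needs at least one sample")
  colnames(samples) <- c("cpdb", "chi")
  samples[, 1L] <- wrap_angle(samples[, 1L])
  samples[, 2L] <- wrap_angle(samples[, 2L])
  structure(list(window = window, samples = samples, n = nrow(samples),
                 acceptance = acceptance),
            class = "biased_ensemble")
}

#' Sample one umbrella window by Metropolis Monte Carlo
#'
#' Runs `n_chains` independent Metropolis chains on
#' `F_true(cpdb, chi) + U_bias(window)` with Gaussian proposals and
#' periodic wrapping, discards the equilibration segment, thins, and pools
#' the chains interleaved in time order (so any prefix of the pooled
#' samples is a cumulative-time prefix). Deterministic for a fixed
#' `params$seed` via [window_seed()].
#'
#' @param surface A [model_surface()] or plain `function(cpdb, chi)`.
#' @param window An [umbrella_window()].
#' @param params An [mc_params()].
#' @param half_k,k_unit Bias conventions, see [bias_energy()].
#' @return A [biased_ensemble()].
#' @export
sample_window_mc <- function(surface, window, params = mc_params(),
                             half_k = FALSE, k_unit = "rad") {
  f <- as_surface_fun(surface)
  kT <- KCAL_R * params$temperature
  nc <- params$n_chains
  set.seed(window_seed(params$seed, window$id))

  energy <- function(x, y) f(x, y) + bias_energy(window, x, y, half_k = half_k, k_unit = k_unit)

  x <- rep(window$cpdb0, nc)
  y <- rep(window$chi0, nc)
  e <- energy(x, y)
  n_keep <- params$n_steps %/% params$thin
  out_x <- matrix(NA_real_, n_keep, nc)
  out_y <- matrix(NA_real_, n_keep, nc)
  acc <- 0L
  n_tot <- params$n_equil + params$n_steps
  kept <- 0L
  for (step in seq_len(n_tot)) {
    xp <- x + stats::rnorm(nc, 0, params$step_sizes[1L])
    yp <- wrap_angle(y + stats::rnorm(nc, 0, params$step_sizes[2L]))
    ep <- energy(xp, yp)
    take <- stats::runif(nc) < exp(pmin(0, -(ep - e) / kT))
    x[take] <- xp[take]
    y[take] <- yp[take]
    e[take] <- ep[take]
    acc <- acc + sum(take)
    if (step == params$n_equil && acc == 0L && params$n_equil > 0L) {
      stop("sample_window_mc: zero acceptance over equilibration; reduce step_sizes")
    }
    if (step > params$n_equil && (step - params$n_equil) %% params$thin == 0L) {
      kept <- kept + 1L
      out_x[kept, ] <- x
      out_y[kept, ] <- y
    }
  }
  # interleave chains in time order: sample index = (time, chain)
  samples <- cbind(cpdb = as.vector(t(out_x[seq_len(kept), , drop = FALSE])),
                   chi  = as.vector(t(out_y[seq_len(kept), , drop = FALSE])))
  biased_ensemble(window, samples, acceptance = acc / (n_tot * nc))
}

#' Generate the full biased-sampling suite for a window grid
#'
#' Runs [sample_window_mc()] for every window of the grid; each window's
#' random stream is derived from `(params$seed, window id)` so the suite
#' is reproducible window by window. Optionally writes one COLVAR-style
#' text file per window.
#'
#' @param surface A [model_surface()] or function.
#' @param grid A [build_window_grid()] result.
#' @param params An [mc_params()].
#' @param colvar_dir Optional directory to write `window_<id>.colvar`
#'   files into (created if missing).
#' @param ... Passed to [sample_window_mc()].
#' @return A list of [biased_ensemble()] objects, one per window.
#' @export
make_window_suite <- function(surface, grid, params = mc_params(),
                              colvar_dir = NULL, ...) {
  stopifnot(inherits(grid, "window_grid"))
  ens <- lapply(grid$windows, function(w) sample_window_mc(surface, w, params, ...))
  if (!is.null(colvar_dir)) {
    dir.create(colvar_dir, showWarnings = FALSE, recursive = TRUE)
    for (e in ens) {
      ts <- data.frame(time = (seq_len(e$n) - 1) * params$thin,
                       cpdb = e$samples[, "cpdb"], chi = e$samples[, "chi"])
      write_colvar(ts, file.path(colvar_dir, sprintf("window_%03d.colvar", e$window$id)))
    }
  }
  ens
}

#' Well-tempered metadynamics parameters
#'
#' `gamma = (T + delta_T)/T` is the bias factor; hill heights decay as
#' `w0 * exp(-V_bias / (kB * delta_T))` at revisited points.
#'
#' @param w0 Initial hill height, kcal/mol.
#' @param stride Steps between hill depositions (one deposition per
#'   notional picosecond).
#' @param hill_widths Gaussian hill standard deviations, degrees.
#' @param gamma Bias factor (> 1); `Inf` gives ordinary metadynamics with
#'   constant hill height.
#' @param temperature Kelvin.
#' @param step_size Proposal standard deviation of the walker, degrees.
#' @return A list of class `metad_params` carrying `delta_t = (gamma-1) T`.
#' @export
metad_params <- function(w0 = 1.0, stride = 30, hill_widths = c(12, 12),
                         gamma = 15, temperature = 300, step_size = 4) {
  stopifnot(gamma > 1, w0 > 0, stride >= 1, all(hill_widths > 0))
  structure(list(w0 = w0, stride = as.integer(stride), hill_widths = hill_widths,
                 gamma = gamma, temperature = temperature,
                 delta_t = (gamma - 1) * temperature, step_size = step_size),
            class = "metad_params")
}

#' Toy well-tempered metadynamics walker on a model surface
#'
#' A Metropolis walker on `F_true + V_bias` deposits Gaussian hills every
#' `stride` steps with the well-tempered height schedule. The history
#' bias is accumulated on an internal 2-degree lookup grid (periodic in
#' chi); a soft quadratic wall beyond `|CPDb| = cpdb_wall` keeps the
#' walker in the physically meaningful flipping range. Used to emulate
#' the coverage study that seeds umbrella windows, not for free-energy
#' estimates.
#'
#' @param surface A [model_surface()] or function.
#' @param params A [metad_params()].
#' @param n_steps Number of walker steps.
#' @param seed Integer seed.
#' @param start Starting point `c(cpdb, chi)` in degrees.
#' @param cpdb_wall Soft-wall onset, degrees.
#' @return A list with `trajectory` (matrix of visited points), `hills`
#'   (data.frame step/cpdb/chi/height), and the final bias lookup grid.
#' @export
sample_wt_metadynamics <- function(surface, params = metad_params(), n_steps = 20000,
                                   seed = 1, start = c(0, -105), cpdb_wall = 115) {
  f <- as_surface_fun(surface)
  kT <- KCAL_R * params$temperature
  kdT <- KCAL_R * params$delta_t
  set.seed(seed)

  gx <- seq(-140, 140, by = 2)
  gy <- seq(-180, 178, by = 2)
  V <- matrix(0, length(gx), length(gy))
  ix_of <- function(x) pmin(pmax(round((x + 140) / 2) + 1, 1L), length(gx))
  iy_of <- function(y) (round((wrap_angle(y) + 180) / 2) %% length(gy)) + 1L

  wall <- function(x) 0.05 * pmax(abs(x) - cpdb_wall, 0)^2

  sx <- params$hill_widths[1L]
  sy <- params$hill_widths[2L]
  # precomputed hill patch out to 3 sigma
  px <- seq(-ceiling(3 * sx / 2), ceiling(3 * sx / 2))       # grid-cell offsets
  py <- seq(-ceiling(3 * sy / 2), ceiling(3 * sy / 2))
  patch <- outer(exp(-0.5 * (2 * px / sx)^2), exp(-0.5 * (2 * py / sy)^2))

  x <- start[1L]; y <- wrap_angle(start[2L])
  eval_e <- function(x, y) f(x, y) + V[ix_of(x), iy_of(y)] + wall(x)
  e <- eval_e(x, y)
  traj <- matrix(NA_real_, n_steps, 2L)
  hills <- vector("list", n_steps %/% params$stride)
  nh <- 0L
  for (step in seq_len(n_steps)) {
    xp <- x + stats::rnorm(1, 0, params$step_size)
    yp <- wrap_angle(y + stats::rnorm(1, 0, params$step_size))
    ep <- eval_e(xp, yp)
    if (stats::runif(1) < exp(min(0, -(ep - e) / kT))) {
      x <- xp; y <- yp; e <- ep
    }
    traj[step, ] <- c(x, y)
    if (step %% params$stride == 0L) {
      vhere <- V[ix_of(x), iy_of(y)]
      h <- if (is.finite(kdT)) params$w0 * exp(-vhere / kdT) else params$w0
      ii <- ix_of(x) + px
      ok <- ii >= 1L & ii <= length(gx)
      jj <- ((iy_of(y) + py - 1L) %% length(gy)) + 1L
      V[ii[ok], jj] <- V[ii[ok], jj] + h * patch[ok, , drop = FALSE]
      nh <- nh + 1L
      hills[[nh]] <- c(step, x, y, h)
      e <- eval_e(x, y)  # bias under the walker changed
    }
  }
  hills <- do.call(rbind, hills[seq_len(nh)])
  colnames(traj) <- c("cpdb", "chi")
  hills <- as.data.frame(hills)
  names(hills) <- c("step", "cpdb", "chi", "height")
  list(trajectory = traj, hills = hills, bias = list(cpdb = gx, chi = gy, V = V))
}

#' Fraction of umbrella-window cells visited by a trajectory
#'
#' Assigns every trajectory point to its nearest window centre and
#' reports the fraction of windows visited at least once; mirrors the
#' check that a metadynamics exploration run has touched (almost) every
#' window region before umbrella sampling starts.
#'
#' @param trajectory Matrix with columns cpdb, chi (degrees).
#' @param grid A [build_window_grid()] result.
#' @return Fraction in `[0, 1]`.
#' @export
window_coverage <- function(trajectory, grid) {
  stopifnot(inherits(grid, "window_grid"))
  xc <- grid$cpdb_centers
  yc <- grid$chi_centers
  ix <- vapply(trajectory[, 1L], function(x) which.min(abs(xc - x)), integer(1))
  iy <- vapply(trajectory[, 2L], function(y) which.min(abs(angle_diff(yc, y))), integer(1))
  visited <- unique(paste(ix, iy))
  length(visited) / (grid$n_cpdb * grid$n_chi)
}
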