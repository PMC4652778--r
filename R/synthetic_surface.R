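# Analytic model free-energy surface F_true(CPDb, chi) with the landscape
# features reported for the WC -> HG switch in an A-tract duplex: an anti WC
# global minimum, a syn HG minimum 4.4 kcal/mol above it, a minor-groove
# locally stable intermediate near (-57.3, 51.2), a chi-rotation ridge that is
# highest at intermediate flipping and lowest either inside the helix (small
# routes, barriers ~10-11) or in the flipped-out plateau (large routes,
# ~13-14), and a saturating base-opening cost toward each groove. The surface
# is smooth, chi-periodic, and exactly calibrated at construction so that
# F(HG) - F(WC) equals the designed free-energy difference.

#' Designed parameters of the default model surface
#'
#' The numbers encode the reported landscape as design targets for the
#' synthetic generator (they are targets of the toy surface, not claims
#' about real DNA): a WC/HG free-energy difference of 4.4 kcal/mol, a
#' locally stable minor-groove intermediate at (-57.3, 51.2) degrees, route
#' barriers in the 10-14 kcal/mol band with the small-flipping routes
#' lowest, and base-opening plateau costs of about 8.0 (major) and 8.4
#' (minor groove) kcal/mol.
#'
#' @param delta_g Designed F(HG) - F(WC), kcal/mol.
#' @param ls_height Designed F at the LS intermediate, kcal/mol.
#' @param ts2_height Designed height of the barrier separating LS from HG.
#' @return A list of class `model_surface_spec`; see [model_surface()].
#' @export
default_surface_spec <- function(delta_g = 4.4, ls_height = 6.0, ts2_height = 12.6) {
  ridge_knots <- data.frame(
    chi = seq(-180, 180, by = 15),
    height = c(7.8, 7.4, 7.0, 6.5, 5.6, 4.0,   # -180 .. -105: anti valley
               5.6, 11.9, 9.2,                  # -90, -75 (ccw crest), -60
               7.4, 6.8, 6.2, 5.8, 5.5, 5.2,    # -45 .. 30: syn corridor ramp
               5.2, 5.2,                        # 45, 60: HG valley
               10.6, 10.8, 9.6,                 # 75, 90 (cw crest), 105
               8.9, 8.5, 8.2, 8.0, 7.8)         # 120 .. 180: seam arc
  )
  structure(list(
    basins = list(
      wc = list(label = "WC", center = c(0, -105), height = 0,        widths = c(16, 16)),
      hg = list(label = "HG", center = c(0, 55),   height = delta_g,  widths = c(16, 20)),
      ls = list(label = "LS", center = c(-57.3, 51.2), height = ls_height, widths = c(13, 15))
    ),
    plateau = list(height_major = 8.0, height_minor = 8.4, sigma = 30),
    wall = list(onset = 97, k = 2.2 / 15^2),
    ridge = list(knots = ridge_knots,
                 gate = list(center = -8, sigma_major = 40, sigma_minor = 34, floor = 0.40)),
    ts2 = list(center = c(-30, 52), sigma = c(10, 40), height = ts2_height),
    delta_g = delta_g
  ), class = "model_surface_spec")
}

gauss_per <- function(x, x0, s) exp(-0.5 * (angle_diff(x, x0) / s)^2)

surface_base_fun <- function(spec) {
  rk <- spec$ridge$knots
  # periodic monotone Hermite interpolation of the rotation-cost profile:
  # tile the knots over three turns and use monoH.FC, which cannot
  # overshoot between knots (no spurious wells on the chi circle)
  chi1 <- rk$chi[-length(rk$chi)]
  h1 <- rk$height[-length(rk$height)]
  ridge_fun <- stats::splinefun(c(chi1 - 360, chi1, chi1 + 360), rep(h1, 3L),
                                method = "monoH.FC")
  g <- spec$ridge$gate
  pl <- spec$plateau
  wl <- spec$wall
  function(cpdb, chi) {
    plateau <- ifelse(cpdb >= 0,
                      pl$height_major * (1 - exp(-0.5 * (cpdb / pl$sigma)^2)),
                      pl$height_minor * (1 - exp(-0.5 * (cpdb / pl$sigma)^2)))
    sig <- ifelse(cpdb >= g$center, g$sigma_major, g$sigma_minor)
    gate <- g$floor + (1 - g$floor) * exp(-0.5 * ((cpdb - g$center) / sig)^2)
    ridge <- pmax(ridge_fun(wrap_angle(chi)), 0)
    wall <- if (is.null(wl)) 0 else wl$k * pmax(abs(cpdb) - wl$onset, 0)^2
    plateau + ridge * gate + wall
  }
}

surface_raw_fun <- function(spec, depths, ts2_height) {
  base <- surface_base_fun(spec)
  basins <- spec$basins
  ts2 <- spec$ts2
  function(cpdb, chi) {
    f <- base(cpdb, chi)
    if (!is.null(ts2) && ts2_height != 0) {
      f <- f + ts2_height *
        exp(-0.5 * ((cpdb - ts2$center[1]) / ts2$sigma[1])^2) *
        gauss_per(chi, ts2$center[2], ts2$sigma[2])
    }
    for (i in seq_along(basins)) {
      b <- basins[[i]]
      f <- f - depths[i] *
        exp(-0.5 * ((cpdb - b$center[1]) / b$widths[1])^2) *
        gauss_per(chi, b$center[2], b$widths[2])
    }
    f
  }
}

#' Construct an evaluable model free-energy surface
#'
#' Assembles the analytic surface from a spec and, when `calibrate` is
#' set, solves for the basin well depths (and the LS-HG barrier height)
#' so that the surface passes exactly through each basin's designed
#' height, by fixed-point iteration on the anchor values. The global
#' minimum is then shifted to zero (located on a 1-degree scan).
#'
#' @param spec A `model_surface_spec`, by default [default_surface_spec()].
#'   For uncalibrated use a spec may carry `depth` entries in its basins
#'   (interpreted as literal well depths) instead of `height` targets.
#' @param calibrate Calibrate well depths to the basins' designed heights.
#' @return An object of class `model_surface` with elements `f` (vectorised
#'   `function(cpdb, chi)` in kcal/mol), `spec`, `depths`, `offset`.
#' @examples
#' ms <- model_surface()
#' ms$f(0, 55) - ms$f(0, -105)  # designed free-energy difference, 4.4
#' @export
model_surface <- function(spec = default_surface_spec(), calibrate = TRUE) {
  stopifnot(inherits(spec, "model_surface_spec") || is.list(spec))
  basins <- spec$basins
  if (length(basins) < 1L) stop("model_surface: spec needs at least one basin")
  nb <- length(basins)
  ts2_target <- if (!is.null(spec$ts2)) spec$ts2$height else 0

  if (calibrate) {
    depths <- rep(0, nb)
    h2 <- 0
    targets <- vapply(basins, function(b) b$height, numeric(1))
    for (iter in seq_len(200L)) {
      f <- surface_raw_fun(spec, depths, h2)
      vals <- vapply(basins, function(b) f(b$center[1], b$center[2]), numeric(1))
      err <- vals - targets
      depths <- depths + err
      if (!is.null(spec$ts2)) {
        e2 <- f(spec$ts2$center[1], spec$ts2$center[2]) - ts2_target
        h2 <- h2 - e2
      } else {
        e2 <- 0
      }
      if (max(abs(c(err, e2))) < 1e-9) break
    }
  } else {
    depths <- vapply(basins, function(b) if (!is.null(b$depth)) b$depth else 0, numeric(1))
    h2 <- if (!is.null(spec$ts2)) spec$ts2$height else 0
  }

  depths <- unname(depths)
  h2 <- unname(h2)
  fraw <- surface_raw_fun(spec, depths, h2)
  # global reference: minimum on a 1-degree scan of the plausible region
  xs <- seq(-130, 130, by = 1)
  ys <- seq(-180, 179, by = 1)
  grid <- expand.grid(cpdb = xs, chi = ys)
  offset <- min(fraw(grid$cpdb, grid$chi))
  f <- function(cpdb, chi) fraw(cpdb, chi) - offset

  structure(list(f = f, spec = spec, depths = depths, ts2_height = h2, offset = offset),
            class = "model_surface")
}

#' @export
print.model_surface <- function(x, ...) {
  b <- x$spec$basins
  cat("model_surface with", length(b), "basins:\n")
  for (bb in b) {
    cat(sprintf("  %-5s at (%7.1f, %7.1f)  F = %5.2f kcal/mol\n",
                if (!is.null(bb$label)) bb$label else "?",
                bb$center[1], bb$center[2],
                x$f(bb$center[1], bb$center[2])))
  }
  invisible(x)
}

#' Mirror a surface spec in the base-flipping coordinate
#'
#' Negates the CPDb coordinate of every feature (basins, gate asymmetry,
#' LS-HG barrier) and swaps the major/minor plateau costs, so that
#' `model_surface(mirror_surface_spec(s))$f(-x, y)` equals
#' `model_surface(s)$f(x, y)`.
#'
#' @param spec A `model_surface_spec`.
#' @return The mirrored spec.
#' @export
mirror_surface_spec <- function(spec) {
  out <- spec
  out$basins <- lapply(spec$basins, function(b) { b$center[1] <- -b$center[1]; b })
  out$plateau$height_major <- spec$plateau$height_minor
  out$plateau$height_minor <- spec$plateau$height_major
  out$ridge$gate$center <- -spec$ridge$gate$center
  sm <- spec$ridge$gate$sigma_major
  out$ridge$gate$sigma_major <- spec$ridge$gate$sigma_minor
  out$ridge$gate$sigma_minor <- sm
  if (!is.null(spec$ts2)) out$ts2$center[1] <- -spec$ts2$center[1]
  out
}

#' Evaluate a surface argument as a function
#'
#' Accepts either a `model_surface` or a plain vectorised
#' `function(cpdb, chi)`; used by the samplers and estimator tests.
#' @param surface Surface object or function.
#' @return A vectorised function of (cpdb, chi).
#' @keywords internal
as_surface_fun <- function(surface) {
  if (inherits(surface, "model_surface")) return(surface$f)
  if (is.function(surface)) return(surface)
  stop("expected a model_surface or a function(cpdb, chi)")
}
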