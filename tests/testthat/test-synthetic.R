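# The synthetic generator: calibrated model surface, Metropolis window
# sampler, the well-tempered metadynamics walker and seed handling.

test_that("the default surface is calibrated to its designed landscape", {
  ms <- model_surface()
  f <- ms$f
  expect_equal(f(0, 55) - f(0, -105), 4.4, tolerance = 1e-6)
  expect_equal(f(-57.3, 51.2) - f(0, -105), 6.0, tolerance = 1e-6)
  # chi-periodic and globally referenced to zero
  xs <- seq(-110, 110, by = 17)
  ys <- seq(-180, 170, by = 23)
  g <- expand.grid(x = xs, y = ys)
  expect_equal(f(g$x, g$y + 360), f(g$x, g$y), tolerance = 1e-9)
  expect_true(all(f(g$x, g$y) > -1e-6))
})

test_that("single-basin and mirrored specs behave as designed", {
  spec <- default_surface_spec()
  spec$basins <- list(list(label = "only", center = c(10, -30), depth = 5, widths = c(15, 15)))
  spec$ts2 <- NULL
  spec$ridge$knots$height[] <- 0
  spec$plateau$height_major <- 0; spec$plateau$height_minor <- 0
  ms1 <- model_surface(spec, calibrate = FALSE)
  g <- expand.grid(x = seq(-60, 80, by = 2.7), y = seq(-120, 60, by = 3.3))
  v <- ms1$f(g$x, g$y)
  k <- which.min(v)
  expect_equal(c(g$x[k], g$y[k]), c(10, -30), tolerance = 3)

  ms <- model_surface()
  msm <- model_surface(mirror_surface_spec(ms$spec))
  gg <- expand.grid(x = seq(-100, 100, by = 13), y = seq(-180, 170, by = 17))
  expect_equal(msm$f(-gg$x, gg$y), ms$f(gg$x, gg$y), tolerance = 1e-6)
})

test_that("the designed topography is present on the binned truth surface", {
  ms <- model_surface()
  ref <- truth_reference(ms)
  # basins within one bin of the designed centres
  expect_lt(abs(ref$wc$point$cpdb - 0), 5.1)
  expect_lt(abs(angle_diff(ref$wc$point$chi, -105)), 5.1)
  expect_lt(abs(angle_diff(ref$hg$point$chi, 55)), 5.1)
  expect_false(is.null(ref$ls))
  expect_lt(abs(ref$ls$point$cpdb - (-57.3)), 7.6)
  expect_lt(abs(angle_diff(ref$ls$point$chi, 51.2)), 7.6)
  expect_equal(ref$delta_g, 4.4, tolerance = 0.05)
  # six routes, barriers in the designed band, small-flipping routes lowest
  barriers <- vapply(ref$paths, function(p) p$forward_barrier, numeric(1))
  expect_equal(names(barriers), c("R1", "R2", "R3", "L1", "L2", "L3"))
  expect_true(all(barriers >= 9.5 & barriers <= 14.5))
  expect_lt(max(barriers[c("R1", "L1")]), min(barriers[c("R2", "R3", "L2", "L3")]))
  expect_equal(ref$lowest_barrier, barriers[["R1"]], tolerance = 1e-9)
  # every transition state is in the syn range
  for (p in ref$paths) expect_equal(classify_chi(p$ts$chi), "syn")
  # the rotation profile without flipping is at least as high as the lowest path
  s0 <- slice_profile(ref$fes, 0)
  expect_gte(max(s0$F, na.rm = TRUE), ref$lowest_barrier - 1e-9)
})

test_that("window seeds are deterministic, distinct and platform-stable", {
  expect_identical(window_seed(1, 1), window_seed(1, 1))
  ids <- vapply(1:312, function(i) window_seed(101, i), integer(1))
  expect_equal(anyDuplicated(ids), 0L)
  expect_false(window_seed(1, 2) == window_seed(2, 1))
})

test_that("the window sampler is reproducible and equilibrates around the bias centre", {
  flat <- function(cpdb, chi) rep(0, length(cpdb))
  w <- umbrella_window(3, 20, -60, k_cpdb = 2000, k_chi = 2000)
  p <- mc_params(step_sizes = c(1.5, 1.5), n_steps = 1000, seed = 17)
  e1 <- sample_window_mc(flat, w, p)
  e2 <- sample_window_mc(flat, w, p)
  expect_identical(e1$samples, e2$samples)
  # strong bias: sample mean within 2 standard errors of the centre
  for (col in c("cpdb", "chi")) {
    x <- angle_diff(e1$samples[, col], if (col == "cpdb") 20 else -60)
    se <- stats::sd(x) / sqrt(length(x) / 10)  # generous autocorrelation allowance
    expect_lt(abs(mean(x)), 2 * se + 0.05)
  }
})

test_that("sampled variance matches the combined-stiffness Gaussian closed form", {
  a <- 20  # kcal/mol/rad^2 surface curvature in chi
  f_true <- function(cpdb, chi) a * (wrap_angle(chi) * pi / 180)^2
  w <- umbrella_window(1, 0, 0, k_cpdb = 60, k_chi = 50)
  e <- sample_window_mc(f_true, w, mc_params(n_steps = 6000, thin = 2, seed = 23))
  v_chi <- stats::var(e$samples[, "chi"] * pi / 180)
  kT <- 1.9872041e-3 * 300
  expect_equal(v_chi, kT / (2 * (a + 50)), tolerance = 0.05)
})

test_that("a flat unbiased chain samples the circle uniformly", {
  flat <- function(cpdb, chi) rep(0, length(cpdb))
  w <- umbrella_window(1, 0, 0, k_cpdb = 0, k_chi = 0)
  e <- sample_window_mc(flat, w, mc_params(step_sizes = c(90, 90), n_steps = 4000,
                                           thin = 5, n_chains = 4, seed = 29))
  h <- table(cut(e$samples[, "chi"], breaks = seq(-180, 180, by = 18)))
  gof <- stats::chisq.test(as.vector(h))
  expect_gt(gof$p.value, 0.01)
})

test_that("window acceptance rates stay in the tuned band on the default surface", {
  ms <- model_surface()
  grid <- build_window_grid()
  probe <- c(1, 12, 150, 157, 301, 312)  # corners and centre of the grid
  for (i in probe) {
    e <- sample_window_mc(ms, grid$windows[[i]], mc_params(n_steps = 600, seed = 41))
    expect_gt(e$acceptance, 0.2)
    expect_lt(e$acceptance, 0.8)
  }
})

test_that("well-tempered hills decay as prescribed and cover the window grid", {
  ms <- model_surface()
  # gamma -> infinity limit: constant hill heights
  run_inf <- sample_wt_metadynamics(ms, metad_params(gamma = 1e9, stride = 25),
                                    n_steps = 2000, seed = 2)
  expect_equal(run_inf$hills$height, rep(1, nrow(run_inf$hills)), tolerance = 1e-6)
  # finite gamma: heights at revisited points never increase
  run <- sample_wt_metadynamics(ms, metad_params(), n_steps = 30000, seed = 3)
  h <- run$hills
  for (i in seq_len(min(nrow(h), 400))) {
    near <- which(abs(h$cpdb - h$cpdb[i]) < 2 & abs(angle_diff(h$chi, h$chi[i])) < 2)
    later <- near[near > i]
    if (length(later)) expect_true(all(h$height[later] <= h$height[i] + 1e-9))
  }
  expect_true(all(h$height <= 1 + 1e-9))
})

test_that("a long exploration run visits nearly every umbrella window cell", {
  ms <- model_surface()
  grid <- build_window_grid()
  run <- sample_wt_metadynamics(ms, metad_params(), n_steps = 120000, seed = 5)
  expect_gte(window_coverage(run$trajectory, grid), 0.9)
})
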