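# Topography analysis: minima, minimax transition states, basin labels, the
# route taxonomy and the cumulative-time convergence diagnostic.

toy_fes <- function(F, sampled = NULL, bw_x = 5, bw_chi = NULL) {
  nx <- nrow(F); ny <- ncol(F)
  if (is.null(bw_chi)) bw_chi <- 360 / ny
  xe <- seq(0, by = bw_x, length.out = nx + 1)
  ye <- seq(-182.5, by = bw_chi, length.out = ny + 1)
  if (is.null(sampled)) sampled <- matrix(TRUE, nx, ny)
  fes_grid(xe, ye, F, sampled)
}

critical_point_of <- function(fes, ix, iy) {
  bpflip:::critical_point("minimum", fes$cpdb_centers[ix], fes$chi_centers[iy],
                          fes$F[ix, iy], ix, iy)
}

gauss_per_test <- function(x, x0, s) exp(-0.5 * (wrap_angle(x - x0) / s)^2)

f_surface_obj <- function(f) structure(list(f = f), class = "model_surface")

test_that("find_minima locates paraboloid bottoms and separated wells", {
  xc <- 1:9; yc <- 1:9
  F1 <- outer((xc - 5)^2, rep(1, 9)) + outer(rep(1, 9), (yc - 5)^2)
  m1 <- find_minima(toy_fes(F1, bw_chi = 40))
  expect_length(m1, 1)
  expect_equal(c(m1[[1]]$ix, m1[[1]]$iy), c(5, 5))
  F2 <- pmin(outer((xc - 3)^2, rep(1, 9)) + outer(rep(1, 9), (yc - 3)^2),
             1 + outer((xc - 7)^2, rep(1, 9)) + outer(rep(1, 9), (yc - 7)^2))
  m2 <- find_minima(toy_fes(F2, bw_chi = 40))
  expect_length(m2, 2)
  expect_equal(m2[[1]]$F, 0)  # sorted by F
})

test_that("find_ts solves the three-bin ridge and the symmetric double well", {
  f1 <- toy_fes(matrix(c(0, 5, 1), 3, 1), bw_chi = 360)
  a <- critical_point_of(f1, 1, 1)
  b <- critical_point_of(f1, 3, 1)
  ts <- find_ts(f1, a, b)
  expect_equal(ts$F, 5)
  expect_equal(ts$ix, 2)
  # symmetric double well with a saddle in the middle column
  x <- seq(-2, 2, length.out = 11)
  Fdw <- outer((x^2 - 1)^2 * 3, rep(1, 7)) + outer(rep(1, 11), c(3, 2, 1, 0, 1, 2, 3))
  fdw <- toy_fes(Fdw, bw_chi = 360 / 7)
  mins <- find_minima(fdw)
  expect_length(mins, 2)
  ts2 <- find_ts(fdw, mins[[1]], mins[[2]])
  expect_equal(ts2$ix, 6)    # the symmetric middle column
  expect_equal(ts2$F, Fdw[6, 4] - min(Fdw))  # grid is minimum-referenced
})

test_that("minimax barriers equal the threshold-connectivity oracle on random grids", {
  set.seed(202)
  for (rep in 1:30) {
    nx <- sample(4:12, 1); ny <- sample(4:12, 1)
    F <- matrix(stats::runif(nx * ny, 0, 10), nx, ny)
    S <- matrix(stats::runif(nx * ny) > 0.1, nx, ny)
    from <- c(sample(nx, 1), sample(ny, 1))
    to <- c(sample(nx, 1), sample(ny, 1))
    S[from[1], from[2]] <- TRUE; S[to[1], to[2]] <- TRUE
    fes <- toy_fes(F, sampled = S)
    mp <- minimax_path(fes, from, to)
    # compare on the grid's own (minimum-referenced) scale
    oracle <- minimax_oracle(ifelse(fes$sampled, fes$F, Inf), fes$sampled, from, to)
    if (is.null(mp)) {
      expect_equal(oracle, Inf)
    } else {
      expect_equal(mp$barrier_F, oracle, tolerance = 1e-12)
      expect_equal(max(fes$F[mp$path]), mp$barrier_F)
    }
  }
})

test_that("disconnected basins raise a no-path error", {
  F <- matrix(0, 5, 1)
  S <- matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE), 5, 1)
  fes <- toy_fes(F, sampled = S, bw_chi = 360)
  a <- critical_point_of(fes, 1, 1); b <- critical_point_of(fes, 5, 1)
  expect_error(find_ts(fes, a, b), "not connected")
})

test_that("basin labelling follows the anti/syn and flipping rules", {
  mk <- function(cpdb, chi, F) bpflip:::critical_point("minimum", cpdb, chi, F)
  basic <- label_basins(list(mk(0, -105, 0), mk(0, 55, 4.4)))
  expect_equal(vapply(basic, function(b) b$label, character(1)), c("WC", "HG"))
  with_ls <- label_basins(list(mk(0, -105, 0), mk(0, 55, 4.4), mk(-57, 51, 6)))
  expect_equal(vapply(with_ls, function(b) b$label, character(1)), c("WC", "HG", "LS"))
  only_anti <- label_basins(list(mk(3, -120, 0)))
  expect_equal(only_anti[[1]]$label, "WC")
  expect_warning(label_basins(list(mk(0, 30, 0))), "no anti")
  # heavily flipped anti minimum is not WC
  flipped <- suppressWarnings(label_basins(list(mk(-80, -110, 0), mk(0, 50, 2))))
  expect_equal(vapply(flipped, function(b) b$label, character(1)), c("other", "HG"))
})

test_that("path classification implements the printed route taxonomy", {
  # clockwise small flipping: chi decreasing through the seam
  p_r1 <- data.frame(cpdb = c(0, 5, 5, 5, 0), chi = c(-105, -160, 150, 90, 55))
  expect_equal(classify_path(p_r1), "R1")
  # counterclockwise through the minor groove
  p_l3 <- data.frame(cpdb = c(0, -75, -75, 0), chi = c(-105, -60, 20, 55))
  expect_equal(classify_path(p_l3), "L3")
  # between the printed cutoffs: unclassified
  p_mid <- data.frame(cpdb = c(0, 40, 0), chi = c(-105, -30, 55))
  expect_equal(classify_path(p_mid), "unclassified")
  # mirroring chi about the starting basin flips the rotation sense
  mirror_chi <- function(p, about = -105) within(p, chi <- wrap_angle(2 * about - chi))
  expect_equal(classify_path(mirror_chi(p_r1)), "L1")
  expect_equal(classify_path(mirror_chi(p_l3)), "R3")
})

test_that("delta_g is antisymmetric and barriers ignore the additive reference", {
  fes <- truth_fes(model_surface())
  mins <- find_minima(fes)
  bas <- label_basins(mins)
  labs <- vapply(bas, function(b) b$label, character(1))
  wc <- bas[[which(labs == "WC")]]; hg <- bas[[which(labs == "HG")]]
  expect_equal(delta_g(fes, wc, hg), -delta_g(fes, hg, wc))
  ts <- find_ts(fes, wc, hg)
  shifted <- fes_grid(fes$cpdb_edges, fes$chi_edges, fes$F + 7.3, fes$sampled,
                      temperature = fes$temperature)
  mins2 <- find_minima(shifted)
  bas2 <- label_basins(mins2)
  labs2 <- vapply(bas2, function(b) b$label, character(1))
  wc2 <- bas2[[which(labs2 == "WC")]]; hg2 <- bas2[[which(labs2 == "HG")]]
  expect_equal(delta_g(shifted, wc2, hg2), delta_g(fes, wc, hg), tolerance = 1e-9)
  ts2 <- find_ts(shifted, wc2, hg2)
  expect_equal(ts2$F - wc2$point$F, ts$F - wc$point$F, tolerance = 1e-9)
})

test_that("forward barriers dominate the endpoint free-energy difference", {
  fes <- truth_fes(model_surface())
  bas <- label_basins(find_minima(fes))
  labs <- vapply(bas, function(b) b$label, character(1))
  wc <- bas[[which(labs == "WC")]]; hg <- bas[[which(labs == "HG")]]
  ls <- bas[[which(labs == "LS")]]
  paths <- extract_paths(fes, wc, hg, ls)
  for (p in paths) {
    if (is.null(p)) next
    expect_gte(p$forward_barrier, delta_g(fes, wc, hg) - 1e-9)
    expect_gte(p$forward_barrier, 0)
    expect_equal(p$forward_barrier - p$reverse_barrier, delta_g(fes, wc, hg),
                 tolerance = 1e-9)
  }
})

test_that("route constraints separate the small channel from the forced detours", {
  # a surface with a single low rotation channel at small |CPDb|
  f_chan <- function(cpdb, chi) {
    gate <- 0.3 + 0.7 * exp(-0.5 * (cpdb / 25)^2)
    ridge <- 8 * (gauss_per_test(chi, 90, 25) + gauss_per_test(chi, -75, 25))
    0.004 * cpdb^2 + ridge * (2 - gate)
  }
  fes <- truth_fes(f_surface_obj(f_chan))
  a <- critical_point_of(fes, which.min(abs(fes$cpdb_centers)),
                         which.min(abs(fes$chi_centers + 105)))
  b <- critical_point_of(fes, which.min(abs(fes$cpdb_centers)),
                         which.min(abs(fes$chi_centers - 55)))
  wc <- structure(list(label = "WC", point = a), class = "basin_label")
  hg <- structure(list(label = "HG", point = b), class = "basin_label")
  paths <- extract_paths(fes, wc, hg)
  expect_false(is.null(paths$R1))
  for (nm in c("R2", "R3", "L2", "L3")) {
    if (is.null(paths[[nm]])) next
    expect_gt(paths[[nm]]$forward_barrier, paths$R1$forward_barrier)
    expect_gt(paths[[nm]]$forward_barrier, paths$L1$forward_barrier)
  }
})

test_that("cumulative-fraction diagnostics vanish for identical data", {
  f_true <- function(cpdb, chi) 1 - cos(chi * pi / 180)
  # well-overlapped windows (sigma ~ 14 deg vs 30 deg spacing) so the WHAM
  # fixed point is reached rather than approached
  wins <- lapply(1:12, function(i) umbrella_window(i, 0, -180 + (i - 1) * 30, k_chi = 8))
  ens <- lapply(wins, function(w) sample_window_mc(f_true, w, mc_params(seed = 9, n_steps = 400)))
  cr1 <- convergence_report(ens, fractions = 1, bin_width = 20)
  expect_equal(cr1$rms, 0)
  expect_equal(cr1$threshold, 1.9872041e-3 * 300, tolerance = 1e-12)
  # duplicated samples: the first half equals the full histogram
  dup <- lapply(ens, function(e) {
    biased_ensemble(e$window, rbind(e$samples, e$samples))
  })
  cr2 <- convergence_report(dup, fractions = c(0.5, 1), bin_width = 20)
  expect_lt(cr2$rms[1], 1e-5)
  expect_error(convergence_report(ens, fractions = c(0.5, 0.8)), "all.equal|1")
})
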