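# Reaction-coordinate geometry: signed dihedrals, centres of mass, the chi
# and CPDb coordinates, and the anti/syn classification.

test_that("dihedral reproduces the planar reference arrangements", {
  a <- c(1, 0, 0); b <- c(0, 0, 0); c3 <- c(0, 0, 1)
  expect_equal(dihedral(a, b, c3, c(1, 0, 1)), 0)
  expect_equal(dihedral(a, b, c3, c(-1, 0, 1)), -180)  # trans, wrapped
})

test_that("dihedral matches an explicit rotation-matrix construction", {
  a <- c(1, 0, 0); b <- c(0, 0, 0); c3 <- c(0, 0, 1)
  d_cis <- c(1, 0, 1)
  for (theta in c(37, -37, 1, 89.5, -120, 175, -179.5)) {
    d <- rotate_about(d_cis - c3, c3 - b, theta) + c3
    expect_equal(dihedral(a, b, c3, d), wrap_angle(theta), tolerance = 1e-9)
  }
})

test_that("dihedral is invariant under rigid motion and flips sign on reflection", {
  set.seed(7)
  for (rep in 1:20) {
    pts <- lapply(1:4, function(i) stats::rnorm(3, sd = 3))
    phi <- tryCatch(do.call(dihedral, pts), error = function(e) NULL)
    if (is.null(phi)) next
    rot <- random_rotation()
    shift <- stats::rnorm(3, sd = 10)
    moved <- lapply(pts, function(p) rot(p) + shift)
    expect_equal(do.call(dihedral, moved), phi, tolerance = 1e-9)
    mirrored <- lapply(pts, function(p) p * c(-1, 1, 1))
    expect_equal(do.call(dihedral, mirrored), wrap_angle(-phi), tolerance = 1e-9)
  }
})

test_that("dihedral rejects degenerate geometry naming the points", {
  a <- c(0, 0, 0)
  expect_error(dihedral(a, a + 1e-14, c(0, 0, 1), c(1, 0, 1)), "collinear|coincide")
  expect_error(dihedral(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), "a, b, c")
})

test_that("center_of_mass is the mass-weighted mean", {
  expect_equal(center_of_mass(5, c(1, 2, 3)), c(1, 2, 3))
  expect_equal(center_of_mass(c(1, 1), rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(center_of_mass(c(12, 1), rbind(c(0, 0, 0), c(13, 0, 0))), c(1, 0, 0))
  expect_error(center_of_mass(numeric(0), matrix(0, 0, 3)), "empty")
  expect_error(center_of_mass(c(1, -1), rbind(c(0, 0, 0), c(1, 0, 0))), "> 0")
})

# a minimal purine-bearing frame whose chi-defining atoms are laid out
# explicitly (values in Angstrom; geometry synthetic)
chi_frame <- function(theta = 0) {
  d <- rotate_about(c(1, 0, 0), c(0, 0, 1), theta) + c(0, 0, 1.5)
  structure_frame(
    resno = c(16, 16, 16, 16, 16),
    resid = "DA",
    elety = c("O4'", "C1'", "N9", "C4", "N7"),
    x = c(1.4, 0, 0, d[1], 2), y = c(0, 0, 0, d[2], 2), z = c(0, 0, 1.5, d[3], 2)
  )
}

test_that("chi_angle resolves atoms by name, not input order", {
  fr <- chi_frame(0)
  expect_equal(chi_angle(fr, 16), 0)
  shuffled <- fr[c(4, 2, 5, 1, 3), ]
  class(shuffled) <- class(fr)
  expect_equal(chi_angle(shuffled, 16), 0)
  fr37 <- chi_frame(37)
  expect_equal(chi_angle(fr37, 16), 37, tolerance = 1e-9)
  missing <- fr[fr$elety != "N9", ]
  class(missing) <- class(fr)
  expect_error(chi_angle(missing, 16), "N9")
})

test_that("cpdb_angle reduces to the plain dihedral for single-atom groups", {
  fr <- structure_frame(
    resno = 1:4, resid = "X", elety = rep("C1'", 4),
    x = c(1, 0, 0, 1), y = c(0, 0, 0, 0.8), z = c(0, 0, 1, 1)
  )
  spec <- pseudoatom_spec(
    p1 = list(list(resno = 1, atoms = NULL)), p2 = list(list(resno = 2, atoms = NULL)),
    p3 = list(list(resno = 3, atoms = NULL)), p4 = list(list(resno = 4, atoms = NULL))
  )
  expect_equal(cpdb_angle(fr, spec),
               dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(1, 0.8, 1)))
})

test_that("cpdb_angle equals the dihedral of independently computed centroids", {
  set.seed(21)
  xyz <- matrix(stats::rnorm(36, sd = 4), ncol = 3)
  fr <- structure_frame(resno = rep(1:4, each = 3), resid = "X",
                        elety = paste0("C", 1:12),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  spec <- pseudoatom_spec(
    p1 = list(list(resno = 1, atoms = NULL)), p2 = list(list(resno = 2, atoms = NULL)),
    p3 = list(list(resno = 3, atoms = NULL)), p4 = list(list(resno = 4, atoms = NULL))
  )
  coms <- lapply(1:4, function(r) colMeans(xyz[rep(1:4, each = 3) == r, ]))
  expect_equal(cpdb_angle(fr, spec), do.call(dihedral, coms), tolerance = 1e-9)
  # chirality: mirror-imaging the frame negates the pseudodihedral
  fr_m <- fr; fr_m$x <- -fr_m$x
  expect_equal(cpdb_angle(fr_m, spec), wrap_angle(-cpdb_angle(fr, spec)),
               tolerance = 1e-9)
  bad <- pseudoatom_spec(p1 = list(list(resno = 9, atoms = NULL)),
                         p2 = spec$p2, p3 = spec$p3, p4 = spec$p4)
  expect_error(cpdb_angle(fr, bad), "pseudoatom p1")
})

test_that("classify_chi partitions the circle with the printed boundaries", {
  expect_equal(classify_chi(c(-120, 0, 135)), c("anti", "syn", "other"))
  expect_equal(classify_chi(-90), "syn")   # printed syn interval closed at -90
  expect_equal(classify_chi(90), "syn")
  expect_equal(classify_chi(-180), "anti")
  grid <- seq(-180, 179.75, by = 0.25)
  labels <- classify_chi(grid)
  expect_true(all(labels %in% c("anti", "syn", "other")))
  expect_equal(sum(labels == "anti") + sum(labels == "syn") + sum(labels == "other"),
               length(grid))
})

test_that("extract_timeseries preserves order and names failing frames", {
  frames <- list(chi_frame(10), chi_frame(-30), chi_frame(120))
  spec <- pseudoatom_spec(
    p1 = list(list(resno = 16, atoms = "O4'")), p2 = list(list(resno = 16, atoms = "C1'")),
    p3 = list(list(resno = 16, atoms = "N9")), p4 = list(list(resno = 16, atoms = "C4"))
  )
  ts <- extract_timeseries(frames, 16, spec)
  expect_s3_class(ts, "torsion_series")
  expect_equal(ts$chi, c(10, -30, 120), tolerance = 1e-9)
  expect_equal(ts$time, c(0, 1, 2))
  broken <- frames
  broken[[2]] <- broken[[2]][broken[[2]]$elety != "C4", ]
  class(broken[[2]]) <- class(frames[[2]])
  expect_error(extract_timeseries(broken, 16, spec), "frame 2")
})

test_that("multi-model PDB input round-trips through the frame reader", {
  pdb_text <- c(
    "MODEL        1",
    "ATOM      1  O4'  DA A  16       1.400   0.000   0.000  1.00  0.00           O",
    "ATOM      2  C1'  DA A  16       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N9   DA A  16       0.000   0.000   1.500  1.00  0.00           N",
    "ATOM      4  C4   DA A  16       1.000   0.000   1.500  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  O4'  DA A  16       1.400   0.000   0.000  1.00  0.00           O",
    "ATOM      2  C1'  DA A  16       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N9   DA A  16       0.000   0.000   1.500  1.00  0.00           N",
    "ATOM      4  C4   DA A  16       0.000   1.000   1.500  1.00  0.00           C",
    "ENDMDL",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_text, path)
  frames <- read_pdb_frames(path)
  expect_length(frames, 2)
  expect_equal(chi_angle(frames[[1]], 16), 0, tolerance = 1e-6)
  expect_equal(abs(chi_angle(frames[[2]], 16)), 90, tolerance = 1e-6)
  expect_true(all(frames[[1]]$mass > 10))
})
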