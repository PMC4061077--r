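test_that("bond vectors have the stated polar angle and unit length", {
  g0 <- helix_geometry(bond_azimuth_beta = 0)
  u <- bond_vector(1, g0)
  expect_equal(u, c(sin(121.1 * pi / 180), 0, cos(121.1 * pi / 180)),
               tolerance = 1e-12)
  expect_equal(round(u, 4), c(0.8563, 0, -0.5165))

  ## degenerate polar angle: bond along the helix axis for any residue
  gz <- helix_geometry(bond_polar_alpha = 0)
  for (i in c(1, 7, 21)) {
    expect_equal(bond_vector(i, gz), c(0, 0, 1), tolerance = 1e-12)
  }

  g <- helix_geometry()
  for (i in 1:21) {
    expect_equal(sqrt(sum(bond_vector(i, g)^2)), 1, tolerance = 1e-12)
  }
  ## 18 residues x 100 deg/residue = 5 turns: same azimuth mod 360
  expect_equal((bond_azimuth(3, g) - bond_azimuth(21, g)) %% 360,
               0, tolerance = 1e-9)
  expect_error(bond_vector(0, g), "out of range")
  expect_error(bond_vector(25, g, sequence_length = 21), "out of range")
})

test_that("angle to the membrane normal follows the tilt/rotation geometry", {
  g <- helix_geometry()
  ## untilted helix: theta = alpha for every residue, any rho
  for (rho in c(0, 77, 300)) {
    th <- vapply(1:21, angle_to_normal, numeric(1),
                 orient = orientation(0, rho), geom = g)
    expect_equal(th, rep(121.1, 21), tolerance = 1e-9)
  }
  ## aligned case: tau = 90, alpha = 90, bond azimuth == rho
  g90 <- helix_geometry(bond_polar_alpha = 90, bond_azimuth_beta = 0)
  expect_equal(angle_to_normal(g90$reference_residue, orientation(90, 0), g90),
               0, tolerance = 1e-9)
  ## direct trigonometric case: tau 55, phi - rho = 60
  phi1 <- bond_azimuth(1, g)
  expect_equal(angle_to_normal(1, orientation(55, phi1 - 60), g),
               86.88, tolerance = 1e-2)
  ## periodicity in rho
  expect_equal(angle_to_normal(5, orientation(40, 10), g),
               angle_to_normal(5, orientation(40, 370), g),
               tolerance = 1e-12)
})

test_that("uniform azimuthal averaging reproduces the addition theorem", {
  g <- helix_geometry()
  p2 <- function(x) (3 * x^2 - 1) / 2
  for (tau in c(10, 55, 90, 140)) {
    th <- vapply(seq(0, 359.5, by = 0.5), function(r)
      angle_to_normal(10, orientation(tau, r), g), numeric(1))
    expect_equal(mean(p2(cos(th * pi / 180))),
                 p2(cos(tau * pi / 180)) * p2(cos(121.1 * pi / 180)),
                 tolerance = 1e-6)
  }
})

test_that("helix coordinates realise the requested tilt", {
  g <- helix_geometry()
  co <- build_helix_coordinates(tp10_sequence, orientation(0, 0), g)
  expect_equal(diff(co$ca_z), rep(1.5, 20), tolerance = 1e-12)

  ## principal axis of the Calpha set recovers tau; a 36-mer spans an
  ## integer number of turns, so the principal component is free of
  ## the end effects a fractional final turn adds
  seq36 <- strrep("A", 36)
  for (tau in c(0, 17, 55, 90, 123)) {
    co <- build_helix_coordinates(seq36, orientation(tau, 120), g)
    xyz <- as.matrix(co[, c("ca_x", "ca_y", "ca_z")])
    ax <- prcomp(xyz)$rotation[, 1]
    ang <- acos(abs(ax[3]) / sqrt(sum(ax^2))) * 180 / pi
    expect_lt(abs(ang - min(tau, 180 - tau)), 1)
  }
  ## the 21-mer (5.8 turns) still recovers its tilt to ~1 degree
  co <- build_helix_coordinates(tp10_sequence, orientation(55, 120), g)
  ax <- prcomp(as.matrix(co[, c("ca_x", "ca_y", "ca_z")]))$rotation[, 1]
  expect_lt(abs(acos(abs(ax[3])) * 180 / pi - 55), 1.5)
  expect_error(build_helix_coordinates("", orientation(0, 0)), "empty")
})

test_that("at the fitted monomer orientation the lysines point to the water", {
  co <- build_helix_coordinates(tp10_sequence, orientation(55, 120))
  dz <- co$cb_z - co$ca_z   # side-chain z offset, independent of axis drift
  lys <- c(11, 18, 19)
  hydrophobic_c <- c(10, 13, 16, 20, 21)
  ## Lys11/Lys18 point clearly up; Lys19 lies almost in the membrane
  ## plane but still above every hydrophobic C-terminal side chain
  expect_true(all(dz[c(11, 18)] > 0))
  expect_true(all(dz[hydrophobic_c] < 0))
  expect_true(min(dz[lys]) > max(dz[hydrophobic_c]))
})

test_that("helical wheel faces follow rho and the 100-degree twist", {
  g <- helix_geometry()
  w <- helical_wheel(tp10_sequence, orientation(55, 120), 10:21, g)
  dd <- diff(w$azimuth) %% 360
  expect_equal(dd, rep((-g$twist_per_residue) %% 360, length(dd)),
               tolerance = 1e-9)
  expect_true(all(w$face[w$residue_index %in% c(11, 18, 19)] ==
                    "polar-facing"))
  expect_true(all(w$face[w$residue_index %in% c(10, 13, 16, 20, 21)] ==
                    "membrane-facing"))
  ## rotating rho by 180 flips every face
  w2 <- helical_wheel(tp10_sequence, orientation(55, 300), 10:21, g)
  expect_true(all(w$face != w2$face))
  expect_error(helical_wheel(tp10_sequence, orientation(0, 0), integer(0)),
               "empty")
  expect_error(helical_wheel(tp10_sequence, orientation(0, 0), 19:25),
               "outside")
})

test_that("PDB export round-trips through a standard reader", {
  tmp <- tempfile(fileext = ".pdb")
  co <- build_helix_coordinates(tp10_sequence, orientation(0, 0))
  write_helix_pdb(co, tmp)
  pdb <- bio3d::read.pdb(tmp)
  expect_equal(nrow(pdb$atom), 2 * 21)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  expect_equal(nrow(ca), 21)
  ## untilted: Calpha z strictly increasing
  expect_true(all(diff(ca$z[order(ca$resno)]) > 0))
  unlink(tmp)
})
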