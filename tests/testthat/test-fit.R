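test_that("rmsd is zero for self-consistent data and matches hand arithmetic", {
  o <- orientation(55, 120)
  d <- dynamics_params(0, 16)
  m <- make_helix_couplings(55, 120, 0, 16)
  expect_lt(coupling_rmsd(m, o, d), 1e-9)

  m2 <- m[m$tilt_deg == 0, ][1:2, ]
  m2$splitting_khz <- predict_splittings(m2$residue_index, o, d) + c(1, -1)
  expect_equal(coupling_rmsd(m2, o, d), 1.0, tolerance = 1e-9)

  mp <- m
  mp$powder_flag[1] <- TRUE
  expect_error(coupling_rmsd(mp, o, d), "powder")
})

test_that("noiseless couplings are recovered exactly on the grid,
           with the mirror solution in the degenerate set", {
  m <- make_helix_couplings(55, 120, 0, 16)
  ft <- fit_orientation(m)
  sol <- ft$solution
  expect_equal(sol$tau, 55)
  expect_equal(sol$rho, 120)
  expect_equal(sol$sigma_tau, 0)
  expect_equal(sol$sigma_rho, 16)
  expect_lt(sol$rmsd, 1e-6)
  expect_equal(sol$n_labels, 5)
  ## mirror orientation predicts identical couplings (P2 is even)
  expect_true(any(sol$degenerate_set$tau == 125 &
                    sol$degenerate_set$rho == 300))
  ## degenerate set contains the canonical cell
  expect_true(any(sol$degenerate_set$tau == sol$tau &
                    sol$degenerate_set$rho == sol$rho))
  ## landscape minimum is at best_cell and matches the solution RMSD
  ## to the floating-point floor
  ls <- ft$landscape
  expect_equal(min(ls$rmsd), ls$rmsd[ls$best_cell[1], ls$best_cell[2]])
  expect_equal(sol$rmsd, ls$rmsd[ls$best_cell[1], ls$best_cell[2]],
               tolerance = 1e-6)
})

test_that("reported rmsd equals rmsd recomputed at the reported parameters", {
  m <- make_helix_couplings(40, 200, 0, 0, noise_sd = 0.5, seed = 3)
  ft <- fit_orientation(m)
  sol <- ft$solution
  expect_equal(coupling_rmsd(m, orientation(sol$tau, sol$rho),
                             dynamics_params(sol$sigma_tau, sol$sigma_rho)),
               sol$rmsd, tolerance = 1e-6)
})

test_that("the fit is invariant under measurement reordering and does not
           degrade when an exactly-predicted measurement is added", {
  m <- make_helix_couplings(70, 30, 0, 0, noise_sd = 0.5, seed = 9)
  ft1 <- fit_orientation(m)
  ft2 <- fit_orientation(m[rev(seq_len(nrow(m))), ])
  expect_equal(ft1$solution$tau, ft2$solution$tau)
  expect_equal(ft1$solution$rho, ft2$solution$rho)
  expect_equal(ft1$landscape$rmsd, ft2$landscape$rmsd, tolerance = 1e-12)

  sol <- ft1$solution
  extra <- m[1, ]
  extra$residue_index <- 14L
  extra$site <- "A14"
  extra$tilt_deg <- 0
  extra$splitting_khz <- predict_splittings(
    14L, orientation(sol$tau, sol$rho),
    dynamics_params(sol$sigma_tau, sol$sigma_rho))
  ft3 <- fit_orientation(rbind(m, extra))
  expect_lte(ft3$solution$rmsd, sol$rmsd + 1e-9)
})

test_that("a single measurement yields a degenerate band, not a point", {
  m <- make_helix_couplings(55, 120, 0, 0)[1, , drop = FALSE]
  expect_warning(ft <- fit_orientation(m), "degenerate")
  expect_gt(nrow(ft$solution$degenerate_set), 50)
  expect_lt(min(ft$solution$degenerate_set$rmsd), 1e-6)
})

test_that("all-powder input cannot be fitted to an oriented model", {
  m <- make_helix_couplings(55, 120, 0, 0)
  m$powder_flag <- TRUE
  expect_error(fit_orientation(m), "immobilized")
})

test_that("segmental analysis separates the unstructured N-terminus from
           the helical C-terminus of the monomer fixture", {
  fx <- make_tp10_fixture("L_monomer_1to400", noise_sd = 0.5, seed = 1)
  sf <- segmental_fit(fx)
  expect_named(sf, c("N_terminal", "C_terminal"), ignore.order = TRUE)
  expect_equal(sf$N_terminal$verdict, "unstructured")
  expect_equal(sf$C_terminal$verdict, "helical_fit")
  expect_lt(sf$C_terminal$solution$rmsd, 1.0)
  expect_gt(sf$N_terminal$solution$rmsd, 1.0)
  ## a straight helix through all nine labels is far worse than the
  ## 5-label C-terminal fit
  ft_all <- fit_orientation(fx)
  expect_gt(ft_all$solution$rmsd, 3 * sf$C_terminal$solution$rmsd)
})

test_that("labels generated from one helix give the same segmental answer
           in both segments", {
  m <- make_helix_couplings(55, 120, 0, 16,
                            positions = c(2L, 4L, 5L, 8L, 10L, 13L, 16L,
                                          20L, 21L))
  sf <- segmental_fit(m, segment_map = tp10_segments)
  expect_equal(sf$N_terminal$solution$tau, sf$C_terminal$solution$tau)
  expect_equal(sf$N_terminal$solution$rho, sf$C_terminal$solution$rho)
  expect_equal(sf$N_terminal$verdict, "helical_fit")
})

test_that("a two-label segment returns a flagged, degenerate solution", {
  m <- make_helix_couplings(55, 120, 0, 0, positions = c(10L, 13L))
  ft <- fit_orientation(m)
  expect_lt(ft$solution$rmsd, 1e-6)
  expect_gt(nrow(ft$solution$degenerate_set), 2)
})

test_that("dipolar wave is periodic over 18 residues and flat for an
           untilted helix", {
  o <- orientation(55, 120)
  w <- dipolar_wave(o, dynamics_params(0, 0), residue_range = 1:40)
  expect_equal(w$predicted_khz[1:20], w$predicted_khz[19:38],
               tolerance = 1e-9)

  w0 <- dipolar_wave(orientation(0, 0), residue_range = 1:21)
  expect_equal(w0$predicted_khz, rep(static_splitting(121.1), 21),
               tolerance = 1e-9)

  ## the wave at the fitted parameters reproduces the fit's predictions
  m <- make_helix_couplings(55, 120, 0, 16)
  ft <- fit_orientation(m)
  sol <- ft$solution
  wv <- dipolar_wave(orientation(sol$tau, sol$rho),
                     dynamics_params(sol$sigma_tau, sol$sigma_rho),
                     residue_range = m$residue_index[m$tilt_deg == 0])
  obs <- m$splitting_khz[m$tilt_deg == 0]
  expect_equal(sqrt(mean((wv$predicted_khz - obs)^2)), 0, tolerance = 1e-6)
})
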