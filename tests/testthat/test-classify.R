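test_that("mobility is read from the 0/90-degree scaling behaviour", {
  expect_equal(mobility_call(7.0, -3.5), "mobile")
  expect_equal(mobility_call(-8.0, -8.0), "immobile")
  ## degenerate zero case satisfies both rules
  expect_equal(mobility_call(0.0, 0.0), "indeterminate")
  expect_warning(r <- mobility_call(7.0, NA), "missing")
  expect_equal(r, "indeterminate")
})

test_that("uniform couplings near +7 kHz are called unstructured", {
  expect_true(unstructured_call(c(7.2, 6.8, 7.0, 6.5)))
  expect_false(unstructured_call(c(7.0, -1.6)))
  expect_warning(r <- unstructured_call(numeric(0)), "fewer than 2")
  expect_true(is.na(r))
})

test_that("the positional scan flags exactly the aggregation-prone
           C-terminal substitution sites", {
  d <- make_tp10_fixture("D_highconc_1to50", noise_sd = 0.5, seed = 1)
  sc <- scan_states(d)
  agg <- sc$calls[sc$calls$conformation == "aggregated_beta_candidate", ]
  expect_setequal(agg$residue_index, c(13, 16, 20, 21))
  expect_true(all(agg$mobility == "immobile"))
  non <- sc$calls[!sc$calls$residue_index %in% c(13, 16, 20, 21), ]
  expect_setequal(non$residue_index, c(2, 4, 5, 8, 10))
  expect_false(any(non$conformation == "aggregated_beta_candidate"))
  expect_equal(sc$summary$n_aggregated, 4)
  expect_equal(sc$summary$aggregated_positions, "13,16,20,21")
})

test_that("an all-mobile helical dataset yields no aggregation calls and
           helical_fit for the fitted sites", {
  m <- make_helix_couplings(55, 120, 0, 0)
  sc <- scan_states(m)
  expect_false(any(sc$calls$conformation == "aggregated_beta_candidate"))
  ## sites with near-zero splittings cannot distinguish the two tilt
  ## rules and stay indeterminate; every determinate site is a mobile
  ## helix member
  det <- sc$calls[sc$calls$mobility != "indeterminate", ]
  expect_gte(nrow(det), 4)
  expect_true(all(det$mobility == "mobile"))
  expect_true(all(det$conformation == "helical_fit"))
  ## mutual exclusivity: helical calls are mobile
  expect_true(all(sc$calls$mobility[sc$calls$conformation == "helical_fit"]
                  == "mobile"))
})

test_that("a site with coexisting sharp and powder components is reported
           as partly aggregated", {
  m <- make_helix_couplings(55, 120, 0, 0)
  pw <- m[m$residue_index == 13, ]
  pw$splitting_khz <- powder_splitting()
  pw$powder_flag <- TRUE
  sc <- scan_states(rbind(m, pw))
  r13 <- sc$calls[sc$calls$residue_index == 13, ]
  expect_equal(r13$conformation, "aggregated_beta_candidate")
  expect_match(r13$evidence, "partly aggregated")
  expect_match(r13$evidence, "powder component")
})

test_that("state calls are invariant under consistent kHz -> Hz rescaling", {
  d <- make_tp10_fixture("D_highconc_1to50", noise_sd = 0.5, seed = 5)
  sc1 <- scan_states(d)
  d2 <- d
  d2$splitting_khz <- d2$splitting_khz * 1000
  d2$error_khz <- d2$error_khz * 1000
  cst2 <- model_constants(max_splitting = 16000,
                          unstructured_reference = 7000,
                          classification_tolerance = 1500)
  sc2 <- scan_states(d2, constants = cst2, mobility_tolerance = 1000,
                     helix_rejection = 1000)
  expect_equal(sc1$calls$mobility, sc2$calls$mobility)
  expect_equal(sc1$calls$conformation, sc2$calls$conformation)
})

test_that("the scan is a pure function of the dataset", {
  d <- make_tp10_fixture("D_highconc_1to50", noise_sd = 0.5, seed = 2)
  sc1 <- scan_states(d)
  sc2 <- scan_states(d[rev(seq_len(nrow(d))), ])
  expect_equal(sc1$calls, sc2$calls)
  expect_equal(sc1$summary, sc2$summary)
})

test_that("inconsistent duplicate measurements are rejected with a listing", {
  m <- make_helix_couplings(55, 120, 0, 0)
  dup <- m[1, ]
  dup$splitting_khz <- dup$splitting_khz + 2
  expect_error(scan_states(rbind(m, dup)), "inconsistent duplicate")
})
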