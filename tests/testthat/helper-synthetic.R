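## Shared helpers for building tiny synthetic datasets in tests.

## mirror-aware recovery error: the model cannot distinguish
## (tau, rho) from (180 - tau, rho + 180), so report the error of the
## closer branch
recovery_error <- function(tau_hat, rho_hat, tau_true, rho_true) {
  circ <- function(x) abs(((x + 180) %% 360) - 180)
  e1 <- c(tau = abs(tau_hat - tau_true), rho = circ(rho_hat - rho_true))
  e2 <- c(tau = abs((180 - tau_hat) - tau_true),
          rho = circ(rho_hat + 180 - rho_true))
  if (sum(e1) <= sum(e2)) e1 else e2
}

## a 5-label single-segment helical dataset at given truth
make_helix_couplings <- function(tau, rho, sigma_tau = 0, sigma_rho = 0,
                                 noise_sd = 0, seed = NULL,
                                 positions = c(10L, 13L, 16L, 20L, 21L)) {
  cfg <- synthetic_config(
    tp10_sequence, positions,
    stats::setNames(rep("seg", length(positions)), positions),
    list(seg = list(orientation = orientation(tau, rho),
                    dynamics = dynamics_params(sigma_tau, sigma_rho))),
    noise_sd = noise_sd, seed = seed)
  generate_couplings(cfg)
}

## independent Monte-Carlo oracle for the motionally averaged
## splitting: plain Gaussian sampling with antithetic variates in both
## angles, evaluated through the static angular dependence only
mc_averaged_splitting <- function(pos, tau, rho, sigma_tau, sigma_rho,
                                  n_pairs = 1e6,
                                  geom = helix_geometry(),
                                  constants = model_constants()) {
  z <- stats::rnorm(n_pairs)
  w <- stats::rnorm(n_pairs)
  a <- geom$bond_polar_alpha * pi / 180
  phi <- bond_azimuth(pos, geom) * pi / 180
  f <- function(tt, rr) {
    ct <- cos(tt) * cos(a) + sin(tt) * sin(a) * cos(phi - rr)
    constants$max_splitting * (3 * ct^2 - 1) / 2
  }
  tp <- (tau + sigma_tau * z) * pi / 180
  tm <- (tau - sigma_tau * z) * pi / 180
  rp <- (rho + sigma_rho * w) * pi / 180
  rm <- (rho - sigma_rho * w) * pi / 180
  mean(f(tp, rp) + f(tm, rp) + f(tp, rm) + f(tm, rm)) / 4
}
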