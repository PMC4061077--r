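#' Static (motion-free) CF3 dipolar splitting for a bond at angle
#' theta to the field
#'
#' The axially averaged dipolar coupling of the rotating CF3 group
#' scales with the second Legendre polynomial of the angle theta
#' between the Calpha--Cbeta bond and the magnetic field:
#' \deqn{\Delta\nu(\theta) = \Delta\nu_{max} \, P_2(\cos\theta),\quad
#'   P_2(x) = (3x^2 - 1)/2.}
#'
#' @param theta Angle(s) between bond and field, degrees.
#' @param constants A [model_constants()].
#' @return Signed splitting(s), kHz.
#' @export
#' @examples
#' static_splitting(0)                    # +max_splitting
#' static_splitting(model_constants()$magic_angle)   # ~0
static_splitting <- function(theta, constants = model_constants()) {
  x <- cos(deg2rad(theta))
  constants$max_splitting * (3 * x^2 - 1) / 2
}

## Fourier decomposition of P2(cos theta) in the bond azimuth.
## With A = cos(tau) cos(alpha), B = sin(tau) sin(alpha) and
## u = phi - rho:
##   P2(A + B cos u) = c0 + c1 cos u + c2 cos 2u,
##   c0 = (3A^2 - 1)/2 + (3/4)B^2,  c1 = 3AB,  c2 = (3/4)B^2.
## A Gaussian average over u ~ N(mu, s) then damps the harmonics:
##   <cos ku> = exp(-k^2 s^2/2) cos(k mu).
p2_fourier_coefs <- function(tau_rad, alpha_rad) {
  A <- cos(tau_rad) * cos(alpha_rad)
  B <- sin(tau_rad) * sin(alpha_rad)
  list(c0 = (3 * A^2 - 1) / 2 + 0.75 * B^2,
       c1 = 3 * A * B,
       c2 = 0.75 * B^2)
}

## Gauss-Hermite average of the Fourier coefficients over
## tau' ~ N(tau, sigma_tau). Returns scalar c0, c1, c2.
averaged_fourier_coefs <- function(tau_deg, sigma_tau_deg, alpha_rad,
                                   n_quad = 41) {
  if (sigma_tau_deg == 0) {
    p2_fourier_coefs(deg2rad(tau_deg), alpha_rad)
  } else {
    gh <- gauss_hermite_rule(n_quad)
    tq <- deg2rad(tau_deg + sqrt(2) * sigma_tau_deg * gh$x)
    co <- p2_fourier_coefs(tq, alpha_rad)
    list(c0 = sum(gh$w * co$c0),
         c1 = sum(gh$w * co$c1),
         c2 = sum(gh$w * co$c2))
  }
}

## cached Gauss-Hermite nodes/weights, normalised to a probability rule
gauss_hermite_cache <- new.env(parent = emptyenv())
gauss_hermite_rule <- function(n) {
  if (n < 3) stop("quadrature rule too coarse (need >= 3 nodes)",
                  call. = FALSE)
  key <- as.character(n)
  if (is.null(gauss_hermite_cache[[key]])) {
    gh <- pracma::gaussHermite(n)
    gauss_hermite_cache[[key]] <- list(x = gh$x, w = gh$w / sqrt(pi))
  }
  gauss_hermite_cache[[key]]
}

#' Motionally averaged CF3 dipolar splitting
#'
#' Averages the static splitting over Gaussian whole-body fluctuations
#' of the helix orientation: tilt tau' ~ N(tau, sigma_tau) and
#' azimuthal rotation rho' ~ N(rho, sigma_rho), independent. The
#' azimuthal average is evaluated in closed form (the integrand is a
#' second-order Fourier series in rho', and the Gaussian average of
#' cos(k rho') is exp(-k^2 sigma^2/2) cos(k rho)); the tilt average
#' uses Gauss-Hermite quadrature with `n_quad` nodes. With
#' sigma_tau = sigma_rho = 0 this is exactly [static_splitting()] of
#' [angle_to_normal()].
#'
#' As sigma_rho grows beyond a few full turns the result converges to
#' the uniform-azimuth limit
#' `max_splitting * P2(cos tau) * P2(cos alpha)` (spherical-harmonic
#' addition theorem).
#'
#' @param site A [label_site()] or residue index.
#' @param orient An [orientation()].
#' @param dyn A [dynamics_params()].
#' @param geom A [helix_geometry()].
#' @param constants A [model_constants()].
#' @param n_quad Number of Gauss-Hermite nodes for the tilt average.
#' @return Signed splitting, kHz (0-degree sample tilt).
#' @export
averaged_splitting <- function(site, orient, dyn = dynamics_params(),
                               geom = helix_geometry(),
                               constants = model_constants(),
                               n_quad = 41) {
  i <- site_index(site)
  alpha <- deg2rad(geom$bond_polar_alpha)
  co <- averaged_fourier_coefs(orient$tau, dyn$sigma_tau, alpha, n_quad)
  sr <- deg2rad(dyn$sigma_rho)
  mu <- deg2rad(bond_azimuth(i, geom) - orient$rho)
  p2 <- co$c0 +
    exp(-sr^2 / 2) * co$c1 * cos(mu) +
    exp(-2 * sr^2) * co$c2 * cos(2 * mu)
  constants$max_splitting * p2
}

#' Predicted splittings for several labelled sites at once
#'
#' @param residue_index Integer vector of label positions.
#' @inheritParams averaged_splitting
#' @return Numeric vector of signed 0-degree splittings, kHz.
#' @export
predict_splittings <- function(residue_index, orient,
                               dyn = dynamics_params(),
                               geom = helix_geometry(),
                               constants = model_constants(),
                               n_quad = 41) {
  vapply(residue_index, averaged_splitting, numeric(1),
         orient = orient, dyn = dyn, geom = geom,
         constants = constants, n_quad = n_quad)
}

#' Effect of tilting the oriented sample from 0 to 90 degrees
#'
#' A peptide undergoing fast rotational diffusion about the membrane
#' normal (mobile) has all its dipolar splittings scaled by -1/2 when
#' the aligned sample is turned from 0 deg (normal parallel to the
#' field) to 90 deg. An immobilized peptide shows no such scaling: its
#' powder-type splitting is unchanged at 90 deg, which is flagged in
#' the `powder` attribute of the result.
#'
#' @param splitting Signed 0-degree splitting(s), kHz.
#' @param tilt `"deg0"` or `"deg90"`.
#' @param mobile Logical (recycled): fast rotational diffusion about
#'   the normal?
#' @return Splitting(s) at the requested sample tilt, kHz, with a
#'   logical attribute `powder` marking entries that are static powder
#'   contributions rather than oriented-model responses.
#' @export
#' @examples
#' sample_tilt_transform(7, "deg90", mobile = TRUE)    # -3.5
sample_tilt_transform <- function(splitting, tilt = c("deg0", "deg90"),
                                  mobile = TRUE) {
  tilt <- match.arg(tilt)
  mobile <- rep_len(mobile, length(splitting))
  if (tilt == "deg0") {
    out <- splitting
    powder <- rep(FALSE, length(splitting))
  } else {
    out <- ifelse(mobile, -splitting / 2, splitting)
    powder <- !mobile
  }
  attr(out, "powder") <- powder
  out
}

#' Dominant splitting of a static uniaxial powder pattern
#'
#' The 90-degree edge of the powder lineshape of immobilized,
#' orientationally disordered molecules: `-max_splitting / 2`
#' (P2(cos 90) = -1/2). With the default calibration this is the
#' -8 kHz signature of aggregated peptide.
#'
#' @param constants A [model_constants()].
#' @return Signed splitting, kHz.
#' @export
powder_splitting <- function(constants = model_constants()) {
  -constants$max_splitting / 2
}
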