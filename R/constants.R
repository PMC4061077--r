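#' Model constants for the CF3 dipolar coupling analysis
#'
#' `max_splitting` is the rigid-limit dipolar splitting of the rotating
#' CF3 group for a Calpha--Cbeta bond parallel to the magnetic field.
#' The default of 16 kHz is calibrated so that the dominant 90-degree
#' edge of a static uniaxial powder (`-max_splitting/2`) equals the
#' -8 kHz powder splitting observed for immobilized, aggregated
#' peptides. `unstructured_reference` (+7 kHz) is the empirical
#' signature splitting of a backbone that is intrinsically unstructured
#' and flexibly averaging within the membrane plane.
#'
#' @param max_splitting Rigid-limit CF3 splitting, kHz (> 0).
#' @param unstructured_reference Signature splitting of an in-plane
#'   unstructured backbone, kHz.
#' @param classification_tolerance Half-width, kHz, used when testing
#'   whether couplings cluster at `unstructured_reference` or at the
#'   powder edge.
#' @return An object of class `model_constants`. The magic angle
#'   (54.7356 deg, the root of P2) is carried along for reference.
#' @export
model_constants <- function(max_splitting = 16.0,
                            unstructured_reference = 7.0,
                            classification_tolerance = 1.5) {
  stopifnot(is.finite(max_splitting), max_splitting > 0,
            is.finite(unstructured_reference),
            is.finite(classification_tolerance),
            classification_tolerance > 0)
  structure(list(max_splitting = max_splitting,
                 magic_angle = 54.7356,
                 unstructured_reference = unstructured_reference,
                 classification_tolerance = classification_tolerance),
            class = "model_constants")
}

#' Gaussian whole-body dynamics of the membrane-bound helix
#'
#' Motional averaging of the peptide is modelled by independent
#' Gaussian distributions of the tilt (sd `sigma_tau`) and of the
#' azimuthal rotation (sd `sigma_rho`), both in degrees.
#'
#' @param sigma_tau,sigma_rho Standard deviations, degrees (>= 0).
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(sigma_tau = 0, sigma_rho = 0) {
  stopifnot(sigma_tau >= 0, sigma_rho >= 0,
            is.finite(sigma_tau), is.finite(sigma_rho))
  structure(list(sigma_tau = sigma_tau, sigma_rho = sigma_rho),
            class = "dynamics_params")
}

#' TP10 sequence and CF3-Bpg label positions
#'
#' The 21-residue cell-penetrating peptide TP10
#' (`AGYLLGKINLKALAALAKKIL`): an N-terminal galanin-derived segment
#' joined to a C-terminal mastoparan-derived segment. CF3-Bpg reporter
#' labels replace Gly2, Leu4, Leu5, Ile8, Leu10, Leu13, Leu16, Ile20
#' and Leu21.
#'
#' @name tp10
NULL

#' @rdname tp10
#' @export
tp10_sequence <- "AGYLLGKINLKALAALAKKIL"

#' @rdname tp10
#' @export
tp10_label_positions <- c(2L, 4L, 5L, 8L, 10L, 13L, 16L, 20L, 21L)

#' @rdname tp10
#' @format `tp10_segments` assigns each labelled position to the
#'   flexible N-terminal (galanin) or helical C-terminal (mastoparan)
#'   part of the monomeric structure; Leu10 belongs to the fitted
#'   C-terminal helix while Ile8 belongs to the flexible N-terminus.
#' @export
tp10_segments <- c(`2` = "N_terminal", `4` = "N_terminal",
                   `5` = "N_terminal", `8` = "N_terminal",
                   `10` = "C_terminal", `13` = "C_terminal",
                   `16` = "C_terminal", `20` = "C_terminal",
                   `21` = "C_terminal")

#' Published CD secondary-structure deconvolution of membrane-bound
#' TP10 (alpha-helix fractions from three algorithms)
#'
#' @export
tp10_cd_helix_fractions <- c(contin_ll = 0.58, cdsstr = 0.59,
                             selcon3 = 0.52)

#' Summarise CD helix fractions into a mean percentage and a
#' residue-count of the helical stretch
#'
#' @param fractions Named numeric vector of alpha-helix fractions in
#'   \[0, 1\] (default: the three deconvolution results for TP10).
#' @param n_residues Peptide length (default 21 for TP10).
#' @return List with `mean_fraction`, `percent` (rounded to the
#'   nearest percent), and `n_helical_residues` (the fraction applied
#'   to the sequence length, rounded to whole residues).
#' @export
#' @examples
#' helix_fraction_summary()
helix_fraction_summary <- function(fractions = tp10_cd_helix_fractions,
                                   n_residues = 21L) {
  stopifnot(length(fractions) >= 1, all(fractions >= 0 & fractions <= 1))
  m <- mean(fractions)
  list(mean_fraction = m,
       percent = round(100 * m),
       n_helical_residues = round(round(100 * m) / 100 * n_residues))
}
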