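#' Configuration for the synthetic coupling generator
#'
#' Describes the ground truth from which a coupling table is drawn:
#' the peptide sequence, the labelled positions, and the state of each
#' segment — helical (with an [orientation()] and [dynamics_params()]),
#' `"unstructured"` (in-plane flexible, +7 kHz reference) or
#' `"aggregated"` (immobilized, static powder edge). Gaussian noise of
#' sd `noise_sd` (default 0.5 kHz, the experimental coupling error) is
#' added to every mobile measurement after tilt scaling; powder rows
#' carry the powder-edge value without noise (the -8 kHz edge is a
#' lineshape feature, not a resolved splitting).
#'
#' @param sequence Peptide sequence, one-letter string.
#' @param label_positions Integer vector of labelled residues.
#' @param segment_of Named character vector mapping each labelled
#'   position to a segment name.
#' @param segment_states Named list, one entry per segment: either the
#'   string `"unstructured"` / `"aggregated"` or a list with elements
#'   `orientation` and `dynamics`.
#' @param noise_sd Measurement noise sd, kHz.
#' @param seed Integer RNG seed; a fixed seed makes the output
#'   byte-identical across runs.
#' @param epimer `"L"` or `"D"` label stereochemistry of the series.
#' @param pl_ratio Peptide-to-lipid ratio string, e.g. `"1:400"`.
#' @param include_90deg Generate the 90-degree-tilt rows as well?
#' @param geom,constants Model setup used by the forward model.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(sequence, label_positions, segment_of,
                             segment_states, noise_sd = 0.5, seed = NULL,
                             epimer = "L", pl_ratio = "1:400",
                             include_90deg = TRUE,
                             geom = helix_geometry(),
                             constants = model_constants()) {
  stopifnot(noise_sd >= 0)
  n <- nchar(sequence)
  if (any(label_positions < 1 | label_positions > n))
    stop("label site outside sequence (length ", n, ")", call. = FALSE)
  if (!all(as.character(label_positions) %in% names(segment_of)))
    stop("every label position needs a segment assignment", call. = FALSE)
  if (!all(unique(unname(segment_of)) %in% names(segment_states)))
    stop("every segment needs a state", call. = FALSE)
  structure(list(sequence = sequence,
                 label_positions = as.integer(label_positions),
                 segment_of = segment_of,
                 segment_states = segment_states,
                 noise_sd = noise_sd, seed = seed, epimer = epimer,
                 pl_ratio = pl_ratio, include_90deg = include_90deg,
                 geom = geom, constants = constants),
            class = "synthetic_config")
}

#' Draw a synthetic coupling table from a ground-truth configuration
#'
#' Helical segments get forward-model splittings (plus noise);
#' unstructured segments get the +7 kHz reference (plus noise);
#' aggregated segments get the static powder edge with the powder
#' flag set, identical at both sample tilts. Mobile 90-degree rows
#' are scaled by -1/2 before noise is added.
#'
#' @param config A [synthetic_config()].
#' @return A coupling data.frame in the canonical tidy dialect (see
#'   [read_couplings()]).
#' @export
generate_couplings <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- strsplit(config$sequence, "")[[1]]
  cst <- config$constants
  rows <- list()
  for (pos in config$label_positions) {
    seg <- unname(config$segment_of[as.character(pos)])
    state <- config$segment_states[[seg]]
    site_name <- paste0(res[pos], pos)
    if (identical(state, "aggregated")) {
      pw <- powder_splitting(cst)
      tilts <- if (config$include_90deg) c(0, 90) else 0
      for (td in tilts)
        rows[[length(rows) + 1]] <- data.frame(
          site = site_name, residue_index = pos, epimer = config$epimer,
          pl_ratio = config$pl_ratio, tilt_deg = td, splitting_khz = pw,
          powder_flag = TRUE, error_khz = 0.5, segment = seg)
    } else {
      base0 <- if (identical(state, "unstructured")) {
        cst$unstructured_reference
      } else {
        averaged_splitting(pos, state$orientation, state$dynamics,
                           config$geom, cst)
      }
      tilts <- if (config$include_90deg) c(0, 90) else 0
      for (td in tilts) {
        v <- if (td == 90) -base0 / 2 else base0
        v <- v + stats::rnorm(1, 0, config$noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          site = site_name, residue_index = pos, epimer = config$epimer,
          pl_ratio = config$pl_ratio, tilt_deg = td, splitting_khz = v,
          powder_flag = FALSE, error_khz = 0.5, segment = seg)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_couplings(out)
}

#' Synthetic TP10 coupling fixtures for the three study conditions
#'
#' Generates a coupling table with the structure of the experimental
#' TP10 datasets:
#' \describe{
#'   \item{`L_monomer_1to400`}{L-epimer labels at low peptide
#'     concentration (monomeric): the N-terminal galanin segment is
#'     in-plane unstructured, the C-terminal mastoparan helix
#'     (Leu10--Leu21) is oriented at tau = 55 deg, rho = 120 deg with
#'     a moderate rotational wobble about the long axis
#'     (sigma_rho = 16 deg) and no resolved tilt wobble.}
#'   \item{`D_lowconc_1to400`}{D-epimer labels at low concentration:
#'     the helix is unfolded, every site shows the +7 kHz in-plane
#'     unstructured signature.}
#'   \item{`D_highconc_1to50`}{D-epimer labels at high concentration:
#'     sites up to Leu10 remain mobile and unstructured, C-terminal
#'     sites Leu13, Leu16, Ile20, Leu21 are immobilized with a static
#'     powder edge (aggregation).}
#' }
#'
#' @param scenario One of the three scenario names.
#' @param noise_sd Measurement noise sd, kHz (default 0.5).
#' @param seed Integer RNG seed.
#' @param tau,rho,sigma_tau,sigma_rho Ground truth of the helical
#'   C-terminal segment in the monomer scenario, degrees.
#' @param geom,constants Model setup.
#' @return A coupling data.frame. The generating configuration is
#'   attached as attribute `"config"`.
#' @export
make_tp10_fixture <- function(scenario = c("L_monomer_1to400",
                                           "D_lowconc_1to400",
                                           "D_highconc_1to50"),
                              noise_sd = 0.5, seed = NULL,
                              tau = 55, rho = 120,
                              sigma_tau = 0, sigma_rho = 16,
                              geom = helix_geometry(),
                              constants = model_constants()) {
  scenario <- match.arg(scenario)
  helix <- list(orientation = orientation(tau, rho),
                dynamics = dynamics_params(sigma_tau, sigma_rho))
  cfg <- switch(scenario,
    L_monomer_1to400 = synthetic_config(
      tp10_sequence, tp10_label_positions, tp10_segments,
      segment_states = list(N_terminal = "unstructured",
                            C_terminal = helix),
      noise_sd = noise_sd, seed = seed, epimer = "L", pl_ratio = "1:400",
      geom = geom, constants = constants),
    D_lowconc_1to400 = synthetic_config(
      tp10_sequence, tp10_label_positions,
      stats::setNames(rep("all", length(tp10_label_positions)),
                      tp10_label_positions),
      segment_states = list(all = "unstructured"),
      noise_sd = noise_sd, seed = seed, epimer = "D", pl_ratio = "1:400",
      geom = geom, constants = constants),
    D_highconc_1to50 = synthetic_config(
      tp10_sequence, tp10_label_positions,
      ## at high concentration Leu10 still behaves like the flexible
      ## N-terminal part; Leu13..Leu21 aggregate
      c(`2` = "mobile", `4` = "mobile", `5` = "mobile", `8` = "mobile",
        `10` = "mobile", `13` = "aggregated", `16` = "aggregated",
        `20` = "aggregated", `21` = "aggregated"),
      segment_states = list(mobile = "unstructured",
                            aggregated = "aggregated"),
      noise_sd = noise_sd, seed = seed, epimer = "D", pl_ratio = "1:50",
      geom = geom, constants = constants))
  out <- generate_couplings(cfg)
  attr(out, "config") <- cfg
  out
}
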