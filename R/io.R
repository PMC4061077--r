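required_coupling_columns <- c("site", "residue_index", "epimer",
                               "pl_ratio", "tilt_deg", "splitting_khz",
                               "powder_flag")

## Internal: enforce the coupling-table contract on a data.frame.
validate_couplings <- function(x, source = "couplings") {
  if (!is.data.frame(x)) stop(source, ": expected a data.frame",
                              call. = FALSE)
  missing_cols <- setdiff(required_coupling_columns, names(x))
  if (length(missing_cols) > 0)
    stop(source, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(x$error_khz)) x$error_khz <- 0.5
  x$residue_index <- as.integer(x$residue_index)
  bad <- which(!is.finite(x$splitting_khz))
  if (length(bad) > 0)
    stop(source, ": non-numeric splitting_khz in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!x$tilt_deg %in% c(0, 90))
  if (length(bad) > 0)
    stop(source, ": tilt_deg must be 0 or 90; offending row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!all(x$epimer %in% c("L", "D")))
    stop(source, ": epimer must be 'L' or 'D'", call. = FALSE)
  x$powder_flag <- as.logical(x$powder_flag)
  if (anyNA(x$powder_flag))
    stop(source, ": powder_flag must be logical (TRUE/FALSE or 0/1)",
         call. = FALSE)
  if (any(x$error_khz <= 0))
    stop(source, ": error_khz must be > 0", call. = FALSE)
  x
}

#' Read a coupling table from TSV/CSV
#'
#' The canonical dialect is tab-separated with a header and `#`
#' comment lines; comma-separated files are accepted (`.csv`
#' extension or `sep=","`). Required columns: site, residue_index,
#' epimer, pl_ratio, tilt_deg, splitting_khz, powder_flag. An
#' error_khz column is optional (default 0.5 kHz). Unknown columns
#' are preserved.
#'
#' @param path Input file.
#' @param sep Field separator; guessed from the extension by default.
#' @return Validated coupling data.frame.
#' @export
read_couplings <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  validate_couplings(x, source = path)
}

#' Write a coupling table as TSV
#'
#' @param measurements Coupling data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_couplings <- function(measurements, path) {
  measurements <- validate_couplings(measurements)
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an RMSD landscape as a TSV matrix
#'
#' Rows are tau grid values, columns rho grid values, cells RMSD in
#' kHz.
#'
#' @param landscape An `rmsd_landscape` from [fit_orientation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  stopifnot(inherits(landscape, "rmsd_landscape"))
  m <- landscape$rmsd
  rownames(m) <- landscape$tau_grid
  colnames(m) <- landscape$rho_grid
  utils::write.table(cbind(tau = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a structured JSON fit report
#'
#' Parameters, RMSD, degenerate set and per-label residuals of an
#' orientation fit, for machine consumption.
#'
#' @param solution An `orientation_solution`.
#' @param measurements The fitted coupling data.frame (for residuals);
#'   optional.
#' @param path Output file.
#' @param geom,constants Model setup used for the residuals.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(solution, path, measurements = NULL,
                             geom = helix_geometry(),
                             constants = model_constants()) {
  stopifnot(inherits(solution, "orientation_solution"))
  rep <- list(tau = solution$tau, rho = solution$rho,
              sigma_tau = solution$sigma_tau,
              sigma_rho = solution$sigma_rho,
              rmsd_khz = solution$rmsd,
              n_labels = solution$n_labels,
              n_measurements = solution$n_measurements,
              degenerate_set = solution$degenerate_set)
  if (!is.null(measurements)) {
    measurements <- validate_couplings(measurements)
    measurements <- measurements[!measurements$powder_flag, , drop = FALSE]
    pred0 <- predict_splittings(
      measurements$residue_index,
      orientation(solution$tau, solution$rho),
      dynamics_params(solution$sigma_tau, solution$sigma_rho),
      geom, constants)
    pred <- ifelse(measurements$tilt_deg == 90, -pred0 / 2, pred0)
    rep$residuals <- data.frame(site = measurements$site,
                                residue_index = measurements$residue_index,
                                tilt_deg = measurements$tilt_deg,
                                observed_khz = measurements$splitting_khz,
                                predicted_khz = pred,
                                residual_khz = pred -
                                  measurements$splitting_khz)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a flat key-value run configuration (YAML)
#'
#' Recognised keys override the model setup: max_splitting,
#' unstructured_reference, classification_tolerance,
#' twist_per_residue, rise_per_residue, bond_polar_alpha,
#' bond_azimuth_beta, reference_residue, sigma_tau, sigma_rho.
#' All frequencies are kHz, all angles degrees.
#'
#' @param path YAML file of scalar keys.
#' @return List with `geom` ([helix_geometry()]), `constants`
#'   ([model_constants()]), `dynamics` ([dynamics_params()]) and
#'   `extra` (unrecognised keys).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a flat key-value mapping",
                          call. = FALSE)
  take <- function(fun, keys) {
    args <- cfg[intersect(keys, names(cfg))]
    do.call(fun, args)
  }
  geom_keys <- c("twist_per_residue", "rise_per_residue",
                 "bond_polar_alpha", "bond_azimuth_beta",
                 "reference_residue")
  const_keys <- c("max_splitting", "unstructured_reference",
                  "classification_tolerance")
  dyn_keys <- c("sigma_tau", "sigma_rho")
  list(geom = take(helix_geometry, geom_keys),
       constants = take(model_constants, const_keys),
       dynamics = take(dynamics_params, dyn_keys),
       extra = cfg[setdiff(names(cfg),
                           c(geom_keys, const_keys, dyn_keys))])
}

#' Plot an RMSD landscape (tau vs rho)
#'
#' A filled-contour style rendering of the (tau, rho) RMSD surface,
#' dark where the fit is good. Requires ggplot2.
#'
#' @param landscape An `rmsd_landscape`.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  stopifnot(inherits(landscape, "rmsd_landscape"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- expand.grid(tau = landscape$tau_grid, rho = landscape$rho_grid)
  df$rmsd <- as.vector(landscape$rmsd)
  ggplot2::ggplot(df, ggplot2::aes(x = rho, y = tau, fill = rmsd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "RMSD (kHz)") +
    ggplot2::labs(x = expression(rho ~ "(deg)"),
                  y = expression(tau ~ "(deg)")) +
    ggplot2::theme_minimal()
}
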