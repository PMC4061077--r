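#' Root-mean-square deviation between measured and predicted couplings
#'
#' Predictions come from the motionally averaged forward model at the
#' given orientation; measurements taken at 90-degree sample tilt are
#' compared against the -1/2-scaled prediction. Measurements flagged
#' as powder components cannot be described by an oriented model and
#' raise an error.
#'
#' @param measurements Coupling data.frame (see [read_couplings()] for
#'   the column contract).
#' @param orient An [orientation()].
#' @param dyn A [dynamics_params()].
#' @param geom A [helix_geometry()].
#' @param constants A [model_constants()].
#' @param n_quad Gauss-Hermite nodes for the tilt average.
#' @return RMSD in kHz.
#' @export
coupling_rmsd <- function(measurements, orient, dyn = dynamics_params(),
                          geom = helix_geometry(),
                          constants = model_constants(), n_quad = 41) {
  measurements <- validate_couplings(measurements)
  if (any(measurements$powder_flag))
    stop("cannot fit immobilized (powder) measurements to an oriented model",
         call. = FALSE)
  if (nrow(measurements) < 1) stop("no measurements", call. = FALSE)
  pred0 <- predict_splittings(measurements$residue_index, orient, dyn,
                              geom, constants, n_quad)
  pred <- ifelse(measurements$tilt_deg == 90, -pred0 / 2, pred0)
  sqrt(mean((pred - measurements$splitting_khz)^2))
}

## Fourier coefficient vectors c0, c1, c2 over a whole tau grid for
## one sigma_tau (degrees). Vectorised over the grid.
grid_fourier_coefs <- function(tau_grid, sigma_tau, alpha_rad, n_quad = 41) {
  if (sigma_tau == 0) {
    p2_fourier_coefs(deg2rad(tau_grid), alpha_rad)
  } else {
    gh <- gauss_hermite_rule(n_quad)
    tq <- deg2rad(outer(tau_grid, sqrt(2) * sigma_tau * gh$x, `+`))
    A <- cos(tq) * cos(alpha_rad)
    B <- sin(tq) * sin(alpha_rad)
    list(c0 = drop(((3 * A^2 - 1) / 2 + 0.75 * B^2) %*% gh$w),
         c1 = drop((3 * A * B) %*% gh$w),
         c2 = drop((0.75 * B^2) %*% gh$w))
  }
}

#' Exhaustive least-squares fit of helix orientation and dynamics
#'
#' Minimizes the sum of squared deviations between measured couplings
#' and the forward model over a full grid of tilt `tau`, azimuthal
#' rotation `rho` and Gaussian dynamics `sigma_tau`, `sigma_rho`.
#' 90-degree-tilt measurements enter through the -1/2 mobility
#' scaling. The returned landscape holds, at every (tau, rho) cell,
#' the RMSD minimized over both sigma grids — the machine-readable
#' form of the published RMSD contour plots.
#'
#' Degeneracy: grid cells whose RMSD lies within `tie_tol` of the
#' global minimum are reported in `degenerate_set` (the possible
#' range of tau and rho with the same RMSD). The canonical solution
#' is the exact grid argmin; exact ties are broken by smallest tau,
#' then smallest rho. Because P2 is even, the mirror orientation
#' (180 - tau, rho + 180) predicts identical couplings and is always
#' part of the degenerate set.
#'
#' @inheritParams coupling_rmsd
#' @param tau_grid,rho_grid,sigma_tau_grid,sigma_rho_grid Search grids
#'   in degrees. Defaults: tau 0..180 and rho 0..359 in 1-degree
#'   steps, both sigmas 0..30 in 2-degree steps.
#' @param tie_tol RMSD tolerance (kHz) for membership in the
#'   degenerate set.
#' @param refine If `TRUE`, polish the canonical grid solution with a
#'   bounded quasi-Newton search at sub-grid resolution.
#' @return List with components `solution` (class
#'   `orientation_solution`: tau, rho, sigma_tau, sigma_rho, rmsd,
#'   degenerate_set, n_labels, n_measurements) and `landscape` (class
#'   `rmsd_landscape`: tau_grid, rho_grid, rmsd matrix, best_cell).
#' @export
fit_orientation <- function(measurements,
                            geom = helix_geometry(),
                            constants = model_constants(),
                            tau_grid = seq(0, 180, by = 1),
                            rho_grid = seq(0, 359, by = 1),
                            sigma_tau_grid = seq(0, 30, by = 2),
                            sigma_rho_grid = seq(0, 30, by = 2),
                            n_quad = 41, tie_tol = 0.01, refine = FALSE) {
  measurements <- validate_couplings(measurements)
  if (all(measurements$powder_flag))
    stop("cannot fit immobilized (powder) measurements to an oriented model",
         call. = FALSE)
  if (any(measurements$powder_flag)) {
    warning("dropping ", sum(measurements$powder_flag),
            " powder-flagged measurement(s) from the oriented fit")
    measurements <- measurements[!measurements$powder_flag, , drop = FALSE]
  }
  n <- nrow(measurements)
  if (n < 2)
    warning("fewer than 2 measurements: the fit is degenerate; ",
            "inspect the full degenerate_set")

  alpha <- deg2rad(geom$bond_polar_alpha)
  dmax <- constants$max_splitting

  ## collapse measurements per labelled site:
  ##   SS(tau, rho) = sum_s [ a_s p_s^2 - 2 b_s p_s ] + sum y^2
  ## with p_s the 0-deg prediction of site s and per-row scale
  ## s_i = 1 (0 deg) or -1/2 (90 deg, mobile).
  scale_i <- ifelse(measurements$tilt_deg == 90, -0.5, 1)
  sites <- sort(unique(measurements$residue_index))
  a_s <- vapply(sites, function(s)
    sum(scale_i[measurements$residue_index == s]^2), numeric(1))
  b_s <- vapply(sites, function(s) {
    k <- measurements$residue_index == s
    sum(scale_i[k] * measurements$splitting_khz[k])
  }, numeric(1))
  yy <- sum(measurements$splitting_khz^2)

  mu <- deg2rad(outer(bond_azimuth(sites, geom), rho_grid, `-`))
  cos1 <- cos(mu)
  cos2 <- cos(2 * mu)

  nt <- length(tau_grid); nr <- length(rho_grid)
  best_rmsd <- matrix(Inf, nt, nr)
  best_st <- matrix(NA_real_, nt, nr)
  best_sr <- matrix(NA_real_, nt, nr)

  for (st in sigma_tau_grid) {
    co <- grid_fourier_coefs(tau_grid, st, alpha, n_quad)
    for (sr in sigma_rho_grid) {
      d1 <- exp(-deg2rad(sr)^2 / 2)
      d2 <- exp(-2 * deg2rad(sr)^2)
      SS <- matrix(yy, nt, nr)
      for (k in seq_along(sites)) {
        P <- dmax * (co$c0 +
                       d1 * outer(co$c1, cos1[k, ]) +
                       d2 * outer(co$c2, cos2[k, ]))
        SS <- SS + a_s[k] * P^2 - 2 * b_s[k] * P
      }
      RM <- sqrt(pmax(SS, 0) / n)
      upd <- RM < best_rmsd
      if (any(upd)) {
        best_rmsd[upd] <- RM[upd]
        best_st[upd] <- st
        best_sr[upd] <- sr
      }
    }
  }

  mn <- min(best_rmsd)
  deg_idx <- which(best_rmsd <= mn + tie_tol, arr.ind = TRUE)
  degenerate_set <- data.frame(tau = tau_grid[deg_idx[, 1]],
                               rho = rho_grid[deg_idx[, 2]],
                               rmsd = best_rmsd[deg_idx])
  ord <- order(degenerate_set$tau, degenerate_set$rho)
  degenerate_set <- degenerate_set[ord, , drop = FALSE]
  rownames(degenerate_set) <- NULL

  ## canonical cell: the argmin; ties at floating-point resolution
  ## (always including the mirror solution 180 - tau, rho + 180, since
  ## P2 is even) are broken by smallest tau, then smallest rho.
  ## 1e-6 kHz absorbs the floating-point floor of the expanded
  ## sum-of-squares while staying far below physical RMSD differences.
  ex_idx <- which(best_rmsd <= mn + 1e-6, arr.ind = TRUE)
  ex_ord <- order(tau_grid[ex_idx[, 1]], rho_grid[ex_idx[, 2]])
  ci <- unname(ex_idx[ex_ord[1], ])

  ## the landscape's best_cell is the exact matrix argmin
  mn_idx <- which(best_rmsd == mn, arr.ind = TRUE)
  mn_ord <- order(tau_grid[mn_idx[, 1]], rho_grid[mn_idx[, 2]])
  best_cell <- unname(mn_idx[mn_ord[1], ])

  solution <- structure(list(
    tau = tau_grid[ci[1]], rho = rho_grid[ci[2]],
    sigma_tau = best_st[ci[1], ci[2]], sigma_rho = best_sr[ci[1], ci[2]],
    rmsd = best_rmsd[ci[1], ci[2]],
    degenerate_set = degenerate_set,
    n_labels = length(sites), n_measurements = n),
    class = "orientation_solution")

  if (refine && n >= 2) {
    obj <- function(p) {
      coupling_rmsd(measurements, orientation(p[1], wrap360(p[2])),
                    dynamics_params(p[3], p[4]), geom, constants, n_quad)
    }
    opt <- stats::optim(c(solution$tau, solution$rho,
                          solution$sigma_tau, solution$sigma_rho),
                        obj, method = "L-BFGS-B",
                        lower = c(0, solution$rho - 10, 0, 0),
                        upper = c(180, solution$rho + 10,
                                  max(sigma_tau_grid), max(sigma_rho_grid)))
    if (opt$value <= solution$rmsd) {
      solution$tau <- opt$par[1]
      solution$rho <- wrap360(opt$par[2])
      solution$sigma_tau <- opt$par[3]
      solution$sigma_rho <- opt$par[4]
      solution$rmsd <- opt$value
    }
  }

  landscape <- structure(list(tau_grid = tau_grid, rho_grid = rho_grid,
                              rmsd = best_rmsd, best_cell = best_cell),
                         class = "rmsd_landscape")
  list(solution = solution, landscape = landscape)
}

#' @export
print.orientation_solution <- function(x, ...) {
  cat(sprintf(paste0("orientation solution (%d labels, %d couplings)\n",
                     "  tau = %.1f deg, rho = %.1f deg\n",
                     "  sigma_tau = %.1f deg, sigma_rho = %.1f deg\n",
                     "  RMSD = %.3f kHz; %d grid cell(s) in degenerate set\n"),
              x$n_labels, x$n_measurements, x$tau, x$rho,
              x$sigma_tau, x$sigma_rho, x$rmsd, nrow(x$degenerate_set)))
  invisible(x)
}

#' @export
print.rmsd_landscape <- function(x, ...) {
  cat(sprintf(paste0("RMSD landscape: %d x %d (tau x rho) grid, ",
                     "min %.3f kHz at tau = %g, rho = %g\n"),
              length(x$tau_grid), length(x$rho_grid),
              min(x$rmsd), x$tau_grid[x$best_cell[1]],
              x$rho_grid[x$best_cell[2]]))
  invisible(x)
}

#' Segmental orientation analysis
#'
#' Fits each peptide segment independently and classifies segments
#' that cannot be described by a straight helix. A segment fails the
#' helix fit when its best RMSD exceeds `helix_rejection` (default
#' 1 kHz, twice the experimental coupling error); if in addition all
#' of its couplings (90-degree rows unscaled back to their 0-degree
#' equivalents) cluster within `classification_tolerance` of the
#' +7 kHz in-plane-unstructured reference, the segment is reported as
#' `"unstructured"` rather than oriented.
#'
#' @inheritParams fit_orientation
#' @param segment_map Optional named character vector mapping residue
#'   indices (names) to segment labels; if `NULL`, the `segment`
#'   column of `measurements` is used.
#' @param helix_rejection RMSD threshold (kHz) above which a straight
#'   helix is rejected for a segment.
#' @param ... Passed on to [fit_orientation()] (grids, `n_quad`, ...).
#' @return Named list, one entry per segment: `solution`, `landscape`,
#'   `verdict` (`"helical_fit"`, `"unstructured"` or `"poor_fit"`),
#'   `n_measurements`.
#' @export
segmental_fit <- function(measurements, segment_map = NULL,
                          geom = helix_geometry(),
                          constants = model_constants(),
                          helix_rejection = 1.0, ...) {
  measurements <- validate_couplings(measurements)
  if (!is.null(segment_map)) {
    measurements$segment <-
      unname(segment_map[as.character(measurements$residue_index)])
  }
  if (is.null(measurements$segment) || anyNA(measurements$segment))
    stop("every measurement needs a segment assignment", call. = FALSE)
  segs <- unique(measurements$segment)
  out <- list()
  for (sg in segs) {
    sub <- measurements[measurements$segment == sg & !measurements$powder_flag,
                        , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("segment '", sg, "' has no mobile measurements; skipped")
      next
    }
    ft <- fit_orientation(sub, geom = geom, constants = constants, ...)
    verdict <- "helical_fit"
    if (ft$solution$rmsd > helix_rejection) {
      ## per-site 0-degree-equivalent couplings (90-deg rows unscaled);
      ## averaging the tilt pair halves the leverage of the doubled
      ## noise on unscaled 90-degree values
      eq0 <- ifelse(sub$tilt_deg == 90, -2 * sub$splitting_khz,
                    sub$splitting_khz)
      site_mean <- tapply(eq0, sub$residue_index, mean)
      near_ref <- abs(site_mean - constants$unstructured_reference) <=
        constants$classification_tolerance
      verdict <- if (all(near_ref)) "unstructured" else "poor_fit"
    }
    out[[sg]] <- list(solution = ft$solution, landscape = ft$landscape,
                      verdict = verdict, n_measurements = nrow(sub))
  }
  out
}

#' Predicted dipolar-wave curve along the sequence
#'
#' Samples the forward model at every residue of a range, holding the
#' orientation and dynamics fixed: the sinusoid-like "dipolar wave"
#' expected as labels march around the helix (period 3.6 residues for
#' 100 deg/residue twist).
#'
#' @inheritParams coupling_rmsd
#' @param residue_range Integer vector of residue indices.
#' @return data.frame: residue_index, predicted_khz.
#' @export
dipolar_wave <- function(orient, dyn = dynamics_params(),
                         geom = helix_geometry(),
                         constants = model_constants(),
                         residue_range = 1:21, n_quad = 41) {
  if (length(residue_range) == 0) stop("empty residue range", call. = FALSE)
  data.frame(residue_index = residue_range,
             predicted_khz = predict_splittings(residue_range, orient, dyn,
                                                geom, constants, n_quad))
}
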