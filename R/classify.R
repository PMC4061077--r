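#' Mobility call from the 0/90-degree sample-tilt pair
#'
#' A peptide in fast rotational diffusion about the membrane normal
#' scales its dipolar splittings by -1/2 when the sample is tilted
#' from 0 to 90 degrees; an immobilized peptide shows the same
#' splitting at both tilts. Sites where both or neither rule holds
#' within `tolerance` are indeterminate.
#'
#' @param split_0deg,split_90deg Signed splittings at 0 and 90 degree
#'   sample tilt, kHz. A missing 90-degree value yields
#'   `"indeterminate"` with a warning.
#' @param tolerance Agreement tolerance, kHz (default 1.0, twice the
#'   experimental coupling error).
#' @return `"mobile"`, `"immobile"` or `"indeterminate"`.
#' @export
#' @examples
#' mobility_call(7, -3.5)    # mobile
#' mobility_call(-8, -8)     # immobile
mobility_call <- function(split_0deg, split_90deg, tolerance = 1.0) {
  if (is.na(split_90deg) || is.na(split_0deg)) {
    warning("missing 0/90-degree measurement; mobility indeterminate")
    return("indeterminate")
  }
  mobile_ok <- abs(split_90deg - (-0.5 * split_0deg)) <= tolerance
  immobile_ok <- abs(split_90deg - split_0deg) <= tolerance
  if (mobile_ok && !immobile_ok) "mobile"
  else if (immobile_ok && !mobile_ok) "immobile"
  else "indeterminate"
}

#' Is a set of splittings the signature of an in-plane unstructured
#' backbone?
#'
#' `TRUE` iff every splitting lies within `classification_tolerance`
#' of the +7 kHz unstructured reference. Fewer than 2 sites cannot
#' support the call and return `NA` with a warning.
#'
#' @param splittings Signed 0-degree splittings from mobile sites, kHz.
#' @param constants A [model_constants()].
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
unstructured_call <- function(splittings, constants = model_constants()) {
  if (length(splittings) < 2) {
    warning("fewer than 2 sites; unstructured call unknown")
    return(NA)
  }
  all(abs(splittings - constants$unstructured_reference) <=
        constants$classification_tolerance)
}

#' Per-site conformational-state scan of a coupling dataset
#'
#' The machine form of a positional scan for aggregation-prone
#' regions: for every labelled site (within one peptide-to-lipid
#' ratio and epimer series) the 0/90-degree pair gives a mobility
#' call; mobile sites with couplings at the +7 kHz reference are
#' called intrinsically unstructured; the remaining mobile sites are
#' fitted jointly to a helix and called `helical_fit` when the fit
#' succeeds; immobile sites whose splitting sits at the powder edge
#' (-max_splitting/2) become `aggregated_beta_candidate` ("candidate"
#' because the NMR powder pattern alone proves immobilization, not
#' beta-sheet conformation). Sites showing both a mobile sharp
#' component and a powder component are reported as partly aggregated
#' via two evidence entries on the same site.
#'
#' @param measurements Coupling data.frame; may mix peptide-to-lipid
#'   ratios and epimers, which are scanned separately.
#' @param geom,constants Model setup.
#' @param mobility_tolerance kHz tolerance of [mobility_call()].
#' @param helix_rejection RMSD threshold (kHz) for the joint helix fit
#'   of mobile non-unstructured sites.
#' @param fit_grids Optional list of grid arguments forwarded to
#'   [fit_orientation()].
#' @return List with `calls` (data.frame: site, residue_index, epimer,
#'   pl_ratio, mobility, conformation, evidence) and `summary`
#'   (data.frame per epimer/pl_ratio: aggregated positions, counts).
#' @export
scan_states <- function(measurements, geom = helix_geometry(),
                        constants = model_constants(),
                        mobility_tolerance = 1.0,
                        helix_rejection = 1.0,
                        fit_grids = list()) {
  measurements <- validate_couplings(measurements)
  check_duplicate_conflicts(measurements)

  groups <- unique(measurements[, c("epimer", "pl_ratio")])
  calls <- list()
  for (g in seq_len(nrow(groups))) {
    gm <- measurements[measurements$epimer == groups$epimer[g] &
                         measurements$pl_ratio == groups$pl_ratio[g],
                       , drop = FALSE]
    calls[[g]] <- scan_states_one(gm, geom, constants,
                                  mobility_tolerance, helix_rejection,
                                  fit_grids)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  agg <- calls[calls$conformation == "aggregated_beta_candidate", ,
               drop = FALSE]
  summary <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    k <- agg$epimer == groups$epimer[g] & agg$pl_ratio == groups$pl_ratio[g]
    data.frame(epimer = groups$epimer[g], pl_ratio = groups$pl_ratio[g],
               n_aggregated = sum(k),
               aggregated_positions = paste(sort(agg$residue_index[k]),
                                            collapse = ","))
  }))
  list(calls = calls, summary = summary)
}

scan_states_one <- function(gm, geom, constants, mobility_tolerance,
                            helix_rejection, fit_grids) {
  sites <- sort(unique(gm$residue_index))
  pw <- powder_splitting(constants)
  tol <- constants$classification_tolerance

  row_for <- function(s) {
    sm <- gm[gm$residue_index == s, , drop = FALSE]
    mob <- sm[!sm$powder_flag, , drop = FALSE]
    pwd <- sm[sm$powder_flag, , drop = FALSE]
    evid <- character(0)

    s0 <- mob$splitting_khz[mob$tilt_deg == 0][1]
    s90 <- mob$splitting_khz[mob$tilt_deg == 90][1]
    mobility <- NA_character_
    if (nrow(mob) > 0) {
      mobility <- if (is.na(s90) || is.na(s0)) "indeterminate"
      else mobility_call(s0, s90, mobility_tolerance)
      if (identical(mobility, "mobile"))
        evid <- c(evid, sprintf(
          "sharp component scales by -1/2 at 90 deg (%+0.1f -> %+0.1f kHz)",
          s0, s90))
    }
    if (nrow(pwd) > 0) {
      near_edge <- abs(pwd$splitting_khz - pw) <= tol
      evid <- c(evid, sprintf(
        "powder component at %+0.1f kHz unchanged by sample tilt%s",
        pwd$splitting_khz[1],
        if (nrow(mob) > 0) " (partly aggregated: mobile component coexists)"
        else ""))
      if (any(near_edge)) {
        return(data.frame(site = sm$site[1], residue_index = s,
                          epimer = sm$epimer[1], pl_ratio = sm$pl_ratio[1],
                          mobility = "immobile",
                          conformation = "aggregated_beta_candidate",
                          evidence = paste(evid, collapse = "; ")))
      }
    }
    data.frame(site = sm$site[1], residue_index = s,
               epimer = sm$epimer[1], pl_ratio = sm$pl_ratio[1],
               mobility = if (is.na(mobility)) "indeterminate" else mobility,
               conformation = "unknown",
               evidence = paste(evid, collapse = "; "))
  }
  calls <- do.call(rbind, lapply(sites, row_for))

  ## conformation of the mobile sites: unstructured reference first,
  ## then joint helix membership of whatever remains
  mobile_idx <- which(calls$mobility == "mobile" &
                        calls$conformation == "unknown")
  if (length(mobile_idx) > 0) {
    eq0 <- vapply(calls$residue_index[mobile_idx], function(s) {
      sm <- gm[gm$residue_index == s & !gm$powder_flag, , drop = FALSE]
      v <- sm$splitting_khz[sm$tilt_deg == 0]
      if (length(v) == 0) -2 * sm$splitting_khz[sm$tilt_deg == 90][1]
      else v[1]
    }, numeric(1))
    near_ref <- abs(eq0 - constants$unstructured_reference) <= tol
    calls$conformation[mobile_idx[near_ref]] <- "unstructured"
    calls$evidence[mobile_idx[near_ref]] <- paste0(
      calls$evidence[mobile_idx[near_ref]],
      sprintf("; 0-deg coupling %+0.1f kHz at the +%g kHz unstructured reference",
              eq0[near_ref], constants$unstructured_reference))

    rest <- mobile_idx[!near_ref]
    if (length(rest) >= 2) {
      sub <- gm[gm$residue_index %in% calls$residue_index[rest] &
                  !gm$powder_flag, , drop = FALSE]
      ft <- do.call(fit_orientation,
                    c(list(sub, geom = geom, constants = constants),
                      fit_grids))
      if (ft$solution$rmsd <= helix_rejection) {
        calls$conformation[rest] <- "helical_fit"
        calls$evidence[rest] <- paste0(
          calls$evidence[rest],
          sprintf("; joint helix fit tau = %g, rho = %g, RMSD %.2f kHz",
                  ft$solution$tau, ft$solution$rho, ft$solution$rmsd))
      }
    }
  }
  calls
}

check_duplicate_conflicts <- function(measurements) {
  key <- paste(measurements$residue_index, measurements$epimer,
               measurements$pl_ratio, measurements$tilt_deg,
               measurements$powder_flag, sep = "|")
  bad <- character(0)
  for (k in unique(key[duplicated(key)])) {
    v <- measurements$splitting_khz[key == k]
    if (length(unique(v)) > 1)
      bad <- c(bad, sprintf("%s -> {%s} kHz", k,
                            paste(unique(v), collapse = ", ")))
  }
  if (length(bad) > 0)
    stop("inconsistent duplicate measurements:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}
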