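deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap an angle in degrees into [0, 360)
wrap360 <- function(x) ((x %% 360) + 360) %% 360

## wrap a signed angular difference into (-180, 180]
wrap180 <- function(x) {
  y <- wrap360(x)
  ifelse(y > 180, y - 360, y)
}

#' Ideal alpha-helix geometry and the CF3 side-chain bond convention
#'
#' Bundles the parameters of an ideal alpha-helix together with the
#' two-angle description of the Calpha--Cbeta bond of the CF3-labelled
#' side chain: `bond_polar_alpha` is the polar angle of the bond away
#' from the helix long axis, and `bond_azimuth_beta` is the azimuthal
#' offset of the bond from the residue's radial direction on the
#' helical wheel. The defaults (alpha = 121.1 deg, beta = 53.2 deg) are
#' the established values for the CF3-Bpg reporter side chain.
#'
#' Sign convention: for a right-handed alpha-helix viewed from the
#' N-terminus, the wheel azimuth decreases by `twist_per_residue`
#' (default 100 deg) per residue going N to C; the azimuthal rotation
#' `rho` of an [orientation()] rotates the wheel counterclockwise in
#' that view.
#'
#' @param twist_per_residue Helical twist, degrees per residue (0, 360).
#' @param rise_per_residue Rise along the helix axis, Angstrom.
#' @param bond_polar_alpha Polar angle of the Calpha--Cbeta bond from
#'   the helix axis, degrees in \[0, 180\].
#' @param bond_azimuth_beta Azimuthal offset of the bond from the
#'   residue's radial wheel direction, degrees in \[0, 360).
#' @param reference_residue 1-based residue index whose wheel azimuth is
#'   0 deg before `rho` is applied.
#' @return An object of class `helix_geometry`.
#' @export
#' @examples
#' geom <- helix_geometry()
#' bond_vector(1, geom)
helix_geometry <- function(twist_per_residue = 100.0,
                           rise_per_residue = 1.5,
                           bond_polar_alpha = 121.1,
                           bond_azimuth_beta = 53.2,
                           reference_residue = 1L) {
  stopifnot(is.numeric(twist_per_residue), length(twist_per_residue) == 1,
            twist_per_residue > 0, twist_per_residue < 360)
  stopifnot(rise_per_residue > 0)
  stopifnot(bond_polar_alpha >= 0, bond_polar_alpha <= 180)
  stopifnot(bond_azimuth_beta >= 0, bond_azimuth_beta < 360)
  stopifnot(reference_residue >= 1)
  structure(list(twist_per_residue = twist_per_residue,
                 rise_per_residue = rise_per_residue,
                 bond_polar_alpha = bond_polar_alpha,
                 bond_azimuth_beta = bond_azimuth_beta,
                 reference_residue = as.integer(reference_residue)),
            class = "helix_geometry")
}

#' Helix orientation in the membrane frame
#'
#' @param tau Tilt of the helix long axis away from the membrane
#'   normal, degrees in \[0, 180\].
#' @param rho Azimuthal rotation of the helix about its own axis,
#'   degrees; stored modulo 360.
#' @return An object of class `orientation`.
#' @export
orientation <- function(tau, rho) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau >= 0, tau <= 180)
  stopifnot(is.numeric(rho), length(rho) == 1, is.finite(rho))
  structure(list(tau = tau, rho = wrap360(rho)), class = "orientation")
}

#' @export
print.orientation <- function(x, ...) {
  cat(sprintf("helix orientation: tau = %.1f deg, rho = %.1f deg\n",
              x$tau, x$rho))
  invisible(x)
}

#' One CF3-labelled site in the peptide sequence
#'
#' @param residue_index 1-based position of the label in the sequence.
#' @param residue_name One-letter code of the substituted residue.
#' @param epimer `"L"` or `"D"` backbone stereochemistry of the label.
#' @param segment Segment assignment used by the segmental analysis:
#'   `"N_terminal"`, `"C_terminal"` or `"unassigned"`.
#' @return An object of class `label_site`.
#' @export
label_site <- function(residue_index, residue_name = NA_character_,
                       epimer = c("L", "D"),
                       segment = c("unassigned", "N_terminal", "C_terminal")) {
  epimer <- match.arg(epimer)
  segment <- match.arg(segment)
  stopifnot(is.numeric(residue_index), length(residue_index) == 1,
            residue_index >= 1, residue_index == round(residue_index))
  structure(list(residue_index = as.integer(residue_index),
                 residue_name = residue_name,
                 epimer = epimer, segment = segment),
            class = "label_site")
}

site_index <- function(site) {
  if (inherits(site, "label_site")) site$residue_index
  else as.integer(site)
}

#' Wheel azimuth of the Calpha--Cbeta bond of a residue (helix frame)
#'
#' phi_i = -twist * (i - reference_residue) + beta, degrees (signed;
#' not wrapped). The minus sign encodes the right-handed helix viewed
#' from the N-terminus.
#'
#' @param residue_index 1-based residue index (vectorised).
#' @param geom A [helix_geometry()].
#' @return Azimuth(s) in degrees.
#' @export
bond_azimuth <- function(residue_index, geom = helix_geometry()) {
  -geom$twist_per_residue * (residue_index - geom$reference_residue) +
    geom$bond_azimuth_beta
}

#' Unit Calpha--Cbeta bond vector in the helix frame
#'
#' The helix long axis is +z; the returned vector has polar angle
#' `bond_polar_alpha` from +z and azimuth [bond_azimuth()].
#'
#' @param site A [label_site()] or a plain residue index.
#' @param geom A [helix_geometry()].
#' @param sequence_length Optional; if given, the residue index is
#'   checked against it.
#' @return A numeric unit 3-vector.
#' @export
bond_vector <- function(site, geom = helix_geometry(), sequence_length = NULL) {
  i <- site_index(site)
  if (i < 1 || (!is.null(sequence_length) && i > sequence_length))
    stop("residue index ", i, " out of range", call. = FALSE)
  a <- deg2rad(geom$bond_polar_alpha)
  phi <- deg2rad(bond_azimuth(i, geom))
  c(sin(a) * cos(phi), sin(a) * sin(phi), cos(a))
}

#' Angle between a labelled bond and the membrane normal
#'
#' For a helix tilted by `tau` and rotated by `rho`, the angle theta
#' between the Calpha--Cbeta bond of residue i and the membrane normal
#' satisfies
#' \deqn{\cos\theta = \cos\tau\cos\alpha +
#'   \sin\tau\sin\alpha\cos(\phi_i - \rho)}
#' with phi_i the wheel azimuth of the bond ([bond_azimuth()]).
#'
#' @inheritParams bond_vector
#' @param orient An [orientation()].
#' @return theta in degrees, in \[0, 180\].
#' @export
angle_to_normal <- function(site, orient, geom = helix_geometry()) {
  i <- site_index(site)
  tau <- deg2rad(orient$tau)
  a <- deg2rad(geom$bond_polar_alpha)
  phi <- deg2rad(bond_azimuth(i, geom) - orient$rho)
  ct <- cos(tau) * cos(a) + sin(tau) * sin(a) * cos(phi)
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}

#' Build ideal-helix Calpha (and Cbeta stub) coordinates in the
#' membrane frame
#'
#' Constructs an ideal alpha-helix for `sequence`, rotates it so the
#' helix axis makes angle `tau` with the membrane normal (+z) and the
#' wheel face is set by `rho`. Cbeta stubs are placed along the
#' side-chain bond direction of [bond_vector()] for every residue.
#'
#' @param sequence Peptide sequence (one-letter string).
#' @param orient An [orientation()].
#' @param geom A [helix_geometry()].
#' @param ca_radius Radius of the Calpha helix, Angstrom.
#' @param cb_length Calpha--Cbeta bond length, Angstrom.
#' @return A data.frame with one row per residue: residue_index,
#'   residue_name, ca_x/y/z, cb_x/y/z (Angstrom, membrane frame).
#' @export
build_helix_coordinates <- function(sequence, orient = orientation(0, 0),
                                    geom = helix_geometry(),
                                    ca_radius = 2.3, cb_length = 1.53) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n == 0) stop("empty sequence", call. = FALSE)
  i <- seq_len(n)
  ## Calpha radial azimuth excludes the side-chain offset beta
  psi <- deg2rad(bond_azimuth(i, geom) - geom$bond_azimuth_beta - orient$rho)
  z0 <- geom$rise_per_residue * (i - 1)
  ca <- cbind(ca_radius * cos(psi), ca_radius * sin(psi), z0)
  u <- t(vapply(i, function(k) {
    a <- deg2rad(geom$bond_polar_alpha)
    phi <- deg2rad(bond_azimuth(k, geom) - orient$rho)
    c(sin(a) * cos(phi), sin(a) * sin(phi), cos(a))
  }, numeric(3)))
  cb <- ca + cb_length * u
  ## tilt: rotate about y so that the helix axis (+z) acquires tilt tau
  tau <- deg2rad(orient$tau)
  R <- rbind(c(cos(tau), 0, -sin(tau)),
             c(0, 1, 0),
             c(sin(tau), 0, cos(tau)))
  ca <- ca %*% t(R)
  cb <- cb %*% t(R)
  data.frame(residue_index = i, residue_name = res,
             ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
             cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3])
}

#' Helical wheel projection with polar/membrane face labels
#'
#' Projects a residue range onto the helical wheel and labels each
#' residue's side-chain azimuth as facing the aqueous phase
#' (`polar-facing`) or the bilayer interior (`membrane-facing`),
#' given the azimuthal rotation `rho`. A residue is membrane-facing
#' when its bond azimuth lies within 90 deg of the membrane-interior
#' direction implied by `rho`.
#'
#' @inheritParams build_helix_coordinates
#' @param residue_range Integer vector of residue indices to project.
#' @return data.frame: residue_index, residue_name, azimuth (deg, in
#'   \[0,360)), face (`"polar-facing"` / `"membrane-facing"`).
#' @export
helical_wheel <- function(sequence, orient, residue_range = NULL,
                          geom = helix_geometry()) {
  res <- strsplit(sequence, "")[[1]]
  if (is.null(residue_range)) residue_range <- seq_along(res)
  if (length(residue_range) == 0) stop("empty residue range", call. = FALSE)
  if (any(residue_range < 1 | residue_range > length(res)))
    stop("residue range outside sequence", call. = FALSE)
  phi <- bond_azimuth(residue_range, geom)
  rel <- wrap180(phi - orient$rho)
  face <- ifelse(abs(rel) <= 90, "polar-facing", "membrane-facing")
  data.frame(residue_index = residue_range,
             residue_name = res[residue_range],
             azimuth = wrap360(phi),
             face = face)
}

#' Export helix coordinates as a PDB file
#'
#' Writes the Calpha trace and pseudo-Cbeta stubs of
#' [build_helix_coordinates()] as standard ATOM records (chain A,
#' occupancy 1.00), membrane normal along +z.
#'
#' @param coords Output of [build_helix_coordinates()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_helix_pdb <- function(coords, path) {
  n <- nrow(coords)
  xyz <- as.numeric(t(rbind(
    as.matrix(coords[, c("ca_x", "ca_y", "ca_z")]),
    as.matrix(coords[, c("cb_x", "cb_y", "cb_z")]))))
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  resid <- aa3[coords$residue_name]
  resid[is.na(resid)] <- "UNK"
  bio3d::write.pdb(file = path,
                   xyz = xyz,
                   resno = c(coords$residue_index, coords$residue_index),
                   resid = c(resid, resid),
                   eleno = seq_len(2 * n),
                   elety = c(rep("CA", n), rep("CB", n)),
                   chain = rep("A", 2 * n),
                   o = rep(1, 2 * n), b = rep(0, 2 * n),
                   elesy = rep("C", 2 * n))
  invisible(path)
}
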