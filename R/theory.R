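# Closed-form hydrodynamic limits for 1D diffusion on DNA: how fast can a
# particle of given size slide (tracking the helical groove, paying
# rotational friction) or hop (pure translation) along the double helix.

#' Hydrodynamic model constants
#'
#' Container for the physical constants used by the sliding/hopping
#' diffusion-limit calculations. Defaults reproduce aqueous buffer at
#' room temperature.
#'
#' @param eta dynamic viscosity, pN s/nm^2 (water at room temperature,
#'   9e-10).
#' @param kT thermal energy, pN nm (4.1143 corresponds to 298 K).
#' @param helical_pitch_nm rise of one helical turn of B-DNA, nm
#'   (10 bp = 3.4 nm).
#' @param partial_specific_volume protein partial specific volume,
#'   cm^3/g (0.73, the canonical globular-protein value).
#' @return An object of class `hydrodynamic_model`.
#' @export
hydrodynamic_model <- function(eta = 9e-10, kT = 4.1143,
                               helical_pitch_nm = 3.4,
                               partial_specific_volume = 0.73) {
  stop_if_not_scalar(eta, "eta", positive = TRUE)
  stop_if_not_scalar(kT, "kT", positive = TRUE)
  stop_if_not_scalar(helical_pitch_nm, "helical_pitch_nm", positive = TRUE)
  stop_if_not_scalar(partial_specific_volume, "partial_specific_volume",
                     positive = TRUE)
  structure(list(eta = eta, kT = kT,
                 helical_pitch_nm = helical_pitch_nm,
                 partial_specific_volume = partial_specific_volume),
            class = "hydrodynamic_model")
}

#' Minimal radius of gyration from molecular mass
#'
#' Estimates the radius of a compact sphere of protein of mass `mass_da`
#' using the partial specific volume: the particle volume in nm^3 is
#' \eqn{V = v_bar \cdot 10^{21} M / N_A} and the radius
#' \eqn{R = (3V/4\pi)^{1/3}}.
#'
#' @param mass_da molecular mass in Daltons.
#' @param model a [hydrodynamic_model()].
#' @return radius in nm.
#' @examples
#' radius_of_gyration(1e6)    # ~6.62 nm, a ~1 MDa remodeler complex
#' radius_of_gyration(25.4e3) # ~1.94 nm, a small DNA-binding subunit
#' @export
radius_of_gyration <- function(mass_da, model = hydrodynamic_model()) {
  stop_if_not_scalar(mass_da, "mass_da", positive = TRUE)
  avogadro <- 6.023e23  # value used in the volume relation
  v_nm3 <- model$partial_specific_volume * 1e21 / avogadro * mass_da
  (3 * v_nm3 / (4 * pi))^(1 / 3)
}

#' Translational (no-rotation) diffusion limit
#'
#' Upper bound on 1D diffusion for a sphere that translates without
#' tracking the DNA helix: \eqn{D = k_B T / (6 \pi \eta R)}. This is the
#' relevant limit for hopping-dominated motion.
#'
#' @param R_nm particle radius, nm.
#' @param model a [hydrodynamic_model()].
#' @return diffusion coefficient in um^2/s.
#' @export
d_limit_no_rotation <- function(R_nm, model = hydrodynamic_model()) {
  stop_if_not_scalar(R_nm, "R_nm", positive = TRUE)
  f <- 6 * pi * model$eta * R_nm           # pN s/nm
  (model$kT / f) * 1e-6                    # nm^2/s -> um^2/s
}

#' Rotation-coupled (sliding) diffusion limit
#'
#' Upper bound on 1D diffusion for a sphere that follows the helical
#' groove, turning once per helical pitch while translating. The
#' friction is
#' \deqn{f = 6\pi\eta R + (2\pi/p)^2 [\, 8\pi\eta R^3
#'       + 6\pi\eta R R_{oc}^2 \,]}
#' with pitch p = 3.4 nm; the second bracket is rotational drag about the
#' helical axis when the particle's centre of mass sits a distance
#' `Roc_nm` off that axis. `Roc = R` gives the slowest (minimal) limit,
#' `Roc = 0` the fastest.
#'
#' @param R_nm particle radius, nm.
#' @param Roc_nm distance between the DNA helical axis and the particle
#'   centre of mass, nm.
#' @param model a [hydrodynamic_model()].
#' @return diffusion coefficient in um^2/s.
#' @export
d_limit_with_rotation <- function(R_nm, Roc_nm = R_nm,
                                  model = hydrodynamic_model()) {
  stop_if_not_scalar(R_nm, "R_nm", positive = TRUE)
  stop_if_not_scalar(Roc_nm, "Roc_nm", nonnegative = TRUE)
  (model$kT / sliding_friction(R_nm, Roc_nm, model)) * 1e-6
}

# Friction coefficient (pN s/nm) of rotation-coupled sliding.
sliding_friction <- function(R_nm, Roc_nm, model = hydrodynamic_model()) {
  eta <- model$eta
  6 * pi * eta * R_nm +
    (2 * pi / model$helical_pitch_nm)^2 *
      (8 * pi * eta * R_nm^3 + 6 * pi * eta * R_nm * Roc_nm^2)
}

#' Time to scan a stretch of DNA by 1D diffusion
#'
#' Converts a basepair length to physical length at the stretched
#' inter-bead tension and applies the 1D first-passage scaling
#' \eqn{l = \sqrt{2 D t}}, i.e. \eqn{t = l^2 / (2D)}. The alternative
#' convention \eqn{t = l^2/D} (as if l = 2Dt were read literally) is
#' returned alongside for transparency; `t_s` is the formula-consistent
#' value.
#'
#' @param length_bp number of basepairs scanned.
#' @param D diffusion coefficient, um^2/s.
#' @param nm_per_bp physical length per basepair at the working tension
#'   (0.31 nm at 5 pN, ~92% of contour length).
#' @return list with `l_um` (scan length), `t_s` (= l^2/2D) and
#'   `t_alt_s` (= l^2/D).
#' @examples
#' scan_time(150, D = 0.024) # ~46 ms to traverse a 150 bp NDR
#' @export
scan_time <- function(length_bp, D, nm_per_bp = 0.31) {
  stop_if_not_scalar(length_bp, "length_bp", positive = TRUE)
  stop_if_not_scalar(D, "D", positive = TRUE, finite = FALSE)
  stop_if_not_scalar(nm_per_bp, "nm_per_bp", positive = TRUE)
  l_um <- length_bp * nm_per_bp * 1e-3
  list(l_um = l_um, t_s = l_um^2 / (2 * D), t_alt_s = l_um^2 / D)
}

#' Length per basepair at partial extension
#'
#' @param extension_fraction fraction of contour length at the working
#'   tension (in (0, 1]).
#' @param contour_nm_per_bp crystallographic rise per basepair, nm.
#' @return nm per basepair.
#' @export
length_per_bp <- function(extension_fraction, contour_nm_per_bp = 0.338) {
  stop_if_not_scalar(extension_fraction, "extension_fraction")
  if (extension_fraction <= 0 || extension_fraction > 1)
    stop("'extension_fraction' must be in (0, 1]", call. = FALSE)
  stop_if_not_scalar(contour_nm_per_bp, "contour_nm_per_bp", positive = TRUE)
  extension_fraction * contour_nm_per_bp
}

#' Table of sliding/hopping diffusion limits for a particle of given mass
#'
#' Convenience wrapper combining [radius_of_gyration()],
#' [d_limit_no_rotation()] and [d_limit_with_rotation()] at the two
#' bracketing centre-of-mass offsets (Roc = 0 and Roc = R).
#'
#' @param mass_da molecular mass in Daltons.
#' @param model a [hydrodynamic_model()].
#' @return data.frame with one row: radius and the three limits.
#' @export
diffusion_limits <- function(mass_da, model = hydrodynamic_model()) {
  R <- radius_of_gyration(mass_da, model)
  data.frame(
    mass_da = mass_da,
    radius_nm = R,
    d_no_rotation_um2_s = d_limit_no_rotation(R, model),
    d_rotation_roc_R_um2_s = d_limit_with_rotation(R, R, model),
    d_rotation_roc_0_um2_s = d_limit_with_rotation(R, 0, model)
  )
}
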