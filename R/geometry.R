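# Pore geometry: access-resistance cylinder conductance, beta-barrel
# geometry, Stokes-Einstein radii, and permeant-size logic.

#' Conductance of a water-filled cylindrical pore with access resistance
#'
#' Hille-style model: the pore resistance is the series sum of the channel
#' resistance l / (sigma pi r^2) and the access resistance 1 / (2 sigma r)
#' of the two converging solution hemispheres, so
#' G = sigma [ l / (pi r^2) + 1 / (2 r) ]^-1.
#' At l = 0 this reduces to the pure access-limited G = 2 sigma r.
#'
#' @param radius_nm pore radius in nm.
#' @param length_nm pore (membrane) length in nm; default 5, a typical
#'   bilayer span.
#' @param sigma_S_m bulk solution conductivity in S/m; default 1.66,
#'   appropriate for 150 mM KCl at 25 C.
#' @return conductance in nS.
#' @export
cylinder_conductance <- function(radius_nm, length_nm = 5, sigma_S_m = 1.66) {
  stopifnot(all(radius_nm > 0), all(length_nm >= 0), all(sigma_S_m > 0))
  sigma_nS_nm <- sigma_S_m  # S/m = nS/nm: 1 S/m * 1e9 nS/S * 1e-9 m/nm
  sigma_nS_nm / (length_nm / (pi * radius_nm^2) + 1 / (2 * radius_nm))
}

#' Pore radius implied by a conductance
#'
#' Closed-form inverse of [cylinder_conductance()]: G sigma^-1 =
#' [l/(pi r^2) + 1/(2r)]^-1 is quadratic in r, with positive root
#' r = [ G/2 + sqrt(G^2/4 + 4 sigma G l / pi) ] / (2 sigma).
#'
#' @param conductance_nS pore conductance in nS.
#' @param length_nm pore length in nm.
#' @param sigma_S_m solution conductivity in S/m.
#' @return radius in nm.
#' @export
radius_from_conductance <- function(conductance_nS, length_nm = 5,
                                    sigma_S_m = 1.66) {
  stopifnot(all(conductance_nS > 0), all(length_nm >= 0), all(sigma_S_m > 0))
  g <- conductance_nS; s <- sigma_S_m  # nS and nS/nm
  (g / 2 + sqrt(g^2 / 4 + 4 * s * g * length_nm / pi)) / (2 * s)
}

#' Beta-barrel backbone radius and lumen diameter
#'
#' The C-alpha backbone of a closed n_s-stranded barrel sits on a regular
#' polygon of side d (the interstrand spacing), giving circumradius
#' d / (2 sin(pi / n_s)); strand tilt alpha widens the barrel by 1/cos(alpha).
#' The aqueous lumen is narrower than the backbone circle by a wall
#' allowance for side chains.
#'
#' @param n_protomers number of protomers in the ring (>= 2).
#' @param strands_per_protomer beta strands contributed per protomer
#'   (default 2, a beta-hairpin).
#' @param d_A interstrand (hydrogen-bonding) distance in Angstrom
#'   (default 4.8).
#' @param tilt_deg strand tilt from the barrel axis in degrees (default 0).
#' @param wall_allowance_nm radial allowance for side chains in nm
#'   (default 0.25).
#' @return list with `n_strands`, `backbone_radius_nm`, `lumen_diameter_nm`.
#' @export
barrel_radius <- function(n_protomers, strands_per_protomer = 2,
                          d_A = 4.8, tilt_deg = 0, wall_allowance_nm = 0.25) {
  stopifnot(n_protomers >= 2, strands_per_protomer >= 1, d_A > 0,
            tilt_deg >= 0, tilt_deg < 90)
  n_s <- n_protomers * strands_per_protomer
  if (n_s < 4) stop("barrel needs at least 4 strands")
  d_nm <- d_A / 10
  r_bb <- d_nm / (2 * sin(pi / n_s)) / cos(tilt_deg * pi / 180)
  list(n_strands = n_s,
       backbone_radius_nm = r_bb,
       lumen_diameter_nm = 2 * (r_bb - wall_allowance_nm))
}

#' Stokes-Einstein radius from a diffusion coefficient
#'
#' r = k_B T / (6 pi eta D): the radius of the sphere that would diffuse at
#' the observed rate.
#'
#' @param D_m2_s diffusion coefficient in m^2/s.
#' @param temperature_K temperature in kelvin (default 298.15).
#' @param viscosity_Pa_s solvent viscosity in Pa s (default 8.9e-4, water at
#'   25 C).
#' @return hydrodynamic radius in nm.
#' @export
stokes_einstein_radius <- function(D_m2_s, temperature_K = 298.15,
                                   viscosity_Pa_s = 8.9e-4) {
  stopifnot(all(D_m2_s > 0), temperature_K > 0, viscosity_Pa_s > 0)
  1e9 * BOLTZMANN * temperature_K / (6 * pi * viscosity_Pa_s * D_m2_s)
}

#' Diffusion coefficient from a Stokes-Einstein radius
#'
#' Inverse of [stokes_einstein_radius()].
#'
#' @param radius_nm hydrodynamic radius in nm.
#' @param temperature_K temperature in kelvin.
#' @param viscosity_Pa_s solvent viscosity in Pa s.
#' @return diffusion coefficient in m^2/s.
#' @export
diffusion_from_radius <- function(radius_nm, temperature_K = 298.15,
                                  viscosity_Pa_s = 8.9e-4) {
  stopifnot(all(radius_nm > 0), temperature_K > 0, viscosity_Pa_s > 0)
  BOLTZMANN * temperature_K / (6 * pi * viscosity_Pa_s * radius_nm * 1e-9)
}

#' Size-exclusion permeation predicate
#'
#' A solute probe passes the pore iff its hydrodynamic radius does not exceed
#' the pore radius; the margin is the radial clearance.
#'
#' @param probe_radius_nm solute Stokes-Einstein radius in nm.
#' @param pore_radius_nm pore radius in nm.
#' @param name optional probe label.
#' @return list with `name`, `permeant` (logical), `margin_nm`.
#' @export
permeation_predicate <- function(probe_radius_nm, pore_radius_nm,
                                 name = NA_character_) {
  stopifnot(probe_radius_nm > 0, pore_radius_nm > 0)
  list(name = name,
       permeant = probe_radius_nm <= pore_radius_nm,
       margin_nm = pore_radius_nm - probe_radius_nm)
}
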