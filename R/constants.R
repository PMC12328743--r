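# Physical and chemical constants used throughout the package.

# Monoisotopic residue masses (Da) for the 20 standard amino acids,
# i.e. the mass each residue contributes inside a peptide chain.
RESIDUE_MONO_MASS <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
  V = 99.06841390, T = 101.04767846, C = 103.00918448, L = 113.08406396,
  I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496301, E = 129.04259308, M = 131.04048508, H = 137.05891186,
  F = 147.06841390, R = 156.10111102, Y = 163.06332853, W = 186.07931294
)

MASS_WATER <- 18.010565    # monoisotopic H2O, Da
MASS_H_ATOM <- 1.0078250319  # monoisotopic atomic hydrogen, Da

# Proton mass used in m/z arithmetic. "paper" mode uses the rounded constant
# printed in the deconvolution protocol so worked examples reproduce exactly;
# "physical" mode uses the CODATA proton mass.
PROTON_MASS <- c(paper = 1.007, physical = 1.00727646677)

# Kyte-Doolittle hydropathy scale (dimensionless).
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Default hydrophobic residue classification (configurable in all callers).
HYDROPHOBIC_SET_DEFAULT <- c("A", "F", "G", "I", "L", "M", "V", "W")

# Gas constant R (J mol^-1 K^-1) and Faraday constant F (C mol^-1), CODATA.
GAS_CONSTANT <- 8.31446261815324
FARADAY <- 96485.33212

# Boltzmann constant (J/K) for Stokes-Einstein conversions.
BOLTZMANN <- 1.380649e-23

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature_K temperature in kelvin.
#' @return RT/F in mV.
#' @export
rt_over_f_mV <- function(temperature_K = 298.15) {
  stopifnot(temperature_K > 0)
  1000 * GAS_CONSTANT * temperature_K / FARADAY
}
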