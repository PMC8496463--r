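# Physical constants and unit conversions used throughout the package.
# Eq.-level formulas expect PAR in mol quanta m^-2 s^-1 and cross sections in
# m^2; user-facing values are in umol quanta m^-2 s^-1 and nm^2.

#' @keywords internal
AVOGADRO <- 6.02214076e23 # mol^-1

UMOL_TO_MOL <- 1e-6
M2_TO_NM2 <- 1e18
NM2_TO_M2 <- 1e-18

# PSI/PSII excitation split used for relative electron transport rates
ETR_FACTOR <- 0.5

# Conversion factor from PAR (umol quanta m^-2 s^-1) to the PSII-specific
# quantum absorption rate PAR(II) (quanta PSII^-1 s^-1), per nm^2 of
# functional absorption cross section.
PARII_PER_NM2 <- NM2_TO_M2 * AVOGADRO * UMOL_TO_MOL
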