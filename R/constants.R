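# Physical constants (CODATA 2018 where applicable)

#' @keywords internal
R_GAS <- 8.314            # universal gas constant, J mol^-1 K^-1

PLANCK_H <- 6.62607015e-34      # Planck constant, J s
BOHR_MAGNETON <- 9.2740100783e-24  # Bohr magneton, J T^-1
GAMMA_PROTON <- 2.6752218744e8     # proton gyromagnetic ratio, rad s^-1 T^-1
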