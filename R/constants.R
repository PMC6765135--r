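#' Concentration to number-density conversion
#'
#' One nanomolar corresponds to `0.6022` molecules per cubic micrometre
#' (Avogadro's number times 1e-9 mol/L times 1e-15 L/um^3). Used everywhere
#' a fluorophore concentration (nM) is converted to a molecule count in an
#' imaged volume and back.
#'
#' @format A length-one numeric.
#' @export
molecules_per_um3_per_nM <- 0.6022
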