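#' Pressure unit conversions
#'
#' The model works in SI units (Pa) internally; measurement interfaces use
#' cm H2O, the customary unit for subglottal and collision pressures.
#' 1 cm H2O = 98.0665 Pa.
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @export
cmh2o_to_pa <- function(x) x * 98.0665

#' @rdname cmh2o_to_pa
#' @export
pa_to_cmh2o <- function(x) x / 98.0665
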