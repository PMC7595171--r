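#' Physical constants and unit conventions
#'
#' Internal units throughout the package are nanometres for lengths and
#' kJ/mol for energies; temperatures are in Kelvin. Angstroms appear only at
#' I/O boundaries (PDB files, order parameters, RMSDs) with explicit
#' conversion.
#'
#' @format `KB_KJ_MOL_K` is the Boltzmann constant in kJ/mol/K.
#' @export
KB_KJ_MOL_K <- 0.0083145

#' Inverse temperature
#'
#' @param temperature Temperature in K, > 0.
#' @return beta = 1 / (kB * T) in mol/kJ.
#' @export
beta_of <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) >= 1L)
  if (any(temperature <= 0)) {
    stop("temperature must be > 0 K", call. = FALSE)
  }
  1 / (KB_KJ_MOL_K * temperature)
}

#' @rdname unit_conversion
#' @param x Numeric vector of lengths.
#' @return Converted lengths.
#' @export
nm_to_angstrom <- function(x) x * 10

#' Length unit conversion
#'
#' @name unit_conversion
#' @export
angstrom_to_nm <- function(x) x / 10
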