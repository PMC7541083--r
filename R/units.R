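#' Unit conventions
#'
#' Geometry is held internally in nanometres; electrotonic lengths in
#' nm^(1/2) (length divided by the square root of radius, both in nm).
#' One unit of internal electrotonic length equals sqrt(1e-9) m^(1/2).
#' The hemibrain pixel convention is 8 nm per pixel.
#'
#' @name aplspread-units
#' @keywords internal
NULL

# nm^(1/2) -> m^(1/2): (d*1e-9 m)/sqrt(r*1e-9 m) = (d/sqrt(r)) * sqrt(1e-9)
.ELECTROTONIC_NM_TO_M12 <- sqrt(1e-9)
.NM_PER_UM <- 1e3
.NM_PER_M <- 1e9
.NM_PER_HEMIBRAIN_PIXEL <- 8
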