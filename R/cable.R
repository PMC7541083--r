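#' Passive-cable parameter conversions
#'
#' For a passive cylindrical cable, lambda = sqrt(r * Rm / (2 * Ra)) with r
#' the neurite radius, Rm the specific membrane resistance (Ohm m^2) and Ra
#' the specific axial resistance (Ohm m). Factoring out sqrt(r) gives the
#' space constant in electrotonic space, k = sqrt(Rm / (2 Ra)) (m^(1/2)),
#' which relates to the radius-normalized space constant lambda via the
#' skeleton's length-to-electrotonic-length ratio:
#' lambda = k * conversion_ratio (see \code{\link{skeleton_totals}}).
#'
#' @param Rm_over_Ra Rm/Ra in m.
#' @param conversion_ratio total real length / total electrotonic length of
#'   the skeleton, in m^(1/2).
#' @return list of class \code{cable_params} with \code{Rm_over_Ra_m},
#'   \code{k_m12}, \code{lambda_um}, \code{conversion_ratio_m12}.
#' @export
cable_to_space_constant <- function(Rm_over_Ra, conversion_ratio) {
  if (!is.numeric(Rm_over_Ra) || Rm_over_Ra <= 0)
    stop("Rm_over_Ra must be positive")
  if (!is.numeric(conversion_ratio) || conversion_ratio <= 0)
    stop("conversion_ratio must be positive")
  k <- sqrt(Rm_over_Ra / 2)
  structure(list(Rm_over_Ra_m = Rm_over_Ra, k_m12 = k,
                 lambda_um = k * conversion_ratio * 1e6,
                 conversion_ratio_m12 = conversion_ratio),
            class = "cable_params")
}

#' @rdname cable_to_space_constant
#' @param lambda_um radius-normalized space constant in um.
#' @export
lambda_to_cable <- function(lambda_um, conversion_ratio) {
  if (!is.numeric(lambda_um) || lambda_um <= 0)
    stop("lambda must be positive")
  if (!is.numeric(conversion_ratio) || conversion_ratio <= 0)
    stop("conversion_ratio must be positive")
  k <- (lambda_um * 1e-6) / conversion_ratio
  structure(list(Rm_over_Ra_m = 2 * k^2, k_m12 = k,
                 lambda_um = lambda_um,
                 conversion_ratio_m12 = conversion_ratio),
            class = "cable_params")
}

#' @export
print.cable_params <- function(x, ...) {
  cat(sprintf("cable_params: Rm/Ra = %.4g m; k = %.4g m^1/2; lambda = %.4g um\n",
              x$Rm_over_Ra_m, x$k_m12, x$lambda_um))
  invisible(x)
}
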