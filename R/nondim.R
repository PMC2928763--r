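#' Nondimensionalize a kinetic parameter set
#'
#' Rescales concentrations by the total site concentration `D0` and time by
#' the degradation timescale `1/k8`. The resulting dimensionless groups are
#' the control parameters of the reduced system:
#' `K0 = k0/(k8*D0)`, `K1 = k1*D0/k8`, `K2 = k2/k8`, `K3 = k3*D0/k8`,
#' `K4 = k4/k8`, `K5 = k5/(k8*D0)`, `K7 = k7/D0`, plus the dimensionless
#' TBP--DNA dissociation constant `K = K4/K3 = k4/(k3*D0)`. The Hill
#' coefficient `k6` is already dimensionless and is carried unchanged.
#'
#' @param p a [tbp_parameters()] object.
#' @return An object of class `tbp_dimensionless`: a named list with
#'   K0, K1, K2, K3, K4, K5, K7, K, k6 and the reference scales D0, k8.
#' @seealso [dimensionalize()] for the exact inverse.
#' @export
#' @examples
#' nondimensionalize(default_parameters())$K7  # 0.5: k7 is half of D0
nondimensionalize <- function(p) {
  validate_parameters(p)
  structure(list(
    K0 = p$k0 / (p$k8 * p$D0),
    K1 = p$k1 * p$D0 / p$k8,
    K2 = p$k2 / p$k8,
    K3 = p$k3 * p$D0 / p$k8,
    K4 = p$k4 / p$k8,
    K5 = p$k5 / (p$k8 * p$D0),
    K7 = p$k7 / p$D0,
    K  = p$k4 / (p$k3 * p$D0),
    k6 = p$k6,
    D0 = p$D0,
    k8 = p$k8
  ), class = "tbp_dimensionless")
}

#' Recover dimensional parameters from dimensionless groups
#'
#' Exact inverse of [nondimensionalize()] given the reference scales.
#'
#' @param dp a `tbp_dimensionless` object.
#' @param D0 reference concentration (M); defaults to the scale stored in `dp`.
#' @param k8 reference rate (s^-1); defaults to the scale stored in `dp`.
#' @return A [tbp_parameters()] object.
#' @export
dimensionalize <- function(dp, D0 = dp$D0, k8 = dp$k8) {
  if (is.null(D0) || is.null(k8) || D0 <= 0 || k8 <= 0)
    stop("positive reference scales D0 and k8 are required")
  tbp_parameters(
    k0 = dp$K0 * k8 * D0,
    k1 = dp$K1 * k8 / D0,
    k2 = dp$K2 * k8,
    k3 = dp$K3 * k8 / D0,
    k4 = dp$K4 * k8,
    k5 = dp$K5 * k8 * D0,
    k6 = dp$k6,
    k7 = dp$K7 * D0,
    k8 = k8,
    D0 = D0
  )
}

#' @export
print.tbp_dimensionless <- function(x, ...) {
  cat("Dimensionless parameters (concentration scale D0 =", x$D0,
      "M, time scale 1/k8 =", 1 / x$k8, "s)\n")
  for (nm in c("K0", "K1", "K2", "K3", "K4", "K5", "K7", "K", "k6"))
    cat(sprintf("  %-2s = %g\n", nm, x[[nm]]))
  invisible(x)
}
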