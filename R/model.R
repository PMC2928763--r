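#' System state of the TBP model
#'
#' Concentrations of the four species at one time point: free TBP monomer
#' `T`, TBP dimer `T2`, promoter-bound TBP `TD`, and free binding sites `D`.
#' Free sites are tied to the site-conservation relation `D + TD = D0`; if
#' `D` is omitted it is filled in as `D0 - TD`.
#'
#' @param T free TBP monomer concentration (M).
#' @param T2 TBP dimer concentration (M).
#' @param TD TBP--DNA complex concentration (M).
#' @param D free binding-site concentration (M); default `D0 - TD`.
#' @param D0 total promoter-site concentration (M), required when `D` is
#'   omitted or when conservation should be checked.
#' @param check_conservation if `TRUE` (default when `D0` is given), error
#'   unless `|D + TD - D0| <= 1e-6 * D0`.
#' @return A named numeric vector `c(T, T2, TD, D)` of class `tbp_state`.
#' @export
#' @examples
#' system_state(T = 1e-9, T2 = 1e-9, TD = 1e-9, D0 = 2.5e-8)
system_state <- function(T, T2, TD, D = NULL, D0 = NULL,
                         check_conservation = !is.null(D0)) {
  if (is.null(D)) {
    if (is.null(D0)) stop("either D or D0 must be supplied")
    D <- D0 - TD
  }
  s <- c(T = T, T2 = T2, TD = TD, D = D)
  if (any(!is.finite(s))) stop("state concentrations must be finite")
  if (any(s < 0)) stop("state concentrations must be >= 0")
  if (check_conservation && !is.null(D0) &&
      abs(D + TD - D0) > 1e-6 * D0)
    stop("site conservation violated: D + TD differs from D0")
  structure(s, class = "tbp_state")
}

#' Regulated TBP synthesis rate
#'
#' Hill-type production rate `k0 + k5 * TD^k6 / (k7^k6 + TD^k6)` as a
#' function of the promoter-bound TBP concentration. The Hill form is
#' phenomenological (lumped transcription + translation); it does not
#' encode a specific promoter mechanism.
#'
#' @param TD bound-TBP concentration (M); vectorized.
#' @param p a [tbp_parameters()] object.
#' @return Synthesis rate (M s^-1), same length as `TD`. Equals `k0` at
#'   `TD = 0` and saturates at `k0 + k5`.
#' @export
#' @examples
#' synthesis_rate(1.25e-8, default_parameters())  # half-saturation: k0 + k5/2
synthesis_rate <- function(TD, p) {
  if (any(TD < 0)) stop("TD must be >= 0")
  hill <- ifelse(TD > 0, TD^p$k6 / (p$k7^p$k6 + TD^p$k6), 0)
  p$k0 + p$k5 * hill
}

#' Time derivatives of the four-species system
#'
#' Mass-balance right-hand side for (T, T2, TD, D): reversible dimerization
#' (stoichiometric factor 2 on the monomer), reversible DNA binding,
#' Hill-type synthesis driven by bound TBP, and first-order degradation of
#' the free monomer only. `dD/dt = -dTD/dt` holds exactly, so `D + TD` is
#' conserved along trajectories.
#'
#' @param s a state vector as from [system_state()] (named T, T2, TD, D).
#' @param p a [tbp_parameters()] object.
#' @return Named numeric vector of derivatives (M s^-1) for T, T2, TD, D.
#' @export
tbp_rhs <- function(s, p) {
  if (any(s < 0)) stop("state concentrations must be >= 0")
  d <- rhs_raw(s[["T"]], s[["T2"]], s[["TD"]], s[["D"]], p)
  c(T = d[[1L]], T2 = d[[2L]], TD = d[[3L]], D = d[[4L]])
}

# core derivatives; tolerant of the tiny negative excursions adaptive
# solvers produce (species clamped at 0 inside the Hill term only)
rhs_raw <- function(T, T2, TD, D, p) {
  syn <- p$k0 + p$k5 * {
    TDc <- max(TD, 0)
    if (TDc > 0) TDc^p$k6 / (p$k7^p$k6 + TDc^p$k6) else 0
  }
  bind <- p$k3 * T * D - p$k4 * TD
  dim  <- p$k1 * T^2 - p$k2 * T2
  dT  <- -2 * dim - bind + syn - p$k8 * T
  dT2 <- dim
  dTD <- bind
  list(dT, dT2, dTD, -bind)
}

# deSolve-style wrappers
ode_rhs_full <- function(t, y, p) {
  d <- rhs_raw(y[[1L]], y[[2L]], y[[3L]], y[[4L]], p)
  list(c(d[[1L]], d[[2L]], d[[3L]], d[[4L]]))
}

ode_rhs_reduced <- function(t, y, p) {
  d <- rhs_raw(y[[1L]], y[[2L]], y[[3L]], p$D0 - y[[3L]], p)
  list(c(d[[1L]], d[[2L]], d[[3L]]))
}

#' Time derivatives of the reduced three-variable system
#'
#' Site conservation `D = D0 - TD` eliminates the free-site equation; the
#' reduced state is (T, T2, TD). This is the system used for Jacobian-based
#' stability analysis; the full four-variable form is kept for conservation
#' testing.
#'
#' @param s named numeric vector with elements T, T2, TD (M).
#' @param p a [tbp_parameters()] object.
#' @return Named numeric vector of derivatives (M s^-1) for T, T2, TD.
#' @export
tbp_rhs_reduced <- function(s, p) {
  if (any(s[c("T", "T2", "TD")] < 0)) stop("state concentrations must be >= 0")
  if (s[["TD"]] > p$D0) stop("TD exceeds D0 on the reduced manifold")
  d <- rhs_raw(s[["T"]], s[["T2"]], s[["TD"]], p$D0 - s[["TD"]], p)
  c(T = d[[1L]], T2 = d[[2L]], TD = d[[3L]])
}

#' Equivalent total TBP concentration
#'
#' Monomer-equivalent bookkeeping: each dimer contributes two monomers, so
#' the total is `T + 2*T2 + TD`. This is the quantity the steady-state and
#' bifurcation analyses report on their concentration axes.
#'
#' @param s a state vector (named T, T2, TD), or a trajectory/steady-state
#'   data.frame with those columns.
#' @return Total TBP (M), vectorized over rows for data.frame input.
#' @export
total_tbp <- function(s) {
  if (is.data.frame(s)) return(s$T + 2 * s$T2 + s$TD)
  s[["T"]] + 2 * s[["T2"]] + s[["TD"]]
}
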