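#' Jacobian of the reduced three-variable system
#'
#' Analytic partial derivatives of the (T, T2, TD) right-hand side with
#' free sites eliminated via `D = D0 - TD`. The Hill-term derivative at
#' `TD = 0` is 0 for `k6 > 1`, `k5*k6/k7` for `k6 = 1`, and divergent for
#' `k6 < 1`; in the divergent case the affected entry is returned as `NA`
#' and stability must be decided by the numeric-perturbation fallback in
#' [classify_stability()].
#'
#' @param s a state: named vector or one-row data.frame with T, T2, TD (M).
#' @param p a [tbp_parameters()] object.
#' @return A 3x3 numeric matrix (s^-1) with rows/columns T, T2, TD.
#' @export
tbp_jacobian <- function(s, p) {
  if (is.data.frame(s)) s <- unlist(s[1, c("T", "T2", "TD")])
  T <- s[["T"]]; TD <- s[["TD"]]
  D <- p$D0 - TD
  hprime <- hill_derivative(TD, p)
  J <- matrix(0, 3, 3, dimnames = list(c("T", "T2", "TD"),
                                       c("T", "T2", "TD")))
  J["T", "T"]   <- -4 * p$k1 * T - p$k3 * D - p$k8
  J["T", "T2"]  <- 2 * p$k2
  J["T", "TD"]  <- p$k4 + p$k3 * T + hprime
  J["T2", "T"]  <- 2 * p$k1 * T
  J["T2", "T2"] <- -p$k2
  J["TD", "T"]  <- p$k3 * D
  J["TD", "TD"] <- -p$k3 * T - p$k4
  J
}

# d/dTD of k5 * TD^k6 / (k7^k6 + TD^k6)
hill_derivative <- function(TD, p) {
  if (TD == 0) {
    if (p$k6 > 1) return(0)
    if (p$k6 == 1) return(p$k5 / p$k7)
    return(NA_real_)  # divergent for k6 < 1
  }
  num <- p$k5 * p$k6 * p$k7^p$k6 * TD^(p$k6 - 1)
  num / (p$k7^p$k6 + TD^p$k6)^2
}

#' Linear stability of a fixed point
#'
#' Classifies a fixed point from the eigenvalues of the reduced Jacobian:
#' `stable` if all real parts are below `-tol`, `unstable` if any exceeds
#' `+tol`, `marginal` if the largest real part lies within `±tol`. When
#' the Jacobian is undefined (divergent Hill derivative at the zero state
#' for `k6 < 1`) the call falls back to numeric perturbation: trajectories
#' started at ±1% of each coordinate are integrated and checked for
#' return versus escape.
#'
#' @param ss a fixed point: one-row `tbp_steady_states` data.frame or a
#'   named state vector with T, T2, TD.
#' @param p a [tbp_parameters()] object.
#' @param tol eigenvalue sign tolerance (s^-1); defaults to `1e-12` scaled
#'   by `k8` relative to the reference degradation rate `7.4e-5 s^-1`, so
#'   it stays far below the slowest kinetic rate for any rescaling of the
#'   system.
#' @return A list of class `tbp_stability`: `eigenvalues` (complex,
#'   length 3; `NA` when the Jacobian was undefined), `classification`
#'   (`stable`, `unstable`, `marginal`, or `undetermined`), `method`
#'   (`eigenvalue` or `perturbation`), and `relaxation_time`
#'   (`1/|max Re of the stable spectrum|`, s; `NA` unless all eigenvalues
#'   are stable).
#' @export
#' @examples
#' p <- default_parameters(k0 = 0)
#' ss <- find_steady_states(p, classify = FALSE)
#' classify_stability(ss[nrow(ss), ], p)  # high state: stable
classify_stability <- function(ss, p, tol = 1e-12 * p$k8 / 7.4e-5) {
  s <- if (is.data.frame(ss)) unlist(ss[1, c("T", "T2", "TD")]) else
    ss[c("T", "T2", "TD")]
  J <- tbp_jacobian(s, p)
  if (any(is.na(J))) {
    cls <- perturbation_classify(s, p)
    return(structure(list(eigenvalues = rep(NA_complex_, 3),
                          classification = cls,
                          method = "perturbation",
                          relaxation_time = NA_real_),
                     class = "tbp_stability"))
  }
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)[order(-Re(as.complex(ev)))]
  re <- Re(ev)
  cls <- if (all(re < -tol)) "stable"
         else if (any(re > tol)) "unstable"
         else "marginal"
  relax <- if (all(re < -tol)) 1 / abs(max(re)) else NA_real_
  structure(list(eigenvalues = ev, classification = cls,
                 method = "eigenvalue", relaxation_time = relax),
            class = "tbp_stability")
}

#' @export
print.tbp_stability <- function(x, ...) {
  cat("Stability:", x$classification, paste0("(", x$method, ")"), "\n")
  if (!all(is.na(x$eigenvalues)))
    cat("  eigenvalues (s^-1):",
        paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  if (!is.na(x$relaxation_time))
    cat("  dominant relaxation time:", format(x$relaxation_time), "s\n")
  invisible(x)
}

# numeric fallback: perturb each coordinate by +/-1% (1e-3 * D0 for zero
# coordinates), integrate to 10/k8, test return to within 0.1%
perturbation_classify <- function(s, p) {
  scale0 <- 1e-3 * p$D0
  t_end <- 10 / p$k8
  returned <- TRUE
  for (i in 1:3) {
    for (sgn in c(-1, 1)) {
      s1 <- s
      eps <- if (s[i] > 0) 0.01 * s[i] else scale0
      s1[i] <- max(s[i] + sgn * eps, 0)
      if (i == 3) s1[i] <- min(s1[i], p$D0)
      tr <- integrate_tbp(p, state3_to_full(s1, p), t_end = t_end,
                          n_times = 120)
      fin <- unlist(tr[nrow(tr), c("T", "T2", "TD")])
      dev <- abs(fin - s) / pmax(abs(s), scale0)
      if (any(dev > 1e-3)) returned <- FALSE
    }
  }
  if (returned) "stable" else "unstable"
}

state3_to_full <- function(s, p) {
  c(T = unname(s[["T"]]), T2 = unname(s[["T2"]]),
    TD = unname(s[["TD"]]), D = p$D0 - unname(s[["TD"]]))
}

#' Linearized response-time estimate at a stable fixed point
#'
#' Single-exponential estimate of the time to recover a given fraction of
#' a small perturbation, from the slowest stable eigenvalue of the
#' Jacobian: `t = -log(1 - recovery_fraction) / |Re lambda_slow|`. This is
#' an analytical estimate to compare against the simulated
#' [response_time()]; for strongly coupled relaxation the two agree in
#' order of magnitude rather than exactly.
#'
#' @param ss a stable fixed point (row of a classified steady-state table,
#'   or a state vector).
#' @param p a [tbp_parameters()] object.
#' @param recovery_fraction fraction of the perturbation to recover
#'   (e.g. 0.9 for the standard protocol).
#' @return Estimated recovery time (s).
#' @export
linearized_response_time <- function(ss, p, recovery_fraction = 0.9) {
  if (recovery_fraction < 0 || recovery_fraction >= 1)
    stop("recovery_fraction must be in [0, 1)")
  rep_ <- classify_stability(ss, p)
  if (rep_$classification != "stable")
    stop("linearized response time is defined only at a stable fixed point")
  lam_slow <- max(Re(rep_$eigenvalues))
  -log(1 - recovery_fraction) / abs(lam_slow)
}
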