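# Independent oracles and random-draw generators for the test suite.
# Everything here recomputes the science from first principles (direct
# formula evaluation, dense scans, finite differences) without going
# through the package's own solver paths.

# reference mammalian constants
ref_params <- function(...) default_parameters(...)

# steady-state function written out directly (independent of the package's
# steady_state_function)
oracle_f <- function(T, p) {
  Kd <- p$k4 / p$k3
  TD <- ifelse(T > 0, T * p$D0 / (Kd + T), 0)
  hill <- ifelse(TD > 0, TD^p$k6, 0)
  (p$k8 * T - p$k0) * (p$k7^p$k6 + hill) - p$k5 * hill
}

# brute-force sign scan: returns the bracketing intervals of every sign
# change of f on a dense log grid
oracle_sign_brackets <- function(p, lower = 1e-16, upper = 1e-3,
                                 n = 1e5) {
  g <- exp(seq(log(lower), log(upper), length.out = n))
  fv <- oracle_f(g, p)
  i <- which(fv[-1] * fv[-n] < 0)
  cbind(lo = g[i], hi = g[i + 1])
}

# numeric tangency oracle for the fold in k5: along the nonzero branch
# f = 0 is equivalent to k5 = g(T); the fold is the minimum of g
oracle_k5c_tangency <- function(p) {
  g <- function(logT) {
    T <- exp(logT)
    TD <- T * p$D0 / (p$k4 / p$k3 + T)
    p$k8 * T * (p$k7^p$k6 + TD^p$k6) / TD^p$k6
  }
  stats::optimize(g, c(log(1e-16), log(1e-3)))$objective
}

# fold in k3: root of min_T g(T; k3) - k5 over k3
oracle_k3c_tangency <- function(p) {
  h <- function(k3) {
    q <- p; q$k3 <- k3
    oracle_k5c_tangency(q) - p$k5
  }
  stats::uniroot(h, c(p$k3 * 1e-4, p$k3 * 1e4), tol = p$k3 * 1e-10)$root
}

# central finite-difference Jacobian of the reduced 3-variable system
oracle_fd_jacobian <- function(s, p, h_rel = 1e-6) {
  s <- unlist(s[c("T", "T2", "TD")])
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- max(abs(s[j]) * h_rel, 1e-9 * p$D0 * h_rel)
    sp <- s; sm <- s
    sp[j] <- s[j] + h; sm[j] <- max(s[j] - h, 0)
    dp <- tbp_rhs_reduced(sp, p)
    dm <- tbp_rhs_reduced(sm, p)
    J[, j] <- (dp - dm) / (sp[j] - sm[j])
  }
  dimnames(J) <- list(c("T", "T2", "TD"), c("T", "T2", "TD"))
  J
}

# random parameter draws spanning the physiological ranges; k5 is drawn
# relative to the closed-form fold value at the drawn (k3, k4, k7, D0, k8)
# so both monostable and bistable regimes are exercised
rlog <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

rand_params <- function(k6 = 2, k0_mode = c("zero", "basal"),
                        k5_rel_range = c(0.1, 100)) {
  k0_mode <- match.arg(k0_mode)
  D0 <- rlog(1, 1e-9, 1e-5)
  k7 <- rlog(1, 1e-2, 1e2) * D0
  k3 <- rlog(1, 1e4, 1e7)
  k4 <- rlog(1, 1e-5, 1e-2)
  k8 <- rlog(1, 1e-5, 1e-3)
  K <- k4 / (k3 * D0); K7 <- k7 / D0
  K5c <- 2 * (K * K7^2 + sqrt(K^2 * K7^2 + K^2 * K7^4))
  k5 <- rlog(1, k5_rel_range[1], k5_rel_range[2]) * K5c * k8 * D0
  k0 <- if (k0_mode == "zero") 0 else rlog(1, 1e-4, 5e-2) * k5
  tbp_parameters(k0 = k0, k1 = rlog(1, 1e3, 1e7),
                 k2 = rlog(1, 1e-5, 1e-1), k3 = k3, k4 = k4, k5 = k5,
                 k6 = k6, k7 = k7, k8 = k8, D0 = D0)
}

rand_state <- function(p) {
  TD <- stats::runif(1, 0, p$D0)
  system_state(T = rlog(1, 1e-12, 1e-6), T2 = rlog(1, 1e-12, 1e-6),
               TD = TD, D0 = p$D0)
}

# strict relative comparison for concentration-scale quantities (plain
# expect_equal tolerances degrade to absolute comparison at magnitudes
# near zero, which would be vacuous for molar values)
expect_rel <- function(actual, expected, tol, info = NULL) {
  stopifnot(length(actual) == length(expected))
  scale <- abs(expected)
  if (any(expected == 0))
    scale[expected == 0] <- max(abs(expected), .Machine$double.xmin)
  dev <- max(abs(actual - expected) / scale)
  testthat::expect_lt(dev, tol,
                      label = paste0("relative deviation",
                                     if (!is.null(info)) paste0(" [", info, "]"),
                                     sprintf(" (actual %s vs expected %s)",
                                             paste(signif(actual, 8), collapse = ","),
                                             paste(signif(expected, 8), collapse = ","))))
}
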