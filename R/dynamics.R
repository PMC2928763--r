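#' Integrate the TBP kinetics in time
#'
#' Stiff-capable adaptive integration of the four-species mass balances
#' with `deSolve` (lsoda, which switches to a BDF method on stiffness).
#' The default absolute tolerance is far below the smallest physiological
#' concentration so that near-zero species are resolved.
#'
#' @param p a [tbp_parameters()] object.
#' @param s0 initial state: named vector with T, T2, TD and optionally D
#'   (filled as `D0 - TD` when absent).
#' @param t_end final time (s).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param times optional explicit output times (s); by default `n_times`
#'   log-spaced points from `t_end * 1e-8` to `t_end`, plus 0.
#' @param n_times number of default output points.
#' @param method deSolve method name.
#' @return A data.frame of class `tbp_trajectory` with columns
#'   `time, T, T2, TD, D`, parameter set in `attr(, "parameters")`.
#' @export
#' @examples
#' p <- default_parameters(k0 = 0)
#' ss <- find_steady_states(p)
#' hs <- high_state(ss)
#' tr <- integrate_tbp(p, c(T = hs$T * 1.05, T2 = hs$T2, TD = hs$TD),
#'                     t_end = 10 / p$k8)
integrate_tbp <- function(p, s0, t_end, rtol = 1e-8, atol = 1e-20,
                          times = NULL, n_times = 400,
                          method = "lsoda") {
  validate_parameters(p)
  if (t_end <= 0) stop("t_end must be > 0")
  if (!("D" %in% names(s0)))
    s0 <- c(s0[c("T", "T2", "TD")], D = p$D0 - unname(s0[["TD"]]))
  y0 <- c(T = unname(s0[["T"]]), T2 = unname(s0[["T2"]]),
          TD = unname(s0[["TD"]]), D = unname(s0[["D"]]))
  if (any(y0 < 0)) stop("initial concentrations must be >= 0")
  if (is.null(times))
    times <- c(0, exp(seq(log(t_end * 1e-8), log(t_end),
                          length.out = n_times)))
  out <- deSolve::ode(y = y0, times = times, func = ode_rhs_full,
                      parms = p, method = method, rtol = rtol,
                      atol = atol)
  attr_ds <- attributes(out)
  if (!is.null(attr_ds$istate) && attr_ds$istate[1] < 0)
    stop("integration failed at t = ", max(out[, "time"]),
         " s (istate ", attr_ds$istate[1], ")")
  tr <- as.data.frame(out[, c("time", "T", "T2", "TD", "D")])
  structure(tr, class = c("tbp_trajectory", "data.frame"),
            parameters = p)
}

#' Phase-plane trajectories and basin bracketing
#'
#' Integrates the system from a list of initial conditions and labels the
#' attractor each trajectory reaches (by proximity, within 1% on the
#' total-TBP scale, to a verified fixed point). With the bistable `k0 = 0`
#' baseline, it also reports the separatrix bracket: the largest sampled
#' initial total that decays to the zero state and the smallest that
#' reaches the high state.
#'
#' @param p a [tbp_parameters()] object.
#' @param initial_states list of initial states (each as for
#'   [integrate_tbp()]).
#' @param t_end integration horizon (s); default `50/k8`.
#' @param ... further arguments to [integrate_tbp()].
#' @return A list of class `tbp_phase_plane`: `trajectories` (list of
#'   `tbp_trajectory`), `attractor` (character vector: `zero`, `high`,
#'   `low`, or `undetermined`), `initial_total`, `separatrix_bracket`
#'   (c(lower, upper), M; NA if one side is unsampled), and the
#'   steady-state table used for labeling.
#' @export
phase_plane <- function(p, initial_states, t_end = 50 / p$k8, ...) {
  ss <- find_steady_states(p)
  scale <- max(ss$total, p$D0)
  trajs <- lapply(initial_states, function(s0)
    integrate_tbp(p, s0, t_end = t_end, ...))
  lab <- vapply(trajs, function(tr)
    attractor_label(tr, ss, scale), "")
  tot0 <- vapply(trajs, function(tr) total_tbp(tr[1, ]), 0)
  to_zero <- tot0[lab == "zero"]
  to_high <- tot0[lab == "high"]
  bracket <- c(lower = if (length(to_zero)) max(to_zero) else NA_real_,
               upper = if (length(to_high)) min(to_high) else NA_real_)
  structure(list(trajectories = trajs, attractor = lab,
                 initial_total = tot0, separatrix_bracket = bracket,
                 steady_states = ss),
            class = "tbp_phase_plane")
}

attractor_label <- function(tr, ss, scale) {
  fin <- total_tbp(tr[nrow(tr), ])
  d <- abs(ss$total - fin) / scale
  i <- which.min(d)
  if (d[i] <= 0.01) ss$label[i] else "undetermined"
}

#' Slow-manifold equilibrium-ratio check
#'
#' After the fast DNA-binding transient, trajectories collapse onto the
#' binding pseudo-equilibrium where `T * D / TD` equals the dissociation
#' constant `k4/k3`. Returns the time-resolved ratio on the late-time
#' segment (`t > t_min`, default `10/k4`) and its median; points with
#' `TD` below `td_floor` are excluded as numerically meaningless.
#'
#' @param traj a `tbp_trajectory`.
#' @param p the parameter set (defaults to the trajectory's own).
#' @param t_min start of the late-time segment (s).
#' @param td_floor exclusion threshold on TD (M).
#' @return List: `time`, `ratio` (M) on the retained segment,
#'   `median_ratio` (M), `expected` (`k4/k3`, M).
#' @export
slow_manifold_ratio <- function(traj, p = attr(traj, "parameters"),
                                t_min = 10 / p$k4, td_floor = 1e-18) {
  seg <- traj[traj$time > t_min & traj$TD > td_floor, , drop = FALSE]
  if (!nrow(seg))
    stop("no late-time points past the fast transient (t > ", t_min, " s)")
  ratio <- seg$T * seg$D / seg$TD
  list(time = seg$time, ratio = ratio,
       median_ratio = stats::median(ratio),
       expected = p$k4 / p$k3)
}

#' Response time to a perturbation in free TBP
#'
#' Standard protocol: start at the stable high-TBP fixed point, decrease
#' the free monomer by `perturbation` (dimer and bound pools untouched),
#' and report the first time after which `|T(t) - Tss|` stays within
#' `(1 - recovery) * Tss` for the rest of the integration. Recovery is
#' detected as *sustained* return (checked to `t_end`), not first
#' crossing, because the three-variable relaxation can overshoot. The
#' crossing time is linearly interpolated between output points.
#'
#' @param p a [tbp_parameters()] object; must have a stable high state.
#' @param perturbation fractional decrease of free TBP (default 0.10).
#' @param recovery fraction of the steady-state value to regain (default
#'   0.99, i.e. recovery of 90% of a 10% perturbation).
#' @param t_end integration horizon (s); default `50/k8`.
#' @param n_times trajectory sampling density.
#' @param rtol,atol solver tolerances.
#' @return Recovery time (s); 0 when `perturbation = 0`.
#' @export
response_time <- function(p, perturbation = 0.10, recovery = 0.99,
                          t_end = 50 / p$k8, n_times = 3000,
                          rtol = 1e-8, atol = 1e-20) {
  if (perturbation < 0 || perturbation >= 1)
    stop("perturbation must be in [0, 1)")
  if (perturbation == 0) return(0)
  ss <- find_steady_states(p)
  hs <- high_state(ss, require_stable = TRUE)
  if (is.null(hs))
    stop("no stable high-TBP state at these parameters")
  s0 <- c(T = hs$T * (1 - perturbation), T2 = hs$T2, TD = hs$TD)
  tr <- integrate_tbp(p, s0, t_end = t_end, n_times = n_times,
                      rtol = rtol, atol = atol)
  thr <- (1 - recovery)
  dev <- abs(tr$T - hs$T) / hs$T
  if (dev[length(dev)] > thr) {
    fin <- total_tbp(tr[nrow(tr), ])
    if (fin < 0.5 * hs$total)
      stop("perturbation escaped basin of the high-TBP state")
    stop("free TBP did not recover to within ", thr,
         " of steady state by t_end = ", t_end, " s")
  }
  bad <- which(dev > thr)
  if (!length(bad)) return(0)
  i <- max(bad)
  t1 <- tr$time[i]; t2 <- tr$time[i + 1]
  d1 <- dev[i]; d2 <- dev[i + 1]
  if (d1 == d2) return(t2)
  t1 + (d1 - thr) * (t2 - t1) / (d1 - d2)
}

#' Effect of the dimer pool on recovery from perturbation
#'
#' Compares the [response_time()] of the given system with that of the
#' hypothetical dimer-free variant (`k1 = 0`). Each variant is perturbed
#' at its *own* high-TBP fixed point; free and bound steady-state levels
#' are identical between the two (the steady-state function contains
#' neither k1 nor k2), only the dimer pool differs. The ratio of the two
#' times measures how much the dimer reservoir buffers the free pool, and
#' is reported together with the dimer:bound concentration ratio
#' `T2ss/TDss` of the with-dimer system.
#'
#' @param p a [tbp_parameters()] object.
#' @param scenario_id optional identifier copied into the result.
#' @param ... further arguments to [response_time()].
#' @return A list of class `tbp_response_comparison`: `scenario_id`,
#'   `t_with_dimer`, `t_without_dimer` (s), `ratio`
#'   (`t_with/t_without`), `dimer_to_bound_ratio` (`T2ss/TDss`).
#' @export
#' @examples
#' \donttest{
#' compare_dimer_effect(default_parameters(k0 = 0))  # mammalian-like: ~1
#' }
compare_dimer_effect <- function(p, scenario_id = NA_character_, ...) {
  p_nd <- set_parameters(p, k1 = 0)
  hs <- high_state(find_steady_states(p), require_stable = TRUE)
  if (is.null(hs))
    stop("with-dimer system has no stable high-TBP state")
  if (is.null(high_state(find_steady_states(p_nd), require_stable = TRUE)))
    stop("dimer-free (k1 = 0) variant has no stable high-TBP state")
  t_w <- response_time(p, ...)
  t_wo <- response_time(p_nd, ...)
  structure(list(scenario_id = scenario_id,
                 t_with_dimer = t_w, t_without_dimer = t_wo,
                 ratio = t_w / t_wo,
                 dimer_to_bound_ratio = hs$T2 / hs$TD),
            class = "tbp_response_comparison")
}

#' @export
print.tbp_response_comparison <- function(x, ...) {
  cat(sprintf(
    "Response time with dimer %.4g s, without %.4g s (ratio %.3g); T2ss/TDss = %.3g\n",
    x$t_with_dimer, x$t_without_dimer, x$ratio, x$dimer_to_bound_ratio))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param traj a `tbp_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
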