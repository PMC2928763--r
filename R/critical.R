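#' Saddle-node critical values of k3, k5 and k0
#'
#' A fold (saddle-node) bifurcation occurs where the steady-state function
#' and its derivative vanish simultaneously (`f = 0`, `df/dT = 0`): the
#' low- and high-TBP branches coalesce. For the cooperative case `k6 = 2`
#' with no basal synthesis (`k0 = 0`) the tangency condition has closed
#' forms in the dimensionless groups (`K = K4/K3`, i.e. `k4/(k3*D0)`):
#'
#' \deqn{K3_c = 2\,(K4 K5 K7^2 + \sqrt{K4^2 K5^2 K7^2 + K4^2 K5^2 K7^4})/K5^2}
#' \deqn{K5_c = 2\,(K K7^2 + \sqrt{K^2 K7^2 + K^2 K7^4})}
#'
#' dimensionalized via `k3 = K3 * k8 / D0` and `k5 = K5 * k8 * D0`. Below
#' the critical value only the zero state remains; above it the system is
#' bistable. Outside the `k6 = 2`, `k0 = 0` case the closed forms do not
#' apply and a numeric scan (bisection on the positive-root count of
#' [find_steady_states()]) is used.
#'
#' For the basal rate, `critical_k0()` bisects `k0` on `[0, k5]` for the
#' value below which three steady states coexist; no closed form is
#' available.
#'
#' @param p a [tbp_parameters()] object giving the baseline at which the
#'   other parameters are held.
#' @param method `"closed_form"` (default where valid) or
#'   `"numeric_scan"`.
#' @param lower,upper,n_grid root-search controls passed to the scan.
#' @return An object of class `tbp_critical`: list with `parameter`,
#'   `value` (units of that parameter), `method`, and `regime` (state
#'   counts below/above). `critical_k0()` additionally reports
#'   `ratio_to_k5`; if the root count never changes on `[0, k5]` its
#'   `value` is `NA` and `regime` says `"no critical value"`.
#' @export
#' @examples
#' p <- default_parameters(k0 = 0)
#' critical_k3(p)                          # closed form, ~9.58e4 M^-1 s^-1
#' critical_k5(p, method = "numeric_scan") # ~2.394e-13 M s^-1
critical_k3 <- function(p, method = c("closed_form", "numeric_scan"),
                        lower = 1e-16, upper = 1e-3, n_grid = 6000) {
  method <- match.arg(method)
  if (p$k5 <= 0) stop("k5 must be > 0 for a critical k3 to exist")
  if (method == "closed_form") {
    if (!(p$k6 == 2 && p$k0 == 0)) {
      method <- "numeric_scan"
    } else {
      d <- nondimensionalize(p)
      K3c <- 2 * (d$K4 * d$K5 * d$K7^2 +
                    sqrt(d$K4^2 * d$K5^2 * d$K7^2 +
                           d$K4^2 * d$K5^2 * d$K7^4)) / d$K5^2
      return(new_critical("k3", K3c * p$k8 / p$D0, "closed_form"))
    }
  }
  val <- bisect_fold(p, "k3", lower, upper, n_grid)
  new_critical("k3", val, "numeric_scan")
}

#' @rdname critical_k3
#' @export
critical_k5 <- function(p, method = c("closed_form", "numeric_scan"),
                        lower = 1e-16, upper = 1e-3, n_grid = 6000) {
  method <- match.arg(method)
  if (p$k3 <= 0) stop("k3 must be > 0 for a critical k5 to exist")
  if (method == "closed_form") {
    if (!(p$k6 == 2 && p$k0 == 0)) {
      method <- "numeric_scan"
    } else {
      d <- nondimensionalize(p)
      K5c <- 2 * (d$K * d$K7^2 +
                    sqrt(d$K^2 * d$K7^2 + d$K^2 * d$K7^4))
      return(new_critical("k5", K5c * p$k8 * p$D0, "closed_form"))
    }
  }
  val <- bisect_fold(p, "k5", lower, upper, n_grid)
  new_critical("k5", val, "numeric_scan")
}

#' @rdname critical_k3
#' @param n_grid_k0 scan resolution for the root count during the `k0`
#'   bisection; finer than the default because the coalescing pair of
#'   roots must stay resolvable close to the fold.
#' @export
critical_k0 <- function(p, lower = 1e-16, upper = 1e-3,
                        n_grid_k0 = 20000) {
  if (p$k5 <= 0) stop("k5 must be > 0")
  count_at <- function(k0) {
    count_positive_roots(set_parameters(p, k0 = k0), lower, upper,
                         n_grid_k0)
  }
  n_lo <- count_at(0)
  n_hi <- count_at(p$k5)
  if (n_lo < 2 || n_hi >= 3) {
    return(structure(list(parameter = "k0", value = NA_real_,
                          ratio_to_k5 = NA_real_, method = "numeric_scan",
                          regime = "no critical value in [0, k5]"),
                     class = "tbp_critical"))
  }
  lo <- 0; hi <- p$k5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (count_at(mid) >= 3) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-8 * hi) break
  }
  val <- (lo + hi) / 2
  structure(list(parameter = "k0", value = val,
                 ratio_to_k5 = val / p$k5, method = "numeric_scan",
                 regime = "3 states below, 1 above"),
            class = "tbp_critical")
}

new_critical <- function(parameter, value, method) {
  structure(list(parameter = parameter, value = value, method = method,
                 regime = "monostable zero below, bistable above"),
            class = "tbp_critical")
}

#' @export
print.tbp_critical <- function(x, ...) {
  cat(sprintf("Critical %s = %g (%s); %s\n",
              x$parameter, x$value, x$method, x$regime))
  invisible(x)
}

# log-bisection on the count of positive roots as `name` varies; the
# bracket is found by scanning +/- 4 decades around the baseline value.
bisect_fold <- function(p, name, lower, upper, n_grid, decades = 4,
                        rel_tol = 1e-7) {
  count_at <- function(v) {
    q <- p; q[[name]] <- v
    count_positive_roots(q, lower, upper, n_grid)
  }
  base <- p[[name]]
  grid <- base * 10^seq(-decades, decades, by = 0.5)
  cnt <- vapply(grid, count_at, 0L)
  multi <- cnt >= 2
  if (all(multi) || !any(multi))
    stop("no fold found for ", name, " within +/-", decades,
         " decades of its baseline value")
  i <- which(multi)[1]
  if (i == 1) stop("fold bracket open at the lower scan edge")
  lo <- grid[i - 1]; hi <- grid[i]
  while ((hi - lo) > rel_tol * hi) {
    mid <- sqrt(lo * hi)
    if (count_at(mid) >= 2) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}
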