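#' Predicted number of steady states from the tabulated conditions
#'
#' Evaluates the analytical multiplicity conditions for the tabulated
#' cooperativity cases `k6 = 1` and `k6 = 2`, in the dimensionless groups
#' (`K = K4/K3`, `K5`, `K7`, `K0`). The prediction counts fixed points the
#' same way [find_steady_states()] reports them: the zero state is included
#' when `k0 = 0` (it is always a root there), so e.g. the bistable
#' cooperative regime predicts 3 states (zero, low, high).
#'
#' Conditions implemented:
#' \itemize{
#'   \item `k6 = 2`, `k0 = 0`: 3 states iff `K5 > K5_c` with
#'     `K5_c = 2 (K K7^2 + sqrt(K^2 K7^2 + K^2 K7^4))` (the exact fold
#'     threshold from the tangency condition), else 1 (zero only).
#'   \item `k6 = 2`, `k0 > 0`: 3 states iff `k0 < k0_c` (computed
#'     numerically by [critical_k0()]), else 1.
#'   \item `k6 = 1`, `k0 = 0`: 2 states (zero + one positive) iff
#'     `K5 > K7 * K`, else 1.
#'   \item `k6 = 1`, `k0 > 0`: 1 state if `K0` is far below `K`
#'     (heuristic factor `basal_factor`, default 100) and `K5 > K7 * K`;
#'     outside that region the tabulated conditions make no prediction and
#'     `NA` is returned with `heuristic = TRUE`.
#' }
#'
#' @param dp a `tbp_dimensionless` object from [nondimensionalize()]
#'   (carries `k6` and `K0`; pass `k0_zero` to override the basal-rate
#'   case).
#' @param k0_zero logical; treat the basal rate as exactly zero. Defaults
#'   to `dp$K0 == 0`.
#' @param basal_factor the "much less than" factor for the `k6 = 1`,
#'   `k0 > 0` case; the condition is `K0 < K / basal_factor`.
#' @return A list of class `tbp_multiplicity`: `count` (integer or `NA`),
#'   `condition` (human-readable inequality evaluated), `heuristic`
#'   (logical).
#' @export
#' @examples
#' predicted_multiplicity(nondimensionalize(default_parameters(k0 = 0)))
predicted_multiplicity <- function(dp, k0_zero = dp$K0 == 0,
                                   basal_factor = 100) {
  k6 <- dp$k6
  if (!(k6 %in% c(1, 2)))
    stop("multiplicity conditions are tabulated only for k6 = 1 or 2")
  K <- dp$K; K5 <- dp$K5; K7 <- dp$K7; K0 <- dp$K0
  if (k6 == 2) {
    if (k0_zero) {
      K5c <- 2 * (K * K7^2 + sqrt(K^2 * K7^2 + K^2 * K7^4))
      n <- if (K5 > K5c) 3L else 1L
      return(mult_result(n, sprintf("K5 %s K5_c = %.4g",
                                    if (K5 > K5c) ">" else "<=", K5c),
                         FALSE))
    }
    p <- dimensionalize(dp)
    k0c <- critical_k0(p)$value
    if (is.na(k0c))
      return(mult_result(NA_integer_, "no k0 fold in [0, k5]", FALSE))
    n <- if (p$k0 < k0c) 3L else 1L
    return(mult_result(n, sprintf("k0 %s k0_c = %.4g",
                                  if (p$k0 < k0c) "<" else ">=", k0c),
                       FALSE))
  }
  # k6 == 1
  thr <- K7 * K
  if (k0_zero) {
    n <- if (K5 > thr) 2L else 1L
    return(mult_result(n, sprintf("K5 %s K7*K = %.4g",
                                  if (K5 > thr) ">" else "<=", thr),
                       FALSE))
  }
  if (K0 < K / basal_factor && K5 > thr)
    return(mult_result(1L,
      sprintf("K0 = %.4g << K = %.4g (factor %g) and K5 > K7*K",
              K0, K, basal_factor), TRUE))
  mult_result(NA_integer_,
              "outside the tabulated k6 = 1, k0 > 0 condition", TRUE)
}

mult_result <- function(count, condition, heuristic) {
  structure(list(count = count, condition = condition,
                 heuristic = heuristic),
            class = "tbp_multiplicity")
}

#' @export
print.tbp_multiplicity <- function(x, ...) {
  cat("Predicted steady states:", x$count,
      if (x$heuristic) "(heuristic)" else "", "\n  condition:",
      x$condition, "\n")
  invisible(x)
}
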