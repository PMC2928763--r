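#' Bound-TBP concentration in binding equilibrium with free TBP
#'
#' At steady state the DNA-binding reaction equilibrates, giving
#' `TD = T * D0 / (k4/k3 + T)`. Used to reduce the fixed-point problem to a
#' scalar function of the free monomer concentration.
#'
#' @param T free TBP concentration (M); vectorized.
#' @param p a [tbp_parameters()] object.
#' @return Bound-TBP concentration (M).
#' @export
bound_equilibrium <- function(T, p) {
  if (p$k3 == 0) return(rep(0, length(T)))
  Kd <- p$k4 / p$k3
  as.numeric(ifelse(T > 0, T * p$D0 / (Kd + T), 0))
}

#' Scalar steady-state function f(T)
#'
#' Fixed points of the model are the nonnegative zeros of
#' `f(T) = (k8*T - k0) * (k7^k6 + TD(T)^k6) - k5 * TD(T)^k6`
#' with `TD(T)` the binding-equilibrium bound concentration. For `k0 = 0`,
#' `T = 0` is always a root (the zero state); for `k0 > 0`,
#' `f(0) = -k0 * k7^k6 < 0`, so the zero state disappears.
#'
#' @param T free TBP concentration (M); vectorized.
#' @param p a [tbp_parameters()] object.
#' @return Value of f (units M^(k6+1) s^-1 scale); sign changes bracket
#'   fixed points.
#' @export
#' @examples
#' p <- default_parameters(k0 = 0)
#' steady_state_function(c(0, 1e-10, 1e-9, 1e-8), p)
steady_state_function <- function(T, p) {
  if (any(T < 0)) stop("T must be >= 0")
  TD <- bound_equilibrium(T, p)
  hill <- ifelse(TD > 0, TD^p$k6, 0)
  (p$k8 * T - p$k0) * (p$k7^p$k6 + hill) - p$k5 * hill
}

# positive roots of f by log-grid sign scan + uniroot refinement.
# near-tangent pairs agreeing within merge_tol relative are collapsed to a
# single root with multiplicity 2.
scan_positive_roots <- function(p, lower = 1e-16, upper = 1e-3,
                                n_grid = 2000, merge_tol = 1e-4) {
  g <- exp(seq(log(lower), log(upper), length.out = n_grid))
  fv <- steady_state_function(g, p)
  idx <- which(fv[-1] * fv[-n_grid] < 0)
  roots <- numeric(0)
  converged <- logical(0)
  for (i in idx) {
    r <- tryCatch(
      stats::uniroot(steady_state_function, c(g[i], g[i + 1]), p = p,
                     tol = 1e-10 * g[i], maxiter = 200)$root,
      error = function(e) NA_real_)
    converged <- c(converged, !is.na(r))
    roots <- c(roots, if (is.na(r)) sqrt(g[i] * g[i + 1]) else r)
  }
  # exact zeros landing on grid points
  hit <- g[fv == 0]
  if (length(hit)) {
    roots <- c(roots, hit)
    converged <- c(converged, rep(TRUE, length(hit)))
  }
  o <- order(roots)
  roots <- roots[o]; converged <- converged[o]
  mult <- rep(1L, length(roots))
  if (length(roots) > 1) {
    keep <- rep(TRUE, length(roots))
    for (i in seq_along(roots)[-1]) {
      if (keep[i - 1] && abs(roots[i] - roots[i - 1]) <=
          merge_tol * roots[i]) {
        keep[i] <- FALSE
        mult[i - 1] <- mult[i - 1] + 1L
      }
    }
    roots <- roots[keep]; converged <- converged[keep]; mult <- mult[keep]
  }
  list(roots = roots, converged = converged, multiplicity = mult)
}

count_positive_roots <- function(p, lower = 1e-16, upper = 1e-3,
                                 n_grid = 2000) {
  g <- exp(seq(log(lower), log(upper), length.out = n_grid))
  fv <- steady_state_function(g, p)
  sum(fv[-1] * fv[-n_grid] < 0)
}

#' Locate all steady states of the model
#'
#' Finds every nonnegative root of [steady_state_function()] on a
#' log-spaced search grid (sign-change bracketing, refined to relative
#' tolerance 1e-10), completes each root to a full state via the
#' dimerization (`T2 = (k1/k2) T^2`) and binding-equilibrium relations,
#' and classifies linear stability from the reduced Jacobian. The `T = 0`
#' root is included analytically when `k0 = 0`. Near-tangent root pairs
#' (relative separation below 1e-4) are merged with multiplicity 2.
#'
#' Labels follow the field's naming: with three states they are `zero`,
#' `low` and `high` in ascending total; with two (e.g. `k6 < 1`) `zero`
#' and `high`; a single state is `high` (or `zero` if it is the origin);
#' otherwise ordinal labels `s1, s2, ...` are used.
#'
#' @param p a [tbp_parameters()] object.
#' @param lower,upper search interval for free TBP (M); the default spans
#'   every physiological regime considered by at least three decades on
#'   each side.
#' @param n_grid number of log-spaced scan points.
#' @param classify if `TRUE` (default), append stability labels and
#'   eigenvalues from [classify_stability()].
#' @return A data.frame of class `tbp_steady_states` with one row per
#'   fixed point: `label`, `T`, `T2`, `TD`, `D`, `total`, `multiplicity`,
#'   `converged`, and (when classified) `stability`, `eig1..eig3`
#'   (complex, s^-1), sorted by ascending total.
#' @export
#' @examples
#' find_steady_states(default_parameters(k0 = 0))
find_steady_states <- function(p, lower = 1e-16, upper = 1e-3,
                               n_grid = 2000, classify = TRUE) {
  validate_parameters(p)
  sc <- scan_positive_roots(p, lower, upper, n_grid)
  T <- sc$roots; converged <- sc$converged; mult <- sc$multiplicity
  if (p$k0 == 0) {  # grid cannot bracket the origin
    T <- c(0, T); converged <- c(TRUE, converged); mult <- c(1L, mult)
  }
  TD <- bound_equilibrium(T, p)
  T2 <- if (p$k2 > 0) (p$k1 / p$k2) * T^2 else rep(0, length(T))
  ss <- data.frame(
    label = ordinal_labels(T), T = T, T2 = T2, TD = TD, D = p$D0 - TD,
    total = T + 2 * T2 + TD, multiplicity = mult, converged = converged,
    stringsAsFactors = FALSE)
  ss <- ss[order(ss$total), , drop = FALSE]
  ss$label <- state_labels(ss$T, ss$total)
  rownames(ss) <- NULL
  if (classify && nrow(ss)) {
    rep_list <- lapply(seq_len(nrow(ss)), function(i)
      classify_stability(ss[i, ], p))
    ss$stability <- vapply(rep_list, `[[`, "", "classification")
    ev <- t(vapply(rep_list, function(r) {
      e <- r$eigenvalues
      length(e) <- 3L
      e
    }, complex(3)))
    ss$eig1 <- ev[, 1]; ss$eig2 <- ev[, 2]; ss$eig3 <- ev[, 3]
  }
  structure(ss, class = c("tbp_steady_states", "data.frame"),
            parameters = p)
}

ordinal_labels <- function(T) {
  if (!length(T)) return(character(0))
  paste0("s", seq_along(T))
}

state_labels <- function(T, total) {
  n <- length(T)
  if (n == 0) return(character(0))
  if (n == 3 && T[1] == 0) return(c("zero", "low", "high"))
  if (n == 2 && T[1] == 0) return(c("zero", "high"))
  if (n == 1) return(if (T[1] == 0) "zero" else "high")
  paste0("s", seq_len(n))
}

#' Extract the high-TBP state from a steady-state table
#'
#' @param ss a `tbp_steady_states` data.frame.
#' @param require_stable if `TRUE`, the state must be classified stable.
#' @return The single row with the largest total, or `NULL` if there is no
#'   positive (stable, if required) state.
#' @export
high_state <- function(ss, require_stable = FALSE) {
  pos <- ss[ss$T > 0, , drop = FALSE]
  if (require_stable && "stability" %in% names(pos))
    pos <- pos[pos$stability == "stable", , drop = FALSE]
  if (!nrow(pos)) return(NULL)
  pos[which.max(pos$total), , drop = FALSE]
}

#' @export
print.tbp_steady_states <- function(x, digits = 6, ...) {
  cat("Steady states (", nrow(x), " fixed point",
      if (nrow(x) != 1) "s", "):\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits)
  print(df, ...)
  invisible(x)
}

#' Write a steady-state table to CSV
#'
#' Complex eigenvalues are split into real and imaginary columns so the
#' file is plain text round-trippable.
#'
#' @param ss a `tbp_steady_states` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_steady_states <- function(ss, path) {
  df <- as.data.frame(ss)
  for (nm in c("eig1", "eig2", "eig3")) {
    if (nm %in% names(df)) {
      df[[paste0(nm, "_re")]] <- Re(df[[nm]])
      df[[paste0(nm, "_im")]] <- Im(df[[nm]])
      df[[nm]] <- NULL
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
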