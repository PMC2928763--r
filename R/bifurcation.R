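#' One-parameter bifurcation sweep
#'
#' Recomputes the full steady-state set at each value of one swept rate
#' constant, all others held at the baseline. Critical (fold) values are
#' detected where the count of positive fixed points changes between
#' consecutive sweep values and refined by bisection on the root count.
#'
#' @param name parameter symbol to sweep (one of k0..k8, D0).
#' @param values sweep values (positive, sorted ascending).
#' @param p baseline [tbp_parameters()].
#' @param classify append stability classification per state (default
#'   TRUE).
#' @param refine_critical refine detected fold locations by bisection
#'   (default TRUE).
#' @return A data.frame of class `tbp_branch`, one row per (sweep value,
#'   fixed point): columns `parameter`, `value`, then the steady-state
#'   columns. Detected critical values are in `attr(, "critical_values")`
#'   and the swept symbol in `attr(, "parameter")`.
#' @export
#' @examples
#' p <- default_parameters(k0 = 0)
#' br <- sweep_1d("k3", c(5e4, 2e5), p)
#' attr(br, "critical_values")
sweep_1d <- function(name, values, p, classify = TRUE,
                     refine_critical = TRUE) {
  if (!length(values)) stop("empty sweep")
  if (!(name %in% names(p))) stop("unknown parameter: ", name)
  if (any(values < 0) || is.unsorted(values))
    stop("sweep values must be nonnegative and sorted ascending")
  rows <- lapply(values, function(v) {
    q <- p; q[[name]] <- v
    ss <- as.data.frame(find_steady_states(q, classify = classify))
    if (!nrow(ss)) return(NULL)
    cbind(parameter = name, value = v, ss, stringsAsFactors = FALSE)
  })
  br <- do.call(rbind, rows)
  counts <- vapply(values, function(v) {
    q <- p; q[[name]] <- v
    count_positive_roots(q)
  }, 0L)
  crit <- numeric(0)
  if (length(values) > 1) {
    chg <- which(diff(counts) != 0)
    for (i in chg) {
      lo <- values[i]; hi <- values[i + 1]
      if (refine_critical) {
        n_lo <- counts[i]
        while ((hi - lo) > 1e-7 * hi) {
          mid <- sqrt(lo * hi)
          q <- p; q[[name]] <- mid
          if (count_positive_roots(q) == n_lo) lo <- mid else hi <- mid
        }
      }
      crit <- c(crit, sqrt(lo * hi))
    }
  }
  structure(br, class = c("tbp_branch", "data.frame"),
            parameter = name, critical_values = crit,
            root_counts = data.frame(value = values, n_positive = counts))
}

#' Two-parameter (k3, k5) region classification
#'
#' Classifies each cell of a (k3, k5) grid by the number of positive fixed
#' points of the `k0 = 0` system: `bistable` (two positive states: the
#' stable high and unstable low branch coexisting with the stable zero
#' state) or `monostable_zero` (no positive state). Other counts, should
#' they occur, are labeled `other`.
#'
#' @param k3_values,k5_values grid axes (M^-1 s^-1 and M s^-1).
#' @param p baseline [tbp_parameters()] (typically with `k0 = 0`).
#' @return A data.frame of class `tbp_region_map` with columns `k3`, `k5`,
#'   `n_positive`, `region`.
#' @export
region_map_2d <- function(k3_values, k5_values, p) {
  grid <- expand.grid(k3 = k3_values, k5 = k5_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n_positive <- vapply(seq_len(nrow(grid)), function(i) {
    q <- set_parameters(p, k3 = grid$k3[i], k5 = grid$k5[i])
    count_positive_roots(q)
  }, 0L)
  grid$region <- ifelse(grid$n_positive >= 2, "bistable",
                        ifelse(grid$n_positive == 0, "monostable_zero",
                               "other"))
  structure(grid, class = c("tbp_region_map", "data.frame"),
            parameters = p)
}

#' Relative sensitivity of the high-TBP state to one parameter
#'
#' Scales one parameter by `factor`, recomputes the steady states, and
#' reports the percent change of the high-TBP *total* concentration
#' (monomer equivalents): `100 * (total_base - total_perturbed) /
#' total_base`, positive for a reduction. If the perturbed system has no
#' positive fixed point the high state was lost through the fold and
#' `state_lost` is set instead of a percentage.
#'
#' @param name parameter symbol.
#' @param factor multiplicative perturbation (e.g. 0.5 to halve).
#' @param p baseline [tbp_parameters()]; must have a high-TBP state.
#' @return A list of class `tbp_sensitivity`: `parameter`, `factor`,
#'   `percent_change`, `state_lost`, `total_base`, `total_perturbed`.
#' @export
#' @examples
#' relative_sensitivity("k3", 0.5, default_parameters(k0 = 0))
relative_sensitivity <- function(name, factor, p) {
  if (!(name %in% names(p))) stop("unknown parameter: ", name)
  base <- high_state(find_steady_states(p, classify = FALSE))
  if (is.null(base))
    stop("baseline has no high-TBP state; sensitivity undefined")
  q <- p; q[[name]] <- p[[name]] * factor
  validate_parameters(q)
  pert <- high_state(find_steady_states(q, classify = FALSE))
  if (is.null(pert)) {
    return(structure(list(parameter = name, factor = factor,
                          percent_change = NA_real_, state_lost = TRUE,
                          total_base = base$total,
                          total_perturbed = NA_real_),
                     class = "tbp_sensitivity"))
  }
  structure(list(parameter = name, factor = factor,
                 percent_change = 100 * (base$total - pert$total) /
                   base$total,
                 state_lost = FALSE, total_base = base$total,
                 total_perturbed = pert$total),
            class = "tbp_sensitivity")
}

#' @export
print.tbp_sensitivity <- function(x, ...) {
  if (x$state_lost) {
    cat(sprintf("%s x %g: high-TBP state lost (fold crossed)\n",
                x$parameter, x$factor))
  } else {
    cat(sprintf("%s x %g: high-TBP total %s by %.3g%% (%.4g -> %.4g M)\n",
                x$parameter, x$factor,
                if (x$percent_change >= 0) "reduced" else "increased",
                abs(x$percent_change), x$total_base, x$total_perturbed))
  }
  invisible(x)
}
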