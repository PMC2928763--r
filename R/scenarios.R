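#' Reference (mammalian) parameter set
#'
#' The default kinetic constants: dimerization and DNA-binding rates from
#' in vitro TBP measurements, degradation from reported TBP half-life,
#' site concentration for ~25000 binding sites in a mammalian nucleus,
#' half-saturation at half the site concentration, Hill coefficient 2,
#' and basal synthesis at 1% of the maximal regulated rate.
#'
#' @param ... overrides passed to [set_parameters()], e.g. `k0 = 0` for
#'   the no-basal-synthesis analyses.
#' @return A [tbp_parameters()] object.
#' @export
#' @examples
#' default_parameters()          # full reference set
#' default_parameters(k0 = 0)    # bistable baseline
default_parameters <- function(...) {
  p <- tbp_parameters(k0 = 5e-15, k1 = 1e5, k2 = 1e-3, k3 = 2e5,
                      k4 = 4e-4, k5 = 5e-13, k6 = 2, k7 = 1.25e-8,
                      k8 = 7.4e-5, D0 = 2.5e-8)
  if (length(list(...))) p <- set_parameters(p, ...)
  p
}

#' Convert molecule counts to molar concentration
#'
#' `N / (N_A * V)` with Avogadro's number `6.02214076e23`.
#'
#' @param n molecule count.
#' @param volume_l compartment volume (litres).
#' @return Concentration (M).
#' @export
#' @examples
#' molecules_to_molar(3000, 4.17e-15)  # ~3000 sites in a yeast cell
molecules_to_molar <- function(n, volume_l) {
  n / (6.02214076e23 * volume_l)
}

#' @rdname molecules_to_molar
#' @param conc concentration (M).
#' @export
molar_to_molecules <- function(conc, volume_l) {
  conc * 6.02214076e23 * volume_l
}

#' Named physiological presets
#'
#' `mammalian`: the reference parameter set (~25000 TBP molecules and
#' ~25000 binding sites in a ~1.7 pL nucleus, i.e. `D0 = 2.5e-8` M).
#' `yeast`: site concentration recomputed from ~3000 expressed genes in a
#' 4.17e-15 L cell (1 um radius); `k7` kept at half of `D0` and `k5`
#' scaled proportionally to `D0` so the dimensionless synthesis strength
#' `K5` matches the reference set, which keeps the system in the bistable
#' regime. `k0` is held at 1% of `k5`. The rescaling is recorded in the
#' scenario notes.
#'
#' @param name `"mammalian"` or `"yeast"`.
#' @return A list of class `tbp_scenario`: `id`, `label`, `parameters`,
#'   `tbp_scale` (intended high-state total scale, M), `notes`.
#' @export
#' @examples
#' scenario_preset("yeast")$parameters$D0
scenario_preset <- function(name = c("mammalian", "yeast")) {
  name <- match.arg(name)
  if (name == "mammalian") {
    p <- default_parameters()
    notes <- "reference set: ~25000 molecules / ~25000 sites"
  } else {
    D0 <- molecules_to_molar(3000, 4.17e-15)
    ref <- default_parameters()
    K5_ref <- nondimensionalize(ref)$K5
    k5 <- K5_ref * ref$k8 * D0
    p <- set_parameters(ref, D0 = D0, k7 = D0 / 2, k5 = k5,
                        k0 = 0.01 * k5)
    notes <- paste("D0 from 3000 sites in 4.17e-15 L;",
                   "k5, k7 rescaled with D0 to hold K5, K7 at the",
                   "reference values (bistable regime)")
  }
  hs <- high_state(find_steady_states(set_parameters(p, k0 = 0)))
  structure(list(id = name, label = paste0(name, "-like"),
                 parameters = p,
                 tbp_scale = if (is.null(hs)) NA_real_ else hs$total,
                 notes = notes),
            class = "tbp_scenario")
}

#' Factorial grid of physiological scenarios
#'
#' Stand-in generator for the range of cellular conditions the dimer
#' buffering question spans: site concentrations `D0` across
#' `[1e-9, 1e-5]` M, half-saturation `k7` across `[1e-2, 1e2] * D0`, and
#' synthesis rate `k5` from just above the fold (`1.1 * k5_c` at that
#' `(k7, D0)`) up to `1e3 * k5_c`, all log-spaced. `k0 = 0` (the
#' bistable setting) and every other constant is held at the reference
#' values. Along each axis a count of 1 collapses to the reference value,
#' so `generate_grid(1, 1, 1)` is exactly the reference set.
#'
#' Each scenario is completed with its computed high state; scenarios
#' whose stable high-state total lies inside the physiological TBP window
#' `[1e-8, 1e-5]` M are labeled `physiological`, all others `extreme`.
#' The construction is fully deterministic; `seed` is recorded in the
#' output attributes so grid provenance is explicit in downstream files.
#'
#' @param n_k5,n_k7,n_D0 points per axis (>= 1).
#' @param seed integer recorded with the grid.
#' @param D0_range,k7_factor_range,k5_factor_range axis ranges (see
#'   above); `k5_factor_range` multiplies the per-cell closed-form
#'   `k5_c`.
#' @return A data.frame of class `tbp_scenario_grid`, one row per
#'   scenario: `id`, `label`, the ten parameters, `T_high`, `total_high`,
#'   `dimer_to_bound_ratio`, `stable_high`.
#' @export
#' @examples
#' g <- generate_grid(2, 2, 2, seed = 1)
#' table(g$label)
generate_grid <- function(n_k5 = 3, n_k7 = 3, n_D0 = 3, seed = 1L,
                          D0_range = c(1e-9, 1e-5),
                          k7_factor_range = c(1e-2, 1e2),
                          k5_factor_range = c(1.1, 1e3)) {
  if (min(n_k5, n_k7, n_D0) < 1) stop("axis counts must be >= 1")
  ref <- default_parameters(k0 = 0)
  axis <- function(n, range, collapse) {
    if (n == 1) collapse else exp(seq(log(range[1]), log(range[2]),
                                      length.out = n))
  }
  D0s <- axis(n_D0, D0_range, ref$D0)
  k7f <- axis(n_k7, k7_factor_range, ref$k7 / ref$D0)
  k5f <- axis(n_k5, k5_factor_range, NA)
  rows <- list()
  id <- 0L
  for (D0 in D0s) for (f7 in k7f) {
    base <- set_parameters(ref, D0 = D0, k7 = f7 * D0)
    k5c <- critical_k5(base)$value
    k5s <- if (n_k5 == 1) ref$k5 * D0 / ref$D0 else k5f * k5c
    for (k5 in k5s) {
      id <- id + 1L
      q <- set_parameters(base, k5 = k5)
      ss <- find_steady_states(q)
      hs <- high_state(ss, require_stable = TRUE)
      rows[[id]] <- data.frame(
        id = sprintf("s%03d", id),
        label = if (!is.null(hs) && hs$total >= 1e-8 &&
                    hs$total <= 1e-5) "physiological" else "extreme",
        as.data.frame(q),
        T_high = if (is.null(hs)) NA_real_ else hs$T,
        total_high = if (is.null(hs)) NA_real_ else hs$total,
        dimer_to_bound_ratio =
          if (is.null(hs)) NA_real_ else hs$T2 / hs$TD,
        stable_high = !is.null(hs),
        stringsAsFactors = FALSE)
    }
  }
  g <- do.call(rbind, rows)
  rownames(g) <- NULL
  structure(g, class = c("tbp_scenario_grid", "data.frame"),
            seed = as.integer(seed))
}

#' Extract the parameter set of one grid scenario
#'
#' @param grid a `tbp_scenario_grid` data.frame.
#' @param i row index or scenario `id` string.
#' @return A [tbp_parameters()] object.
#' @export
scenario_parameters <- function(grid, i) {
  if (is.character(i)) i <- match(i, grid$id)
  if (is.na(i) || i < 1 || i > nrow(grid)) stop("no such scenario")
  r <- grid[i, ]
  tbp_parameters(k0 = r$k0, k1 = r$k1, k2 = r$k2, k3 = r$k3, k4 = r$k4,
                 k5 = r$k5, k6 = r$k6, k7 = r$k7, k8 = r$k8, D0 = r$D0)
}
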