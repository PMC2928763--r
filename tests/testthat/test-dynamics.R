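test_that("integration conserves sites and respects fixed points", {
  p <- ref_params(k0 = 0)
  # the origin is a fixed point of the basal-free system
  tr0 <- integrate_tbp(p, c(T = 0, T2 = 0, TD = 0), t_end = 10 / p$k8)
  expect_lt(max(abs(tr0$T), abs(tr0$T2), abs(tr0$TD)), 1e-15 * p$D0)
  # generic trajectory: site conservation within solver tolerance
  tr <- integrate_tbp(p, c(T = 1e-8, T2 = 1e-9, TD = 0),
                      t_end = 50 / p$k8)
  expect_lt(max(abs(tr$D + tr$TD - p$D0)), 1e-6 * p$D0)
  # a nudge off the high state relaxes back onto it
  hs <- high_state(find_steady_states(p))
  tr2 <- integrate_tbp(p, c(T = hs$T * 1.05, T2 = hs$T2, TD = hs$TD),
                       t_end = 100 / p$k8)
  fin <- tr2[nrow(tr2), ]
  expect_rel(total_tbp(fin), hs$total, 1e-4)
  expect_error(integrate_tbp(p, c(T = 0, T2 = 0, TD = 0), t_end = -1),
               "t_end")
})

test_that("tolerance refinement leaves the terminal state unchanged", {
  p <- ref_params(k0 = 0)
  s0 <- c(T = 1e-8, T2 = 0, TD = 0)
  t_end <- 20 / p$k8
  a <- integrate_tbp(p, s0, t_end = t_end, rtol = 1e-8)
  b <- integrate_tbp(p, s0, t_end = t_end, rtol = 5e-9)
  fa <- unlist(a[nrow(a), c("T", "T2", "TD")])
  fb <- unlist(b[nrow(b), c("T", "T2", "TD")])
  expect_lt(max(abs(fa - fb) / fb), 10 * 1e-8)
})

test_that("phase plane splits initial totals between the two attractors", {
  p <- ref_params(k0 = 0)
  pp <- phase_plane(p, list(c(T = 1e-11, T2 = 0, TD = 0),
                            c(T = 5e-10, T2 = 0, TD = 0),
                            c(T = 1e-7, T2 = 0, TD = 0)))
  expect_identical(pp$attractor[1], "zero")   # below ~0.1 nM
  expect_identical(pp$attractor[3], "high")
  expect_true(all(pp$attractor %in% c("zero", "high")))
  br <- pp$separatrix_bracket
  expect_lt(br[["lower"]], br[["upper"]])
  # starting exactly on the unstable low state: stays put for >= 1/k8
  ls <- find_steady_states(p)[2, ]
  tr <- integrate_tbp(p, c(T = ls$T, T2 = ls$T2, TD = ls$TD),
                      t_end = 1 / p$k8)
  expect_rel(tr$T[nrow(tr)], ls$T, 1e-3)
})

test_that("late-time trajectories sit on the binding pseudo-equilibrium", {
  p <- ref_params(k0 = 0)
  # start far off the slow manifold (everything unbound)
  tr <- integrate_tbp(p, c(T = 1e-8, T2 = 0, TD = 0),
                      t_end = 20 / p$k8, n_times = 2000)
  sm <- slow_manifold_ratio(tr)
  expect_rel(sm$expected, 2e-9, 1e-12)        # k4/k3 from the constants
  expect_rel(sm$median_ratio, sm$expected, 0.05)
  expect_true(all(sm$time > 10 / p$k4))       # fast transient excluded
  # doubling the association rate halves the equilibrium ratio
  p2 <- set_parameters(p, k3 = 2 * p$k3)
  tr2 <- integrate_tbp(p2, c(T = 1e-8, T2 = 0, TD = 0),
                       t_end = 20 / p2$k8, n_times = 2000)
  sm2 <- slow_manifold_ratio(tr2)
  expect_rel(sm2$median_ratio, sm$expected / 2, 0.05)
  expect_error(slow_manifold_ratio(tr[tr$time < 1, ], p), "late-time")
})

test_that("response time measures sustained recovery of free TBP", {
  p <- ref_params(k0 = 0)
  expect_identical(response_time(p, perturbation = 0), 0)
  rt <- response_time(p)
  expect_gt(rt, 0)
  # monotone in the recovery threshold
  expect_lt(response_time(p, recovery = 0.9), rt)
  # stable under tolerance refinement
  expect_rel(response_time(p, rtol = 1e-9), rt, 1e-3)
  expect_error(response_time(ref_params(k0 = 0, k3 = 5e4)), "high-TBP")
})

test_that("dimer-free comparison isolates the buffering effect", {
  p <- ref_params(k0 = 0)
  # without any dimerization the two systems are the same
  cmp0 <- compare_dimer_effect(set_parameters(p, k1 = 0))
  expect_identical(cmp0$ratio, 1)
  expect_identical(cmp0$dimer_to_bound_ratio, 0)
  # mammalian-like reference: dimer pool small, recovery nearly identical
  cmp_m <- compare_dimer_effect(p)
  expect_gt(cmp_m$ratio, 0.8); expect_lt(cmp_m$ratio, 1.25)
  # yeast-like conditions: large dimer pool, much faster with dimer
  py <- scenario_preset("yeast")$parameters
  cmp_y <- compare_dimer_effect(set_parameters(py, k0 = 0))
  expect_gt(cmp_y$dimer_to_bound_ratio, cmp_m$dimer_to_bound_ratio)
  expect_lt(cmp_y$ratio, 0.5)
  # free/bound steady states agree between variants; totals differ by
  # exactly the dimer pool
  ss_w <- find_steady_states(p, classify = FALSE)
  ss_wo <- find_steady_states(set_parameters(p, k1 = 0),
                              classify = FALSE)
  expect_rel(ss_w$T, ss_wo$T, 1e-9)
  expect_rel(ss_w$TD, ss_wo$TD, 1e-9)
  expect_rel(ss_w$total - ss_wo$total, 2 * (p$k1 / p$k2) * ss_w$T^2,
             1e-6)
  # both variants must have a stable high state
  expect_error(compare_dimer_effect(ref_params(k0 = 0, k3 = 5e4)),
               "high-TBP state")
})
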