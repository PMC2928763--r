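test_that("synthesis rate follows the Hill form with basal offset", {
  p <- ref_params()
  # no production at zero occupancy without basal rate
  expect_identical(synthesis_rate(0, set_parameters(p, k0 = 0)), 0)
  expect_rel(synthesis_rate(0, p), p$k0, 1e-12)
  # half-saturation: bound TBP at k7 gives k0 + k5/2
  expect_rel(synthesis_rate(p$k7, set_parameters(p, k0 = 0)),
             p$k5 / 2, 1e-12)
  # frozen hand evaluation at TD = 1.7e-8 M with the reference constants:
  # 5e-15 + 5e-13 * (1.7e-8)^2 / ((1.25e-8)^2 + (1.7e-8)^2)
  expect_rel(synthesis_rate(1.7e-8, p), 3.29536777e-13, 1e-8)
  # monotone nondecreasing and bounded by k0 + k5
  TD <- exp(seq(log(1e-12), log(1e-5), length.out = 200))
  r <- synthesis_rate(TD, p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= p$k0 + p$k5))
  expect_error(synthesis_rate(-1e-9, p), "TD")
})

test_that("mass balances: fixed origin, site conservation, bookkeeping", {
  p <- ref_params(k0 = 0)
  s0 <- system_state(T = 0, T2 = 0, TD = 0, D0 = p$D0)
  expect_equal(unname(tbp_rhs(s0, p)), rep(0, 4))
  set.seed(11)
  for (i in 1:25) {
    q <- rand_params(k0_mode = sample(c("zero", "basal"), 1))
    s <- rand_state(q)
    d <- tbp_rhs(s, q)
    # free and bound site equations are exact negatives
    expect_identical(d[["D"]], -d[["TD"]])
    # d(total TBP)/dt collapses to synthesis - degradation: the
    # dimerization and binding fluxes cancel in monomer equivalents
    lhs <- d[["T"]] + 2 * d[["T2"]] + d[["TD"]]
    rhs <- synthesis_rate(s[["TD"]], q) - q$k8 * s[["T"]]
    # the binding and dimerization fluxes cancel exactly; the residual
    # must be at rounding level relative to the largest cancelling flux
    flux <- max(abs(c(q$k3 * s[["T"]] * s[["D"]], q$k4 * s[["TD"]],
                      q$k1 * s[["T"]]^2, q$k2 * s[["T2"]],
                      q$k8 * s[["T"]])))
    expect_lt(abs(lhs - rhs), 1e-12 * flux)
    # reduced system agrees with the full one on the manifold
    expect_equal(unname(tbp_rhs_reduced(s[c("T", "T2", "TD")], q)),
                 unname(d[c("T", "T2", "TD")]))
  }
  expect_error(tbp_rhs(c(T = -1e-9, T2 = 0, TD = 0, D = p$D0), p),
               ">= 0")
})

test_that("dimensionless groups use D0 and 1/k8 as references", {
  p <- ref_params()
  d <- nondimensionalize(p)
  expect_equal(d$K7, 0.5)       # k7 is half of D0
  expect_equal(d$K, 0.08)       # k4/(k3*D0)
  expect_equal(nondimensionalize(set_parameters(p, k7 = p$D0))$K7, 1)
  set.seed(21)
  for (i in 1:20) {
    q <- rand_params()
    back <- dimensionalize(nondimensionalize(q))
    for (nm in names(q))
      expect_rel(back[[nm]], q[[nm]], 1e-12, info = nm)
  }
})

test_that("dimensionless trajectories rescale onto dimensional ones", {
  p <- ref_params(k0 = 0)
  # the nondimensional reduced system is the same model with unit scales
  p_nd <- dimensionalize(nondimensionalize(p), D0 = 1, k8 = 1)
  s0 <- c(T = 1e-8, T2 = 1e-9, TD = 5e-9)
  t_end <- 5 / p$k8
  times <- seq(0, t_end, length.out = 50)
  tr <- integrate_tbp(p, s0, t_end = t_end, times = times)
  tr_nd <- integrate_tbp(p_nd, s0 / p$D0, t_end = t_end * p$k8,
                         times = times * p$k8)
  for (nm in c("T", "T2", "TD", "D"))
    expect_lt(max(abs(tr_nd[[nm]] - tr[[nm]] / p$D0)), 1e-5)
})

test_that("total TBP counts each dimer as two monomer equivalents", {
  expect_identical(total_tbp(c(T = 0, T2 = 0, TD = 0)), 0)
  expect_rel(total_tbp(c(T = 1e-9, T2 = 1e-9, TD = 1e-9)), 4e-9, 1e-12)
  # the convention is validated by the reference high-TBP state (~2.55e-8)
  hs <- high_state(find_steady_states(ref_params(k0 = 0), classify = FALSE))
  expect_rel(hs$total, 2.55e-8, 0.01)
})

test_that("state constructor enforces invariants", {
  expect_error(system_state(T = -1, T2 = 0, TD = 0, D0 = 1e-8), ">= 0")
  expect_error(system_state(T = 0, T2 = 0, TD = 2e-8, D = 2e-8,
                            D0 = 2.5e-8), "conservation")
  s <- system_state(T = 1e-9, T2 = 0, TD = 1e-8, D0 = 2.5e-8)
  expect_rel(s[["D"]], 1.5e-8, 1e-12)
})

test_that("parameter objects validate, update and round-trip to JSON", {
  expect_error(default_parameters(k6 = 0), "k6")
  expect_error(default_parameters(k8 = -1), ">= 0")
  expect_error(set_parameters(default_parameters(), bogus = 1), "unknown")
  p <- default_parameters(k0 = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, path)
  expect_equal(read_parameters(path), p)
})
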