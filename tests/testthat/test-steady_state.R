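test_that("scalar fixed-point function behaves at the origin and brackets roots", {
  p <- ref_params(k0 = 0)
  expect_identical(steady_state_function(0, p), 0)
  pb <- ref_params()  # k0 > 0
  expect_rel(steady_state_function(0, pb), -pb$k0 * pb$k7^2, 1e-10)
  expect_lt(steady_state_function(0, pb), 0)
  # with the reference constants and no basal rate, f changes sign
  # exactly twice on (0, 1e-6): the low and high branches
  g <- exp(seq(log(1e-12), log(1e-6), length.out = 4000))
  fv <- steady_state_function(g, p)
  expect_identical(sum(fv[-1] * fv[-length(fv)] < 0), 2L)
  expect_error(steady_state_function(-1e-9, p), ">= 0")
})

test_that("reference steady states: zero, low and high fixed points", {
  p <- ref_params(k0 = 0)
  ss <- find_steady_states(p)
  expect_identical(nrow(ss), 3L)
  expect_identical(ss$label, c("zero", "low", "high"))
  # frozen from an exact rational-arithmetic polynomial solve of f = 0
  expect_rel(ss$T, c(0, 1.808074e-10, 4.424598e-9), 1e-5)
  expect_rel(ss$total, c(0, 2.260057e-9, 2.555742e-8), 1e-5)
  # every record satisfies the dimer and binding-equilibrium relations
  expect_rel(ss$T2, (p$k1 / p$k2) * ss$T^2, 1e-12)
  expect_rel(ss$TD, ss$T * p$D0 / (p$k4 / p$k3 + ss$T), 1e-12)
  expect_rel(ss$D + ss$TD, rep(p$D0, 3), 1e-12)
  expect_true(all(abs(steady_state_function(ss$T, p)) <=
                    1e-6 * abs(steady_state_function(2e-9, p))))
})

test_that("basal synthesis leaves a single state near the high branch", {
  ss <- find_steady_states(ref_params())  # k0 = 5e-15
  expect_identical(nrow(ss), 1L)
  expect_identical(ss$label, "high")
  hs0 <- high_state(find_steady_states(ref_params(k0 = 0)))
  # basal synthesis at 1% of k5 lifts the state slightly above the
  # k0 = 0 high branch; "nearly identical" here means within 2%
  expect_rel(ss$total, hs0$total, 0.02)
})

test_that("weak DNA binding leaves only the zero state", {
  ss <- find_steady_states(ref_params(k0 = 0, k3 = 5e4))
  expect_identical(nrow(ss), 1L)
  expect_identical(ss$label, "zero")
})

test_that("dense sign-scan oracle finds no root the solver misses", {
  set.seed(101)
  for (i in 1:30) {
    q <- rand_params(k0_mode = sample(c("zero", "basal"), 1))
    br <- oracle_sign_brackets(q, n = 2e4)
    roots <- find_steady_states(q, classify = FALSE)
    pos <- roots$T[roots$T > 0]
    if (nrow(br)) {
      for (j in seq_len(nrow(br)))
        expect_true(any(pos >= br[j, "lo"] * 0.999 &
                          pos <= br[j, "hi"] * 1.001),
                    info = sprintf("draw %d bracket %d", i, j))
    }
  }
})

test_that("dimerization constants do not shift the fixed-point structure", {
  p <- ref_params(k0 = 0)
  ss0 <- find_steady_states(p, classify = FALSE)
  set.seed(31)
  for (k1 in c(0, 1e3, 1e7)) {
    q <- set_parameters(p, k1 = k1, k2 = rlog(1, 1e-4, 1e-2))
    ss <- find_steady_states(q, classify = FALSE)
    expect_rel(ss$T, ss0$T, 1e-9)
    expect_rel(ss$TD, ss0$TD, 1e-9)
    # totals differ exactly by the dimer pool, 2*(k1/k2)*T^2
    expect_rel(ss$total - ss0$total,
               2 * (q$k1 / q$k2 - p$k1 / p$k2) * ss0$T^2, 1e-6)
  }
})

test_that("closed-form criticals match printed values, scans and tangency", {
  p <- ref_params(k0 = 0)
  k3c <- critical_k3(p)
  k5c <- critical_k5(p)
  expect_identical(k3c$method, "closed_form")
  # printed closed-form evaluations: 9.58e4 M^-1 s^-1 and 2.39e-13 M/s
  expect_rel(k3c$value, 9.58e4, 0.01)
  expect_rel(k5c$value, 2.39e-13, 0.01)
  # numeric root-count bisection lands on the same folds
  expect_rel(critical_k3(p, method = "numeric_scan")$value, k3c$value,
             1e-4)
  expect_rel(critical_k5(p, method = "numeric_scan")$value, k5c$value,
             1e-4)
  # independent tangency oracle across random bistable baselines
  set.seed(41)
  n_ok <- 0
  for (i in 1:50) {
    q <- rand_params(k5_rel_range = c(2, 50))
    expect_rel(critical_k5(q)$value, oracle_k5c_tangency(q), 5e-3,
               info = paste("draw", i))
    expect_rel(critical_k3(q)$value, oracle_k3c_tangency(q), 5e-3,
               info = paste("draw", i))
  }
  expect_error(critical_k3(set_parameters(p, k5 = 0)), "k5")
})

test_that("branches coalesce at the fold", {
  p <- ref_params(k0 = 0)
  k3c <- critical_k3(p)$value
  # a hair above the fold the two branches are barely separated; a fine
  # scan grid is needed to resolve them before they are compared
  ss <- find_steady_states(set_parameters(p, k3 = k3c * (1 + 1e-8)),
                           classify = FALSE, n_grid = 4e5)
  pos <- ss[ss$T > 0, ]
  # just above the critical value the low and high branches are equal to
  # within 0.1% (or already merged as one double root)
  if (nrow(pos) == 2) {
    expect_lt(abs(pos$total[2] - pos$total[1]) / pos$total[2], 1e-3)
  } else {
    expect_identical(nrow(pos), 1L)
    expect_identical(pos$multiplicity, 2L)
  }
})

test_that("critical k0 is located by bisection and stable to refinement", {
  p <- ref_params()
  c0 <- critical_k0(p)
  expect_identical(c0$ratio_to_k5, c0$value / p$k5)
  # default basal rate (1% of k5) exceeds the fold: monostable
  expect_gt(p$k0, c0$value)
  expect_identical(nrow(find_steady_states(p)), 1L)
  # just below the fold the system regains three states
  expect_identical(
    nrow(find_steady_states(set_parameters(p, k0 = c0$value * 0.95))), 3L)
  # self-consistency under 2x scan refinement
  c2 <- critical_k0(p, n_grid_k0 = 40000)
  expect_rel(c2$value, c0$value, 1e-3)
  # no fold when the system is monostable-zero at k0 = 0
  expect_true(is.na(critical_k0(set_parameters(p, k3 = 5e4))$value))
})

test_that("tabulated multiplicity conditions match computed root counts", {
  p <- ref_params(k0 = 0)
  d <- nondimensionalize(p)
  expect_identical(predicted_multiplicity(d)$count, 3L)
  # cooperative case with basal rate above the fold: single state
  expect_identical(
    predicted_multiplicity(nondimensionalize(ref_params()))$count, 1L)
  # non-cooperative case: two states when synthesis beats the threshold
  d1 <- nondimensionalize(set_parameters(p, k6 = 1))
  pred1 <- predicted_multiplicity(d1)
  expect_identical(pred1$count,
                   nrow(find_steady_states(set_parameters(p, k6 = 1),
                                           classify = FALSE)))
  expect_error(predicted_multiplicity(
    nondimensionalize(set_parameters(p, k6 = 3))), "k6")
  # heuristic flag for the k6 = 1, k0 > 0 condition
  ph <- set_parameters(ref_params(), k6 = 1)
  pr <- predicted_multiplicity(nondimensionalize(ph))
  expect_true(pr$heuristic)
})
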