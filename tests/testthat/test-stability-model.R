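test_that("per-step CoM drift follows the pendulum closed form", {
  expect_equal(delta_com(0, 0.81), 0)
  # frozen value checked against an independent scipy/math evaluation
  expect_equal(delta_com(0.88, 0.81, 9.81), 0.2528661, tolerance = 1e-6)
  # linear in v
  expect_equal(delta_com(1.76, 0.81), 2 * delta_com(0.88, 0.81))
  # identical to v / omega0 with omega0 = sqrt(g/l), to machine precision
  v <- c(0.3, 0.88, 1.4); l <- c(0.6, 0.81, 1.0)
  expect_equal(delta_com(v, l), v / sqrt(9.81 / l), tolerance = 1e-15)
  expect_error(delta_com(1, -1), "positive")
  expect_error(delta_com(1, 1, 0), "positive")
})

test_that("lower step-depth bound matches direct arithmetic and grows with N", {
  expect_equal(sdp_lower_bound(0.08, 0.11, 0, 1), 0.19)
  expect_equal(sdp_lower_bound(0.08, 0.11, 0.2528661, 12), 0.2476273,
               tolerance = 1e-6)
  # when the drift exceeds pfc + eta, longer flights need deeper treads
  b <- sdp_lower_bound(0.08, 0.11, 0.2528661, 2:20)
  expect_true(all(diff(b) > 0))
  # and conversely shrink when drift is small
  b2 <- sdp_lower_bound(0.08, 0.11, 0.05, 2:20)
  expect_true(all(diff(b2) < 0))
  expect_error(sdp_lower_bound(0.08, 0.11, 0.25, 0), ">= 1")
})

test_that("upper step-depth bound matches direct arithmetic and shrinks with N", {
  expect_equal(sdp_upper_bound(0.08, 0.224, 0.2528661, 12), 0.3034903,
               tolerance = 1e-6)
  expect_equal(sdp_upper_bound(0.08, 0.224, 0, 2), 0.304)
  b <- sdp_upper_bound(0.08, 0.224, 0.2528661, 2:20)
  expect_true(all(diff(b) < 0))
  expect_error(sdp_upper_bound(0.08, 0.224, 0.25, 1), ">= 2")
})

test_that("design range composes both bounds at the reference means", {
  r <- sdp_range(ref_params(), N = 12)
  expect_equal(unname(r), c(0.2476273, 0.3034903), tolerance = 1e-6)
  r0 <- sdp_range(model_params(v = 0), N = 2)
  expect_equal(unname(r0), c(0.095, 0.304))
  # feasibility holds across random plausible parameters
  tup <- random_tuples(200, seed = 7)
  for (i in seq_len(nrow(tup))) {
    p <- model_params(v = tup$v[i], l = tup$l[i], L = tup$L[i],
                      eta = tup$eta[i], pfc = tup$pfc[i])
    r <- sdp_range(p, N = tup$N[i] + (tup$N[i] < 2))
    expect_lt(r[["lower"]], r[["upper"]])
  }
})

test_that("step-by-step simulation agrees with the closed-form bounds", {
  p <- ref_params()
  sc_safe <- staircase_spec(0.15, 0.28, 1.36, 12)
  sim <- simulate_descent(p, sc_safe)
  expect_false(any(sim$risky))
  expect_false(any(sim$over_reach))
  # depth below the 12-step lower bound must trip at least one risk flag
  sc_bad <- staircase_spec(0.15, 0.24, 1.36, 12)
  expect_true(any(simulate_descent(p, sc_bad)$risky))
  # stationary pendulum never drifts past the edge when d > pfc + eta
  sim0 <- simulate_descent(model_params(v = 0), staircase_spec(0.15, 0.20, 1, 12))
  expect_false(any(sim0$risky))
  # margin column is consistent with the flags
  expect_true(all((sim$margin < 0) == sim$risky))
})

test_that("dimensional sanity: lengths scale together", {
  # scaling lengths by c and speed by sqrt(c) scales both bounds by c
  c_ <- 1.7
  p1 <- ref_params()
  p2 <- model_params(v = p1$v * sqrt(c_), l = p1$l * c_, L = p1$L * c_,
                     eta = p1$eta * c_, pfc = p1$pfc * c_)
  expect_equal(unname(sdp_range(p2, 10)), c_ * unname(sdp_range(p1, 10)),
               tolerance = 1e-12)
})

test_that("staircase audit gives per-N verdicts and an overall range", {
  a <- audit_staircase(chengguan(), ref_params(), N_range = 7:12)
  expect_true(a$safe)
  expect_true(all(a$per_N$safe))
  expect_true(a$d_low < 0.28 && 0.28 < a$d_high)
  # a 0.10 m going violates the lower bound everywhere
  shallow <- staircase_spec(0.15, 0.10, 1.36, 12)
  a2 <- audit_staircase(shallow, ref_params(), N_range = 7:12)
  expect_false(a2$safe)
  expect_true(all(a2$per_N$violation == "below lower bound"))
  # degenerate single-N audit reduces to sdp_range
  a3 <- audit_staircase(chengguan(), ref_params(), N_range = 2)
  expect_equal(c(a3$d_low, a3$d_high), unname(sdp_range(ref_params(), 2)))
  expect_error(audit_staircase(chengguan(), ref_params(), N_range = integer(0)),
               "non-empty")
  expect_error(audit_staircase(chengguan(), ref_params(), N_range = 13),
               "n_steps")
})

test_that("staircase geometry validates and computes inclination", {
  sc <- staircase_spec(0.15, 0.30, 1.6, 12, name = "Gugua")
  expect_equal(sc$incline, atan(0.5) * 180 / pi)
  expect_error(staircase_spec(0.15, 0.30, 1.6, 12, incline = 30),
               "inconsistent")
  expect_error(staircase_spec(-0.1, 0.3, 1, 12), "positive")
  expect_error(staircase_spec(0.15, 0.3, 1, 1), ">= 2")
  # tabular round trip preserves the geometry
  df <- staircases_to_df(experiment_staircases())
  back <- staircases_from_df(df)
  expect_equal(staircases_to_df(back), df)
})

test_that("model parameter validation rejects impossible bodies", {
  expect_error(model_params(v = -1), "non-negative")
  expect_error(model_params(eta = 0.3, L = 0.224), "\\[0, L\\]")
  expect_error(model_params(l = 0), "positive")
})
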