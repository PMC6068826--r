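test_that("t-intervals reproduce the cohort parameter table at 3 decimals", {
  expect_equal(round(unname(t_interval(0.08, 0.02, 72)), 3), c(0.075, 0.085))
  expect_equal(round(unname(t_interval(0.11, 0.01, 72)), 3), c(0.108, 0.112))
  expect_equal(round(unname(t_interval(0.81, 0.09, 72)), 3), c(0.789, 0.831))
  # degenerate SD gives a zero-width interval
  expect_equal(unname(t_interval(5, 0, 10)), c(5, 5))
  expect_error(t_interval(1, 0.1, 1), ">= 2")
  expect_error(t_interval(1, -0.1, 10), ">= 0")
})

test_that("the parameter table computes CIs and carries N as a fixed range", {
  pt <- parameter_table(reference_estimates(), alpha = 0.05, N_range = 7:12)
  eta <- pt[pt$name == "eta", ]
  expect_equal(round(c(eta$ci_low, eta$ci_high), 3), c(0.108, 0.112))
  v <- pt[pt$name == "v", ]
  # recomputed speed interval (the printed one does not follow from the formula)
  expect_equal(round(c(v$ci_low, v$ci_high), 3), c(0.861, 0.899))
  printed_v <- table5_printed()
  expect_gt(abs(v$ci_low - printed_v$ci_low[printed_v$name == "v"]), 0.1)
  N <- pt[pt$name == "N", ]
  expect_equal(c(N$ci_low, N$ci_high), c(7, 12))
  expect_error(parameter_table(reference_estimates()[-1, ]), "missing required")
})

test_that("interval width grows monotonically as alpha shrinks", {
  alphas <- c(0.5, 0.2, 0.1, 0.05, 0.01, 0.001)
  widths <- vapply(alphas, function(a) diff(t_interval(0.88, 0.08, 72, a)), 0)
  expect_true(all(diff(widths) > 0))
})

test_that("degenerate sweeps collapse the combined range onto the point design", {
  est <- reference_estimates()
  est$sd <- 0
  dr <- combine_subranges(parameter_table(est, N_range = 12), N_range = 12)
  point <- sdp_range(ref_params(), 12)
  expect_equal(dr$d_low, point[["lower"]])
  expect_equal(dr$d_high, point[["upper"]])
})

test_that("widening any confidence interval only tightens the design range", {
  # more parameter uncertainty must never relax the safety envelope: the
  # wider-CI design range is always contained in the narrower-CI one
  base <- combine_subranges(parameter_table(reference_estimates()))
  set.seed(31)
  for (rep in 1:20) {
    est <- reference_estimates()
    k <- sample(which(est$name != "L"), 1)
    est$sd[k] <- est$sd[k] * runif(1, 1, 3)
    wider <- combine_subranges(parameter_table(est))
    expect_gte(wider$d_low, base$d_low - 1e-12)
    expect_lte(wider$d_high, base$d_high + 1e-12)
  }
})

test_that("the combined range is contained in the most permissive point range", {
  dr <- combine_subranges(parameter_table(reference_estimates()))
  lo_permissive <- min(vapply(7:12, function(N) sdp_range(ref_params(), N)[[1]], 0))
  hi_permissive <- max(vapply(7:12, function(N) sdp_range(ref_params(), N)[[2]], 0))
  expect_gte(dr$d_low, lo_permissive)
  expect_lte(dr$d_high, hi_permissive)
})

test_that("factorial sweeps are at least as conservative as one-at-a-time", {
  pt <- parameter_table(reference_estimates())
  oat <- combine_subranges(pt)
  fact <- combine_subranges(pt, sweep = "factorial")
  expect_gte(fact$d_low, oat$d_low)
  expect_lte(fact$d_high, oat$d_high)
})
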