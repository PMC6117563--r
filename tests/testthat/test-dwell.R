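test_that("resolution imposition follows the concatenation rule", {
  dt <- dead_times(50e-6)
  ## O 1 ms, unresolvable S 20 us, O 2 ms -> single opening of 3.02 ms
  dw <- dwell_sequence(c(1e-3, 2e-5, 2e-3), c("open", "shut", "open"))
  out <- impose_resolution(dw, dt)
  expect_equal(nrow(out), 1L)
  expect_equal(out$class, "open")
  expect_equal(out$duration, 3.02e-3, tolerance = 1e-12)
})

test_that("resolution imposition is idempotent and conserves total duration", {
  m <- build_tetramer(table3_rates("desens", "composite"))
  traj <- simulate_trajectory(m, n_transitions = 20000, seed = 5)
  raw <- to_dwells(traj)
  dt <- dead_times(50e-6)
  r1 <- impose_resolution(raw, dt)
  expect_equal(sum(r1$duration), sum(raw$duration), tolerance = 1e-12)
  expect_true(all(r1$duration[r1$class == "open"] >= dt$tau_open))
  expect_true(all(r1$duration[r1$class == "shut"] >= dt$tau_shut))
  r2 <- impose_resolution(r1, dt)
  expect_equal(as.data.frame(r2), as.data.frame(r1))
  ## already-resolved input is returned unchanged
  ok <- dwell_sequence(c(1e-3, 2e-3, 3e-3, 4e-3),
                       c("open", "shut", "open", "shut"))
  expect_equal(as.data.frame(impose_resolution(ok, dt))$duration,
               ok$duration)
  expect_error(impose_resolution(
    dwell_sequence(c(1e-5, 2e-5), c("open", "shut")), dt), "shorter")
})

test_that("exponential mixture fitting recovers known components", {
  set.seed(23)
  ## single component
  x <- stats::rexp(10000, rate = 1000)
  fit1 <- fit_exp_mixture(x, 1)
  expect_equal(fit1$tau, 1e-3, tolerance = 3 / sqrt(10000) + 0.005)
  ## truncated single component: ML tau is the shifted sample mean
  t0 <- 2e-4
  xt <- x[x > t0]
  fit1t <- fit_exp_mixture(xt, 1, resolution = t0)
  expect_equal(fit1t$tau, mean(xt) - t0, tolerance = 1e-6)
  ## two well-separated components recovered with areas within 2 points
  y <- c(stats::rexp(30000, 1 / 1e-4), stats::rexp(70000, 1 / 5e-3))
  fit2 <- fit_exp_mixture(y, 2, seed = 2)
  expect_equal(fit2$tau, c(1e-4, 5e-3), tolerance = 0.05)
  expect_equal(fit2$area, c(0.3, 0.7), tolerance = 0.02 / 0.3)
})

test_that("mixture log-likelihood does not decrease with extra components", {
  set.seed(29)
  y <- c(stats::rexp(3000, 1 / 1e-4), stats::rexp(7000, 1 / 5e-3))
  ll <- vapply(1:3, function(k)
    attr(fit_exp_mixture(y, k, seed = 3), "loglik"), numeric(1))
  expect_true(all(diff(ll) > -1e-6))
})

test_that("t-crit solves the equal-misclassification criterion", {
  ## components like the packaged shut-time table: 3.3 ms vs 1000 ms
  mix <- exp_mixture(tau = c(3.3e-3, 1), area = c(0.9979, 0.0021))
  tc <- compute_tcrit(mix, 1)
  expect_gt(tc, 3.3e-3); expect_lt(tc, 1)
  ## brute-force oracle on a 1 us grid
  grid <- seq(1e-3, 0.2, by = 1e-6)
  mis <- 0.0021 * (1 - exp(-grid / 1)) - 0.9979 * exp(-grid / 3.3e-3)
  oracle <- grid[which.min(abs(mis))]
  expect_lt(abs(tc - oracle), 1e-6 + 1e-9)
  ## time rescaling scales t-crit linearly
  mix2 <- exp_mixture(tau = c(3.3e-3, 1) * 7, area = c(0.9979, 0.0021))
  expect_equal(compute_tcrit(mix2, 1), tc * 7, tolerance = 1e-6)
  ## overlapping components are an error
  expect_error(compute_tcrit(exp_mixture(c(1e-3, 1e-3 + 1e-12),
                                         c(0.5, 0.5)), 1), "degenerate")
})

test_that("burst segmentation delimits at the critical shut time", {
  dw <- dwell_sequence(
    c(1e-3, 1e-3, 2e-3, 40e-3, 3e-3, 2e-3, 4e-3),
    c("open", "shut", "open", "shut", "open", "shut", "open"))
  sb <- segment_bursts(dw, t_crit = 0.035)
  expect_equal(max(sb$burst, na.rm = TRUE), 2L)
  expect_true(is.na(sb$burst[4]))
  ## bursts begin and end with openings
  for (b in split(seq_len(nrow(sb)), sb$burst)) {
    expect_equal(sb$class[b[1]], "open")
    expect_equal(sb$class[b[length(b)]], "open")
  }
  ## all open time is within bursts
  expect_equal(sum(sb$duration[sb$class == "open" & !is.na(sb$burst)]),
               sum(dw$duration[dw$class == "open"]))
})

test_that("simulated records show the reported burst closing frequency", {
  ## the desensitizing model at the packaged rates, bursts at 35 ms
  m <- build_dimer_desensitization(table3_rates("desens", "composite"))
  dt <- dead_times(50e-6)
  dw <- sim_dwells(m, 40000, seed = 37, dt = dt)
  sb <- segment_bursts(dw, t_crit = 0.035)
  inb <- !is.na(sb$burst)
  closings <- sum(inb & sb$class == "shut")
  burst_time <- sum(sb$duration[inb])
  rate <- closings / burst_time
  expect_gt(rate, 352 * 0.75)
  expect_lt(rate, 352 * 1.25)
})

test_that("adjacent-interval correlation behaves under independence and reversal", {
  m <- two_state()
  dt <- dead_times(25e-6)
  dw <- sim_dwells(m, 20000, seed = 43, dt = dt)
  r <- adjacent_correlation(dw)
  expect_lt(abs(r), 3 / sqrt(attr(r, "n")))
  ## reversibility: pairing shut with following open gives the same r within
  ## sampling error on a time-reversible mechanism
  m2 <- build_tetramer(table3_rates("desens", "composite"))
  dw2 <- sim_dwells(m2, 40000, seed = 44, dt = dt)
  r_fwd <- adjacent_correlation(dw2)
  r_rev <- adjacent_correlation(dw2, reverse = TRUE)
  se <- 2 / sqrt(min(attr(r_fwd, "n"), attr(r_rev, "n")))
  expect_lt(abs(r_fwd - r_rev), 3 * se)
  expect_error(adjacent_correlation(dwell_sequence(c(1e-3, 1e-3),
                                                   c("open", "shut"))),
               "at least 10")
})
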