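test_that("with vanishing dead time the open-dwell pdf is the bare exponential", {
  m <- two_state()
  q <- assemble_q(m)
  dt <- dead_times(1e-12)
  tt <- c(2e-4, 1e-3, 3e-3, 8e-3)
  expect_equal(hjc_pdf(q, dt, tt, "open"), 900 * exp(-900 * tt),
               tolerance = 1e-6)
  expect_equal(hjc_pdf(q, dt, tt, "shut"), 100 * exp(-100 * tt),
               tolerance = 1e-6)
})

test_that("matrix dwell densities integrate to a row-stochastic transition matrix", {
  m <- three_state()
  q <- assemble_q(m)
  dt <- dead_times(30e-6)
  setup <- scgate_setup(m, dt)
  ## quadrature of the matrix density over all resolvable durations
  for (agg in c("open", "shut")) {
    kin <- if (agg == "open") q$kA else q$kF
    kout <- if (agg == "open") q$kF else q$kA
    tau_own <- if (agg == "open") dt$tau_open else dt$tau_shut
    G <- matrix(0, kin, kout)
    for (i in seq_len(kin)) for (j in seq_len(kout)) {
      G[i, j] <- stats::integrate(function(ts) vapply(ts, function(t)
        scgate:::egar_density_setup(setup, t, agg)[i, j], numeric(1)),
        tau_own * 1.000001, 2, rel.tol = 1e-9, subdivisions = 500L)$value
    }
    expect_equal(unname(rowSums(G)), rep(1, kin), tolerance = 1e-3)
  }
})

test_that("scalar dwell pdfs integrate to one above the dead time", {
  for (mech in list(two_state(), three_state(),
                    build_tetramer(table3_rates("desens", "composite")))) {
    for (tau in c(25e-6, 50e-6)) {
      dt <- dead_times(tau)
      setup <- scgate_setup(mech, dt)
      for (agg in c("open", "shut")) {
        mass <- sum(scgate:::hjc_pdf_bin_mass(
          setup, c(if (agg == "open") dt$tau_open else dt$tau_shut, 60), agg))
        expect_equal(mass, 1, tolerance = 1e-3)
      }
    }
  }
})

test_that("asymptotic roots: count, sign, and the two-state limit", {
  q2 <- assemble_q(two_state())
  r <- asymptotic_roots(q2, dead_times(1e-9), "open")
  expect_length(r$roots, 1)
  expect_equal(r$roots, -900, tolerance = 1e-5)
  ## the model at the packaged rates: one root per shut state, all negative
  m <- build_tetramer(table3_rates("desens", "composite"))
  rs <- asymptotic_roots(assemble_q(m), dead_times(50e-6), "shut")
  expect_length(rs$roots, 9)
  expect_true(all(rs$roots < 0))
})

test_that("slowest shut root matches the slowest mixture component of simulated data", {
  m <- build_tetramer(table3_rates("nondesens", "composite"))
  dt <- dead_times(50e-6)
  rs <- asymptotic_roots(assemble_q(m), dt, "shut")
  tau_slowest <- -1 / max(rs$roots)
  dw <- sim_dwells(m, 40000, seed = 41, dt = dt)
  mix <- fit_exp_mixture(dw$duration[dw$class == "shut"], 4,
                         resolution = dt$tau_shut, seed = 1)
  expect_equal(mix$tau[nrow(mix)], tau_slowest, tolerance = 0.15)
})

test_that("exact and asymptotic branches agree at the switchover", {
  dt <- dead_times(50e-6)
  for (mech in list(build_tetramer(table3_rates("nondesens", "composite")),
                    build_tetramer(table3_rates("desens", "composite")),
                    build_dimer_desensitization(
                      table3_rates("desens", "composite")))) {
    cont <- scgate:::branch_continuity(assemble_q(mech), dt)
    expect_lt(max(cont), 0.01)
  }
})

test_that("dwell histograms from simulation match the missed-event pdf", {
  m <- build_dimer_desensitization(table3_rates("desens", "composite"))
  dt <- dead_times(50e-6)
  dw <- sim_dwells(m, 30000, seed = 7, dt = dt)
  expect_gt(dwell_chisq_p(dw, m, dt, "open"), 0.01)
  expect_gt(dwell_chisq_p(dw, m, dt, "shut"), 0.01)
})

test_that("log-likelihood is additive over independent records", {
  m <- two_state()
  dt <- dead_times(25e-6)
  d1 <- sim_dwells(m, 500, seed = 51, dt = dt)
  d2 <- sim_dwells(m, 500, seed = 52, dt = dt)
  both <- dwell_sequence(c(d1$duration, d2$duration),
                         c(d1$class, d2$class),
                         segment = rep(1:2, c(nrow(d1), nrow(d2))),
                         resolution = dt)
  expect_equal(hjc_loglik(both, m, dt),
               hjc_loglik(d1, m, dt) + hjc_loglik(d2, m, dt),
               tolerance = 1e-10)
})

test_that("two-state likelihood reduces to the product of exponentials as tau -> 0", {
  m <- two_state()
  dt <- dead_times(1e-12)
  dw <- sim_dwells(m, 2000, seed = 42)
  ll <- hjc_loglik(dw, m, dt)
  to <- dw$duration[dw$class == "open"]; ts <- dw$duration[dw$class == "shut"]
  ll0 <- sum(log(900) - 900 * to) + sum(log(100) - 100 * ts)
  expect_equal(ll, ll0, tolerance = 1e-6)
})

test_that("likelihood is maximal near the generating rates", {
  m <- build_tetramer(table3_rates("desens", "composite"))
  dt <- dead_times(50e-6)
  dw <- sim_dwells(m, 20000, seed = 61, dt = dt)
  ll_true <- hjc_loglik(dw, m, dt)
  set.seed(62)
  free <- setdiff(names(m$rates), "k12")
  for (i in 1:20) {
    fac <- stats::runif(length(free), 0.5, 1.5)
    m2 <- scgate:::set_rates(m, stats::setNames(
      scgate:::rate_values(m)[free] * fac, free))
    expect_lt(hjc_loglik(dw, m2, dt), ll_true)
  }
})

test_that("likelihood rejects invalid records", {
  m <- two_state()
  dt <- dead_times(25e-6)
  expect_error(hjc_loglik(dwell_sequence(c(1e-3, 1e-5, 2e-3),
                                         c("open", "shut", "open")),
                          m, dt), "unresolved")
})

test_that("likelihood is invariant under state relabelling", {
  m1 <- three_state()
  dt <- dead_times(25e-6)
  dw <- sim_dwells(m1, 1500, seed = 71, dt = dt)
  m2 <- m1
  ren <- c(C1 = "zz", C2 = "aa", O = "O")
  m2$states$id <- unname(ren[m2$states$id])
  m2$transitions$from <- unname(ren[m2$transitions$from])
  m2$transitions$to <- unname(ren[m2$transitions$to])
  m2 <- mechanism(m2$states, m2$rates, m2$transitions)
  expect_equal(hjc_loglik(dw, m1, dt), hjc_loglik(dw, m2, dt),
               tolerance = 1e-9)
})
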