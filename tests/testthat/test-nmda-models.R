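test_that("tetramer builder has 9 shut + 2 open states and MR-derived k12", {
  r <- table3_rates("desens", "composite")
  m <- build_tetramer(r)
  expect_equal(nrow(m$states), 11L)
  expect_equal(sum(m$states$class == "shut"), 9L)
  expect_equal(n_free_rates(m), 9L)
  ## k12 follows from the open-state cycle, close to the packaged value
  expect_equal(m$rates$k12$value, 1393.4, tolerance = 1e-4)
  m2 <- build_tetramer(table3_rates("nondesens", "composite"))
  expect_equal(m2$rates$k12$value, 566.36, tolerance = 1e-4)
  ## detailed balance holds everywhere
  q <- assemble_q(m)
  expect_lt(detailed_balance_error(q), 1e-8 * max(abs(q$Q)))
})

test_that("automatic MR constraint selection recovers k12 on the grid model", {
  m <- build_tetramer(table3_rates("desens", "composite"))
  k12_mr <- m$rates$k12$value
  m$constraints$mr <- list()
  m <- enforce_mr(m)
  expect_length(m$constraints$mr, 1)
  expect_equal(m$constraints$mr[[1]]$rate, "k12")
  expect_equal(m$rates$k12$value, k12_mr, tolerance = 1e-10)
})

test_that("fit results are invariant to which rate of the MR pair is constrained", {
  ## constrain k21 (on the reversed cycle) instead of k12: with the same
  ## free-rate values both parameterizations produce the same Q matrix
  r <- table3_rates("desens", "composite")
  m1 <- build_tetramer(r)
  m2 <- m1
  m2$constraints$mr <- list(list(rate = "k21",
                                 cycle = c("O2", "O1", "C22", "C21")))
  m2$rates$k12$value <- m1$rates$k12$value
  m2 <- apply_mr(m2)
  expect_equal(m2$rates$k21$value, m1$rates$k21$value, tolerance = 1e-10)
  expect_equal(assemble_q(m1)$Q, assemble_q(m2)$Q, tolerance = 1e-10)
})

test_that("swapping the f and s subunit labels leaves the dwell spectrum unchanged", {
  r <- table3_rates("desens", "composite")
  rsym <- r; rsym$kp_s <- r$kp_f; rsym$km_s <- r$km_f
  m1 <- build_tetramer(rsym)
  rswap <- rsym
  rswap$kp_f <- rsym$kp_s; rswap$km_f <- rsym$km_s
  rswap$kp_s <- rsym$kp_f; rswap$km_s <- rsym$km_f
  m2 <- build_tetramer(rswap)
  e1 <- sort(eigen(assemble_q(m1)$Q, only.values = TRUE)$values)
  e2 <- sort(eigen(assemble_q(m2)$Q, only.values = TRUE)$values)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("dimer model enumerates unordered pairs: 15 shut + 2 open states", {
  m <- build_dimer_desensitization(table3_rates("desens", "composite"))
  expect_equal(nrow(m$states), 17L)
  expect_equal(n_free_rates(m), 11L)
  ## the two one-GluN1-one-GluN2-active configurations are distinct states
  expect_true(all(c("C00.11", "C01.10") %in% m$states$id))
  q <- assemble_q(m)
  expect_lt(detailed_balance_error(q), 1e-8 * max(abs(q$Q)))
})

test_that("dimer model with vanishing desensitization matches the grid spectrum", {
  r <- table3_rates("desens", "composite")
  r$kp_d <- 1e-9; r$km_d <- 1
  md <- build_dimer_desensitization(r)
  mg <- build_tetramer(r)
  ## the aggregated generator keeps the grid eigenvalues; the extra dimer
  ## states contribute additional modes, so the grid spectrum must be a
  ## subset of the dimer spectrum
  ed <- sort(eigen(assemble_q(md)$Q, only.values = TRUE)$values)
  eg <- sort(eigen(assemble_q(mg)$Q, only.values = TRUE)$values)
  match_err <- vapply(eg, function(x) min(abs(ed - x)), numeric(1))
  expect_lt(max(match_err) / max(abs(eg)), 1e-6)
})

test_that("binding extension: 28 shut + 2 open, no opening without glutamate", {
  mb <- build_binding_extended(tableA1_rates("gateway2", "macroscopic"))
  expect_equal(nrow(mb$states), 28L)
  w <- respond(mb, protocol_step(0, 0.2))
  expect_lt(max(abs(w$popen)), 1e-10)
})

test_that("binding model reduces to the dimer model at saturation without unbinding", {
  r <- tableA1_rates("gateway2", "macroscopic")
  r$km_a <- 1e-6
  mb <- build_binding_extended(r)
  md <- build_dimer_desensitization(tableA1_rates("gateway2", "macroscopic"))
  q <- assemble_q(mb, c(glu = 1e-3))
  ## at saturating glutamate with no unbinding, the fully bound subspace
  ## carries the dimer-model dynamics: compare equilibrium open probability
  po_b <- sum(equilibrium_dist(q)[q$class == "open"])
  qd <- assemble_q(md)
  po_d <- sum(equilibrium_dist(qd)[qd$class == "open"])
  expect_equal(po_b, po_d, tolerance = 1e-3)
})

test_that("all-four-gateway model has a single gateway and 10 free parameters", {
  r <- tableA1_rates("allfour", "single_channel")
  m <- build_all_four_gate(r, extension = "dimer")
  expect_equal(n_free_rates(m), 10L)
  ## exactly one closed state connects to the open states
  tr <- m$transitions
  cls <- stats::setNames(m$states$class, m$states$id)
  gateways <- unique(tr$from[cls[tr$from] == "shut" & cls[tr$to] == "open"])
  expect_length(gateways, 1L)
  ## alpha2/beta2 are rejected
  expect_error(build_all_four_gate(tableA1_rates("gateway2", "single_channel"),
                                   extension = "dimer"),
               "alpha2")
})

test_that("gateway count drives the sign of adjacent open-shut correlations", {
  dt <- dead_times(50e-6)
  ## two gateways: negative correlation
  m2g <- build_tetramer(table3_rates("desens", "composite"))
  dw <- sim_dwells(m2g, 300000, seed = 31, dt = dt)
  r2 <- adjacent_correlation(dw)
  expect_lt(r2, 0)
  expect_lt(attr(r2, "p.value"), 0.05)
  ## single gateway: no correlation (|r| below 3 standard errors)
  r <- tableA1_rates("allfour", "single_channel")
  m1g <- build_all_four_gate(r, extension = "grid")
  dw1 <- sim_dwells(m1g, 40000, seed = 32, dt = dt)
  r1 <- adjacent_correlation(dw1)
  expect_lt(abs(r1), 3 / sqrt(attr(r1, "n")))
})

test_that("packaged rate tables expose the fitted rate sets", {
  r <- table3_rates("desens", "composite")
  expect_equal(r$kp_s, 256)
  expect_equal(r$km_s, 225)
  expect_equal(tableA1_rates("gateway2", "macroscopic")$kp_a, 6.7e6)
  expect_equal(tableA1_rates("allfour", "macroscopic")$km_a, 483)
  expect_error(nmda_rates(k12 = -1, k21 = 1, alpha1 = 1, beta1 = 1,
                          kp_f = 1, km_f = 1, kp_s = 1, km_s = 1),
               "positive")
})
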