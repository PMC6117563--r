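test_that("Q assembly places open states first and conserves probability", {
  m <- two_state()
  q <- assemble_q(m)
  expect_equal(q$states, c("O", "C"))
  expect_equal(unname(q$Q), matrix(c(-900, 100, 900, -100), 2))

  for (mech in list(three_state(), four_cycle(),
                    build_tetramer(table3_rates("desens", "composite")))) {
    qq <- assemble_q(mech)
    expect_lt(max(abs(rowSums(qq$Q))), 1e-10 * max(abs(qq$Q)))
    expect_true(all(qq$class[seq_len(qq$kA)] == "open"))
    expect_true(all(qq$Q[row(qq$Q) != col(qq$Q)] >= 0))
  }
})

test_that("Q assembly validates ligands and concentrations", {
  mb <- build_binding_extended(tableA1_rates("gateway2", "macroscopic"))
  expect_error(assemble_q(mb), "ligand")
  expect_error(assemble_q(mb, c(glu = -1)), ">= 0")
  q <- assemble_q(mb, c(glu = 1e-3))
  expect_equal(q$kA + q$kF, 28L)
})

test_that("equilibrium solves p Q = 0 and matches analytic two-state value", {
  q <- assemble_q(two_state())
  p <- equilibrium_dist(q)
  expect_equal(unname(p["O"]), 0.1, tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_lt(max(abs(p %*% q$Q)), 1e-10)
})

test_that("equilibrium is invariant to state relabelling", {
  m1 <- three_state()
  ## relabel so the lexicographic canonical order changes
  m2 <- m1
  m2$states$id <- c("zC1", "aC2", "O")[match(m2$states$id, c("C1", "C2", "O"))]
  m2$transitions$from <- c("zC1", "aC2", "O")[match(m2$transitions$from,
                                                   c("C1", "C2", "O"))]
  m2$transitions$to <- c("zC1", "aC2", "O")[match(m2$transitions$to,
                                                  c("C1", "C2", "O"))]
  m2 <- mechanism(m2$states, m2$rates, m2$transitions)
  p1 <- equilibrium_dist(assemble_q(m1))
  p2 <- equilibrium_dist(assemble_q(m2))
  expect_equal(unname(p1[c("C1", "C2", "O")]),
               unname(p2[c("zC1", "aC2", "O")]), tolerance = 1e-12)
})

test_that("equilibrium open probability matches a long stochastic simulation", {
  m <- build_tetramer(table3_rates("desens", "composite"))
  q <- assemble_q(m)
  p_eq <- sum(equilibrium_dist(q)[q$class == "open"])
  traj <- simulate_trajectory(m, n_transitions = 3e5, seed = 101)
  open <- traj$classes == "open"
  ## batch-means standard error for the correlated time-fraction estimate
  nb <- 50
  grp <- cut(cumsum(traj$durations), nb, labels = FALSE)
  batches <- tapply(traj$durations * open, grp, sum) /
    tapply(traj$durations, grp, sum)
  est <- sum(traj$durations[open]) / sum(traj$durations)
  se <- stats::sd(batches) / sqrt(nb)
  expect_lt(abs(est - p_eq), 3 * se)
})

test_that("a tree mechanism needs no MR constraints", {
  m <- enforce_mr(three_state())
  expect_length(m$constraints$mr, 0)
})

test_that("MR on a 4-cycle fixes the off-tree rate and restores detailed balance", {
  m <- four_cycle()
  expect_gt(detailed_balance_error(assemble_q(m)), 1)  # violated before
  m <- enforce_mr(m)
  expect_length(m$constraints$mr, 1)   # edges - (states - 1) = 4 - 3
  q <- assemble_q(m)
  expect_lt(detailed_balance_error(q), 1e-8 * max(abs(q$Q)))
  ## the constrained value equals the cycle product ratio by hand:
  ## product of rates one way round the cycle equals the product the other way
  p <- equilibrium_dist(q)
  flux <- p * q$Q
  expect_lt(max(abs(flux - t(flux))), 1e-10 * max(abs(flux)))
})

test_that("MR-derived rates update when cycle rates change", {
  m <- enforce_mr(four_cycle())
  con <- m$constraints$mr[[1]]$rate
  v1 <- m$rates[[con]]$value
  free <- setdiff(names(m$rates), con)[1]
  m2 <- scgate:::set_rates(m, stats::setNames(
    m$rates[[free]]$value * 2, free))
  expect_false(isTRUE(all.equal(v1, m2$rates[[con]]$value)))
  expect_lt(detailed_balance_error(assemble_q(m2)), 1e-8 * 1e3)
})

test_that("spectral relaxation matches identity, ergodic limit and an RK4 oracle", {
  m <- three_state()
  q <- assemble_q(m)
  p0 <- c(0, 0, 1); names(p0) <- q$states
  expect_equal(spectral_relax(q, p0, 0), p0, tolerance = 1e-12)
  expect_equal(unname(spectral_relax(q, p0, 10)),
               unname(equilibrium_dist(q)), tolerance = 1e-6)
  ## fixed-step RK4 integration of dp/dt = p Q at 1 us steps
  rk4 <- function(p, Q, t_end, h = 1e-6) {
    f <- function(p) as.numeric(p %*% Q)
    for (i in seq_len(round(t_end / h))) {
      k1 <- f(p); k2 <- f(p + h / 2 * k1)
      k3 <- f(p + h / 2 * k2); k4 <- f(p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    p
  }
  t_end <- 2e-3
  expect_equal(unname(spectral_relax(q, p0, t_end)),
               rk4(unname(p0), q$Q, t_end), tolerance = 1e-6)
  expect_equal(sum(spectral_relax(q, p0, t_end)), 1, tolerance = 1e-8)
})

test_that("constraint declarations are validated", {
  expect_error(mechanism(
    states = data.frame(id = c("O", "C"), class = c("open", "shut")),
    rates = list(rate_param("a", 1)),
    transitions = data.frame(from = "O", to = "C", rate = "a")),
    "reverse")
  expect_error(mechanism(
    states = data.frame(id = c("O", "O"), class = c("open", "shut")),
    rates = list(rate_param("a", 1), rate_param("b", 2)),
    transitions = data.frame(from = c("O", "O"), to = c("O", "O"),
                             rate = c("a", "b"))),
    "unique")
})
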