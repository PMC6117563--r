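mb_macro <- build_binding_extended(tableA1_rates("gateway2", "macroscopic"))

test_that("no response without glutamate; occupancy is conserved", {
  w <- respond(mb_macro, protocol_step(0, 0.5))
  expect_lt(max(abs(w$popen)), 1e-10)
  w1 <- respond(mb_macro, protocol_step(1e-3, 0.5))
  occ <- attr(w1, "occupancy")
  expect_true(all(w1$popen >= 0 & w1$popen <= 1))
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-6)
})

test_that("spectral and ODE solvers agree on a constant step", {
  p0 <- rest_state(mb_macro)
  ws <- respond(mb_macro, protocol_step(1e-3, 0.05), p0 = p0)
  ## the same step expressed as a transient with an enormous time constant
  wt <- respond(mb_macro, protocol_transient(1e-3, 1e6, 0.05), p0 = p0)
  expect_equal(ws$popen, wt$popen, tolerance = 1e-5)
  ## and against a brute-force fixed-step Euler integration at 1 us
  Q0 <- assemble_q(mb_macro, c(glu = 0))$Q
  Q1 <- assemble_q(mb_macro, c(glu = 1))$Q - Q0
  Qc <- Q0 + 1e-3 * Q1
  p <- as.numeric(p0); h <- 1e-6
  open_idx <- which(assemble_q(mb_macro, c(glu = 0))$class == "open")
  for (i in 1:5000) p <- p + h * as.numeric(p %*% Qc)
  euler <- sum(p[open_idx])
  spectral <- ws$popen[which.min(abs(ws$time - 5e-3))]
  expect_equal(spectral, euler, tolerance = 1e-4)
})

test_that("rise time extraction matches analytic waveforms", {
  ## linear ramp 0 -> 1 over 1 ms: rise time 0.8 ms
  ramp <- structure(data.frame(time = seq(0, 1e-3, 1e-6),
                               popen = seq(0, 1, length.out = 1001)),
                    class = c("waveform", "data.frame"))
  expect_equal(rise_time_10_90(ramp), 0.8e-3, tolerance = 1e-3)
  ## single-exponential rise, tau = 1 ms: rise time ln(9) ms
  t <- seq(0, 20e-3, 1e-6)
  expo <- structure(data.frame(time = t, popen = 1 - exp(-t / 1e-3)),
                    class = c("waveform", "data.frame"))
  expect_equal(rise_time_10_90(expo), log(9) * 1e-3, tolerance = 1e-3)
  falling <- structure(data.frame(time = t, popen = exp(-t / 1e-3)),
                       class = c("waveform", "data.frame"))
  expect_error(rise_time_10_90(falling), "rising")
})

test_that("exponential decay fits recover exact time constants", {
  t <- seq(0, 0.5, 5e-4)
  w <- structure(data.frame(time = t, popen = 0.4 * exp(-t / 0.05)),
                 class = c("waveform", "data.frame"))
  f <- fit_exponential_decay(w, n = 1, resample = NULL)
  expect_equal(f$tau, 0.05, tolerance = 1e-6)
  ## with uniform resampling the error stays small
  expect_equal(fit_exponential_decay(w, n = 1)$tau, 0.05, tolerance = 1e-4)
  ## two components plus offset
  w2 <- structure(data.frame(
    time = t, popen = 0.1 + 0.3 * exp(-t / 0.01) + 0.2 * exp(-t / 0.15)),
    class = c("waveform", "data.frame"))
  f2 <- fit_exponential_decay(w2, n = 2, offset = TRUE, resample = NULL)
  expect_equal(f2$tau, c(0.01, 0.15), tolerance = 1e-4)
  expect_equal(f2$offset, 0.1, tolerance = 1e-4)
  expect_equal(f2$weighted_tau, (0.3 * 0.01 + 0.2 * 0.15) / 0.5,
               tolerance = 1e-4)
})

test_that("Hill fits are self-consistent", {
  concs <- 10^seq(-7, -3, by = 0.5)
  resp <- 0.8 / (1 + (5e-6 / concs)^1.3)
  h <- hill_fit(concs, resp)
  expect_equal(h$ec50, 5e-6, tolerance = 1e-6)
  expect_equal(h$nh, 1.3, tolerance = 1e-6)
  expect_equal(h$max, 0.8, tolerance = 1e-6)
})

test_that("peak open probability for a saturating step lies in the reported band", {
  w <- respond(mb_macro, protocol_step(1e-3, 1))
  expect_gt(max(w$popen), 0.35)
  expect_lt(max(w$popen), 0.65)
})

test_that("train peaks decline monotonically and recover at long intervals", {
  tr <- synaptic_train(mb_macro, n_stimuli = 6, interval = 0.1)
  expect_true(all(diff(tr$peaks) < 0))
  expect_false(is.na(tr$tau_decay))
  ## with very long intervals all peaks are equal
  tr2 <- synaptic_train(mb_macro, n_stimuli = 3, interval = 60)
  expect_lt(diff(range(tr2$peaks)) / tr2$peaks[1], 1e-4)
  expect_error(synaptic_train(mb_macro, n_stimuli = 3, interval = 5e-3),
               "interval")
})

test_that("paired-pulse recovery: no desensitization means no depression", {
  r0 <- tableA1_rates("gateway2", "macroscopic")
  r0$kp_d <- 1e-9
  m0 <- build_binding_extended(r0)
  expect_warning(pp <- paired_pulse_recovery(m0, intervals = c(.3, .6, 1, 2, 4)),
                 "no depression")
  expect_true(is.na(pp$tau_recovery))
})

test_that("recovery time constant approaches 1/km_d for weak desensitization", {
  r <- tableA1_rates("gateway2", "macroscopic")
  r$kp_d <- 2      # weak entry; recovery dominated by km_d = 1.54
  m <- build_binding_extended(r)
  pp <- paired_pulse_recovery(m, intervals = c(0.25, 0.5, 1, 2, 4, 8))
  expect_equal(pp$tau_recovery, 1 / r$km_d, tolerance = 0.3)
})

test_that("macroscopic rate fitting recovers binding and desensitization rates", {
  truth <- tableA1_rates("gateway2", "macroscopic")
  protos <- list(protocol(list(protocol_step(1e-3, 1), protocol_step(0, 0.3))),
                 protocol(list(protocol_step(3e-6, 1), protocol_step(0, 0.3))))
  gen <- lapply(protos, function(p)
    respond(mb_macro, p, dt_fine = 5e-5, fine_window = 0.02))
  ## noiseless self-fit: SSQ at the generating rates is already tiny
  f0 <- fit_macroscopic_rates(mb_macro, gen, protos,
                              dt_fine = 5e-5, fine_window = 0.02)
  expect_lt(f0$ssq, 1e-6)
  ## 1% noise, perturbed start: all four recovered within 15%
  set.seed(55)
  noisy <- lapply(gen, function(w) {
    w$popen <- w$popen + stats::rnorm(nrow(w), 0, 0.01 * max(w$popen))
    w
  })
  start <- truth
  for (nm in c("kp_a", "km_a", "kp_d", "km_d")) start[[nm]] <- truth[[nm]] * 1.8
  m_start <- build_binding_extended(start)
  fit <- fit_macroscopic_rates(m_start, noisy, protos,
                               dt_fine = 5e-5, fine_window = 0.02)
  for (nm in c("kp_a", "km_a", "kp_d", "km_d"))
    expect_equal(unname(fit$rates[nm]), truth[[nm]], tolerance = 0.15)
})

test_that("restricted equilibrium binding matches the bimolecular limit", {
  ## with GluN2 pre-gating removed the sites are plain bimolecular binders:
  ## site occupancy EC50 = km_a / kp_a
  r <- tableA1_rates("gateway2", "macroscopic")
  r$kp_s <- 1e-9
  m <- build_binding_extended(r)
  b <- binding_occupancy_ec50(m, restrict = "no_glun1_gating",
                              metric = "site")
  expect_equal(b$ec50, r$km_a / r$kp_a, tolerance = 1e-3)
  ## receptor-level binding with gating: analytic EC50
  ## K/(1+E) * (sqrt(2)-1) with K = km_a/kp_a, E = kp_s/km_s
  r2 <- tableA1_rates("gateway2", "macroscopic")
  m2 <- build_binding_extended(r2)
  b2 <- binding_occupancy_ec50(m2, restrict = "no_glun1_gating")
  K <- r2$km_a / r2$kp_a; E <- r2$kp_s / r2$km_s
  expect_equal(b2$ec50, K / (1 + E) * (sqrt(2) - 1), tolerance = 0.01)
})
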