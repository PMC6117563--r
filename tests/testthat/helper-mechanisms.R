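# Small mechanisms and fixtures shared across tests (built in code).

two_state <- function(alpha = 900, beta = 100) {
  mechanism(
    states = data.frame(id = c("O", "C"), class = c("open", "shut")),
    rates = list(rate_param("alpha", alpha), rate_param("beta", beta)),
    transitions = data.frame(from = c("O", "C"), to = c("C", "O"),
                             rate = c("alpha", "beta")))
}

# linear C1 - C2 - O chain
three_state <- function(k12 = 200, k21 = 400, beta = 1500, alpha = 600) {
  mechanism(
    states = data.frame(id = c("C1", "C2", "O"),
                        class = c("shut", "shut", "open")),
    rates = list(rate_param("k12", k12), rate_param("k21", k21),
                 rate_param("beta", beta), rate_param("alpha", alpha)),
    transitions = data.frame(
      from = c("C1", "C2", "C2", "O"),
      to = c("C2", "C1", "O", "C2"),
      rate = c("k12", "k21", "beta", "alpha")))
}

# single 4-cycle with 8 distinct rates; the 8th is determined by MR
four_cycle <- function(r = c(a_f = 100, a_r = 250, b_f = 900, b_r = 150,
                             c_f = 300, c_r = 700, d_f = 50, d_r = 999)) {
  mechanism(
    states = data.frame(id = c("O1", "C1", "C2", "C3"),
                        class = c("open", "shut", "shut", "shut")),
    rates = lapply(names(r), function(n) rate_param(n, r[[n]])),
    transitions = data.frame(
      from = c("O1", "C1", "C1", "C2", "C2", "C3", "C3", "O1"),
      to = c("C1", "O1", "C2", "C1", "C3", "C2", "O1", "C3"),
      rate = c("a_f", "a_r", "b_f", "b_r", "c_f", "c_r", "d_f", "d_r")))
}

sim_dwells <- function(mech, n, seed, dt = NULL, concentrations = numeric(0)) {
  simulate_patches(mech, concentrations, n_patches = 1,
                   transitions_per_patch = n, seed = seed, dt = dt)
}

# chi-square goodness of fit of resolved dwell durations against the
# missed-event pdf of a mechanism (expected masses from analytic bin
# integrals, bins merged to expected counts >= 5)
dwell_chisq_p <- function(dwells, mech, dt, aggregate) {
  setup <- scgate_setup(mech, dt)
  d <- dwells$duration[dwells$class == aggregate]
  tau_own <- if (aggregate == "open") dt$tau_open else dt$tau_shut
  br <- exp(seq(log(tau_own * 1.0001), log(max(d) * 1.001), length.out = 40))
  br[1] <- tau_own
  obs <- graphics::hist(d, breaks = c(br, Inf), plot = FALSE)$counts
  pm <- scgate:::hjc_pdf_bin_mass(setup, br, aggregate)
  pm <- c(pm, max(0, 1 - sum(pm)))
  pm <- pm / sum(pm)
  expct <- pm * length(d)
  grp <- cumsum(expct) %/% 5
  o <- tapply(obs, grp, sum); e <- tapply(expct, grp, sum)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, length(e) - 1, lower.tail = FALSE)
}

scgate_setup <- function(mech, dt, concentrations = numeric(0)) {
  scgate:::hjc_setup(assemble_q(mech, concentrations), dt)
}
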