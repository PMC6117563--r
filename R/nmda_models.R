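#' Rate-constant set for the tetrameric NMDA receptor schemes
#'
#' Collects the named rate constants used by the model builders. `kp_f`/`km_f`
#' are the forward/backward GluN1 pre-gating rates, `kp_s`/`km_s` the GluN2
#' pre-gating rates, `beta1`/`alpha1` and `beta2`/`alpha2` the opening/closing
#' rates of the two open states, `k12`/`k21` the open-open interconversion,
#' `kp_d`/`km_d` dimer desensitization entry/recovery and `kp_a`/`km_a`
#' glutamate association (M^-1 s^-1) and dissociation.
#'
#' @param k12,k21,alpha1,beta1,alpha2,beta2,kp_f,km_f,kp_s,km_s rates in s^-1;
#'   `alpha2`/`beta2` may be `NULL` for the all-four-gateway scheme.
#' @param kp_d,km_d optional desensitization rates (s^-1).
#' @param kp_a,km_a optional glutamate association (M^-1 s^-1) and
#'   dissociation (s^-1) rates.
#' @return Named list of class `nmda_rates`.
#' @export
nmda_rates <- function(k12, k21, alpha1, beta1, alpha2 = NULL, beta2 = NULL,
                       kp_f, km_f, kp_s, km_s,
                       kp_d = NULL, km_d = NULL, kp_a = NULL, km_a = NULL) {
  r <- list(k12 = k12, k21 = k21, alpha1 = alpha1, beta1 = beta1,
            alpha2 = alpha2, beta2 = beta2, kp_f = kp_f, km_f = km_f,
            kp_s = kp_s, km_s = km_s, kp_d = kp_d, km_d = km_d,
            kp_a = kp_a, km_a = km_a)
  r <- r[!vapply(r, is.null, logical(1))]
  for (nm in names(r)) {
    if (!is.numeric(r[[nm]]) || length(r[[nm]]) != 1L || r[[nm]] <= 0)
      stop("rate '", nm, "' must be a positive scalar")
  }
  structure(r, class = "nmda_rates")
}

rate_set_db <- function() {
  path <- system.file("extdata", "nmda_rate_sets.json", package = "scgate")
  jsonlite::fromJSON(path)
}

#' Packaged fitted rate sets
#'
#' `table3_rates()` returns the single-channel fitted rates of the
#' non-desensitizing (burst-analysis) or desensitizing scheme, either the
#' composite fit of all patches or the per-patch means. `tableA1_rates()`
#' returns the rate sets comparing the two-gateway scheme with the
#' all-four-gateway alternative, each as fitted to single-channel data or with
#' the binding/desensitization rates from the macroscopic least-squares fit.
#'
#' @param model for `table3_rates()`, `"nondesens"` or `"desens"`; for
#'   `tableA1_rates()`, `"gateway2"` or `"allfour"`.
#' @param fit for `table3_rates()`, `"composite"` or `"mean"`; for
#'   `tableA1_rates()`, `"single_channel"` or `"macroscopic"`.
#' @return An [nmda_rates()] object.
#' @export
table3_rates <- function(model = c("nondesens", "desens"),
                         fit = c("composite", "mean")) {
  model <- match.arg(model); fit <- match.arg(fit)
  do.call(nmda_rates, rate_set_db()$table3[[model]][[fit]])
}

#' @rdname table3_rates
#' @export
tableA1_rates <- function(model = c("gateway2", "allfour"),
                          fit = c("single_channel", "macroscopic")) {
  model <- match.arg(model); fit <- match.arg(fit)
  do.call(nmda_rates, rate_set_db()$tableA1[[model]][[fit]])
}

need_rates <- function(rates, need) {
  miss <- setdiff(need, names(rates))
  if (length(miss)) stop("missing rate(s): ", paste(miss, collapse = ", "))
}

## shared rate_param list for the gating core
gating_rate_params <- function(rates, two_open = TRUE) {
  nm <- c("k12", "k21", "alpha1", "beta1",
          if (two_open) c("alpha2", "beta2"),
          "kp_f", "km_f", "kp_s", "km_s")
  lapply(stats::setNames(nm, nm), function(n) rate_param(n, rates[[n]]))
}

fac <- function(on, n) if (on) as.integer(n) else 1L

## ---- tetramer grid (no binding, no desensitization) ----------------------

#' Tetrameric subunit pre-gating mechanism (two open gateways)
#'
#' Builds the fully liganded scheme in which each of the four subunits
#' independently undergoes a pre-gating conformational change: a 3x3 grid of
#' closed states indexed by the number of activated GluN1 (0-2) and GluN2
#' (0-2) subunits, plus two open states. O1 opens from the fully gated state
#' (`beta1`/`alpha1`), O2 from the state with both GluN1 and one GluN2 gated
#' (`beta2`/`alpha2`), and the open states interconvert with `k12`
#' microscopically-reversibility-constrained on the cycle through the two
#' gateway states.
#'
#' @param rates an [nmda_rates()] set without binding rates.
#' @param statistical_factors logical; include combinatorial multiplicities
#'   for identical independent subunits (e.g. `2*kp_f` for the first of two
#'   GluN1 steps). Default `TRUE`, the convention consistent with the
#'   packaged fitted `k12` values.
#' @return A [mechanism()] with 9 shut and 2 open states.
#' @export
build_tetramer <- function(rates, statistical_factors = TRUE) {
  need_rates(rates, c("k12", "k21", "alpha1", "beta1", "alpha2", "beta2",
                      "kp_f", "km_f", "kp_s", "km_s"))
  sf <- statistical_factors
  st <- expand.grid(n1 = 0:2, n2 = 0:2)
  states <- data.frame(id = paste0("C", st$n1, st$n2), class = "shut",
                       n1 = st$n1, n2 = st$n2, stringsAsFactors = FALSE)
  states <- rbind(data.frame(id = c("O1", "O2"), class = "open",
                             n1 = c(2, 2), n2 = c(2, 1),
                             stringsAsFactors = FALSE), states)
  tr <- list()
  add <- function(f, t, r, fct = 1L)
    tr[[length(tr) + 1L]] <<- data.frame(from = f, to = t, rate = r,
                                         factor = as.integer(fct),
                                         stringsAsFactors = FALSE)
  for (i in 0:2) for (j in 0:2) {
    id <- paste0("C", i, j)
    if (i < 2) { add(id, paste0("C", i + 1, j), "kp_f", fac(sf, 2 - i))
                 add(paste0("C", i + 1, j), id, "km_f", fac(sf, i + 1)) }
    if (j < 2) { add(id, paste0("C", i, j + 1), "kp_s", fac(sf, 2 - j))
                 add(paste0("C", i, j + 1), id, "km_s", fac(sf, j + 1)) }
  }
  add("C22", "O1", "beta1"); add("O1", "C22", "alpha1")
  add("C21", "O2", "beta2"); add("O2", "C21", "alpha2")
  add("O2", "O1", "k21");    add("O1", "O2", "k12")
  mech <- mechanism(states, gating_rate_params(rates),
                    do.call(rbind, tr),
                    constraints = list(mr = list(list(
                      rate = "k12", cycle = c("O1", "O2", "C21", "C22")))))
  apply_mr(mech)
}

## ---- dimer desensitization ----------------------------------------------

## per-dimer configuration moves shared by the pair-based builders
dimer_moves <- function(codes, desens = TRUE) {
  mv <- list(c("00", "10", "kp_f"), c("10", "00", "km_f"),
             c("00", "01", "kp_s"), c("01", "00", "km_s"),
             c("10", "11", "kp_s"), c("11", "10", "km_s"),
             c("01", "11", "kp_f"), c("11", "01", "km_f"))
  if (desens) mv <- c(mv, list(c("11", "D", "kp_d"), c("D", "11", "km_d")))
  mv
}

pair_id <- function(a, b, order) {
  two <- c(a, b)[order(match(c(a, b), order))]
  paste0("C", two[1], ".", two[2])
}

## build a mechanism over unordered pairs of per-dimer configurations
build_pair_mechanism <- function(codes, moves, open_spec, rate_params,
                                 mr, statistical_factors, state_extra = NULL,
                                 move_allowed = NULL, pair_allowed = NULL) {
  pairs <- list()
  for (i in seq_along(codes)) for (j in i:length(codes)) {
    if (!is.null(pair_allowed) && !pair_allowed(codes[i], codes[j])) next
    pairs[[length(pairs) + 1L]] <- c(codes[i], codes[j])
  }
  ids <- vapply(pairs, function(p) pair_id(p[1], p[2], codes), character(1))
  states <- data.frame(id = ids, class = "shut", stringsAsFactors = FALSE)
  states$dimer1 <- vapply(pairs, `[`, "", 1L)
  states$dimer2 <- vapply(pairs, `[`, "", 2L)
  if (!is.null(state_extra)) states <- cbind(states, state_extra(states))
  states <- rbind(open_spec$states, states)

  agg <- new.env(parent = emptyenv())
  for (s in seq_along(pairs)) {
    p <- pairs[[s]]
    for (slot in 1:2) {
      this <- p[slot]; other <- p[3 - slot]
      for (mv in moves) {
        if (mv[1] != this) next
        if (!is.null(move_allowed) && !move_allowed(mv, other)) next
        to <- pair_id(mv[2], other, codes)
        key <- paste(ids[s], to, mv[3], sep = "\r")
        agg[[key]] <- (agg[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- sort(ls(agg))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  tr <- data.frame(from = vapply(parts, `[`, "", 1L),
                   to = vapply(parts, `[`, "", 2L),
                   rate = vapply(parts, `[`, "", 3L),
                   factor = vapply(keys, function(k)
                     if (statistical_factors) agg[[k]] else 1L, integer(1)),
                   stringsAsFactors = FALSE)
  rownames(tr) <- NULL
  tr <- rbind(tr, open_spec$transitions)
  mech <- mechanism(states, rate_params, tr, constraints = list(mr = mr))
  apply_mr(mech)
}

#' Dimer-dependent desensitization mechanism
#'
#' Extends [build_tetramer()] by tracking which dimer each pre-gating step
#' occurred in: states are unordered pairs of per-dimer configurations
#' (GluN1 gated?, GluN2 gated?, or desensitized `D`), so the receptor with one
#' GluN1 and one GluN2 step completed occupies two distinct states depending
#' on whether both steps happened within one dimer. A dimer whose two subunits
#' have both undergone pre-gating may desensitize (`kp_d`, recovery `km_d`);
#' a desensitized dimer freezes its internal state and the channel cannot
#' open while any dimer is desensitized.
#'
#' @inheritParams build_tetramer
#' @param rates an [nmda_rates()] set including `kp_d`, `km_d`.
#' @return A [mechanism()] with 15 shut and 2 open states.
#' @export
build_dimer_desensitization <- function(rates, statistical_factors = TRUE) {
  need_rates(rates, c("k12", "k21", "alpha1", "beta1", "alpha2", "beta2",
                      "kp_f", "km_f", "kp_s", "km_s", "kp_d", "km_d"))
  codes <- c("00", "01", "10", "11", "D")
  rp <- c(gating_rate_params(rates),
          list(kp_d = rate_param("kp_d", rates$kp_d),
               km_d = rate_param("km_d", rates$km_d)))
  gate1 <- pair_id("11", "11", codes)
  gate2 <- pair_id("11", "10", codes)
  open_spec <- list(
    states = data.frame(id = c("O1", "O2"), class = "open",
                        dimer1 = NA, dimer2 = NA, stringsAsFactors = FALSE),
    transitions = data.frame(
      from = c(gate1, "O1", gate2, "O2", "O2", "O1"),
      to = c("O1", gate1, "O2", gate2, "O1", "O2"),
      rate = c("beta1", "alpha1", "beta2", "alpha2", "k21", "k12"),
      factor = 1L, stringsAsFactors = FALSE))
  build_pair_mechanism(codes, dimer_moves(codes), open_spec, rp,
                       mr = list(list(rate = "k12",
                                      cycle = c("O1", "O2", gate2, gate1))),
                       statistical_factors = statistical_factors)
}

## ---- glutamate binding extension ----------------------------------------

binding_moves <- function() {
  mv <- list()
  for (g in c("0", "1")) {
    mv <- c(mv, list(c(paste0(g, "u"), paste0(g, "b"), "kp_a"),
                     c(paste0(g, "b"), paste0(g, "u"), "km_a"),
                     c(paste0(g, "b"), paste0(g, "g"), "kp_s"),
                     c(paste0(g, "g"), paste0(g, "b"), "km_s")))
  }
  for (x in c("u", "b", "g")) {
    mv <- c(mv, list(c(paste0("0", x), paste0("1", x), "kp_f"),
                     c(paste0("1", x), paste0("0", x), "km_f")))
  }
  c(mv, list(c("1g", "D", "kp_d"), c("D", "1g", "km_d")))
}

#' Glutamate-binding extension of the tetrameric mechanism
#'
#' Adds explicit glutamate binding to [build_dimer_desensitization()]:
#' each dimer's GluN2 site is unbound (`u`), bound (`b`) or bound-and-gated
#' (`g`). Glutamate associates at `kp_a * [glu]` and dissociates at `km_a`,
#' both only while the GluN2 pre-gating step has not occurred; GluN2
#' pre-gating proceeds only from the bound site (the rate from an unbound
#' subunit is zero); GluN1 pre-gating is glutamate-independent (glycine is
#' taken as saturating). Desensitization requires all four subunits
#' agonist-bound with a fully activated dimer, and while any dimer is
#' desensitized agonist exchange is frozen on the whole receptor (agonist
#' trapping), which keeps every cycle reversible; configurations pairing a
#' desensitized dimer with an unbound partner are therefore unreachable and
#' are excluded. Channel opening requires all four subunits bound: O1 opens
#' from both dimers fully activated, O2 from one fully activated dimer with
#' the partner GluN2 bound but not yet gated.
#'
#' @inheritParams build_tetramer
#' @param rates an [nmda_rates()] set including `kp_d`, `km_d`, `kp_a`,
#'   `km_a`.
#' @return A [mechanism()] with 26 shut and 2 open states; assemble with
#'   `assemble_q(mech, c(glu = <molar>))`.
#' @export
build_binding_extended <- function(rates, statistical_factors = TRUE) {
  need_rates(rates, c("k12", "k21", "alpha1", "beta1", "alpha2", "beta2",
                      "kp_f", "km_f", "kp_s", "km_s", "kp_d", "km_d",
                      "kp_a", "km_a"))
  codes <- c("0u", "0b", "0g", "1u", "1b", "1g", "D")
  rp <- c(gating_rate_params(rates),
          list(kp_d = rate_param("kp_d", rates$kp_d),
               km_d = rate_param("km_d", rates$km_d),
               kp_a = rate_param("kp_a", rates$kp_a, ligand = "glu"),
               km_a = rate_param("km_a", rates$km_a)))
  gate1 <- pair_id("1g", "1g", codes)
  gate2 <- pair_id("1g", "1b", codes)
  open_spec <- list(
    states = data.frame(id = c("O1", "O2"), class = "open",
                        dimer1 = NA, dimer2 = NA, stringsAsFactors = FALSE),
    transitions = data.frame(
      from = c(gate1, "O1", gate2, "O2", "O2", "O1"),
      to = c("O1", gate1, "O2", gate2, "O1", "O2"),
      rate = c("beta1", "alpha1", "beta2", "alpha2", "k21", "k12"),
      factor = 1L, stringsAsFactors = FALSE))
  bound <- function(code) substr(code, 2, 2) %in% c("b", "g") || code == "D"
  move_allowed <- function(mv, other) {
    if (mv[3] %in% c("kp_d", "km_d")) return(bound(other))
    ## agonist trapping: no binding or unbinding while a dimer is desensitized
    if (mv[3] %in% c("kp_a", "km_a")) return(other != "D")
    TRUE
  }
  build_pair_mechanism(codes, binding_moves(), open_spec, rp,
                       mr = list(list(rate = "k12",
                                      cycle = c("O1", "O2", gate2, gate1))),
                       statistical_factors = statistical_factors,
                       move_allowed = move_allowed,
                       pair_allowed = function(a, b)
                         !(("D" %in% c(a, b)) &&
                             any(substr(c(a, b), 2, 2) == "u")))
}

## ---- all-four-gateway alternative ---------------------------------------

#' Alternative scheme: opening only after all four pre-gating steps
#'
#' Identical closed-state structure to the corresponding two-gateway builder,
#' but the only closed-to-open gateway is the fully gated configuration,
#' connected to O1 via `beta1`/`alpha1`, with O2 reached from O1 in series
#' via `k12`/`k21`. There is no cycle through the open states, so `k12` is a
#' free parameter. `alpha2`/`beta2` must not be supplied (no second gateway
#' exists in this topology).
#'
#' @inheritParams build_tetramer
#' @param rates an [nmda_rates()] set without `alpha2`/`beta2`; `kp_d`/`km_d`
#'   required for `extension != "grid"`, `kp_a`/`km_a` for
#'   `extension = "binding"`.
#' @param extension closed-state structure: plain `"grid"` (no
#'   desensitization), `"dimer"` (dimer-dependent desensitization) or
#'   `"binding"` (explicit glutamate binding).
#' @return A [mechanism()].
#' @export
build_all_four_gate <- function(rates, extension = c("dimer", "grid", "binding"),
                                statistical_factors = TRUE) {
  extension <- match.arg(extension)
  if (!is.null(rates$alpha2) || !is.null(rates$beta2))
    stop("alpha2/beta2 do not exist in the all-four-gateway topology")
  need_rates(rates, c("k12", "k21", "alpha1", "beta1",
                      "kp_f", "km_f", "kp_s", "km_s"))
  sf <- statistical_factors
  rp <- gating_rate_params(rates, two_open = FALSE)
  if (extension == "grid") {
    base <- build_tetramer(c(rates, list(alpha2 = 1, beta2 = 1)),
                           statistical_factors = sf)
    gate <- "C22"
  } else if (extension == "dimer") {
    base <- build_dimer_desensitization(c(rates, list(alpha2 = 1, beta2 = 1)),
                                        statistical_factors = sf)
    gate <- pair_id("11", "11", c("00", "01", "10", "11", "D"))
  } else {
    base <- build_binding_extended(c(rates, list(alpha2 = 1, beta2 = 1)),
                                   statistical_factors = sf)
    gate <- pair_id("1g", "1g", c("0u", "0b", "0g", "1u", "1b", "1g", "D"))
  }
  ## strip the O2 gateway and rewire O2 in series behind O1
  tr <- base$transitions
  drop <- (tr$rate %in% c("alpha2", "beta2"))
  tr <- tr[!drop, , drop = FALSE]
  states <- base$states
  rates_list <- base$rates[setdiff(names(base$rates), c("alpha2", "beta2"))]
  rates_list$k12$value <- rates$k12   # free again: undo the base builder's MR
  mechanism(states, rates_list, tr, constraints = list())  # k12 free, no MR
}

#' Number of free rate parameters of a mechanism
#'
#' Counts rate constants minus fixed rates, equality ties and
#' MR-constrained rates.
#'
#' @param mech a [mechanism()].
#' @return Integer count.
#' @export
n_free_rates <- function(mech) {
  length(mech$rates) - length(mech$constraints$fixed) -
    length(mech$constraints$equal) - length(mech$constraints$mr)
}
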