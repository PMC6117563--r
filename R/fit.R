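#' Reduce rate constraints to a free parameterization
#'
#' Fitting works on log-transformed rates, where fixed values, equality ties
#' and microscopic-reversibility conditions are all linear. The constraint
#' system `A x = b` (x = log rates) is reduced by orthogonal (QR)
#' factorization to a parameterization `x = x0 + N theta` in which every
#' feasible rate vector is reachable and every `theta` is feasible.
#'
#' @param mech a [mechanism()] whose rate values currently satisfy all of its
#'   constraints (run [apply_mr()] first if in doubt).
#' @return Object of class `free_param_map`: list with `names`, `x0`, `N`,
#'   `n_free`, plus the raw system `A`, `b`.
#' @export
reduce_constraints <- function(mech) {
  nm <- names(mech$rates)
  n <- length(nm)
  x0 <- log(rate_values(mech))
  rows <- list(); b <- numeric(0)
  add_row <- function(coef, rhs) {
    rows[[length(rows) + 1L]] <<- coef
    b <<- c(b, rhs)
  }
  for (f in mech$constraints$fixed) {
    coef <- numeric(n); names(coef) <- nm
    coef[f] <- 1
    add_row(coef, x0[f])
  }
  for (eq in mech$constraints$equal) {
    coef <- numeric(n); names(coef) <- nm
    coef[eq[1]] <- 1; coef[eq[2]] <- -1
    add_row(coef, 0)
  }
  look <- transition_lookup(mech)
  for (mrc in mech$constraints$mr) {
    cyc <- mrc$cycle; m <- length(cyc)
    coef <- numeric(n); names(coef) <- nm
    rhs <- 0
    for (s in seq_len(m)) {
      a <- cyc[s]; to <- cyc[if (s == m) 1L else s + 1L]
      i_f <- look[paste(a, to, sep = "\r")]
      i_r <- look[paste(to, a, sep = "\r")]
      rf <- mech$transitions$rate[i_f]; rr <- mech$transitions$rate[i_r]
      coef[rf] <- coef[rf] + 1
      rhs <- rhs - log(mech$transitions$factor[i_f])
      coef[rr] <- coef[rr] - 1
      rhs <- rhs + log(mech$transitions$factor[i_r])
    }
    add_row(coef, rhs)
  }
  if (length(rows)) {
    A <- do.call(rbind, rows)
    qrA <- qr(t(A))
    if (qrA$rank < nrow(A))
      stop("redundant (rank-deficient) constraints: rank ", qrA$rank,
           " < ", nrow(A), " rows")
    if (max(abs(A %*% x0 - b)) > 1e-8)
      stop("current rate values do not satisfy the declared constraints")
    Qc <- qr.Q(qrA, complete = TRUE)
    N <- Qc[, seq.int(qrA$rank + 1L, n), drop = FALSE]
  } else {
    A <- matrix(0, 0, n); N <- diag(n)
  }
  structure(list(names = nm, x0 = x0, N = N, n_free = ncol(N), A = A, b = b),
            class = "free_param_map")
}

#' @export
print.free_param_map <- function(x, ...) {
  cat("<free_param_map> ", length(x$names), " rates, ",
      nrow(x$A), " constraints, ", x$n_free, " free parameters\n", sep = "")
  invisible(x)
}

#' Map free parameters to rate values (and back)
#'
#' @param map a [reduce_constraints()] result.
#' @param theta free-parameter vector (log-rate space).
#' @return `rates_from_theta()`: named vector of rates;
#'   `theta_from_rates()`: free-parameter vector.
#' @export
rates_from_theta <- function(map, theta) {
  stats::setNames(as.numeric(exp(map$x0 + map$N %*% theta)), map$names)
}

#' @rdname rates_from_theta
#' @param rates named vector of rate values satisfying the constraints.
#' @export
theta_from_rates <- function(map, rates) {
  as.numeric(crossprod(map$N, log(rates[map$names]) - map$x0))
}

## likelihood evaluator closure shared by fitting and profiling
make_ll_fun <- function(mech, dwells, dt, start, tcrit, concentrations,
                        score_data = NULL) {
  sd <- score_data %||%
    prepare_score_data(split_for_scoring(dwells, dt, start, tcrit)$segments)
  shift_first <- if (start == "burst") dt$tau_open else 0
  n <- sd$n_seg
  function(mech2) {
    q <- assemble_q(mech2, concentrations)
    setup <- hjc_setup(q, dt)
    if (start == "burst") {
      bv <- chs_vectors(setup, tcrit)
      phi <- rep(list(bv$initial), n); fin <- rep(list(bv$final), n)
    } else {
      p0 <- setup$p[setup$A]; p0 <- p0 / sum(p0)
      phi <- rep(list(as.numeric(p0)), n); fin <- rep(list(rep(1, setup$kA)), n)
    }
    loglik_call(setup, sd, phi, fin, shift_first)
  }
}

#' Maximum-likelihood fit of rate constants to a dwell sequence
#'
#' Quasi-Newton (BFGS) ascent of the missed-event log-likelihood over the
#' free parameters of the constraint-reduced log-rate space, with a
#' Nelder-Mead refinement pass if BFGS fails to converge. Deterministic given
#' the initial rates and options.
#'
#' @inheritParams hjc_loglik
#' @param options list: `initial_rates` (named vector; defaults to the
#'   mechanism's current values), `seed` (when given and no initial rates are
#'   supplied, the current values are perturbed by factors U(0.5, 2)),
#'   `max_iter` (default 500), `reltol` (default 1e-10).
#' @return Object of class `scfit`: free-parameter estimates, full rate
#'   table, log-likelihood, convergence diagnostics, and the context needed
#'   by [profile_loglik()] and [profile_interval()].
#' @export
maximize_likelihood <- function(mech, dwells, dt,
                                start = c("equilibrium", "burst"),
                                tcrit = NULL, concentrations = numeric(0),
                                options = list()) {
  start <- match.arg(start)
  if (start == "burst" && is.null(tcrit)) stop("burst start needs tcrit")
  o <- utils::modifyList(list(initial_rates = NULL, seed = NULL,
                              max_iter = 500L, reltol = 1e-10,
                              score_data = NULL), options)
  mech <- apply_mr(mech)
  if (!is.null(o$initial_rates)) {
    mech <- set_rates(mech, o$initial_rates)
  } else if (!is.null(o$seed)) {
    set.seed(o$seed)
    constrained <- c(mech$constraints$fixed,
                     vapply(mech$constraints$mr, `[[`, "", "rate"))
    free_nm <- setdiff(names(mech$rates), constrained)
    fac <- stats::runif(length(free_nm), 0.5, 2)
    mech <- set_rates(mech, stats::setNames(
      rate_values(mech)[free_nm] * fac, free_nm))
  }
  map <- reduce_constraints(mech)
  sd <- o$score_data %||%
    prepare_score_data(split_for_scoring(dwells, dt, start, tcrit)$segments)
  llf <- make_ll_fun(mech, dwells, dt, start, tcrit, concentrations,
                     score_data = sd)
  negll <- function(theta) {
    r <- rates_from_theta(map, theta)
    m2 <- mech
    for (nm in map$names) m2$rates[[nm]]$value <- r[[nm]]
    ll <- tryCatch(llf(m2), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  theta0 <- rep(0, map$n_free)
  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = o$max_iter, reltol = o$reltol,
                                     ndeps = rep(1e-5, map$n_free)))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 2000,
                                        reltol = o$reltol))
    if (opt2$value < opt$value) opt <- opt2
  }
  rates <- rates_from_theta(map, opt$par)
  mech_hat <- set_rates(mech, rates)
  structure(list(theta = opt$par, rates = rates, loglik = -opt$value,
                 converged = opt$convergence == 0,
                 counts = opt$counts, message = opt$message,
                 map = map, mech = mech_hat, dt = dt, start = start,
                 tcrit = tcrit, concentrations = concentrations,
                 dwells = dwells, seed = o$seed, score_data = sd,
                 n_dwells = nrow(dwells)),
            class = "scfit")
}

#' @export
print.scfit <- function(x, ...) {
  cat("<scfit> ", x$map$n_free, " free parameters, ", x$n_dwells,
      " dwells, start = ", x$start, "\n", sep = "")
  cat("  log-likelihood ", format(x$loglik, nsmall = 1),
      if (!x$converged) "  (NOT converged)", "\n", sep = "")
  print(signif(x$rates, 4))
  invisible(x)
}

#' Profile log-likelihood at a fixed rate value
#'
#' Fixes one rate constant and re-maximizes the likelihood over the remaining
#' free parameters.
#'
#' @param fit an [maximize_likelihood()] result.
#' @param param rate name (must be free in the fit).
#' @param value value (s^-1) at which to fix it.
#' @return List with `loglik` and the refit's `rates`.
#' @export
profile_loglik <- function(fit, param, value) {
  mech <- set_rates(fit$mech, stats::setNames(value, param))
  mech$constraints$fixed <- union(mech$constraints$fixed, param)
  refit <- maximize_likelihood(mech, fit$dwells, fit$dt, fit$start,
                               fit$tcrit, fit$concentrations,
                               options = list(initial_rates = rate_values(mech),
                                              score_data = fit$score_data))
  list(loglik = refit$loglik, rates = refit$rates)
}

#' Profile-likelihood interval for a fitted rate
#'
#' Finds the values of one rate at which the profile log-likelihood (all
#' other free parameters re-optimized) falls `delta_ll` units below its
#' maximum, stepping geometrically away from the estimate and interpolating
#' the crossing with a cubic polynomial in log-rate.
#'
#' @param fit an [maximize_likelihood()] result (converged).
#' @param param rate name.
#' @param delta_ll log-likelihood drop defining the interval (0.5 for the
#'   conventional interval, 2 for an approximate 95\% interval).
#' @param step_factor geometric step between probe points.
#' @param max_steps probes per side; an interval edge not bracketed within
#'   these is reported as open-ended (`-Inf`/`Inf`).
#' @return Numeric `c(lo, hi)` with attribute `profile` (probe table).
#' @export
profile_interval <- function(fit, param, delta_ll = 0.5,
                             step_factor = exp(0.15), max_steps = 25L) {
  v0 <- fit$rates[[param]]
  ll0 <- fit$loglik
  drop <- ll0 - delta_ll
  probes <- data.frame(value = v0, loglik = ll0)
  prof <- function(v) {
    pl <- profile_loglik(fit, param, v)$loglik
    probes <<- rbind(probes, data.frame(value = v, loglik = pl))
    pl
  }
  side <- function(dir) {
    ## step geometrically until the profile falls below the target drop
    v_in <- v0; v <- v0; pl <- ll0
    for (i in seq_len(max_steps)) {
      v_in <- v
      v <- v * step_factor^dir
      pl <- prof(v)
      if (pl < drop) break
    }
    if (pl >= drop) return(if (dir < 0) -Inf else Inf)
    br <- sort(log(c(v_in, v)))
    root <- stats::uniroot(function(lv) prof(exp(lv)) - drop, br,
                           tol = 1e-4)$root
    ## cubic polish through the probes nearest the crossing
    pr <- probes[!duplicated(probes$value), ]
    x <- log(pr$value); y <- pr$loglik
    use <- order(abs(x - root))[seq_len(min(4, length(x)))]
    if (length(use) >= 3) {
      fitp <- stats::lm(y ~ poly(x, degree = min(3, length(use) - 1),
                                 raw = TRUE),
                        data = data.frame(x = x[use], y = y[use]))
      g <- function(z) stats::predict(fitp,
                                      newdata = data.frame(x = z)) - drop
      root <- tryCatch(stats::uniroot(g, br)$root, error = function(e) root)
    }
    exp(root)
  }
  lo <- side(-1); hi <- side(1)
  structure(c(lo = lo, hi = hi), profile = probes[order(probes$value), ])
}

#' Objective surface over a parameter pair
#'
#' Evaluates an objective on the outer product of two parameter grids.
#'
#' @param objective function of two scalar parameter values returning the
#'   objective (e.g. a log-likelihood with other rates fixed or
#'   re-optimized, or a macroscopic sum of squares).
#' @param values1,values2 grid values for the two parameters.
#' @return Matrix of objective values (`values1` in rows).
#' @export
sensitivity_surface <- function(objective, values1, values2) {
  if (!length(values1) || !length(values2))
    return(matrix(numeric(0), length(values1), length(values2)))
  out <- outer(values1, values2,
               Vectorize(function(a, b) objective(a, b)))
  dimnames(out) <- list(signif(values1, 6), signif(values2, 6))
  out
}

#' Likelihood-ratio comparison of two nested fits
#'
#' Twice the log-likelihood difference referred to a chi-squared distribution
#' with degrees of freedom equal to the difference in free parameter counts.
#'
#' @param fit_big,fit_small [maximize_likelihood()] results, the first
#'   nesting the second.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(fit_big, fit_small) {
  stat <- 2 * (fit_big$loglik - fit_small$loglik)
  df <- fit_big$map$n_free - fit_small$map$n_free
  if (df <= 0) stop("fit_big must have more free parameters")
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}
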