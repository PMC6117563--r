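#' Dead times (time resolution) of an idealized record
#'
#' @param tau_open,tau_shut resolutions in seconds for open and shut events;
#'   events shorter than these are taken to have been missed.
#' @return Object of class `dead_times`.
#' @export
dead_times <- function(tau_open, tau_shut = tau_open) {
  stopifnot(tau_open > 0, tau_shut > 0)
  structure(list(tau_open = as.numeric(tau_open),
                 tau_shut = as.numeric(tau_shut)), class = "dead_times")
}

## (1 - exp(-x tau))/x with the analytic limit at x -> 0
f_phi <- function(x, tau) {
  y <- x * tau
  small <- abs(y) < 1e-6
  out <- numeric(length(x))
  out[small] <- tau * (1 - y[small] / 2 + y[small]^2 / 6)
  out[!small] <- (1 - exp(-y[!small])) / x[!small]
  out
}

## d/ds of f_phi's contribution to W: (1-e^{-x tau})/x^2 - tau e^{-x tau}/x
g_phi <- function(x, tau) {
  y <- x * tau
  small <- abs(y) < 1e-4
  out <- numeric(length(x))
  out[small] <- tau^2 * (1 / 2 - y[small] / 3 + y[small]^2 / 8)
  xs <- x[!small]; ys <- y[!small]
  out[!small] <- (1 - exp(-ys)) / xs^2 - tau * exp(-ys) / xs
  out
}

## W(s) = s I - H(s) machinery for one aggregate, where H(s) folds missed
## sojourns in the complementary aggregate (shorter than tau) into the
## sub-generator. Returns closures W(s), Wp(s) = dW/ds and H(s). When the
## chain is reversible (equilibrium p supplied), also provides the
## symmetrised form T(s) = D^1/2 H(s) D^-1/2 = Qaa_sym + M diag(f) M^T,
## whose eigenvalue branches give a robust root search.
wmat_factory <- function(Q, a_idx, f_idx, tau, p = NULL) {
  Qaa <- Q[a_idx, a_idx, drop = FALSE]
  Qaf <- Q[a_idx, f_idx, drop = FALSE]
  Qfa <- Q[f_idx, a_idx, drop = FALSE]
  Qff <- Q[f_idx, f_idx, drop = FALSE]
  pf <- if (!is.null(p)) p[f_idx] / sum(p[f_idx]) else NULL
  sp <- q_spectral(Qff, p = pf)
  L <- Qaf %*% sp$V
  R <- sp$Vinv %*% Qfa
  d <- sp$values
  kA <- length(a_idx)
  out <- list(
    H = function(s) Qaa + L %*% (f_phi(s - d, tau) * R),
    W = function(s) diag(s, kA) - H_eval(Qaa, L, R, d, tau, s),
    Wp = function(s) diag(1, kA) + L %*% (g_phi(s - d, tau) * R),
    detW = function(s) detw_batch(s, Qaa, L, R, d, tau),
    sub_eigs = eigen(Qaa, only.values = TRUE)$values
  )
  if (!is.null(p)) {
    sa <- sqrt(p[a_idx])                  # global equilibrium weights
    sf <- sqrt(p[f_idx])
    Qaa_sym <- Qaa * outer(sa, 1 / sa)
    sym_ok <- max(abs(Qaa_sym - t(Qaa_sym))) < 1e-7 * max(abs(Qaa), 1)
    B <- (Qaf * outer(sa, 1 / sf))        # D_A^1/2 Qaf D_F^-1/2
    Qffs <- Qff * outer(sf, 1 / sf)
    if (sym_ok && max(abs(Qffs - t(Qffs))) < 1e-7 * max(abs(Qff), 1)) {
      es <- eigen((Qffs + t(Qffs)) / 2, symmetric = TRUE)
      M <- B %*% es$vectors
      ds <- es$values
      out$Qs <- (Qaa_sym + t(Qaa_sym)) / 2
      out$M <- M
      out$ds <- ds
      out$Tsym <- function(s) {
        S <- out$Qs + M %*% (f_phi(s - ds, tau) * t(M))
        (S + t(S)) / 2
      }
      out$Tp <- function(s) M %*% (g_phi(s - ds, tau) * t(M))
      out$sa <- sa
    }
  }
  out
}

H_eval <- function(Qaa, L, R, d, tau, s) Qaa + L %*% (f_phi(s - d, tau) * R)

#' Asymptotic dwell-time roots and area matrices
#'
#' Locates the roots `s_k` of `det W(s) = 0` governing the asymptotic
#' (long-dwell) missed-event-corrected dwell distribution of one aggregate,
#' together with the spectral area matrices `R_k = c r / (r W'(s_k) c)`.
#' Roots are bracketed starting from the eigenvalues of the uncorrected
#' sub-generator, located by scanning for sign changes and refined by
#' bisection; a count mismatch signals an ill-conditioned mechanism and is an
#' error.
#'
#' @param q a `q_matrix`.
#' @param dt a [dead_times()] object.
#' @param aggregate `"open"` or `"shut"`.
#' @return List with `roots` (all real, negative; one per state of the
#'   aggregate) and `areas` (list of matrices).
#' @export
asymptotic_roots <- function(q, dt, aggregate = c("open", "shut")) {
  aggregate <- match.arg(aggregate)
  q <- as_q(q)
  idx <- which(q$class == if (aggregate == "open") "open" else "shut")
  oth <- setdiff(seq_along(q$class), idx)
  tau <- if (aggregate == "open") dt$tau_shut else dt$tau_open
  p <- tryCatch(equilibrium_dist(q), error = function(e) NULL)
  fac <- wmat_factory(q$Q, idx, oth, tau, p = p)
  k <- length(idx)
  detW <- fac$detW
  sub <- sort(Re(fac$sub_eigs))
  lo0 <- 2 * min(sub, Re(eigen(q$Q, only.values = TRUE)$values))
  bisect_all <- function(fun, lo_b, hi_b, flo) {
    for (it in 1:60) {
      mid <- (lo_b + hi_b) / 2
      fm <- fun(mid)
      left <- flo * fm <= 0
      hi_b[left] <- mid[left]
      lo_b[!left] <- mid[!left]; flo[!left] <- fm[!left]
    }
    (lo_b + hi_b) / 2
  }
  ## roots span many decades: work on a log-magnitude grid
  log_grid <- function(npts) {
    hi_mag <- abs(lo0)
    lo_mag <- hi_mag * 1e-10
    sort(-exp(seq(log(lo_mag), log(hi_mag), length.out = npts)))
  }
  roots <- NULL
  if (!is.null(fac$Tsym)) {
    ## reversible chain: bisect each eigenvalue branch of the symmetrised
    ## H(s) against s (robust to nearly degenerate roots)
    roots <- sym_branch_roots(fac$Qs, fac$M, fac$ds, tau, log_grid(240L))
    if (length(roots) > 1)
      roots <- roots[c(TRUE, diff(roots) > 1e-10 * abs(roots[-1]))]
    if (length(roots) != k) roots <- NULL
  }
  if (is.null(roots)) {
    ## general path: scan det W for sign changes
    for (npts in c(1024L, 8192L, 32768L)) {
      xs <- log_grid(npts)
      fs <- detW(xs)
      chg <- which(fs[-1] * fs[-npts] < 0)
      if (length(chg) == k) {
        roots <- bisect_all(detW, xs[chg], xs[chg + 1], fs[chg])
        break
      }
    }
  }
  if (length(roots) != k)
    stop("asymptotic root count mismatch for the ", aggregate,
         " aggregate (expected ", k, ", found ", length(roots), ")")
  roots <- sort(roots)
  areas <- lapply(roots, function(s) {
    if (!is.null(fac$Tsym)) {
      e <- eigen(fac$Tsym(s), symmetric = TRUE)
      u <- e$vectors[, which.min(abs(e$values - s))]
      cvec <- u / fac$sa
      rvec <- u * fac$sa
    } else {
      sv <- svd(fac$W(s))
      cvec <- sv$v[, k]
      rvec <- sv$u[, k]
    }
    den <- as.numeric(rvec %*% fac$Wp(s) %*% cvec)
    (cvec %*% t(rvec)) / den
  })
  list(roots = roots, areas = areas, tau = tau, W = fac$W, H = fac$H)
}

## Precompute everything needed to evaluate missed-event densities and the
## log-likelihood for a mechanism at fixed rates and dead times.
hjc_setup <- function(q, dt) {
  q <- as_q(q)
  A <- which(q$class == "open"); F_ <- which(q$class == "shut")
  kA <- length(A); kF <- length(F_)
  Q <- q$Q
  p <- equilibrium_dist(q)
  sp <- q_spectral(Q, p = p)
  pA <- p[A] / sum(p[A]); pF <- p[F_] / sum(p[F_])
  eQff <- expm_q(Q[F_, F_, drop = FALSE], dt$tau_shut,
                 q_spectral(Q[F_, F_, drop = FALSE], p = pF))
  eQaa <- expm_q(Q[A, A, drop = FALSE], dt$tau_open,
                 q_spectral(Q[A, A, drop = FALSE], p = pA))
  Mo <- Q[A, F_, drop = FALSE] %*% eQff    # terminal factor of open dwells
  Ms <- Q[F_, A, drop = FALSE] %*% eQaa    # terminal factor of shut dwells

  ro <- asymptotic_roots(q, dt, "open")
  rs <- asymptotic_roots(q, dt, "shut")
  AO <- lapply(ro$areas, function(R) R %*% Mo)   # kA x kF per root
  AS <- lapply(rs$areas, function(R) R %*% Ms)   # kF x kA per root

  ## total (time-integrated) dwell transition matrices; row-stochastic
  Go_tot <- solve(-ro$H(0), Mo)
  Gs_tot <- solve(-rs$H(0), Ms)

  ## stationary entry vectors of the alternating dwell chain
  left_unit <- function(M) {
    e <- eigen(t(M))
    v <- Re(e$vectors[, which.min(abs(e$values - 1))])
    v <- v / sum(v)
    if (min(v) < -1e-8) v <- abs(v) / sum(abs(v))
    v
  }
  phiA <- left_unit(Go_tot %*% Gs_tot)
  phiF <- left_unit(Gs_tot %*% Go_tot)

  list(q = q, dt = dt, A = A, F = F_, kA = kA, kF = kF,
       p = p, spec = sp, Mo = Mo, Ms = Ms,
       UA = sp$V[A, , drop = FALSE], BO = sp$Vinv[, A, drop = FALSE] %*% Mo,
       US = sp$V[F_, , drop = FALSE], BS = sp$Vinv[, F_, drop = FALSE] %*% Ms,
       roots_o = ro$roots, AO = AO, roots_s = rs$roots, AS = AS,
       Go_tot = Go_tot, Gs_tot = Gs_tot, phiA = phiA, phiF = phiF)
}

## integral over apparent shut times >= tcrit of the shut dwell density
## (matrix F -> A); asymptotic branch, valid for tcrit well beyond the
## exact/asymptotic switchover
shut_tail_matrix <- function(setup, tcrit) {
  v <- tcrit - setup$dt$tau_shut
  M <- matrix(0, setup$kF, setup$kA)
  for (i in seq_along(setup$roots_s))
    M <- M + setup$AS[[i]] * (exp(setup$roots_s[i] * v) / -setup$roots_s[i])
  M
}

## burst boundary vectors conditioned on the critical shut time: initial row
## vector over open states (normalised to sum 1) and final column vector over
## shut states
chs_vectors <- function(setup, tcrit) {
  tail_m <- shut_tail_matrix(setup, tcrit)
  phi <- as.numeric(setup$phiF %*% tail_m)
  phi <- phi / sum(phi)
  ef <- as.numeric(tail_m %*% rep(1, setup$kA))
  list(initial = phi, final = ef)
}

#' Missed-event-corrected dwell density matrix
#'
#' Evaluates the matrix-valued density `eG_AF(t)` of apparent open dwells (or
#' `eG_FA(t)` for shut dwells) under the assumption that all events shorter
#' than the dead times are missed. Durations up to the sum of the two dead
#' times use the exact branch; longer durations use the asymptotic
#' exponential form.
#'
#' @param q a `q_matrix`.
#' @param dt a [dead_times()].
#' @param t dwell duration in seconds (must exceed the aggregate's dead
#'   time).
#' @param aggregate `"open"` or `"shut"`.
#' @param shift dead-time shift applied to `t`; defaults to the aggregate's
#'   own dead time (the convention used within an alternating record).
#' @return A `kA x kF` (open) or `kF x kA` (shut) matrix density in s^-1.
#' @export
egar_density <- function(q, dt, t, aggregate = c("open", "shut"),
                         shift = NULL) {
  aggregate <- match.arg(aggregate)
  setup <- hjc_setup(q, dt)
  egar_density_setup(setup, t, aggregate, shift)
}

egar_density_setup <- function(setup, t, aggregate, shift = NULL) {
  dt <- setup$dt
  if (aggregate == "open") {
    tau_own <- dt$tau_open; span <- dt$tau_shut
    U <- setup$UA; B <- setup$BO; roots <- setup$roots_o; Ak <- setup$AO
  } else {
    tau_own <- dt$tau_shut; span <- dt$tau_open
    U <- setup$US; B <- setup$BS; roots <- setup$roots_s; Ak <- setup$AS
  }
  if (is.null(shift)) shift <- tau_own
  if (t <= tau_own) stop("dwell of ", t, " s is unresolvable at this dead time")
  v <- t - shift
  if (v <= span) {
    U %*% (exp(setup$spec$values * v) * B)
  } else {
    M <- 0
    for (i in seq_along(roots)) M <- M + exp(roots[i] * v) * Ak[[i]]
    M
  }
}

#' Scalar missed-event dwell-time probability density
#'
#' The apparent (resolved) dwell-time pdf of one aggregate, scalarized with
#' the stationary entry vector of the alternating dwell chain, normalised
#' over durations above the dead time.
#'
#' @inheritParams egar_density
#' @param t vector of durations (s), each above the aggregate's dead time.
#' @param setup optional precomputed internal setup (recomputed if `NULL`).
#' @return Numeric vector of densities (s^-1).
#' @export
hjc_pdf <- function(q, dt, t, aggregate = c("open", "shut"), setup = NULL) {
  aggregate <- match.arg(aggregate)
  if (is.null(setup)) setup <- hjc_setup(q, dt)
  co <- pdf_coefs(setup, aggregate)
  vapply(t, function(tt) {
    v <- tt - co$tau_own
    if (v < 0) return(0)
    if (v <= co$span) sum(co$c_exact * exp(setup$spec$values * v))
    else sum(co$c_asym * exp(co$roots * v))
  }, numeric(1))
}

## scalarization coefficients for the stationary dwell pdf
pdf_coefs <- function(setup, aggregate) {
  if (aggregate == "open") {
    phi <- setup$phiA
    tau_own <- setup$dt$tau_open; span <- setup$dt$tau_shut
    U <- setup$UA; B <- setup$BO; roots <- setup$roots_o; Ak <- setup$AO
  } else {
    phi <- setup$phiF
    tau_own <- setup$dt$tau_shut; span <- setup$dt$tau_open
    U <- setup$US; B <- setup$BS; roots <- setup$roots_s; Ak <- setup$AS
  }
  kout <- ncol(B)
  u <- rep(1, kout)
  list(c_exact = as.numeric(phi %*% U) * as.numeric(B %*% u),
       c_asym = vapply(Ak, function(M) sum(phi %*% M), numeric(1)),
       roots = roots, tau_own = tau_own, span = span)
}

## exact integral of the stationary scalar pdf over duration bins
hjc_pdf_bin_mass <- function(setup, breaks, aggregate) {
  co <- pdf_coefs(setup, aggregate)
  int_exp <- function(coef, lambda, a, b) {
    ## integral of sum coef_i exp(lambda_i v) over [a, b]; the series branch
    ## covers near-zero exponents where exp differences underflow
    small <- abs(lambda * b) < 1e-8
    z <- numeric(length(lambda))
    z[small] <- (b - a) * (1 + lambda[small] * (a + b) / 2)
    z[!small] <- (exp(lambda[!small] * b) - exp(lambda[!small] * a)) /
      lambda[!small]
    sum(coef * z)
  }
  piece <- function(a, b) {
    ## integrate over v in [a, b] with branch switch at span
    m <- 0
    if (a < co$span) m <- m + int_exp(co$c_exact, setup$spec$values,
                                      a, min(b, co$span))
    if (b > co$span) m <- m + int_exp(co$c_asym, co$roots,
                                      max(a, co$span), b)
    m
  }
  v <- pmax(breaks - co$tau_own, 0)
  vapply(seq_len(length(v) - 1L), function(i) piece(v[i], v[i + 1]),
         numeric(1))
}

## relative branch mismatch of the scalar pdf at the exact/asymptotic
## switchover (diagnostic)
branch_continuity <- function(q, dt) {
  setup <- hjc_setup(q, dt)
  out <- c(open = NA_real_, shut = NA_real_)
  for (agg in c("open", "shut")) {
    co <- pdf_coefs(setup, agg)
    fe <- sum(co$c_exact * exp(setup$spec$values * co$span))
    fa <- sum(co$c_asym * exp(co$roots * co$span))
    out[agg] <- abs(fe - fa) / abs(fe)
  }
  out
}

## ---- log-likelihood ------------------------------------------------------

## flatten scoring segments (list of data.frames with columns class,
## duration) into the per-dwell arrays consumed by the C++ propagator
prepare_score_data <- function(segments) {
  seg_id <- rep(seq_along(segments), vapply(segments, nrow, integer(1)))
  list(t = unlist(lapply(segments, function(s) s$duration), use.names = FALSE),
       is_open = as.integer(unlist(lapply(segments,
                                          function(s) s$class == "open"),
                                   use.names = FALSE)),
       seg_id = as.integer(seg_id),
       first = !duplicated(seg_id),
       n_seg = length(segments))
}

loglik_call <- function(setup, segments, phi, fin, shift_first = 0) {
  sd <- if (is.data.frame(segments[[1]])) prepare_score_data(segments)
        else segments
  hjc_loglik_cpp(sd$t, sd$is_open, sd$seg_id, sd$first,
                 shift_first,
                 setup$dt$tau_open, setup$dt$tau_shut,
                 setup$dt$tau_shut, setup$dt$tau_open,
                 setup$spec$values,
                 setup$UA, setup$BO, setup$US, setup$BS,
                 setup$roots_o, unlist(setup$AO),
                 setup$roots_s, unlist(setup$AS),
                 phi, fin)
}

#' Missed-event log-likelihood of an idealized record
#'
#' Computes the total log-likelihood of a resolved dwell sequence under a
#' mechanism with dead-time correction: the product of matrix dwell densities
#' propagated along the alternating record, with per-dwell rescaling. With
#' `start = "equilibrium"`, each record segment is scored from the
#' equilibrium occupancies of the open states (segments separated by shut
#' times of at least `tcrit`, when given, are scored independently). With
#' `start = "burst"`, bursts are delimited at `tcrit` and each burst is
#' scored with boundary vectors conditioned on its flanking long shut times.
#'
#' @param dwells a [dwell_sequence()] whose durations all exceed the dead
#'   times (see [impose_resolution()]).
#' @param mech a [mechanism()], or a `q_matrix`.
#' @param dt a [dead_times()].
#' @param start `"equilibrium"` or `"burst"`.
#' @param tcrit critical shut time in seconds (required for
#'   `start = "burst"`).
#' @param concentrations ligand concentrations for Q assembly, if needed.
#' @return Log-likelihood (scalar). `-Inf` for an impossible record.
#' @export
hjc_loglik <- function(dwells, mech, dt, start = c("equilibrium", "burst"),
                       tcrit = NULL, concentrations = numeric(0)) {
  start <- match.arg(start)
  q <- as_q(mech, concentrations)
  setup <- hjc_setup(q, dt)
  parts <- split_for_scoring(dwells, dt, start, tcrit)
  n <- length(parts$segments)
  if (start == "burst") {
    bv <- chs_vectors(setup, tcrit)
    phi <- rep(list(bv$initial), n)
    fin <- rep(list(bv$final), n)
    ## the boundary vectors already carry the dead-time survival of the
    ## flanking gaps, so the first opening is scored like an in-sequence one
    shift_first <- dt$tau_open
  } else {
    p0 <- setup$p[setup$A]; p0 <- p0 / sum(p0)
    phi <- rep(list(as.numeric(p0)), n)
    fin <- rep(list(rep(1, setup$kA)), n)
    shift_first <- 0
  }
  loglik_call(setup, parts$segments, phi, fin, shift_first)
}

## split a dwell_sequence into scoring segments; validates alternation and
## resolvability
split_for_scoring <- function(dwells, dt, start, tcrit) {
  df <- as.data.frame(dwells)
  if (any(df$class == "open" & df$duration <= dt$tau_open) ||
      any(df$class == "shut" & df$duration <= dt$tau_shut))
    stop("record contains unresolved dwells; run impose_resolution() first")
  segs <- list()
  for (s in split(df, df$segment)) {
    cl <- s$class
    if (any(cl[-1] == cl[-length(cl)]))
      stop("dwell classes must alternate within a segment")
    ## trim to start open, end shut/open depending on mode
    i0 <- match("open", cl)
    if (is.na(i0)) stop("segment contains no opening")
    s <- s[i0:nrow(s), , drop = FALSE]
    if (start == "burst") {
      ## split at long gaps; bursts end with an opening
      gap <- s$class == "shut" & s$duration >= tcrit
      grp <- cumsum(gap)
      for (b in split(s[!gap, , drop = FALSE], grp[!gap])) {
        if (nrow(b) == 0) next
        ## must start and end open
        i1 <- match("open", b$class)
        i2 <- max(which(b$class == "open"))
        if (is.na(i1) || i2 < i1) next
        segs[[length(segs) + 1L]] <- b[i1:i2, , drop = FALSE]
      }
    } else {
      if (!is.null(tcrit)) {
        gap <- s$class == "shut" & s$duration >= tcrit
        grp <- cumsum(c(0, utils::head(gap, -1)))
        pieces <- split(s, grp)
      } else pieces <- list(s)
      for (p in pieces) {
        i1 <- match("open", p$class)
        if (is.na(i1)) next
        i2 <- max(which(p$class == "shut"))
        if (is.na(i2) || i2 < i1) next
        segs[[length(segs) + 1L]] <- p[i1:i2, , drop = FALSE]
      }
    }
  }
  if (!length(segs)) stop("no scorable segments in record")
  list(segments = segs)
}
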