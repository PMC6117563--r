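#' Alternating open/shut dwell sequence
#'
#' Container for an idealized single-channel record: alternating dwell
#' classes with durations in seconds, an optional segment index (independent
#' records), the imposed time resolution and, after [segment_bursts()], a
#' per-dwell burst id.
#'
#' @param durations numeric vector of dwell durations (s), all positive.
#' @param classes character vector (`"open"`/`"shut"`), or 0/1 with 1 = open.
#' @param segment integer segment index per dwell (default all 1).
#' @param resolution optional [dead_times()] recording the imposed
#'   resolution.
#' @return A data.frame of class `dwell_sequence` with columns `segment`,
#'   `class`, `duration`.
#' @export
dwell_sequence <- function(durations, classes, segment = 1L,
                           resolution = NULL) {
  if (length(durations) == 0L)
    return(structure(data.frame(segment = integer(0), class = character(0),
                                duration = numeric(0)),
                     resolution = resolution,
                     class = c("dwell_sequence", "data.frame")))
  if (is.numeric(classes)) classes <- ifelse(classes > 0, "open", "shut")
  stopifnot(length(durations) == length(classes),
            all(classes %in% c("open", "shut")))
  if (any(!is.finite(durations) | durations <= 0))
    stop("all durations must be positive")
  df <- data.frame(segment = as.integer(segment), class = classes,
                   duration = as.numeric(durations),
                   stringsAsFactors = FALSE)
  for (s in split(df$class, df$segment)) {
    if (any(s[-1] == s[-length(s)]))
      stop("dwell classes must alternate within a segment")
  }
  structure(df, resolution = resolution,
            class = c("dwell_sequence", "data.frame"))
}

#' @export
print.dwell_sequence <- function(x, ...) {
  cat("<dwell_sequence> ", nrow(x), " dwells in ",
      length(unique(x$segment)), " segment(s); total ",
      signif(sum(x$duration), 4), " s, P(open) = ",
      signif(sum(x$duration[x$class == "open"]) / sum(x$duration), 3), "\n",
      sep = "")
  res <- attr(x, "resolution")
  if (!is.null(res))
    cat("  resolution: tau_open ", res$tau_open * 1e6, " us, tau_shut ",
        res$tau_shut * 1e6, " us\n", sep = "")
  invisible(x)
}

#' Impose a time resolution (dead times) on a record
#'
#' Standard concatenation rule applied left to right within each segment:
#' an event shorter than its class dead time is unobservable, and its
#' duration is merged into the enclosing dwell of the opposite class
#' (together with any following events until the next resolvable
#' opposite-class event). Unresolvable events before the first resolvable one
#' are merged forward into it, so total record duration is conserved exactly.
#' The operation is idempotent.
#'
#' @param dwells a [dwell_sequence()].
#' @param dt a [dead_times()].
#' @return A resolved [dwell_sequence()] carrying `dt` as its resolution.
#' @export
impose_resolution <- function(dwells, dt) {
  out <- lapply(split(as.data.frame(dwells), dwells$segment), function(s) {
    r <- impose_resolution_cpp(s$duration, as.integer(s$class == "open"),
                               dt$tau_open, dt$tau_shut)
    data.frame(segment = s$segment[1],
               class = ifelse(r$classes == 1L, "open", "shut"),
               duration = r$durations, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  dwell_sequence(out$duration, out$class, out$segment, resolution = dt)
}

#' Exponential mixture distribution
#'
#' @param tau component time constants (s), distinct and positive.
#' @param area component areas summing to 1.
#' @return Object of class `exp_mixture` (data.frame with columns `tau`,
#'   `area`, sorted by ascending `tau`).
#' @export
exp_mixture <- function(tau, area) {
  stopifnot(length(tau) == length(area), all(tau > 0), all(area > 0))
  area <- area / sum(area)
  o <- order(tau)
  structure(data.frame(tau = tau[o], area = area[o]),
            class = c("exp_mixture", "data.frame"))
}

#' @export
print.exp_mixture <- function(x, ...) {
  cat("<exp_mixture> ", nrow(x), " components\n", sep = "")
  print(data.frame(tau_ms = signif(x$tau * 1e3, 4),
                   area_pct = signif(x$area * 100, 3)))
  ll <- attr(x, "loglik")
  if (!is.null(ll)) cat("  loglik ", ll, "\n", sep = "")
  invisible(x)
}

#' Maximum-likelihood exponential mixture fit to dwell durations
#'
#' Fits a mixture of exponentials to durations left-truncated at the
#' resolution (dead time), by EM on the shifted durations with seeded
#' multi-start. Areas are reported as fractions of the resolved (observed)
#' events.
#'
#' @param durations dwell durations (s), all above `resolution`.
#' @param n_components number of exponential components.
#' @param resolution truncation point (s); typically the class dead time.
#' @param seed RNG seed for the multi-start jitter.
#' @param n_start number of EM restarts.
#' @return An [exp_mixture()] with attribute `loglik`.
#' @export
fit_exp_mixture <- function(durations, n_components, resolution = 0,
                            seed = 1, n_start = 10) {
  stopifnot(n_components >= 1)
  u <- durations - resolution
  if (any(u <= 0)) stop("durations must all exceed the resolution")
  n <- length(u)
  if (n_components == 1) {
    tau <- mean(u)
    out <- exp_mixture(tau, 1)
    attr(out, "loglik") <- sum(stats::dexp(u, 1 / tau, log = TRUE))
    return(out)
  }
  em <- function(tau0, w0) {
    tau <- tau0; w <- w0; ll_old <- -Inf
    for (it in 1:500) {
      dens <- vapply(seq_along(tau),
                     function(i) w[i] * stats::dexp(u, 1 / tau[i]),
                     numeric(n))
      tot <- rowSums(dens)
      if (any(tot <= 0)) return(NULL)
      ll <- sum(log(tot))
      r <- dens / tot
      w <- colMeans(r)
      tau <- colSums(r * u) / colSums(r)
      if (abs(ll - ll_old) < 1e-10 * abs(ll)) break
      ll_old <- ll
    }
    list(tau = tau, w = w, ll = ll)
  }
  set.seed(seed)
  qs <- stats::quantile(u, probs = seq(0.1, 0.9,
                                       length.out = n_components))
  best <- NULL
  for (s in seq_len(n_start)) {
    tau0 <- as.numeric(qs) * exp(stats::rnorm(n_components, 0, 0.5))
    fit <- em(tau0, rep(1 / n_components, n_components))
    if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed")
  o <- order(best$tau)
  tau <- best$tau[o]; w <- best$w[o]
  if (any(diff(tau) / tau[-length(tau)] < 0.01))
    warning("degenerate fit: merged components")
  out <- exp_mixture(tau, w)
  attr(out, "loglik") <- best$ll
  out
}

#' Critical shut time between two groups of mixture components
#'
#' Solves the equal-misclassified-numbers criterion: the expected number of
#' slow ("between burst") events shorter than t equals the number of fast
#' ("within burst") events longer than t, by bisection between the adjacent
#' time constants.
#'
#' @param shut_mixture an [exp_mixture()] of shut times (at least two
#'   components).
#' @param between_index index of the last "within burst" component; all
#'   slower components count as between-burst. Defaults to all but the
#'   slowest.
#' @return Critical time in seconds.
#' @export
compute_tcrit <- function(shut_mixture, between_index = nrow(shut_mixture) - 1L) {
  m <- nrow(shut_mixture)
  if (m < 2) stop("need at least two components")
  if (between_index < 1 || between_index >= m) stop("invalid between_index")
  tf <- shut_mixture$tau[seq_len(between_index)]
  af <- shut_mixture$area[seq_len(between_index)]
  ts <- shut_mixture$tau[(between_index + 1):m]
  as <- shut_mixture$area[(between_index + 1):m]
  if (min(ts) / max(tf) < 1 + 1e-6)
    stop("degenerate mixture: component time constants overlap")
  crit <- function(t) sum(as * (1 - exp(-t / ts))) - sum(af * exp(-t / tf))
  lo <- max(tf); hi <- min(ts)
  if (crit(lo) * crit(hi) > 0) {
    lo <- min(tf) * 1e-3; hi <- max(ts) * 50
    if (crit(lo) * crit(hi) > 0)
      stop("no root: components overlap too strongly for a t-crit")
  }
  stats::uniroot(crit, c(lo, hi), tol = 1e-12)$root
}

#' Segment a record into bursts at a critical shut time
#'
#' Shut dwells at least `t_crit` long delimit bursts; the delimiting shut
#' dwells (and any dwells outside a burst) receive burst id `NA`. Every burst
#' begins and ends with an open dwell.
#'
#' @param dwells a resolved [dwell_sequence()].
#' @param t_crit critical shut time in seconds (default 35 ms, the value
#'   used for the packaged GluN1/GluN2A analyses).
#' @return The dwell sequence with an added `burst` column and attribute
#'   `tcrit`.
#' @export
segment_bursts <- function(dwells, t_crit = 0.035) {
  df <- as.data.frame(dwells)
  burst <- rep(NA_integer_, nrow(df))
  nb <- 0L
  for (segi in unique(df$segment)) {
    idx <- which(df$segment == segi)
    gap <- df$class[idx] == "shut" & df$duration[idx] >= t_crit
    grp <- cumsum(gap)
    for (g in unique(grp)) {
      sel <- idx[grp == g & !gap]
      if (!length(sel)) next
      op <- which(df$class[sel] == "open")
      if (!length(op)) next
      sel <- sel[min(op):max(op)]
      nb <- nb + 1L
      burst[sel] <- nb
    }
  }
  out <- dwell_sequence(df$duration, df$class, df$segment,
                        resolution = attr(dwells, "resolution"))
  out$burst <- burst
  attr(out, "tcrit") <- t_crit
  out
}

#' Correlation of adjacent open and shut durations
#'
#' Pearson correlation of each open duration with the immediately following
#' shut duration. When a `burst` column is present (see [segment_bursts()])
#' only pairs within the same burst are used.
#'
#' @param dwells a [dwell_sequence()].
#' @param reverse pair each shut time with the following open time instead.
#' @return Correlation coefficient with attributes `p.value` and `n`.
#' @export
adjacent_correlation <- function(dwells, reverse = FALSE) {
  df <- as.data.frame(dwells)
  lead_cl <- if (reverse) "shut" else "open"
  i <- which(df$class == lead_cl)
  i <- i[i < nrow(df)]
  j <- i + 1L
  keep <- df$segment[i] == df$segment[j]
  if (!is.null(df$burst))
    keep <- keep & !is.na(df$burst[i]) & df$burst[i] == df$burst[j]
  i <- i[keep]; j <- j[keep]
  if (length(i) < 10) stop("need at least 10 adjacent pairs")
  x <- df$duration[i]; y <- df$duration[j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant durations: correlation undefined")
  ct <- stats::cor.test(x, y)
  structure(unname(ct$estimate), p.value = ct$p.value, n = length(i))
}
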