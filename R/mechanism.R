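#' Declarative gating mechanisms
#'
#' A mechanism is a reversible state graph for an aggregated continuous-time
#' Markov model of channel gating: states carry a conductance class (open or
#' shut), transitions carry a named rate constant and an integer statistical
#' factor, and constraints record fixed rates, equality ties and microscopic
#' reversibility (MR) conditions. States are stored open block first, then
#' shut, lexicographically within each block, so that assembled Q matrices are
#' reproducible.
#'
#' @param states data.frame with columns `id` (unique character) and `class`
#'   (`"open"` or `"shut"`); further columns are kept as annotations.
#' @param rates named list of [rate_param()] objects (or a list that can be
#'   coerced, one element per rate constant).
#' @param transitions data.frame with columns `from`, `to`, `rate` and
#'   optionally `factor` (positive integer multiplicity, default 1). Every
#'   transition must have a declared reverse.
#' @param constraints list with optional elements `fixed` (character vector of
#'   rate names), `equal` (list of character pairs `c(master, tied)`) and `mr`
#'   (list of MR constraints as produced by [enforce_mr()]).
#' @return An object of class `mechanism`.
#' @seealso [assemble_q()], [enforce_mr()], [equilibrium_dist()]
#' @export
mechanism <- function(states, rates, transitions, constraints = list()) {
  states <- as.data.frame(states, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (is.null(transitions$factor)) transitions$factor <- 1L
  stopifnot(all(c("id", "class") %in% names(states)),
            all(c("from", "to", "rate") %in% names(transitions)))
  if (anyDuplicated(states$id)) stop("state ids must be unique")
  if (!all(states$class %in% c("open", "shut")))
    stop("state class must be 'open' or 'shut'")
  if (!any(states$class == "open") || !any(states$class == "shut"))
    stop("mechanism needs at least one open and one shut state")

  ## canonical order: open block first, lexicographic ids within block
  ord <- order(match(states$class, c("open", "shut")), states$id, method = "radix")
  states <- states[ord, , drop = FALSE]
  rownames(states) <- NULL

  if (is.null(names(rates)))
    names(rates) <- vapply(rates, function(r) r$name, character(1))
  rates <- lapply(rates, function(r) {
    if (!inherits(r, "rate_param")) r <- do.call(rate_param, r)
    r
  })
  for (r in rates) {
    if (!is.finite(r$value) || r$value < 0)
      stop("rate '", r$name, "' must be a non-negative finite number")
  }

  bad <- setdiff(c(transitions$from, transitions$to), states$id)
  if (length(bad)) stop("transitions reference unknown states: ",
                        paste(unique(bad), collapse = ", "))
  bad <- setdiff(transitions$rate, names(rates))
  if (length(bad)) stop("transitions reference unknown rates: ",
                        paste(unique(bad), collapse = ", "))
  if (any(transitions$factor < 1 | transitions$factor != round(transitions$factor)))
    stop("statistical factors must be positive integers")
  key <- paste(transitions$from, transitions$to)
  if (anyDuplicated(key)) stop("duplicate transition")
  if (!all(paste(transitions$to, transitions$from) %in% key))
    stop("every transition needs a declared reverse transition")

  constraints$fixed <- as.character(constraints$fixed %||% character(0))
  constraints$equal <- constraints$equal %||% list()
  constraints$mr <- constraints$mr %||% list()

  structure(list(states = states, rates = rates, transitions = transitions,
                 constraints = constraints),
            class = "mechanism")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rate constant parameter
#'
#' @param name identifier of the rate constant.
#' @param value value in s^-1, or M^-1 s^-1 when `ligand` is set (the value is
#'   multiplied by the ligand concentration at Q-matrix assembly only).
#' @param ligand optional ligand identifier for concentration-dependent rates.
#' @param fixed logical; fixed rates are excluded from free parameters when
#'   fitting.
#' @return An object of class `rate_param`.
#' @export
rate_param <- function(name, value, ligand = NA_character_, fixed = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, value = as.numeric(value),
                 ligand = as.character(ligand), fixed = isTRUE(fixed)),
            class = "rate_param")
}

#' @export
print.mechanism <- function(x, ...) {
  k <- nrow(x$states)
  cat("<mechanism> ", sum(x$states$class == "open"), " open + ",
      sum(x$states$class == "shut"), " shut states, ",
      nrow(x$transitions), " transitions, ", length(x$rates), " rate constants\n",
      sep = "")
  nmr <- length(x$constraints$mr)
  if (nmr) cat("  MR-constrained: ",
               paste(vapply(x$constraints$mr, `[[`, "", "rate"), collapse = ", "),
               "\n", sep = "")
  invisible(x)
}

## named numeric vector of rate values
rate_values <- function(mech) {
  vapply(mech$rates, function(r) r$value, numeric(1))
}

## replace rate values (named vector), re-deriving MR-constrained rates
set_rates <- function(mech, values) {
  stopifnot(all(names(values) %in% names(mech$rates)))
  for (nm in names(values)) mech$rates[[nm]]$value <- unname(values[[nm]])
  apply_mr(mech)
}

transition_lookup <- function(mech) {
  tr <- mech$transitions
  structure(seq_len(nrow(tr)), names = paste(tr$from, tr$to, sep = "\r"))
}

## Q entry implied by a transition row (concentration taken as 1 M)
entry_value <- function(mech, i) {
  tr <- mech$transitions[i, ]
  tr$factor * mech$rates[[tr$rate]]$value
}

#' Assemble the transition-rate (Q) matrix
#'
#' Builds the generator of the gating chain at given ligand concentrations.
#' Entry `Q[i, j]` for `i != j` is `factor * rate` (times concentration for a
#' ligand-dependent rate) and the diagonal is minus the row sum, so rows sum
#' to zero. The state order is the mechanism's canonical order: open states
#' first.
#'
#' @param mech a [mechanism()].
#' @param concentrations named numeric vector of molar concentrations, one per
#'   ligand referenced by the mechanism's rates. May be empty if no rate is
#'   ligand-dependent.
#' @return An object of class `q_matrix`: list with elements `Q` (matrix,
#'   s^-1), `states`, `class`, `kA` (number of open states) and `kF`.
#' @export
assemble_q <- function(mech, concentrations = numeric(0)) {
  k <- nrow(mech$states)
  ids <- mech$states$id
  tr <- mech$transitions
  rv <- rate_values(mech)
  lig <- vapply(mech$rates, function(r) r$ligand, character(1))
  v <- tr$factor * rv[tr$rate]
  tlig <- lig[tr$rate]
  has <- !is.na(tlig)
  if (any(has)) {
    miss <- setdiff(unique(tlig[has]), names(concentrations))
    if (length(miss))
      stop("no concentration supplied for ligand '", miss[1], "'")
    conc <- concentrations[tlig[has]]
    if (any(!is.finite(conc) | conc < 0))
      stop("ligand concentrations must be finite and >= 0")
    v[has] <- v[has] * conc
  }
  Q <- matrix(0, k, k, dimnames = list(ids, ids))
  Q[cbind(match(tr$from, ids), match(tr$to, ids))] <- v
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, states = mech$states$id, class = mech$states$class,
                 kA = sum(mech$states$class == "open"),
                 kF = sum(mech$states$class == "shut")),
            class = "q_matrix")
}

#' @export
print.q_matrix <- function(x, ...) {
  cat("<q_matrix> ", length(x$states), " states (kA = ", x$kA,
      ", kF = ", x$kF, ")\n", sep = "")
  print(signif(x$Q, 4))
  invisible(x)
}

as_q <- function(q, mech_conc = NULL) {
  if (inherits(q, "q_matrix")) return(q)
  if (inherits(q, "mechanism")) return(assemble_q(q, mech_conc %||% numeric(0)))
  stop("expected a q_matrix or mechanism")
}

## strong connectivity of the positive-rate graph
check_irreducible <- function(Q) {
  g <- igraph::graph_from_adjacency_matrix((Q > 0) * 1, mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L)
    stop("Q is reducible: equilibrium distribution is not unique")
  invisible(TRUE)
}

#' Equilibrium occupancies from the Q matrix
#'
#' Solves `p Q = 0`, `sum(p) = 1` by a linear null-space solve (no
#' simulation).
#'
#' @param q a `q_matrix` (or a mechanism with no ligand-dependent rates).
#' @return Named numeric vector of equilibrium state probabilities.
#' @export
equilibrium_dist <- function(q) {
  q <- as_q(q)
  check_irreducible(q$Q)
  k <- length(q$states)
  A <- rbind(t(q$Q), rep(1, k))
  p <- qr.solve(A, c(rep(0, k), 1))
  if (min(p) < -1e-8) stop("negative equilibrium probability: ill-conditioned Q")
  p <- pmax(p, 0); p <- p / sum(p)
  names(p) <- q$states
  p
}

## spectral decomposition of a generator; symmetrised when detailed balance
## holds (guaranteed for MR-consistent mechanisms), general eigen otherwise
q_spectral <- function(Q, p = NULL) {
  k <- nrow(Q)
  if (is.null(p)) {
    p <- tryCatch(equilibrium_dist(structure(list(
      Q = Q, states = rownames(Q) %||% as.character(seq_len(k)),
      class = rep("shut", k), kA = 0L, kF = k), class = "q_matrix")),
      error = function(e) NULL)
  }
  if (!is.null(p) && min(p) > 0) {
    s <- sqrt(p)
    S <- Q * outer(s, 1 / s)
    if (max(abs(S - t(S))) < 1e-7 * max(abs(Q), 1)) {
      e <- eigen((S + t(S)) / 2, symmetric = TRUE)
      V <- e$vectors / s          # right eigenvectors of Q
      Vinv <- t(e$vectors * s)    # rows: left eigenvectors
      return(list(values = e$values, V = V, Vinv = Vinv))
    }
  }
  e <- eigen(Q)
  if (max(abs(Im(e$values))) > 1e-8 * max(abs(Re(e$values)), 1))
    warning("complex eigenvalues in Q; using real parts")
  V <- Re(e$vectors)
  list(values = Re(e$values), V = V, Vinv = solve(V))
}

## dense matrix exponential expm(Q t) through the spectral decomposition
expm_q <- function(Q, t, spec = NULL) {
  if (is.null(spec)) spec <- q_spectral(Q)
  spec$V %*% (exp(spec$values * t) * spec$Vinv)
}

#' Relax occupancies under a constant Q
#'
#' Computes `p0 %*% expm(Q t)` by eigendecomposition; occupancy normalisation
#' is preserved to numerical accuracy.
#'
#' @param q a `q_matrix`.
#' @param p0 occupancy vector summing to 1.
#' @param t time in seconds (finite, >= 0).
#' @return Occupancy vector at time `t`.
#' @export
spectral_relax <- function(q, p0, t) {
  q <- as_q(q)
  if (!is.finite(t)) stop("t must be finite")
  stopifnot(length(p0) == length(q$states))
  if (abs(sum(p0) - 1) > 1e-6) stop("p0 must sum to 1")
  p <- as.numeric(p0 %*% expm_q(q$Q, t))
  names(p) <- q$states
  p
}

#' Maximum detailed-balance violation across edges
#'
#' Returns `max_ij |p_i Q_ij - p_j Q_ji|`, which is zero (to numerical
#' accuracy) for mechanisms satisfying microscopic reversibility.
#'
#' @param q a `q_matrix`.
#' @return Scalar violation in s^-1.
#' @export
detailed_balance_error <- function(q) {
  q <- as_q(q)
  p <- equilibrium_dist(q)
  F <- p * q$Q               # flux matrix p_i Q_ij
  max(abs(F - t(F)))
}

## ---- microscopic reversibility ------------------------------------------

## MR constraint value for constraint list(rate=, trans=i, cycle=c(f,t,...)):
## the constrained transition is cycle[1] -> cycle[2]; the cycle closes
## cycle[m] -> cycle[1]. Detailed balance around the cycle determines the
## constrained Q entry, divided by its statistical factor to give the rate.
mr_value <- function(mech, mrc) {
  cyc <- mrc$cycle
  m <- length(cyc)
  look <- transition_lookup(mech)
  idx <- function(f, t) {
    i <- look[paste(f, t, sep = "\r")]
    if (is.na(i)) stop("MR cycle uses missing transition ", f, " -> ", t)
    i
  }
  fwd_lig <- 0L; rev_lig <- 0L
  num <- 0; den <- 0   # log scale
  for (s in seq_len(m)) {
    a <- cyc[s]; b <- cyc[if (s == m) 1L else s + 1L]
    i_f <- idx(a, b); i_r <- idx(b, a)
    rf <- mech$rates[[mech$transitions$rate[i_f]]]
    rr <- mech$rates[[mech$transitions$rate[i_r]]]
    if (s > 1L) {  # forward product excludes the constrained entry itself
      den <- den + log(entry_value(mech, i_f))
      if (!is.na(rf$ligand)) fwd_lig <- fwd_lig + 1L
    } else if (!is.na(rf$ligand)) fwd_lig <- fwd_lig + 1L
    num <- num + log(entry_value(mech, i_r))
    if (!is.na(rr$ligand)) rev_lig <- rev_lig + 1L
  }
  if (fwd_lig != rev_lig)
    stop("MR cycle is not concentration-balanced for rate '", mrc$rate, "'")
  i_c <- idx(cyc[1], cyc[2])
  v <- exp(num - den) / mech$transitions$factor[i_c]
  if (!is.finite(v) || v <= 0)
    stop("MR constraint for rate '", mrc$rate, "' yields a non-positive value")
  v
}

#' Re-derive MR-constrained rate values
#'
#' Recomputes every microscopic-reversibility-constrained rate from the free
#' rates around its defining cycle. Called automatically after parameter
#' updates during fitting.
#'
#' @param mech a [mechanism()] with MR constraints attached.
#' @return The mechanism with constrained rate values updated.
#' @export
apply_mr <- function(mech) {
  for (mrc in mech$constraints$mr)
    mech$rates[[mrc$rate]]$value <- mr_value(mech, mrc)
  mech
}

#' Attach microscopic-reversibility constraints
#'
#' Treats the mechanism as an undirected graph and finds a minimum spanning
#' tree; each edge not in the tree contributes one MR-constrained rate whose
#' defining cycle is the off-tree edge plus the shortest tree path between its
#' endpoints. Edges whose rates are already fixed or equality-tied are
#' weighted so the tree prefers to retain them (keeping them free of MR
#' constraints); remaining ties are broken by lexicographic edge order. Of the
#' two rates on an off-tree edge, the one whose transition is listed second in
#' the mechanism is constrained, unless it is fixed or equality-tied, in which
#' case the other is used.
#'
#' @param mech a [mechanism()].
#' @return The mechanism with `constraints$mr` populated and constrained rate
#'   values re-derived.
#' @export
enforce_mr <- function(mech) {
  tr <- mech$transitions
  ekey <- ifelse(tr$from < tr$to, paste(tr$from, tr$to, sep = "\r"),
                 paste(tr$to, tr$from, sep = "\r"))
  edges <- !duplicated(ekey)
  e_from <- tr$from[edges]; e_to <- tr$to[edges]; e_id <- ekey[edges]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e_from, to = e_to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = mech$states$id)
  if (igraph::components(g)$no != 1L) stop("mechanism graph is not connected")

  ## prefer to keep already-tied rates free of MR constraints: rates that
  ## are fixed, equality-tied, or shared across several transitions (one
  ## parameter, many edges) pull their edges into the spanning tree
  shared <- names(which(table(tr$rate) > 1L))
  tied <- unique(c(mech$constraints$fixed, unlist(mech$constraints$equal),
                   shared))
  edge_rates <- lapply(seq_along(e_id), function(i)
    tr$rate[ekey == e_id[i]])
  w <- vapply(edge_rates, function(rs) if (any(rs %in% tied)) 0.01 else 1,
              numeric(1))
  w <- w + 1e-9 * rank(e_id, ties.method = "first")   # deterministic ties
  mst <- igraph::mst(g, weights = w)
  in_tree <- igraph::as_ids(igraph::E(mst))
  all_ids <- igraph::as_ids(igraph::E(g))
  off <- which(!all_ids %in% in_tree)
  off <- off[order(e_id[off], method = "radix")]

  mech$constraints$mr <- list()
  constrained <- character(0)
  make_cycle <- function(row) {
    f <- tr$from[row]; t2 <- tr$to[row]
    path <- igraph::shortest_paths(mst, from = t2, to = f)$vpath[[1]]
    path <- igraph::as_ids(path)            # t2, ..., f
    c(f, path[-length(path)])               # f, t2, intermediates
  }
  for (i in off) {
    rows <- which(ekey == e_id[i])          # the two directed transitions
    pick <- rows[length(rows)]              # second-listed by convention
    alt <- rows[1L]
    if (cycle_balanced(mech, make_cycle(pick))) next  # holds identically
    if (tr$rate[pick] %in% c(tied, constrained)) { tmp <- pick; pick <- alt; alt <- tmp }
    if (tr$rate[pick] %in% c(tied, constrained))
      stop("both rates on off-tree edge ", gsub("\r", "-", e_id[i]),
           " are already constrained")
    cyc <- make_cycle(pick)
    mech$constraints$mr <- c(mech$constraints$mr,
                             list(list(rate = tr$rate[pick], cycle = cyc)))
    constrained <- c(constrained, tr$rate[pick])
  }
  apply_mr(mech)
}

## a cycle is symbolically balanced (microscopic reversibility holds for any
## parameter values) when the forward and reverse directions use the same
## multiset of rate names with equal statistical-factor products
cycle_balanced <- function(mech, cyc) {
  look <- transition_lookup(mech)
  m <- length(cyc)
  fwd <- character(m); rev_ <- character(m)
  ffac <- 1; rfac <- 1
  for (s in seq_len(m)) {
    a <- cyc[s]; b <- cyc[if (s == m) 1L else s + 1L]
    i_f <- look[paste(a, b, sep = "\r")]
    i_r <- look[paste(b, a, sep = "\r")]
    if (is.na(i_f) || is.na(i_r)) return(FALSE)
    fwd[s] <- mech$transitions$rate[i_f]
    rev_[s] <- mech$transitions$rate[i_r]
    ffac <- ffac * mech$transitions$factor[i_f]
    rfac <- rfac * mech$transitions$factor[i_r]
  }
  identical(sort(fwd), sort(rev_)) && ffac == rfac
}
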