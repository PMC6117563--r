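#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact CTMC sampling with R's RNG: exponential sojourns, embedded-chain
// jumps. Runs for a fixed number of transitions, or until the summed sojourn
// time first exceeds `duration` (pass n_transitions <= 0).
// [[Rcpp::export]]
List sim_ctmc(NumericMatrix Q, int start, int n_transitions, double duration) {
  const int k = Q.nrow();
  std::vector<double> exitr(k);
  std::vector< std::vector<double> > cum(k, std::vector<double>(k, 0.0));
  for (int i = 0; i < k; ++i) {
    double tot = 0.0;
    for (int j = 0; j < k; ++j) {
      if (j != i && Q(i, j) > 0) tot += Q(i, j);
      cum[i][j] = tot;
    }
    exitr[i] = tot;
    if (tot <= 0) stop("absorbing state in Q");
  }
  std::vector<int> states;
  std::vector<double> dur;
  const bool by_n = n_transitions > 0;
  if (by_n) { states.reserve(n_transitions + 1); dur.reserve(n_transitions + 1); }
  int s = start - 1;
  double total = 0.0;
  for (R_xlen_t step = 0; ; ++step) {
    double d = R::rexp(1.0 / exitr[s]);
    states.push_back(s + 1);
    dur.push_back(d);
    total += d;
    if (by_n) { if (step >= n_transitions) break; }
    else if (total >= duration) break;
    double u = R::runif(0.0, exitr[s]);
    int nxt = 0;
    while (cum[s][nxt] < u) ++nxt;
    s = nxt;
  }
  return List::create(_["states"] = wrap(states), _["durations"] = wrap(dur));
}

// Left-to-right concatenation of events below the resolution into the
// enclosing opposite-class dwell. classes: 1 = open, 0 = shut. Events before
// the first resolvable one are merged forward into it.
// [[Rcpp::export]]
List impose_resolution_cpp(NumericVector d, IntegerVector cl,
                           double tau_open, double tau_shut) {
  const int n = d.size();
  auto dead = [&](int c) { return c ? tau_open : tau_shut; };
  int i0 = -1;
  for (int i = 0; i < n; ++i)
    if (d[i] >= dead(cl[i])) { i0 = i; break; }
  if (i0 < 0) stop("record shorter than one resolved dwell");
  std::vector<double> rd; rd.reserve(n);
  std::vector<int> rc; rc.reserve(n);
  int cur_cl = cl[i0];
  double cur_d = 0.0;
  for (int i = 0; i <= i0; ++i) cur_d += d[i];
  for (int j = i0 + 1; j < n; ++j) {
    if (cl[j] == cur_cl) {
      cur_d += d[j];
    } else if (d[j] >= dead(cl[j])) {
      rd.push_back(cur_d); rc.push_back(cur_cl);
      cur_cl = cl[j]; cur_d = d[j];
    } else {
      cur_d += d[j];
    }
  }
  rd.push_back(cur_d); rc.push_back(cur_cl);
  return List::create(_["durations"] = wrap(rd), _["classes"] = wrap(rc));
}

// Batched evaluation of det W(s) = det(s I - H(s)) for the asymptotic
// missed-event root search, with H(s) = Qaa + L diag(f(s - d)) R and
// f(x) = (1 - exp(-x tau))/x (analytic at x = 0). LU with partial pivoting.
// [[Rcpp::export]]
NumericVector detw_batch(NumericVector s, NumericMatrix Qaa, NumericMatrix L,
                         NumericMatrix R, NumericVector d, double tau) {
  const int k = Qaa.nrow(), m = d.size(), ns = s.size();
  NumericVector out(ns);
  std::vector<double> A(k * k), f(m);
  for (int q = 0; q < ns; ++q) {
    const double sv = s[q];
    for (int j = 0; j < m; ++j) {
      const double x = sv - d[j], y = x * tau;
      f[j] = (std::fabs(y) < 1e-6)
        ? tau * (1.0 - y / 2.0 + y * y / 6.0)
        : (1.0 - std::exp(-y)) / x;
    }
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j) {
        double h = Qaa(i, j);
        for (int r = 0; r < m; ++r) h += L(i, r) * f[r] * R(r, j);
        A[i * k + j] = (i == j ? sv : 0.0) - h;
      }
    // LU with partial pivoting; det = prod of pivots * sign
    double det = 1.0;
    for (int c = 0; c < k; ++c) {
      int piv = c;
      double best = std::fabs(A[c * k + c]);
      for (int i = c + 1; i < k; ++i) {
        const double a = std::fabs(A[i * k + c]);
        if (a > best) { best = a; piv = i; }
      }
      if (best == 0.0) { det = 0.0; break; }
      if (piv != c) {
        for (int j = 0; j < k; ++j) std::swap(A[c * k + j], A[piv * k + j]);
        det = -det;
      }
      const double p = A[c * k + c];
      det *= p;
      for (int i = c + 1; i < k; ++i) {
        const double fac = A[i * k + c] / p;
        if (fac != 0.0)
          for (int j = c + 1; j < k; ++j) A[i * k + j] -= fac * A[c * k + j];
      }
    }
    out[q] = det;
  }
  return out;
}

// Eigenvalues of a small dense symmetric matrix by cyclic Jacobi rotations.
static void jacobi_eigs(std::vector<double>& A, int n, std::vector<double>& ev) {
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < n; ++p)
      for (int q = p + 1; q < n; ++q) off += A[p * n + q] * A[p * n + q];
    if (off < 1e-28) break;
    for (int p = 0; p < n; ++p)
      for (int q = p + 1; q < n; ++q) {
        const double apq = A[p * n + q];
        if (std::fabs(apq) < 1e-300) continue;
        const double theta = (A[q * n + q] - A[p * n + p]) / (2.0 * apq);
        const double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        const double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int i = 0; i < n; ++i) {
          const double aip = A[i * n + p], aiq = A[i * n + q];
          A[i * n + p] = c * aip - s * aiq;
          A[i * n + q] = s * aip + c * aiq;
        }
        for (int i = 0; i < n; ++i) {
          const double api = A[p * n + i], aqi = A[q * n + i];
          A[p * n + i] = c * api - s * aqi;
          A[q * n + i] = s * api + c * aqi;
        }
      }
  }
  ev.resize(n);
  for (int i = 0; i < n; ++i) ev[i] = A[i * n + i];
  std::sort(ev.begin(), ev.end());
}

// Sorted eigenvalue branches of the symmetrised H(s) = Qs + M diag(f(s-d)) M^T.
static void tsym_eigs(double s, const NumericMatrix& Qs, const NumericMatrix& M,
                      const NumericVector& d, double tau,
                      std::vector<double>& A, std::vector<double>& ev) {
  const int k = Qs.nrow(), m = d.size();
  std::vector<double> f(m);
  for (int j = 0; j < m; ++j) {
    const double x = s - d[j], y = x * tau;
    f[j] = (std::fabs(y) < 1e-6)
      ? tau * (1.0 - y / 2.0 + y * y / 6.0)
      : (1.0 - std::exp(-y)) / x;
  }
  A.assign(k * k, 0.0);
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) {
      double h = Qs(i, j);
      for (int r = 0; r < m; ++r) h += M(i, r) * f[r] * M(j, r);
      A[i * k + j] = h; A[j * k + i] = h;
    }
  jacobi_eigs(A, k, ev);
}

// Root search on the eigenvalue branches of the symmetrised H(s): for each
// branch i, bisect h_i(s) - s = 0 between grid points where it changes sign.
// Returns the roots found (possibly fewer than k if a branch never crosses).
// [[Rcpp::export]]
NumericVector sym_branch_roots(NumericMatrix Qs, NumericMatrix M,
                               NumericVector d, double tau,
                               NumericVector grid) {
  const int k = Qs.nrow(), ng = grid.size();
  std::vector<double> A, ev;
  std::vector< std::vector<double> > hb(ng);
  for (int g = 0; g < ng; ++g) {
    tsym_eigs(grid[g], Qs, M, d, tau, A, ev);
    hb[g] = ev;
  }
  std::vector<double> roots;
  for (int i = 0; i < k; ++i) {
    int j = -1;
    double flo = 0.0;
    for (int g = 0; g + 1 < ng; ++g) {
      const double g0 = hb[g][i] - grid[g], g1 = hb[g + 1][i] - grid[g + 1];
      if (g0 * g1 <= 0) { j = g; flo = g0; break; }
    }
    if (j < 0) continue;
    double lo = grid[j], hi = grid[j + 1];
    for (int it = 0; it < 55; ++it) {
      const double mid = 0.5 * (lo + hi);
      tsym_eigs(mid, Qs, M, d, tau, A, ev);
      const double fm = ev[i] - mid;
      if (flo * fm <= 0) hi = mid; else { lo = mid; flo = fm; }
    }
    roots.push_back(0.5 * (lo + hi));
  }
  std::sort(roots.begin(), roots.end());
  return wrap(roots);
}

// Missed-event-corrected log-likelihood of a sequence of resolved dwells.
//
// Each dwell contributes a matrix factor eG(t) built from either the exact
// branch (shifted time v = t - shift within the exact window: the AA/FF block
// of expm(Q v), evaluated in the eigenbasis of the full Q) or the asymptotic
// branch (sum of nroot exponential terms with precomputed area matrices).
// The row vector is rescaled after every dwell and the log-scale accumulated.
//
// Arguments (o = open dwell factors, mapping kA -> kF; s = shut, kF -> kA):
//  t, is_open, segment: per-dwell duration, class, 1-based segment index
//  first: per-dwell flag, TRUE for the first dwell of a segment (which uses
//         shift_first instead of its class shift)
//  shift_o/shift_s: dead-time shifts; exact_o/exact_s: exact-branch spans
//  ev: eigenvalues of the full Q (length k)
//  UA (kA x k), BO (k x kF): exact open factors, eG = (v UA . exp(ev v)) BO
//  US (kF x k), BS (k x kA): exact shut factors
//  ro (nro), AO (kA x kF x nro): asymptotic open roots and matrices
//  rs (nrs), AS (kF x kA x nrs): asymptotic shut
//  phi: list of initial row vectors (one per segment)
//  fin: list of final column vectors (one per segment)
// [[Rcpp::export]]
double hjc_loglik_cpp(NumericVector t, IntegerVector is_open,
                      IntegerVector segment, LogicalVector first,
                      double shift_first,
                      double shift_o, double shift_s,
                      double exact_o, double exact_s,
                      NumericVector ev,
                      NumericMatrix UA, NumericMatrix BO,
                      NumericMatrix US, NumericMatrix BS,
                      NumericVector ro, NumericVector AO,
                      NumericVector rs, NumericVector AS,
                      List phi, List fin) {
  const int n = t.size();
  const int k = ev.size();
  const int kA = UA.nrow(), kF = US.nrow();
  const int nro = ro.size(), nrs = rs.size();
  std::vector<double> v(std::max(kA, kF)), w(std::max(kA, kF)), e(k);
  double ll = 0.0;
  int cur = 0;            // current vector length
  int seg = -1;
  for (int i = 0; i < n; ++i) {
    if (first[i]) {
      if (seg >= 0) return R_NegInf;  // segment ended mid-way (caller bug)
      seg = segment[i];
      NumericVector p0 = phi[seg - 1];
      cur = p0.size();
      for (int a = 0; a < cur; ++a) v[a] = p0[a];
    }
    const bool open = is_open[i] != 0;
    const double shift = first[i] ? shift_first : (open ? shift_o : shift_s);
    const double tv = t[i] - shift;
    if (tv <= 0) return R_NegInf;
    const int kin = open ? kA : kF, kout = open ? kF : kA;
    if (cur != kin) return R_NegInf;
    const double span = open ? exact_o : exact_s;
    if (tv <= span) {
      // exact branch: (v U . exp(ev tv)) B
      const NumericMatrix& U = open ? UA : US;
      const NumericMatrix& B = open ? BO : BS;
      for (int m = 0; m < k; ++m) {
        double acc = 0.0;
        for (int a = 0; a < kin; ++a) acc += v[a] * U(a, m);
        e[m] = acc * std::exp(ev[m] * tv);
      }
      for (int j = 0; j < kout; ++j) {
        double acc = 0.0;
        for (int m = 0; m < k; ++m) acc += e[m] * B(m, j);
        w[j] = acc;
      }
    } else {
      // asymptotic branch: sum_r exp(root_r tv) * (v A_r)
      const NumericVector& roots = open ? ro : rs;
      const NumericVector& A = open ? AO : AS;
      const int nr = open ? nro : nrs;
      for (int j = 0; j < kout; ++j) w[j] = 0.0;
      for (int r = 0; r < nr; ++r) {
        const double er = std::exp(roots[r] * tv);
        const double* Ar = &A[(R_xlen_t)r * kin * kout];
        for (int j = 0; j < kout; ++j) {
          double acc = 0.0;
          const double* col = Ar + (R_xlen_t)j * kin;
          for (int a = 0; a < kin; ++a) acc += v[a] * col[a];
          w[j] += er * acc;
        }
      }
    }
    double sc = 0.0;
    for (int j = 0; j < kout; ++j) sc += w[j];
    if (!(sc > 0.0) || !std::isfinite(sc)) return R_NegInf;
    ll += std::log(sc);
    for (int j = 0; j < kout; ++j) v[j] = w[j] / sc;
    cur = kout;
    // close the segment when the next dwell starts a new one (or at the end)
    if (i + 1 == n || first[i + 1]) {
      NumericVector fv = fin[seg - 1];
      if (fv.size() != cur) return R_NegInf;
      double acc = 0.0;
      for (int j = 0; j < cur; ++j) acc += v[j] * fv[j];
      if (!(acc > 0.0) || !std::isfinite(acc)) return R_NegInf;
      ll += std::log(acc);
      seg = -1;
    }
  }
  return ll;
}
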