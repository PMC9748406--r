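#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

// Destination-interval probabilities of the recombination-conditional
// coalescent transition kernel, integrated in closed form over the grid.
//
// Continuous kernel from source TMRCA s: the recombination point u is uniform
// on (0, s); the new lineage re-coalesces at t > u with hazard 1/lam(t), so the
// density in t is (1/lam(t)) * exp(-(G(t)-G(u))) integrated over u in
// (0, min(s,t)), with G the cumulative hazard. Each destination interval is
// integrated analytically; only exponentials of non-positive arguments are
// formed, so arbitrarily small lam (large hazard) stays finite.
//
// lam: per-interval sizes (length n); reps: representative source times, one
// strictly inside each interval; bounds: n+1 boundaries with bounds[0] = 0.
// The last interval [bounds[n-1], .) integrates to +Inf (bounds[n] nominal).
// [[Rcpp::export]]
NumericMatrix q_kernel_cpp(NumericVector lam, NumericVector reps,
                           NumericVector bounds) {
  const int n = lam.size();
  if (reps.size() != n || bounds.size() != n + 1)
    stop("q_kernel_cpp: inconsistent dimensions");
  NumericMatrix Q(n, n);
  // K(x) = exp(-G(x)) * I(x) with I(x) = int_0^x exp(G(u)) du; the recursion
  // K(b_{j+1}) = e^{-d_j} K(b_j) + lam_j (1 - e^{-d_j}) avoids exp overflow.
  std::vector<double> K_at(n), Dlt(n);
  K_at[0] = 0.0;
  for (int j = 0; j < n - 1; ++j) {
    double d = (bounds[j + 1] - bounds[j]) / lam[j];
    Dlt[j] = d;
    double e = std::exp(-d);
    K_at[j + 1] = e * K_at[j] + lam[j] * (1.0 - e);
  }
  Dlt[n - 1] = R_PosInf;

  for (int is = 0; is < n; ++is) {
    const double s = reps[is];
    const double a_is = bounds[is];
    const double lam_is = lam[is];
    const double es = std::exp(-(s - a_is) / lam_is);
    const double Ks = es * K_at[is] + lam_is * (1.0 - es); // K(s)

    // destinations wholly below s
    for (int j = 0; j < is; ++j) {
      double e = std::exp(-Dlt[j]);
      Q(is, j) =
          ((K_at[j] - lam[j]) * (1.0 - e) + (bounds[j + 1] - bounds[j])) / s;
    }
    // source interval: split the integral at s
    {
      double lower = ((K_at[is] - lam_is) * (1.0 - es) + (s - a_is)) / s;
      double upper;
      if (is == n - 1) {
        upper = Ks / s;
      } else {
        upper = Ks / s * (1.0 - std::exp(-(bounds[is + 1] - s) / lam_is));
      }
      Q(is, is) = lower + upper;
    }
    // destinations above s; D accumulates the hazard from s to bounds[j]
    if (is < n - 1) {
      double D = (bounds[is + 1] - s) / lam_is;
      for (int j = is + 1; j < n; ++j) {
        double eD = std::exp(-D);
        if (j == n - 1) {
          Q(is, j) = Ks / s * eD;
        } else {
          Q(is, j) = Ks / s * eD * (1.0 - std::exp(-Dlt[j]));
          D += Dlt[j];
        }
      }
    }
  }
  return Q;
}

// ---- internal helpers shared by the fast ECDLL evaluator ----------------

// q kernel into a dense n*n buffer (row-major: row s, col t), same math as
// q_kernel_cpp.
static void q_kernel_fill(const std::vector<double> &lam,
                          const std::vector<double> &reps,
                          const std::vector<double> &bounds, int n,
                          std::vector<double> &Q) {
  std::vector<double> K_at(n), Dlt(n);
  K_at[0] = 0.0;
  for (int j = 0; j < n - 1; ++j) {
    double d = (bounds[j + 1] - bounds[j]) / lam[j];
    Dlt[j] = d;
    double e = std::exp(-d);
    K_at[j + 1] = e * K_at[j] + lam[j] * (1.0 - e);
  }
  for (int is = 0; is < n; ++is) {
    const double s = reps[is];
    const double a_is = bounds[is];
    const double lam_is = lam[is];
    const double es = std::exp(-(s - a_is) / lam_is);
    const double Ks = es * K_at[is] + lam_is * (1.0 - es);
    double *row = &Q[(size_t)is * n];
    for (int j = 0; j < is; ++j) {
      double e = std::exp(-Dlt[j]);
      row[j] = ((K_at[j] - lam[j]) * (1.0 - e) + (bounds[j + 1] - bounds[j])) / s;
    }
    {
      double lower = ((K_at[is] - lam_is) * (1.0 - es) + (s - a_is)) / s;
      double upper = (is == n - 1)
          ? Ks / s
          : Ks / s * (1.0 - std::exp(-(bounds[is + 1] - s) / lam_is));
      row[is] = lower + upper;
    }
    if (is < n - 1) {
      double D = (bounds[is + 1] - s) / lam_is;
      for (int j = is + 1; j < n; ++j) {
        double eD = std::exp(-D);
        if (j == n - 1) {
          row[j] = Ks / s * eD;
        } else {
          row[j] = Ks / s * eD * (1.0 - std::exp(-Dlt[j]));
          D += Dlt[j];
        }
      }
    }
  }
}

// conditional-mean representatives under lam; last interval t_max + 1
static void representatives_fill(const std::vector<double> &lam,
                                 const std::vector<double> &bounds, int n,
                                 double t_max, std::vector<double> &reps) {
  for (int j = 0; j < n - 1; ++j) {
    double a = bounds[j], len = bounds[j + 1] - bounds[j];
    double x = len / lam[j];
    reps[j] = (x < 1e-8) ? (a + 0.5 * len)
                         : (a + lam[j] - len / std::expm1(x));
  }
  reps[n - 1] = t_max + 1.0;
}

// Expected complete-data log-likelihood of a candidate parameter point,
// given pooled E-step statistics. Mirrors the R model-construction path
// (representatives under lambda', three-case admixture kernel, row
// renormalization, self-transition mixing, stationary coalescent initial
// distribution, PSMC emissions).
// [[Rcpp::export]]
double ecdll_cpp(NumericVector lam_groups, IntegerVector group_map,
                 double admix_ratio, int t_a_index, double theta, double rho,
                 NumericVector boundaries, double t_max,
                 NumericMatrix A, NumericVector het_counts,
                 NumericVector hom_counts, NumericVector init_counts) {
  const int n = group_map.size();
  const double LOG_FLOOR = 1e-300;
  std::vector<double> bounds(boundaries.begin(), boundaries.end());
  std::vector<double> lam_a(n), lamp(n);
  for (int i = 0; i < n; ++i) {
    lam_a[i] = lam_groups[group_map[i] - 1];
    lamp[i] = (i < t_a_index) ? lam_a[i] * (1.0 + admix_ratio) : lam_a[i];
  }
  std::vector<double> reps(n);
  representatives_fill(lamp, bounds, n, t_max, reps);

  const bool admixed = t_a_index > 0 && admix_ratio > 0;
  std::vector<double> Q((size_t)n * n), Qtmp;
  if (!admixed) {
    q_kernel_fill(lam_a, reps, bounds, n, Q);
  } else {
    q_kernel_fill(lam_a, reps, bounds, n, Q); // case t above t_a everywhere
    Qtmp.resize((size_t)n * n);
    q_kernel_fill(lamp, reps, bounds, n, Qtmp); // merged kernel
    const int k = t_a_index;
    for (int i = 0; i < k; ++i) // rows at/below t_a, dests at/below
      for (int j = 0; j < k; ++j) Q[(size_t)i * n + j] = Qtmp[(size_t)i * n + j];
    if (k < n) {
      std::vector<double> lam_b(n);
      for (int i = 0; i < n; ++i) lam_b[i] = admix_ratio * lam_a[i];
      q_kernel_fill(lam_b, reps, bounds, n, Qtmp);
      for (int i = k; i < n; ++i) { // rows above, dests at/below
        for (int j = 0; j < k; ++j) {
          double qa = Q[(size_t)i * n + j], qb = Qtmp[(size_t)i * n + j];
          Q[(size_t)i * n + j] = qa + qb - 2.0 * qa * qb;
        }
      }
    }
  }

  double out = 0.0;
  // transition term with renormalized rows and self-transition mixing
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    const double *row = &Q[(size_t)i * n];
    for (int j = 0; j < n; ++j) rs += row[j];
    double stay = std::exp(-rho * reps[i]);
    for (int j = 0; j < n; ++j) {
      double p = (1.0 - stay) * row[j] / rs + ((i == j) ? stay : 0.0);
      out += A(i, j) * std::log(std::max(p, LOG_FLOOR));
    }
  }
  // emission term
  for (int i = 0; i < n; ++i) {
    double hom_p = std::exp(-theta * reps[i]);
    out += hom_counts[i] * std::log(std::max(hom_p, LOG_FLOOR)) +
           het_counts[i] * std::log(std::max(1.0 - hom_p, LOG_FLOOR));
  }
  // initial distribution term (stationary coalescent prior under lambda')
  {
    std::vector<double> surv(n);
    surv[0] = 1.0;
    double haz = 0.0;
    for (int j = 0; j < n - 1; ++j) {
      haz += (bounds[j + 1] - bounds[j]) / lamp[j];
      surv[j + 1] = std::exp(-haz);
    }
    double tot = 0.0;
    std::vector<double> pi_(n);
    for (int j = 0; j < n - 1; ++j) { pi_[j] = surv[j] - surv[j + 1]; tot += pi_[j]; }
    pi_[n - 1] = surv[n - 1];
    tot += pi_[n - 1];
    for (int j = 0; j < n; ++j)
      out += init_counts[j] * std::log(std::max(pi_[j] / tot, LOG_FLOOR));
  }
  return out;
}

// Draw a Markov state path by inverse-CDF lookup. cum_trans_t holds the
// transposed cumulative transition matrix (column s = cumulative row of
// state s); u are iid uniforms, one per position.
// [[Rcpp::export]]
IntegerVector sample_path_cpp(NumericMatrix cum_trans_t, NumericVector cum_init,
                              NumericVector u) {
  const int L = u.size();
  const int n = cum_init.size();
  IntegerVector st(L);
  {
    int s = 0;
    while (s < n - 1 && cum_init[s] < u[0]) ++s;
    st[0] = s + 1;
  }
  for (int l = 1; l < L; ++l) {
    const double *col = &cum_trans_t(0, st[l - 1] - 1);
    int s = 0;
    while (s < n - 1 && col[s] < u[l]) ++s;
    st[l] = s + 1;
  }
  return st;
}

// Forward-only scaled log-likelihood (no statistics, no posterior).
// [[Rcpp::export]]
double loglik_cpp(IntegerVector obs, NumericMatrix emission,
                  NumericMatrix trans, NumericVector init) {
  const int L = obs.size();
  const int n = init.size();
  std::vector<double> a(n), anew(n);
  double ll = 0.0;
  {
    int o = obs[0];
    double c0 = 0.0;
    for (int i = 0; i < n; ++i) { a[i] = init[i] * emission(i, o); c0 += a[i]; }
    if (!(c0 > 0.0)) stop("zero-probability observation at position 1");
    for (int i = 0; i < n; ++i) a[i] /= c0;
    ll += std::log(c0);
  }
  for (int l = 1; l < L; ++l) {
    int o = obs[l];
    double cl = 0.0;
    for (int j = 0; j < n; ++j) {
      const double *tcol = &trans(0, j);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += a[i] * tcol[i];
      anew[j] = s * emission(j, o);
      cl += anew[j];
    }
    if (!(cl > 0.0))
      stop("zero-probability observation at position " + std::to_string(l + 1));
    for (int j = 0; j < n; ++j) a[j] = anew[j] / cl;
    ll += std::log(cl);
  }
  return ll;
}

// Scaled forward-backward over a ternary observation sequence.
// obs: 0 = HOM, 1 = HET, 2 = MISSING; emission: n x 3 (columns in that
// order); trans: n x n row-stochastic; init: length n.
// Returns the log-likelihood, pooled expected transition counts, expected
// per-state HET/HOM emission counts, the position-1 posterior, and (optionally)
// the full L x n posterior matrix.
// [[Rcpp::export]]
List fb_cpp(IntegerVector obs, NumericMatrix emission, NumericMatrix trans,
            NumericVector init, bool want_posterior) {
  const int L = obs.size();
  const int n = init.size();
  if (L < 1) stop("empty observation sequence");
  if (emission.nrow() != n || trans.nrow() != n || trans.ncol() != n)
    stop("fb_cpp: inconsistent dimensions");

  NumericMatrix alpha(n, L); // column l = scaled forward vector at position l
  std::vector<double> scale(L);
  {
    int o = obs[0];
    double c0 = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = init[i] * emission(i, o);
      alpha(i, 0) = v;
      c0 += v;
    }
    if (!(c0 > 0.0))
      stop("observation has zero probability under all states at position 1");
    for (int i = 0; i < n; ++i) alpha(i, 0) /= c0;
    scale[0] = c0;
  }
  for (int l = 1; l < L; ++l) {
    int o = obs[l];
    double cl = 0.0;
    const double *aprev = &alpha(0, l - 1);
    for (int j = 0; j < n; ++j) {
      const double *tcol = &trans(0, j);
      double ssum = 0.0;
      for (int i = 0; i < n; ++i) ssum += aprev[i] * tcol[i];
      double v = ssum * emission(j, o);
      alpha(j, l) = v;
      cl += v;
    }
    if (!(cl > 0.0))
      stop("observation has zero probability under all states at position " +
           std::to_string(l + 1));
    for (int j = 0; j < n; ++j) alpha(j, l) /= cl;
    scale[l] = cl;
  }

  NumericMatrix A(n, n);
  NumericVector het(n), hom(n), initc(n);
  NumericMatrix post;
  if (want_posterior) post = NumericMatrix(L, n);

  std::vector<double> beta(n, 1.0), betanew(n), v(n);
  {
    int o = obs[L - 1];
    for (int i = 0; i < n; ++i) {
      double g = alpha(i, L - 1);
      if (want_posterior) post(L - 1, i) = g;
      if (o == 0) hom[i] += g; else if (o == 1) het[i] += g;
    }
  }
  for (int l = L - 2; l >= 0; --l) {
    int o = obs[l + 1];
    double cl1 = scale[l + 1];
    for (int j = 0; j < n; ++j) v[j] = emission(j, o) * beta[j] / cl1;
    std::fill(betanew.begin(), betanew.end(), 0.0);
    const double *ap = &alpha(0, l);
    // column-major sweep: for each destination j accumulate the expected
    // transition counts A(., j) and the backward recursion in one pass
    for (int j = 0; j < n; ++j) {
      const double vj = v[j];
      const double *tcol = &trans(0, j);
      double *Acol = &A(0, j);
      for (int i = 0; i < n; ++i) {
        double t = tcol[i] * vj;
        betanew[i] += t;
        Acol[i] += ap[i] * t; // expected transition count at this junction
      }
    }
    int ol = obs[l];
    for (int i = 0; i < n; ++i) {
      beta[i] = betanew[i];
      double g = alpha(i, l) * beta[i];
      if (want_posterior) post(l, i) = g;
      if (ol == 0) hom[i] += g; else if (ol == 1) het[i] += g;
      if (l == 0) initc[i] = g;
    }
  }
  if (L == 1) for (int i = 0; i < n; ++i) initc[i] = alpha(i, 0);

  double ll = 0.0;
  for (int l = 0; l < L; ++l) ll += std::log(scale[l]);

  return List::create(_["loglik"] = ll, _["trans_counts"] = A,
                      _["het_counts"] = het, _["hom_counts"] = hom,
                      _["init_counts"] = initc,
                      _["posterior"] = want_posterior ? (SEXP)post : R_NilValue);
}
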