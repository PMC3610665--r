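#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Emission lookup for one marker: tab[(a_j << 1) | a_k] = P(g | templates a_j, a_k)
// under the per-allele miscopy model q(x|a) = 1-e if x == a else e.
// Missing genotype (NA) -> all-ones (uninformative).
static inline void emission_table(int g, double e, double tab[4]) {
  if (g == NA_INTEGER) { tab[0] = tab[1] = tab[2] = tab[3] = 1.0; return; }
  double q0[2], q1[2];            // q0[a] = P(obs 0 | a), q1[a] = P(obs 1 | a)
  q0[0] = 1.0 - e; q0[1] = e;
  q1[0] = e;       q1[1] = 1.0 - e;
  for (int aj = 0; aj < 2; ++aj) {
    for (int ak = 0; ak < 2; ++ak) {
      double p;
      if (g == 0)      p = q0[aj] * q0[ak];
      else if (g == 2) p = q1[aj] * q1[ak];
      else             p = q0[aj] * q1[ak] + q1[aj] * q0[ak];
      tab[(aj << 1) | ak] = p;
    }
  }
}

// Scaled forward pass over ordered template pairs (j,k), K^2 states.
// alleles: K x M integer matrix of {0,1}; g: length-M dosages with NA for missing;
// theta: length-(M-1) per-interval switch probabilities.
// Each marker slice is renormalized to sum 1; scale[m] holds the raw slice sum so that
// prod(scale) equals the marginal likelihood. The transition sum uses the rank-1
// structure of the jump process: O(K^2) per marker.
// [[Rcpp::export]]
List cpp_forward(const IntegerMatrix& alleles, const IntegerVector& g,
                 const NumericVector& theta, double e) {
  const int K = alleles.nrow(), M = alleles.ncol();
  if (K < 2) stop("pool must contain at least 2 haplotypes");
  if (g.size() != M) stop("genotype vector length does not match marker count");
  if (theta.size() != M - 1) stop("theta must have length M - 1");

  NumericVector F(no_init(static_cast<R_xlen_t>(K) * K * M));
  NumericVector scale(M);
  double* Fp = REAL(F);
  std::vector<double> rs(K), cs(K), em0(K), em1(K);
  double tab[4];

  // Every slice is symmetric in (j,k): the emission is symmetric, the chromatid
  // transitions are exchangeable and the initial distribution is uniform. Only
  // the lower triangle (j <= k in column-major terms) is computed; the upper is
  // mirrored afterwards.
  const R_xlen_t KK = static_cast<R_xlen_t>(K) * K;

  // marker 0: raw value (1/K^2) * emission
  emission_table(g[0], e, tab);
  {
    const int* a0 = &alleles(0, 0);
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      const int ak2 = a0[k];
      double* Fk = Fp + static_cast<R_xlen_t>(K) * k;
      for (int j = 0; j <= k; ++j) {
        double v = tab[(a0[j] << 1) | ak2];
        Fk[j] = v;
        s += (j == k) ? v : 2.0 * v;
      }
    }
    if (s <= 0.0)
      stop("degenerate likelihood: all forward mass vanished at marker 1");
    scale[0] = s / (static_cast<double>(K) * K);
    const double inv = 1.0 / s;
    for (int k = 0; k < K; ++k)
      for (int j = 0; j <= k; ++j)
        Fp[j + static_cast<R_xlen_t>(K) * k] *= inv;
  }

  for (int m = 1; m < M; ++m) {
    const double* P = Fp + KK * (m - 1);
    double* Fm = Fp + KK * m;
    const double th = theta[m - 1];
    const double q = 1.0 - th, tk = th / K;
    // marginal sums of the (normalized, sum-1, symmetric) previous slice
    std::fill(rs.begin(), rs.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double* Pk = P + static_cast<R_xlen_t>(K) * k;
      double ck = 0.0;
      for (int j = 0; j < k; ++j) { ck += Pk[j]; rs[j] += Pk[j]; }
      rs[k] += ck + Pk[k];
    }
    emission_table(g[m], e, tab);
    const int* am = &alleles(0, m);
    for (int j = 0; j < K; ++j) {
      em0[j] = tab[(am[j] << 1)];
      em1[j] = tab[(am[j] << 1) | 1];
    }
    const double q2 = q * q, qt = q * tk, tt = tk * tk;  // prev slice sums to 1
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      const double* emj = am[k] ? em1.data() : em0.data();
      const double* Pk = P + static_cast<R_xlen_t>(K) * k;
      double* Fk = Fm + static_cast<R_xlen_t>(K) * k;
      const double ck = qt * rs[k] + tt;
      double srow = 0.0, sdiag;
      for (int j = 0; j < k; ++j) {
        double v = emj[j] * (q2 * Pk[j] + qt * rs[j] + ck);
        Fk[j] = v;
        srow += v;
      }
      sdiag = emj[k] * (q2 * Pk[k] + qt * rs[k] + ck);
      Fk[k] = sdiag;
      s += 2.0 * srow + sdiag;
    }
    if (s <= 0.0)
      stop("degenerate likelihood: all forward mass vanished at marker %d", m + 1);
    scale[m] = s;
    const double inv = 1.0 / s;
    for (int k = 0; k < K; ++k)
      for (int j = 0; j <= k; ++j)
        Fm[j + static_cast<R_xlen_t>(K) * k] *= inv;
  }

  // mirror the lower triangle into the upper half for all slices
  for (int m = 0; m < M; ++m) {
    double* Fm = Fp + KK * m;
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < k; ++j)
        Fm[k + static_cast<R_xlen_t>(K) * j] = Fm[j + static_cast<R_xlen_t>(K) * k];
  }

  F.attr("dim") = IntegerVector::create(K, K, M);
  return List::create(_["F"] = F, _["scale"] = scale);
}

// Forward-backward posteriors over ordered pairs; each M-slice sums to 1.
// [[Rcpp::export]]
NumericVector cpp_forward_backward(const NumericVector& F, const IntegerMatrix& alleles,
                                   const IntegerVector& g, const NumericVector& theta,
                                   double e) {
  const int K = alleles.nrow(), M = alleles.ncol();
  const R_xlen_t S = static_cast<R_xlen_t>(K) * K;
  if (F.size() != S * M) stop("forward matrix shape does not match pool/markers");

  NumericVector post(S * M);
  const double* Fp = REAL(F);
  double* Pp = REAL(post);
  std::vector<double> B(S, 1.0), G(S), grs(K), gcs(K), em0(K), em1(K);
  double tab[4];

  for (int m = M - 1; m >= 0; --m) {
    // posterior slice m = F[m] .* B, renormalized
    double s = 0.0;
    const double* Fm = Fp + S * m;
    double* Pm = Pp + S * m;
    for (R_xlen_t i = 0; i < S; ++i) { Pm[i] = Fm[i] * B[i]; s += Pm[i]; }
    if (s <= 0.0) stop("degenerate posterior at marker %d", m + 1);
    for (R_xlen_t i = 0; i < S; ++i) Pm[i] /= s;
    if (m == 0) break;

    // roll B back across interval m-1: G = em_m .* B, then apply transposed jump
    emission_table(g[m], e, tab);
    for (int j = 0; j < K; ++j) {
      em0[j] = tab[(alleles(j, m) << 1)];
      em1[j] = tab[(alleles(j, m) << 1) | 1];
    }
    double gtot = 0.0;
    std::fill(grs.begin(), grs.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double* emj = alleles(k, m) ? em1.data() : em0.data();
      double ck = 0.0;
      for (int j = 0; j < K; ++j) {
        double v = emj[j] * B[j + static_cast<R_xlen_t>(K) * k];
        G[j + static_cast<R_xlen_t>(K) * k] = v;
        ck += v; grs[j] += v;
      }
      gcs[k] = ck; gtot += ck;
    }
    const double th = theta[m - 1];
    const double q = 1.0 - th, tk = th / K;
    const double q2 = q * q, qt = q * tk, tt = tk * tk * gtot;
    double bmax = 0.0;
    for (int k = 0; k < K; ++k) {
      const double ck = qt * gcs[k] + tt;
      double* Bk = B.data() + static_cast<R_xlen_t>(K) * k;
      const double* Gk = G.data() + static_cast<R_xlen_t>(K) * k;
      for (int j = 0; j < K; ++j) {
        double v = q2 * Gk[j] + qt * grs[j] + ck;
        Bk[j] = v;
        if (v > bmax) bmax = v;
      }
    }
    if (bmax <= 0.0) stop("degenerate backward value at marker %d", m);
    for (R_xlen_t i = 0; i < S; ++i) B[i] /= bmax;  // guard against underflow
  }

  post.attr("dim") = IntegerVector::create(K, K, M);
  return post;
}

// Mirror subtraction on a weight vector over ordered pairs: for pairs where both
// mates are defined, w'(j,k) = max(w(j,k) - w(mate(j), mate(k)), eps_rel * sum(w)).
// mate is 0-based, -1 where undefined. Operates on w in place via a scratch copy.
static inline void mirror_adjust_raw(std::vector<double>& w, int K,
                                     const int* mate, double eps_rel,
                                     std::vector<double>& scratch) {
  const R_xlen_t S = static_cast<R_xlen_t>(K) * K;
  double tot = 0.0;
  for (R_xlen_t i = 0; i < S; ++i) tot += w[i];
  const double eps_abs = eps_rel * tot;
  scratch.assign(w.begin(), w.end());
  bool adjacent = (K % 2 == 0);
  if (adjacent)
    for (int j = 0; j < K; ++j)
      if (mate[j] != (j ^ 1)) { adjacent = false; break; }
  if (adjacent) {
    // mate(j) = j XOR 1 everywhere (pools of intact individual pairs):
    // branch-free 2x2 block update
    for (int k = 0; k < K; k += 2) {
      const double* s0 = scratch.data() + static_cast<R_xlen_t>(K) * k;
      const double* s1 = s0 + K;
      double* w0 = w.data() + static_cast<R_xlen_t>(K) * k;
      double* w1 = w0 + K;
      for (int j = 0; j < K; j += 2) {
        const double a = s0[j] - s1[j + 1];
        const double b = s0[j + 1] - s1[j];
        const double c = s1[j] - s0[j + 1];
        const double d = s1[j + 1] - s0[j];
        w0[j] = (a > eps_abs) ? a : eps_abs;
        w0[j + 1] = (b > eps_abs) ? b : eps_abs;
        w1[j] = (c > eps_abs) ? c : eps_abs;
        w1[j + 1] = (d > eps_abs) ? d : eps_abs;
      }
    }
    return;
  }
  for (int k = 0; k < K; ++k) {
    const int mk = mate[k];
    if (mk < 0) continue;
    for (int j = 0; j < K; ++j) {
      const int mj = mate[j];
      if (mj < 0) continue;
      double v = scratch[j + static_cast<R_xlen_t>(K) * k] -
                 scratch[mj + static_cast<R_xlen_t>(K) * mk];
      w[j + static_cast<R_xlen_t>(K) * k] = (v > eps_abs) ? v : eps_abs;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_mirror_adjust(const NumericMatrix& w, const IntegerVector& mate,
                                double eps_rel) {
  const int K = w.nrow();
  if (w.ncol() != K) stop("weight matrix must be square");
  if (mate.size() != K) stop("mate map length must equal pool size");
  std::vector<double> wv(w.begin(), w.end()), scratch;
  double tot = 0.0;
  for (double v : wv) { if (v < 0) stop("weights must be non-negative"); tot += v; }
  if (tot <= 0.0) stop("all-zero weight vector");
  std::vector<int> mv(K);
  for (int i = 0; i < K; ++i) mv[i] = (mate[i] == NA_INTEGER) ? -1 : mate[i] - 1;
  mirror_adjust_raw(wv, K, mv.data(), eps_rel, scratch);
  double s = 0.0;
  for (double v : wv) s += v;
  NumericMatrix out(K, K);
  for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(K) * K; ++i) out[i] = wv[i] / s;
  return out;
}

// Backward sampling of n_draws state paths from a forward matrix.
// mode: 0 = original, 1 = mirror. mate: 1-based with NA where undefined.
// mirror_on_forward: in mirror mode, subtract on the forward slice before the
// transition factors are applied (default engine behaviour; a copy pair and
// its mirror carry equal forward mass by symmetry, so every copy pair is
// floored at every marker and the chain can never settle in the copy-pair
// sink). The alternative (false) subtracts on the conditional weight vector.
// Returns an n_draws x 2M integer matrix: columns 1..M are j (first chromatid,
// 1-based), columns M+1..2M are k. Consumes n_draws * M uniforms from R's RNG,
// one per marker per draw, sampled from marker M-1 down to 0.
// [[Rcpp::export]]
IntegerMatrix cpp_backward_sample(const NumericVector& F, int K, int M,
                                  const NumericVector& theta, const IntegerVector& mate,
                                  int mode, double eps_rel, int n_draws,
                                  bool mirror_on_forward = true) {
  const R_xlen_t S = static_cast<R_xlen_t>(K) * K;
  if (F.size() != S * M) stop("forward matrix shape mismatch");
  if (mode != 0 && mode != 1) stop("invalid sampling mode");
  const double* Fp = REAL(F);
  std::vector<int> mv(K);
  bool any_mate = false;
  for (int i = 0; i < K; ++i) {
    mv[i] = (mate[i] == NA_INTEGER) ? -1 : mate[i] - 1;
    if (mv[i] >= 0) any_mate = true;
  }
  const bool adjust = (mode == 1) && any_mate;

  IntegerMatrix out(n_draws, 2 * M);
  std::vector<double> w(S), fadj(S), scratch;
  RNGScope rng;

  // adjusted forward slices are draw-independent: cache the marker index the
  // fadj buffer currently holds to avoid recomputation across draws
  int fadj_marker = -1;

  for (int d = 0; d < n_draws; ++d) {
    int jn = -1, kn = -1;
    for (int m = M - 1; m >= 0; --m) {
      const double* Fm = Fp + S * m;
      if (adjust && mirror_on_forward && fadj_marker != m) {
        std::copy(Fm, Fm + S, fadj.begin());
        mirror_adjust_raw(fadj, K, mv.data(), eps_rel, scratch);
        fadj_marker = m;
      }
      const double* src = (adjust && mirror_on_forward) ? fadj.data() : Fm;
      if (m == M - 1) {
        std::copy(src, src + S, w.begin());
      } else {
        const double th = theta[m];
        const double q = 1.0 - th, tk = th / K;
        for (int k = 0; k < K; ++k) {
          const double fk = tk + (k == kn ? q : 0.0);
          double* wk = w.data() + static_cast<R_xlen_t>(K) * k;
          const double* Fk = src + static_cast<R_xlen_t>(K) * k;
          for (int j = 0; j < K; ++j)
            wk[j] = Fk[j] * fk * (tk + (j == jn ? q : 0.0));
        }
      }
      if (adjust && !mirror_on_forward) mirror_adjust_raw(w, K, mv.data(), eps_rel, scratch);
      double tot = 0.0;
      for (R_xlen_t i = 0; i < S; ++i) tot += w[i];
      if (tot <= 0.0)
        stop("degenerate sampling weights at marker %d", m + 1);
      double r = unif_rand() * tot, acc = 0.0;
      R_xlen_t pick = S - 1;
      for (R_xlen_t i = 0; i < S; ++i) {
        acc += w[i];
        if (r <= acc) { pick = i; break; }
      }
      jn = static_cast<int>(pick % K);
      kn = static_cast<int>(pick / K);
      out(d, m) = jn + 1;
      out(d, M + m) = kn + 1;
    }
  }
  return out;
}

// Haploid Li & Stephens forward-backward: posterior P(allele 1) per marker for one
// haplotype with missing (NA) entries, conditioned on a fixed panel.
// [[Rcpp::export]]
NumericVector cpp_haploid_posterior(const IntegerVector& hap, const IntegerMatrix& panel,
                                    const NumericVector& theta, double e) {
  const int K = panel.nrow(), M = panel.ncol();
  if (K < 1) stop("empty reference panel");
  if (hap.size() != M) stop("haplotype length does not match panel marker count");

  std::vector<double> fwd(static_cast<R_xlen_t>(K) * M), em(K);
  auto emit = [&](int m) {
    const int x = hap[m];
    for (int j = 0; j < K; ++j)
      em[j] = (x == NA_INTEGER) ? 1.0 : (panel(j, m) == x ? 1.0 - e : e);
  };

  // scaled forward
  emit(0);
  double s = 0.0;
  for (int j = 0; j < K; ++j) { fwd[j] = em[j]; s += em[j]; }
  for (int j = 0; j < K; ++j) fwd[j] /= s;
  for (int m = 1; m < M; ++m) {
    const double th = theta[m - 1], q = 1.0 - th, tk = th / K;
    emit(m);
    double* f = fwd.data() + static_cast<R_xlen_t>(K) * m;
    const double* p = fwd.data() + static_cast<R_xlen_t>(K) * (m - 1);
    s = 0.0;
    for (int j = 0; j < K; ++j) { f[j] = em[j] * (q * p[j] + tk); s += f[j]; }
    if (s <= 0.0) stop("degenerate haploid likelihood at marker %d", m + 1);
    for (int j = 0; j < K; ++j) f[j] /= s;
  }

  NumericVector out(M);
  std::vector<double> B(K, 1.0), G(K);
  for (int m = M - 1; m >= 0; --m) {
    const double* f = fwd.data() + static_cast<R_xlen_t>(K) * m;
    double tot = 0.0, p1 = 0.0;
    for (int j = 0; j < K; ++j) tot += f[j] * B[j];
    for (int j = 0; j < K; ++j) {
      const double post = f[j] * B[j] / tot;
      p1 += post * (panel(j, m) ? 1.0 - e : e);
    }
    out[m] = p1;
    if (m == 0) break;
    const double th = theta[m - 1], q = 1.0 - th, tk = th / K;
    emit(m);
    double gtot = 0.0;
    for (int j = 0; j < K; ++j) { G[j] = em[j] * B[j]; gtot += G[j]; }
    double bmax = 0.0;
    for (int j = 0; j < K; ++j) {
      B[j] = q * G[j] + tk * gtot;
      if (B[j] > bmax) bmax = B[j];
    }
    for (int j = 0; j < K; ++j) B[j] /= bmax;
  }
  return out;
}
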