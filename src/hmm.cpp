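// Diploid ancestral-haplotype copying HMM (Li & Stephens style).
//
// Hidden state at grid g: an ordered pair (k1, k2) of ancestral haplotypes,
// stored as a K x K matrix. Each haplotype switches ancestry between
// adjacent grids with probability rho = 1 - exp(-nGen * r * d); the
// transition kernel T = s*I + (1-s)*1*pi^T (s = survival) is rank-one plus
// diagonal, so applying it costs O(K^2) instead of O(K^3). Grids without
// reads contribute emission 1 and are collapsed exactly by composing
// survival probabilities, so the per-iteration cost scales with the number
// of covered grids, not the grid count.
//
// Emissions: per read r at site m, P(b_r | k1,k2) = 0.5*(B(k1) + B(k2)),
// B(k) = theta[k,m]*palt_r + (1-theta[k,m])*pref_r.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<double> vec;

// F' = T^T F T  (forward propagation), in place
static void fwd_trans(vec &F, double s, const double *pi, int K) {
  const double t = 1.0 - s;
  // A = F T : A(k1,k2') = s F(k1,k2') + t pi(k2') rowsum(k1)
  vec rowsum(K, 0.0);
  for (int k2 = 0; k2 < K; ++k2)
    for (int k1 = 0; k1 < K; ++k1) rowsum[k1] += F[k1 + K * k2];
  for (int k2 = 0; k2 < K; ++k2)
    for (int k1 = 0; k1 < K; ++k1)
      F[k1 + K * k2] = s * F[k1 + K * k2] + t * pi[k2] * rowsum[k1];
  // F' = T^T A : F'(k1',k2) = s A(k1',k2) + t pi(k1') colsum(k2)
  vec colsum(K, 0.0);
  for (int k2 = 0; k2 < K; ++k2)
    for (int k1 = 0; k1 < K; ++k1) colsum[k2] += F[k1 + K * k2];
  for (int k2 = 0; k2 < K; ++k2)
    for (int k1 = 0; k1 < K; ++k1)
      F[k1 + K * k2] = s * F[k1 + K * k2] + t * pi[k1] * colsum[k2];
}

// B' = T B T^T (backward propagation), in place
static void bwd_trans(vec &B, double s, const double *pi, int K) {
  const double t = 1.0 - s;
  // A = B T^T : A(k1,k2) = s B(k1,k2) + t sum_j B(k1,j) pi(j)
  vec wrow(K, 0.0);
  for (int j = 0; j < K; ++j)
    for (int k1 = 0; k1 < K; ++k1) wrow[k1] += B[k1 + K * j] * pi[j];
  for (int k2 = 0; k2 < K; ++k2)
    for (int k1 = 0; k1 < K; ++k1)
      B[k1 + K * k2] = s * B[k1 + K * k2] + t * wrow[k1];
  // B' = T A : B'(k1,k2) = s A(k1,k2) + t sum_j pi(j) A(j,k2)
  vec wcol(K, 0.0);
  for (int k2 = 0; k2 < K; ++k2)
    for (int j = 0; j < K; ++j) wcol[k2] += pi[j] * B[j + K * k2];
  for (int k2 = 0; k2 < K; ++k2)
    for (int k1 = 0; k1 < K; ++k1)
      B[k1 + K * k2] = s * B[k1 + K * k2] + t * wcol[k2];
}

static double normalize(vec &x) {
  double tot = 0.0;
  for (double v : x) tot += v;
  if (tot > 0.0) for (double &v : x) v /= tot;
  return tot;
}

// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix theta,       // K x M
                          NumericVector pi,          // K, sums to 1
                          NumericVector cumlog_surv, // length n_grids
                          IntegerVector grid_of_site,// M, 0-based
                          IntegerVector read_site,   // 0-based, sorted within sample
                          NumericVector read_palt,
                          NumericVector read_pref,
                          IntegerVector sample_offsets, // n_samples + 1
                          bool want_suffstats,
                          bool want_posteriors,
                          int gamma_sample)          // 0-based, -1 = none
{
  const int K = theta.nrow(), M = theta.ncol();
  const int G = cumlog_surv.size();
  const int N = sample_offsets.size() - 1;
  const int KK = K * K;
  const double *piv = REAL(pi);

  NumericMatrix theta_num, theta_den;
  if (want_suffstats) {
    theta_num = NumericMatrix(K, M);
    theta_den = NumericMatrix(K, M);
  }
  NumericMatrix p0, p1, p2;
  if (want_posteriors) {
    p0 = NumericMatrix(N, M);
    p1 = NumericMatrix(N, M);
    p2 = NumericMatrix(N, M);
  }
  NumericMatrix gamma_out;
  if (gamma_sample >= 0) gamma_out = NumericMatrix(KK, G);

  double total_loglik = 0.0;
  vec prior(KK);
  for (int k2 = 0; k2 < K; ++k2)
    for (int k1 = 0; k1 < K; ++k1) prior[k1 + K * k2] = piv[k1] * piv[k2];

  // scratch
  vec F(KK), Bm(KK), gam(KK), hapB(K);

  for (int i = 0; i < N; ++i) {
    const int r0 = sample_offsets[i], r1 = sample_offsets[i + 1];

    // active grids (sorted unique grids with reads) and read ranges
    std::vector<int> ag;          // active grid ids
    std::vector<int> astart, aend; // read ranges per active grid
    for (int r = r0; r < r1; ++r) {
      int g = grid_of_site[read_site[r]];
      if (ag.empty() || g != ag.back()) {
        ag.push_back(g); astart.push_back(r); aend.push_back(r + 1);
      } else aend.back() = r + 1;
    }
    const int A = (int)ag.size();

    // emissions per active grid
    std::vector<vec> E(A, vec(KK, 1.0));
    for (int a = 0; a < A; ++a) {
      for (int r = astart[a]; r < aend[a]; ++r) {
        const int m = read_site[r];
        const double pa = read_palt[r], pr = read_pref[r];
        for (int k = 0; k < K; ++k)
          hapB[k] = theta(k, m) * pa + (1.0 - theta(k, m)) * pr;
        for (int k2 = 0; k2 < K; ++k2)
          for (int k1 = 0; k1 < K; ++k1)
            E[a][k1 + K * k2] *= 0.5 * (hapB[k1] + hapB[k2]);
      }
    }

    // forward over active grids (store normalized F per active grid)
    std::vector<vec> Fs(A);
    double loglik = 0.0;
    for (int a = 0; a < A; ++a) {
      if (a == 0) F = prior;
      else {
        double s = std::exp(cumlog_surv[ag[a]] - cumlog_surv[ag[a - 1]]);
        fwd_trans(F, s, piv, K);
      }
      for (int j = 0; j < KK; ++j) F[j] *= E[a][j];
      double c = normalize(F);
      if (c <= 0.0) stop("zero forward probability (degenerate emission)");
      loglik += std::log(c);
      Fs[a] = F;
    }
    total_loglik += loglik;

    // backward: Xs[a] = normalized Bm_a * E_a (emission-inclusive)
    std::vector<vec> Bs(A), Xs(A);
    for (int a = A - 1; a >= 0; --a) {
      if (a == A - 1) Bm.assign(KK, 1.0);
      else {
        Bm = Xs[a + 1];
        double s = std::exp(cumlog_surv[ag[a + 1]] - cumlog_surv[ag[a]]);
        bwd_trans(Bm, s, piv, K);
      }
      Bs[a] = Bm;
      vec X(KK);
      for (int j = 0; j < KK; ++j) X[j] = Bm[j] * E[a][j];
      normalize(X);
      Xs[a] = X;
    }

    // posterior at active grids + per-read sufficient statistics
    if (want_suffstats) {
      for (int a = 0; a < A; ++a) {
        for (int j = 0; j < KK; ++j) gam[j] = Fs[a][j] * Bs[a][j];
        normalize(gam);
        for (int r = astart[a]; r < aend[a]; ++r) {
          const int m = read_site[r];
          const double pa = read_palt[r], pr = read_pref[r];
          vec walt(K), wref(K);
          for (int k = 0; k < K; ++k) {
            walt[k] = 0.5 * theta(k, m) * pa;
            wref[k] = 0.5 * (1.0 - theta(k, m)) * pr;
          }
          for (int k2 = 0; k2 < K; ++k2) {
            for (int k1 = 0; k1 < K; ++k1) {
              const double g = gam[k1 + K * k2];
              if (g <= 0.0) continue;
              const double D = walt[k1] + wref[k1] + walt[k2] + wref[k2];
              if (D <= 0.0) continue;
              theta_num(k1, m) += g * walt[k1] / D;
              theta_den(k1, m) += g * (walt[k1] + wref[k1]) / D;
              theta_num(k2, m) += g * walt[k2] / D;
              theta_den(k2, m) += g * (walt[k2] + wref[k2]) / D;
            }
          }
        }
      }
    }

    // full posteriors over sites (and optional per-grid gamma export)
    if (want_posteriors || i == gamma_sample) {
      // per-site read ranges for the shared-allele genotype posterior
      int rp = r0;
      // walk grids via sites; track bracketing active grids
      int a_prev = -1; // last active grid index with ag[a_prev] <= current g
      vec Fg(KK), Bg(KK);
      int cached_g = -2;
      for (int m = 0; m < M; ++m) {
        const int g = grid_of_site[m];
        while (a_prev + 1 < A && ag[a_prev + 1] <= g) ++a_prev;
        if (g != cached_g) {
          // forward part
          if (a_prev < 0) Fg = prior;
          else {
            Fg = Fs[a_prev];
            if (ag[a_prev] != g) {
              double s = std::exp(cumlog_surv[g] - cumlog_surv[ag[a_prev]]);
              fwd_trans(Fg, s, piv, K);
            }
          }
          // backward part: first active grid strictly after g
          int a_next = a_prev + 1;
          if (a_prev >= 0 && ag[a_prev] == g) {
            Bg = Bs[a_prev];
          } else if (a_next >= A) {
            Bg.assign(KK, 1.0);
          } else {
            Bg = Xs[a_next];
            double s = std::exp(cumlog_surv[ag[a_next]] - cumlog_surv[g]);
            bwd_trans(Bg, s, piv, K);
          }
          cached_g = g;
        }
        for (int j = 0; j < KK; ++j) gam[j] = Fg[j] * Bg[j];
        normalize(gam);
        if (i == gamma_sample)
          for (int j = 0; j < KK; ++j) gamma_out(j, g) = gam[j];
        if (!want_posteriors) continue;

        // reads at this site (reads sorted by site within sample)
        while (rp < r1 && read_site[rp] < m) ++rp;
        int re = rp;
        while (re < r1 && read_site[re] == m) ++re;

        double q0 = 0.0, q1 = 0.0, q2 = 0.0;
        if (re == rp) {
          // no reads: alleles independent Bernoulli(theta) given state
          double E1 = 0.0, E2 = 0.0, E12 = 0.0;
          for (int k2 = 0; k2 < K; ++k2) {
            const double t2 = theta(k2, m);
            for (int k1 = 0; k1 < K; ++k1) {
              const double g_ = gam[k1 + K * k2];
              const double t1 = theta(k1, m);
              E1 += g_ * t1; E2 += g_ * t2; E12 += g_ * t1 * t2;
            }
          }
          q2 = E12; q1 = E1 + E2 - 2.0 * E12; q0 = 1.0 - q1 - q2;
        } else {
          // shared-allele likelihood of the site's reads, per (a1, a2)
          double lik[2][2] = {{1.0, 1.0}, {1.0, 1.0}};
          for (int r = rp; r < re; ++r) {
            const double pa = read_palt[r], pr = read_pref[r];
            lik[0][0] *= pr;
            lik[0][1] *= 0.5 * (pr + pa);
            lik[1][0] *= 0.5 * (pa + pr);
            lik[1][1] *= pa;
          }
          for (int k2 = 0; k2 < K; ++k2) {
            const double t2 = theta(k2, m);
            for (int k1 = 0; k1 < K; ++k1) {
              const double g_ = gam[k1 + K * k2];
              if (g_ <= 0.0) continue;
              const double t1 = theta(k1, m);
              const double w00 = (1 - t1) * (1 - t2) * lik[0][0];
              const double w01 = (1 - t1) * t2 * lik[0][1];
              const double w10 = t1 * (1 - t2) * lik[1][0];
              const double w11 = t1 * t2 * lik[1][1];
              const double W = w00 + w01 + w10 + w11;
              if (W <= 0.0) continue;
              q0 += g_ * w00 / W;
              q1 += g_ * (w01 + w10) / W;
              q2 += g_ * w11 / W;
            }
          }
        }
        const double qs = q0 + q1 + q2;
        if (qs > 0.0) { q0 /= qs; q1 /= qs; q2 /= qs; }
        p0(i, m) = q0; p1(i, m) = q1; p2(i, m) = q2;
        rp = re;
      }
    }
  }

  List out = List::create(_["loglik"] = total_loglik);
  if (want_suffstats) {
    out["theta_num"] = theta_num;
    out["theta_den"] = theta_den;
  }
  if (want_posteriors) {
    out["p0"] = p0; out["p1"] = p1; out["p2"] = p2;
  }
  if (gamma_sample >= 0) out["gamma"] = gamma_out;
  return out;
}
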