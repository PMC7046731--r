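#include <Rcpp.h>
using namespace Rcpp;

// Haplotype-cluster HMM with jump-style transitions:
//   P(z_1 = k)            = alpha(1, k)
//   P(z_j = k' | z_{j-1}) = (1 - r_j) * 1{k' = z_{j-1}} + r_j * alpha(j, k')
//   P(h_j = 1 | z_j = k)  = theta(j, k)
// All recursions below use per-site scaling; matrices are p x K.

static inline double emit(const double th, const int h) {
  return h == 1 ? th : 1.0 - th;
}

// Scaled forward pass for one haplotype; fills A (p x K, row-normalized) and
// returns the log-likelihood. Returns -Inf on an impossible observation.
static double forward_one(const IntegerMatrix& H, const int i,
                          const NumericMatrix& alpha, const NumericMatrix& theta,
                          const NumericVector& r, std::vector<double>& A) {
  const int p = alpha.nrow(), K = alpha.ncol();
  double ll = 0.0;
  double c = 0.0;
  for (int k = 0; k < K; ++k) {
    double v = alpha(0, k) * emit(theta(0, k), H(i, 0));
    A[k] = v;
    c += v;
  }
  if (c <= 0.0) return R_NegInf;
  for (int k = 0; k < K; ++k) A[k] /= c;
  ll += std::log(c);
  for (int j = 1; j < p; ++j) {
    const double rj = r[j];
    c = 0.0;
    for (int k = 0; k < K; ++k) {
      // previous row sums to one, so the jump mass is just r_j * alpha(j, k)
      double pre = (1.0 - rj) * A[(j - 1) * K + k] + rj * alpha(j, k);
      double v = pre * emit(theta(j, k), H(i, j));
      A[j * K + k] = v;
      c += v;
    }
    if (c <= 0.0) return R_NegInf;
    for (int k = 0; k < K; ++k) A[j * K + k] /= c;
    ll += std::log(c);
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector cpp_hap_loglik(IntegerMatrix H, NumericMatrix alpha,
                             NumericMatrix theta, NumericVector r) {
  const int n = H.nrow(), p = alpha.nrow(), K = alpha.ncol();
  std::vector<double> A((size_t)p * K);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = forward_one(H, i, alpha, theta, r, A);
  return out;
}

// One full Baum-Welch fit (single start). Returns the per-iteration
// log-likelihood trace evaluated at the entry parameters of each iteration.
// [[Rcpp::export]]
List cpp_em_fit(IntegerMatrix H, NumericMatrix alpha0, NumericMatrix theta0,
                NumericVector r0, int max_iter, double tol) {
  const int n = H.nrow(), p = alpha0.nrow(), K = alpha0.ncol();
  NumericMatrix alpha = clone(alpha0), theta = clone(theta0);
  NumericVector r = clone(r0);
  const double eps_th = 1e-6, eps_r = 1e-6;
  std::vector<double> A((size_t)p * K), B(K), Bnext(K), gamma(K);
  std::vector<double> cvec(p);
  std::vector<double> Sg1(K), SjN((size_t)p * K), SJ(p), StN((size_t)p * K),
      StD((size_t)p * K);
  std::vector<double> ll_trace;

  for (int it = 0; it < max_iter; ++it) {
    std::fill(Sg1.begin(), Sg1.end(), 0.0);
    std::fill(SjN.begin(), SjN.end(), 0.0);
    std::fill(SJ.begin(), SJ.end(), 0.0);
    std::fill(StN.begin(), StN.end(), 0.0);
    std::fill(StD.begin(), StD.end(), 0.0);
    double ll = 0.0;

    for (int i = 0; i < n; ++i) {
      // forward with stored scales
      double c = 0.0;
      for (int k = 0; k < K; ++k) {
        double v = alpha(0, k) * emit(theta(0, k), H(i, 0));
        A[k] = v;
        c += v;
      }
      if (c <= 0.0) stop("impossible observation under current parameters");
      for (int k = 0; k < K; ++k) A[k] /= c;
      cvec[0] = c;
      ll += std::log(c);
      for (int j = 1; j < p; ++j) {
        const double rj = r[j];
        c = 0.0;
        for (int k = 0; k < K; ++k) {
          double pre = (1.0 - rj) * A[(j - 1) * K + k] + rj * alpha(j, k);
          double v = pre * emit(theta(j, k), H(i, j));
          A[j * K + k] = v;
          c += v;
        }
        if (c <= 0.0) stop("impossible observation under current parameters");
        for (int k = 0; k < K; ++k) A[j * K + k] /= c;
        cvec[j] = c;
        ll += std::log(c);
      }
      // backward, accumulating statistics
      std::fill(B.begin(), B.end(), 1.0);
      for (int j = p - 1; j >= 1; --j) {
        // gamma_j and theta stats
        for (int k = 0; k < K; ++k) {
          double g = A[j * K + k] * B[k];
          gamma[k] = g;
          StD[j * K + k] += g;
          if (H(i, j) == 1) StN[j * K + k] += g;
        }
        // jump posterior at transition (j-1) -> j
        const double rj = r[j];
        double S = 0.0;  // sum_k alpha(j,k) e_j(k) B_j(k)
        for (int k = 0; k < K; ++k) {
          double ae = alpha(j, k) * emit(theta(j, k), H(i, j)) * B[k];
          S += ae;
          double jn = rj * ae / cvec[j];
          SjN[j * K + k] += jn;
          SJ[j] += jn;
        }
        // propagate B to site j-1
        for (int k = 0; k < K; ++k) {
          Bnext[k] = ((1.0 - rj) * emit(theta(j, k), H(i, j)) * B[k] + rj * S) /
                     cvec[j];
        }
        std::swap(B, Bnext);
      }
      for (int k = 0; k < K; ++k) {
        double g = A[k] * B[k];
        Sg1[k] += g;
        StD[k] += g;
        if (H(i, 0) == 1) StN[k] += g;
      }
    }

    ll_trace.push_back(ll);
    if (it > 0 && ll - ll_trace[it - 1] < tol) break;

    // M-step
    double s1 = 0.0;
    for (int k = 0; k < K; ++k) s1 += Sg1[k];
    for (int k = 0; k < K; ++k) alpha(0, k) = Sg1[k] / s1;
    for (int j = 1; j < p; ++j) {
      double J = SJ[j];
      double rj = J / n;
      if (rj < eps_r) rj = eps_r;
      if (rj > 1.0 - eps_r) rj = 1.0 - eps_r;
      r[j] = rj;
      if (J > 1e-12) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += SjN[j * K + k];
        for (int k = 0; k < K; ++k) alpha(j, k) = SjN[j * K + k] / s;
      }
    }
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < K; ++k) {
        double d = StD[j * K + k];
        double th = d > 1e-12 ? StN[j * K + k] / d : theta(j, k);
        if (th < eps_th) th = eps_th;
        if (th > 1.0 - eps_th) th = 1.0 - eps_th;
        theta(j, k) = th;
      }
    }
  }

  return List::create(_["alpha"] = alpha, _["theta"] = theta, _["r"] = r,
                      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()));
}

static inline int sample_state(const std::vector<double>& w, const int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += w[k];
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// Draw one latent path per haplotype from the exact posterior P(Z | H = h),
// by backward sampling from the scaled forward quantities. 1-based states.
// [[Rcpp::export]]
IntegerMatrix cpp_posterior_sample(IntegerMatrix H, NumericMatrix alpha,
                                   NumericMatrix theta, NumericVector r) {
  const int n = H.nrow(), p = alpha.nrow(), K = alpha.ncol();
  std::vector<double> A((size_t)p * K), w(K);
  IntegerMatrix Z(n, p);
  for (int i = 0; i < n; ++i) {
    double ll = forward_one(H, i, alpha, theta, r, A);
    if (!R_finite(ll)) stop("impossible observation: haplotype has probability zero under the model");
    for (int k = 0; k < K; ++k) w[k] = A[(p - 1) * K + k];
    int z = sample_state(w, K);
    Z(i, p - 1) = z + 1;
    for (int j = p - 2; j >= 0; --j) {
      const double rn = r[j + 1];
      const double aj = alpha(j + 1, z);
      for (int k = 0; k < K; ++k) w[k] = A[j * K + k] * rn * aj;
      w[z] += A[j * K + z] * (1.0 - rn);
      z = sample_state(w, K);
      Z(i, j) = z + 1;
    }
  }
  return Z;
}

// Group knockoff copy of latent Markov paths by sequential conditional
// independent pairs. For each group (sites a..b) the knockoff segment is
// drawn jointly from its conditional law given (z, ztilde of earlier groups),
// via a forward pass restricted to the group and backward sampling. The
// normalizing function n_s(k) carried between groups makes the pair
// exchangeable within every group. O(p K^2) per path.
// `group` is a 1-based, non-decreasing, contiguous group index of length p.
// [[Rcpp::export]]
IntegerMatrix cpp_knockoff_chain(IntegerMatrix Z, NumericMatrix alpha,
                                 NumericVector r, IntegerVector group) {
  const int n = Z.nrow(), p = alpha.nrow(), K = alpha.ncol();
  if (group.size() != p) stop("group index length must equal p");
  // group boundaries
  std::vector<int> ga, gb;
  for (int j = 0; j < p; ++j) {
    if (j == 0 || group[j] != group[j - 1]) ga.push_back(j);
    if (j == p - 1 || group[j] != group[j + 1]) gb.push_back(j);
  }
  const int L = (int)ga.size();
  IntegerMatrix Zt(n, p);
  std::vector<double> phi((size_t)p * K), nprev(K), w(K), V(K);

  for (int i = 0; i < n; ++i) {
    std::fill(nprev.begin(), nprev.end(), 1.0);
    for (int s = 0; s < L; ++s) {
      const int a = ga[s], b = gb[s];
      // V: weight at the group's first site
      if (a == 0) {
        for (int k = 0; k < K; ++k) V[k] = alpha(0, k);
      } else {
        const double ra = r[a];
        const int zl = Z(i, a - 1) - 1, ztl = Zt(i, a - 1) - 1;
        for (int k = 0; k < K; ++k) {
          double qz = ra * alpha(a, k) + (k == zl ? 1.0 - ra : 0.0);
          double qt = ra * alpha(a, k) + (k == ztl ? 1.0 - ra : 0.0);
          double num = qz * qt;
          V[k] = num > 0.0 ? num / std::max(nprev[k], 1e-300) : 0.0;
        }
      }
      // forward pass within the group (row-normalized for stability)
      double c = 0.0;
      for (int k = 0; k < K; ++k) c += V[k];
      if (c <= 0.0) stop("zero-probability path in knockoff sampler");
      for (int k = 0; k < K; ++k) phi[a * K + k] = V[k] / c;
      for (int j = a + 1; j <= b; ++j) {
        const double rj = r[j];
        c = 0.0;
        for (int k = 0; k < K; ++k) {
          double v = (1.0 - rj) * phi[(j - 1) * K + k] + rj * alpha(j, k);
          phi[j * K + k] = v;
          c += v;
        }
        for (int k = 0; k < K; ++k) phi[j * K + k] /= c;
      }
      // sample the last site of the group
      if (b == p - 1) {
        for (int k = 0; k < K; ++k) w[k] = phi[b * K + k];
      } else {
        const double rn = r[b + 1];
        const int zn = Z(i, b + 1) - 1;
        const double an = alpha(b + 1, zn);
        for (int k = 0; k < K; ++k) w[k] = phi[b * K + k] * rn * an;
        w[zn] += phi[b * K + zn] * (1.0 - rn);
      }
      int zt = sample_state(w, K);
      Zt(i, b) = zt + 1;
      // backward sampling within the group
      for (int j = b - 1; j >= a; --j) {
        const double rn = r[j + 1];
        const double an = alpha(j + 1, zt);
        for (int k = 0; k < K; ++k) w[k] = phi[j * K + k] * rn * an;
        w[zt] += phi[j * K + zt] * (1.0 - rn);
        zt = sample_state(w, K);
        Zt(i, j) = zt + 1;
      }
      // normalizing function for the next group: n_s(k) = sum_m phi_b(m) Q_{b+1}(m, k)
      if (b < p - 1) {
        const double rn = r[b + 1];
        double sp = 0.0;
        for (int k = 0; k < K; ++k) sp += phi[b * K + k];
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          nprev[k] = (1.0 - rn) * phi[b * K + k] + rn * alpha(b + 1, k) * sp;
          tot += nprev[k];
        }
        for (int k = 0; k < K; ++k) nprev[k] /= tot;
      }
    }
  }
  return Zt;
}
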