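// Uncollapsed Gibbs sampler for the sparse Poisson factorization model:
// IBP prior on the binary activation matrix Z, Gamma priors on the
// nonnegative factor/bias weights, Bernoulli-Poisson observations
// P(x=1) = 1 - exp(-lambda) with lambda = bias + Z beta. Weight updates
// are Gamma-conjugate through zero-truncated Poisson count augmentation
// on the observed x=1 cells. Missing cells are coded -1 and masked.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef std::vector<std::vector<int> > ZCols;     // columns of Z, length N
typedef std::vector<std::vector<double> > BetaRows; // rows of beta, length D

// zero-truncated Poisson via inversion (counts are almost always small)
static int rztpois(double lambda) {
    if (lambda < 1e-12) return 1;
    double u = unif_rand();
    double p = lambda / expm1(lambda); // P(c = 1)
    double cum = p;
    int j = 1;
    while (u > cum && j < 500) {
        ++j;
        p *= lambda / j;
        cum += p;
    }
    return j;
}

static double cell_ll(int x, double lam) {
    if (x == 1) {
        if (lam <= 0) return R_NegInf;
        return std::log(-expm1(-lam));
    }
    return -lam;
}

static double row_ll(const IntegerMatrix& X, int n,
                     const std::vector<double>& lam) {
    const int D = X.ncol();
    double out = 0.0;
    for (int d = 0; d < D; ++d) {
        int x = X(n, d);
        if (x < 0) continue;
        out += cell_ll(x, lam[d]);
    }
    return out;
}

static double full_ll(const IntegerMatrix& X, const ZCols& Z,
                      const BetaRows& beta,
                      const std::vector<double>& bias) {
    const int N = X.nrow(), D = X.ncol(), K = (int)Z.size();
    double out = 0.0;
    std::vector<double> lam(D);
    for (int n = 0; n < N; ++n) {
        for (int d = 0; d < D; ++d) lam[d] = bias[d];
        for (int k = 0; k < K; ++k)
            if (Z[k][n])
                for (int d = 0; d < D; ++d) lam[d] += beta[k][d];
        out += row_ll(X, n, lam);
    }
    return out;
}

// log probability of the left-ordered equivalence class of Z under the
// IBP(alpha): alpha^K / (prod_h K_h!) * exp(-alpha H_N) *
//             prod_k (N - m_k)! (m_k - 1)! / N!
static double ibp_lp(const ZCols& Z, double alpha, int N) {
    const int K = (int)Z.size();
    double hN = 0.0;
    for (int i = 1; i <= N; ++i) hN += 1.0 / i;
    double out = K * std::log(alpha) - alpha * hN;
    std::vector<int> seen(K, 0);
    for (int k = 0; k < K; ++k) {
        if (seen[k]) continue;
        int c = 1;
        for (int j = k + 1; j < K; ++j)
            if (!seen[j] && Z[j] == Z[k]) { seen[j] = 1; ++c; }
        out -= R::lgammafn(c + 1.0);
    }
    for (int k = 0; k < K; ++k) {
        int m = 0;
        for (size_t n = 0; n < Z[k].size(); ++n) m += Z[k][n];
        out += R::lgammafn(N - m + 1.0) + R::lgammafn((double)m)
             - R::lgammafn(N + 1.0);
    }
    return out;
}

static double gamma_lp(const BetaRows& beta, const std::vector<double>& bias,
                       double a, double b) {
    double out = 0.0;
    for (size_t k = 0; k < beta.size(); ++k)
        for (size_t d = 0; d < beta[k].size(); ++d)
            out += R::dgamma(beta[k][d], a, 1.0 / b, 1);
    for (size_t d = 0; d < bias.size(); ++d)
        out += R::dgamma(bias[d], a, 1.0 / b, 1);
    return out;
}

static IntegerMatrix z_as_matrix(const ZCols& Z, int N) {
    const int K = (int)Z.size();
    IntegerMatrix out(N, K);
    for (int k = 0; k < K; ++k)
        for (int n = 0; n < N; ++n) out(n, k) = Z[k][n];
    return out;
}

static NumericMatrix beta_as_matrix(const BetaRows& beta, int D) {
    const int K = (int)beta.size();
    NumericMatrix out(K, D);
    for (int k = 0; k < K; ++k)
        for (int d = 0; d < D; ++d) out(k, d) = beta[k][d];
    return out;
}

// [[Rcpp::export]]
List spfm_gibbs(IntegerMatrix X, int n_iter, int burn_in,
                double alpha, NumericVector alpha_prior,
                double beta_shape, double beta_rate,
                int max_new, int thin,
                int k_init, double z_init_prob) {
    const int N = X.nrow(), D = X.ncol();
    double hN = 0.0;
    for (int i = 1; i <= N; ++i) hN += 1.0 / i;

    // per-item observed counts (bias exposure)
    std::vector<int> nObs(D, 0);
    for (int d = 0; d < D; ++d)
        for (int n = 0; n < N; ++n)
            if (X(n, d) >= 0) ++nObs[d];

    // overcomplete random initialization: k_init factors with random
    // memberships; surplus factors lose members during burn-in and are
    // pruned, which nucleates shared factors far more reliably than
    // growing them from single-patient births alone
    ZCols Z;
    BetaRows beta;
    std::vector<int> m;       // column sums of Z
    for (int k = 0; k < k_init; ++k) {
        std::vector<int> col(N, 0);
        int mk = 0;
        for (int n = 0; n < N; ++n)
            if (unif_rand() < z_init_prob) { col[n] = 1; ++mk; }
        if (mk == 0) continue;
        std::vector<double> row(D);
        for (int d = 0; d < D; ++d)
            row[d] = R::rgamma(beta_shape, 1.0 / beta_rate);
        Z.push_back(col);
        beta.push_back(row);
        m.push_back(mk);
    }
    std::vector<double> bias(D);
    for (int d = 0; d < D; ++d)
        bias[d] = R::rgamma(beta_shape, 1.0 / beta_rate);

    // lambda[n][d], kept in sync with Z/beta/bias
    std::vector<std::vector<double> > lam(N, std::vector<double>(D));
    for (int n = 0; n < N; ++n) {
        for (int d = 0; d < D; ++d) lam[n][d] = bias[d];
        for (size_t k = 0; k < Z.size(); ++k)
            if (Z[k][n])
                for (int d = 0; d < D; ++d) lam[n][d] += beta[k][d];
    }

    NumericVector trace(n_iter);
    std::vector<int> kSamples;
    List thinned;
    std::map<int, List> lastByK;

    for (int it = 0; it < n_iter; ++it) {
        int K = (int)Z.size();

        // ---- Gibbs updates of existing activations + singleton MH ----
        for (int n = 0; n < N; ++n) {
            K = (int)Z.size();
            for (int k = 0; k < K; ++k) {
                int z = Z[k][n];
                int mOther = m[k] - z;
                if (mOther == 0) continue;   // singleton: handled by MH
                double loglr = 0.0;
                for (int d = 0; d < D; ++d) {
                    int x = X(n, d);
                    if (x < 0) continue;
                    double bkd = beta[k][d];
                    if (bkd == 0.0) continue;
                    double lam0 = lam[n][d] - z * bkd;
                    if (x == 1)
                        loglr += cell_ll(1, lam0 + bkd) - cell_ll(1, lam0);
                    else
                        loglr -= bkd;
                }
                double logit = std::log((double)mOther)
                             - std::log((double)(N - mOther)) + loglr;
                int zNew = (unif_rand() < 1.0 / (1.0 + std::exp(-logit)))
                           ? 1 : 0;
                if (zNew != z) {
                    Z[k][n] = zNew;
                    m[k] += zNew - z;
                    double sgn = zNew - z;
                    for (int d = 0; d < D; ++d)
                        lam[n][d] += sgn * beta[k][d];
                }
            }

            // MH birth/death of this patient's singleton factors,
            // proposing from the prior: k* ~ Poisson(alpha/N) (capped),
            // new weight rows from the Gamma prior.
            std::vector<int> own;
            for (int k = 0; k < (int)Z.size(); ++k)
                if (m[k] == 1 && Z[k][n] == 1) own.push_back(k);
            int kNew = (int)R::rpois(alpha / N);
            if (kNew > max_new) kNew = max_new;
            if (kNew == (int)own.size() && kNew == 0) continue;

            std::vector<std::vector<double> > prop(kNew,
                std::vector<double>(D));
            for (int j = 0; j < kNew; ++j)
                for (int d = 0; d < D; ++d)
                    prop[j][d] = R::rgamma(beta_shape, 1.0 / beta_rate);

            std::vector<double> lamNew(D);
            for (int d = 0; d < D; ++d) {
                double v = lam[n][d];
                for (size_t j = 0; j < own.size(); ++j)
                    v -= beta[own[j]][d];
                for (int j = 0; j < kNew; ++j) v += prop[j][d];
                lamNew[d] = v;
            }
            double logAcc = 0.0;
            for (int d = 0; d < D; ++d) {
                int x = X(n, d);
                if (x < 0) continue;
                logAcc += cell_ll(x, lamNew[d]) - cell_ll(x, lam[n][d]);
            }
            if (std::log(unif_rand()) < logAcc) {
                // delete old singleton columns (descending indices)
                for (int j = (int)own.size() - 1; j >= 0; --j) {
                    int k = own[j];
                    Z.erase(Z.begin() + k);
                    beta.erase(beta.begin() + k);
                    m.erase(m.begin() + k);
                }
                for (int j = 0; j < kNew; ++j) {
                    std::vector<int> col(N, 0);
                    col[n] = 1;
                    Z.push_back(col);
                    beta.push_back(prop[j]);
                    m.push_back(1);
                }
                lam[n] = lamNew;
            }
        }

        // ---- prune empty factors ----
        for (int k = (int)Z.size() - 1; k >= 0; --k) {
            if (m[k] == 0) {
                Z.erase(Z.begin() + k);
                beta.erase(beta.begin() + k);
                m.erase(m.begin() + k);
            }
        }
        K = (int)Z.size();

        // ---- Poisson count augmentation on observed x = 1 cells ----
        std::vector<std::vector<double> > S(K, std::vector<double>(D, 0.0));
        std::vector<double> Sb(D, 0.0);
        std::vector<int> act;
        for (int n = 0; n < N; ++n) {
            act.clear();
            for (int k = 0; k < K; ++k) if (Z[k][n]) act.push_back(k);
            for (int d = 0; d < D; ++d) {
                if (X(n, d) != 1) continue;
                double l = lam[n][d];
                int c = rztpois(l);
                // multinomial thinning over {bias, active factors}
                int rem = c;
                double tot = l;
                double w = bias[d];
                int cb = (tot > 0)
                    ? (int)R::rbinom(rem, std::min(1.0, w / tot)) : rem;
                Sb[d] += cb;
                rem -= cb; tot -= w;
                for (size_t j = 0; j < act.size() && rem > 0; ++j) {
                    int k = act[j];
                    if (j + 1 == act.size()) { S[k][d] += rem; rem = 0; break; }
                    double wk = beta[k][d];
                    int ck = (tot > 0)
                        ? (int)R::rbinom(rem, std::min(1.0, wk / tot)) : 0;
                    S[k][d] += ck;
                    rem -= ck; tot -= wk;
                }
            }
        }

        // ---- conjugate Gamma updates of weights ----
        for (int k = 0; k < K; ++k) {
            std::vector<int> expo(D, 0);   // active & observed cells
            for (int n = 0; n < N; ++n) {
                if (!Z[k][n]) continue;
                for (int d = 0; d < D; ++d)
                    if (X(n, d) >= 0) ++expo[d];
            }
            for (int d = 0; d < D; ++d)
                beta[k][d] = R::rgamma(beta_shape + S[k][d],
                                       1.0 / (beta_rate + expo[d]));
        }
        for (int d = 0; d < D; ++d)
            bias[d] = R::rgamma(beta_shape + Sb[d],
                                1.0 / (beta_rate + nObs[d]));

        // rates changed wholesale: rebuild lambda
        for (int n = 0; n < N; ++n) {
            for (int d = 0; d < D; ++d) lam[n][d] = bias[d];
            for (int k = 0; k < K; ++k)
                if (Z[k][n])
                    for (int d = 0; d < D; ++d) lam[n][d] += beta[k][d];
        }

        // ---- optional alpha update under Gamma hyperprior ----
        if (alpha_prior.size() == 2)
            alpha = R::rgamma(alpha_prior[0] + K,
                              1.0 / (alpha_prior[1] + hN));

        trace[it] = ibp_lp(Z, alpha, N)
                  + gamma_lp(beta, bias, beta_shape, beta_rate)
                  + full_ll(X, Z, beta, bias);

        if (it >= burn_in) {
            kSamples.push_back(K);
            lastByK[K] = List::create(
                _["Z"] = z_as_matrix(Z, N),
                _["beta"] = beta_as_matrix(beta, D),
                _["bias"] = NumericVector(bias.begin(), bias.end()));
            if ((it - burn_in) % thin == 0)
                thinned.push_back(List::create(
                    _["beta"] = beta_as_matrix(beta, D),
                    _["bias"] = NumericVector(bias.begin(), bias.end())));
        }
    }

    List lbk;
    CharacterVector lbkNames;
    for (std::map<int, List>::iterator it2 = lastByK.begin();
         it2 != lastByK.end(); ++it2) {
        lbk.push_back(it2->second);
        lbkNames.push_back(std::to_string(it2->first));
    }
    lbk.attr("names") = lbkNames;

    return List::create(
        _["trace"] = trace,
        _["K_samples"] = IntegerVector(kSamples.begin(), kSamples.end()),
        _["thinned"] = thinned,
        _["last_by_K"] = lbk,
        _["alpha"] = alpha);
}
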