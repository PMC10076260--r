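#include <Rcpp.h>
using namespace Rcpp;

// Li & Stephens copying-model forward-backward with per-site scaling.
//
// donors: N x L matrix of {0,1,NA} donor alleles
// recip:  length-L vector of {0,1,NA} recipient alleles
// dist:   length-(L-1) physical distances (bp) between adjacent sites;
//         a non-positive distance (chromosome break) forces a free switch.
// switch probability over d bp: s = 1 - exp(-Ne * rho * d / N); the copied
// donor then resets uniformly (self-copy keeps its 1/N share of the switch
// mass). Emission: allele matches the copied donor with prob 1 - mu.
//
// Returns posterior copying probabilities (L x N), the log-likelihood,
// per-interval switch-event posteriors, and the expected miscopy count and
// number of informative emissions (for EM updates of mu).
// [[Rcpp::export]]
List ls_forward_backward(IntegerMatrix donors, IntegerVector recip,
                         NumericVector dist, double Ne, double rho,
                         double mu) {
  const int N = donors.nrow(), L = donors.ncol();
  if (N < 1) stop("at least one donor haplotype is required");
  if (recip.size() != L) stop("recipient and donors disagree on site count");
  if (dist.size() != L - 1) stop("dist must have length n_sites - 1");

  NumericMatrix emit(N, L);
  for (int l = 0; l < L; ++l) {
    int y = recip[l];
    for (int j = 0; j < N; ++j) {
      int d = donors(j, l);
      if (y == NA_INTEGER || d == NA_INTEGER) emit(j, l) = 1.0;
      else emit(j, l) = (d == y) ? (1.0 - mu) : mu;
    }
  }

  NumericVector s(L - 1);
  for (int l = 0; l < L - 1; ++l) {
    double d = dist[l];
    s[l] = (d <= 0) ? 1.0 : (1.0 - std::exp(-Ne * rho * d / N));
  }

  NumericMatrix fwd(N, L);
  NumericVector c(L);
  double loglik = 0.0;
  {
    double tot = 0.0;
    for (int j = 0; j < N; ++j) { fwd(j, 0) = emit(j, 0) / N; tot += fwd(j, 0); }
    c[0] = tot;
    for (int j = 0; j < N; ++j) fwd(j, 0) /= tot;
    loglik += std::log(tot);
  }
  for (int l = 1; l < L; ++l) {
    double sw = s[l - 1], stay = 1.0 - sw, tot = 0.0;
    for (int j = 0; j < N; ++j) {
      double v = emit(j, l) * (stay * fwd(j, l - 1) + sw / N);
      fwd(j, l) = v; tot += v;
    }
    c[l] = tot;
    for (int j = 0; j < N; ++j) fwd(j, l) /= tot;
    loglik += std::log(tot);
  }

  NumericMatrix bwd(N, L);
  for (int j = 0; j < N; ++j) bwd(j, L - 1) = 1.0;
  NumericVector switch_post(std::max(L - 1, 0));
  for (int l = L - 2; l >= 0; --l) {
    double sw = s[l], stay = 1.0 - sw;
    double pool = 0.0;
    for (int j = 0; j < N; ++j) pool += emit(j, l + 1) * bwd(j, l + 1);
    double nostay = 0.0;
    for (int j = 0; j < N; ++j) {
      bwd(j, l) = (stay * emit(j, l + 1) * bwd(j, l + 1) + sw / N * pool) / c[l + 1];
      nostay += fwd(j, l) * stay * emit(j, l + 1) * bwd(j, l + 1);
    }
    switch_post[l] = 1.0 - nostay / c[l + 1];
  }

  NumericMatrix gamma(L, N);
  double exp_miscopy = 0.0, n_emit = 0.0;
  for (int l = 0; l < L; ++l) {
    int y = recip[l];
    for (int j = 0; j < N; ++j) {
      double g = fwd(j, l) * bwd(j, l);
      gamma(l, j) = g;
      int d = donors(j, l);
      if (y != NA_INTEGER && d != NA_INTEGER) {
        n_emit += g;
        if (d != y) exp_miscopy += g;
      }
    }
  }

  return List::create(_["gamma"] = gamma, _["loglik"] = loglik,
                      _["switch_post"] = switch_post,
                      _["exp_miscopy"] = exp_miscopy,
                      _["n_emit"] = n_emit);
}

// Haplotype-cluster HMM (fastPHASE-style LD model) EM fit.
//
// haps:  H x L matrix of {0,1,NA} alleles
// dist:  length-(L-1) distances; non-positive forces a free jump
// theta: K x L initial cluster allele frequencies (modified in place copy)
// alpha: K x L initial cluster weights (columns sum to 1)
// rho:   initial per-bp jump intensity
// Jump model: between adjacent sites a jump occurs with prob
// 1 - exp(-rho * d); on a jump the new cluster is drawn from alpha[, l+1].
//
// Returns fitted theta/alpha/rho, the log-likelihood trace, and per-
// haplotype cluster posteriors (H x L x K, returned as a list of K
// H x L slices when return_gamma, else only summed by pop).
// [[Rcpp::export]]
List cluster_hmm_em(IntegerMatrix haps, NumericVector dist,
                    NumericMatrix theta0, NumericMatrix alpha0,
                    double rho, IntegerVector pop, int n_pop,
                    int max_iter, double tol, bool return_gamma) {
  const int H = haps.nrow(), L = haps.ncol();
  const int K = theta0.nrow();
  if (theta0.ncol() != L || alpha0.ncol() != L)
    stop("theta/alpha must be K x L");
  NumericMatrix theta(clone(theta0)), alpha(clone(alpha0));

  std::vector<double> loglik_trace;
  NumericVector jump(L - 1);

  // per-pop haplotype counts
  std::vector<double> pop_n(n_pop, 0.0);
  for (int h = 0; h < H; ++h) pop_n[pop[h]] += 1.0;

  // outputs
  NumericVector pop_freq(n_pop * K * L);   // [pop + n_pop*(k + K*l)]
  List gamma_out(return_gamma ? K : 0);
  std::vector<NumericMatrix> gam_slices;
  if (return_gamma)
    for (int k = 0; k < K; ++k) gam_slices.push_back(NumericMatrix(H, L));

  std::vector<double> fwd(K * L), bwd(K * L), cs(L), em(K);
  double prev_ll = R_NegInf;
  double total_dist = 0.0;
  for (int l = 0; l < L - 1; ++l) if (dist[l] > 0) total_dist += dist[l];

  for (int iter = 0; iter < max_iter; ++iter) {
    for (int l = 0; l < L - 1; ++l)
      jump[l] = (dist[l] <= 0) ? 1.0 : (1.0 - std::exp(-rho * dist[l]));

    // accumulators
    NumericMatrix th_num(K, L), th_den(K, L);
    NumericMatrix arr(K, L);           // expected jump arrivals (and l=0 start)
    double exp_jumps = 0.0;
    std::fill(pop_freq.begin(), pop_freq.end(), 0.0);
    double ll = 0.0;

    for (int h = 0; h < H; ++h) {
      // forward
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        int y = haps(h, 0);
        double e = (y == NA_INTEGER) ? 1.0 : (y == 1 ? theta(k, 0) : 1.0 - theta(k, 0));
        fwd[k] = alpha(k, 0) * e; tot += fwd[k];
      }
      cs[0] = tot; for (int k = 0; k < K; ++k) fwd[k] /= tot;
      ll += std::log(tot);
      for (int l = 1; l < L; ++l) {
        double j = jump[l - 1], stay = 1.0 - j;
        int y = haps(h, l);
        tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double e = (y == NA_INTEGER) ? 1.0 : (y == 1 ? theta(k, l) : 1.0 - theta(k, l));
          double v = e * (stay * fwd[(l - 1) * K + k] + j * alpha(k, l));
          fwd[l * K + k] = v; tot += v;
        }
        cs[l] = tot;
        for (int k = 0; k < K; ++k) fwd[l * K + k] /= tot;
        ll += std::log(tot);
      }
      // backward + accumulation
      for (int k = 0; k < K; ++k) bwd[(L - 1) * K + k] = 1.0;
      for (int l = L - 2; l >= 0; --l) {
        double j = jump[l], stay = 1.0 - j;
        int y = haps(h, l + 1);
        double pool = 0.0;
        for (int k = 0; k < K; ++k) {
          em[k] = (y == NA_INTEGER) ? 1.0 : (y == 1 ? theta(k, l + 1) : 1.0 - theta(k, l + 1));
          pool += alpha(k, l + 1) * em[k] * bwd[(l + 1) * K + k];
        }
        double jp = 0.0;
        for (int k = 0; k < K; ++k) {
          bwd[l * K + k] = (stay * em[k] * bwd[(l + 1) * K + k] + j * pool) / cs[l + 1];
          // expected jump arrival into k between l and l+1
          double a = j * alpha(k, l + 1) * em[k] * bwd[(l + 1) * K + k] / cs[l + 1];
          arr(k, l + 1) += a; jp += a;
        }
        exp_jumps += jp;
      }
      for (int l = 0; l < L; ++l) {
        int y = haps(h, l);
        for (int k = 0; k < K; ++k) {
          double g = fwd[l * K + k] * bwd[l * K + k];
          if (l == 0) arr(k, 0) += g;
          if (y != NA_INTEGER) {
            th_den(k, l) += g;
            if (y == 1) th_num(k, l) += g;
          }
          pop_freq[pop[h] + n_pop * (k + K * l)] += g;
          if (return_gamma) gam_slices[k](h, l) = g;
        }
      }
    }

    loglik_trace.push_back(ll);

    bool last = (iter == max_iter - 1) ||
      (iter > 0 && std::abs(ll - prev_ll) < tol);
    prev_ll = ll;

    if (last) {
      for (int p = 0; p < n_pop; ++p)
        for (int k = 0; k < K; ++k)
          for (int l = 0; l < L; ++l)
            pop_freq[p + n_pop * (k + K * l)] /= pop_n[p];
      break;
    }

    // M-step
    for (int l = 0; l < L; ++l) {
      for (int k = 0; k < K; ++k) {
        if (th_den(k, l) > 1e-12) {
          double t = th_num(k, l) / th_den(k, l);
          theta(k, l) = std::min(std::max(t, 1e-4), 1.0 - 1e-4);
        }
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += arr(k, l);
      if (tot > 1e-10)
        for (int k = 0; k < K; ++k)
          alpha(k, l) = std::min(std::max(arr(k, l) / tot, 1e-6), 1.0);
      // renormalise
      double a = 0.0;
      for (int k = 0; k < K; ++k) a += alpha(k, l);
      for (int k = 0; k < K; ++k) alpha(k, l) /= a;
    }
    if (total_dist > 0) {
      double r = exp_jumps / (H * total_dist);
      rho = std::min(std::max(r, 1e-12), 1e-2);
    }
  }

  if (return_gamma)
    for (int k = 0; k < K; ++k) gamma_out[k] = gam_slices[k];

  return List::create(_["theta"] = theta, _["alpha"] = alpha, _["rho"] = rho,
                      _["loglik"] = NumericVector(loglik_trace.begin(),
                                                  loglik_trace.end()),
                      _["pop_freq"] = pop_freq,
                      _["gamma"] = gamma_out);
}
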