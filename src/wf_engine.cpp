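#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// risk families: 0 linear, 1 power, 2 sigmoid; frac = C / W0
static inline double risk_prob(int family, double lambda, double frac) {
  double p;
  switch (family) {
  case 0: p = 1.0 - lambda * frac; break;
  case 1: p = 1.0 - std::pow(frac, lambda); break;
  default: p = 1.0 / (std::exp(lambda * (frac - 0.5)) + 1.0);
  }
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// timing: 0 every_round, 1 first_round, 2 last_round, 3 random_round

// Wright-Fisher evolution of threshold strategies over the multi-round
// collective-risk game. `pops` holds one strategy matrix (N x 3*omega, trait
// order tau_r, a_r, b_r) per coevolving population. In paired mode each game
// takes one individual from every population (m == npop); otherwise a single
// population supplies m distinct players per game. Uses R's RNG throughout,
// so results are reproducible via set.seed().
// [[Rcpp::export]]
List wf_engine_cpp(List pops, NumericVector w0, NumericVector alpha,
                   IntegerVector family, NumericVector lambda,
                   double norm, int m, int omega, int timing,
                   int generations, int games_per_gen,
                   double mu, double sigma, bool paired, bool selection) {
  const int npop = pops.size();
  const int P = paired ? npop : m;  // players per game
  const int ntraits = 3 * omega;

  std::vector<NumericMatrix> cur(npop), nxt(npop);
  int N = 0;
  for (int p = 0; p < npop; ++p) {
    NumericMatrix mat = as<NumericMatrix>(pops[p]);
    if (p == 0) N = mat.nrow();
    if (mat.nrow() != N) stop("all populations must have the same size N");
    if (mat.ncol() != ntraits) stop("strategy matrix must have 3*omega columns");
    cur[p] = clone(mat);
    nxt[p] = NumericMatrix(N, ntraits);
  }
  if (!paired && m > N) stop("group size m cannot exceed population size N");

  // per-population / per-slot parameters (paired: slot k <- population k;
  // single population: all slots share population 0's parameters)
  std::vector<double> slot_w0(P), slot_alpha(P), slot_lambda(P);
  std::vector<int> slot_fam(P), slot_pop(P);
  for (int k = 0; k < P; ++k) {
    int p = paired ? k : 0;
    slot_pop[k] = p;
    slot_w0[k] = w0[p];
    slot_alpha[k] = alpha[p];
    slot_fam[k] = family[p];
    slot_lambda[k] = lambda[p];
  }

  // outputs
  std::vector<NumericMatrix> contrib_out(npop), risk_out(npop);
  std::vector<NumericVector> payoff_out(npop);
  for (int p = 0; p < npop; ++p) {
    contrib_out[p] = NumericMatrix(generations, omega);
    risk_out[p] = NumericMatrix(generations, omega);
    payoff_out[p] = NumericVector(generations);
  }
  List pi_out(npop), parents_out(npop);

  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;

  std::vector<int> idx(P);
  std::vector<double> wealth(P), cbuf(P);
  std::vector<std::vector<double> > pay_sum(npop, std::vector<double>(N));
  std::vector<std::vector<int> > cnt(npop, std::vector<int>(N));
  std::vector<std::vector<double> > ca(npop, std::vector<double>(omega));
  std::vector<std::vector<double> > ra(npop, std::vector<double>(omega));
  std::vector<std::vector<double> > pi(npop, std::vector<double>(N));
  std::vector<double> cum(N);

  for (int gen = 0; gen < generations; ++gen) {
    for (int p = 0; p < npop; ++p) {
      std::fill(pay_sum[p].begin(), pay_sum[p].end(), 0.0);
      std::fill(cnt[p].begin(), cnt[p].end(), 0);
      std::fill(ca[p].begin(), ca[p].end(), 0.0);
      std::fill(ra[p].begin(), ra[p].end(), 0.0);
    }

    for (int g = 0; g < games_per_gen; ++g) {
      if (paired) {
        for (int k = 0; k < P; ++k) {
          int j = (int)(unif_rand() * N);
          if (j >= N) j = N - 1;
          idx[k] = j;
        }
      } else {
        // partial Fisher-Yates: m distinct players from population 0
        for (int k = 0; k < P; ++k) {
          int j = k + (int)(unif_rand() * (N - k));
          if (j >= N) j = N - 1;
          std::swap(perm[k], perm[j]);
          idx[k] = perm[k];
        }
      }
      for (int k = 0; k < P; ++k) wealth[k] = slot_w0[k];
      int loss_round = -1;
      if (timing == 3) {
        loss_round = (int)(unif_rand() * omega);
        if (loss_round >= omega) loss_round = omega - 1;
      }
      double pot = 0.0;
      for (int r = 0; r < omega; ++r) {
        // simultaneous decisions on the pot of previous rounds
        for (int k = 0; k < P; ++k) {
          const NumericMatrix &M = cur[slot_pop[k]];
          int i = idx[k];
          double tau = M(i, 3 * r), a = M(i, 3 * r + 1), b = M(i, 3 * r + 2);
          double lev = (pot <= tau) ? a : b;
          cbuf[k] = (lev < wealth[k]) ? lev : wealth[k];
        }
        for (int k = 0; k < P; ++k) {
          pot += cbuf[k];
          wealth[k] -= cbuf[k];
          ca[slot_pop[k]][r] += cbuf[k];
        }
        bool capable = (timing == 0) || (timing == 1 && r == 0) ||
                       (timing == 2 && r == omega - 1) ||
                       (timing == 3 && r == loss_round);
        double frac = pot / norm;
        for (int k = 0; k < P; ++k) {
          double p = risk_prob(slot_fam[k], slot_lambda[k], frac);
          ra[slot_pop[k]][r] += p;
          if (capable && unif_rand() < p) {
            wealth[k] *= (1.0 - slot_alpha[k]);
          }
        }
      }
      for (int k = 0; k < P; ++k) {
        pay_sum[slot_pop[k]][idx[k]] += wealth[k];
        cnt[slot_pop[k]][idx[k]] += 1;
      }
    }

    // average payoff per individual; those sampled into no game receive the
    // mean payoff of the individuals that did play (neutral treatment)
    for (int p = 0; p < npop; ++p) {
      double tot = 0.0;
      int nplayed = 0;
      for (int i = 0; i < N; ++i) {
        if (cnt[p][i] > 0) {
          pi[p][i] = pay_sum[p][i] / cnt[p][i];
          tot += pi[p][i];
          ++nplayed;
        }
      }
      double mean_played = (nplayed > 0) ? tot / nplayed : 0.0;
      double pisum = 0.0;
      for (int i = 0; i < N; ++i) {
        if (cnt[p][i] == 0) pi[p][i] = mean_played;
        pisum += pi[p][i];
      }
      int slots_per_game = paired ? 1 : m;  // players drawn from pop p per game
      double denom = (double)games_per_gen * slots_per_game;
      for (int r = 0; r < omega; ++r) {
        contrib_out[p](gen, r) = ca[p][r] / denom;
        risk_out[p](gen, r) = ra[p][r] / denom;
      }
      payoff_out[p][gen] = pisum / N;
    }

    // Wright-Fisher selection + mutation, within each population
    for (int p = 0; p < npop; ++p) {
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        acc += selection ? std::exp(pi[p][i]) : 1.0;
        cum[i] = acc;
      }
      IntegerVector parents(N);
      for (int j = 0; j < N; ++j) {
        double u = unif_rand() * acc;
        int lo = 0, hi = N - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (cum[mid] < u) lo = mid + 1; else hi = mid;
        }
        parents[j] = lo;
        for (int t = 0; t < ntraits; ++t) {
          double v = cur[p](lo, t);
          if (mu > 0.0 && unif_rand() < mu) {
            if (t % 3 == 0) {
              v += norm_rand() * sigma;
              if (v < 0.0) v = 0.0;
            } else {
              v = unif_rand() * w0[p];
            }
          }
          nxt[p](j, t) = v;
        }
      }
      if (gen == generations - 1) {
        parents_out[p] = parents;
        pi_out[p] = wrap(pi[p]);
      }
      std::swap(cur[p], nxt[p]);
    }
  }

  List final_pops(npop);
  List contrib(npop), risk(npop), payoff(npop);
  for (int p = 0; p < npop; ++p) {
    final_pops[p] = cur[p];
    contrib[p] = contrib_out[p];
    risk[p] = risk_out[p];
    payoff[p] = payoff_out[p];
  }
  return List::create(_["contrib"] = contrib, _["risk"] = risk,
                      _["payoff"] = payoff, _["pi"] = pi_out,
                      _["parents"] = parents_out, _["pops"] = final_pops);
}
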