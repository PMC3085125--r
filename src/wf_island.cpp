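#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Forward-time Wright-Fisher finite-island model, microsatellite-style loci.
//
// State: one allele label per gene copy, 2*N copies per deme, K demes,
// n_loci independent loci.  Each generation every copy in deme k picks a
// source deme (own with prob 1-m, otherwise uniform over the K-1 others),
// then a uniform parental copy from that deme, then mutates with prob mu
// (model 0 = stepwise +/-1 repeat; model 1 = infinite alleles, fresh label).
// Uses R's RNG so set.seed() in R governs reproducibility.
//
// [[Rcpp::export(name = ".wf_microsat_cpp")]]
IntegerMatrix wf_microsat_cpp(int K, int N, double m, double mu,
                              int n_gen, int n_loci, int model,
                              int init_allele) {
  const int C = 2 * N;          // gene copies per deme
  const int total = C * K;
  std::vector<int> cur((size_t)total * n_loci, init_allele);
  std::vector<int> nxt((size_t)total * n_loci);
  int next_new = init_allele + 1;   // infinite-alleles label counter

  for (int g = 0; g < n_gen; ++g) {
    for (int l = 0; l < n_loci; ++l) {
      const int* curl = &cur[(size_t)l * total];
      int* nxtl = &nxt[(size_t)l * total];
      for (int k = 0; k < K; ++k) {
        for (int c = 0; c < C; ++c) {
          int src = k;
          if (K > 1 && m > 0.0 && unif_rand() < m) {
            src = (int)(unif_rand() * (K - 1));
            if (src >= k) ++src;
          }
          int par = (int)(unif_rand() * C);
          if (par == C) par = C - 1;  // guard against unif_rand()==1
          int val = curl[src * C + par];
          if (mu > 0.0 && unif_rand() < mu) {
            if (model == 0) {
              val += (unif_rand() < 0.5) ? -1 : 1;
            } else {
              val = next_new++;
            }
          }
          nxtl[k * C + c] = val;
        }
      }
    }
    cur.swap(nxt);
  }

  IntegerMatrix out(total, n_loci);
  for (int l = 0; l < n_loci; ++l)
    for (int i = 0; i < total; ++i)
      out(i, l) = cur[(size_t)l * total + i];
  return out;
}

// Haploid finite-sites locus (mtDNA-style): Nh haploid copies per deme,
// L sites with states 1..4; per-site mutation to a uniformly chosen
// different base at rate mu.  Offspring copy a full parental sequence and
// receive Binomial(L, mu) mutations at uniform positions.
//
// [[Rcpp::export(name = ".wf_seq_cpp")]]
IntegerMatrix wf_seq_cpp(int K, int Nh, double m, double mu,
                         int n_gen, int L) {
  const int total = Nh * K;
  std::vector<int> cur((size_t)total * L, 1);  // row-major: row*L + site
  std::vector<int> nxt((size_t)total * L);

  for (int g = 0; g < n_gen; ++g) {
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < Nh; ++i) {
        int src = k;
        if (K > 1 && m > 0.0 && unif_rand() < m) {
          src = (int)(unif_rand() * (K - 1));
          if (src >= k) ++src;
        }
        int par = (int)(unif_rand() * Nh);
        if (par == Nh) par = Nh - 1;
        const size_t row = (size_t)(k * Nh + i) * L;
        const size_t prow = (size_t)(src * Nh + par) * L;
        std::memcpy(&nxt[row], &cur[prow], sizeof(int) * L);
        if (mu > 0.0) {
          int nmut = (int)R::rbinom((double)L, mu);
          for (int j = 0; j < nmut; ++j) {
            int s = (int)(unif_rand() * L);
            if (s == L) s = L - 1;
            int old = nxt[row + s];
            int nb = 1 + (int)(unif_rand() * 3.0);
            if (nb >= old) ++nb;  // uniform over the 3 other bases
            nxt[row + s] = nb;
          }
        }
      }
    }
    cur.swap(nxt);
  }

  IntegerMatrix out(total, L);
  for (int i = 0; i < total; ++i)
    for (int s = 0; s < L; ++s)
      out(i, s) = cur[(size_t)i * L + s];
  return out;
}
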