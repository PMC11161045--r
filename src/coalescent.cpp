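// Single-population Hudson coalescent with piecewise-constant haploid Ne and
// infinite-sites mutation.  Time runs backward from the end of the forward
// simulation; lineages not coalesced by the oldest epoch enter a panmictic
// source pool of constant size.  Pairwise diversity is accumulated per
// mutation as d*(n-d) differing pairs, d = descendants of the mutated branch.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_coalescent_pi(NumericVector epoch_len, NumericVector epoch_ne,
                       double pool_ne, int n_hap, double mu_per_site,
                       int locus_length) {
  RNGScope scope;
  int k = n_hap;
  std::vector<double> born(k, 0.0);  // backward time each lineage began
  std::vector<int> desc(k, 1);       // sample descendants per lineage

  double t = 0.0;           // current backward time (generations)
  int ep = 0;               // current epoch index
  double left = (epoch_len.size() > 0) ? epoch_len[0] : 0.0;
  int n_ep = epoch_len.size();

  double mu_locus = mu_per_site * (double)locus_length;
  double diff_sum = 0.0;    // sum over mutations of d*(n-d)
  int seg = 0;

  while (k > 1) {
    // waiting time to next coalescence: integrate rate k(k-1)/(2 Ne(t))
    double E = exp_rand();
    double pairs = 0.5 * (double)k * (double)(k - 1);
    for (;;) {
      double ne = (ep < n_ep) ? epoch_ne[ep] : pool_ne;
      double rate = pairs / ne;
      if (ep >= n_ep) {  // source pool: unbounded epoch
        t += E / rate;
        break;
      }
      double need = E / rate;
      if (need <= left) {
        t += need;
        left -= need;
        break;
      }
      E -= rate * left;
      t += left;
      ep++;
      left = (ep < n_ep) ? epoch_len[ep] : 0.0;
    }
    // choose the coalescing pair
    int i = (int)(unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) j++;
    // drop mutations on the two terminating branches
    for (int b = 0; b < 2; b++) {
      int v = (b == 0) ? i : j;
      double len = t - born[v];
      if (len > 0.0 && mu_locus > 0.0) {
        int mut = (int)R::rpois(len * mu_locus);
        if (mut > 0) {
          seg += mut;
          diff_sum += (double)mut * (double)desc[v] *
                      (double)(n_hap - desc[v]);
        }
      }
    }
    // merge j into i, swap-remove j
    desc[i] += desc[j];
    born[i] = t;
    desc[j] = desc[k - 1]; desc.pop_back();
    born[j] = born[k - 1]; born.pop_back();
    k--;
  }

  double npairs = 0.5 * (double)n_hap * (double)(n_hap - 1);
  double pi = (locus_length > 0) ? diff_sum / npairs / (double)locus_length
                                 : 0.0;
  return List::create(_["pi"] = pi, _["segregating_sites"] = seg,
                      _["tmrca"] = t);
}
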