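// Forward-time zero-sum death-birth engine.
//
// State is kept at species level: all conspecifics share one trait value, so
// every individual of a species has the same death rate and per-individual
// bookkeeping reduces to two counts per species (founder-descended vs
// colonist-descended individuals).  Pairwise / beta competition rates are
// maintained by O(S) incremental updates of the species-aggregated sums, with
// a full O(S^2) refresh every generation to bound floating-point drift.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

enum Model { NEUTRAL = 0, FILTERING = 1, MEANCOMP = 2, PAIRWISE = 3, BETACOMP = 4 };

// exponent clamp: arguments below -700 would underflow to denormals
static inline double kern(double sE, double dz) {
  double a = -sE * dz * dz;
  if (a < -700.0) return 0.0;
  return std::exp(a);
}

struct Community {
  std::vector<int> id;               // species identifier
  std::vector<double> z;             // species trait
  std::vector<int> nf, nc;           // founder / colonist individual counts
  std::vector<double> colgen;        // most recent colonization generation (-1 = founding)
  std::vector<double> q;             // per-individual death rate (filtering: fixed; pair/beta: maintained)
  std::vector< std::vector<double> > K;  // competition kernel matrix (pairwise/beta only)
  double sum_nz;                     // sum over individuals of trait values
  long total_nf;                     // founder-descended individuals
  int J;

  int n(int s) const { return nf[s] + nc[s]; }
  int S() const { return (int)id.size(); }
};

struct Pars {
  double m, nu, sE, zE, bi, be, sigma_sp;
  int model, J;
};

// raw per-individual death rate vector, one entry per species (shared by its
// conspecifics).  Used for initialization, the per-generation refresh, and
// exported below for cross-checking against the R reference implementation.
static std::vector<double> species_rates(const std::vector<int> &n,
                                         const std::vector<double> &z,
                                         const Pars &p) {
  int S = (int)n.size();
  std::vector<double> q(S, 1.0);
  long J = 0;
  for (int s = 0; s < S; s++) J += n[s];
  switch (p.model) {
  case NEUTRAL:
    break;
  case FILTERING:
    for (int s = 0; s < S; s++) q[s] = 1.0 - kern(p.sE, z[s] - p.zE);
    break;
  case MEANCOMP: {
    double zbar = 0.0;
    for (int s = 0; s < S; s++) zbar += (double)n[s] * z[s];
    zbar /= (double)J;
    for (int s = 0; s < S; s++) q[s] = kern(p.sE, z[s] - zbar);
    break;
  }
  case PAIRWISE:
  case BETACOMP: {
    double bi = (p.model == PAIRWISE) ? 1.0 : p.bi;
    double be = (p.model == PAIRWISE) ? 1.0 : p.be;
    for (int s = 0; s < S; s++) {
      double acc = 0.0;
      for (int t = 0; t < S; t++)
        if (t != s) acc += (double)n[t] * kern(p.sE, z[s] - z[t]);
      q[s] = bi * (double)(n[s] - 1) + be * acc;
    }
    break;
  }
  }
  return q;
}

// ---- incremental maintenance for pairwise/beta -----------------------------

static void refresh_pair_rates(Community &C, const Pars &p) {
  double bi = (p.model == PAIRWISE) ? 1.0 : p.bi;
  double be = (p.model == PAIRWISE) ? 1.0 : p.be;
  int S = C.S();
  for (int s = 0; s < S; s++) {
    double acc = 0.0;
    for (int t = 0; t < S; t++)
      if (t != s) acc += (double)C.n(t) * C.K[s][t];
    C.q[s] = bi * (double)(C.n(s) - 1) + be * acc;
  }
}

static void pair_add(Community &C, const Pars &p, int s) {
  double bi = (p.model == PAIRWISE) ? 1.0 : p.bi;
  double be = (p.model == PAIRWISE) ? 1.0 : p.be;
  int S = C.S();
  for (int t = 0; t < S; t++)
    if (t != s) C.q[t] += be * C.K[t][s];
  C.q[s] += bi;
}

static void pair_remove(Community &C, const Pars &p, int s) {
  double bi = (p.model == PAIRWISE) ? 1.0 : p.bi;
  double be = (p.model == PAIRWISE) ? 1.0 : p.be;
  int S = C.S();
  for (int t = 0; t < S; t++)
    if (t != s) C.q[t] -= be * C.K[t][s];
  C.q[s] -= bi;
}

// add one individual of species s (class: founder if f) and maintain caches
static void add_individual(Community &C, const Pars &p, int s, bool f) {
  if (p.model == PAIRWISE || p.model == BETACOMP) pair_add(C, p, s);
  if (f) { C.nf[s]++; C.total_nf++; } else C.nc[s]++;
  C.sum_nz += C.z[s];
}

static void remove_individual(Community &C, const Pars &p, int s, bool f) {
  if (p.model == PAIRWISE || p.model == BETACOMP) pair_remove(C, p, s);
  if (f) { C.nf[s]--; C.total_nf--; } else C.nc[s]--;
  C.sum_nz -= C.z[s];
}

// create an empty species record (n = 0); caller adds the first individual
static int create_species(Community &C, const Pars &p, int sid, double trait,
                          double gen) {
  C.id.push_back(sid);
  C.z.push_back(trait);
  C.nf.push_back(0);
  C.nc.push_back(0);
  C.colgen.push_back(gen);
  int s = C.S() - 1;
  if (p.model == PAIRWISE || p.model == BETACOMP) {
    double bi = (p.model == PAIRWISE) ? 1.0 : p.bi;
    double be = (p.model == PAIRWISE) ? 1.0 : p.be;
    std::vector<double> row(C.S());
    double acc = 0.0;
    for (int t = 0; t < s; t++) {
      double k = kern(p.sE, trait - C.z[t]);
      row[t] = k;
      C.K[t].push_back(k);
      acc += (double)C.n(t) * k;
    }
    row[s] = 1.0;
    C.K.push_back(row);
    // q of an (about-to-exist) first individual: bi*(1-1) + be*acc; pair_add
    // will contribute the +bi for self, so seed with -bi + be*acc
    C.q.push_back(-bi + be * acc);
  } else if (p.model == FILTERING) {
    C.q.push_back(1.0 - kern(p.sE, trait - p.zE));
  } else {
    C.q.push_back(1.0);
  }
  return s;
}

// swap-remove an extinct species record
static void drop_species(Community &C, const Pars &p, int s) {
  int L = C.S() - 1;
  if (p.model == PAIRWISE || p.model == BETACOMP) {
    C.K[s] = C.K[L];
    C.K.pop_back();
    for (int t = 0; t < (int)C.K.size(); t++) {
      C.K[t][s] = C.K[t][L];
      C.K[t].pop_back();
    }
  }
  C.id[s] = C.id[L]; C.id.pop_back();
  C.z[s] = C.z[L]; C.z.pop_back();
  C.nf[s] = C.nf[L]; C.nf.pop_back();
  C.nc[s] = C.nc[L]; C.nc.pop_back();
  C.colgen[s] = C.colgen[L]; C.colgen.pop_back();
  C.q[s] = C.q[L]; C.q.pop_back();
}

// sample a species index proportional to weights w (length S, sum W > 0)
static int sample_index(const std::vector<double> &w, double W) {
  double u = unif_rand() * W;
  double acc = 0.0;
  int S = (int)w.size();
  for (int s = 0; s < S; s++) {
    acc += w[s];
    if (u < acc) return s;
  }
  return S - 1;
}

// [[Rcpp::export]]
List cpp_run_assembly(int J, double m, double nu, double sE, double zE,
                      double beta_intra, double beta_inter, int model,
                      NumericVector meta_cum, NumericVector meta_trait,
                      double sigma_sp, int founder_meta, double lambda_target,
                      int max_generations, int snapshot_every) {
  RNGScope scope;
  Pars p;
  p.m = m; p.nu = nu; p.sE = sE; p.zE = zE;
  p.bi = beta_intra; p.be = beta_inter; p.sigma_sp = sigma_sp;
  p.model = model; p.J = J;

  Community C;
  C.sum_nz = 0.0; C.total_nf = 0; C.J = J;
  // founding population: J individuals of one metacommunity species
  create_species(C, p, founder_meta + 1, meta_trait[founder_meta], -1.0);
  for (int i = 0; i < J; i++) add_individual(C, p, 0, true);
  if (p.model == PAIRWISE || p.model == BETACOMP) refresh_pair_rates(C, p);

  int next_id = (int)meta_trait.size() + 1;
  long fallback_events = 0;

  // trajectory / timeline records
  std::vector<int> tr_gen, tr_id, tr_n;
  std::vector<double> tl_gen, tl_lambda, tl_zbar;
  std::vector<int> tl_S;

  std::vector<double> w;  // scratch death / parent weights

  bool use_lambda = (lambda_target > 0.0 && lambda_target <= 1.0);
  double lambda = 0.0;
  int gen = 0;
  bool done = false;

  // snapshot at generation 0 (founding state)
  tl_gen.push_back(0); tl_S.push_back(C.S());
  tl_lambda.push_back(0.0); tl_zbar.push_back(C.sum_nz / J);
  for (int s = 0; s < C.S(); s++) {
    tr_gen.push_back(0); tr_id.push_back(C.id[s]); tr_n.push_back(C.n(s));
  }

  while (!done && gen < max_generations) {
    gen++;
    for (int e = 0; e < J; e++) {
      int S = C.S();
      w.resize(S);
      double W = 0.0;
      // ---- death weights -------------------------------------------------
      switch (p.model) {
      case NEUTRAL:
        for (int s = 0; s < S; s++) { w[s] = (double)C.n(s); W += w[s]; }
        break;
      case FILTERING:
      case PAIRWISE:
      case BETACOMP:
        for (int s = 0; s < S; s++) {
          double v = (double)C.n(s) * C.q[s];
          w[s] = (v > 0.0) ? v : 0.0;
          W += w[s];
        }
        break;
      case MEANCOMP: {
        double zbar = C.sum_nz / (double)J;
        for (int s = 0; s < S; s++) {
          w[s] = (double)C.n(s) * kern(p.sE, C.z[s] - zbar);
          W += w[s];
        }
        break;
      }
      }
      if (W <= 1e-300) {  // degenerate rate vector: fall back to neutral
        fallback_events++;
        W = 0.0;
        for (int s = 0; s < S; s++) { w[s] = (double)C.n(s); W += w[s]; }
      }
      int dead = sample_index(w, W);
      bool dead_f;
      {
        int n = C.n(dead);
        dead_f = (C.nf[dead] == n) ? true
               : (C.nc[dead] == n) ? false
               : (unif_rand() * n < (double)C.nf[dead]);
      }
      remove_individual(C, p, dead, dead_f);

      // ---- replacement ---------------------------------------------------
      double gnow = (double)(gen - 1) + (double)(e + 1) / (double)J;
      if (unif_rand() < p.m) {
        // immigration from the fixed regional pool
        double u = unif_rand();
        int mi = (int)(std::upper_bound(meta_cum.begin(), meta_cum.end(), u) -
                       meta_cum.begin());
        if (mi >= meta_cum.size()) mi = meta_cum.size() - 1;
        int sid = mi + 1;
        int loc = -1;
        for (int s = 0; s < C.S(); s++)
          if (C.id[s] == sid) { loc = s; break; }
        if (loc < 0) {
          loc = create_species(C, p, sid, meta_trait[mi], gnow);
        } else if (C.n(loc) == 0) {
          C.colgen[loc] = gnow;  // recolonization within one event window
        }
        add_individual(C, p, loc, false);
      } else {
        // local reproduction: parent uniform among the J-1 survivors
        int S2 = C.S();
        w.resize(S2);
        double W2 = 0.0;
        for (int s = 0; s < S2; s++) { w[s] = (double)C.n(s); W2 += w[s]; }
        int par = sample_index(w, W2);
        bool par_f;
        {
          int n = C.n(par);
          par_f = (C.nf[par] == n) ? true
                : (C.nc[par] == n) ? false
                : (unif_rand() * n < (double)C.nf[par]);
        }
        if (p.nu > 0.0 && unif_rand() < p.nu) {
          // point-mutation speciation: new lineage, perturbed trait
          double znew = C.z[par] + norm_rand() * p.sigma_sp;
          int loc = create_species(C, p, next_id++, znew, gnow);
          add_individual(C, p, loc, false);
        } else {
          add_individual(C, p, par, par_f);
        }
      }
      if (C.n(dead) == 0) drop_species(C, p, dead);
    }

    // ---- generation boundary: refresh caches, record, check stop --------
    {
      double nz = 0.0;
      for (int s = 0; s < C.S(); s++) nz += (double)C.n(s) * C.z[s];
      C.sum_nz = nz;
    }
    if (p.model == PAIRWISE || p.model == BETACOMP) refresh_pair_rates(C, p);
    lambda = 1.0 - (double)C.total_nf / (double)J;
    done = (use_lambda && lambda >= lambda_target);

    if (gen % snapshot_every == 0 || done || gen == max_generations) {
      tl_gen.push_back(gen); tl_S.push_back(C.S());
      tl_lambda.push_back(lambda); tl_zbar.push_back(C.sum_nz / J);
      for (int s = 0; s < C.S(); s++) {
        tr_gen.push_back(gen); tr_id.push_back(C.id[s]); tr_n.push_back(C.n(s));
      }
    }
  }

  int S = C.S();
  IntegerVector oid(S), on(S), onf(S), onc(S);
  NumericVector oz(S), ocol(S);
  for (int s = 0; s < S; s++) {
    oid[s] = C.id[s]; oz[s] = C.z[s]; on[s] = C.n(s);
    onf[s] = C.nf[s]; onc[s] = C.nc[s]; ocol[s] = C.colgen[s];
  }
  return List::create(
    _["species_id"] = oid, _["trait"] = oz, _["abundance"] = on,
    _["n_founder"] = onf, _["n_colonist"] = onc,
    _["colonization_gen"] = ocol,
    _["traj_gen"] = wrap(tr_gen), _["traj_id"] = wrap(tr_id),
    _["traj_n"] = wrap(tr_n),
    _["tl_gen"] = wrap(tl_gen), _["tl_S"] = wrap(tl_S),
    _["tl_lambda"] = wrap(tl_lambda), _["tl_zbar"] = wrap(tl_zbar),
    _["lambda"] = lambda, _["generations"] = gen,
    _["truncated"] = (use_lambda && lambda < lambda_target),
    _["fallback_events"] = (double)fallback_events);
}

// [[Rcpp::export]]
NumericVector cpp_species_rates(IntegerVector n, NumericVector z, int model,
                                double sE, double zE, double beta_intra,
                                double beta_inter) {
  Pars p;
  p.m = 0; p.nu = 0; p.sE = sE; p.zE = zE;
  p.bi = beta_intra; p.be = beta_inter; p.sigma_sp = 0;
  p.model = model; p.J = 0;
  std::vector<int> nn(n.begin(), n.end());
  std::vector<double> zz(z.begin(), z.end());
  std::vector<double> q = species_rates(nn, zz, p);
  return wrap(q);
}
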