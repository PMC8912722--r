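#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Two-deme structured coalescent with piecewise-constant sizes, a windowed
// asymmetric migration phase, and strict stepwise mutation on the resulting
// genealogy. Time runs backward in generations; demes are 0 (species A,
// "cau") and 1 (species B, "mor"). Migration rates follow the backward
// lineage-movement convention: m1 is the forward rate A->B, so backward a
// lineage resident in deme 1 jumps to deme 0 at rate m1 (and vice versa for
// m2). Models: 0=SI (no migration), 1=AM (window (t2,t1)), 2=SC (window
// (0,t2)), 3=CM (window (0,t1)).
// ---------------------------------------------------------------------------

static inline int pick_pair(int k) { return (int)std::floor(unif_rand() * k); }

// [[Rcpp::export]]
List sim_locus_cpp(int n1, int n2, int model,
                   double ne_c_t2, double ne_m_t2,
                   double ne_c_t1, double ne_m_t1, double ne_anc,
                   double m1, double m2, double t1, double t2,
                   double mu, int anc_state) {
  int n = n1 + n2;
  int n_nodes = 2 * n - 1;
  std::vector<int> parent(n_nodes, -1);
  std::vector<double> ntime(n_nodes, 0.0);
  // per-deme stacks of active node ids: O(1) migration and coalescence
  std::vector<int> pool[2];
  pool[0].reserve(n); pool[1].reserve(n);
  for (int i = 0; i < n1; ++i) pool[0].push_back(i);
  for (int i = 0; i < n2; ++i) pool[1].push_back(n1 + i);
  int next_node = n;
  double t = 0.0;
  int k_total = n;

  while (k_total > 1) {
    double N0, N1d;
    bool merged = t >= t1;
    if (merged) { N0 = ne_anc; N1d = ne_anc; }
    else if (t >= t2) { N0 = ne_c_t1; N1d = ne_m_t1; }
    else { N0 = ne_c_t2; N1d = ne_m_t2; }
    bool mig_on = false;
    if (!merged) {
      if (model == 1) mig_on = true;        // AM: window (t2, t1)
      else if (model == 2) mig_on = (t < t2); // SC: window (0, t2)
      else if (model == 3) mig_on = true;   // CM: window (0, t1)
      if (model == 1 && t < t2) mig_on = false;
    }
    double k0 = (double)pool[0].size(), k1 = (double)pool[1].size();
    double rc0, rc1, rm0 = 0.0, rm1 = 0.0;
    if (merged) {
      rc0 = k_total * (k_total - 1) / 2.0 / (2.0 * ne_anc);
      rc1 = 0.0;
    } else {
      rc0 = k0 * (k0 - 1) / 2.0 / (2.0 * N0);
      rc1 = k1 * (k1 - 1) / 2.0 / (2.0 * N1d);
      if (mig_on) { rm1 = k1 * m1; rm0 = k0 * m2; }
    }
    double total = rc0 + rc1 + rm0 + rm1;
    double t_next = merged ? R_PosInf : (t < t2 ? t2 : t1);
    if (total <= 0.0) {
      t = t_next;
      if (t >= t1) {  // merge demes into the ancestral population
        for (size_t i = 0; i < pool[1].size(); ++i) pool[0].push_back(pool[1][i]);
        pool[1].clear();
      }
      continue;
    }
    double dt = exp_rand() / total;
    if (t + dt >= t_next) {
      t = t_next;
      if (t >= t1) {
        for (size_t i = 0; i < pool[1].size(); ++i) pool[0].push_back(pool[1][i]);
        pool[1].clear();
      }
      continue;
    }
    t += dt;
    double u = unif_rand() * total;
    if (u < rc0 + rc1) {
      int d = (u < rc0) ? 0 : 1;
      std::vector<int>& v = pool[d];
      int k = (int)v.size();
      int ia = pick_pair(k);
      int ib = pick_pair(k - 1);
      if (ib >= ia) ib++;
      int p = next_node++;
      ntime[p] = t;
      parent[v[ia]] = p;
      parent[v[ib]] = p;
      // replace ia by parent, remove ib by swap-with-last
      v[ia] = p;
      if (ib != k - 1) v[ib] = v[k - 1];
      else if (ia == k - 1) v[ib] = p; // cannot happen (ia != ib) but safe
      v.pop_back();
      k_total--;
    } else {
      int d_from = (u < rc0 + rc1 + rm1) ? 1 : 0; // rm1 moves deme1 -> deme0
      std::vector<int>& v = pool[d_from];
      int j = pick_pair((int)v.size());
      pool[1 - d_from].push_back(v[j]);
      v[j] = v.back();
      v.pop_back();
    }
  }
  int root = pool[0].empty() ? pool[1][0] : pool[0][0];
  double height = ntime[root];

  // drop stepwise mutations top-down; allele states floored at 2 repeats
  std::vector<int> state(n_nodes, anc_state);
  int n_boundary = 0;
  // children lists
  std::vector<std::vector<int> > kids(n_nodes);
  for (int i = 0; i < n_nodes; ++i)
    if (parent[i] >= 0) kids[parent[i]].push_back(i);
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (size_t c = 0; c < kids[v].size(); ++c) {
      int w = kids[v][c];
      double len = ntime[v] - ntime[w];
      int nm = (int)R::rpois(mu * len);
      int s = state[v];
      for (int m = 0; m < nm; ++m) {
        s += (unif_rand() < 0.5) ? -1 : 1;
        if (s < 2) { s = 2; n_boundary++; }
      }
      state[w] = s;
      stack.push_back(w);
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = state[i];
  return List::create(_["states"] = out, _["height"] = height,
                      _["n_boundary"] = n_boundary);
}

// ---------------------------------------------------------------------------
// Admixture-model Gibbs sampler (STRUCTURE-style, no admixture-alpha update,
// independent Dirichlet(lambda) allele-frequency prior per cluster x locus).
// geno: n x (2L) matrix of 0-based allele codes, -1 = missing, columns
// (l, copy) = 2l and 2l+1. n_alleles: number of distinct alleles per locus.
// Returns posterior-mean Q, posterior-mean P (flattened), and the
// log-likelihood trace.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         int K, int n_sweeps, int burn_in,
                         double alpha, double lambda) {
  int n = geno.nrow();
  int L = n_alleles.size();
  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + n_alleles[l];
  int A = off[L];

  std::vector<double> P(K * A);       // P[k*A + off[l]+a]
  std::vector<double> Q(n * K, 1.0 / K);
  std::vector<double> Qsum(n * K, 0.0);
  std::vector<double> Psum(K * A, 0.0);
  NumericVector loglik(n_sweeps);

  // init P from flat Dirichlet
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) {
      double s = 0.0;
      for (int a = 0; a < n_alleles[l]; ++a) {
        double g = R::rgamma(1.0, 1.0);
        P[k * A + off[l] + a] = g; s += g;
      }
      for (int a = 0; a < n_alleles[l]; ++a) P[k * A + off[l] + a] /= s;
    }

  std::vector<double> cntP(K * A);
  std::vector<double> cntQ(n * K);
  std::vector<double> pk(K);
  int n_kept = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    std::fill(cntP.begin(), cntP.end(), 0.0);
    std::fill(cntQ.begin(), cntQ.end(), 0.0);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a < 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            pk[k] = Q[i * K + k] * P[k * A + off[l] + a];
            s += pk[k];
          }
          ll += std::log(s > 0 ? s : 1e-300);
          double u = unif_rand() * s;
          int z = 0; double acc = pk[0];
          while (z < K - 1 && u > acc) { z++; acc += pk[z]; }
          cntP[z * A + off[l] + a] += 1.0;
          cntQ[i * K + z] += 1.0;
        }
      }
    }
    loglik[sweep] = ll;
    // update P | Z
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double g = R::rgamma(lambda + cntP[k * A + off[l] + a], 1.0);
          P[k * A + off[l] + a] = g; s += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a) P[k * A + off[l] + a] /= s;
      }
    // update Q | Z
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + cntQ[i * K + k], 1.0);
        Q[i * K + k] = g; s += g;
      }
      for (int k = 0; k < K; ++k) Q[i * K + k] /= s;
    }
    if (sweep >= burn_in) {
      n_kept++;
      for (int i = 0; i < n * K; ++i) Qsum[i] += Q[i];
      for (int i = 0; i < K * A; ++i) Psum[i] += P[i];
    }
  }
  NumericMatrix Qm(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qm(i, k) = Qsum[i * K + k] / n_kept;
  NumericVector Pm(K * A);
  for (int i = 0; i < K * A; ++i) Pm[i] = Psum[i] / n_kept;
  return List::create(_["Q"] = Qm, _["P"] = Pm, _["loglik"] = loglik,
                      _["offsets"] = wrap(off));
}

// ---------------------------------------------------------------------------
// AMOVA on allele-identity distances with per-locus variance components
// summed over loci (handles locus-wise missing data). Units are allele
// copies grouped by population, populations nested in groups (species).
// a1, a2: n x L matrices of 0-based allele codes, -1 = missing.
// pop: 0-based population index per individual; grp_of_pop: 0-based group
// index per population. Returns summed SSDs, summed variance components and
// permutation exceedance counts for Phi_ST, Phi_SC, Phi_CT.
// ---------------------------------------------------------------------------

struct AmovaComp { double ssd_ag, ssd_ap, ssd_wp, va, vb, vc; };

static AmovaComp amova_components(const IntegerMatrix& a1,
                                  const IntegerMatrix& a2,
                                  const std::vector<int>& pop,
                                  const std::vector<int>& grp_of_pop,
                                  const IntegerVector& n_alleles,
                                  int P, int G) {
  int n = a1.nrow(), L = a1.ncol();
  AmovaComp out = {0, 0, 0, 0, 0, 0};
  std::vector<double> cnt;       // P x A_l counts
  std::vector<double> np(P), ng(G), ca;
  std::vector<double> gsum;
  for (int l = 0; l < L; ++l) {
    int A = n_alleles[l];
    cnt.assign((size_t)P * A, 0.0);
    std::fill(np.begin(), np.end(), 0.0);
    std::fill(ng.begin(), ng.end(), 0.0);
    ca.assign(A, 0.0);
    double N = 0.0;
    for (int i = 0; i < n; ++i) {
      int p = pop[i];
      int x = a1(i, l);
      if (x >= 0) { cnt[(size_t)p * A + x] += 1; np[p] += 1; ca[x] += 1; N += 1; }
      x = a2(i, l);
      if (x >= 0) { cnt[(size_t)p * A + x] += 1; np[p] += 1; ca[x] += 1; N += 1; }
    }
    if (N < 2) continue;
    double sum_ca2 = 0.0;
    for (int a = 0; a < A; ++a) sum_ca2 += ca[a] * ca[a];
    double ssd_t = (N - sum_ca2 / N) / 2.0;
    double ssd_wp = 0.0;
    int P_l = 0;
    for (int p = 0; p < P; ++p) {
      if (np[p] <= 0) continue;
      P_l++;
      double s2 = 0.0;
      for (int a = 0; a < A; ++a) {
        double c = cnt[(size_t)p * A + a];
        s2 += c * c;
      }
      ssd_wp += (np[p] - s2 / np[p]) / 2.0;
    }
    // group-level identities
    double ssd_wg = 0.0;
    int G_l = 0;
    std::vector<double> sum_np2_g(G, 0.0);
    gsum.assign((size_t)G * A, 0.0);
    for (int p = 0; p < P; ++p) {
      if (np[p] <= 0) continue;
      int g = grp_of_pop[p];
      ng[g] += np[p];
      sum_np2_g[g] += np[p] * np[p];
      for (int a = 0; a < A; ++a) gsum[(size_t)g * A + a] += cnt[(size_t)p * A + a];
    }
    double sum_np2 = 0.0;
    for (int p = 0; p < P; ++p) sum_np2 += np[p] * np[p];
    for (int g = 0; g < G; ++g) {
      if (ng[g] <= 0) continue;
      G_l++;
      double s2 = 0.0;
      for (int a = 0; a < A; ++a) {
        double c = gsum[(size_t)g * A + a];
        s2 += c * c;
      }
      ssd_wg += (ng[g] - s2 / ng[g]) / 2.0;
    }
    double ssd_ap = ssd_wg - ssd_wp;
    double ssd_ag = ssd_t - ssd_wg;
    int df_wp = (int)N - P_l;
    int df_ap = P_l - G_l;
    int df_ag = G_l - 1;
    if (df_wp <= 0) continue;
    double vc = ssd_wp / df_wp;
    double vb = 0.0, va = 0.0;
    if (df_ap > 0) {
      double n1 = 0.0;
      for (int g = 0; g < G; ++g)
        if (ng[g] > 0) n1 += ng[g] - sum_np2_g[g] / ng[g];
      n1 /= df_ap;
      if (n1 > 0) vb = (ssd_ap / df_ap - vc) / n1;
    }
    if (df_ag > 0) {
      double sum_g = 0.0, sum_ng2 = 0.0;
      for (int g = 0; g < G; ++g) {
        if (ng[g] <= 0) continue;
        sum_g += sum_np2_g[g] / ng[g];
        sum_ng2 += ng[g] * ng[g];
      }
      double n2 = (sum_g - sum_np2 / N) / df_ag;
      double n3 = (N - sum_ng2 / N) / df_ag;
      if (n3 > 0) va = (ssd_ag / df_ag - vc - n2 * vb) / n3;
    }
    out.ssd_ag += ssd_ag; out.ssd_ap += ssd_ap; out.ssd_wp += ssd_wp;
    out.va += va; out.vb += vb; out.vc += vc;
  }
  return out;
}

static void shuffle_int(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    std::swap(v[i], v[j]);
  }
}

// [[Rcpp::export]]
List amova_cpp(IntegerMatrix a1, IntegerMatrix a2,
               IntegerVector pop, IntegerVector grp_of_pop,
               IntegerVector n_alleles, int n_perm) {
  int n = a1.nrow();
  int P = grp_of_pop.size();
  int G = 0;
  for (int p = 0; p < P; ++p) G = std::max(G, grp_of_pop[p] + 1);
  std::vector<int> popv(pop.begin(), pop.end());
  std::vector<int> grpv(grp_of_pop.begin(), grp_of_pop.end());

  AmovaComp obs = amova_components(a1, a2, popv, grpv, n_alleles, P, G);
  double tot = obs.va + obs.vb + obs.vc;
  double phi_ct = (G > 1 && tot > 0) ? obs.va / tot : NA_REAL;
  double phi_sc = (obs.vb + obs.vc > 0) ? obs.vb / (obs.vb + obs.vc) : NA_REAL;
  double phi_st = (tot > 0) ? (obs.va + obs.vb) / tot : NA_REAL;

  int ge_st = 0, ge_sc = 0, ge_ct = 0;
  std::vector<int> pv(n), gv(P);
  for (int r = 0; r < n_perm; ++r) {
    // Phi_ST: permute individuals among all populations
    pv = popv; shuffle_int(pv);
    AmovaComp c1 = amova_components(a1, a2, pv, grpv, n_alleles, P, G);
    double t1 = c1.va + c1.vb + c1.vc;
    double s1 = (t1 > 0) ? (c1.va + c1.vb) / t1 : 0.0;
    if (!ISNA(phi_st) && s1 >= phi_st) ge_st++;
    // Phi_SC: permute individuals among populations within groups
    pv = popv;
    for (int g = 0; g < G; ++g) {
      std::vector<int> idx, lab;
      for (int i = 0; i < n; ++i)
        if (grpv[popv[i]] == g) { idx.push_back(i); lab.push_back(popv[i]); }
      shuffle_int(lab);
      for (size_t k = 0; k < idx.size(); ++k) pv[idx[k]] = lab[k];
    }
    AmovaComp c2 = amova_components(a1, a2, pv, grpv, n_alleles, P, G);
    double s2 = (c2.vb + c2.vc > 0) ? c2.vb / (c2.vb + c2.vc) : 0.0;
    if (!ISNA(phi_sc) && s2 >= phi_sc) ge_sc++;
    if (G > 1) {
      // Phi_CT: permute whole populations among groups
      gv = grpv; shuffle_int(gv);
      AmovaComp c3 = amova_components(a1, a2, popv, gv, n_alleles, P, G);
      double t3 = c3.va + c3.vb + c3.vc;
      double s3 = (t3 > 0) ? c3.va / t3 : 0.0;
      if (!ISNA(phi_ct) && s3 >= phi_ct) ge_ct++;
    }
  }
  return List::create(
    _["ssd_ag"] = obs.ssd_ag, _["ssd_ap"] = obs.ssd_ap, _["ssd_wp"] = obs.ssd_wp,
    _["va"] = obs.va, _["vb"] = obs.vb, _["vc"] = obs.vc,
    _["phi_ct"] = phi_ct, _["phi_sc"] = phi_sc, _["phi_st"] = phi_st,
    _["ge_st"] = ge_st, _["ge_sc"] = ge_sc, _["ge_ct"] = ge_ct,
    _["n_perm"] = n_perm);
}

// Pairwise two-level AMOVA-type F_ST over all population pairs.
// [[Rcpp::export]]
NumericMatrix pairwise_fst_cpp(IntegerMatrix a1, IntegerMatrix a2,
                               IntegerVector pop, int n_pop,
                               IntegerVector n_alleles) {
  int n = a1.nrow();
  NumericMatrix out(n_pop, n_pop);
  for (int p = 0; p < n_pop; ++p)
    for (int q = p + 1; q < n_pop; ++q) {
      std::vector<int> rows;
      for (int i = 0; i < n; ++i)
        if (pop[i] == p || pop[i] == q) rows.push_back(i);
      int m = (int)rows.size();
      IntegerMatrix b1(m, a1.ncol()), b2(m, a1.ncol());
      std::vector<int> pp(m);
      for (int i = 0; i < m; ++i) {
        for (int l = 0; l < a1.ncol(); ++l) {
          b1(i, l) = a1(rows[i], l); b2(i, l) = a2(rows[i], l);
        }
        pp[i] = (pop[rows[i]] == p) ? 0 : 1;
      }
      std::vector<int> grp(2, 0);
      AmovaComp c = amova_components(b1, b2, pp, grp, n_alleles, 2, 1);
      // two-level design: "populations" play the among role via vb
      double tot = c.vb + c.vc;
      double f = (tot > 0) ? c.vb / tot : NA_REAL;
      out(p, q) = f; out(q, p) = f;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Fixed-order SSR summary-statistic vector for ABC. Per species: mean
// expected and observed heterozygosity, mean allele count, mean allele-size
// variance, mean M-ratio; joint: between-species F_ST (Hs/Ht over pooled
// species frequencies, ratio of sums over loci), mean squared difference in
// mean allele size (delta-mu^2), proportion of shared alleles, and private
// allele counts scaled by the number of sampled copies.
// a1, a2: n x L allele-size matrices (raw integers, NA_INTEGER = missing);
// species: 0/1 per individual.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector summary_stats_cpp(IntegerMatrix a1, IntegerMatrix a2,
                                IntegerVector species) {
  int n = a1.nrow(), L = a1.ncol();
  double he[2] = {0, 0}, ho[2] = {0, 0}, ka[2] = {0, 0}, va[2] = {0, 0},
         mr[2] = {0, 0};
  int nl_he[2] = {0, 0}, nl_ho[2] = {0, 0};
  double ht_sum = 0.0, hs_sum = 0.0, dmu2 = 0.0;
  int dmu_loci = 0;
  double shared_num = 0.0, shared_den = 0.0;
  double priv_cnt[2] = {0, 0};
  double copies[2] = {0, 0};

  for (int l = 0; l < L; ++l) {
    std::map<int, double> cnt[2];
    double nn[2] = {0, 0};
    double ssum[2] = {0, 0}, ssum2[2] = {0, 0};
    double nhet[2] = {0, 0}, nind[2] = {0, 0};
    for (int i = 0; i < n; ++i) {
      int s = species[i];
      int x = a1(i, l), y = a2(i, l);
      if (x == NA_INTEGER || y == NA_INTEGER) continue;
      cnt[s][x] += 1; cnt[s][y] += 1;
      nn[s] += 2;
      ssum[s] += x + y; ssum2[s] += (double)x * x + (double)y * y;
      nind[s] += 1;
      if (x != y) nhet[s] += 1;
    }
    double h_within[2] = {NA_REAL, NA_REAL};
    double mean_size[2] = {NA_REAL, NA_REAL};
    for (int s = 0; s < 2; ++s) {
      copies[s] += nn[s];
      if (nn[s] > 0) {
        double sum_p2 = 0.0;
        int kk = 0, amin = 0, amax = 0; bool first = true;
        for (std::map<int, double>::iterator it = cnt[s].begin();
             it != cnt[s].end(); ++it) {
          double p = it->second / nn[s];
          sum_p2 += p * p;
          kk++;
          if (first) { amin = amax = it->first; first = false; }
          else { amin = std::min(amin, it->first); amax = std::max(amax, it->first); }
        }
        h_within[s] = 1.0 - sum_p2;
        he[s] += h_within[s]; nl_he[s]++;
        ka[s] += kk;
        mr[s] += (double)kk / (amax - amin + 1);
        mean_size[s] = ssum[s] / nn[s];
        va[s] += ssum2[s] / nn[s] - mean_size[s] * mean_size[s];
      }
      if (nind[s] > 0) { ho[s] += nhet[s] / nind[s]; nl_ho[s]++; }
    }
    if (nn[0] > 0 && nn[1] > 0) {
      // pooled Ht and mean within-species Hs for this locus
      std::map<int, double> tot(cnt[0]);
      for (std::map<int, double>::iterator it = cnt[1].begin();
           it != cnt[1].end(); ++it) tot[it->first] += it->second;
      double N = nn[0] + nn[1], sum_p2 = 0.0;
      for (std::map<int, double>::iterator it = tot.begin();
           it != tot.end(); ++it) {
        double p = it->second / N;
        sum_p2 += p * p;
      }
      ht_sum += 1.0 - sum_p2;
      hs_sum += (h_within[0] + h_within[1]) / 2.0;
      double d = mean_size[0] - mean_size[1];
      dmu2 += d * d; dmu_loci++;
      for (std::map<int, double>::iterator it = tot.begin();
           it != tot.end(); ++it) {
        bool in0 = cnt[0].count(it->first) > 0;
        bool in1 = cnt[1].count(it->first) > 0;
        shared_den += 1;
        if (in0 && in1) shared_num += 1;
        else if (in0) priv_cnt[0] += 1;
        else priv_cnt[1] += 1;
      }
    }
  }
  NumericVector out(15);
  out[0] = nl_he[0] ? he[0] / nl_he[0] : 0.0;
  out[1] = nl_ho[0] ? ho[0] / nl_ho[0] : 0.0;
  out[2] = nl_he[0] ? ka[0] / nl_he[0] : 0.0;
  out[3] = nl_he[0] ? va[0] / nl_he[0] : 0.0;
  out[4] = nl_he[0] ? mr[0] / nl_he[0] : 0.0;
  out[5] = nl_he[1] ? he[1] / nl_he[1] : 0.0;
  out[6] = nl_ho[1] ? ho[1] / nl_ho[1] : 0.0;
  out[7] = nl_he[1] ? ka[1] / nl_he[1] : 0.0;
  out[8] = nl_he[1] ? va[1] / nl_he[1] : 0.0;
  out[9] = nl_he[1] ? mr[1] / nl_he[1] : 0.0;
  out[10] = (ht_sum > 0) ? (ht_sum - hs_sum) / ht_sum : 0.0;
  out[11] = dmu_loci ? dmu2 / dmu_loci : 0.0;
  out[12] = (shared_den > 0) ? shared_num / shared_den : 0.0;
  out[13] = (copies[0] > 0) ? priv_cnt[0] / copies[0] * 100.0 : 0.0;
  out[14] = (copies[1] > 0) ? priv_cnt[1] / copies[1] * 100.0 : 0.0;
  out.attr("names") = CharacterVector::create(
    "he_a", "ho_a", "ka_a", "va_a", "mr_a",
    "he_b", "ho_b", "kb_b", "vb_b", "mr_b",
    "fst", "dmu2", "shared", "priv_a", "priv_b");
  return out;
}
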