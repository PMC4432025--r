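// Structured-coalescent simulator with population divergence and migration,
// plus infinite-sites mutation and fast pairwise-distance kernels.
//
// Time runs backwards in generations.  Demes occupy fixed slots 0..k-1; a
// divergence event at time ev_time[e] moves every lineage in slot ev_from[e]
// into slot ev_to[e] (the receiving slot's size for the next epoch is read
// from the sizes matrix).  Coalescence within a deme of diploid size N
// happens at rate choose(k,2)/(2N); migration moves single lineages between
// slots at the per-lineage backward rates in `mig`.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct SimTree {
  int n;                       // number of leaves
  std::vector<double> time;    // 2n-1 node times, leaves first
  std::vector<int> parent, lchild, rchild;
};

// One structured-coalescent genealogy.
SimTree sim_tree_core(const IntegerVector& samp,
                      const NumericMatrix& sizes,    // epochs x k
                      const NumericVector& mig,      // epochs*k*k, [e,i,j]
                      const NumericVector& ev_time,  // epochs-1, ascending
                      const IntegerVector& ev_from,
                      const IntegerVector& ev_to) {
  const int k = samp.size();
  const int nE = sizes.nrow();
  int n = 0;
  for (int d = 0; d < k; ++d) n += samp[d];
  if (n < 2) stop("need at least 2 sampled lineages");

  SimTree T;
  T.n = n;
  const int nn = 2 * n - 1;
  T.time.assign(nn, 0.0);
  T.parent.assign(nn, -1);
  T.lchild.assign(nn, -1);
  T.rchild.assign(nn, -1);

  std::vector<std::vector<int> > live(k);
  int id = 0;
  for (int d = 0; d < k; ++d)
    for (int i = 0; i < samp[d]; ++i) live[d].push_back(id++);

  int next_node = n, nlive = n, ep = 0;
  double t = 0.0;
  std::vector<double> crate(k), mrate(k);

  while (nlive > 1) {
    double ctot = 0.0, mtot = 0.0;
    for (int d = 0; d < k; ++d) {
      const double kd = (double)live[d].size();
      const double N = sizes(ep, d);
      crate[d] = (kd >= 2.0 && N > 0.0) ? kd * (kd - 1.0) * 0.5 / (2.0 * N) : 0.0;
      double mr = 0.0;
      if (kd > 0.0)
        for (int j = 0; j < k; ++j)
          if (j != d) mr += mig[(ep * k + d) * k + j];
      mrate[d] = kd * mr;
      ctot += crate[d];
      mtot += mrate[d];
    }
    const double tot = ctot + mtot;
    const double tnext = (ep < nE - 1) ? ev_time[ep] : R_PosInf;
    double dt = (tot > 0.0) ? R::exp_rand() / tot : R_PosInf;
    if (t + dt >= tnext) {
      if (!R_FINITE(tnext))
        stop("lineages can never coalesce under this demography");
      t = tnext;
      const int a = ev_from[ep], b = ev_to[ep];
      for (size_t i = 0; i < live[a].size(); ++i) live[b].push_back(live[a][i]);
      live[a].clear();
      ++ep;
      continue;
    }
    t += dt;
    double u = R::unif_rand() * tot;
    int d = -1;
    bool coal = true;
    for (int dd = 0; dd < k; ++dd) {
      if (u < crate[dd]) { d = dd; break; }
      u -= crate[dd];
    }
    if (d < 0) {
      coal = false;
      for (int dd = 0; dd < k; ++dd) {
        if (u < mrate[dd]) { d = dd; break; }
        u -= mrate[dd];
      }
      if (d < 0) d = k - 1;  // numerical guard
    }
    if (coal) {
      const int kd = (int)live[d].size();
      int i = (int)(R::unif_rand() * kd);
      if (i >= kd) i = kd - 1;
      int j = (int)(R::unif_rand() * (kd - 1));
      if (j >= kd - 1) j = kd - 2;
      if (j >= i) ++j;
      const int a = live[d][i], b = live[d][j];
      const int v = next_node++;
      T.time[v] = t;
      T.lchild[v] = a;
      T.rchild[v] = b;
      T.parent[a] = v;
      T.parent[b] = v;
      // replace the two lineages by their parent
      if (i > j) std::swap(i, j);
      live[d][i] = v;
      live[d][j] = live[d].back();
      live[d].pop_back();
      --nlive;
    } else {
      // migration: pick lineage in d and destination j with prob mig[d][j]
      const int kd = (int)live[d].size();
      int i = (int)(R::unif_rand() * kd);
      if (i >= kd) i = kd - 1;
      double mr = 0.0;
      for (int j = 0; j < k; ++j)
        if (j != d) mr += mig[(ep * k + d) * k + j];
      double v = R::unif_rand() * mr;
      int dest = -1;
      for (int j = 0; j < k; ++j) {
        if (j == d) continue;
        const double m = mig[(ep * k + d) * k + j];
        if (v < m) { dest = j; break; }
        v -= m;
      }
      if (dest < 0) { for (int j = k - 1; j >= 0; --j) if (j != d) { dest = j; break; } }
      live[dest].push_back(live[d][i]);
      live[d][i] = live[d].back();
      live[d].pop_back();
    }
  }
  return T;
}

double total_length(const SimTree& T) {
  const int nn = 2 * T.n - 1;
  double L = 0.0;
  for (int v = 0; v < nn; ++v)
    if (T.parent[v] >= 0) L += T.time[T.parent[v]] - T.time[v];
  return L;
}

// per-node counts of descendant leaves in each sampling group
void group_counts(const SimTree& T, const IntegerVector& leaf_group, int ngrp,
                  std::vector<int>& cnt) {
  const int nn = 2 * T.n - 1;
  cnt.assign((size_t)nn * ngrp, 0);
  for (int v = 0; v < T.n; ++v) cnt[(size_t)v * ngrp + leaf_group[v]] = 1;
  for (int v = T.n; v < nn; ++v) {
    const int a = T.lchild[v], b = T.rchild[v];
    for (int g = 0; g < ngrp; ++g)
      cnt[(size_t)v * ngrp + g] =
          cnt[(size_t)a * ngrp + g] + cnt[(size_t)b * ngrp + g];
  }
}

// sample a branch proportionally to its length; returns the child node
int sample_branch(const SimTree& T, double Ltot) {
  const int nn = 2 * T.n - 1;
  double u = R::unif_rand() * Ltot;
  for (int v = 0; v < nn; ++v) {
    if (T.parent[v] < 0) continue;
    const double bl = T.time[T.parent[v]] - T.time[v];
    if (u < bl) return v;
    u -= bl;
  }
  for (int v = nn - 1; v >= 0; --v)
    if (T.parent[v] >= 0) return v;
  return 0;
}

void leaves_under(const SimTree& T, int node, std::vector<int>& out) {
  out.clear();
  std::vector<int> stack(1, node);
  while (!stack.empty()) {
    const int v = stack.back();
    stack.pop_back();
    if (v < T.n) {
      out.push_back(v);
    } else {
      stack.push_back(T.lchild[v]);
      stack.push_back(T.rchild[v]);
    }
  }
}

}  // namespace

// Simulate genealogies only; returns per-replicate (tmrca, total length).
// [[Rcpp::export(name = ".cpp_tree_summaries")]]
NumericMatrix cpp_tree_summaries(IntegerVector samp, NumericMatrix sizes,
                                 NumericVector mig, NumericVector ev_time,
                                 IntegerVector ev_from, IntegerVector ev_to,
                                 int reps) {
  NumericMatrix out(reps, 2);
  for (int r = 0; r < reps; ++r) {
    SimTree T = sim_tree_core(samp, sizes, mig, ev_time, ev_from, ev_to);
    out(r, 0) = T.time[2 * T.n - 2];
    out(r, 1) = total_length(T);
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(out) = CharacterVector::create("tmrca", "total_length");
  return out;
}

// One genealogy as parent/time arrays (leaves first, root last).
// [[Rcpp::export(name = ".cpp_sim_tree")]]
List cpp_sim_tree(IntegerVector samp, NumericMatrix sizes, NumericVector mig,
                  NumericVector ev_time, IntegerVector ev_from,
                  IntegerVector ev_to) {
  SimTree T = sim_tree_core(samp, sizes, mig, ev_time, ev_from, ev_to);
  return List::create(_["parent"] = wrap(T.parent), _["time"] = wrap(T.time),
                      _["n_leaves"] = T.n);
}

// Whole multilocus dataset, returned as per-group derived-allele counts
// (ngroups x total_SNPs).  mu_l = per-locus expected mutations per unit
// branch length (mu * length).  If shared_tree, all loci reuse one genealogy
// (uniparental organelle loci); otherwise each locus gets its own.
// [[Rcpp::export(name = ".cpp_sim_counts")]]
IntegerMatrix cpp_sim_counts(IntegerVector samp, NumericMatrix sizes,
                             NumericVector mig, NumericVector ev_time,
                             IntegerVector ev_from, IntegerVector ev_to,
                             IntegerVector leaf_group, int ngrp,
                             NumericVector mu_l, bool shared_tree) {
  const int nloci = mu_l.size();
  std::vector<int> cols;  // flattened count columns
  std::vector<int> cnt;
  SimTree T;
  double Ltot = 0.0;
  bool have_tree = false;
  for (int l = 0; l < nloci; ++l) {
    if (!have_tree || !shared_tree) {
      T = sim_tree_core(samp, sizes, mig, ev_time, ev_from, ev_to);
      Ltot = total_length(T);
      group_counts(T, leaf_group, ngrp, cnt);
      have_tree = true;
    }
    const int nmut = (int)R::rpois(mu_l[l] * Ltot);
    for (int m = 0; m < nmut; ++m) {
      const int v = sample_branch(T, Ltot);
      for (int g = 0; g < ngrp; ++g)
        cols.push_back(cnt[(size_t)v * ngrp + g]);
    }
    Rcpp::checkUserInterrupt();
  }
  const int S = (int)(cols.size() / ngrp);
  IntegerMatrix out(ngrp, S);
  for (int s = 0; s < S; ++s)
    for (int g = 0; g < ngrp; ++g) out(g, s) = cols[(size_t)s * ngrp + g];
  return out;
}

// Same, but returning per-locus 0/1 haplotype matrices (n x S_l).
// [[Rcpp::export(name = ".cpp_sim_matrices")]]
List cpp_sim_matrices(IntegerVector samp, NumericMatrix sizes,
                      NumericVector mig, NumericVector ev_time,
                      IntegerVector ev_from, IntegerVector ev_to,
                      NumericVector mu_l, bool shared_tree) {
  const int nloci = mu_l.size();
  List out(nloci);
  SimTree T;
  double Ltot = 0.0;
  bool have_tree = false;
  std::vector<int> lv;
  for (int l = 0; l < nloci; ++l) {
    if (!have_tree || !shared_tree) {
      T = sim_tree_core(samp, sizes, mig, ev_time, ev_from, ev_to);
      Ltot = total_length(T);
      have_tree = true;
    }
    const int nmut = (int)R::rpois(mu_l[l] * Ltot);
    IntegerMatrix M(T.n, nmut);
    for (int m = 0; m < nmut; ++m) {
      const int v = sample_branch(T, Ltot);
      leaves_under(T, v, lv);
      for (size_t i = 0; i < lv.size(); ++i) M(lv[i], m) = 1;
    }
    out[l] = M;
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Pairwise sequence comparison kernel.  `code` is an n x L integer matrix,
// 0 = missing, >0 = allele code.  `w` gives per-column weights contributing
// to the comparable-length denominator; `use_col` marks columns whose
// mismatches are counted.  Returns n x n matrices of mismatch counts and
// weighted comparable lengths (upper+lower symmetric).
// [[Rcpp::export(name = ".cpp_pair_stats")]]
List cpp_pair_stats(IntegerMatrix code, NumericVector w, LogicalVector use_col) {
  const int n = code.nrow(), L = code.ncol();
  NumericMatrix diff(n, n), comp(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0, c = 0.0;
      for (int s = 0; s < L; ++s) {
        const int a = code(i, s), b = code(j, s);
        if (a == 0 || b == 0) continue;
        c += w[s];
        if (use_col[s] && a != b) d += 1.0;
      }
      diff(i, j) = diff(j, i) = d;
      comp(i, j) = comp(j, i) = c;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["diff"] = diff, _["comp"] = comp);
}
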