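#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent with population merges and pulse admixture.
//
// Populations are indexed 0..npop-1 with constant diploid size N[p]; pairwise
// coalescence within a population occurs at rate 1/(2N) per generation.
// Events (rows of `events`, sorted by time, backward in time):
//   time, type (0 = merge: all lineages in `from` move to `to`;
//               1 = admixture pulse: each lineage in `from` moves to `to`
//                   with probability gamma), from, to, gamma.
// After the last merge exactly one population must remain reachable; the
// caller validates that (see demographic_scenario()).
//
// Uses R's RNG throughout so set.seed() on the R side governs results.

namespace {

struct Node {
  int left = -1, right = -1;
  double time = 0.0;
};

// Simulates one gene tree; fills nodes (2n-1 entries, tips 0..n-1) and
// returns the root index.
int simulate_tree(const IntegerVector &samples, const NumericVector &sizes,
                  const NumericMatrix &events, std::vector<Node> &nodes) {
  int npop = samples.size();
  int n = 0;
  for (int p = 0; p < npop; p++) n += samples[p];
  nodes.assign(2 * n - 1, Node());
  std::vector<int> lin, pop;
  for (int p = 0; p < npop; p++)
    for (int i = 0; i < samples[p]; i++) {
      lin.push_back((int)lin.size());
      pop.push_back(p);
    }
  int next_node = n;
  double t = 0.0;
  int ev = 0, nev = events.nrow();
  std::vector<int> kcount(npop);
  while ((int)lin.size() > 1) {
    std::fill(kcount.begin(), kcount.end(), 0);
    for (size_t i = 0; i < lin.size(); i++) kcount[pop[i]]++;
    double total_rate = 0.0;
    for (int p = 0; p < npop; p++)
      if (kcount[p] > 1)
        total_rate += kcount[p] * (kcount[p] - 1) / 2.0 / (2.0 * sizes[p]);
    double t_event = (ev < nev) ? events(ev, 0) : R_PosInf;
    double dt = (total_rate > 0) ? R::rexp(1.0 / total_rate) : R_PosInf;
    if (ev < nev && t + dt >= t_event) {
      t = t_event;
      int type = (int)events(ev, 1);
      int from = (int)events(ev, 2), to = (int)events(ev, 3);
      double gamma = events(ev, 4);
      for (size_t i = 0; i < lin.size(); i++) {
        if (pop[i] != from) continue;
        if (type == 0 || R::unif_rand() < gamma) pop[i] = to;
      }
      ev++;
      continue;
    }
    if (!R_FINITE(dt)) stop("no coalescence possible: lineages stranded in isolated populations");
    t += dt;
    // choose population proportional to its pair rate
    double u = R::unif_rand() * total_rate, acc = 0.0;
    int cpop = -1;
    for (int p = 0; p < npop; p++) {
      if (kcount[p] > 1) {
        acc += kcount[p] * (kcount[p] - 1) / 2.0 / (2.0 * sizes[p]);
        if (u <= acc) { cpop = p; break; }
      }
    }
    if (cpop < 0) cpop = npop - 1;
    // pick two distinct lineages in cpop
    std::vector<int> idx;
    for (size_t i = 0; i < lin.size(); i++)
      if (pop[i] == cpop) idx.push_back((int)i);
    int i1 = idx[(int)(R::unif_rand() * idx.size()) % idx.size()];
    int i2 = i1;
    while (i2 == i1) i2 = idx[(int)(R::unif_rand() * idx.size()) % idx.size()];
    Node &nd = nodes[next_node];
    nd.left = lin[i1];
    nd.right = lin[i2];
    nd.time = t;
    lin[i1] = next_node;
    if (i2 != (int)lin.size() - 1) {
      lin[i2] = lin.back();
      pop[i2] = pop.back();
    }
    lin.pop_back();
    pop.pop_back();
    next_node++;
  }
  return next_node - 1;
}

}  // namespace

// Returns a list describing one coalescent gene tree: parent index (1-based,
// 0 for the root), node times in generations, and n_tips. Tips come first in
// sampling order (population blocks).
// [[Rcpp::export]]
List cpp_coalescent_tree(IntegerVector samples, NumericVector sizes,
                         NumericMatrix events) {
  std::vector<Node> nodes;
  int root = simulate_tree(samples, sizes, events, nodes);
  int nn = (int)nodes.size();
  IntegerVector parent(nn, 0);
  NumericVector time(nn);
  for (int i = 0; i < nn; i++) {
    time[i] = nodes[i].time;
    if (nodes[i].left >= 0) {
      parent[nodes[i].left] = i + 1;
      parent[nodes[i].right] = i + 1;
    }
  }
  int ntip = (nn + 1) / 2;
  return List::create(_["parent"] = parent, _["time"] = time,
                      _["n_tip"] = ntip, _["root"] = root + 1);
}

// Simulates a microsatellite panel under the strict stepwise mutation model:
// per locus an independent gene tree, mutation count Poisson(mu * branch),
// each mutation +/-1 repeat with probability 1/2. Returns an integer matrix
// (haploid lineages x loci) of allele sizes relative to the root allele.
// [[Rcpp::export]]
IntegerMatrix cpp_ssr_panel(IntegerVector samples, NumericVector sizes,
                            NumericMatrix events, int n_loci, double mu) {
  int n = 0;
  for (int p = 0; p < samples.size(); p++) n += samples[p];
  IntegerMatrix out(n, n_loci);
  std::vector<Node> nodes;
  std::vector<int> allele;
  for (int l = 0; l < n_loci; l++) {
    int root = simulate_tree(samples, sizes, events, nodes);
    int nn = (int)nodes.size();
    allele.assign(nn, 0);
    // preorder from root: children indices are always < parent index for
    // internal nodes created in coalescent order, so walk downward
    for (int i = root; i >= n; i--) {
      int a = allele[i];
      for (int c : {nodes[i].left, nodes[i].right}) {
        double branch = nodes[i].time - nodes[c].time;
        int m = (int)R::rpois(mu * branch);
        int shift = 0;
        for (int j = 0; j < m; j++) shift += (R::unif_rand() < 0.5) ? 1 : -1;
        allele[c] = a + shift;
      }
    }
    for (int i = 0; i < n; i++) out(i, l) = allele[i];
  }
  return out;
}
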