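#include <Rcpp.h>
#include <map>
using namespace Rcpp;

// Microsatellite summary statistics: per population mean allele count,
// mean unbiased expected heterozygosity, mean allele-size SD; per pair
// Weir-Cockerham theta (variance components summed over alleles and loci)
// and Goldstein's (delta-mu)^2; global mean allele count. Lineage rows are
// grouped by population with consecutive pairs forming individuals.
// Layout must match the names assigned in R (sumstats_from_matrix).

// [[Rcpp::export]]
NumericVector cpp_ssr_sumstats(IntegerMatrix alleles, IntegerVector pop,
                               int npop) {
  int n_loci = alleles.ncol(), n_row = alleles.nrow();
  int npair = npop * (npop - 1) / 2;
  NumericVector out(3 * npop + 2 * npair + 1);
  std::vector<std::vector<int> > rows(npop);
  for (int i = 0; i < n_row; i++) rows[pop[i]].push_back(i);

  for (int p = 0; p < npop; p++) {
    double K = 0, H = 0, SD = 0;
    int n = (int)rows[p].size();
    for (int l = 0; l < n_loci; l++) {
      std::map<int, int> tab;
      double s = 0, s2 = 0;
      for (int i : rows[p]) {
        int a = alleles(i, l);
        tab[a]++;
        s += a;
        s2 += (double)a * a;
      }
      K += (double)tab.size();
      double sumsq = 0;
      for (auto &kv : tab) {
        double f = (double)kv.second / n;
        sumsq += f * f;
      }
      H += (double)n / (n - 1) * (1 - sumsq);
      SD += std::sqrt(std::max(0.0, (s2 - s * s / n) / (n - 1)));
    }
    out[3 * p] = K / n_loci;
    out[3 * p + 1] = H / n_loci;
    out[3 * p + 2] = SD / n_loci;
  }

  int k = 3 * npop;
  for (int p = 0; p < npop; p++) {
    for (int q = p + 1; q < npop; q++) {
      double A = 0, B = 0, C = 0, dmu2 = 0;
      double n1 = rows[p].size() / 2.0, n2 = rows[q].size() / 2.0;
      double r = 2, nbar = (n1 + n2) / 2;
      double nc = (r * nbar - (n1 * n1 + n2 * n2) / (r * nbar)) / (r - 1);
      for (int l = 0; l < n_loci; l++) {
        std::map<int, int> uall;
        double m1 = 0, m2 = 0;
        for (int i : rows[p]) { uall[alleles(i, l)]++; m1 += alleles(i, l); }
        for (int i : rows[q]) { uall[alleles(i, l)]++; m2 += alleles(i, l); }
        m1 /= rows[p].size();
        m2 /= rows[q].size();
        dmu2 += (m1 - m2) * (m1 - m2);
        if (uall.size() < 2) continue;
        for (auto &kv : uall) {
          int al = kv.first;
          double p_i[2], h_i[2];
          const std::vector<int> *rr[2] = {&rows[p], &rows[q]};
          double nn[2] = {n1, n2};
          for (int g = 0; g < 2; g++) {
            int cnt = 0, het = 0, nind = (int)rr[g]->size() / 2;
            for (int j = 0; j < nind; j++) {
              int a1 = alleles((*rr[g])[2 * j], l);
              int a2 = alleles((*rr[g])[2 * j + 1], l);
              cnt += (a1 == al) + (a2 == al);
              het += ((a1 == al) != (a2 == al));
            }
            p_i[g] = cnt / (2.0 * nind);
            h_i[g] = (double)het / nind;
          }
          double pbar = (nn[0] * p_i[0] + nn[1] * p_i[1]) / (r * nbar);
          double s2 = (nn[0] * (p_i[0] - pbar) * (p_i[0] - pbar) +
                       nn[1] * (p_i[1] - pbar) * (p_i[1] - pbar)) /
                      ((r - 1) * nbar);
          double hbar = (nn[0] * h_i[0] + nn[1] * h_i[1]) / (r * nbar);
          double a = nbar / nc *
                     (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                              (nbar - 1));
          double b = nbar / (nbar - 1) *
                     (pbar * (1 - pbar) - (r - 1) / r * s2 -
                      (2 * nbar - 1) / (4 * nbar) * hbar);
          double c = hbar / 2;
          A += a; B += b; C += c;
        }
      }
      out[k++] = (A + B + C == 0) ? NA_REAL : A / (A + B + C);
      out[k++] = dmu2 / n_loci;
    }
  }
  double ktot = 0;
  for (int l = 0; l < n_loci; l++) {
    std::map<int, int> tab;
    for (int i = 0; i < n_row; i++) tab[alleles(i, l)]++;
    ktot += (double)tab.size();
  }
  out[k] = ktot / n_loci;
  return out;
}
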