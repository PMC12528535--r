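#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Brent's derivative-free bounded minimizer (Brent 1973, the algorithm
// behind stats::optimize), local copy since R does not export its own.
static double brent_fmin(double ax, double bx,
                         double (*f)(double, void *), void *info,
                         double tol) {
  const double c = (3. - std::sqrt(5.)) * .5;
  double a = ax, b = bx, eps = std::sqrt(DBL_EPSILON);
  double v = a + c * (b - a), w = v, x = v;
  double d = 0., e = 0.;
  double fx = f(x, info), fv = fx, fw = fx;
  double tol3 = tol / 3.;
  for (;;) {
    double xm = (a + b) * .5;
    double tol1 = eps * std::fabs(x) + tol3;
    double t2 = tol1 * 2.;
    if (std::fabs(x - xm) <= t2 - (b - a) * .5) break;
    double p = 0., q = 0., r = 0.;
    if (std::fabs(e) > tol1) {  // fit parabola
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = (q - r) * 2.;
      if (q > 0.) p = -p; else q = -q;
      r = e;
      e = d;
    }
    if (std::fabs(p) >= std::fabs(q * .5 * r) || p <= q * (a - x) ||
        p >= q * (b - x)) {  // golden-section step
      if (x < xm) e = b - x; else e = a - x;
      d = c * e;
    } else {  // parabolic step
      d = p / q;
      double u = x + d;
      if (u - a < t2 || b - u < t2) {
        d = tol1;
        if (x >= xm) d = -d;
      }
    }
    double u;
    if (std::fabs(d) >= tol1) u = x + d;
    else if (d > 0.) u = x + tol1;
    else u = x - tol1;
    double fu = f(u, info);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}

// Felsenstein pruning over a postorder edge list. Trees here are tiny
// (4-16 tips), so no partial-likelihood rescaling is needed: the smallest
// per-site likelihood at the bounds used (branches <= 10) is far above
// double underflow for this tip count.
//
// Conventions (ape): tips are nodes 1..ntip, root is ntip+1, edges are rows
// (parent, child) sorted in postorder so children are visited before parents.
// Tip partial likelihoods encode IUPAC ambiguity (1 for every compatible
// state, gaps all-ones).

namespace {

struct Kernel {
  int ntip, nnode, npat, ncat;
  const int *parent, *child;     // nedge
  int nedge;
  const double *tippart;         // 4 x npat x ntip
  const double *V, *Vinv;        // 4 x 4 eigenvectors of Q
  const double *lambda;          // 4 eigenvalues
  const double *pi;              // 4 stationary frequencies
  const double *rates;           // ncat category rates (mean 1)
  const double *weights;         // npat pattern weights

  // transition matrix P(t) = V diag(exp(lambda t)) Vinv, row-major [from][to]
  void pmat(double t, double *P) const {
    double e[4];
    for (int i = 0; i < 4; i++) e[i] = std::exp(lambda[i] * t);
    for (int a = 0; a < 4; a++)
      for (int b = 0; b < 4; b++) {
        double s = 0.0;
        for (int k = 0; k < 4; k++) s += V[a + 4 * k] * e[k] * Vinv[k + 4 * b];
        P[4 * a + b] = s < 0 ? 0.0 : s;  // clip tiny negative round-off
      }
  }

  // per-pattern site likelihoods (not logged), averaged over rate categories
  void site_likelihoods(const double *edge_len, double *out) const {
    int nn = ntip + nnode;
    std::vector<double> part(4 * (size_t)npat * nn);
    std::vector<double> P(16 * (size_t)nedge);
    std::vector<char> internal_seen(nn, 0);
    for (int c = 0; c < ncat; c++) {
      for (int e = 0; e < nedge; e++) pmat(edge_len[e] * rates[c], &P[16 * (size_t)e]);
      std::fill(internal_seen.begin(), internal_seen.end(), 0);
      for (int e = 0; e < nedge; e++) {
        int pa = parent[e] - 1, ch = child[e] - 1;
        const double *chpart =
            (ch < ntip) ? tippart + 4 * (size_t)npat * ch : &part[4 * (size_t)npat * ch];
        double *papart = &part[4 * (size_t)npat * pa];
        const double *Pm = &P[16 * (size_t)e];
        if (!internal_seen[pa]) {
          std::fill(papart, papart + 4 * (size_t)npat, 1.0);
          internal_seen[pa] = 1;
        }
        for (int s = 0; s < npat; s++) {
          const double *x = chpart + 4 * s;
          double *y = papart + 4 * s;
          for (int a = 0; a < 4; a++) {
            double v = Pm[4 * a] * x[0] + Pm[4 * a + 1] * x[1] +
                       Pm[4 * a + 2] * x[2] + Pm[4 * a + 3] * x[3];
            y[a] *= v;
          }
        }
      }
      const double *rootpart = &part[4 * (size_t)npat * ntip];  // root = ntip+1
      for (int s = 0; s < npat; s++) {
        double L = 0.0;
        for (int a = 0; a < 4; a++) L += pi[a] * rootpart[4 * s + a];
        if (c == 0) out[s] = L / ncat; else out[s] += L / ncat;
      }
    }
  }

  double total_loglik(const double *edge_len) const {
    std::vector<double> site(npat);
    site_likelihoods(edge_len, site.data());
    double ll = 0.0;
    for (int s = 0; s < npat; s++)
      ll += weights[s] * std::log(std::max(site[s], 1e-300));
    return ll;
  }
};

struct EdgeObjective {
  Kernel *k;
  std::vector<double> *len;
  int edge;
};

double edge_negloglik(double x, void *info) {
  EdgeObjective *o = static_cast<EdgeObjective *>(info);
  (*o->len)[o->edge] = x;
  return -o->k->total_loglik(o->len->data());
}

Kernel make_kernel(const IntegerMatrix &edge, int ntip, int nnode,
                   const NumericVector &tippart, int npat,
                   const NumericMatrix &V, const NumericMatrix &Vinv,
                   const NumericVector &lambda, const NumericVector &pi,
                   const NumericVector &rates, const NumericVector &weights,
                   std::vector<int> &pa, std::vector<int> &ch) {
  int nedge = edge.nrow();
  pa.resize(nedge); ch.resize(nedge);
  for (int e = 0; e < nedge; e++) { pa[e] = edge(e, 0); ch[e] = edge(e, 1); }
  Kernel k;
  k.ntip = ntip; k.nnode = nnode; k.npat = npat; k.ncat = rates.size();
  k.parent = pa.data(); k.child = ch.data(); k.nedge = nedge;
  k.tippart = tippart.begin();
  k.V = V.begin(); k.Vinv = Vinv.begin(); k.lambda = lambda.begin();
  k.pi = pi.begin(); k.rates = rates.begin(); k.weights = weights.begin();
  return k;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_site_loglik(IntegerMatrix edge, int ntip, int nnode,
                              NumericVector tippart, int npat,
                              NumericVector edge_len, NumericMatrix V,
                              NumericMatrix Vinv, NumericVector lambda,
                              NumericVector pi, NumericVector rates,
                              NumericVector weights) {
  std::vector<int> pa, ch;
  Kernel k = make_kernel(edge, ntip, nnode, tippart, npat, V, Vinv, lambda, pi,
                         rates, weights, pa, ch);
  std::vector<double> site(npat);
  k.site_likelihoods(edge_len.begin(), site.data());
  NumericVector out(npat);
  for (int s = 0; s < npat; s++) out[s] = std::log(std::max(site[s], 1e-300));
  return out;
}

// Coordinate-wise Brent optimization of branch lengths within [lo, hi],
// sweeping edges until the relative log-likelihood improvement drops below
// tol or max_sweeps is reached.
// [[Rcpp::export]]
List cpp_optimize_edges(IntegerMatrix edge, int ntip, int nnode,
                        NumericVector tippart, int npat,
                        NumericVector edge_len0, NumericMatrix V,
                        NumericMatrix Vinv, NumericVector lambda,
                        NumericVector pi, NumericVector rates,
                        NumericVector weights, double lo, double hi,
                        double tol, int max_sweeps) {
  std::vector<int> pa, ch;
  Kernel k = make_kernel(edge, ntip, nnode, tippart, npat, V, Vinv, lambda, pi,
                         rates, weights, pa, ch);
  int nedge = edge.nrow();
  std::vector<double> len(edge_len0.begin(), edge_len0.end());
  for (int e = 0; e < nedge; e++) len[e] = std::min(std::max(len[e], lo), hi);
  double ll = k.total_loglik(len.data());
  bool converged = false;
  int sweeps = 0;
  for (; sweeps < max_sweeps; sweeps++) {
    double ll_prev = ll;
    for (int e = 0; e < nedge; e++) {
      EdgeObjective obj{&k, &len, e};
      double cur = len[e];
      double best = brent_fmin(lo, hi, edge_negloglik, &obj, 1e-7);
      len[e] = best;
      double ll_new = k.total_loglik(len.data());
      if (ll_new < ll) { len[e] = cur; } else { ll = ll_new; }
    }
    if (std::fabs(ll - ll_prev) <= tol * (std::fabs(ll_prev) + 1e-12)) {
      converged = true;
      sweeps++;
      break;
    }
  }
  return List::create(_["edge_len"] = NumericVector(len.begin(), len.end()),
                      _["loglik"] = ll, _["converged"] = converged,
                      _["sweeps"] = sweeps);
}
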