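#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log(1/(1+exp(-e))), stable for large |e|
static inline double log_sig(double e) {
  return e > 0.0 ? -log1p(std::exp(-e)) : e - log1p(std::exp(e));
}

// Marginal negative log-likelihood (and gradient) of the three-level
// random-intercept logit, integrating the cluster intercept v ~ N(0, sv^2)
// and the household-within-cluster intercept u ~ N(0, su^2) by a nested
// Gauss-Hermite product rule.
//
// theta = c(beta[1..p], sv, su); X is n x p; y in {0,1}.
// hh: 0-based household index per child; cl_of_hh: 0-based cluster index per
// household; zv/lwv, zu/lwu: standard-normal quadrature nodes and log-weights.
//
// The likelihood factors by cluster:
//   L_k = sum_q w_q prod_{j in k} [ sum_r w_r prod_{i in j} f(y_i | eta_i + sv z_q + su z_r) ]
// computed throughout in logs with log-sum-exp.
// [[Rcpp::export]]
List ll3_nested_cpp(NumericVector theta, NumericMatrix X, IntegerVector y,
                    IntegerVector hh, IntegerVector cl_of_hh, int n_cl,
                    NumericVector zv, NumericVector lwv,
                    NumericVector zu, NumericVector lwu, bool grad) {
  const int n = X.nrow(), p = X.ncol();
  const int Qv = zv.size(), Qu = zu.size(), C = Qu * Qv;
  const int H = cl_of_hh.size();
  const double sv = theta[p], su = theta[p + 1];

  std::vector<double> eta0(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const double b = theta[j];
    const double* xj = X.begin() + (size_t)j * n;
    for (int i = 0; i < n; ++i) eta0[i] += b * xj[i];
  }

  std::vector<double> off((size_t)C);
  for (int q = 0; q < Qv; ++q)
    for (int r = 0; r < Qu; ++r)
      off[(size_t)q * Qu + r] = sv * zv[q] + su * zu[r];

  // Sh[c*H + h]: log prod_i f for household h at node pair c = (q,r)
  std::vector<double> Sh((size_t)H * C, 0.0);
  std::vector<double> Pmat;
  if (grad) Pmat.resize((size_t)n * C);
  for (int c = 0; c < C; ++c) {
    const double o = off[c];
    double* shc = &Sh[(size_t)c * H];
    double* pc = grad ? &Pmat[(size_t)c * n] : (double*)0;
    for (int i = 0; i < n; ++i) {
      const double e = eta0[i] + o;
      shc[hh[i]] += (y[i] == 1) ? log_sig(e) : log_sig(-e);
      if (grad) pc[i] = 1.0 / (1.0 + std::exp(-e));
    }
  }

  // household-level integral over u for each outer node q
  std::vector<double> logB((size_t)H * Qv);
  for (int q = 0; q < Qv; ++q) {
    for (int h = 0; h < H; ++h) {
      double m = -INFINITY;
      for (int r = 0; r < Qu; ++r) {
        const double v = Sh[(size_t)(q * Qu + r) * H + h] + lwu[r];
        if (v > m) m = v;
      }
      double s = 0.0;
      for (int r = 0; r < Qu; ++r)
        s += std::exp(Sh[(size_t)(q * Qu + r) * H + h] + lwu[r] - m);
      logB[(size_t)q * H + h] = m + std::log(s);
    }
  }

  // cluster-level products and integral over v
  std::vector<double> Tk((size_t)n_cl * Qv, 0.0);
  for (int q = 0; q < Qv; ++q)
    for (int h = 0; h < H; ++h)
      Tk[(size_t)q * n_cl + cl_of_hh[h]] += logB[(size_t)q * H + h];

  std::vector<double> logLk(n_cl);
  double nll = 0.0;
  for (int k = 0; k < n_cl; ++k) {
    double m = -INFINITY;
    for (int q = 0; q < Qv; ++q) {
      const double v = Tk[(size_t)q * n_cl + k] + lwv[q];
      if (v > m) m = v;
    }
    double s = 0.0;
    for (int q = 0; q < Qv; ++q)
      s += std::exp(Tk[(size_t)q * n_cl + k] + lwv[q] - m);
    logLk[k] = m + std::log(s);
    nll -= logLk[k];
  }
  if (!grad) return List::create(_["nll"] = nll);

  // posterior node weights: Pk (cluster x q) and, within q, household weights
  std::vector<double> Pk((size_t)n_cl * Qv);
  for (int q = 0; q < Qv; ++q)
    for (int k = 0; k < n_cl; ++k)
      Pk[(size_t)q * n_cl + k] =
        std::exp(Tk[(size_t)q * n_cl + k] + lwv[q] - logLk[k]);

  std::vector<double> rs(n, 0.0);  // sum_c G_i(c) * (y_i - p_i(c))
  double gsv = 0.0, gsu = 0.0;
  for (int c = 0; c < C; ++c) {
    const int q = c / Qu, r = c % Qu;
    const double* shc = &Sh[(size_t)c * H];
    const double* pc = &Pmat[(size_t)c * n];
    const double* lB = &logB[(size_t)q * H];
    const double* pk = &Pk[(size_t)q * n_cl];
    for (int i = 0; i < n; ++i) {
      const int h = hh[i];
      const double w = std::exp(shc[h] + lwu[r] - lB[h]) * pk[cl_of_hh[h]];
      const double res = w * ((double)y[i] - pc[i]);
      rs[i] += res;
      gsv += res * zv[q];
      gsu += res * zu[r];
    }
  }

  NumericVector g(p + 2);
  for (int j = 0; j < p; ++j) {
    const double* xj = X.begin() + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * rs[i];
    g[j] = -s;
  }
  g[p] = -gsv;
  g[p + 1] = -gsu;
  return List::create(_["nll"] = nll, _["gradient"] = g);
}
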