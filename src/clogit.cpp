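// Inner computational kernels of the latent-class conditional logit:
// choice probabilities, and the weighted score / observed-information
// pieces of one conditional-logit class, over a compressed sparse row
// (CSR) effects-coded design matrix. Tasks are contiguous row blocks
// given by taskptr (0-based, length n_tasks + 1).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void softmax_blocks(const std::vector<double>& eta,
                           const IntegerVector& taskptr,
                           std::vector<double>& p,
                           std::vector<double>& logp) {
  int n_tasks = taskptr.size() - 1;
  for (int t = 0; t < n_tasks; ++t) {
    int a = taskptr[t], b = taskptr[t + 1];
    double m = eta[a];
    for (int r = a + 1; r < b; ++r) if (eta[r] > m) m = eta[r];
    double Z = 0.0;
    for (int r = a; r < b; ++r) { p[r] = std::exp(eta[r] - m); Z += p[r]; }
    double lZ = std::log(Z);
    for (int r = a; r < b; ++r) { logp[r] = eta[r] - m - lZ; p[r] /= Z; }
  }
}

static void linpred(const IntegerVector& rowptr, const IntegerVector& colidx,
                    const NumericVector& val, const NumericVector& beta,
                    std::vector<double>& eta) {
  int n_rows = eta.size();
  for (int r = 0; r < n_rows; ++r) {
    double s = 0.0;
    for (int k = rowptr[r]; k < rowptr[r + 1]; ++k)
      s += val[k] * beta[colidx[k]];
    eta[r] = s;
  }
}

// [[Rcpp::export]]
List cpp_task_logprobs(IntegerVector rowptr, IntegerVector colidx,
                       NumericVector val, IntegerVector taskptr,
                       NumericVector beta) {
  int n_rows = rowptr.size() - 1;
  std::vector<double> eta(n_rows), p(n_rows), logp(n_rows);
  linpred(rowptr, colidx, val, beta, eta);
  softmax_blocks(eta, taskptr, p, logp);
  return List::create(_["logp"] = NumericVector(logp.begin(), logp.end()),
                      _["p"] = NumericVector(p.begin(), p.end()));
}

// weighted log-likelihood only (used by the Newton line search);
// wc[r] is the total observation weight that chose row r
// [[Rcpp::export]]
double cpp_clogit_ll(IntegerVector rowptr, IntegerVector colidx,
                     NumericVector val, IntegerVector taskptr,
                     NumericVector wc, NumericVector beta, double ridge) {
  int n_rows = rowptr.size() - 1;
  std::vector<double> eta(n_rows), p(n_rows), logp(n_rows);
  linpred(rowptr, colidx, val, beta, eta);
  softmax_blocks(eta, taskptr, p, logp);
  double ll = 0.0;
  for (int r = 0; r < n_rows; ++r) if (wc[r] != 0.0) ll += wc[r] * logp[r];
  for (int j = 0; j < beta.size(); ++j) ll -= ridge * beta[j] * beta[j];
  return ll;
}

// log-likelihood, gradient and negative Hessian of the weighted
// conditional logit; W_task[t] is the total observation weight on task t
// [[Rcpp::export]]
List cpp_clogit_eval(IntegerVector rowptr, IntegerVector colidx,
                     NumericVector val, int P, IntegerVector taskptr,
                     NumericVector W_task, NumericVector wc,
                     NumericVector beta, double ridge, bool want_hess) {
  int n_rows = rowptr.size() - 1;
  int n_tasks = taskptr.size() - 1;
  std::vector<double> eta(n_rows), p(n_rows), logp(n_rows);
  linpred(rowptr, colidx, val, beta, eta);
  softmax_blocks(eta, taskptr, p, logp);

  double ll = 0.0;
  for (int r = 0; r < n_rows; ++r) if (wc[r] != 0.0) ll += wc[r] * logp[r];
  for (int j = 0; j < P; ++j) ll -= ridge * beta[j] * beta[j];

  NumericVector grad(P);
  NumericMatrix A(want_hess ? P : 1, want_hess ? P : 1);
  std::vector<int> cols; cols.reserve(64);
  std::vector<double> xb; xb.reserve(64);

  for (int t = 0; t < n_tasks; ++t) {
    int a = taskptr[t], b = taskptr[t + 1];
    double Wt = W_task[t];
    cols.clear(); xb.clear();
    for (int r = a; r < b; ++r) {
      double cr = wc[r] - Wt * p[r];
      double wpr = Wt * p[r];
      for (int k = rowptr[r]; k < rowptr[r + 1]; ++k) {
        int ci = colidx[k];
        double vi = val[k];
        grad[ci] += vi * cr;
        if (want_hess) {
          // xbar accumulation on the task's (small) column support
          double pv = p[r] * vi;
          int pos = -1;
          for (size_t q = 0; q < cols.size(); ++q)
            if (cols[q] == ci) { pos = (int) q; break; }
          if (pos < 0) { cols.push_back(ci); xb.push_back(pv); }
          else xb[pos] += pv;
          // sum_r w p_r x_r x_r'
          for (int k2 = rowptr[r]; k2 < rowptr[r + 1]; ++k2)
            A(ci, colidx[k2]) += wpr * vi * val[k2];
        }
      }
    }
    if (want_hess) {
      for (size_t q1 = 0; q1 < cols.size(); ++q1)
        for (size_t q2 = 0; q2 < cols.size(); ++q2)
          A(cols[q1], cols[q2]) -= Wt * xb[q1] * xb[q2];
    }
  }
  for (int j = 0; j < P; ++j) {
    grad[j] -= 2.0 * ridge * beta[j];
    if (want_hess) A(j, j) += 2.0 * ridge;
  }
  return List::create(_["ll"] = ll, _["grad"] = grad, _["neg_hessian"] = A);
}
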