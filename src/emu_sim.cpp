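// Compiled core of the steady-state EMU labeling simulator.
//
// The R side (emu_decompose) turns a network + fragment panel into a cascade
// of size-ordered linear systems encoded as sparse triplets whose values are
// linear in the unidirectional fluxes. This evaluator fills the matrices for
// one flux vector, convolves the source-term MIDs, solves each level densely
// and returns all EMU MIDs in one flat buffer. Called thousands of times per
// fit, so it avoids R-level allocation in the inner loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// y (len ny) <- conv(y, x); result length ny + nx - 1
static void conv_into(std::vector<double> &y, const double *x, int nx) {
  int ny = (int)y.size();
  std::vector<double> out(ny + nx - 1, 0.0);
  for (int i = 0; i < ny; ++i)
    for (int j = 0; j < nx; ++j)
      out[i + j] += y[i] * x[j];
  y.swap(out);
}

// [[Rcpp::export]]
NumericVector emu_eval_cpp(List levels, NumericVector F,
                           NumericVector mids_template,
                           IntegerVector emu_off, IntegerVector emu_len,
                           double clamp) {
  NumericVector buf = clone(mids_template);
  int n_levels = levels.size();
  for (int li = 0; li < n_levels; ++li) {
    List lv = levels[li];
    int L = as<int>(lv["L"]);
    IntegerVector gids = lv["gids"];
    IntegerVector ai = lv["ai"], aj = lv["aj"], af = lv["af"];
    NumericVector ac = lv["ac"];
    IntegerVector bi = lv["bi"], bk = lv["bk"], bf = lv["bf"];
    NumericVector bc = lv["bc"];
    List src_comps = lv["src_comps"];
    int n = gids.size();
    int nsrc = src_comps.size();
    int w = L + 1;

    arma::mat A(n, n, arma::fill::zeros);
    for (int t = 0; t < ai.size(); ++t)
      A(ai[t], aj[t]) += ac[t] * F[af[t]];
    // singular-system guard: a zero diagonal means no flux reaches this EMU
    for (int i = 0; i < n; ++i) {
      if (std::fabs(A(i, i)) < clamp) {
        CharacterVector keys = lv["keys"];
        stop("EMU level %d singular: no flux through EMU '%s'", L,
             std::string(keys[i]).c_str());
      }
    }

    arma::mat Y(nsrc, w, arma::fill::zeros);
    for (int k = 0; k < nsrc; ++k) {
      IntegerVector comps = src_comps[k];
      std::vector<double> y(1, 1.0);
      for (int c = 0; c < comps.size(); ++c) {
        int g = comps[c];
        conv_into(y, &buf[emu_off[g]], emu_len[g]);
      }
      if ((int)y.size() != w)
        stop("EMU source term size mismatch at level %d", L);
      for (int j = 0; j < w; ++j) Y(k, j) = y[j];
    }

    arma::mat B(n, nsrc, arma::fill::zeros);
    for (int t = 0; t < bi.size(); ++t)
      B(bi[t], bk[t]) += bc[t] * F[bf[t]];

    arma::mat RHS = -(B * Y);
    arma::mat X;
    bool ok = arma::solve(X, A, RHS, arma::solve_opts::no_approx);
    if (!ok) stop("EMU level %d solve failed (singular system)", L);

    for (int i = 0; i < n; ++i) {
      int g = gids[i];
      double s = 0.0;
      for (int j = 0; j < w; ++j) s += X(i, j);
      // renormalize tiny drift; guard against pathological rows
      if (s <= 0) stop("EMU level %d produced a non-positive MID", L);
      for (int j = 0; j < w; ++j) buf[emu_off[g] + j] = X(i, j) / s;
    }
  }
  return buf;
}
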