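// Computational kernels: Gaussian-overlap pRF predictions (with analytic
// derivatives), the generative attend-stimulus neural signal, and the
// gain-field position prediction used both standalone and inside the
// 50 x 50 grid fit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Generative neural signal for an attend-bar condition: for each unique bar
// frame f the effective pRF is the pointwise product of the stimulus-drive
// profile g with the AF-smoothed frame S(,f), scaled to a maximum of 1; the
// neural response is the sum of the effective pRF over the pixels of the
// binary frame mask.
// [[Rcpp::export]]
arma::vec cpp_neural_attend(const arma::sp_mat& masks_t, const arma::mat& S,
                            const arma::vec& g) {
  const arma::uword F = S.n_cols, N = S.n_rows;
  arma::vec out(F, arma::fill::zeros);
  for (arma::uword f = 0; f < F; ++f) {
    const double* sc = S.colptr(f);
    double m = 0.0;
    for (arma::uword i = 0; i < N; ++i) {
      const double v = g[i] * sc[i];
      if (v > m) m = v;
    }
    if (m <= 0.0) continue;
    double acc = 0.0;
    for (arma::sp_mat::const_col_iterator it = masks_t.begin_col(f);
         it != masks_t.end_col(f); ++it)
      acc += (*it) * g[it.row()] * sc[it.row()];
    out[f] = acc / m;
  }
  return out;
}

// One gain-field position prediction: normalized products of the SD profile
// with each smoothed bar frame, averaged with frame weights, argmax on the
// pixel grid. Returns false when every product is identically zero.
static bool predict_one(const arma::mat& S, const arma::vec& wts,
                        const arma::vec& gx, const arma::vec& gy,
                        double x0, double y0, double sigma,
                        double& px, double& py) {
  const arma::uword N = S.n_rows, F = S.n_cols;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  arma::vec g(N);
  for (arma::uword i = 0; i < N; ++i) {
    const double dx = gx[i] - x0, dy = gy[i] - y0;
    g[i] = std::exp(-(dx * dx + dy * dy) * inv2s2);
  }
  arma::vec wv(F);
  bool any = false;
  const double* gp = g.memptr();
  for (arma::uword f = 0; f < F; ++f) {
    const double* sc = S.colptr(f);
    double m0 = 0.0, m1 = 0.0, m2 = 0.0, m3 = 0.0;
    arma::uword i = 0;
    for (; i + 4 <= N; i += 4) {
      m0 = std::max(m0, gp[i] * sc[i]);
      m1 = std::max(m1, gp[i + 1] * sc[i + 1]);
      m2 = std::max(m2, gp[i + 2] * sc[i + 2]);
      m3 = std::max(m3, gp[i + 3] * sc[i + 3]);
    }
    double m = std::max(std::max(m0, m1), std::max(m2, m3));
    for (; i < N; ++i) m = std::max(m, gp[i] * sc[i]);
    if (m > 0.0) { wv[f] = wts[f] / m; any = true; } else wv[f] = 0.0;
  }
  if (!any) return false;
  arma::vec u = S * wv;
  arma::vec A = g % u;
  const arma::uword best = A.index_max();
  px = gx[best];
  py = gy[best];
  return true;
}

// Time-averaged normalized product profile of one stimulus-drive Gaussian
// with an AF-smoothed frame stack: the model's "smeared" effective pRF,
// whose argmax is the predicted attend-stimulus position. Scaled to a
// maximum of 1. Returns all zeros when every product is zero.
// [[Rcpp::export]]
arma::vec cpp_avg_profile(const arma::mat& S, const arma::vec& wts,
                          const arma::vec& gx, const arma::vec& gy,
                          double x0, double y0, double sigma) {
  const arma::uword N = S.n_rows, F = S.n_cols;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  arma::vec g(N);
  for (arma::uword i = 0; i < N; ++i) {
    const double dx = gx[i] - x0, dy = gy[i] - y0;
    g[i] = std::exp(-(dx * dx + dy * dy) * inv2s2);
  }
  arma::vec wv(F, arma::fill::zeros);
  bool any = false;
  for (arma::uword f = 0; f < F; ++f) {
    const double* sc = S.colptr(f);
    double m = 0.0;
    for (arma::uword i = 0; i < N; ++i) {
      const double v = g[i] * sc[i];
      if (v > m) m = v;
    }
    if (m > 0.0) { wv[f] = wts[f] / m; any = true; }
  }
  if (!any) return arma::vec(N, arma::fill::zeros);
  arma::vec A = g % (S * wv);
  return A / A.max();
}

// Predicted attend-stimulus positions for a set of stimulus-drive Gaussians
// against one AF-smoothed frame stack. Rows with all-zero products return
// NaN coordinates.
// [[Rcpp::export]]
arma::mat cpp_predict_positions(const arma::mat& S, const arma::vec& wts,
                                const arma::vec& gx, const arma::vec& gy,
                                const arma::vec& sd_x, const arma::vec& sd_y,
                                const arma::vec& sd_sigma) {
  const arma::uword M = sd_x.n_elem;
  arma::mat out(M, 2);
  out.fill(arma::datum::nan);
  for (arma::uword m = 0; m < M; ++m) {
    double px, py;
    if (predict_one(S, wts, gx, gy, sd_x[m], sd_y[m], sd_sigma[m], px, py)) {
      out(m, 0) = px;
      out(m, 1) = py;
    }
  }
  return out;
}

// Per-voxel variant of the gain-field objective: derive the SD and predict
// the attend-stimulus position for every voxel, aggregate predictions into
// the same weighted visual-field bins as the measured end positions, and
// sum squared distances between binned predicted and binned measured
// positions. bin_id is 0-based; obs_x/obs_y hold the measured bin means.
// [[Rcpp::export]]
arma::mat cpp_af_objective_binned(const arma::mat& S, const arma::vec& wts,
                                  const arma::vec& gx, const arma::vec& gy,
                                  const arma::vec& sigma_fix,
                                  const arma::vec& start_x,
                                  const arma::vec& start_y,
                                  const arma::vec& start_sigma,
                                  const arma::vec& w,
                                  const arma::ivec& bin_id,
                                  const arma::vec& obs_x,
                                  const arma::vec& obs_y) {
  const arma::uword nf = sigma_fix.n_elem, nv = start_x.n_elem,
    nb = obs_x.n_elem;
  arma::mat out(nf, 2, arma::fill::zeros);
  for (arma::uword a = 0; a < nf; ++a) {
    const double sf = sigma_fix[a];
    arma::vec bx(nb, arma::fill::zeros), by(nb, arma::fill::zeros),
      bw(nb, arma::fill::zeros);
    arma::uword used = 0;
    for (arma::uword v = 0; v < nv; ++v) {
      const double sm = start_sigma[v];
      if (!(sm < sf)) continue;
      const double s2 = sm * sm * sf * sf / (sf * sf - sm * sm);
      const double scale = (sf * sf + s2) / (sf * sf);
      double px, py;
      if (!predict_one(S, wts, gx, gy, start_x[v] * scale,
                       start_y[v] * scale, std::sqrt(s2), px, py))
        continue;
      const arma::uword b = bin_id[v];
      bx[b] += w[v] * px;
      by[b] += w[v] * py;
      bw[b] += w[v];
      ++used;
    }
    double obj = 0.0;
    for (arma::uword b = 0; b < nb; ++b) {
      if (bw[b] <= 0.0) continue;
      const double dx = bx[b] / bw[b] - obs_x[b];
      const double dy = by[b] / bw[b] - obs_y[b];
      obj += dx * dx + dy * dy;
    }
    out(a, 0) = (used > 0) ? obj : arma::datum::inf;
    out(a, 1) = used;
  }
  return out;
}

// Gain-field objective for one stimulus-AF kernel (one smoothed frame
// stack) across all fixation-AF sizes: for each sigma_fix, derive the SD of
// every binned vector by Gaussian division of its measured Attend Fixation
// pRF, predict the attend-stimulus position, and sum squared distances to
// the measured end positions. Vectors whose measured size is not smaller
// than sigma_fix are non-invertible and excluded.
// [[Rcpp::export]]
arma::mat cpp_af_objective(const arma::mat& S, const arma::vec& wts,
                           const arma::vec& gx, const arma::vec& gy,
                           const arma::vec& sigma_fix,
                           const arma::vec& start_x, const arma::vec& start_y,
                           const arma::vec& start_sigma,
                           const arma::vec& end_x, const arma::vec& end_y) {
  const arma::uword nf = sigma_fix.n_elem, nv = start_x.n_elem;
  arma::mat out(nf, 2, arma::fill::zeros);
  for (arma::uword a = 0; a < nf; ++a) {
    const double sf = sigma_fix[a];
    double obj = 0.0;
    arma::uword used = 0;
    for (arma::uword v = 0; v < nv; ++v) {
      const double sm = start_sigma[v];
      if (!(sm < sf)) continue;
      const double s2 = sm * sm * sf * sf / (sf * sf - sm * sm);
      const double scale = (sf * sf + s2) / (sf * sf);
      double px, py;
      if (!predict_one(S, wts, gx, gy, start_x[v] * scale, start_y[v] * scale,
                       std::sqrt(s2), px, py))
        continue;
      const double dx = px - end_x[v], dy = py - end_y[v];
      obj += dx * dx + dy * dy;
      ++used;
    }
    out(a, 0) = (used > 0) ? obj : arma::datum::inf;
    out(a, 1) = used;
  }
  return out;
}
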