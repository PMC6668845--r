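// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// All randomness goes through R's RNG so that set.seed() controls every draw
// and the R reference implementations can reproduce the exact stream.

static vec runif_vec(int n, double lo, double hi) {
  vec out(n);
  for (int i = 0; i < n; ++i) out[i] = R::runif(lo, hi);
  return out;
}

// Place-field projection of a set of points: rows = points, cols = cells.
// f_k(s) = exp(-||s - c_k||^2 / w)
// [[Rcpp::export]]
arma::mat cpp_encode(const arma::mat& pts, const arma::mat& centers, double w) {
  const int n = pts.n_rows, K = centers.n_rows;
  mat out(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) {
      double dx = pts(i, 0) - centers(k, 0), dy = pts(i, 1) - centers(k, 1);
      out(i, k) = std::exp(-(dx * dx + dy * dy) / w);
    }
  return out;
}

// One pass of online delta-rule training over an episode of snippets.
// patterns: list of K x s_j matrices (snippet activation slices, already in
// replay order). State is reset to U[-reset_amp, reset_amp] before each
// snippet; the readout weight matrix is updated every `b` steps with the
// batch-mean descent step, flushing the remainder at the snippet boundary.
// Returns the trained readout and the per-snippet mean squared error.
// [[Rcpp::export]]
Rcpp::List cpp_train_on_episode(const arma::mat& w_ffwd, const arma::mat& w_rec,
                                arma::mat w_ro, const Rcpp::List& patterns,
                                double h, double theta_res, double theta_ro,
                                double alpha, int b, double reset_amp) {
  const int N = w_ffwd.n_rows, K = w_ro.n_rows;
  const int n_snip = patterns.size();
  vec losses(n_snip, fill::value(datum::nan));
  for (int j = 0; j < n_snip; ++j) {
    mat Xin = Rcpp::as<mat>(patterns[j]);  // K x s
    int s = Xin.n_cols;
    if (s < 2) continue;  // no next-step target available
    vec P = runif_vec(N, -reset_amp, reset_amp);
    vec X = tanh(P);
    mat Uf = w_ffwd * Xin;
    mat Xb(N, s - 1);
    mat E(K, s - 1);
    double sse = 0.0;
    int nb = 0;
    for (int i = 0; i + 1 < s; ++i) {
      vec U = Uf.col(i) + w_rec * X;
      P = h * U + (1.0 - h) * P;
      X = tanh(P - theta_res);
      vec Xro = tanh(w_ro * X - theta_ro);
      vec err = Xro - Xin.col(i + 1);
      sse += dot(err, err);
      Xb.col(nb) = X;
      E.col(nb) = err % (1.0 - square(Xro));
      ++nb;
      if (nb == b) {
        w_ro -= (alpha / nb) * E.cols(0, nb - 1) * Xb.cols(0, nb - 1).t();
        nb = 0;
      }
    }
    if (nb > 0)
      w_ro -= (alpha / nb) * E.cols(0, nb - 1) * Xb.cols(0, nb - 1).t();
    losses[j] = sse / ((s - 1) * K);
  }
  return Rcpp::List::create(Rcpp::Named("w_ro") = w_ro,
                            Rcpp::Named("loss") = losses);
}

// Teacher-forced drive: feed a K x T input sequence from an initial membrane
// potential, return the reservoir state and readout traces (no learning).
// [[Rcpp::export]]
Rcpp::List cpp_drive(const arma::mat& w_ffwd, const arma::mat& w_rec,
                     const arma::mat& w_ro, const arma::mat& inputs,
                     double h, double theta_res, double theta_ro,
                     const arma::vec& p0) {
  const int N = w_ffwd.n_rows, T = inputs.n_cols;
  vec P = p0;
  vec X = tanh(P - theta_res);
  mat Xres(N, T), Xro(w_ro.n_rows, T);
  for (int i = 0; i < T; ++i) {
    vec U = w_ffwd * inputs.col(i) + w_rec * X;
    P = h * U + (1.0 - h) * P;
    X = tanh(P - theta_res);
    Xres.col(i) = X;
    Xro.col(i) = tanh(w_ro * X - theta_ro);
  }
  return Rcpp::List::create(Rcpp::Named("x_res") = Xres,
                            Rcpp::Named("x_ro") = Xro,
                            Rcpp::Named("p_res") = P);
}

// Closed-loop (autonomous) generation. The reservoir is teacher-forced with
// the priming points, then the readout prediction is decoded to the most
// probable reachable location by the spatial filter and re-encoded as the
// next input. Candidate set: polar lattice of n_r radii x n_a angles within
// +/- cone of the current heading (full circle while heading is undefined).
// A per-candidate U(0, noise_m) score perturbation matches the R reference
// draw-for-draw (single runif stream, radius index varying fastest).
// [[Rcpp::export]]
arma::mat cpp_autonomous(const arma::mat& w_ffwd, const arma::mat& w_rec,
                         const arma::mat& w_ro, const arma::mat& centers,
                         double w_field, const arma::mat& prime_pts,
                         int n_steps, double h, double theta_res,
                         double theta_ro, double reset_amp, double max_step,
                         double cone, int n_r, int n_a, double noise_m) {
  const int N = w_ffwd.n_rows, K = centers.n_rows;
  const int np = prime_pts.n_rows;
  vec P = runif_vec(N, -reset_amp, reset_amp);
  vec X = tanh(P - theta_res);
  mat out(np + n_steps, 2);
  out.rows(0, np - 1) = prime_pts;
  mat prime_in = cpp_encode(prime_pts, centers, w_field);  // np x K
  for (int i = 0; i < np; ++i) {
    vec U = w_ffwd * prime_in.row(i).t() + w_rec * X;
    P = h * U + (1.0 - h) * P;
    X = tanh(P - theta_res);
  }
  double cx = prime_pts(np - 1, 0), cy = prime_pts(np - 1, 1);
  bool have_heading = false;
  double heading = 0.0;
  if (np >= 2) {
    double dx = cx - prime_pts(np - 2, 0), dy = cy - prime_pts(np - 2, 1);
    if (dx != 0.0 || dy != 0.0) { heading = std::atan2(dy, dx); have_heading = true; }
  }
  for (int t = 0; t < n_steps; ++t) {
    vec eta = tanh(w_ro * X - theta_ro);
    // spatial filter: current location first, then the polar lattice
    double best = -datum::inf;
    double bx = cx, by = cy;
    {
      double sse = 0.0;
      for (int k = 0; k < K; ++k) {
        double dx = cx - centers(k, 0), dy = cy - centers(k, 1);
        double f = std::exp(-(dx * dx + dy * dy) / w_field);
        double d = f - eta[k];
        sse += d * d;
      }
      best = -sse / K;
      if (noise_m > 0) best += R::runif(0.0, noise_m);
    }
    for (int a = 0; a < n_a; ++a) {
      double ang = have_heading
        ? heading - cone + 2.0 * cone * a / (n_a - 1)
        : -datum::pi + 2.0 * datum::pi * a / (n_a - 1);
      for (int r = 0; r < n_r; ++r) {
        double rad = max_step * (r + 1.0) / n_r;
        double qx = cx + rad * std::cos(ang), qy = cy + rad * std::sin(ang);
        double sse = 0.0;
        for (int k = 0; k < K; ++k) {
          double dx = qx - centers(k, 0), dy = qy - centers(k, 1);
          double f = std::exp(-(dx * dx + dy * dy) / w_field);
          double d = f - eta[k];
          sse += d * d;
        }
        double sc = -sse / K;
        if (noise_m > 0) sc += R::runif(0.0, noise_m);
        if (sc > best) { best = sc; bx = qx; by = qy; }
      }
    }
    if (bx != cx || by != cy) { heading = std::atan2(by - cy, bx - cx); have_heading = true; }
    cx = bx; cy = by;
    out(np + t, 0) = cx;
    out(np + t, 1) = cy;
    // re-encode the reached location and advance the reservoir
    rowvec pt(2); pt[0] = cx; pt[1] = cy;
    mat xin = cpp_encode(pt, centers, w_field);
    vec U = w_ffwd * xin.row(0).t() + w_rec * X;
    P = h * U + (1.0 - h) * P;
    X = tanh(P - theta_res);
  }
  return out;
}

// Discrete Frechet distance between polygonal curves (Eiter-Mannila coupling
// recursion), O(m n) dynamic programme on the pairwise Euclidean distances.
// [[Rcpp::export]]
double cpp_frechet(const arma::mat& A, const arma::mat& B) {
  const int m = A.n_rows, n = B.n_rows;
  mat ca(m, n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      double prev;
      if (i == 0 && j == 0) prev = -datum::inf;
      else if (i == 0) prev = ca(0, j - 1);
      else if (j == 0) prev = ca(i - 1, 0);
      else prev = std::min(ca(i - 1, j), std::min(ca(i - 1, j - 1), ca(i, j - 1)));
      ca(i, j) = std::max(d, prev);
    }
  }
  return ca(m - 1, n - 1);
}
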