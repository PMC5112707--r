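#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Bilinear sample with edge clamping; coordinates are 0-based doubles.
static inline double bilin(const NumericMatrix& img, double r, double c) {
  const int H = img.nrow(), W = img.ncol();
  if (r < 0) r = 0; else if (r > H - 1) r = H - 1;
  if (c < 0) c = 0; else if (c > W - 1) c = W - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < H ? r0 + 1 : r0;
  int c1 = c0 + 1 < W ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
         fr       * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
}

// Oriented line-operator response at a single scale.
//
// For each pixel and each of n_orient evenly spaced angles in [0, 180),
// the response is (mean of the len x len square neighbourhood, clipped at
// the image border) minus (mean of len points spaced 1 px along the rotated
// line through the pixel, bilinearly interpolated). Dark lines on a light
// background therefore give positive strength. S = max over angles,
// O = argmax angle in degrees, ties broken toward the smallest angle.
// Angles are measured counterclockwise from the +column axis with rows
// increasing downward, i.e. 90 degrees is an image-vertical line.
// [[Rcpp::export(name = ".line_response_cpp")]]
List line_response_cpp(NumericMatrix img, int n_orient, int len) {
  const int H = img.nrow(), W = img.ncol();
  if (len < 3 || len % 2 == 0) stop("template_length must be odd and >= 3");
  if (n_orient < 2) stop("n_orientations must be >= 2");
  if (H < len || W < len) stop("image smaller than line template");
  const int h = (len - 1) / 2;

  // summed-area table for clipped box means
  std::vector<double> sat((H + 1) * (W + 1), 0.0);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      sat[(r + 1) * (W + 1) + (c + 1)] = img(r, c) +
        sat[r * (W + 1) + (c + 1)] + sat[(r + 1) * (W + 1) + c] -
        sat[r * (W + 1) + c];

  NumericMatrix S(H, W), O(H, W);
  std::fill(S.begin(), S.end(), R_NegInf);

  std::vector<double> boxmean(H * W);
  for (int r = 0; r < H; ++r) {
    int r0 = std::max(0, r - h), r1 = std::min(H - 1, r + h);
    for (int c = 0; c < W; ++c) {
      int c0 = std::max(0, c - h), c1 = std::min(W - 1, c + h);
      double s = sat[(r1 + 1) * (W + 1) + (c1 + 1)] - sat[r0 * (W + 1) + (c1 + 1)] -
                 sat[(r1 + 1) * (W + 1) + c0] + sat[r0 * (W + 1) + c0];
      boxmean[r * W + c] = s / ((r1 - r0 + 1) * (c1 - c0 + 1));
    }
  }

  for (int k = 0; k < n_orient; ++k) {
    double theta = M_PI * k / n_orient;
    // direction of the line: +col = cos, -row = sin (y up convention)
    double dr = -std::sin(theta), dc = std::cos(theta);
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        double acc = 0.0;
        for (int j = -h; j <= h; ++j)
          acc += bilin(img, r + j * dr, c + j * dc);
        double resp = boxmean[r * W + c] - acc / len;
        if (resp > S(r, c)) {           // strict: ties stay at smallest angle
          S(r, c) = resp;
          O(r, c) = 180.0 * k / n_orient;
        }
      }
    }
  }
  return List::create(_["strength"] = S, _["orientation"] = O);
}

// Exact shortest path on a masked 8-connected pixel grid (Dijkstra).
// Step cost = step_length * (eps(u) + eps(v)) / 2, step_length 1 axial,
// sqrt(2) diagonal. start/goal are 1-based (row, col). Returns the path
// from start to goal and its total cost.
// [[Rcpp::export(name = ".grid_dijkstra_cpp")]]
List grid_dijkstra_cpp(NumericMatrix eps, LogicalMatrix mask,
                       int sr, int sc, int tr, int tc) {
  const int H = eps.nrow(), W = eps.ncol();
  if (mask.nrow() != H || mask.ncol() != W) stop("eps and mask shapes differ");
  --sr; --sc; --tr; --tc;
  if (sr < 0 || sr >= H || sc < 0 || sc >= W) stop("start outside image");
  if (tr < 0 || tr >= H || tc < 0 || tc >= W) stop("goal outside image");
  if (!mask(sr, sc)) stop("start pixel not inside mask");
  if (!mask(tr, tc)) stop("goal pixel not inside mask");

  const int n = H * W;
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::vector<int> parent(n, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  const int s = sr * W + sc, t = tr * W + tc;
  dist[s] = 0.0;
  pq.push(QE(0.0, s));
  const int dR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sq2 = std::sqrt(2.0);

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    if (u == t) break;
    int ur = u / W, uc = u % W;
    for (int m = 0; m < 8; ++m) {
      int vr = ur + dR[m], vc = uc + dC[m];
      if (vr < 0 || vr >= H || vc < 0 || vc >= W) continue;
      if (!mask(vr, vc)) continue;
      double step = (dR[m] != 0 && dC[m] != 0) ? sq2 : 1.0;
      double w = step * 0.5 * (eps(ur, uc) + eps(vr, vc));
      int v = vr * W + vc;
      double nd = dist[u] + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        parent[v] = u;
        pq.push(QE(nd, v));
      }
    }
  }
  if (!std::isfinite(dist[t]))
    stop("goal unreachable within mask (mask disconnected?)");

  std::vector<int> rev;
  for (int v = t; v != -1; v = parent[v]) rev.push_back(v);
  const int L = rev.size();
  IntegerVector prow(L), pcol(L);
  for (int i = 0; i < L; ++i) {
    int v = rev[L - 1 - i];
    prow[i] = v / W + 1;
    pcol[i] = v % W + 1;
  }
  return List::create(_["row"] = prow, _["col"] = pcol, _["cost"] = dist[t]);
}

// Connected-component labelling (4- or 8-connectivity) of a logical raster.
// Labels are assigned in raster-scan order starting at 1; 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix m, int connectivity) {
  const int H = m.nrow(), W = m.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  const int d4R[4] = {-1, 0, 0, 1}, d4C[4] = {0, -1, 1, 0};
  const int d8R[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int d8C[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int *dR = connectivity == 4 ? d4R : d8R;
  const int *dC = connectivity == 4 ? d4C : d8C;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!m(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r * W + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        int ur = u / W, uc = u % W;
        for (int k = 0; k < connectivity; ++k) {
          int vr = ur + dR[k], vc = uc + dC[k];
          if (vr < 0 || vr >= H || vc < 0 || vc >= W) continue;
          if (m(vr, vc) && !lab(vr, vc)) {
            lab(vr, vc) = next;
            stack.push_back(vr * W + vc);
          }
        }
      }
    }
  }
  return lab;
}

// Linear soft-margin SVM via deterministic dual coordinate descent
// (L1 hinge loss). X already carries the bias column; y in {-1, +1}.
// Cyclic sweeps, no random permutation, so results are bit-reproducible.
// Returns the primal weight vector w (length ncol(X)).
// [[Rcpp::export(name = ".svm_dcd_cpp")]]
NumericVector svm_dcd_cpp(NumericMatrix X, NumericVector y, double C,
                          double tol, int max_epochs) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  std::vector<double> alpha(n, 0.0), w(d, 0.0), Qii(n);
  for (int i = 0; i < n; ++i) {
    double q = 0;
    for (int j = 0; j < d; ++j) q += X(i, j) * X(i, j);
    Qii[i] = q;
  }
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (Qii[i] <= 0) continue;
      double G = 0;
      for (int j = 0; j < d; ++j) G += w[j] * X(i, j);
      G = y[i] * G - 1.0;
      double PG = G;
      if (alpha[i] <= 0)      PG = std::min(G, 0.0);
      else if (alpha[i] >= C) PG = std::max(G, 0.0);
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - G / Qii[i], 0.0), C);
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0)
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
      }
    }
    if (max_pg < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
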