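// Mixed-scale dense network (width-1 hidden layers, cycling dilations,
// dense connectivity, linear 1x1 output) with hand-written backprop.
// Double precision, single threaded: bit-reproducible given the weights.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// out(y,x) += sum_{a,b in {-1,0,1}} w[3(a+1)+(b+1)] * in(y+a*d, x+b*d),
// zero padding outside the image. Hand-rolled column-major pointer loops:
// each tap is a contiguous axpy per column, which the compiler vectorises.
static void conv_add(const mat& in, mat& out, const double* w, const int d) {
  const int H = in.n_rows, W = in.n_cols;
  for (int a = -1; a <= 1; ++a) {
    for (int b = -1; b <= 1; ++b) {
      const double wv = w[3 * (a + 1) + (b + 1)];
      const int dy = a * d, dx = b * d;
      const int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
      const int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
      if (r0 > r1 || c0 > c1) continue;
      const int len = r1 - r0 + 1;
      for (int x = c0; x <= c1; ++x) {
        double* po = out.colptr(x) + r0;
        const double* pi = in.colptr(x + dx) + r0 + dy;
        for (int i = 0; i < len; ++i) po[i] += wv * pi[i];
      }
    }
  }
}

// Adjoint of conv_add: din(y+a*d, x+b*d) += w * dout(y,x).
static void conv_back(mat& din, const mat& dout, const double* w, const int d) {
  const int H = din.n_rows, W = din.n_cols;
  for (int a = -1; a <= 1; ++a) {
    for (int b = -1; b <= 1; ++b) {
      const double wv = w[3 * (a + 1) + (b + 1)];
      const int dy = a * d, dx = b * d;
      const int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
      const int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
      if (r0 > r1 || c0 > c1) continue;
      const int len = r1 - r0 + 1;
      for (int x = c0; x <= c1; ++x) {
        double* po = din.colptr(x + dx) + r0 + dy;
        const double* pi = dout.colptr(x) + r0;
        for (int i = 0; i < len; ++i) po[i] += wv * pi[i];
      }
    }
  }
}

// gw[3(a+1)+(b+1)] += sum_{y,x} dout(y,x) * in(y+a*d, x+b*d).
static void conv_grad(const mat& in, const mat& dout, double* gw, const int d) {
  const int H = in.n_rows, W = in.n_cols;
  for (int a = -1; a <= 1; ++a) {
    for (int b = -1; b <= 1; ++b) {
      const int dy = a * d, dx = b * d;
      const int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
      const int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
      if (r0 > r1 || c0 > c1) continue;
      const int len = r1 - r0 + 1;
      double acc = 0.0;
      for (int x = c0; x <= c1; ++x) {
        const double* po = dout.colptr(x) + r0;
        const double* pi = in.colptr(x + dx) + r0 + dy;
        for (int i = 0; i < len; ++i) acc += po[i] * pi[i];
      }
      gw[3 * (a + 1) + (b + 1)] += acc;
    }
  }
}

// Forward pass shared by prediction and training. Fills `maps` with the
// input channels followed by the activated hidden feature maps; returns the
// linear 1x1 output. Weight layout: per hidden layer i (0-based), 9 weights
// for each of the (C0+i) incoming maps then one bias; then C0+depth output
// weights and one output bias.
static mat msd_forward_impl(const vec& w, const cube& input,
                            const ivec& dil, cube& maps) {
  const int H = input.n_rows, W = input.n_cols, C0 = input.n_slices;
  const int depth = dil.n_elem;
  maps.set_size(H, W, C0 + depth);
  for (int j = 0; j < C0; ++j) maps.slice(j) = input.slice(j);
  const double* wp = w.memptr();
  size_t p = 0;
  mat z(H, W);
  for (int li = 0; li < depth; ++li) {
    const int nin = C0 + li;
    z.zeros();
    for (int j = 0; j < nin; ++j) {
      conv_add(maps.slice(j), z, wp + p, dil[li]);
      p += 9;
    }
    z += wp[p];  // bias
    ++p;
    z.for_each([](double& v) { if (v < 0.0) v = 0.0; });  // ReLU
    maps.slice(C0 + li) = z;
  }
  const int nmaps = C0 + depth;
  mat y(H, W);
  y.fill(wp[p + nmaps]);  // output bias
  for (int j = 0; j < nmaps; ++j) y += wp[p + j] * maps.slice(j);
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_msd_forward(const arma::vec& w, const arma::cube& input,
                          const arma::ivec& dilations) {
  cube maps;
  return msd_forward_impl(w, input, dilations, maps);
}

// MSE loss, full gradient, and the prediction for one (input, target) pair.
// [[Rcpp::export]]
Rcpp::List cpp_msd_grad(const arma::vec& w, const arma::cube& input,
                        const arma::mat& target, const arma::ivec& dilations) {
  const int H = input.n_rows, W = input.n_cols, C0 = input.n_slices;
  const int depth = dilations.n_elem;
  const int nmaps = C0 + depth;
  cube maps;
  mat y = msd_forward_impl(w, input, dilations, maps);

  const double npix = static_cast<double>(H) * W;
  mat dy = y - target;
  const double loss = accu(square(dy)) / npix;
  dy *= 2.0 / npix;

  vec g(w.n_elem, fill::zeros);
  // layer weight offsets
  std::vector<size_t> off(depth + 1);
  size_t p = 0;
  for (int li = 0; li < depth; ++li) {
    off[li] = p;
    p += 9 * static_cast<size_t>(C0 + li) + 1;
  }
  off[depth] = p;  // start of output layer block
  const size_t pout = p;

  // output layer
  for (int j = 0; j < nmaps; ++j) g[pout + j] = accu(dy % maps.slice(j));
  g[pout + nmaps] = accu(dy);

  // backpropagated gradient wrt every feature map
  cube delta(H, W, nmaps);
  for (int j = 0; j < nmaps; ++j) delta.slice(j) = w[pout + j] * dy;

  for (int li = depth - 1; li >= 0; --li) {
    const int m = C0 + li;
    const int nin = C0 + li;
    // ReLU derivative: activated map is > 0 exactly where z was > 0
    mat dz = delta.slice(m);
    const mat& act = maps.slice(m);
    dz.elem(find(act == 0.0)).zeros();
    g[off[li] + 9 * static_cast<size_t>(nin)] = accu(dz);  // bias
    for (int j = 0; j < nin; ++j) {
      const size_t pw = off[li] + 9 * static_cast<size_t>(j);
      conv_grad(maps.slice(j), dz, g.memptr() + pw, dilations[li]);
      conv_back(delta.slice(j), dz, w.memptr() + pw, dilations[li]);
    }
  }

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = g,
                            Rcpp::Named("pred") = y);
}
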