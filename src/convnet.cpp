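// Minimal 3D convolutional network engine: conv blocks (3x3x3 kernels,
// zero padding, ReLU, 2x max pooling), global average pooling to M predictor
// variables, fully connected classifier with sigmoid output. Supports
// end-to-end training gradients and input gradients with a predictor mask
// (stop-gradient on excluded predictors) for confounder-free saliency.
//
// Feature maps are stored as (nvox x channels) matrices, voxel index
// v = i + n*(j + n*k) (x fastest), matching R's column-major array layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Leaky rectifier: keeps a small gradient on the closed side so units cannot
// die irrecoverably during the aggressive early phase of Adam.
static const double LEAK = 0.01;

static mat leaky(const mat& Z) {
  mat A = Z;
  A.for_each([](double& v) { if (v < 0) v *= LEAK; });
  return A;
}

// elementwise gate d(leaky)/dz from the pre-activation
static mat leaky_gate(const mat& Z) {
  mat G = conv_to<mat>::from(Z > 0);
  G = G * (1.0 - LEAK) + LEAK;
  return G;
}

// out(i,j,k,:) = X(i+dx, j+dy, k+dz, :), zero outside the grid
static mat shift3d(const mat& X, int n, int dx, int dy, int dz) {
  mat out(X.n_rows, X.n_cols, fill::zeros);
  int i0 = std::max(0, -dx), i1 = std::min(n, n - dx);
  int j0 = std::max(0, -dy), j1 = std::min(n, n - dy);
  int k0 = std::max(0, -dz), k1 = std::min(n, n - dz);
  if (i0 >= i1 || j0 >= j1 || k0 >= k1) return out;
  for (int k = k0; k < k1; ++k)
    for (int j = j0; j < j1; ++j) {
      int dst = i0 + n * (j + n * k);
      int src = (i0 + dx) + n * ((j + dy) + n * (k + dz));
      out.rows(dst, dst + (i1 - i0) - 1) =
        X.rows(src, src + (i1 - i0) - 1);
    }
  return out;
}

static mat conv3_fwd(const mat& X, int n, const mat& W, const rowvec& b) {
  int Cin = X.n_cols;
  mat out(X.n_rows, W.n_cols);
  out.each_row() = b;
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o)
        out += shift3d(X, n, dx, dy, dz) * W.rows(o * Cin, (o + 1) * Cin - 1);
  return out;
}

// accumulates dW, db; returns gradient w.r.t. the block input if wanted
static mat conv3_bwd(const mat& G, const mat& Xin, int n, const mat& W,
                     mat& dW, rowvec& db, bool want_input) {
  int Cin = Xin.n_cols;
  db += sum(G, 0);
  mat Gin;
  if (want_input) Gin.zeros(Xin.n_rows, Cin);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        mat Xs = shift3d(Xin, n, dx, dy, dz);
        dW.rows(o * Cin, (o + 1) * Cin - 1) += Xs.t() * G;
        if (want_input)
          Gin += shift3d(G * W.rows(o * Cin, (o + 1) * Cin - 1).t(),
                         n, -dx, -dy, -dz);
      }
  return Gin;
}

static void maxpool(const mat& X, int n, mat& out, umat& idx) {
  int m = n / 2, C = X.n_cols;
  out.set_size((uword)m * m * m, C);
  idx.set_size((uword)m * m * m, C);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < m; ++k)
      for (int j = 0; j < m; ++j)
        for (int i = 0; i < m; ++i) {
          double best = -datum::inf;
          uword bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                uword v = (2 * i + dx) + (uword)n * ((2 * j + dy) +
                          (uword)n * (2 * k + dz));
                if (X(v, c) > best) { best = X(v, c); bi = v; }
              }
          uword ov = i + (uword)m * (j + (uword)m * k);
          out(ov, c) = best;
          idx(ov, c) = bi;
        }
}

static mat unpool(const mat& G, const umat& idx, int n) {
  mat out((uword)n * n * n, G.n_cols, fill::zeros);
  for (uword c = 0; c < G.n_cols; ++c)
    for (uword v = 0; v < G.n_rows; ++v)
      out(idx(v, c), c) += G(v, c);
  return out;
}

struct Params {
  std::vector<mat> convW;
  std::vector<rowvec> convb;
  std::vector<mat> fcW;
  std::vector<rowvec> fcb;
};

static Params unpack(const Rcpp::List& convW, const Rcpp::List& convb,
                     const Rcpp::List& fcW, const Rcpp::List& fcb) {
  Params p;
  for (int l = 0; l < convW.size(); ++l) {
    p.convW.push_back(Rcpp::as<mat>(convW[l]));
    p.convb.push_back(Rcpp::as<rowvec>(convb[l]));
  }
  for (int l = 0; l < fcW.size(); ++l) {
    p.fcW.push_back(Rcpp::as<mat>(fcW[l]));
    p.fcb.push_back(Rcpp::as<rowvec>(fcb[l]));
  }
  return p;
}

struct Caches {
  std::vector<mat> block_in;   // input map of each conv block
  std::vector<mat> Z;          // pre-ReLU conv output
  std::vector<umat> poolidx;
  std::vector<int> ns;         // grid edge at each block input
  int n_last;                  // edge of the final pooled map
  rowvec P;                    // predictors (1 x M)
  std::vector<rowvec> fc_in;   // input of each fc layer
  double logit;
};

static void forward_one(const vec& x, const Params& p, int n, Caches& c) {
  mat A(x);
  int cur = n;
  size_t nblocks = p.convW.size();
  c.block_in.resize(nblocks);
  c.Z.resize(nblocks);
  c.poolidx.resize(nblocks);
  c.ns.resize(nblocks);
  for (size_t b = 0; b < nblocks; ++b) {
    c.block_in[b] = A;
    c.ns[b] = cur;
    c.Z[b] = conv3_fwd(A, cur, p.convW[b], p.convb[b]);
    mat act = leaky(c.Z[b]);
    mat pooled;
    maxpool(act, cur, pooled, c.poolidx[b]);
    A = pooled;
    cur /= 2;
  }
  c.n_last = cur;
  // predictors = flattened final feature map (position x channel), so each
  // predictor is tied to a spatial receptive field and can be screened and
  // masked regionally
  c.P = conv_to<rowvec>::from(vectorise(A));
  size_t L = p.fcW.size();
  c.fc_in.resize(L);
  rowvec h = c.P;
  for (size_t l = 0; l < L; ++l) {
    c.fc_in[l] = h;
    rowvec z = h * p.fcW[l] + p.fcb[l];
    if (l + 1 < L) h = conv_to<rowvec>::from(leaky(mat(z)));
    else c.logit = z(0);
  }
}

// backprop from d(logit) = g; mask: predictor gradients kept (1) or zeroed.
// If grads != nullptr, parameter gradients are accumulated there.
// Returns input gradient if want_input.
static vec backward_one(double g, const Params& p, const Caches& c,
                        const uvec* keep, Params* grads, bool want_input) {
  size_t L = p.fcW.size();
  rowvec grow(1);
  grow(0) = g;
  for (size_t li = L; li-- > 0;) {
    if (grads) {
      grads->fcW[li] += c.fc_in[li].t() * grow;
      grads->fcb[li] += grow;
    }
    rowvec gin = grow * p.fcW[li].t();
    // fc_in is post-activation; its sign equals the pre-activation sign
    if (li > 0) gin %= conv_to<rowvec>::from(leaky_gate(mat(c.fc_in[li])));
    grow = gin;
  }
  rowvec gP = grow;  // 1 x M
  if (keep) {
    rowvec m(gP.n_elem, fill::zeros);
    for (uword i = 0; i < keep->n_elem; ++i) m((*keep)(i)) = 1.0;
    gP %= m;
  }
  int nl = c.n_last;
  uword nvox_last = (uword)nl * nl * nl;
  mat G = reshape(mat(gP), nvox_last, gP.n_elem / nvox_last);

  size_t nblocks = p.convW.size();
  for (size_t b = nblocks; b-- > 0;) {
    int cur = c.ns[b];
    mat Gu = unpool(G, c.poolidx[b], cur);
    Gu %= leaky_gate(c.Z[b]);
    bool need_in = want_input || b > 0;
    mat dummyW;
    rowvec dummyb;
    if (grads) {
      G = conv3_bwd(Gu, c.block_in[b], cur, p.convW[b],
                    grads->convW[b], grads->convb[b], need_in);
    } else {
      dummyW.zeros(p.convW[b].n_rows, p.convW[b].n_cols);
      dummyb.zeros(p.convb[b].n_elem);
      G = conv3_bwd(Gu, c.block_in[b], cur, p.convW[b],
                    dummyW, dummyb, need_in);
    }
  }
  if (want_input) return vec(G.col(0));
  return vec();
}

static Params zeros_like(const Params& p) {
  Params g;
  for (size_t l = 0; l < p.convW.size(); ++l) {
    g.convW.push_back(mat(p.convW[l].n_rows, p.convW[l].n_cols, fill::zeros));
    g.convb.push_back(rowvec(p.convb[l].n_elem, fill::zeros));
  }
  for (size_t l = 0; l < p.fcW.size(); ++l) {
    g.fcW.push_back(mat(p.fcW[l].n_rows, p.fcW[l].n_cols, fill::zeros));
    g.fcb.push_back(rowvec(p.fcb[l].n_elem, fill::zeros));
  }
  return g;
}

// [[Rcpp::export]]
Rcpp::List cnn_predict_cpp(const arma::mat& X, const Rcpp::List& convW,
                           const Rcpp::List& convb, const Rcpp::List& fcW,
                           const Rcpp::List& fcb, int n) {
  Params p = unpack(convW, convb, fcW, fcb);
  int B = X.n_cols;
  vec scores(B), logits(B);
  mat P;
  for (int s = 0; s < B; ++s) {
    Caches c;
    forward_one(X.col(s), p, n, c);
    if (s == 0) P.set_size(B, c.P.n_elem);
    P.row(s) = c.P;
    logits(s) = c.logit;
    scores(s) = 1.0 / (1.0 + std::exp(-c.logit));
  }
  return Rcpp::List::create(Rcpp::Named("scores") = scores,
                            Rcpp::Named("logits") = logits,
                            Rcpp::Named("predictors") = P);
}

// [[Rcpp::export]]
Rcpp::List cnn_batch_grad_cpp(const arma::mat& X, const arma::vec& y,
                              const Rcpp::List& convW, const Rcpp::List& convb,
                              const Rcpp::List& fcW, const Rcpp::List& fcb,
                              int n) {
  Params p = unpack(convW, convb, fcW, fcb);
  Params g = zeros_like(p);
  int B = X.n_cols;
  double loss = 0.0;
  vec scores(B);
  for (int s = 0; s < B; ++s) {
    Caches c;
    forward_one(X.col(s), p, n, c);
    double z = c.logit;
    // stable BCE: log(1+exp(z)) - y z
    loss += (z > 0 ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z)))
            - y(s) * z;
    double S = 1.0 / (1.0 + std::exp(-z));
    scores(s) = S;
    backward_one((S - y(s)) / B, p, c, nullptr, &g, false);
  }
  loss /= B;
  Rcpp::List gcW(g.convW.size()), gcb(g.convb.size());
  for (size_t l = 0; l < g.convW.size(); ++l) {
    gcW[l] = g.convW[l];
    gcb[l] = Rcpp::wrap(g.convb[l]);
  }
  Rcpp::List gfW(g.fcW.size()), gfb(g.fcb.size());
  for (size_t l = 0; l < g.fcW.size(); ++l) {
    gfW[l] = g.fcW[l];
    gfb[l] = Rcpp::wrap(g.fcb[l]);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("scores") = scores,
                            Rcpp::Named("conv_W") = gcW,
                            Rcpp::Named("conv_b") = gcb,
                            Rcpp::Named("fc_W") = gfW,
                            Rcpp::Named("fc_b") = gfb);
}

// d(logit)/d(input) per sample, with gradient flow restricted to the
// predictors listed in `keep` (1-based indices).
// [[Rcpp::export]]
arma::mat cnn_input_grad_cpp(const arma::mat& X, const Rcpp::List& convW,
                             const Rcpp::List& convb, const Rcpp::List& fcW,
                             const Rcpp::List& fcb, int n,
                             const arma::uvec& keep1) {
  Params p = unpack(convW, convb, fcW, fcb);
  uvec keep = keep1 - 1;
  int B = X.n_cols;
  mat out(X.n_rows, B);
  for (int s = 0; s < B; ++s) {
    Caches c;
    forward_one(X.col(s), p, n, c);
    out.col(s) = backward_one(1.0, p, c, &keep, nullptr, true);
  }
  return out;
}
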