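// 3D UNet engine: encoder-decoder with 3x3x3 convolutions, channelwise
// normalisation, ReLU, 2x max pooling, nearest-neighbour upsampling with a
// 3x3x3 post-convolution, skip concatenation, bottleneck dropout and a
// combined soft-Dice + cross-entropy loss. Forward and backward passes are
// implemented with slab-chunked im2col + BLAS gemm in single precision.
//
// Activations are stored as (Nvox, C) matrices, voxel index linear in
// (x + nx*(y + ny*z)), one column per channel. Convolution weights are
// (27*Cin, Cout) with row index = kernel_offset + 27*channel, kernel
// offsets ordered dx fastest then dy then dz (dx,dy,dz in -1..1).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Dims {
  int nx, ny, nz;
  R_xlen_t n() const { return (R_xlen_t)nx * ny * nz; }
};

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float *A, int lda, const float *B, int ldb, float beta,
                  float *C, int ldc) {
  const arma::blas_int M = m, N = n, K = k, LDA = lda, LDB = ldb, LDC = ldc;
  arma::blas::gemm<float>(&ta, &tb, &M, &N, &K, &alpha, A, &LDA, B, &LDB,
                          &beta, C, &LDC);
}

// The 3x3x3 convolution is evaluated as 27 shifted gemm accumulations on
// the flat (Nvox x C) activation matrices: for kernel offset
// (dx, dy, dz), output rows in the (dy, dz)-valid region accumulate
// X[row + s] * W_o with s the flat index shift. The flat shift wraps at
// the x-boundaries (an x-edge voxel reads the far edge of the adjacent
// row), so those few rows are corrected afterwards by subtracting the
// wrapped contribution; y/z boundaries are handled by restricting the row
// blocks, which is exactly zero padding.

struct ConvBlockRange {
  R_xlen_t start;
  R_xlen_t len;
};

// Contiguous flat row blocks of the output region valid for (dy, dz).
static std::vector<ConvBlockRange> conv_blocks(const Dims &d, int dy, int dz) {
  std::vector<ConvBlockRange> blocks;
  const int k0 = std::max(0, -dz), k1 = d.nz - std::max(0, dz);
  if (dy == 0) {
    blocks.push_back({(R_xlen_t)d.nx * d.ny * k0,
                      (R_xlen_t)d.nx * d.ny * (k1 - k0)});
  } else {
    const int j0 = std::max(0, -dy), j1 = d.ny - std::max(0, dy);
    for (int k = k0; k < k1; ++k) {
      blocks.push_back({(R_xlen_t)d.nx * (j0 + (R_xlen_t)d.ny * k),
                        (R_xlen_t)d.nx * (j1 - j0)});
    }
  }
  return blocks;
}

// Clip a block so that both [start, start+len) and [start+s, start+s+len)
// stay inside [0, n).
static bool clip_block(ConvBlockRange &blk, R_xlen_t s, R_xlen_t n) {
  R_xlen_t lo = blk.start + s;
  if (lo < 0) {
    blk.start -= lo;
    blk.len += lo;
  }
  R_xlen_t hi = blk.start + s + blk.len;
  if (hi > n) blk.len -= hi - n;
  return blk.len > 0;
}

// Visit output rows inside the block whose x index equals the wrap edge
// for this dx (their shifted read wrapped into the adjacent row).
template <typename F>
static void for_wrapped_rows(const ConvBlockRange &blk, int dx, int nx,
                             R_xlen_t s, R_xlen_t n, F fix) {
  const int xe = dx == 1 ? nx - 1 : 0;
  R_xlen_t r = blk.start + ((xe - (int)(blk.start % nx) + nx) % nx);
  for (; r < blk.start + blk.len; r += nx) {
    const R_xlen_t in = r + s;
    if (in >= 0 && in < n) fix(r, in);
  }
}

static arma::fmat conv3_forward(const arma::fmat &X, const Dims &d,
                                const arma::fmat &W, const arma::frowvec &b) {
  const int cin = (int)X.n_cols, cout = (int)W.n_cols;
  const R_xlen_t n = X.n_rows;
  arma::fmat Y(n, cout);
  for (int co = 0; co < cout; ++co) Y.col(co).fill(b(co));
  arma::fmat Wo(cin, cout);
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        for (int ci = 0; ci < cin; ++ci)
          for (int co = 0; co < cout; ++co) Wo(ci, co) = W(o + 27 * ci, co);
        const R_xlen_t s = dx + (R_xlen_t)d.nx * (dy + (R_xlen_t)d.ny * dz);
        for (ConvBlockRange blk : conv_blocks(d, dy, dz)) {
          if (!clip_block(blk, s, n)) continue;
          sgemm('N', 'N', (int)blk.len, cout, cin, 1.0f,
                X.memptr() + blk.start + s, (int)n, Wo.memptr(), cin, 1.0f,
                Y.memptr() + blk.start, (int)n);
          if (dx != 0) {
            for_wrapped_rows(blk, dx, d.nx, s, n, [&](R_xlen_t r, R_xlen_t in) {
              for (int co = 0; co < cout; ++co) {
                float acc = 0;
                for (int ci = 0; ci < cin; ++ci)
                  acc += X(in, ci) * Wo(ci, co);
                Y(r, co) -= acc;
              }
            });
          }
        }
      }
  return Y;
}

// Backward through the convolution: computes dW, db and returns dX.
static arma::fmat conv3_backward(const arma::fmat &gY, const arma::fmat &X,
                                 const Dims &d, const arma::fmat &W,
                                 arma::fmat &dW, arma::frowvec &db) {
  const int cin = (int)X.n_cols, cout = (int)W.n_cols;
  const R_xlen_t n = X.n_rows;
  dW.zeros(W.n_rows, W.n_cols);
  db = arma::sum(gY, 0);
  arma::fmat dX(n, cin, arma::fill::zeros);
  arma::fmat Wo(cin, cout), dWo(cin, cout);
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int o = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        for (int ci = 0; ci < cin; ++ci)
          for (int co = 0; co < cout; ++co) Wo(ci, co) = W(o + 27 * ci, co);
        dWo.zeros();
        const R_xlen_t s = dx + (R_xlen_t)d.nx * (dy + (R_xlen_t)d.ny * dz);
        for (ConvBlockRange blk : conv_blocks(d, dy, dz)) {
          if (!clip_block(blk, s, n)) continue;
          // dX[rows + s] += gY[rows] * Wo^T
          sgemm('N', 'T', (int)blk.len, cin, cout, 1.0f,
                gY.memptr() + blk.start, (int)n, Wo.memptr(), cin, 1.0f,
                dX.memptr() + blk.start + s, (int)n);
          // dWo += X[rows + s]^T * gY[rows]
          sgemm('T', 'N', cin, cout, (int)blk.len, 1.0f,
                X.memptr() + blk.start + s, (int)n, gY.memptr() + blk.start,
                (int)n, 1.0f, dWo.memptr(), cin);
          if (dx != 0) {
            for_wrapped_rows(blk, dx, d.nx, s, n, [&](R_xlen_t r, R_xlen_t in) {
              for (int co = 0; co < cout; ++co) {
                const float g = gY(r, co);
                for (int ci = 0; ci < cin; ++ci) {
                  dX(in, ci) -= g * Wo(ci, co);
                  dWo(ci, co) -= X(in, ci) * g;
                }
              }
            });
          }
        }
        for (int ci = 0; ci < cin; ++ci)
          for (int co = 0; co < cout; ++co) dW(o + 27 * ci, co) += dWo(ci, co);
      }
  return dX;
}

struct BlockActs {
  arma::fmat in;       // conv input
  arma::fmat xhat;     // normalised pre-activation (empty if no norm)
  arma::frowvec invstd;
  arma::fmat out;      // post-ReLU output
};

static const float NORM_EPS = 1e-5f;

static arma::fmat block_forward(const arma::fmat &X, const Dims &d,
                                const arma::fmat &W, const arma::frowvec &b,
                                const arma::frowvec &g, const arma::frowvec &beta,
                                bool use_norm, BlockActs &acts) {
  acts.in = X;
  arma::fmat Y = conv3_forward(X, d, W, b);
  if (use_norm) {
    const arma::frowvec mu = arma::mean(Y, 0);
    Y.each_row() -= mu;
    arma::frowvec sd(Y.n_cols);
    for (arma::uword c = 0; c < Y.n_cols; ++c)
      sd(c) = std::sqrt(arma::mean(arma::square(Y.col(c))) + NORM_EPS);
    acts.invstd = 1.0f / sd;
    Y.each_row() %= acts.invstd;
    acts.xhat = Y;
    Y.each_row() %= g;
    Y.each_row() += beta;
  }
  acts.out = arma::clamp(Y, 0.0f, arma::datum::inf);
  return acts.out;
}

static arma::fmat block_backward(const arma::fmat &gOut, const Dims &d,
                                 const arma::fmat &W, const arma::frowvec &g,
                                 bool use_norm, const BlockActs &acts,
                                 arma::fmat &dW, arma::frowvec &db,
                                 arma::frowvec &dg, arma::frowvec &dbeta) {
  arma::fmat g1 = gOut % arma::conv_to<arma::fmat>::from(acts.out > 0.0f);
  if (use_norm) {
    dbeta = arma::sum(g1, 0);
    dg = arma::sum(g1 % acts.xhat, 0);
    g1.each_row() %= g; // d/d xhat
    const arma::frowvec m1 = arma::mean(g1, 0);
    const arma::frowvec m2 = arma::mean(g1 % acts.xhat, 0);
    g1 -= acts.xhat.each_row() % m2;
    g1.each_row() -= m1;
    g1.each_row() %= acts.invstd;
  } else {
    dg.reset(); dbeta.reset();
  }
  return conv3_backward(g1, acts.in, d, W, dW, db);
}

static arma::fmat maxpool_forward(const arma::fmat &X, const Dims &din,
                                  arma::umat &argmax) {
  const Dims dout = {din.nx / 2, din.ny / 2, din.nz / 2};
  const int C = (int)X.n_cols;
  arma::fmat Y(dout.n(), C);
  argmax.set_size(dout.n(), C);
  for (int c = 0; c < C; ++c) {
    const float *x = X.colptr(c);
    float *y = Y.colptr(c);
    arma::uword *am = argmax.colptr(c);
    R_xlen_t v = 0;
    for (int k = 0; k < dout.nz; ++k)
      for (int j = 0; j < dout.ny; ++j)
        for (int i = 0; i < dout.nx; ++i, ++v) {
          float best = -arma::datum::inf;
          R_xlen_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const R_xlen_t w = (R_xlen_t)(2*i + dx) +
                  (R_xlen_t)din.nx * ((2*j + dy) + (R_xlen_t)din.ny * (2*k + dz));
                if (x[w] > best) { best = x[w]; besti = w; }
              }
          y[v] = best;
          am[v] = (arma::uword)besti;
        }
  }
  return Y;
}

static arma::fmat maxpool_backward(const arma::fmat &gY, R_xlen_t n_in,
                                   const arma::umat &argmax) {
  arma::fmat dX(n_in, gY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < gY.n_cols; ++c) {
    const float *gy = gY.colptr(c);
    const arma::uword *am = argmax.colptr(c);
    float *dx = dX.colptr(c);
    for (arma::uword v = 0; v < gY.n_rows; ++v) dx[am[v]] += gy[v];
  }
  return dX;
}

static arma::fmat upsample_forward(const arma::fmat &X, const Dims &din) {
  const Dims dout = {din.nx * 2, din.ny * 2, din.nz * 2};
  arma::fmat Y(dout.n(), X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const float *x = X.colptr(c);
    float *y = Y.colptr(c);
    R_xlen_t v = 0;
    for (int k = 0; k < dout.nz; ++k)
      for (int j = 0; j < dout.ny; ++j)
        for (int i = 0; i < dout.nx; ++i, ++v)
          y[v] = x[(R_xlen_t)(i / 2) +
                   (R_xlen_t)din.nx * ((j / 2) + (R_xlen_t)din.ny * (k / 2))];
  }
  return Y;
}

static arma::fmat upsample_backward(const arma::fmat &gY, const Dims &dout) {
  const Dims din = {dout.nx / 2, dout.ny / 2, dout.nz / 2};
  arma::fmat dX(din.n(), gY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < gY.n_cols; ++c) {
    const float *gy = gY.colptr(c);
    float *dx = dX.colptr(c);
    R_xlen_t v = 0;
    for (int k = 0; k < dout.nz; ++k)
      for (int j = 0; j < dout.ny; ++j)
        for (int i = 0; i < dout.nx; ++i, ++v)
          dx[(R_xlen_t)(i / 2) +
             (R_xlen_t)din.nx * ((j / 2) + (R_xlen_t)din.ny * (k / 2))] += gy[v];
  }
  return dX;
}

// ---- network plumbing ----------------------------------------------------

struct NetCfg {
  int grid, depth, num_classes;
  std::vector<int> channels;
  double dropout;
  bool norm;
  int entries_per_block() const { return norm ? 4 : 2; }
};

static NetCfg parse_cfg(const List &cfg) {
  NetCfg c;
  c.grid = as<int>(cfg["grid"]);
  c.depth = as<int>(cfg["depth"]);
  c.num_classes = as<int>(cfg["num_classes"]);
  c.channels = as<std::vector<int>>(cfg["channels"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.norm = as<bool>(cfg["batch_norm"]);
  if ((int)c.channels.size() != c.depth)
    stop("channels length must equal depth");
  if (c.grid % (1 << (c.depth - 1)) != 0)
    stop("grid must be a multiple of 2^(depth-1)");
  return c;
}

static arma::fmat get_fmat(const List &weights, int idx) {
  NumericMatrix m = as<NumericMatrix>(weights[idx]);
  arma::fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

static arma::frowvec get_frow(const List &weights, int idx) {
  NumericVector v = as<NumericVector>(weights[idx]);
  arma::frowvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
  return out;
}

struct BlockW {
  arma::fmat W;
  arma::frowvec b, g, beta;
};

static BlockW read_block(const List &weights, int base, bool norm) {
  BlockW bw;
  bw.W = get_fmat(weights, base);
  bw.b = get_frow(weights, base + 1);
  if (norm) {
    bw.g = get_frow(weights, base + 2);
    bw.beta = get_frow(weights, base + 3);
  }
  return bw;
}

struct ForwardState {
  std::vector<BlockActs> acts;     // one per conv block, in forward order
  std::vector<arma::fmat> skips;   // encoder outputs per level
  std::vector<arma::umat> argmax;  // pool argmax per level
  arma::fmat dropout_mask;         // empty if unused
  arma::fmat head_in;              // input to 1x1 head
  arma::fmat logits;
};

// Runs the full forward pass; blocks appended to st.acts in a fixed order
// that the backward pass mirrors.
static void unet_forward(const arma::fmat &input, const NetCfg &c,
                         const List &weights, bool training, int dropout_seed,
                         ForwardState &st) {
  const int nb = c.entries_per_block();
  const int D = c.depth;
  std::vector<Dims> dims(D);
  for (int l = 0; l < D; ++l) {
    const int n = c.grid >> l;
    dims[l] = {n, n, n};
  }
  st.skips.resize(D - 1);
  st.argmax.resize(D - 1);
  st.acts.resize((D - 1) * 2 + 2 + (D - 1) * 3);

  arma::fmat cur = input;
  int ai = 0;
  for (int l = 0; l <= D - 2; ++l) {
    const int base = l * 2 * nb;
    BlockW a = read_block(weights, base, c.norm);
    BlockW b = read_block(weights, base + nb, c.norm);
    cur = block_forward(cur, dims[l], a.W, a.b, a.g, a.beta, c.norm, st.acts[ai++]);
    cur = block_forward(cur, dims[l], b.W, b.b, b.g, b.beta, c.norm, st.acts[ai++]);
    st.skips[l] = cur;
    cur = maxpool_forward(cur, dims[l], st.argmax[l]);
  }
  const int bot_base = (D - 1) * 2 * nb;
  {
    BlockW a = read_block(weights, bot_base, c.norm);
    BlockW b = read_block(weights, bot_base + nb, c.norm);
    cur = block_forward(cur, dims[D - 1], a.W, a.b, a.g, a.beta, c.norm, st.acts[ai++]);
    cur = block_forward(cur, dims[D - 1], b.W, b.b, b.g, b.beta, c.norm, st.acts[ai++]);
  }
  if (training && c.dropout > 0) {
    std::mt19937 rng((unsigned)dropout_seed);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    st.dropout_mask.set_size(cur.n_rows, cur.n_cols);
    const float scale = (float)(1.0 / (1.0 - c.dropout));
    for (arma::uword j = 0; j < cur.n_cols; ++j)
      for (arma::uword i = 0; i < cur.n_rows; ++i)
        st.dropout_mask(i, j) = unif(rng) < c.dropout ? 0.0f : scale;
    cur %= st.dropout_mask;
  }
  const int dec_base0 = bot_base + 2 * nb;
  for (int l = D - 2; l >= 0; --l) {
    const int base = dec_base0 + (D - 2 - l) * 3 * nb;
    BlockW u = read_block(weights, base, c.norm);
    BlockW a = read_block(weights, base + nb, c.norm);
    BlockW b = read_block(weights, base + 2 * nb, c.norm);
    cur = upsample_forward(cur, dims[l + 1]);
    cur = block_forward(cur, dims[l], u.W, u.b, u.g, u.beta, c.norm, st.acts[ai++]);
    arma::fmat cat = arma::join_rows(st.skips[l], cur);
    cur = block_forward(cat, dims[l], a.W, a.b, a.g, a.beta, c.norm, st.acts[ai++]);
    cur = block_forward(cur, dims[l], b.W, b.b, b.g, b.beta, c.norm, st.acts[ai++]);
  }
  const int head_base = dec_base0 + (D - 1) * 3 * nb;
  st.head_in = cur;
  arma::fmat Wh = get_fmat(weights, head_base);
  arma::frowvec bh = get_frow(weights, head_base + 1);
  st.logits = cur * Wh;
  st.logits.each_row() += bh;
}

// [[Rcpp::export]]
IntegerVector unet_predict_cpp(NumericVector image, List weights, List cfg) {
  const NetCfg c = parse_cfg(cfg);
  const R_xlen_t n = (R_xlen_t)c.grid * c.grid * c.grid;
  if (image.size() != n) stop("image size does not match grid");
  arma::fmat input(n, 1);
  for (R_xlen_t i = 0; i < n; ++i) input(i, 0) = (float)image[i];
  ForwardState st;
  unet_forward(input, c, weights, false, 0, st);
  IntegerVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    int best = 0;
    float bv = st.logits(v, 0);
    for (int k = 1; k < c.num_classes; ++k)
      if (st.logits(v, k) > bv) { bv = st.logits(v, k); best = k; }
    out[v] = best;
  }
  return out;
}

// Softmax class probabilities for a preprocessed image (diagnostics and
// uncertainty inspection). Returns an (Nvox x num_classes) matrix.
// [[Rcpp::export]]
NumericMatrix unet_probs_cpp(NumericVector image, List weights, List cfg) {
  const NetCfg c = parse_cfg(cfg);
  const R_xlen_t n = (R_xlen_t)c.grid * c.grid * c.grid;
  if (image.size() != n) stop("image size does not match grid");
  arma::fmat input(n, 1);
  for (R_xlen_t i = 0; i < n; ++i) input(i, 0) = (float)image[i];
  ForwardState st;
  unet_forward(input, c, weights, false, 0, st);
  NumericMatrix out(n, c.num_classes);
  for (R_xlen_t v = 0; v < n; ++v) {
    float mx = st.logits(v, 0);
    for (int k = 1; k < c.num_classes; ++k) mx = std::max(mx, st.logits(v, k));
    double sum = 0;
    for (int k = 0; k < c.num_classes; ++k) {
      out(v, k) = std::exp((double)st.logits(v, k) - mx);
      sum += out(v, k);
    }
    for (int k = 0; k < c.num_classes; ++k) out(v, k) /= sum;
  }
  return out;
}

// One training step: forward, Dice+CE loss, full backward. Returns the loss
// components and the gradient list (same order and shapes as `weights`).
// [[Rcpp::export]]
List unet_train_step_cpp(NumericVector image, IntegerVector labels,
                         List weights, List cfg, int dropout_seed) {
  const NetCfg c = parse_cfg(cfg);
  const int D = c.depth, nb = c.entries_per_block(), K = c.num_classes;
  const R_xlen_t n = (R_xlen_t)c.grid * c.grid * c.grid;
  if (image.size() != n || labels.size() != n)
    stop("image/labels size does not match grid");
  arma::fmat input(n, 1);
  for (R_xlen_t i = 0; i < n; ++i) input(i, 0) = (float)image[i];

  ForwardState st;
  unet_forward(input, c, weights, true, dropout_seed, st);

  // ---- loss and gradient w.r.t. logits ----
  arma::fmat P = st.logits;
  for (R_xlen_t v = 0; v < n; ++v) {
    float mx = P(v, 0);
    for (int k = 1; k < K; ++k) mx = std::max(mx, P(v, k));
    float sum = 0;
    for (int k = 0; k < K; ++k) { P(v, k) = std::exp(P(v, k) - mx); sum += P(v, k); }
    for (int k = 0; k < K; ++k) P(v, k) /= sum;
  }
  double ce = 0;
  for (R_xlen_t v = 0; v < n; ++v) {
    const int y = labels[v];
    if (y < 0 || y >= K) stop("label code outside num_classes");
    ce -= std::log(std::max((double)P(v, y), 1e-12));
  }
  ce /= (double)n;

  // Smoothing of the soft-Dice ratio. A tiny smooth term makes the
  // gradient for a class absent from the sample blow up like 1/smooth once
  // the model suppresses it (num and den both -> smooth), and that noise
  // couples into all classes through the softmax; 1.0 keeps the absent-
  // class gradient bounded while leaving present-class Dice essentially
  // unchanged (class sums are thousands of voxels).
  const double smooth = 1.0;
  arma::fmat G(n, K);                 // d dice_loss / d P
  double dice_loss = 0;
  for (int k = 0; k < K; ++k) {
    double sp = 0, sg = 0, inter = 0;
    const float *pc = P.colptr(k);
    for (R_xlen_t v = 0; v < n; ++v) {
      sp += pc[v];
      if (labels[v] == k) { sg += 1; inter += pc[v]; }
    }
    const double num = 2 * inter + smooth, den = sp + sg + smooth;
    dice_loss += 1.0 - num / den;
    const double a = -1.0 / K / (den * den);
    float *gc = G.colptr(k);
    for (R_xlen_t v = 0; v < n; ++v) {
      const double gv = labels[v] == k ? 1.0 : 0.0;
      gc[v] = (float)(a * (2 * gv * den - num));
    }
  }
  dice_loss /= K;

  arma::fmat dZ(n, K);
  const float invn = 1.0f / (float)n;
  for (R_xlen_t v = 0; v < n; ++v) {
    float dot = 0;
    for (int k = 0; k < K; ++k) dot += G(v, k) * P(v, k);
    for (int k = 0; k < K; ++k) {
      const float onehot = labels[v] == k ? 1.0f : 0.0f;
      dZ(v, k) = (P(v, k) - onehot) * invn + P(v, k) * (G(v, k) - dot);
    }
  }
  G.reset();
  P.reset();

  // ---- backward ----
  std::vector<Dims> dims(D);
  for (int l = 0; l < D; ++l) { const int g = c.grid >> l; dims[l] = {g, g, g}; }
  List grads(weights.size());
  const int bot_base = (D - 1) * 2 * nb;
  const int dec_base0 = bot_base + 2 * nb;
  const int head_base = dec_base0 + (D - 1) * 3 * nb;

  auto store_block_grads = [&](int base, const arma::fmat &dW,
                               const arma::frowvec &db, const arma::frowvec &dg,
                               const arma::frowvec &dbeta) {
    grads[base] = wrap(arma::conv_to<arma::mat>::from(dW));
    grads[base + 1] = wrap(arma::conv_to<arma::rowvec>::from(db));
    if (c.norm) {
      grads[base + 2] = wrap(arma::conv_to<arma::rowvec>::from(dg));
      grads[base + 3] = wrap(arma::conv_to<arma::rowvec>::from(dbeta));
    }
  };

  // head
  arma::fmat Wh = get_fmat(weights, head_base);
  grads[head_base] = wrap(arma::conv_to<arma::mat>::from(st.head_in.t() * dZ));
  grads[head_base + 1] = wrap(arma::conv_to<arma::rowvec>::from(arma::sum(dZ, 0)));
  arma::fmat g = dZ * Wh.t();
  dZ.reset();

  // decoder (reverse of forward: levels 0 .. D-2 correspond to the last
  // processed first)
  std::vector<arma::fmat> skip_grads(D - 1);
  int ai = (int)st.acts.size();
  for (int l = 0; l <= D - 2; ++l) {
    const int base = dec_base0 + (D - 2 - l) * 3 * nb;
    BlockW u = read_block(weights, base, c.norm);
    BlockW a = read_block(weights, base + nb, c.norm);
    BlockW b = read_block(weights, base + 2 * nb, c.norm);
    arma::fmat dW; arma::frowvec db, dg, dbeta;
    g = block_backward(g, dims[l], b.W, b.g, c.norm, st.acts[--ai], dW, db, dg, dbeta);
    store_block_grads(base + 2 * nb, dW, db, dg, dbeta);
    g = block_backward(g, dims[l], a.W, a.g, c.norm, st.acts[--ai], dW, db, dg, dbeta);
    store_block_grads(base + nb, dW, db, dg, dbeta);
    const int cskip = (int)st.skips[l].n_cols;
    skip_grads[l] = g.cols(0, cskip - 1);
    arma::fmat gup = g.cols(cskip, g.n_cols - 1);
    gup = block_backward(gup, dims[l], u.W, u.g, c.norm, st.acts[--ai], dW, db, dg, dbeta);
    store_block_grads(base, dW, db, dg, dbeta);
    g = upsample_backward(gup, dims[l]);
  }

  // bottleneck
  if (st.dropout_mask.n_elem > 0) g %= st.dropout_mask;
  {
    BlockW a = read_block(weights, bot_base, c.norm);
    BlockW b = read_block(weights, bot_base + nb, c.norm);
    arma::fmat dW; arma::frowvec db, dg, dbeta;
    g = block_backward(g, dims[D - 1], b.W, b.g, c.norm, st.acts[--ai], dW, db, dg, dbeta);
    store_block_grads(bot_base + nb, dW, db, dg, dbeta);
    g = block_backward(g, dims[D - 1], a.W, a.g, c.norm, st.acts[--ai], dW, db, dg, dbeta);
    store_block_grads(bot_base, dW, db, dg, dbeta);
  }

  // encoder
  for (int l = D - 2; l >= 0; --l) {
    g = maxpool_backward(g, dims[l].n(), st.argmax[l]);
    g += skip_grads[l];
    const int base = l * 2 * nb;
    BlockW a = read_block(weights, base, c.norm);
    BlockW b = read_block(weights, base + nb, c.norm);
    arma::fmat dW; arma::frowvec db, dg, dbeta;
    g = block_backward(g, dims[l], b.W, b.g, c.norm, st.acts[--ai], dW, db, dg, dbeta);
    store_block_grads(base + nb, dW, db, dg, dbeta);
    g = block_backward(g, dims[l], a.W, a.g, c.norm, st.acts[--ai], dW, db, dg, dbeta);
    store_block_grads(base, dW, db, dg, dbeta);
  }

  return List::create(_["loss"] = ce + dice_loss, _["ce"] = ce,
                      _["dice"] = dice_loss, _["grads"] = grads);
}
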