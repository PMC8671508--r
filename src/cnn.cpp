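// Five-layer CNN EMI canceller: conv(+BN+ReLU) x4 then conv, trained with
// Adam on MSE. A batch is held as one C x (H*W*B) matrix (positions of all
// examples side by side, h fastest, H = readout samples, W = 10 coils).
// Convolutions are im2col + one BLAS sgemm per layer; the col matrices are
// kept from forward to backward. Same-padding on both axes; the 2-channel
// output map is averaged across the coil axis to give the H x 2 prediction.
// Single precision throughout. Weight init and shuffling use R's RNG so
// training is reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct LayerSpec { int cin, cout, k; };

const LayerSpec SPEC[5] = {
  {2, 128, 11}, {128, 64, 9}, {64, 32, 5}, {32, 32, 1}, {32, 2, 7}
};

struct Layer {
  fmat W;              // cout x (cin*k*k)
  fvec b;              // cout
  fvec gamma, beta;    // BN affine (layers 0..3)
  fvec rmean, rvar;    // BN running stats
  bool bn;
  // Adam state
  fmat mW, vW; fvec mb, vb, mg, vg, mbe, vbe;
};

// im2col for a stack of B examples stored as in = cin x (H*W*B):
// out (cin*k*k) x (H*W*B), row r = c + cin*(ki + k*kj); padding never
// crosses example boundaries. Loops are ordered so each output column is
// written sequentially (the input map is small enough to stay in cache),
// which matters: the column stride of `out` is tens of KB for the wide
// layers and strided writes dominate the runtime otherwise.
void im2colB(const fmat& in, int H, int W, int B, int k, fmat& out) {
  const int cin = in.n_rows, pad = (k - 1) / 2, P = H * W;
  out.set_size(cin * k * k, P * B);
  for (int b = 0; b < B; ++b) {
    const int base = P * b;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        float* dst = out.colptr(base + h + H * w);
        for (int kj = 0; kj < k; ++kj) {
          const int ws = w + kj - pad;
          if (ws < 0 || ws >= W) {
            std::memset(dst, 0, cin * k * sizeof(float));
            dst += cin * k;
            continue;
          }
          const float* srcCol = in.colptr(base + H * ws);
          for (int ki = 0; ki < k; ++ki, dst += cin) {
            const int hs = h + ki - pad;
            if (hs < 0 || hs >= H) std::memset(dst, 0, cin * sizeof(float));
            else std::memcpy(dst, srcCol + (size_t)cin * hs,
                             cin * sizeof(float));
          }
        }
      }
    }
  }
}

std::vector<Layer> initLayers(bool adam) {
  std::vector<Layer> L(5);
  for (int l = 0; l < 5; ++l) {
    const LayerSpec& s = SPEC[l];
    const int fanin = s.cin * s.k * s.k;
    // He init for the ReLU blocks, Xavier for the linear output conv
    const double sd = (l < 4) ? std::sqrt(2.0 / fanin) : std::sqrt(1.0 / fanin);
    L[l].W.set_size(s.cout, fanin);
    for (uword j = 0; j < L[l].W.n_cols; ++j)
      for (uword i = 0; i < L[l].W.n_rows; ++i)
        L[l].W(i, j) = (float)(R::norm_rand() * sd);
    L[l].b.zeros(s.cout);
    L[l].bn = (l < 4);
    if (L[l].bn) {
      L[l].gamma.ones(s.cout); L[l].beta.zeros(s.cout);
      L[l].rmean.zeros(s.cout); L[l].rvar.ones(s.cout);
    }
    if (adam) {
      L[l].mW.zeros(size(L[l].W)); L[l].vW.zeros(size(L[l].W));
      L[l].mb.zeros(s.cout); L[l].vb.zeros(s.cout);
      if (L[l].bn) {
        L[l].mg.zeros(s.cout); L[l].vg.zeros(s.cout);
        L[l].mbe.zeros(s.cout); L[l].vbe.zeros(s.cout);
      }
    }
  }
  return L;
}

const float BN_EPS = 1e-5f, BN_MOM = 0.1f;

struct Workspace {
  fmat col[5];     // im2col outputs, kept for backward
  fmat A[6];       // A[0] input stack, A[l+1] post-activation stacks
  fmat XH[4];      // BN xhat
  fvec invstd[4];
  fmat dcol;       // im2col of the output gradient (input-grad path)
};

// rearrange W (cout x cin*k*k) into the flipped-kernel form
// Wf (cin x cout*k*k) with Wf[c, co + cout*(ki + k*kj)] =
// W[co, c + cin*((k-1-ki) + k*(k-1-kj))], so that the adjoint of the
// zero-padded correlation is the zero-padded correlation of the output
// gradient with Wf (valid because same-padding with odd k is symmetric)
void flipKernels(const fmat& W, int cin, int cout, int k, fmat& Wf) {
  Wf.set_size(cin, cout * k * k);
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki)
      for (int co = 0; co < cout; ++co)
        for (int c = 0; c < cin; ++c)
          Wf(c, co + cout * (ki + k * kj)) =
            W(co, c + cin * ((k - 1 - ki) + k * (k - 1 - kj)));
}

// inference-mode forward for a stack of B examples; returns 2 x (H*B)
fmat forwardInfer(const std::vector<Layer>& L, const fmat& x0,
                  int H, int W, int B, fmat& colbuf) {
  fmat a = x0;
  for (int l = 0; l < 5; ++l) {
    im2colB(a, H, W, B, SPEC[l].k, colbuf);
    fmat z = L[l].W * colbuf;
    z.each_col() += L[l].b;
    if (L[l].bn) {
      for (uword c = 0; c < z.n_rows; ++c) {
        const float inv = 1.0f / std::sqrt(L[l].rvar(c) + BN_EPS);
        z.row(c) = (z.row(c) - L[l].rmean(c)) * inv * L[l].gamma(c) + L[l].beta(c);
      }
      z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    }
    a = std::move(z);
  }
  // average across the coil axis: per example, 2 x (H*W) -> 2 x H
  const int P = H * W;
  fmat out(2, H * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      out.cols(H * b, H * b + H - 1) += a.cols(P * b + H * w, P * b + H * w + H - 1);
  return out / (float)W;
}

// stack slices n0..n0+B-1 of a (C x P x N) cube into C x (P*B)
fmat stackSlices(const fcube& x, const std::vector<int>& idx, int n0, int B) {
  fmat out(x.n_rows, x.n_cols * B);
  for (int b = 0; b < B; ++b)
    out.cols(x.n_cols * b, x.n_cols * (b + 1) - 1) = x.slice(idx[n0 + b]);
  return out;
}

// rotate the (re, im) channel pair of a stacked batch by per-example
// global phases: the complex baseband coupling is linear, so the map the
// network learns is exactly equivariant under x -> e^{i theta} x,
// y -> e^{i theta} y; training under random rotations bakes that symmetry
// in instead of leaving it to chance (it matters for windows whose content
// is a near-constant phasor, e.g. a swept source crossing the carrier)
void rotatePhase(fmat& m, int per, const std::vector<float>& cs,
                 const std::vector<float>& sn) {
  for (uword j = 0; j < m.n_cols; ++j) {
    const int b = j / per;
    const float c = cs[b], s = sn[b];
    const float re = m(0, j), im = m(1, j);
    m(0, j) = c * re - s * im;
    m(1, j) = s * re + c * im;
  }
}

// small frequency shift: rotate sample h (time index, fastest within each
// H-block) by slope*h radians; valid to first order in the coupling's
// delay spread, and it fills coverage gaps a nonstationary source leaves
// between the frequencies its training windows happen to hit
void rotateRamp(fmat& m, int H, double slope) {
  for (uword j = 0; j < m.n_cols; ++j) {
    const int h = j % H;
    const float c = (float)std::cos(slope * h), s = (float)std::sin(slope * h);
    const float re = m(0, j), im = m(1, j);
    m(0, j) = c * re - s * im;
    m(1, j) = s * re + c * im;
  }
}

// replace the momentum-averaged BN statistics with exact population
// statistics of the (unaugmented) training set under the final weights:
// the correct inference-time normalization, free of batch-size noise
void finalizeBnStats(std::vector<Layer>& L, const fcube& xtrRaw,
                     int H, int W, fmat& colbuf) {
  const int P = H * W;
  const int CH = 32;
  // estimate the statistics under the same (augmented) input distribution
  // the weights were optimized for: a fixed draw of phase-rotated
  // superpositions, twice the training-set size
  const int N = 2 * (int)xtrRaw.n_slices;
  fcube xtr(xtrRaw.n_rows, xtrRaw.n_cols, N);
  for (int i = 0; i < N; ++i) {
    const int Nr = xtrRaw.n_slices;
    double w0 = unif_rand(), w1 = unif_rand();
    const double g = std::sqrt(w0 * w0 + w1 * w1);
    fmat acc(xtrRaw.n_rows, P, fill::zeros);
    const double ws[2] = {w0 / g, w1 / g};
    for (int k = 0; k < 2; ++k) {
      const int j = (k == 0) ? (i % Nr)
                             : (int)std::floor(unif_rand() * Nr) % Nr;
      const double th = 2.0 * M_PI * unif_rand();
      std::vector<float> ck{(float)(std::cos(th) * ws[k])};
      std::vector<float> sk{(float)(std::sin(th) * ws[k])};
      fmat xp = xtrRaw.slice(j);
      rotatePhase(xp, P, ck, sk);
      acc += xp;
    }
    xtr.slice(i) = acc;
  }
  // one pass per BN layer so every earlier layer is already normalized
  // with its final statistics
  for (int lFix = 0; lFix < 4; ++lFix) {
    fvec s1(SPEC[lFix].cout, fill::zeros), s2(SPEC[lFix].cout, fill::zeros);
    for (int n0 = 0; n0 < N; n0 += CH) {
      const int B = std::min(CH, N - n0);
      fmat a(xtr.n_rows, P * B);
      for (int b = 0; b < B; ++b)
        a.cols(P * b, P * (b + 1) - 1) = xtr.slice(n0 + b);
      for (int l = 0; l <= lFix; ++l) {
        im2colB(a, H, W, B, SPEC[l].k, colbuf);
        fmat z = L[l].W * colbuf;
        z.each_col() += L[l].b;
        if (l == lFix) {
          s1 += sum(z, 1);
          s2 += sum(square(z), 1);
        } else {
          for (uword c = 0; c < z.n_rows; ++c) {
            const float inv = 1.0f / std::sqrt(L[l].rvar(c) + BN_EPS);
            z.row(c) = (z.row(c) - L[l].rmean(c)) * inv * L[l].gamma(c) +
              L[l].beta(c);
          }
          z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
        }
        a = std::move(z);
      }
    }
    const double m = (double)N * P;
    fvec mu = s1 / (float)m;
    L[lFix].rmean = mu;
    L[lFix].rvar = s2 / (float)m - square(mu);
  }
}

double valLoss(const std::vector<Layer>& L, const fcube& xv, const fcube& yv,
               int H, int W, fmat& colbuf) {
  const int N = xv.n_slices;
  if (N == 0) return NA_REAL;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  double s = 0.0;
  const int CH = 32;   // inference chunk
  for (int n0 = 0; n0 < N; n0 += CH) {
    const int B = std::min(CH, N - n0);
    fmat x = stackSlices(xv, idx, n0, B);
    fmat out = forwardInfer(L, x, H, W, B, colbuf);
    for (int b = 0; b < B; ++b) {
      fmat d = out.cols(H * b, H * b + H - 1) - yv.slice(n0 + b);
      s += accu(square(d)) / (double)d.n_elem;
    }
  }
  return s / N;
}

template <typename T>
void adamStep(T& w, T& m, T& v, const T& g,
              double lr, double b1, double b2, double t) {
  m = (float)b1 * m + (float)(1 - b1) * g;
  v = (float)b2 * v + (float)(1 - b2) * square(g);
  const double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
  w -= (float)(lr / c1) * (m / (sqrt(v / (float)c2) + 1e-8f));
}

Rcpp::List layersToList(const std::vector<Layer>& L) {
  Rcpp::List out(5);
  for (int l = 0; l < 5; ++l) {
    Rcpp::List e = Rcpp::List::create(
      Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(L[l].W)),
      Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(L[l].b)));
    if (L[l].bn) {
      e["gamma"] = Rcpp::wrap(conv_to<vec>::from(L[l].gamma));
      e["beta"]  = Rcpp::wrap(conv_to<vec>::from(L[l].beta));
      e["rmean"] = Rcpp::wrap(conv_to<vec>::from(L[l].rmean));
      e["rvar"]  = Rcpp::wrap(conv_to<vec>::from(L[l].rvar));
    }
    out[l] = e;
  }
  return out;
}

std::vector<Layer> layersFromList(const Rcpp::List& ll) {
  std::vector<Layer> L(5);
  for (int l = 0; l < 5; ++l) {
    Rcpp::List e = ll[l];
    L[l].W = conv_to<fmat>::from(Rcpp::as<mat>(e["W"]));
    L[l].b = conv_to<fvec>::from(Rcpp::as<vec>(e["b"]));
    L[l].bn = e.containsElementNamed("gamma");
    if (L[l].bn) {
      L[l].gamma = conv_to<fvec>::from(Rcpp::as<vec>(e["gamma"]));
      L[l].beta  = conv_to<fvec>::from(Rcpp::as<vec>(e["beta"]));
      L[l].rmean = conv_to<fvec>::from(Rcpp::as<vec>(e["rmean"]));
      L[l].rvar  = conv_to<fvec>::from(Rcpp::as<vec>(e["rvar"]));
    }
  }
  return L;
}

fcube asFCube(const cube& c) { return conv_to<fcube>::from(c); }

} // namespace

// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train(const arma::cube& xtrD, const arma::cube& ytrD,
                     const arma::cube& xvalD, const arma::cube& yvalD,
                     int H, int W, int epochs, int batch,
                     double lr, double beta1, double beta2, double jitter) {
  Rcpp::RNGScope rngScope;
  const fcube xtr = asFCube(xtrD), ytr = asFCube(ytrD);
  const fcube xval = asFCube(xvalD), yval = asFCube(yvalD);
  const int N = xtr.n_slices, P = H * W;
  if (N < 1) Rcpp::stop("no training examples");

  std::vector<Layer> L = initLayers(true);
  Workspace ws;
  fmat colbuf;

  std::vector<double> trainHist, valHist;
  valHist.push_back(valLoss(L, xval, yval, H, W, colbuf)); // epoch 0 baseline

  double t = 0.0;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with R's RNG
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double epLoss = 0.0; int nBatches = 0;
    for (int start = 0; start < N; start += batch) {
      const int B = std::min(batch, N - start);
      const float m = (float)((double)B * P);
      // ---- forward ----
      ws.A[0] = stackSlices(xtr, idx, start, B);
      // linearity-consistency augmentation (R RNG, so seeded): rotate each
      // example by a random global phase and superpose it with a second,
      // phase-rotated example; both operations map valid (sensing, receive)
      // pairs to valid pairs because the coupling is linear
      fmat ybatch(2, H * B, fill::zeros);
      {
        const int K = 2;   // examples superposed per training input
        ws.A[0].zeros();
        for (int b = 0; b < B; ++b) {
          // random unit-norm complex weights: keeps the mixture's sensor /
          // receiver noise at the per-window level
          double w[K], g2 = 0.0;
          for (int k = 0; k < K; ++k) { w[k] = unif_rand(); g2 += w[k] * w[k]; }
          for (int k = 0; k < K; ++k) {
            const int j = (k == 0) ? idx[start + b]
                                   : idx[(int)std::floor(unif_rand() * N) % N];
            const double th = 2.0 * M_PI * unif_rand();
            const double a = w[k] / std::sqrt(g2);
            std::vector<float> ck{(float)(std::cos(th) * a)};
            std::vector<float> sk{(float)(std::sin(th) * a)};
            fmat xp = xtr.slice(j), yp = ytr.slice(j);
            rotatePhase(xp, P, ck, sk);
            rotatePhase(yp, H, ck, sk);
            if (jitter > 0) {
              const double slope = jitter * (2.0 * unif_rand() - 1.0);
              rotateRamp(xp, H, slope);
              rotateRamp(yp, H, slope);
            }
            ws.A[0].cols(P * b, P * b + P - 1) += xp;
            ybatch.cols(H * b, H * b + H - 1) += yp;
          }
        }
      }
      for (int l = 0; l < 5; ++l) {
        im2colB(ws.A[l], H, W, B, SPEC[l].k, ws.col[l]);
        ws.A[l + 1] = L[l].W * ws.col[l];
        ws.A[l + 1].each_col() += L[l].b;
        if (L[l].bn) {
          fvec mu = sum(ws.A[l + 1], 1) / m;
          ws.A[l + 1].each_col() -= mu;
          fvec var = sum(square(ws.A[l + 1]), 1) / m;
          ws.invstd[l] = 1.0f / sqrt(var + BN_EPS);
          L[l].rmean = (1 - BN_MOM) * L[l].rmean + BN_MOM * mu;
          L[l].rvar  = (1 - BN_MOM) * L[l].rvar  + BN_MOM * var;
          ws.A[l + 1].each_col() %= ws.invstd[l];      // xhat
          ws.XH[l] = ws.A[l + 1];
          ws.A[l + 1].each_col() %= L[l].gamma;
          ws.A[l + 1].each_col() += L[l].beta;
          ws.A[l + 1].transform([](float v) { return v > 0.0f ? v : 0.0f; });
        }
      }
      // ---- loss + output gradient ----
      fmat dA(2, P * B);
      double bLoss = 0.0;
      for (int b = 0; b < B; ++b) {
        fmat out(2, H, fill::zeros);
        for (int w = 0; w < W; ++w)
          out += ws.A[5].cols(P * b + H * w, P * b + H * w + H - 1);
        out /= (float)W;
        fmat diff = out - ybatch.cols(H * b, H * b + H - 1);
        bLoss += accu(square(diff)) / (double)diff.n_elem;
        // d(loss)/d(A5): broadcast the averaged gradient back over coils
        fmat g = diff * (float)(2.0 / (diff.n_elem * (double)B * W));
        for (int w = 0; w < W; ++w)
          dA.cols(P * b + H * w, P * b + H * w + H - 1) = g;
      }
      bLoss /= B;
      if (!std::isfinite(bLoss))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d with lr %g",
                   ep + 1, lr);
      epLoss += bLoss; ++nBatches;

      // ---- backward ----
      for (int l = 4; l >= 0; --l) {
        fvec dgamma, dbeta;
        if (L[l].bn) {
          dA %= conv_to<fmat>::from(ws.A[l + 1] > 0.0f);   // ReLU mask
          dgamma = sum(dA % ws.XH[l], 1);
          dbeta = sum(dA, 1);
          dA.each_col() %= L[l].gamma;                     // dxhat
          // dz = invstd/m * (m*dxhat - sum(dxhat) - xhat*sum(dxhat*xhat))
          fvec sumDx = sum(dA, 1);
          fvec sumDxX = sum(dA % ws.XH[l], 1);
          dA *= m;
          dA.each_col() -= sumDx;
          dA -= ws.XH[l].each_col() % sumDxX;
          dA.each_col() %= ws.invstd[l] / m;
        }
        fmat dW = dA * ws.col[l].t();
        fvec db = sum(dA, 1);
        if (l > 0) {
          // input gradient as a flipped-kernel convolution of dA
          im2colB(dA, H, W, B, SPEC[l].k, ws.dcol);
          fmat Wf;
          flipKernels(L[l].W, SPEC[l].cin, SPEC[l].cout, SPEC[l].k, Wf);
          dA = Wf * ws.dcol;
        }
        if (l == 4) t += 1.0;
        adamStep(L[l].W, L[l].mW, L[l].vW, dW, lr, beta1, beta2, t);
        adamStep(L[l].b, L[l].mb, L[l].vb, db, lr, beta1, beta2, t);
        if (L[l].bn) {
          adamStep(L[l].gamma, L[l].mg, L[l].vg, dgamma, lr, beta1, beta2, t);
          adamStep(L[l].beta, L[l].mbe, L[l].vbe, dbeta, lr, beta1, beta2, t);
        }
      }
      Rcpp::checkUserInterrupt();
    }
    trainHist.push_back(epLoss / nBatches);
    valHist.push_back(valLoss(L, xval, yval, H, W, colbuf));
  }
  // inference-time BN statistics: exact population stats of the training
  // set under the final weights (recorded val history still reflects the
  // running-average stats used during training)
  finalizeBnStats(L, xtr, H, W, colbuf);
  valHist.back() = valLoss(L, xval, yval, H, W, colbuf);

  return Rcpp::List::create(
    Rcpp::Named("layers") = layersToList(L),
    Rcpp::Named("train_loss") = trainHist,
    Rcpp::Named("val_loss") = valHist);
}

// [[Rcpp::export(name = ".cnn_predict")]]
arma::cube cnn_predict(const Rcpp::List& layers, const arma::cube& xD,
                       int H, int W) {
  std::vector<Layer> L = layersFromList(layers);
  const fcube x = asFCube(xD);
  const int N = x.n_slices;
  cube out(2, H, N);
  fmat colbuf;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  const int CH = 32;
  for (int n0 = 0; n0 < N; n0 += CH) {
    const int B = std::min(CH, N - n0);
    fmat xs = stackSlices(x, idx, n0, B);
    fmat o = forwardInfer(L, xs, H, W, B, colbuf);
    for (int b = 0; b < B; ++b)
      out.slice(n0 + b) = conv_to<mat>::from(o.cols(H * b, H * b + H - 1));
  }
  return out;
}
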