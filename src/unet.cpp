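// Small fully convolutional encoder-decoder with skip connections,
// trained per session to reconstruct normalized open-eye frames from
// closed-eye (or forehead control) frames under an MAE loss.
//
// Layout: a feature map is an arma::mat of size channels x (H*W), pixels
// column-major (p = row + col*H), matching R's matrix vectorization.
// Convolutions are 3x3 same-padding via im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col3(const mat& F, int H, int W, mat& K) {
  const int c = F.n_rows;
  K.zeros(9 * c, H * W);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      const int j0 = std::max(0, -dc), j1 = W - 1 - std::max(0, dc);
      const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      if (j1 < j0 || r1 < r0) continue;
      const int len = r1 - r0 + 1;
      for (int j = j0; j <= j1; ++j) {
        const int pdst = r0 + j * H;
        const int psrc = (r0 + dr) + (j + dc) * H;
        K.submat(k * c, pdst, (k + 1) * c - 1, pdst + len - 1) =
          F.cols(psrc, psrc + len - 1);
      }
    }
  }
}

static void col2im3(const mat& dK, int H, int W, int c, mat& dF) {
  dF.zeros(c, H * W);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr, ++k) {
      const int j0 = std::max(0, -dc), j1 = W - 1 - std::max(0, dc);
      const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      if (j1 < j0 || r1 < r0) continue;
      const int len = r1 - r0 + 1;
      for (int j = j0; j <= j1; ++j) {
        const int pdst = r0 + j * H;
        const int psrc = (r0 + dr) + (j + dc) * H;
        dF.cols(psrc, psrc + len - 1) +=
          dK.submat(k * c, pdst, (k + 1) * c - 1, pdst + len - 1);
      }
    }
  }
}

static mat avgpool2(const mat& F, int H, int W) {
  const int H2 = H / 2, W2 = W / 2, c = F.n_rows;
  mat out(c, H2 * W2);
  for (int j = 0; j < W2; ++j) {
    for (int i = 0; i < H2; ++i) {
      const int p00 = 2 * i + 2 * j * H;
      out.col(i + j * H2) =
        0.25 * (F.col(p00) + F.col(p00 + 1) + F.col(p00 + H) + F.col(p00 + H + 1));
    }
  }
  return out;
}

static mat avgpool2_back(const mat& dOut, int H, int W) {
  const int H2 = H / 2, W2 = W / 2, c = dOut.n_rows;
  mat dF(c, H * W, fill::zeros);
  for (int j = 0; j < W2; ++j) {
    for (int i = 0; i < H2; ++i) {
      const vec g = 0.25 * dOut.col(i + j * H2);
      const int p00 = 2 * i + 2 * j * H;
      dF.col(p00) += g; dF.col(p00 + 1) += g;
      dF.col(p00 + H) += g; dF.col(p00 + H + 1) += g;
    }
  }
  return dF;
}

static mat upsample2(const mat& F, int H2, int W2) {
  const int H = 2 * H2, W = 2 * W2, c = F.n_rows;
  mat out(c, H * W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out.col(i + j * H) = F.col((i / 2) + (j / 2) * H2);
  return out;
}

static mat upsample2_back(const mat& dOut, int H2, int W2) {
  const int H = 2 * H2, W = 2 * W2, c = dOut.n_rows;
  mat dF(c, H2 * W2, fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      dF.col((i / 2) + (j / 2) * H2) += dOut.col(i + j * H);
  return dF;
}

struct Net {
  int H, W, c1, c2, c3;
  mat W1, W2, W3, W4, W5, Wout;
  vec b1, b2, b3, b4, b5, bout;

  std::vector<mat*> wparams() { return {&W1, &W2, &W3, &W4, &W5, &Wout}; }
  std::vector<vec*> bparams() { return {&b1, &b2, &b3, &b4, &b5, &bout}; }

  void init(std::mt19937& rng) {
    auto he = [&](mat& M, int fan_in) {
      std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / fan_in));
      M.for_each([&](double& v) { v = nd(rng); });
    };
    W1.set_size(c1, 9);             he(W1, 9);
    W2.set_size(c2, 9 * c1);        he(W2, 9 * c1);
    W3.set_size(c3, 9 * c2);        he(W3, 9 * c2);
    W4.set_size(c2, 9 * (c3 + c2)); he(W4, 9 * (c3 + c2));
    W5.set_size(c1, 9 * (c2 + c1)); he(W5, 9 * (c2 + c1));
    Wout.set_size(1, c1 + 1);       he(Wout, c1 + 1);
    b1.zeros(c1); b2.zeros(c2); b3.zeros(c3);
    b4.zeros(c2); b5.zeros(c1); bout.zeros(1);
  }
};

struct Cache {
  mat a0, K1, a1, p1, K2, a2, p2, K3, a3, u2, cat2, K4, a4, u1, cat1, K5, a5, catout, yhat;
};

static mat relu(mat x) {
  x.elem(find(x < 0)).zeros();
  return x;
}

static mat relu_mask(const mat& a) {
  return conv_to<mat>::from(a > 0.0);
}

static mat conv_fwd(const mat& F, int H, int W, const mat& Wm, const vec& b, mat& K) {
  im2col3(F, H, W, K);
  mat out = Wm * K;
  out.each_col() += b;
  return out;
}

static void forward(const Net& net, const mat& x, Cache& c) {
  const int H = net.H, W = net.W, H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  c.a0 = x;
  c.a1 = relu(conv_fwd(c.a0, H, W, net.W1, net.b1, c.K1));
  c.p1 = avgpool2(c.a1, H, W);
  c.a2 = relu(conv_fwd(c.p1, H2, W2, net.W2, net.b2, c.K2));
  c.p2 = avgpool2(c.a2, H2, W2);
  c.a3 = relu(conv_fwd(c.p2, H4, W4, net.W3, net.b3, c.K3));
  c.u2 = upsample2(c.a3, H4, W4);
  c.cat2 = join_cols(c.u2, c.a2);
  c.a4 = relu(conv_fwd(c.cat2, H2, W2, net.W4, net.b4, c.K4));
  c.u1 = upsample2(c.a4, H2, W2);
  c.cat1 = join_cols(c.u1, c.a1);
  c.a5 = relu(conv_fwd(c.cat1, H, W, net.W5, net.b5, c.K5));
  c.catout = join_cols(c.a5, c.a0);
  c.yhat = net.Wout * c.catout;
  c.yhat.each_col() += net.bout;
}

// Accumulates gradients for one frame into g; returns the frame's MAE.
static double backward(const Net& net, Cache& c, const mat& y, Net& g) {
  const int H = net.H, W = net.W, H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  const double n = c.yhat.n_elem;
  mat diff = c.yhat - y;
  double mae = accu(abs(diff)) / n;
  mat dy = sign(diff) / n;

  g.Wout += dy * c.catout.t();
  g.bout += sum(dy, 1);
  mat dcatout = net.Wout.t() * dy;
  mat da5 = dcatout.rows(0, net.c1 - 1) % relu_mask(c.a5);
  // dcatout last row feeds a0 (input): no parameters upstream of it.
  g.W5 += da5 * c.K5.t();
  g.b5 += sum(da5, 1);
  mat dK5 = net.W5.t() * da5;
  mat dcat1; col2im3(dK5, H, W, net.c2 + net.c1, dcat1);
  mat du1 = dcat1.rows(0, net.c2 - 1);
  mat da1 = dcat1.rows(net.c2, net.c2 + net.c1 - 1);
  mat da4 = upsample2_back(du1, H2, W2) % relu_mask(c.a4);
  g.W4 += da4 * c.K4.t();
  g.b4 += sum(da4, 1);
  mat dK4 = net.W4.t() * da4;
  mat dcat2; col2im3(dK4, H2, W2, net.c3 + net.c2, dcat2);
  mat du2 = dcat2.rows(0, net.c3 - 1);
  mat da2_skip = dcat2.rows(net.c3, net.c3 + net.c2 - 1);
  mat da3 = upsample2_back(du2, H4, W4) % relu_mask(c.a3);
  g.W3 += da3 * c.K3.t();
  g.b3 += sum(da3, 1);
  mat dK3 = net.W3.t() * da3;
  mat dp2; col2im3(dK3, H4, W4, net.c2, dp2);
  mat da2 = (avgpool2_back(dp2, H2, W2) + da2_skip) % relu_mask(c.a2);
  g.W2 += da2 * c.K2.t();
  g.b2 += sum(da2, 1);
  mat dK2 = net.W2.t() * da2;
  mat dp1; col2im3(dK2, H2, W2, net.c1, dp1);
  da1 = (avgpool2_back(dp1, H, W) + da1) % relu_mask(c.a1);
  g.W1 += da1 * c.K1.t();
  g.b1 += sum(da1, 1);
  return mae;
}

static Rcpp::List net_to_list(const Net& net) {
  return Rcpp::List::create(
    Rcpp::Named("H") = net.H, Rcpp::Named("W") = net.W,
    Rcpp::Named("c1") = net.c1, Rcpp::Named("c2") = net.c2, Rcpp::Named("c3") = net.c3,
    Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
    Rcpp::Named("W2") = net.W2, Rcpp::Named("b2") = net.b2,
    Rcpp::Named("W3") = net.W3, Rcpp::Named("b3") = net.b3,
    Rcpp::Named("W4") = net.W4, Rcpp::Named("b4") = net.b4,
    Rcpp::Named("W5") = net.W5, Rcpp::Named("b5") = net.b5,
    Rcpp::Named("Wout") = net.Wout, Rcpp::Named("bout") = net.bout);
}

static Net net_from_list(const Rcpp::List& l) {
  Net net;
  net.H = l["H"]; net.W = l["W"];
  net.c1 = l["c1"]; net.c2 = l["c2"]; net.c3 = l["c3"];
  net.W1 = Rcpp::as<mat>(l["W1"]); net.b1 = Rcpp::as<vec>(l["b1"]);
  net.W2 = Rcpp::as<mat>(l["W2"]); net.b2 = Rcpp::as<vec>(l["b2"]);
  net.W3 = Rcpp::as<mat>(l["W3"]); net.b3 = Rcpp::as<vec>(l["b3"]);
  net.W4 = Rcpp::as<mat>(l["W4"]); net.b4 = Rcpp::as<vec>(l["b4"]);
  net.W5 = Rcpp::as<mat>(l["W5"]); net.b5 = Rcpp::as<vec>(l["b5"]);
  net.Wout = Rcpp::as<mat>(l["Wout"]); net.bout = Rcpp::as<vec>(l["bout"]);
  return net;
}

// [[Rcpp::export(name = ".unet_train_cpp")]]
Rcpp::List unet_train_cpp(const arma::cube& X, const arma::cube& Y,
                          const arma::uvec& train_idx, const arma::uvec& val_idx,
                          int c1, int c2, int c3,
                          int max_epochs, int patience, double lr,
                          int batch_size, int seed) {
  const int H = X.n_rows, W = X.n_cols;
  if (Y.n_rows != X.n_rows || Y.n_cols != X.n_cols || Y.n_slices != X.n_slices)
    Rcpp::stop("input and target stacks have mismatching shapes");
  if (H % 4 != 0 || W % 4 != 0)
    Rcpp::stop("frame size must be divisible by 4 (two pooling levels)");
  if (train_idx.n_elem == 0 || val_idx.n_elem == 0)
    Rcpp::stop("empty training or validation set");
  if (max_epochs < patience || patience < 1)
    Rcpp::stop("need max_epochs >= patience >= 1");

  std::mt19937 rng(seed);
  Net net; net.H = H; net.W = W; net.c1 = c1; net.c2 = c2; net.c3 = c3;
  net.init(rng);
  Net g = net, m = net, v = net;  // gradient and Adam moments (same shapes)
  auto zero_all = [](Net& n) {
    for (mat* p : n.wparams()) p->zeros();
    for (vec* p : n.bparams()) p->zeros();
  };
  zero_all(m); zero_all(v);

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long adam_t = 0;
  Cache c;
  std::vector<uword> order(train_idx.begin(), train_idx.end());
  std::vector<double> train_log, val_log;
  Net best = net;
  double best_val = datum::inf;
  int best_epoch = -1, epochs_run = 0;

  auto frame = [&](const cube& Z, uword i) { return mat(Z.slice(i).memptr(), 1, H * W); };

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_mae = 0.0;
    size_t done = 0;
    while (done < order.size()) {
      size_t bsz = std::min<size_t>(batch_size, order.size() - done);
      zero_all(g);
      for (size_t b = 0; b < bsz; ++b) {
        uword i = order[done + b];
        forward(net, frame(X, i), c);
        tr_mae += backward(net, c, frame(Y, i), g);
      }
      done += bsz;
      // Adam step on batch-averaged gradients
      ++adam_t;
      const double bc1 = 1.0 - std::pow(beta1, adam_t);
      const double bc2 = 1.0 - std::pow(beta2, adam_t);
      auto wp = net.wparams(); auto gp = g.wparams();
      auto mp = m.wparams(); auto vp = v.wparams();
      for (size_t k = 0; k < wp.size(); ++k) {
        mat grad = *gp[k] / double(bsz);
        *mp[k] = beta1 * *mp[k] + (1 - beta1) * grad;
        *vp[k] = beta2 * *vp[k] + (1 - beta2) * square(grad);
        *wp[k] -= lr * (*mp[k] / bc1) / (sqrt(*vp[k] / bc2) + eps);
      }
      auto wb = net.bparams(); auto gb = g.bparams();
      auto mb = m.bparams(); auto vb = v.bparams();
      for (size_t k = 0; k < wb.size(); ++k) {
        vec grad = *gb[k] / double(bsz);
        *mb[k] = beta1 * *mb[k] + (1 - beta1) * grad;
        *vb[k] = beta2 * *vb[k] + (1 - beta2) * square(grad);
        *wb[k] -= lr * (*mb[k] / bc1) / (sqrt(*vb[k] / bc2) + eps);
      }
    }
    tr_mae /= order.size();
    if (!std::isfinite(tr_mae))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", epoch + 1);
    double va_mae = 0.0;
    for (uword i : val_idx) {
      forward(net, frame(X, i), c);
      va_mae += accu(abs(c.yhat - frame(Y, i))) / c.yhat.n_elem;
    }
    va_mae /= val_idx.n_elem;
    train_log.push_back(tr_mae);
    val_log.push_back(va_mae);
    epochs_run = epoch + 1;
    if (va_mae < best_val) {
      best_val = va_mae;
      best = net;
      best_epoch = epoch + 1;
    } else if (epoch + 1 - best_epoch >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List w = net_to_list(best);
  return Rcpp::List::create(
    Rcpp::Named("weights") = w,
    Rcpp::Named("train_mae") = train_log,
    Rcpp::Named("val_mae") = val_log,
    Rcpp::Named("epochs_run") = epochs_run,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_mae") = best_val);
}

// [[Rcpp::export(name = ".unet_predict_cpp")]]
arma::cube unet_predict_cpp(const Rcpp::List& weights, const arma::cube& X) {
  Net net = net_from_list(weights);
  if ((int)X.n_rows != net.H || (int)X.n_cols != net.W)
    Rcpp::stop("frame geometry (%dx%d) does not match the trained model (%dx%d)",
               X.n_rows, X.n_cols, net.H, net.W);
  cube out(X.n_rows, X.n_cols, X.n_slices);
  Cache c;
  for (uword i = 0; i < X.n_slices; ++i) {
    mat x(X.slice(i).memptr(), 1, net.H * net.W);
    forward(net, x, c);
    out.slice(i) = reshape(c.yhat, net.H, net.W);
  }
  return out;
}
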