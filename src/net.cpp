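// Compact 1D convolutional networks (residual net, MLP, deep CNN baseline)
// with hand-written forward/backward passes and an Adam optimizer.
// Activations are stored as C x (B*L) matrices, column-major; sample b
// occupies columns [b*L, (b+1)*L).

#include <RcppArmadillo.h>
#include <random>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

struct Act {
  mat a;
  uword C = 0, L = 0, B = 0;
};

struct Layer {
  virtual ~Layer() {}
  virtual Act forward(const Act& x) = 0;
  virtual Act backward(const Act& g) = 0;
  virtual void collect(std::vector<mat*>& p, std::vector<mat*>& g) {}
};

static uword conv_out_len(uword Lin, uword k, uword s, uword pad) {
  return (Lin + 2 * pad - k) / s + 1;
}

struct Conv1d : Layer {
  uword cin, cout, k, s, pad;
  mat W, dW, b, db;
  mat col;
  uword Lin = 0, Lout = 0, B = 0;
  std::vector<sword> gidx;
  uword gidx_Lin = (uword)-1;

  Conv1d(uword cin_, uword cout_, uword k_, uword s_, uword pad_,
         std::mt19937_64& rng)
      : cin(cin_), cout(cout_), k(k_), s(s_), pad(pad_) {
    const double sd = std::sqrt(2.0 / (double)(cin * k));
    std::normal_distribution<double> nd(0.0, sd);
    W.set_size(cout, cin * k);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
    b.zeros(cout, 1);
    dW.zeros(cout, cin * k);
    db.zeros(cout, 1);
  }

  void build_gidx(uword Lin_) {
    if (gidx_Lin == Lin_) return;
    Lout = conv_out_len(Lin_, k, s, pad);
    gidx.assign((size_t)cin * k * Lout, -1);
    for (uword t = 0; t < Lout; ++t) {
      const sword start = (sword)(t * s) - (sword)pad;
      for (uword c = 0; c < cin; ++c)
        for (uword kk = 0; kk < k; ++kk) {
          const sword ii = start + (sword)kk;
          gidx[(size_t)t * cin * k + c * k + kk] =
              (ii >= 0 && ii < (sword)Lin_) ? (sword)(c * Lin_ + ii) : -1;
        }
    }
    gidx_Lin = Lin_;
  }

  Act forward(const Act& x) override {
    Lin = x.L;
    B = x.B;
    build_gidx(Lin);
    col.set_size(cin * k, B * Lout);
    const uword rk = cin * k;
    for (uword bi = 0; bi < B; ++bi) {
      for (uword t = 0; t < Lout; ++t) {
        double* cp = col.colptr(bi * Lout + t);
        const size_t base = (size_t)t * rk;
        for (uword r = 0; r < rk; ++r) {
          const sword g = gidx[base + r];
          cp[r] = (g < 0) ? 0.0 : x.a(g / Lin, bi * Lin + g % Lin);
        }
      }
    }
    Act y;
    y.C = cout;
    y.L = Lout;
    y.B = B;
    y.a = W * col;
    y.a.each_col() += b.col(0);
    return y;
  }

  Act backward(const Act& gy) override {
    dW += gy.a * col.t();
    db.col(0) += sum(gy.a, 1);
    mat dcol = W.t() * gy.a;
    Act gx;
    gx.C = cin;
    gx.L = Lin;
    gx.B = B;
    gx.a.zeros(cin, B * Lin);
    const uword rk = cin * k;
    for (uword bi = 0; bi < B; ++bi)
      for (uword t = 0; t < Lout; ++t) {
        const double* cp = dcol.colptr(bi * Lout + t);
        const size_t base = (size_t)t * rk;
        for (uword r = 0; r < rk; ++r) {
          const sword g = gidx[base + r];
          if (g >= 0) gx.a(g / Lin, bi * Lin + g % Lin) += cp[r];
        }
      }
    return gx;
  }

  void collect(std::vector<mat*>& p, std::vector<mat*>& g) override {
    p.push_back(&W);
    g.push_back(&dW);
    p.push_back(&b);
    g.push_back(&db);
  }
};

struct ReLU : Layer {
  mat mask;
  Act forward(const Act& x) override {
    mask = conv_to<mat>::from(x.a > 0);
    Act y = x;
    y.a %= mask;
    return y;
  }
  Act backward(const Act& g) override {
    Act gx = g;
    gx.a %= mask;
    return gx;
  }
};

struct MaxPool2 : Layer {  // kernel 2, stride 2
  uword Lin = 0, Lout = 0, B = 0, C = 0;
  umat arg;  // C x (B*Lout): winning source column offset (0 or 1)
  Act forward(const Act& x) override {
    Lin = x.L;
    B = x.B;
    C = x.C;
    Lout = Lin / 2;
    Act y;
    y.C = C;
    y.L = Lout;
    y.B = B;
    y.a.set_size(C, B * Lout);
    arg.set_size(C, B * Lout);
    for (uword bi = 0; bi < B; ++bi)
      for (uword t = 0; t < Lout; ++t) {
        const uword j0 = bi * Lin + 2 * t;
        const uword jo = bi * Lout + t;
        for (uword c = 0; c < C; ++c) {
          const double v0 = x.a(c, j0), v1 = x.a(c, j0 + 1);
          if (v0 >= v1) {
            y.a(c, jo) = v0;
            arg(c, jo) = 0;
          } else {
            y.a(c, jo) = v1;
            arg(c, jo) = 1;
          }
        }
      }
    return y;
  }
  Act backward(const Act& g) override {
    Act gx;
    gx.C = C;
    gx.L = Lin;
    gx.B = B;
    gx.a.zeros(C, B * Lin);
    for (uword bi = 0; bi < B; ++bi)
      for (uword t = 0; t < Lout; ++t) {
        const uword jo = bi * Lout + t;
        for (uword c = 0; c < C; ++c)
          gx.a(c, bi * Lin + 2 * t + arg(c, jo)) += g.a(c, jo);
      }
    return gx;
  }
};

struct GAP : Layer {
  uword Lin = 0, B = 0, C = 0;
  Act forward(const Act& x) override {
    Lin = x.L;
    B = x.B;
    C = x.C;
    Act y;
    y.C = C;
    y.L = 1;
    y.B = B;
    y.a.set_size(C, B);
    for (uword bi = 0; bi < B; ++bi)
      y.a.col(bi) = mean(x.a.cols(bi * Lin, (bi + 1) * Lin - 1), 1);
    return y;
  }
  Act backward(const Act& g) override {
    Act gx;
    gx.C = C;
    gx.L = Lin;
    gx.B = B;
    gx.a.set_size(C, B * Lin);
    for (uword bi = 0; bi < B; ++bi)
      gx.a.cols(bi * Lin, (bi + 1) * Lin - 1) =
          repmat(g.a.col(bi) / (double)Lin, 1, Lin);
    return gx;
  }
};

struct Linear : Layer {
  uword in, out;
  mat W, dW, b, db;
  mat Xf;
  uword C = 0, L = 0, B = 0;
  Linear(uword in_, uword out_, std::mt19937_64& rng) : in(in_), out(out_) {
    const double sd = std::sqrt(2.0 / (double)in);
    std::normal_distribution<double> nd(0.0, sd);
    W.set_size(out, in);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
    b.zeros(out, 1);
    dW.zeros(out, in);
    db.zeros(out, 1);
  }
  Act forward(const Act& x) override {
    C = x.C;
    L = x.L;
    B = x.B;
    if (C * L != in) Rcpp::stop("linear layer: input size mismatch");
    Xf.set_size(in, B);
    for (uword bi = 0; bi < B; ++bi)
      Xf.col(bi) = vectorise(x.a.cols(bi * L, (bi + 1) * L - 1));
    Act y;
    y.C = out;
    y.L = 1;
    y.B = B;
    y.a = W * Xf;
    y.a.each_col() += b.col(0);
    return y;
  }
  Act backward(const Act& g) override {
    dW += g.a * Xf.t();
    db.col(0) += sum(g.a, 1);
    mat dx = W.t() * g.a;  // in x B
    Act gx;
    gx.C = C;
    gx.L = L;
    gx.B = B;
    gx.a.set_size(C, B * L);
    for (uword bi = 0; bi < B; ++bi)
      gx.a.cols(bi * L, (bi + 1) * L - 1) = reshape(dx.col(bi), C, L);
    return gx;
  }
  void collect(std::vector<mat*>& p, std::vector<mat*>& g) override {
    p.push_back(&W);
    g.push_back(&dW);
    p.push_back(&b);
    g.push_back(&db);
  }
};

struct ResBlock : Layer {
  std::unique_ptr<Conv1d> c1, c2, cp;
  mat mask1, mask2;
  bool proj;
  ResBlock(uword cin, uword cout, uword stride, std::mt19937_64& rng) {
    c1.reset(new Conv1d(cin, cout, 3, stride, 1, rng));
    c2.reset(new Conv1d(cout, cout, 3, 1, 1, rng));
    proj = (stride != 1 || cin != cout);
    if (proj) cp.reset(new Conv1d(cin, cout, 1, stride, 0, rng));
  }
  Act forward(const Act& x) override {
    Act h = c1->forward(x);
    mask1 = conv_to<mat>::from(h.a > 0);
    h.a %= mask1;
    Act h2 = c2->forward(h);
    Act s = proj ? cp->forward(x) : x;
    h2.a += s.a;
    mask2 = conv_to<mat>::from(h2.a > 0);
    h2.a %= mask2;
    return h2;
  }
  Act backward(const Act& g) override {
    Act gy = g;
    gy.a %= mask2;
    Act gh = c2->backward(gy);
    gh.a %= mask1;
    Act gx1 = c1->backward(gh);
    Act gskip = proj ? cp->backward(gy) : gy;
    gx1.a += gskip.a;
    return gx1;
  }
  void collect(std::vector<mat*>& p, std::vector<mat*>& g) override {
    c1->collect(p, g);
    c2->collect(p, g);
    if (proj) cp->collect(p, g);
  }
};

struct Net {
  std::vector<std::unique_ptr<Layer>> layers;
  std::vector<mat*> params, grads;
  uword input_len = 0;

  void finish() {
    params.clear();
    grads.clear();
    for (auto& l : layers) l->collect(params, grads);
  }

  void build(const List& arch, std::mt19937_64& rng) {
    const std::string type = Rcpp::as<std::string>(arch["type"]);
    input_len = Rcpp::as<uword>(arch["input_len"]);
    if (type == "resnet1d") {
      const ivec channels = Rcpp::as<ivec>(arch["channels"]);
      const ivec blocks = Rcpp::as<ivec>(arch["blocks"]);
      const uword k0 = Rcpp::as<uword>(arch["initial_kernel"]);
      if (channels.n_elem != blocks.n_elem)
        Rcpp::stop("channels and blocks must have equal length");
      layers.emplace_back(new Conv1d(1, channels(0), k0, 2, k0 / 2, rng));
      layers.emplace_back(new ReLU());
      uword cin = channels(0);
      for (uword st = 0; st < channels.n_elem; ++st) {
        for (sword bl = 0; bl < blocks(st); ++bl) {
          const uword stride = (bl == 0 && st > 0) ? 2 : 1;
          layers.emplace_back(new ResBlock(cin, channels(st), stride, rng));
          cin = channels(st);
        }
      }
      layers.emplace_back(new GAP());
      layers.emplace_back(new Linear(cin, 2, rng));
    } else if (type == "mlp") {
      const ivec dims = Rcpp::as<ivec>(arch["mlp_dims"]);
      uword in = input_len;
      for (uword i = 0; i < dims.n_elem; ++i) {
        layers.emplace_back(new Linear(in, dims(i), rng));
        if (i + 1 < dims.n_elem) layers.emplace_back(new ReLU());
        in = dims(i);
      }
    } else if (type == "vdcnn1d") {
      const ivec channels = Rcpp::as<ivec>(arch["channels"]);
      layers.emplace_back(new Conv1d(1, channels(0), 3, 1, 1, rng));
      layers.emplace_back(new ReLU());
      uword cin = channels(0);
      for (uword st = 0; st < channels.n_elem; ++st) {
        layers.emplace_back(new Conv1d(cin, channels(st), 3, 1, 1, rng));
        layers.emplace_back(new ReLU());
        layers.emplace_back(new Conv1d(channels(st), channels(st), 3, 1, 1, rng));
        layers.emplace_back(new ReLU());
        cin = channels(st);
        layers.emplace_back(new MaxPool2());
      }
      layers.emplace_back(new GAP());
      layers.emplace_back(new Linear(cin, 2, rng));
    } else {
      Rcpp::stop("unknown architecture: " + type);
    }
    finish();
  }

  mat forward_logits(const mat& X, const uvec& idx) {
    const uword B = idx.n_elem;
    Act a;
    a.C = 1;
    a.L = X.n_cols;
    a.B = B;
    a.a.set_size(1, B * a.L);
    for (uword bi = 0; bi < B; ++bi)
      a.a.cols(bi * a.L, (bi + 1) * a.L - 1) = X.row(idx(bi));
    for (auto& l : layers) a = l->forward(a);
    return a.a;  // 2 x B
  }

  void backward_from(const mat& dlogits, uword B, uword L) {
    Act g;
    g.C = 2;
    g.L = 1;
    g.B = B;
    g.a = dlogits;
    for (size_t i = layers.size(); i-- > 0;) g = layers[i]->backward(g);
  }

  void zero_grad() {
    for (mat* g : grads) g->zeros();
  }

  List get_weights() const {
    List out(params.size());
    for (size_t i = 0; i < params.size(); ++i) out[i] = Rcpp::wrap(*params[i]);
    return out;
  }

  void set_weights(const List& w) {
    if ((size_t)w.size() != params.size())
      Rcpp::stop("weight list does not match architecture");
    for (size_t i = 0; i < params.size(); ++i) {
      mat wi = Rcpp::as<mat>(w[i]);
      if (wi.n_rows != params[i]->n_rows || wi.n_cols != params[i]->n_cols)
        Rcpp::stop("weight shape mismatch at parameter " +
                   std::to_string(i + 1));
      *params[i] = wi;
    }
  }
};

static mat softmax_cols(const mat& z) {
  mat p = z;
  p.each_row() -= max(p, 0);
  p = exp(p);
  p.each_row() /= sum(p, 0);
  return p;
}

// [[Rcpp::export]]
List cpp_train_net(List arch, arma::mat X, arma::ivec y, arma::mat Xval,
                   arma::ivec yval, int epochs, int batch, double lr,
                   int seed) {
  if (X.n_rows != y.n_elem) Rcpp::stop("X/y size mismatch");
  if (Xval.n_rows == 0) Rcpp::stop("validation set is empty");
  std::mt19937_64 rng((uint64_t)seed);
  Net net;
  net.build(arch, rng);
  if (X.n_cols != net.input_len) Rcpp::stop("input length mismatch");

  std::vector<mat> m(net.params.size()), v(net.params.size());
  for (size_t i = 0; i < net.params.size(); ++i) {
    m[i].zeros(net.params[i]->n_rows, net.params[i]->n_cols);
    v[i].zeros(net.params[i]->n_rows, net.params[i]->n_cols);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  const uword n = X.n_rows;
  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  auto eval_acc = [&](const mat& Xe, const ivec& ye) {
    uword correct = 0;
    for (uword start = 0; start < Xe.n_rows; start += 256) {
      const uword end = std::min<uword>(start + 256, Xe.n_rows);
      uvec idx = regspace<uvec>(start, end - 1);
      mat logits = net.forward_logits(Xe, idx);
      for (uword bi = 0; bi < idx.n_elem; ++bi) {
        const int pred = logits(1, bi) > logits(0, bi) ? 1 : 0;
        if (pred == ye(idx(bi))) ++correct;
      }
    }
    return (double)correct / (double)Xe.n_rows;
  };

  std::vector<double> log_loss, log_tracc, log_vacc;
  double best_vacc = -1.0;
  int best_epoch = -1;
  List best_w;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0;
    uword ep_correct = 0;
    for (uword start = 0; start < n; start += (uword)batch) {
      const uword end = std::min<uword>(start + batch, n);
      const uword B = end - start;
      uvec idx(B);
      for (uword i = 0; i < B; ++i) idx(i) = order[start + i];
      net.zero_grad();
      mat logits = net.forward_logits(X, idx);
      mat p = softmax_cols(logits);
      mat dlogits = p;
      for (uword bi = 0; bi < B; ++bi) {
        const int yi = y(idx(bi));
        ep_loss += -std::log(std::max(p(yi, bi), 1e-12));
        dlogits(yi, bi) -= 1.0;
        const int pred = logits(1, bi) > logits(0, bi) ? 1 : 0;
        if (pred == yi) ++ep_correct;
      }
      dlogits /= (double)B;
      net.backward_from(dlogits, B, X.n_cols);
      ++step;
      const double corr = std::sqrt(1.0 - std::pow(b2, (double)step)) /
                          (1.0 - std::pow(b1, (double)step));
      for (size_t i = 0; i < net.params.size(); ++i) {
        m[i] = b1 * m[i] + (1 - b1) * (*net.grads[i]);
        v[i] = b2 * v[i] + (1 - b2) * square(*net.grads[i]);
        *net.params[i] -= lr * corr * m[i] / (sqrt(v[i]) + eps);
      }
    }
    const double vacc = eval_acc(Xval, yval);
    log_loss.push_back(ep_loss / (double)n);
    log_tracc.push_back((double)ep_correct / (double)n);
    log_vacc.push_back(vacc);
    if (vacc > best_vacc) {
      best_vacc = vacc;
      best_epoch = ep + 1;
      best_w = net.get_weights();
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      Rcpp::Named("weights") = best_w,
      Rcpp::Named("final_weights") = net.get_weights(),
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_accuracy") = best_vacc,
      Rcpp::Named("log") = Rcpp::DataFrame::create(
          Rcpp::Named("epoch") = Rcpp::seq(1, epochs),
          Rcpp::Named("train_loss") = log_loss,
          Rcpp::Named("train_accuracy") = log_tracc,
          Rcpp::Named("val_accuracy") = log_vacc));
}

// [[Rcpp::export]]
arma::mat cpp_predict_net(List arch, List weights, arma::mat X, int batch) {
  std::mt19937_64 rng(1);
  Net net;
  net.build(arch, rng);
  if (X.n_cols != net.input_len) Rcpp::stop("input length mismatch");
  net.set_weights(weights);
  mat out(X.n_rows, 2);
  for (uword start = 0; start < X.n_rows; start += (uword)batch) {
    const uword end = std::min<uword>(start + (uword)batch, X.n_rows);
    uvec idx = regspace<uvec>(start, end - 1);
    mat p = softmax_cols(net.forward_logits(X, idx));
    out.rows(start, end - 1) = p.t();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_init_net(List arch, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  Net net;
  net.build(arch, rng);
  return net.get_weights();
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_param_shapes(List arch) {
  std::mt19937_64 rng(1);
  Net net;
  net.build(arch, rng);
  Rcpp::IntegerVector out(net.params.size());
  for (size_t i = 0; i < net.params.size(); ++i)
    out[i] = (int)net.params[i]->n_elem;
  return out;
}
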