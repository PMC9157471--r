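// Four-layer bidirectional LSTM sequence classifier:
//   embedding -> dropout -> bidirectional LSTM -> dense softmax
// Trained with categorical cross-entropy and Adam via full BPTT.
// Single precision throughout; all randomness (init, shuffling, dropout)
// comes from one std::mt19937 seeded from R, so runs are bit-reproducible
// for a given seed on a given platform.
//
// Layout note: embeddings are kept as a flat (B*T x d) matrix, time-major
// (rows [t*B, t*B+B) hold timestep t), so the input projections of all
// timesteps are a single GEMM; only the recurrent matrix products remain
// per-timestep.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>

using namespace arma;

struct Dir { fmat wx, wh, b; };          // b is 1 x 4u
struct Net {
  fmat emb;                              // 5 x d (row 0 reserved padding idx)
  Dir fwd, bwd;
  fmat wout, bout;                       // 2u x nc, 1 x nc
  int d, u, nc;
};

static fmat as_f(const Rcpp::NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = static_cast<float>(m(i, j));
  return out;
}

static imat as_i(const Rcpp::IntegerMatrix& m) {
  imat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = m(i, j);
  return out;
}

static Rcpp::NumericMatrix as_r(const fmat& m) {
  mat dm = conv_to<mat>::from(m);
  return Rcpp::wrap(dm);
}

static Net net_from_list(const Rcpp::List& w) {
  Net n;
  n.emb = as_f(w["emb"]);
  n.fwd.wx = as_f(w["wx_f"]); n.fwd.wh = as_f(w["wh_f"]); n.fwd.b = as_f(w["b_f"]);
  n.bwd.wx = as_f(w["wx_b"]); n.bwd.wh = as_f(w["wh_b"]); n.bwd.b = as_f(w["b_b"]);
  n.wout = as_f(w["w_out"]); n.bout = as_f(w["b_out"]);
  n.d = n.emb.n_cols; n.u = n.fwd.wh.n_rows; n.nc = n.wout.n_cols;
  return n;
}

static Rcpp::List net_to_list(const Net& n) {
  return Rcpp::List::create(
    Rcpp::Named("emb") = as_r(n.emb),
    Rcpp::Named("wx_f") = as_r(n.fwd.wx), Rcpp::Named("wh_f") = as_r(n.fwd.wh),
    Rcpp::Named("b_f") = as_r(n.fwd.b),
    Rcpp::Named("wx_b") = as_r(n.bwd.wx), Rcpp::Named("wh_b") = as_r(n.bwd.wh),
    Rcpp::Named("b_b") = as_r(n.bwd.b),
    Rcpp::Named("w_out") = as_r(n.wout), Rcpp::Named("b_out") = as_r(n.bout));
}

static fmat glorot(int nr, int nc, std::mt19937& rng) {
  float lim = std::sqrt(6.0f / (nr + nc));
  std::uniform_real_distribution<float> un(-lim, lim);
  fmat m(nr, nc);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = un(rng);
  return m;
}

// Orthogonal init for recurrent kernels: one u x u orthogonal block per
// gate (QR of a random normal matrix, sign-corrected), preserving gradient
// norms through long unrolls.
static fmat orthogonal_gates(int u, int n_gates, std::mt19937& rng) {
  std::normal_distribution<float> nd(0.0f, 1.0f);
  fmat out(u, n_gates * u);
  for (int gate = 0; gate < n_gates; ++gate) {
    fmat A(u, u);
    for (uword j = 0; j < A.n_cols; ++j)
      for (uword i = 0; i < A.n_rows; ++i) A(i, j) = nd(rng);
    fmat Q, R;
    qr_econ(Q, R, A);
    for (int j = 0; j < u; ++j) if (R(j, j) < 0) Q.col(j) *= -1.0f;
    out.cols(gate * u, (gate + 1) * u - 1) = Q;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_init_weights(int d, int u, int n_classes, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  Net n;
  n.d = d; n.u = u; n.nc = n_classes;
  std::uniform_real_distribution<float> emb_un(-0.05f, 0.05f);
  n.emb.set_size(5, d);
  for (uword j = 0; j < n.emb.n_cols; ++j)
    for (uword i = 0; i < n.emb.n_rows; ++i) n.emb(i, j) = emb_un(rng);
  for (Dir* dir : { &n.fwd, &n.bwd }) {
    dir->wx = glorot(d, 4 * u, rng);
    dir->wh = orthogonal_gates(u, 4, rng);
    dir->b = fmat(1, 4 * u, fill::zeros);
    dir->b.cols(u, 2 * u - 1).fill(1.0f);   // forget-gate bias init
  }
  n.wout = glorot(2 * u, n_classes, rng);
  n.bout = fmat(1, n_classes, fill::zeros);
  return net_to_list(n);
}

// Per-direction forward cache: gate activations, cell states and hidden
// states for every step (step index s, not timestep t).
struct Cache { fcube G; fcube C, TC, H; };   // G: B x 4u x T

// Embed rows [r0, r1) of X time-major into Eflat (B*T x d).
static void embed_flat(const Net& net, const imat& X, int r0, int r1,
                       fmat& Eflat) {
  const int B = r1 - r0, T = X.n_cols;
  Eflat.set_size(B * T, net.d);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b)
      Eflat.row(t * B + b) = net.emb.row(X(r0 + b, t));
}

// One direction over timestep order; Eflat is time-major (B*T x d).
// Returns the final hidden state; fills the cache when given.
static fmat run_dir(const Dir& dir, const fmat& Eflat, int B,
                    const std::vector<int>& order, int u, Cache* ca) {
  const int T = order.size();
  const fmat Zin = Eflat * dir.wx;       // all input projections at once
  fmat h(B, u, fill::zeros), c(B, u, fill::zeros);
  fmat z, tc;
  if (ca) {
    ca->G.set_size(B, 4 * u, T); ca->C.set_size(B, u, T);
    ca->TC.set_size(B, u, T); ca->H.set_size(B, u, T);
  }
  for (int s = 0; s < T; ++s) {
    const int t = order[s];
    z = Zin.rows(t * B, t * B + B - 1) + h * dir.wh;
    z.each_row() += dir.b.row(0);
    z.cols(0, 2 * u - 1) = 1.0f / (1.0f + exp(-z.cols(0, 2 * u - 1)));   // i,f
    z.cols(2 * u, 3 * u - 1) = tanh(z.cols(2 * u, 3 * u - 1));           // g
    z.cols(3 * u, 4 * u - 1) =
      1.0f / (1.0f + exp(-z.cols(3 * u, 4 * u - 1)));                    // o
    c = z.cols(u, 2 * u - 1) % c + z.cols(0, u - 1) % z.cols(2 * u, 3 * u - 1);
    tc = tanh(c);
    h = z.cols(3 * u, 4 * u - 1) % tc;
    if (ca) {
      ca->G.slice(s) = z; ca->C.slice(s) = c;
      ca->TC.slice(s) = tc; ca->H.slice(s) = h;
    }
  }
  return h;
}

struct DirGrad { fmat wx, wh, b; };

// Backpropagation through time for one direction. Accumulates parameter
// gradients into gd and embedding-input gradients into dEflat (time-major,
// same layout as Eflat).
static void bptt_dir(const Dir& dir, const Cache& ca, const fmat& Eflat,
                     int B, const std::vector<int>& order,
                     const fmat& dh_last, DirGrad& gd, fmat& dEflat) {
  const int T = order.size();
  const int u = dir.wh.n_rows;
  fmat dh = dh_last, dc(B, u, fill::zeros);
  fmat dz(B, 4 * u), do_, zeros_bu(B, u, fill::zeros);
  fmat dZflat(B * T, 4 * u);
  for (int s = T - 1; s >= 0; --s) {
    const int t = order[s];
    const fmat& z = ca.G.slice(s);
    const fmat& tc = ca.TC.slice(s);
    auto i = z.cols(0, u - 1);
    auto f = z.cols(u, 2 * u - 1);
    auto g = z.cols(2 * u, 3 * u - 1);
    auto o = z.cols(3 * u, 4 * u - 1);
    do_ = dh % tc;
    dc += dh % o % (1.0f - tc % tc);
    const fmat& c_prev = (s > 0) ? ca.C.slice(s - 1) : zeros_bu;
    const fmat& h_prev = (s > 0) ? ca.H.slice(s - 1) : zeros_bu;
    dz.cols(0, u - 1)         = (dc % g) % i % (1.0f - i);
    dz.cols(u, 2 * u - 1)     = (dc % c_prev) % f % (1.0f - f);
    dz.cols(2 * u, 3 * u - 1) = (dc % i) % (1.0f - g % g);
    dz.cols(3 * u, 4 * u - 1) = do_ % o % (1.0f - o);
    gd.wh += h_prev.t() * dz;
    dZflat.rows(t * B, t * B + B - 1) = dz;
    dh = dz * dir.wh.t();
    dc = dc % f;
  }
  gd.wx += Eflat.t() * dZflat;           // all input-weight grads at once
  gd.b += sum(dZflat, 0);
  dEflat += dZflat * dir.wx.t();
}

static void softmax_rows(fmat& z) {
  z.each_col() -= max(z, 1);
  z = exp(z);
  z.each_col() /= sum(z, 1);
}

static fmat forward_probs(const Net& net, const imat& X, int r0, int r1,
                          const std::vector<int>& ord_f,
                          const std::vector<int>& ord_b) {
  fmat Eflat;
  embed_flat(net, X, r0, r1, Eflat);
  const int B = r1 - r0;
  fmat hf = run_dir(net.fwd, Eflat, B, ord_f, net.u, nullptr);
  fmat hb = run_dir(net.bwd, Eflat, B, ord_b, net.u, nullptr);
  fmat logits = join_rows(hf, hb) * net.wout;
  logits.each_row() += net.bout.row(0);
  softmax_rows(logits);
  return logits;
}

static void time_orders(int T, std::vector<int>& ord_f,
                        std::vector<int>& ord_b) {
  ord_f.resize(T); ord_b.resize(T);
  for (int t = 0; t < T; ++t) { ord_f[t] = t; ord_b[t] = T - 1 - t; }
}

// Mean cross-entropy and argmax-accuracy over a full dataset, in chunks.
static void evaluate_net(const Net& net, const imat& X, const fmat& Y,
                         double* loss, double* acc) {
  const int n = X.n_rows, T = X.n_cols;
  std::vector<int> ord_f, ord_b;
  time_orders(T, ord_f, ord_b);
  double ls = 0.0; long correct = 0;
  const int chunk = 512;
  for (int r0 = 0; r0 < n; r0 += chunk) {
    int r1 = std::min(n, r0 + chunk);
    fmat P = forward_probs(net, X, r0, r1, ord_f, ord_b);
    fmat Yb = Y.rows(r0, r1 - 1);
    ls += accu(-Yb % log(P + 1e-8f));
    ucolvec pred = index_max(P, 1);
    ucolvec truth = index_max(Yb, 1);
    correct += accu(pred == truth);
  }
  *loss = ls / n;
  *acc = static_cast<double>(correct) / n;
}

struct Adam {
  std::vector<fmat> m, v;
  long t = 0;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  void init(const std::vector<fmat*>& ps) {
    for (fmat* p : ps) {
      m.push_back(fmat(p->n_rows, p->n_cols, fill::zeros));
      v.push_back(fmat(p->n_rows, p->n_cols, fill::zeros));
    }
  }
  void step(const std::vector<fmat*>& ps, const std::vector<fmat*>& gs,
            float lr) {
    ++t;
    float c1 = 1.0f - std::pow(b1, static_cast<float>(t));
    float c2 = 1.0f - std::pow(b2, static_cast<float>(t));
    for (size_t k = 0; k < ps.size(); ++k) {
      m[k] = b1 * m[k] + (1.0f - b1) * (*gs[k]);
      v[k] = b2 * v[k] + (1.0f - b2) * ((*gs[k]) % (*gs[k]));
      *ps[k] -= lr * (m[k] / c1) / (sqrt(v[k] / c2) + eps);
    }
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List weights, Rcpp::IntegerMatrix Xtr,
                     Rcpp::NumericMatrix Ytr, Rcpp::IntegerMatrix Xte,
                     Rcpp::NumericMatrix Yte, int max_epochs, int batch,
                     double lr, double dropout, int seed, bool early_stop,
                     int patience, double min_delta, double target_accuracy,
                     bool verbose) {
  Net net = net_from_list(weights);
  imat X = as_i(Xtr);
  fmat Y = as_f(Ytr);
  imat Xt = as_i(Xte);
  fmat Yt = as_f(Yte);
  const int n = X.n_rows, T = X.n_cols;
  const float flr = static_cast<float>(lr);
  const float keep = 1.0f - static_cast<float>(dropout);

  std::vector<int> ord_f, ord_b;
  time_orders(T, ord_f, ord_b);

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);

  std::vector<fmat*> ps = { &net.emb, &net.fwd.wx, &net.fwd.wh, &net.fwd.b,
                            &net.bwd.wx, &net.bwd.wh, &net.bwd.b,
                            &net.wout, &net.bout };
  Adam adam;
  adam.init(ps);

  std::vector<double> h_tl, h_ta, h_vl, h_va;
  double best_acc = -1.0;
  int wait = 0;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  fmat Eflat, mask, H, P, dlog, dH;
  Cache cf, cb;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    imat Xs(n, T);
    fmat Ys(n, net.nc);
    for (int i = 0; i < n; ++i) {
      Xs.row(i) = X.row(idx[i]);
      Ys.row(i) = Y.row(idx[i]);
    }
    double ep_loss = 0.0;
    long ep_correct = 0;
    for (int r0 = 0; r0 < n; r0 += batch) {
      const int r1 = std::min(n, r0 + batch);
      const int B = r1 - r0;
      embed_flat(net, Xs, r0, r1, Eflat);
      if (keep < 1.0f) {
        mask.set_size(B * T, net.d);
        for (uword ii = 0; ii < mask.n_elem; ++ii)
          mask(ii) = (unif(rng) < keep) ? 1.0f / keep : 0.0f;
        Eflat %= mask;
      }
      fmat hf = run_dir(net.fwd, Eflat, B, ord_f, net.u, &cf);
      fmat hb = run_dir(net.bwd, Eflat, B, ord_b, net.u, &cb);
      H = join_rows(hf, hb);
      P = H * net.wout;
      P.each_row() += net.bout.row(0);
      softmax_rows(P);
      fmat Yb = Ys.rows(r0, r1 - 1);
      double bl = accu(-Yb % log(P + 1e-8f)) / B;
      if (!std::isfinite(bl)) {
        Rcpp::stop("training diverged: non-finite loss at epoch %d (lr=%g)",
                   epoch + 1, lr);
      }
      ep_loss += bl * B;
      ep_correct += accu(index_max(P, 1) == index_max(Yb, 1));

      dlog = (P - Yb) / static_cast<float>(B);
      fmat gwout = H.t() * dlog;
      fmat gbout = sum(dlog, 0);
      dH = dlog * net.wout.t();
      DirGrad gf = { fmat(net.d, 4 * net.u, fill::zeros),
                     fmat(net.u, 4 * net.u, fill::zeros),
                     fmat(1, 4 * net.u, fill::zeros) };
      DirGrad gb = gf;
      fmat dEflat(B * T, net.d, fill::zeros);
      bptt_dir(net.fwd, cf, Eflat, B, ord_f, dH.cols(0, net.u - 1), gf,
               dEflat);
      bptt_dir(net.bwd, cb, Eflat, B, ord_b, dH.cols(net.u, 2 * net.u - 1),
               gb, dEflat);
      if (keep < 1.0f) dEflat %= mask;
      fmat gemb(5, net.d, fill::zeros);
      for (int t = 0; t < T; ++t)
        for (int b = 0; b < B; ++b)
          gemb.row(Xs(r0 + b, t)) += dEflat.row(t * B + b);
      std::vector<fmat*> gs = { &gemb, &gf.wx, &gf.wh, &gf.b,
                                &gb.wx, &gb.wh, &gb.b, &gwout, &gbout };
      adam.step(ps, gs, flr);
    }
    double vl = NA_REAL, va = NA_REAL;
    if (Xt.n_rows > 0) evaluate_net(net, Xt, Yt, &vl, &va);
    h_tl.push_back(ep_loss / n);
    h_ta.push_back(static_cast<double>(ep_correct) / n);
    h_vl.push_back(vl);
    h_va.push_back(va);
    if (verbose) {
      Rcpp::Rcout << "epoch " << (epoch + 1) << "  loss " << ep_loss / n
                  << "  acc " << static_cast<double>(ep_correct) / n
                  << "  val_loss " << vl << "  val_acc " << va << "\n";
    }
    Rcpp::checkUserInterrupt();
    if (Xt.n_rows > 0 && target_accuracy > 0 && va >= target_accuracy) break;
    if (early_stop && Xt.n_rows > 0) {
      if (va > best_acc + min_delta) {
        best_acc = va;
        wait = 0;
      } else if (++wait >= patience) break;
    }
  }

  const int ne = h_tl.size();
  Rcpp::NumericMatrix hist(ne, 4);
  for (int e = 0; e < ne; ++e) {
    hist(e, 0) = h_tl[e]; hist(e, 1) = h_ta[e];
    hist(e, 2) = h_vl[e]; hist(e, 3) = h_va[e];
  }
  Rcpp::colnames(hist) = Rcpp::CharacterVector::create(
      "train_loss", "train_acc", "test_loss", "test_acc");
  return Rcpp::List::create(Rcpp::Named("weights") = net_to_list(net),
                            Rcpp::Named("history") = hist,
                            Rcpp::Named("epochs_run") = ne);
}

// Loss and exact analytic gradients on one full batch, no dropout.
// Exists so the BPTT implementation can be checked against finite
// differences in the test suite.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List weights, Rcpp::IntegerMatrix Xr,
                         Rcpp::NumericMatrix Yr) {
  Net net = net_from_list(weights);
  imat X = as_i(Xr);
  fmat Y = as_f(Yr);
  const int n = X.n_rows, T = X.n_cols;
  std::vector<int> ord_f, ord_b;
  time_orders(T, ord_f, ord_b);
  fmat Eflat;
  embed_flat(net, X, 0, n, Eflat);
  Cache cf, cb;
  fmat hf = run_dir(net.fwd, Eflat, n, ord_f, net.u, &cf);
  fmat hb = run_dir(net.bwd, Eflat, n, ord_b, net.u, &cb);
  fmat H = join_rows(hf, hb);
  fmat P = H * net.wout;
  P.each_row() += net.bout.row(0);
  softmax_rows(P);
  double loss = accu(-Y % log(P + 1e-8f)) / n;
  fmat dlog = (P - Y) / static_cast<float>(n);
  fmat gwout = H.t() * dlog;
  fmat gbout = sum(dlog, 0);
  fmat dH = dlog * net.wout.t();
  DirGrad gf = { fmat(net.d, 4 * net.u, fill::zeros),
                 fmat(net.u, 4 * net.u, fill::zeros),
                 fmat(1, 4 * net.u, fill::zeros) };
  DirGrad gb = gf;
  fmat dEflat(n * T, net.d, fill::zeros);
  bptt_dir(net.fwd, cf, Eflat, n, ord_f, dH.cols(0, net.u - 1), gf, dEflat);
  bptt_dir(net.bwd, cb, Eflat, n, ord_b, dH.cols(net.u, 2 * net.u - 1), gb,
           dEflat);
  fmat gemb(5, net.d, fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < n; ++b)
      gemb.row(X(b, t)) += dEflat.row(t * n + b);
  Net g;
  g.emb = gemb; g.fwd.wx = gf.wx; g.fwd.wh = gf.wh; g.fwd.b = gf.b;
  g.bwd.wx = gb.wx; g.bwd.wh = gb.wh; g.bwd.b = gb.b;
  g.wout = gwout; g.bout = gbout;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("gradients") = net_to_list(g));
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_predict(Rcpp::List weights, Rcpp::IntegerMatrix Xr) {
  Net net = net_from_list(weights);
  imat X = as_i(Xr);
  const int T = X.n_cols;
  std::vector<int> ord_f, ord_b;
  time_orders(T, ord_f, ord_b);
  const int n = X.n_rows, chunk = 512;
  mat out(n, net.nc);
  for (int r0 = 0; r0 < n; r0 += chunk) {
    int r1 = std::min(n, r0 + chunk);
    fmat P = forward_probs(net, X, r0, r1, ord_f, ord_b);
    out.rows(r0, r1 - 1) = conv_to<mat>::from(P);
  }
  return Rcpp::wrap(out);
}

// [[Rcpp::export]]
Rcpp::List cpp_evaluate(Rcpp::List weights, Rcpp::IntegerMatrix Xr,
                        Rcpp::NumericMatrix Yr) {
  Net net = net_from_list(weights);
  imat X = as_i(Xr);
  fmat Y = as_f(Yr);
  double loss, acc;
  evaluate_net(net, X, Y, &loss, &acc);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("accuracy") = acc);
}
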