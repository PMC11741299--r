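// Core network for base-resolution cleavage-profile models.
//
// A model is a flat parameter vector whose layout is fixed by the
// architecture config: an initial 1-D convolution over the 4-row one-hot
// sequence, a stack of dilated convolutions (dilation doubling per layer),
// and two heads — a transposed convolution of width `profile_width`
// producing per-base logits (center-cropped to output_len), and a global
// average pool + dense layer producing the predicted log(1 + total counts).
// Forward, loss gradients (multinomial NLL + lambda * squared error on
// log1p counts, optionally combined with a frozen bias submodel's outputs)
// and input gradients (for attribution) are implemented here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Cfg {
  int F, w1, D, wd, wp, Lin, Lout;
  std::vector<int> dil;   // dilation rate per dilated layer
  int Lh;                 // bottleneck length after all convolutions
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.F   = as<int>(cfg["filters"]);
  c.w1  = as<int>(cfg["conv_width"]);
  c.D   = as<int>(cfg["n_dilated"]);
  c.wd  = as<int>(cfg["dilated_width"]);
  c.wp  = as<int>(cfg["profile_width"]);
  c.Lin = as<int>(cfg["input_len"]);
  c.Lout = as<int>(cfg["output_len"]);
  int d = as<int>(cfg["dilation_base"]);
  int L = c.Lin - (c.w1 - 1);
  for (int l = 0; l < c.D; ++l) {
    c.dil.push_back(d);
    L -= (c.wd - 1) * d;
    d *= 2;
  }
  c.Lh = L;
  if (c.Lh < 1) stop("architecture consumes the whole input: increase input_len");
  if (c.Lh + c.wp - 1 < c.Lout) stop("profile head output shorter than output_len");
  return c;
}

struct Params {
  arma::mat W1; arma::vec b1;
  std::vector<arma::mat> Wd; std::vector<arma::vec> bd;
  arma::mat Wp; double bp;
  arma::vec wc; double bc;
};

// Parameter layout (order matters; mirrored by param_layout() in R):
// W1[F x 4*w1], b1[F], {Wd_l[F x F*wd], bd_l[F]}_{l=1..D},
// Wp[F x wp], bp, wc[F], bc
static Params unpack(const arma::vec& p, const Cfg& c) {
  Params P;
  size_t o = 0;
  auto take_mat = [&](int r, int cc) {
    arma::mat M(const_cast<double*>(p.memptr()) + o, r, cc, false, true);
    o += (size_t)r * cc;
    return arma::mat(M);  // copy; safe and cheap at these sizes
  };
  auto take_vec = [&](int n) {
    arma::vec v(const_cast<double*>(p.memptr()) + o, n, false, true);
    o += n;
    return arma::vec(v);
  };
  P.W1 = take_mat(c.F, 4 * c.w1);
  P.b1 = take_vec(c.F);
  for (int l = 0; l < c.D; ++l) {
    P.Wd.push_back(take_mat(c.F, c.F * c.wd));
    P.bd.push_back(take_vec(c.F));
  }
  P.Wp = take_mat(c.F, c.wp);
  P.bp = p(o++);
  P.wc = take_vec(c.F);
  P.bc = p(o++);
  if (o != p.n_elem) stop("parameter vector length does not match config");
  return P;
}

static size_t n_params(const Cfg& c) {
  size_t n = (size_t)c.F * 4 * c.w1 + c.F;
  n += (size_t)c.D * ((size_t)c.F * c.F * c.wd + c.F);
  n += (size_t)c.F * c.wp + 1 + c.F + 1;
  return n;
}

static arma::mat im2col(const arma::mat& X, int w, int d) {
  const int C = X.n_rows, L = X.n_cols;
  const int Lo = L - (w - 1) * d;
  arma::mat col(C * w, Lo);
  for (int k = 0; k < w; ++k)
    col.rows(k * C, (k + 1) * C - 1) = X.cols(k * d, k * d + Lo - 1);
  return col;
}

static void col2im_add(arma::mat& dX, const arma::mat& dcol, int w, int d) {
  const int C = dX.n_rows;
  const int Lo = dcol.n_cols;
  for (int k = 0; k < w; ++k)
    dX.cols(k * d, k * d + Lo - 1) += dcol.rows(k * C, (k + 1) * C - 1);
}

struct Cache {
  std::vector<arma::mat> H;  // layer outputs; H[0] after first conv, then
                             // H[l+1] = relu(conv(H[l])) + crop(H[l])
  std::vector<arma::mat> Z;  // pre-ReLU activations of every conv
  std::vector<arma::vec> M;  // channel dropout masks (training only)
  arma::vec logits;          // cropped, length Lout
  double log_total;
  int off;                   // crop offset into the full deconv output
};

// The dilated stack uses residual skip connections: each dilated layer's
// ReLU output is added to the previous layer's output center-cropped to
// the new length ((wd-1)*d/2 trimmed from each side). During training a
// channel-wise inverted dropout (rate `dropout`) is applied to each
// convolution's ReLU branch; masks are drawn from R's RNG so runs stay
// seed-reproducible.
static Cache forward_pass(const Params& P, const Cfg& c, const arma::mat& X,
                          double dropout = 0.0) {
  Cache cc;
  auto mask_for = [&](int F) {
    arma::vec m(F, arma::fill::ones);
    if (dropout > 0) {
      for (int i = 0; i < F; ++i)
        m(i) = (R::unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
    }
    return m;
  };
  arma::mat Z = P.W1 * im2col(X, c.w1, 1);
  Z.each_col() += P.b1;
  cc.Z.push_back(Z);
  arma::mat H = arma::clamp(Z, 0.0, arma::datum::inf);
  cc.M.push_back(arma::vec(c.F, arma::fill::ones));  // no dropout on the
  cc.H.push_back(H);                                 // motif-detector layer
  for (int l = 0; l < c.D; ++l) {
    const arma::mat& Hp = cc.H.back();
    arma::mat A = P.Wd[l] * im2col(Hp, c.wd, c.dil[l]);
    A.each_col() += P.bd[l];
    cc.Z.push_back(A);
    A = arma::clamp(A, 0.0, arma::datum::inf);
    cc.M.push_back(mask_for(c.F));
    A.each_col() %= cc.M.back();
    int trim = (c.wd - 1) * c.dil[l] / 2;
    A += Hp.cols(trim, Hp.n_cols - trim - 1);
    cc.H.push_back(A);
  }
  const arma::mat& Hb = cc.H.back();
  // transposed convolution: y[t] = bp + sum_{j,k: j+k=t} Wp(:,k)' H(:,j)
  arma::mat M = P.Wp.t() * Hb;               // wp x Lh
  int Ly = c.Lh + c.wp - 1;
  arma::vec y(Ly, arma::fill::zeros);
  for (int k = 0; k < c.wp; ++k) y.subvec(k, k + c.Lh - 1) += M.row(k).t();
  y += P.bp;
  cc.off = (Ly - c.Lout) / 2;
  cc.logits = y.subvec(cc.off, cc.off + c.Lout - 1);
  arma::vec hbar = arma::mean(Hb, 1);
  cc.log_total = arma::dot(P.wc, hbar) + P.bc;
  return cc;
}

// Backprop from head gradients (dlogits over the cropped window, dn on the
// count head output) down to parameters and, optionally, the input.
static void backward_pass(const Params& P, const Cfg& c, const arma::mat& X,
                          const Cache& cc, const arma::vec& dlogits, double dn,
                          arma::vec* gflat, arma::mat* dXout) {
  const arma::mat& Hb = cc.H.back();
  int Ly = c.Lh + c.wp - 1;
  arma::vec dy(Ly, arma::fill::zeros);
  dy.subvec(cc.off, cc.off + c.Lout - 1) = dlogits;
  arma::mat dM(c.wp, c.Lh);
  for (int k = 0; k < c.wp; ++k) dM.row(k) = dy.subvec(k, k + c.Lh - 1).t();
  arma::mat dWp = Hb * dM.t();
  double dbp = arma::accu(dy);
  arma::mat dH = P.Wp * dM;                    // F x Lh
  arma::vec hbar = arma::mean(Hb, 1);
  arma::vec dwc = dn * hbar;
  double dbc = dn;
  dH.each_col() += (dn / c.Lh) * P.wc;

  std::vector<arma::mat> dWd(c.D);
  std::vector<arma::vec> dbd(c.D);
  for (int l = c.D - 1; l >= 0; --l) {
    arma::mat dA = dH;
    dA.each_col() %= cc.M[l + 1];              // dropout mask
    dA = dA % (cc.Z[l + 1] > 0);               // ReLU mask (pre-skip)
    arma::mat col = im2col(cc.H[l], c.wd, c.dil[l]);
    dWd[l] = dA * col.t();
    dbd[l] = arma::sum(dA, 1);
    arma::mat dcol = P.Wd[l].t() * dA;
    arma::mat dHprev(c.F, cc.H[l].n_cols, arma::fill::zeros);
    col2im_add(dHprev, dcol, c.wd, c.dil[l]);
    int trim = (c.wd - 1) * c.dil[l] / 2;      // skip-connection path
    dHprev.cols(trim, dHprev.n_cols - trim - 1) += dH;
    dH = dHprev;
  }
  arma::mat dA0 = dH;
  dA0.each_col() %= cc.M[0];
  dA0 = dA0 % (cc.Z[0] > 0);
  arma::mat col0 = im2col(X, c.w1, 1);
  arma::mat dW1 = dA0 * col0.t();
  arma::vec db1 = arma::sum(dA0, 1);

  if (gflat) {
    arma::vec& g = *gflat;
    size_t o = 0;
    auto put_mat = [&](const arma::mat& M) {
      g.subvec(o, o + M.n_elem - 1) += arma::vectorise(M);
      o += M.n_elem;
    };
    auto put_vec = [&](const arma::vec& v) {
      g.subvec(o, o + v.n_elem - 1) += v;
      o += v.n_elem;
    };
    put_mat(dW1); put_vec(db1);
    for (int l = 0; l < c.D; ++l) { put_mat(dWd[l]); put_vec(dbd[l]); }
    put_mat(dWp); g(o++) += dbp;
    put_vec(dwc); g(o++) += dbc;
  }
  if (dXout) {
    arma::mat dcol0 = P.W1.t() * dA0;
    dXout->zeros(4, c.Lin);
    col2im_add(*dXout, dcol0, c.w1, 1);
  }
}

static arma::vec softmax_vec(const arma::vec& z) {
  arma::vec p = arma::exp(z - z.max());
  return p / arma::accu(p);
}

// [[Rcpp::export(name = ".cn_n_params")]]
double cn_n_params(List cfg) { return (double)n_params(parse_cfg(cfg)); }

// [[Rcpp::export(name = ".cn_forward")]]
List cn_forward(const arma::vec& par, List cfg, const arma::mat& X) {
  Cfg c = parse_cfg(cfg);
  if ((int)X.n_rows != 4 || (int)X.n_cols != c.Lin)
    stop("input must be a 4 x input_len one-hot matrix");
  if (par.n_elem != n_params(c)) stop("parameter vector length does not match config");
  Params P = unpack(par, c);
  Cache cc = forward_pass(P, c, X);
  return List::create(_["logits"] = cc.logits, _["log_total"] = cc.log_total);
}

// [[Rcpp::export(name = ".cn_forward_batch")]]
List cn_forward_batch(const arma::vec& par, List cfg, List Xs) {
  Cfg c = parse_cfg(cfg);
  Params P = unpack(par, c);
  int n = Xs.size();
  arma::mat logits(c.Lout, n);
  arma::vec totals(n);
  for (int i = 0; i < n; ++i) {
    arma::mat X = as<arma::mat>(Xs[i]);
    if ((int)X.n_rows != 4 || (int)X.n_cols != c.Lin)
      stop("input %d is not 4 x input_len", i + 1);
    Cache cc = forward_pass(P, c, X);
    logits.col(i) = cc.logits;
    totals(i) = cc.log_total;
  }
  return List::create(_["logits"] = logits, _["log_total"] = totals);
}

// Combined loss and gradient over a batch. When bias outputs are supplied
// the prediction is the factorized combination: profile logits add, count
// heads combine either additively on the log1p scale (count_mode = 0, the
// combination as printed) or as log(exp(n_tf) + gamma * exp(n_bias))
// (count_mode = 1). Gradients flow to the residual parameters only.
// [[Rcpp::export(name = ".cn_loss_grad_batch")]]
List cn_loss_grad_batch(const arma::vec& par, List cfg, List Xs, List ks,
                        double lambda, Nullable<List> bias_logits,
                        NumericVector bias_log_totals, double gamma,
                        int count_mode, bool want_grad,
                        double dropout = 0.0) {
  Cfg c = parse_cfg(cfg);
  Params P = unpack(par, c);
  int n = Xs.size();
  bool has_bias = bias_logits.isNotNull();
  List bl;
  if (has_bias) bl = bias_logits.get();
  arma::vec g(n_params(c), arma::fill::zeros);
  double mnll_sum = 0, mse_sum = 0;
  for (int i = 0; i < n; ++i) {
    arma::mat X = as<arma::mat>(Xs[i]);
    arma::vec k = as<arma::vec>(ks[i]);
    if ((int)k.n_elem != c.Lout) stop("observed counts must have length output_len");
    Cache cc = forward_pass(P, c, X, want_grad ? dropout : 0.0);
    arma::vec z = cc.logits;
    double ntf = cc.log_total, ncomb = ntf, dcomb_dtf = 1.0;
    if (has_bias) {
      z += as<arma::vec>(bl[i]);
      double nb = bias_log_totals[i];
      if (count_mode == 0) {
        ncomb = ntf + gamma * nb;
      } else {
        double a = std::exp(ntf), b = gamma * std::exp(nb);
        ncomb = std::log(a + b);
        dcomb_dtf = a / (a + b);
      }
    }
    arma::vec p = softmax_vec(z);
    double nobs = arma::accu(k);
    double mnll = -(std::lgamma(nobs + 1.0) - arma::accu(arma::lgamma(k + 1.0)) +
                    arma::dot(k, arma::log(p)));
    double target = std::log1p(nobs);
    double mse = (target - ncomb) * (target - ncomb);
    mnll_sum += mnll;
    mse_sum += mse;
    if (want_grad) {
      arma::vec dlogits = nobs * p - k;
      double dn = -2.0 * lambda * (target - ncomb) * dcomb_dtf;
      backward_pass(P, c, X, cc, dlogits, dn, &g, nullptr);
    }
  }
  return List::create(_["grad"] = g, _["mnll"] = mnll_sum, _["mse"] = mse_sum,
                      _["loss"] = mnll_sum + lambda * mse_sum, _["n"] = n);
}

// Gradient of a scalar head output with respect to the one-hot input.
// head = 0: the count head output. head = 1: sum_j w_j * logits_j with the
// fixed weight vector `profile_w` (length output_len).
// [[Rcpp::export(name = ".cn_input_grad")]]
arma::mat cn_input_grad(const arma::vec& par, List cfg, const arma::mat& X,
                        int head, const arma::vec& profile_w) {
  Cfg c = parse_cfg(cfg);
  Params P = unpack(par, c);
  Cache cc = forward_pass(P, c, X);
  arma::vec dlogits(c.Lout, arma::fill::zeros);
  double dn = 0;
  if (head == 0) dn = 1.0;
  else {
    if ((int)profile_w.n_elem != c.Lout) stop("profile weights must have length output_len");
    dlogits = profile_w;
  }
  arma::mat dX;
  backward_pass(P, c, X, cc, dlogits, dn, nullptr, &dX);
  return dX;
}

// DeepLIFT (Rescale rule) contributions of a scalar head output relative
// to a reference sequence. Linear layers propagate multipliers like
// gradients; at each ReLU the multiplier is scaled by delta(out)/delta(in)
// between the actual and the reference forward pass (gradient fallback
// where the input delta vanishes). The returned 4 x input_len matrix of
// contributions sums to f(x) - f(ref) exactly up to float error.
// [[Rcpp::export(name = ".cn_deeplift")]]
List cn_deeplift(const arma::vec& par, List cfg, const arma::mat& X,
                 const arma::mat& Xref, int head,
                 const arma::vec& profile_w) {
  Cfg c = parse_cfg(cfg);
  Params P = unpack(par, c);
  if (X.n_rows != 4 || (int)X.n_cols != c.Lin ||
      Xref.n_rows != 4 || (int)Xref.n_cols != c.Lin)
    stop("sequence and reference must be 4 x input_len");
  Cache cx = forward_pass(P, c, X);
  Cache cr = forward_pass(P, c, Xref);

  auto head_scalar = [&](const Cache& cc) {
    if (head == 0) return cc.log_total;
    return arma::dot(profile_w, cc.logits);
  };
  double fx = head_scalar(cx), fref = head_scalar(cr);

  // head multipliers into the bottleneck (both heads are linear in H)
  arma::vec dlogits(c.Lout, arma::fill::zeros);
  double dn = 0;
  if (head == 0) dn = 1.0;
  else {
    if ((int)profile_w.n_elem != c.Lout)
      stop("profile weights must have length output_len");
    dlogits = profile_w;
  }
  int Ly = c.Lh + c.wp - 1;
  arma::vec dy(Ly, arma::fill::zeros);
  dy.subvec(cx.off, cx.off + c.Lout - 1) = dlogits;
  arma::mat dM(c.wp, c.Lh);
  for (int k = 0; k < c.wp; ++k) dM.row(k) = dy.subvec(k, k + c.Lh - 1).t();
  arma::mat m = P.Wp * dM;                       // multipliers on H_final
  m.each_col() += (dn / c.Lh) * P.wc;

  const double eps = 1e-7;
  auto rescale = [&](const arma::mat& mh, int layer) {
    // Rescale ratio of the ReLU itself (pre-skip): delta relu(z) / delta z
    arma::mat dz = cx.Z[layer] - cr.Z[layer];
    arma::mat dh = arma::clamp(cx.Z[layer], 0.0, arma::datum::inf) -
                   arma::clamp(cr.Z[layer], 0.0, arma::datum::inf);
    arma::mat ratio = dh / dz;
    arma::umat small = arma::abs(dz) < eps;
    arma::mat grad_mask = arma::conv_to<arma::mat>::from(cx.Z[layer] > 0);
    ratio.elem(arma::find(small)) = grad_mask.elem(arma::find(small));
    return arma::mat(mh % ratio);
  };

  for (int l = c.D - 1; l >= 0; --l) {
    arma::mat dA = rescale(m, l + 1);
    arma::mat dcol = P.Wd[l].t() * dA;
    arma::mat dHprev(c.F, cx.H[l].n_cols, arma::fill::zeros);
    col2im_add(dHprev, dcol, c.wd, c.dil[l]);
    int trim = (c.wd - 1) * c.dil[l] / 2;      // skip-connection path
    dHprev.cols(trim, dHprev.n_cols - trim - 1) += m;
    m = dHprev;
  }
  arma::mat dA0 = rescale(m, 0);
  arma::mat dcol0 = P.W1.t() * dA0;
  arma::mat mX(4, c.Lin, arma::fill::zeros);
  col2im_add(mX, dcol0, c.w1, 1);
  arma::mat contrib = mX % (X - Xref);
  return List::create(_["contrib"] = contrib, _["delta"] = fx - fref,
                      _["f_x"] = fx, _["f_ref"] = fref);
}
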