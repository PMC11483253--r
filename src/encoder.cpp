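// Small transformer encoder with masked-token prediction head.
// Parameters live in one flat vector; layout is defined by enc_layout() and
// mirrored on the R side. Hidden states are stored d x T (one column per
// token position). Residual blocks are post-layernorm; feed-forward uses
// ReLU. All gradients are hand-derived and checked against finite
// differences in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

namespace {

struct Cfg {
  int V;       // vocabulary size including special tokens
  int d;       // hidden size
  int L;       // transformer layers
  int H;       // attention heads
  int ff;      // feed-forward inner size
  int maxlen;  // maximum positions
};

Cfg read_cfg(const IntegerVector& c) {
  Cfg g;
  g.V = c[0]; g.d = c[1]; g.L = c[2]; g.H = c[3]; g.ff = c[4]; g.maxlen = c[5];
  if (g.d % g.H != 0) stop("hidden size must be divisible by n_heads");
  return g;
}

// Segment order in the flat parameter vector.
struct Layout {
  std::vector<std::string> names;
  std::vector<uword> offset, len;
  uword total;
};

Layout make_layout(const Cfg& g) {
  Layout lay; lay.total = 0;
  auto add = [&](const std::string& nm, uword n) {
    lay.names.push_back(nm); lay.offset.push_back(lay.total);
    lay.len.push_back(n); lay.total += n;
  };
  add("tok_emb", (uword)g.V * g.d);
  add("pos_emb", (uword)g.maxlen * g.d);
  add("emb_ln_g", g.d); add("emb_ln_b", g.d);
  for (int l = 0; l < g.L; ++l) {
    std::string p = "l" + std::to_string(l + 1) + "_";
    add(p + "Wq", (uword)g.d * g.d); add(p + "bq", g.d);
    add(p + "Wk", (uword)g.d * g.d); add(p + "bk", g.d);
    add(p + "Wv", (uword)g.d * g.d); add(p + "bv", g.d);
    add(p + "Wo", (uword)g.d * g.d); add(p + "bo", g.d);
    add(p + "ln1_g", g.d); add(p + "ln1_b", g.d);
    add(p + "W1", (uword)g.ff * g.d); add(p + "b1", g.ff);
    add(p + "W2", (uword)g.d * g.ff); add(p + "b2", g.d);
    add(p + "ln2_g", g.d); add(p + "ln2_b", g.d);
  }
  add("out_W", (uword)g.V * g.d);
  add("out_b", g.V);
  return lay;
}

// Read-only matrix/vector views over the flat parameter vector.
struct Params {
  mat tok_emb, pos_emb, out_W;         // d x V, d x maxlen, V x d
  vec emb_ln_g, emb_ln_b, out_b;
  std::vector<mat> Wq, Wk, Wv, Wo, W1, W2;
  std::vector<vec> bq, bk, bv, bo, b1, b2, ln1g, ln1b, ln2g, ln2b;
};

Params unpack(const vec& th, const Cfg& g, const Layout& lay) {
  Params P; uword k = 0;
  auto nextm = [&](uword r, uword c) { mat M(th.memptr() + lay.offset[k], r, c); ++k; return M; };
  auto nextv = [&](uword n) { vec v(th.memptr() + lay.offset[k], n); ++k; return v; };
  P.tok_emb = nextm(g.d, g.V);
  P.pos_emb = nextm(g.d, g.maxlen);
  P.emb_ln_g = nextv(g.d); P.emb_ln_b = nextv(g.d);
  for (int l = 0; l < g.L; ++l) {
    P.Wq.push_back(nextm(g.d, g.d)); P.bq.push_back(nextv(g.d));
    P.Wk.push_back(nextm(g.d, g.d)); P.bk.push_back(nextv(g.d));
    P.Wv.push_back(nextm(g.d, g.d)); P.bv.push_back(nextv(g.d));
    P.Wo.push_back(nextm(g.d, g.d)); P.bo.push_back(nextv(g.d));
    P.ln1g.push_back(nextv(g.d)); P.ln1b.push_back(nextv(g.d));
    P.W1.push_back(nextm(g.ff, g.d)); P.b1.push_back(nextv(g.ff));
    P.W2.push_back(nextm(g.d, g.ff)); P.b2.push_back(nextv(g.d));
    P.ln2g.push_back(nextv(g.d)); P.ln2b.push_back(nextv(g.d));
  }
  P.out_W = nextm(g.V, g.d);
  P.out_b = nextv(g.V);
  return P;
}

// Mutable gradient views into a flat gradient vector.
struct Grads {
  vec* flat;
  const Layout* lay;
  std::map<std::string, uword> idx;
  Grads(vec* f, const Layout* l) : flat(f), lay(l) {
    for (uword i = 0; i < l->names.size(); ++i) idx[l->names[i]] = i;
  }
  // non-owning writable views
  mat m(const std::string& nm, uword r, uword c) {
    uword i = idx.at(nm);
    return mat(flat->memptr() + lay->offset[i], r, c, false, true);
  }
  vec v(const std::string& nm, uword n) {
    uword i = idx.at(nm);
    return vec(flat->memptr() + lay->offset[i], n, false, true);
  }
};

const double LN_EPS = 1e-5;

// Column-wise layernorm. Returns normalized x_hat and per-column inv-sd.
void layernorm_fwd(const mat& X, const vec& g, const vec& b,
                   mat& Y, mat& Xhat, rowvec& inv_sd) {
  rowvec mu = mean(X, 0);
  rowvec va = mean(square(X.each_row() - mu), 0);
  inv_sd = 1.0 / sqrt(va + LN_EPS);
  Xhat = (X.each_row() - mu);
  Xhat.each_row() %= inv_sd;
  Y = Xhat.each_col() % g;
  Y.each_col() += b;
}

// Backward of column-wise layernorm; writes dg, db, returns dX.
mat layernorm_bwd(const mat& dY, const mat& Xhat, const rowvec& inv_sd,
                  const vec& g, vec& dg, vec& db) {
  dg = sum(dY % Xhat, 1);
  db = sum(dY, 1);
  mat dXhat = dY.each_col() % g;
  rowvec m1 = mean(dXhat, 0);
  rowvec m2 = mean(dXhat % Xhat, 0);
  mat dX = dXhat;
  dX.each_row() -= m1;
  dX -= Xhat.each_row() % m2;
  dX.each_row() %= inv_sd;
  return dX;
}

struct LayerCache {
  mat Hin;               // input to the block, d x T
  mat Q, K, Vv;          // d x T
  std::vector<mat> Pattn; // per-head T x T attention
  mat Ocat;              // d x T
  mat R1hat; rowvec R1inv; mat X1; // post-attention LN cache
  mat Z, A;              // ff x T pre/post ReLU
  mat R2hat; rowvec R2inv;         // post-ffn LN cache
};

struct FwdCache {
  mat E0hat; rowvec E0inv;  // embedding LN
  std::vector<LayerCache> layers;
  mat Xfinal;               // d x T
};

mat forward_sentence(const Params& P, const Cfg& g, const ivec& ids,
                     FwdCache* cache) {
  int T = ids.n_elem;
  if (T > g.maxlen) stop("sentence longer than max_tokens");
  mat X(g.d, T);
  for (int t = 0; t < T; ++t)
    X.col(t) = P.tok_emb.col(ids[t]) + P.pos_emb.col(t);
  mat Xhat; rowvec inv; mat Y;
  layernorm_fwd(X, P.emb_ln_g, P.emb_ln_b, Y, Xhat, inv);
  if (cache) { cache->E0hat = Xhat; cache->E0inv = inv; }
  X = Y;
  int dk = g.d / g.H;
  double scale = 1.0 / std::sqrt((double)dk);
  for (int l = 0; l < g.L; ++l) {
    LayerCache lc;
    lc.Hin = X;
    lc.Q = P.Wq[l] * X; lc.Q.each_col() += P.bq[l];
    lc.K = P.Wk[l] * X; lc.K.each_col() += P.bk[l];
    lc.Vv = P.Wv[l] * X; lc.Vv.each_col() += P.bv[l];
    lc.Ocat.set_size(g.d, T);
    for (int h = 0; h < g.H; ++h) {
      mat Qh = lc.Q.rows(h * dk, (h + 1) * dk - 1);
      mat Kh = lc.K.rows(h * dk, (h + 1) * dk - 1);
      mat Vh = lc.Vv.rows(h * dk, (h + 1) * dk - 1);
      mat S = (Qh.t() * Kh) * scale;          // T x T, row = query
      S.each_col() -= max(S, 1);
      mat Pm = exp(S);
      Pm.each_col() /= sum(Pm, 1);
      lc.Pattn.push_back(Pm);
      lc.Ocat.rows(h * dk, (h + 1) * dk - 1) = Vh * Pm.t();
    }
    mat AttnOut = P.Wo[l] * lc.Ocat; AttnOut.each_col() += P.bo[l];
    mat R1 = X + AttnOut;
    mat X1;
    layernorm_fwd(R1, P.ln1g[l], P.ln1b[l], X1, lc.R1hat, lc.R1inv);
    lc.X1 = X1;
    lc.Z = P.W1[l] * X1; lc.Z.each_col() += P.b1[l];
    lc.A = clamp(lc.Z, 0.0, datum::inf);      // ReLU
    mat F = P.W2[l] * lc.A; F.each_col() += P.b2[l];
    mat R2 = X1 + F;
    mat X2;
    layernorm_fwd(R2, P.ln2g[l], P.ln2b[l], X2, lc.R2hat, lc.R2inv);
    X = X2;
    if (cache) cache->layers.push_back(std::move(lc));
  }
  if (cache) cache->Xfinal = X;
  return X;
}

// Backprop dXfinal (d x T) through the encoder body, accumulating into G.
void backward_sentence(const Params& P, const Cfg& g, const ivec& ids,
                       const FwdCache& c, mat dX, Grads& G) {
  int T = ids.n_elem;
  int dk = g.d / g.H;
  double scale = 1.0 / std::sqrt((double)dk);
  for (int l = g.L - 1; l >= 0; --l) {
    const LayerCache& lc = c.layers[l];
    std::string p = "l" + std::to_string(l + 1) + "_";
    // X2 = LN2(R2)
    vec dg2, db2;
    mat dR2 = layernorm_bwd(dX, lc.R2hat, lc.R2inv, P.ln2g[l], dg2, db2);
    G.v(p + "ln2_g", g.d) += dg2;
    G.v(p + "ln2_b", g.d) += db2;
    // R2 = X1 + F;  F = W2 A + b2; A = relu(Z); Z = W1 X1 + b1
    mat dF = dR2;
    G.m(p + "W2", g.d, g.ff) += dF * lc.A.t();
    G.v(p + "b2", g.d) += sum(dF, 1);
    mat dA = P.W2[l].t() * dF;
    mat dZ = dA % conv_to<mat>::from(lc.Z > 0.0);
    G.m(p + "W1", g.ff, g.d) += dZ * lc.X1.t();
    G.v(p + "b1", g.ff) += sum(dZ, 1);
    mat dX1 = dR2 + P.W1[l].t() * dZ;
    // X1 = LN1(R1)
    vec dg1, db1;
    mat dR1 = layernorm_bwd(dX1, lc.R1hat, lc.R1inv, P.ln1g[l], dg1, db1);
    G.v(p + "ln1_g", g.d) += dg1;
    G.v(p + "ln1_b", g.d) += db1;
    // R1 = Hin + AttnOut; AttnOut = Wo Ocat + bo
    mat dAttnOut = dR1;
    G.m(p + "Wo", g.d, g.d) += dAttnOut * lc.Ocat.t();
    G.v(p + "bo", g.d) += sum(dAttnOut, 1);
    mat dOcat = P.Wo[l].t() * dAttnOut;
    mat dQ(g.d, T, fill::zeros), dK(g.d, T, fill::zeros), dV(g.d, T, fill::zeros);
    for (int h = 0; h < g.H; ++h) {
      mat dOh = dOcat.rows(h * dk, (h + 1) * dk - 1);
      mat Vh = lc.Vv.rows(h * dk, (h + 1) * dk - 1);
      mat Qh = lc.Q.rows(h * dk, (h + 1) * dk - 1);
      mat Kh = lc.K.rows(h * dk, (h + 1) * dk - 1);
      const mat& Pm = lc.Pattn[h];
      // Ocat_h = Vh * Pm.t()
      dV.rows(h * dk, (h + 1) * dk - 1) = dOh * Pm;
      mat dP = dOh.t() * Vh;                 // T x T
      // softmax rows
      vec rowdot = sum(dP % Pm, 1);
      mat dS = (dP.each_col() - rowdot) % Pm;
      dQ.rows(h * dk, (h + 1) * dk - 1) = (Kh * dS.t()) * scale;
      dK.rows(h * dk, (h + 1) * dk - 1) = (Qh * dS) * scale;
    }
    mat dHin = dR1;
    G.m(p + "Wq", g.d, g.d) += dQ * lc.Hin.t();
    G.v(p + "bq", g.d) += sum(dQ, 1);
    dHin += P.Wq[l].t() * dQ;
    G.m(p + "Wk", g.d, g.d) += dK * lc.Hin.t();
    G.v(p + "bk", g.d) += sum(dK, 1);
    dHin += P.Wk[l].t() * dK;
    G.m(p + "Wv", g.d, g.d) += dV * lc.Hin.t();
    G.v(p + "bv", g.d) += sum(dV, 1);
    dHin += P.Wv[l].t() * dV;
    dX = dHin;
  }
  // embedding layernorm
  vec dge, dbe;
  mat dE = layernorm_bwd(dX, c.E0hat, c.E0inv, P.emb_ln_g, dge, dbe);
  G.v("emb_ln_g", g.d) += dge;
  G.v("emb_ln_b", g.d) += dbe;
  mat dTok = G.m("tok_emb", g.d, g.V);
  mat dPos = G.m("pos_emb", g.d, g.maxlen);
  for (int t = 0; t < T; ++t) {
    dTok.col(ids[t]) += dE.col(t);
    dPos.col(t) += dE.col(t);
  }
}

ivec as_ids(SEXP s, int V) {
  IntegerVector iv(s);
  ivec ids(iv.size());
  for (int i = 0; i < iv.size(); ++i) {
    if (iv[i] < 0 || iv[i] >= V) stop("token id out of range");
    ids[i] = iv[i];
  }
  return ids;
}

} // namespace

// [[Rcpp::export]]
List cpp_enc_layout(IntegerVector cfg) {
  Cfg g = read_cfg(cfg);
  Layout lay = make_layout(g);
  return List::create(_["names"] = wrap(lay.names),
                      _["lengths"] = wrap(std::vector<double>(lay.len.begin(), lay.len.end())),
                      _["total"] = (double)lay.total);
}

// Mean loss over masked positions of a batch of corrupted sentences;
// optionally the gradient w.r.t. all parameters.
// [[Rcpp::export]]
List cpp_mlm_batch(NumericVector theta, IntegerVector cfg, List sents,
                   List tgt_pos, List tgt_ids, bool want_grad) {
  Cfg g = read_cfg(cfg);
  Layout lay = make_layout(g);
  if ((uword)theta.size() != lay.total) stop("theta length mismatch");
  vec th(theta.begin(), theta.size(), false, true);
  Params P = unpack(th, g, lay);
  int n = sents.size();
  uword n_tgt = 0;
  for (int i = 0; i < n; ++i) n_tgt += Rf_length(tgt_pos[i]);
  if (n_tgt == 0) stop("batch has no masked target positions");
  double loss = 0.0;
  vec gflat;
  if (want_grad) gflat.zeros(lay.total);
  Grads G(&gflat, &lay);
  for (int i = 0; i < n; ++i) {
    ivec ids = as_ids(sents[i], g.V);
    IntegerVector tp(tgt_pos[i]), ti(tgt_ids[i]);
    if (tp.size() == 0) continue;
    FwdCache c;
    mat X = forward_sentence(P, g, ids, &c);
    mat dX;
    if (want_grad) dX.zeros(g.d, ids.n_elem);
    for (int j = 0; j < tp.size(); ++j) {
      int t = tp[j], y = ti[j];
      if (t < 0 || t >= (int)ids.n_elem) stop("target position out of range");
      if (y < 0 || y >= g.V) stop("target id out of range");
      vec logits = P.out_W * X.col(t) + P.out_b;
      double mx = logits.max();
      vec ex = exp(logits - mx);
      double Z = accu(ex);
      loss += -(logits[y] - mx - std::log(Z));
      if (want_grad) {
        vec dlog = ex / Z;
        dlog[y] -= 1.0;
        dlog /= (double)n_tgt;
        G.m("out_W", g.V, g.d) += dlog * X.col(t).t();
        G.v("out_b", g.V) += dlog;
        dX.col(t) += P.out_W.t() * dlog;
      }
    }
    if (want_grad) backward_sentence(P, g, ids, c, dX, G);
  }
  loss /= (double)n_tgt;
  List out = List::create(_["loss"] = loss, _["n_targets"] = (double)n_tgt);
  if (want_grad) out["grad"] = NumericVector(gflat.begin(), gflat.end());
  return out;
}

// Pooled sentence embeddings, one row per sentence.
// pooling: 0 = mean over positions 1..T-1 (excluding leading CLS), 1 = CLS.
// [[Rcpp::export]]
NumericMatrix cpp_pool_batch(NumericVector theta, IntegerVector cfg,
                             List sents, int pooling) {
  Cfg g = read_cfg(cfg);
  Layout lay = make_layout(g);
  if ((uword)theta.size() != lay.total) stop("theta length mismatch");
  vec th(theta.begin(), theta.size(), false, true);
  Params P = unpack(th, g, lay);
  int n = sents.size();
  mat out(n, g.d);
  for (int i = 0; i < n; ++i) {
    ivec ids = as_ids(sents[i], g.V);
    mat X = forward_sentence(P, g, ids, nullptr);
    if (pooling == 1 || ids.n_elem == 1) {
      out.row(i) = X.col(0).t();
    } else {
      out.row(i) = mean(X.cols(1, ids.n_elem - 1), 1).t();
    }
  }
  return wrap(out);
}

// Gradient of sum_i upstream_i . pooled_i w.r.t. parameters.
// upstream: n x d matrix of per-sentence upstream gradients.
// [[Rcpp::export]]
NumericVector cpp_pool_backward(NumericVector theta, IntegerVector cfg,
                                List sents, NumericMatrix upstream,
                                int pooling) {
  Cfg g = read_cfg(cfg);
  Layout lay = make_layout(g);
  if ((uword)theta.size() != lay.total) stop("theta length mismatch");
  vec th(theta.begin(), theta.size(), false, true);
  Params P = unpack(th, g, lay);
  int n = sents.size();
  if (upstream.nrow() != n || upstream.ncol() != g.d)
    stop("upstream gradient shape mismatch");
  vec gflat(lay.total, fill::zeros);
  Grads G(&gflat, &lay);
  for (int i = 0; i < n; ++i) {
    ivec ids = as_ids(sents[i], g.V);
    int T = ids.n_elem;
    vec up(g.d);
    for (int k = 0; k < g.d; ++k) up[k] = upstream(i, k);
    if (accu(abs(up)) == 0.0) continue;
    FwdCache c;
    forward_sentence(P, g, ids, &c);
    mat dX(g.d, T, fill::zeros);
    if (pooling == 1 || T == 1) {
      dX.col(0) = up;
    } else {
      for (int t = 1; t < T; ++t) dX.col(t) = up / (double)(T - 1);
    }
    backward_sentence(P, g, ids, c, dX, G);
  }
  return NumericVector(gflat.begin(), gflat.end());
}
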