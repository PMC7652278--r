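// Numeric core: greedy composition-tree construction, fixed-structure
// forward pass, backpropagation through structure, per-question loss and
// gradient, and skip-gram pretraining. All formulas mirror the R-level
// reference operations (compose / reconstruct / recon_error_* /
// ranking_error); the R surface is the documented contract, this file is
// the fast path used by training and the objective.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Params {
  arma::mat W1;   // n x 2n
  arma::vec b1;   // n
  arma::mat W2;   // 2n x n
  arma::vec b2;   // 2n
  arma::mat Wl;   // 2 x n
};

// parent of two child vectors: tanh affine composition, optional unit-length
// normalisation. hnorm receives ||tanh(z)|| (1 when normalisation is off or
// the pre-activation is exactly zero).
arma::vec compose_vec(const arma::vec& c1, const arma::vec& c2,
                      const Params& th, bool normalize, double& hnorm) {
  arma::vec h = arma::tanh(th.W1 * arma::join_cols(c1, c2) + th.b1);
  hnorm = 1.0;
  if (normalize) {
    double nrm = arma::norm(h, 2);
    if (nrm > 0) { hnorm = nrm; h /= nrm; }
  }
  return h;
}

double merge_error(const arma::vec& c1, const arma::vec& c2,
                   double n1, double n2, const Params& th,
                   bool normalize, bool weighted) {
  double hnorm;
  arma::vec p = compose_vec(c1, c2, th, normalize, hnorm);
  arma::vec r = th.W2 * p + th.b2;
  const arma::uword n = c1.n_elem;
  double e1 = arma::accu(arma::square(c1 - r.head(n)));
  double e2 = arma::accu(arma::square(c2 - r.tail(n)));
  if (weighted) return (n1 * e1 + n2 * e2) / (n1 + n2);
  return 0.5 * (e1 + e2);
}

// Greedy construction over a leaf sequence: repeatedly merge the adjacent
// pair with the smallest reconstruction error (leftmost on ties). Returns
// (L-1) x 2 matrix of 0-based child node ids; parent of row i is L + i.
arma::imat greedy_structure(const arma::mat& X, const Params& th,
                            bool normalize, bool weighted) {
  const int L = X.n_cols;
  const int nn = 2 * L - 1;
  arma::mat nodes(X.n_rows, nn);
  nodes.head_cols(L) = X;
  arma::vec counts(nn, arma::fill::ones);
  arma::imat trip(std::max(L - 1, 0), 2);

  std::vector<int> act(L);
  for (int i = 0; i < L; ++i) act[i] = i;

  // cached error for each currently-adjacent pair (act[j], act[j+1])
  std::vector<double> err(std::max(L - 1, 0));
  auto pair_err = [&](int a, int b) {
    return merge_error(nodes.col(a), nodes.col(b), counts(a), counts(b),
                       th, normalize, weighted);
  };
  for (int j = 0; j + 1 < L; ++j) err[j] = pair_err(act[j], act[j + 1]);

  for (int step = 0; step < L - 1; ++step) {
    int best = 0;
    for (size_t j = 1; j < err.size(); ++j)
      if (err[j] < err[best]) best = (int)j;  // strict <: leftmost tie-break
    int a = act[best], b = act[best + 1];
    int pid = L + step;
    double hnorm;
    nodes.col(pid) = compose_vec(nodes.col(a), nodes.col(b), th, normalize, hnorm);
    counts(pid) = counts(a) + counts(b);
    trip(step, 0) = a;
    trip(step, 1) = b;
    act[best] = pid;
    act.erase(act.begin() + best + 1);
    err.erase(err.begin() + best);
    if (best > 0) err[best - 1] = pair_err(act[best - 1], act[best]);
    if (best + 1 < (int)act.size()) err[best] = pair_err(act[best], act[best + 1]);
  }
  return trip;
}

struct Forward {
  arma::mat nodes;   // n x (2L-1)
  arma::mat hnorm;   // 1 x (2L-1), pre-normalisation tanh norms (internal)
  arma::mat recon;   // 2n x (L-1), reconstructions at internal nodes
  arma::vec counts;  // word counts per node
  arma::vec erec;    // weighted (or plain) recon error per internal node
  arma::mat dist;    // 2 x (2L-1), softmax class distribution per node
};

arma::vec softmax2(const arma::vec& z) {
  double mx = z.max();
  arma::vec e = arma::exp(z - mx);
  return e / arma::accu(e);
}

Forward forward_fixed(const arma::mat& X, const arma::imat& trip,
                      const Params& th, bool normalize, bool weighted) {
  const int L = X.n_cols;
  const int nn = 2 * L - 1;
  const arma::uword n = X.n_rows;
  Forward f;
  f.nodes.set_size(n, nn);
  f.nodes.head_cols(L) = X;
  f.hnorm.set_size(1, nn);
  f.hnorm.fill(1.0);
  f.recon.set_size(2 * n, std::max(L - 1, 0));
  f.counts.set_size(nn);
  f.counts.head(L).ones();
  f.erec.set_size(std::max(L - 1, 0));
  f.dist.set_size(2, nn);
  for (int i = 0; i < L - 1; ++i) {
    int a = trip(i, 0), b = trip(i, 1), pid = L + i;
    double hnorm;
    arma::vec p = compose_vec(f.nodes.col(a), f.nodes.col(b), th, normalize, hnorm);
    f.nodes.col(pid) = p;
    f.hnorm(0, pid) = hnorm;
    arma::vec r = th.W2 * p + th.b2;
    f.recon.col(i) = r;
    double e1 = arma::accu(arma::square(f.nodes.col(a) - r.head(n)));
    double e2 = arma::accu(arma::square(f.nodes.col(b) - r.tail(n)));
    double na = f.counts(a), nb = f.counts(b);
    f.counts(pid) = na + nb;
    f.erec(i) = weighted ? (na * e1 + nb * e2) / (na + nb) : 0.5 * (e1 + e2);
  }
  for (int s = 0; s < nn; ++s)
    f.dist.col(s) = softmax2(th.Wl * f.nodes.col(s));
  return f;
}

struct Grads {
  arma::mat W1, W2, Wl, emb;
  arma::vec b1, b2;
  void init(arma::uword n, arma::uword V) {
    W1.zeros(n, 2 * n); b1.zeros(n);
    W2.zeros(2 * n, n); b2.zeros(2 * n);
    Wl.zeros(2, n); emb.zeros(n, V);
  }
};

// Backprop through one pair's tree. wtree scales every node's combined
// error (alpha * Erec + (1-alpha) * EcE); gd1 is the extra coefficient on
// the root's d1 coming from the listwise ranking error. t_rel is true when
// the pair's target label is (1,0).
double backward_pair(const arma::mat& X, const arma::imat& trip,
                     const Forward& f, const Params& th,
                     const IntegerVector& toks, bool t_rel,
                     double alpha, double wtree, double gd1,
                     bool normalize, bool weighted, bool fine_tune,
                     Grads& g) {
  const int L = X.n_cols;
  const arma::uword n = X.n_rows;
  const int nn = 2 * L - 1;
  arma::vec t(2);
  t(0) = t_rel ? 1.0 : 0.0;
  t(1) = 1.0 - t(0);

  arma::mat gnode(n, nn, arma::fill::zeros);
  double loss = 0.0;
  const int root = (L == 1) ? 0 : nn - 1;

  // classification / ranking gradient at the root when the pair is a single
  // leaf (no internal nodes: tree error is an empty sum, but the ranking
  // error still reads the root distribution)
  if (L == 1 && gd1 != 0.0) {
    arma::vec d = f.dist.col(0);
    arma::vec gl(2);
    double dd = d(0) * d(1);
    gl(0) = gd1 * dd; gl(1) = -gd1 * dd;
    g.Wl += gl * f.nodes.col(0).t();
    gnode.col(0) += th.Wl.t() * gl;
  }

  for (int i = L - 2; i >= 0; --i) {
    int a = trip(i, 0), b = trip(i, 1), pid = L + i;
    arma::vec p = f.nodes.col(pid);
    arma::vec gp = gnode.col(pid);

    // node classification: cross-entropy against the pair label
    arma::vec d = f.dist.col(pid);
    double eps = 1e-12;
    loss += wtree * (1.0 - alpha) *
            -(t(0) * std::log(std::max(d(0), eps)) +
              t(1) * std::log(std::max(d(1), eps)));
    arma::vec gl = wtree * (1.0 - alpha) * (d - t);
    if (pid == root && gd1 != 0.0) {
      double dd = d(0) * d(1);
      gl(0) += gd1 * dd;
      gl(1) -= gd1 * dd;
    }
    g.Wl += gl * p.t();
    gp += th.Wl.t() * gl;

    // reconstruction error at this node
    loss += wtree * alpha * f.erec(i);
    arma::vec r = f.recon.col(i);
    arma::vec d1v = f.nodes.col(a) - r.head(n);
    arma::vec d2v = f.nodes.col(b) - r.tail(n);
    double na = f.counts(a), nb = f.counts(b);
    double w1c, w2c;
    if (weighted) {
      w1c = 2.0 * na / (na + nb);
      w2c = 2.0 * nb / (na + nb);
    } else {
      w1c = 1.0; w2c = 1.0;
    }
    arma::vec gr(2 * n);
    gr.head(n) = -wtree * alpha * w1c * d1v;
    gr.tail(n) = -wtree * alpha * w2c * d2v;
    gnode.col(a) += wtree * alpha * w1c * d1v;  // children as recon targets
    gnode.col(b) += wtree * alpha * w2c * d2v;
    g.W2 += gr * p.t();
    g.b2 += gr;
    gp += th.W2.t() * gr;

    // through normalisation and tanh into the composition affine map
    arma::vec gh = normalize
      ? (gp - p * arma::dot(p, gp)) / f.hnorm(0, pid)
      : gp;
    arma::vec h = p * f.hnorm(0, pid);  // pre-normalisation tanh output
    arma::vec gz = (1.0 - arma::square(h)) % gh;
    arma::vec cc = arma::join_cols(f.nodes.col(a), f.nodes.col(b));
    g.W1 += gz * cc.t();
    g.b1 += gz;
    arma::vec gc = th.W1.t() * gz;
    gnode.col(a) += gc.head(n);
    gnode.col(b) += gc.tail(n);
  }

  if (fine_tune)
    for (int i = 0; i < L; ++i)
      g.emb.col(toks[i] - 1) += gnode.col(i);
  return loss;  // tree-error part only (ranking part handled by caller)
}

Params unpack(const arma::mat& W1, const arma::vec& b1, const arma::mat& W2,
              const arma::vec& b2, const arma::mat& Wl) {
  Params th; th.W1 = W1; th.b1 = b1; th.W2 = W2; th.b2 = b2; th.Wl = Wl;
  return th;
}

// stable order of indices by descending value (original order on ties)
std::vector<int> order_desc(const arma::vec& v) {
  std::vector<int> idx(v.n_elem);
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v(a) > v(b); });
  return idx;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_greedy_structure(const arma::mat& X, const arma::mat& W1,
                                   const arma::vec& b1, const arma::mat& W2,
                                   const arma::vec& b2, const arma::mat& Wl,
                                   bool normalize, bool weighted) {
  Params th = unpack(W1, b1, W2, b2, Wl);
  arma::imat trip = greedy_structure(X, th, normalize, weighted);
  IntegerMatrix out(trip.n_rows, 2);
  for (arma::uword i = 0; i < trip.n_rows; ++i) {
    out(i, 0) = trip(i, 0) + 1;  // 1-based for R
    out(i, 1) = trip(i, 1) + 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_pair_forward(const arma::mat& X, const IntegerMatrix& triplets,
                      const arma::mat& W1, const arma::vec& b1,
                      const arma::mat& W2, const arma::vec& b2,
                      const arma::mat& Wl, bool normalize, bool weighted) {
  Params th = unpack(W1, b1, W2, b2, Wl);
  const int L = X.n_cols;
  arma::imat trip(std::max(L - 1, 0), 2);
  for (int i = 0; i < triplets.nrow(); ++i) {
    trip(i, 0) = triplets(i, 0) - 1;
    trip(i, 1) = triplets(i, 1) - 1;
  }
  Forward f = forward_fixed(X, trip, th, normalize, weighted);
  return List::create(_["nodes"] = f.nodes, _["recon_errors"] = f.erec,
                      _["counts"] = f.counts, _["dist"] = f.dist);
}

// Per-question loss (and optionally gradient) for one candidate set.
// tok_idx: list of 1-based token index vectors (question tokens ++ snippet
// tokens); labels: 1 = relevant, 0 = irrelevant. structures / denoms freeze
// the discrete choices when supplied (both 1-based / as returned here).
// [[Rcpp::export]]
List cpp_question_eval(const List& tok_idx, const IntegerVector& labels,
                       const arma::mat& emb, const arma::mat& W1,
                       const arma::vec& b1, const arma::mat& W2,
                       const arma::vec& b2, const arma::mat& Wl,
                       double alpha, double beta, bool normalize,
                       bool weighted, std::string variant,
                       Nullable<List> structures, Nullable<NumericVector> denoms,
                       bool want_grad, bool fine_tune) {
  Params th = unpack(W1, b1, W2, b2, Wl);
  const int N = tok_idx.size();
  const arma::uword n = emb.n_rows;

  std::vector<arma::mat> Xs(N);
  std::vector<arma::imat> trips(N);
  std::vector<Forward> fws(N);
  arma::vec d1(N), tree_err(N, arma::fill::zeros);

  List strs;
  bool have_str = structures.isNotNull();
  if (have_str) strs = structures.get();

  for (int q = 0; q < N; ++q) {
    IntegerVector tk = tok_idx[q];
    const int L = tk.size();
    arma::mat X(n, L);
    for (int i = 0; i < L; ++i) X.col(i) = emb.col(tk[i] - 1);
    Xs[q] = X;
    if (have_str) {
      IntegerMatrix tm = strs[q];
      arma::imat trip(std::max(L - 1, 0), 2);
      for (int i = 0; i < tm.nrow(); ++i) {
        trip(i, 0) = tm(i, 0) - 1;
        trip(i, 1) = tm(i, 1) - 1;
      }
      trips[q] = trip;
    } else {
      trips[q] = greedy_structure(X, th, normalize, weighted);
    }
    fws[q] = forward_fixed(X, trips[q], th, normalize, weighted);
    const int root = (L == 1) ? 0 : 2 * L - 2;
    d1(q) = fws[q].dist(0, root);
    // node errors: alpha * Erec + (1-alpha) * EcE summed over internal nodes
    double te = 0.0;
    for (int i = 0; i < L - 1; ++i) {
      arma::vec d = fws[q].dist.col(L + i);
      double eps = 1e-12;
      double ece = labels[q] == 1 ? -std::log(std::max(d(0), eps))
                                  : -std::log(std::max(d(1), eps));
      te += alpha * fws[q].erec(i) + (1.0 - alpha) * ece;
    }
    tree_err(q) = te;
  }

  // listwise ranking error over the relevant candidates
  std::vector<int> rel;
  for (int q = 0; q < N; ++q) if (labels[q] == 1) rel.push_back(q);
  const int m = (int)rel.size();
  arma::vec denom(N, arma::fill::zeros);
  double rank_err = NA_REAL, S = 0.0;
  if (m > 0) {
    if (denoms.isNotNull()) {
      NumericVector dn = denoms.get();
      for (int q = 0; q < N; ++q) denom(q) = dn[q];
    } else if (variant == "global_rank") {
      std::vector<int> ord = order_desc(d1);
      arma::vec pos(N);
      for (int r = 0; r < N; ++r) pos(ord[r]) = r + 1;
      for (int q : rel) denom(q) = pos(q);
    } else {  // relevant_index
      arma::vec dr(m);
      for (int j = 0; j < m; ++j) dr(j) = d1(rel[j]);
      std::vector<int> ord = order_desc(dr);
      for (int r = 0; r < m; ++r) denom(rel[ord[r]]) = r + 1;
    }
    for (int q : rel) S += d1(q) / denom(q);
    rank_err = -std::log(S);
  }

  double loss = beta * (m > 0 ? rank_err : 0.0) +
                (1.0 - beta) * arma::accu(tree_err);

  List out = List::create(
      _["loss"] = loss, _["rank_error"] = rank_err,
      _["tree_errors"] = NumericVector(tree_err.begin(), tree_err.end()),
      _["d1"] = NumericVector(d1.begin(), d1.end()),
      _["denom"] = NumericVector(denom.begin(), denom.end()), _["m"] = m);

  List rstr(N);
  for (int q = 0; q < N; ++q) {
    IntegerMatrix tm(trips[q].n_rows, 2);
    for (arma::uword i = 0; i < trips[q].n_rows; ++i) {
      tm(i, 0) = trips[q](i, 0) + 1;
      tm(i, 1) = trips[q](i, 1) + 1;
    }
    rstr[q] = tm;
  }
  out["structures"] = rstr;

  if (want_grad) {
    Grads g;
    g.init(n, emb.n_cols);
    for (int q = 0; q < N; ++q) {
      double gd1 = 0.0;
      if (m > 0 && labels[q] == 1 && S > 0)
        gd1 = -beta / (denom(q) * S);
      IntegerVector tk = tok_idx[q];
      backward_pair(Xs[q], trips[q], fws[q], th, tk, labels[q] == 1, alpha,
                    1.0 - beta, gd1, normalize, weighted, fine_tune, g);
    }
    out["grad"] = List::create(_["W1"] = g.W1, _["b1"] = g.b1, _["W2"] = g.W2,
                               _["b2"] = g.b2, _["Wlabel"] = g.Wl,
                               _["emb"] = g.emb);
  }
  return out;
}

// Skip-gram with negative sampling. sentences: list of 1-based token index
// vectors; emb_init (n x V) provides the input vectors; context vectors
// start at zero as in word2vec. Single-threaded and deterministic for a
// given seed. Returns the updated input-vector matrix.
// [[Rcpp::export]]
arma::mat cpp_skipgram(const List& sentences, const arma::mat& emb_init,
                       const arma::vec& unigram, int window, int k,
                       double lr, int epochs, int seed) {
  arma::mat W = emb_init;                 // n x V, input vectors
  arma::mat C(arma::size(W), arma::fill::zeros);  // context vectors
  const int V = W.n_cols;
  std::mt19937 rng((unsigned)seed);

  // cumulative unigram^0.75 table for negative sampling
  arma::vec cum = arma::cumsum(arma::pow(unigram, 0.75));
  cum /= cum(cum.n_elem - 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto draw_neg = [&]() {
    double u = unif(rng);
    return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  };

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int T = sent.size();
      for (int t = 0; t < T; ++t) {
        int centre = sent[t] - 1;
        int lo = std::max(0, t - window), hi = std::min(T - 1, t + window);
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          int ctx = sent[c] - 1;
          arma::vec gin(W.n_rows, arma::fill::zeros);
          // positive example then k negatives
          for (int neg = 0; neg <= k; ++neg) {
            int target = neg == 0 ? ctx : draw_neg();
            if (neg > 0 && target == ctx) continue;
            double label = neg == 0 ? 1.0 : 0.0;
            double score = arma::dot(W.col(centre), C.col(target));
            double pred = 1.0 / (1.0 + std::exp(-score));
            double gscal = lr * (label - pred);
            gin += gscal * C.col(target);
            C.col(target) += gscal * W.col(centre);
          }
          W.col(centre) += gin;
        }
      }
    }
  }
  (void)V;
  return W;
}
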