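// Likelihood core for the branch-site codon model (Model A).
//
// State space: the 61 sense codons of the universal genetic code, in the
// order fixed on the R side.  The generator is the Goldman-Yang form
// restricted to single-nucleotide changes; reversibility w.r.t. pi lets us
// compute exp(Qt) through the eigendecomposition of the symmetrized matrix
// D^{1/2} Q D^{-1/2}.  Felsenstein pruning runs over site patterns with
// per-node rescaling so the same code is safe on deeper trees.
//
// The four site classes pair up: classes 0/2a share the background omega0
// generator and classes 1/2b the neutral one; within a pair the likelihood
// differs only across the foreground branch.  The pruning therefore runs
// one shared pass per background generator, freezing the partials on the
// path from the foreground branch to the root, and replays just that path
// per class.  Transition matrices are cached per (generator, edge).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NSTATE = 61;

// Goldman-Yang generator; ctype codes: 0 = multi/no change, 1 = syn
// transversion, 2 = syn transition, 3 = nonsyn transversion, 4 = nonsyn
// transition.  Returns Q (unscaled) and writes the mean rate -sum pi_i q_ii.
static mat build_q(const imat& ctype, const vec& pi, double kappa,
                   double omega, double* rate) {
  mat Q(NSTATE, NSTATE, fill::zeros);
  for (int i = 0; i < NSTATE; ++i) {
    for (int j = 0; j < NSTATE; ++j) {
      int t = ctype(i, j);
      if (t == 0) continue;
      double v = pi(j);
      if (t == 2 || t == 4) v *= kappa;
      if (t >= 3) v *= omega;
      Q(i, j) = v;
    }
  }
  Q.diag() = -sum(Q, 1);
  *rate = -dot(pi, Q.diag());
  return Q;
}

struct Eig {
  vec lam;
  mat U;
  mat Uinv;
};

// Eigendecomposition of the reversible generator via symmetrization.
static Eig codon_eig(const mat& Q, const vec& pi) {
  vec sp = sqrt(pi);
  mat B = Q;
  B.each_col() %= sp;      // B = D^{1/2} Q D^{-1/2}
  B.each_row() /= sp.t();
  B = 0.5 * (B + B.t());
  Eig e;
  mat V;
  eig_sym(e.lam, V, B);
  e.U = V;
  e.U.each_col() /= sp;
  e.Uinv = V.t();
  e.Uinv.each_row() %= sp.t();
  return e;
}

// Small cache of eigensystems keyed by (kappa, omega, pi).  Finite-
// difference gradients perturb one parameter at a time, so most calls
// reuse generators from the previous evaluation.
struct EigCacheEntry {
  double kappa, omega, pihash;
  Eig eig;
  double rate;
};

static Eig eig_for(const imat& ctype, const vec& pi, double kappa,
                   double omega, double* rate) {
  static std::vector<EigCacheEntry> cache;
  static size_t slot = 0;
  double pihash = dot(pi, linspace(1.0, 2.0, pi.n_elem));
  for (const auto& e : cache) {
    if (e.kappa == kappa && e.omega == omega && e.pihash == pihash) {
      *rate = e.rate;
      return e.eig;
    }
  }
  mat Q = build_q(ctype, pi, kappa, omega, rate);
  EigCacheEntry entry{kappa, omega, pihash, codon_eig(Q, pi), *rate};
  if (cache.size() < 12) {
    cache.push_back(entry);
  } else {
    cache[slot] = entry;
    slot = (slot + 1) % cache.size();
  }
  return entry.eig;
}

static mat pmat(const Eig& e, double t) {
  mat P = e.U * diagmat(exp(e.lam * t)) * e.Uinv;
  P.elem(find(P < 0)).zeros();
  return P;
}

// [[Rcpp::export]]
arma::mat codon_pmat_cpp(const arma::imat& ctype, const arma::vec& pi,
                         double kappa, double omega, double t) {
  double r;
  mat Q = build_q(ctype, pi, kappa, omega, &r);
  return pmat(codon_eig(Q, pi), t);
}

// rescale the columns of a partial-likelihood matrix, accumulating logs
static void rescale(mat& L, rowvec& logsc) {
  rowvec m = max(L, 0);
  m.elem(find(m <= 0)).ones();
  L.each_row() /= m;
  logsc += log(m);
}

// Pruning likelihood of the four-class branch-site mixture.
//
// states: ntaxa x npat, 0-based codon state, -1 = missing/gap.
// edge:   postorder edge matrix (ape convention, 1-based node ids, root =
//         ntaxa + 1); children appear before their parent's own edge.
// fg_edge: 1-based row index into edge of the foreground branch.
// Background omegas per class are (w0, 1, w0, 1); foreground (w0, 1, w2, w2).
// All generators share the scale making the mixture-average background rate
// one substitution per codon per unit branch length.
// [[Rcpp::export]]
Rcpp::List bs_core_cpp(const arma::imat& states, const arma::vec& weights,
                       const arma::imat& edge, const arma::vec& elen,
                       const int fg_edge, const arma::vec& pi,
                       const arma::imat& ctype, const double kappa,
                       const double w0, const double w2, const double p0,
                       const double p1, const double scale,
                       const bool want_post) {
  const int ntaxa = states.n_rows;
  const int npat = states.n_cols;
  const int nedge = edge.n_rows;
  const int ntot = edge.max();
  const int root = ntaxa + 1;

  double psum = p0 + p1;
  double prest = 1.0 - psum;
  double p2a = psum > 0 ? prest * p0 / psum : prest / 2.0;
  double p2b = psum > 0 ? prest * p1 / psum : prest / 2.0;
  vec prop = {p0, p1, p2a, p2b};

  double r0, r1, r2;
  Eig eigs[3];
  eigs[0] = eig_for(ctype, pi, kappa, w0, &r0);
  eigs[1] = eig_for(ctype, pi, kappa, 1.0, &r1);
  if (w2 == 1.0) {
    eigs[2] = eigs[1];
  } else if (w2 == w0) {
    eigs[2] = eigs[0];
  } else {
    eigs[2] = eig_for(ctype, pi, kappa, w2, &r2);
  }

  // mean background rate under the mixture proportions
  double rate = (p0 + p2a) * r0 + (p1 + p2b) * r1;
  double tfac = scale / rate;

  // transition-matrix cache per (generator, edge)
  std::vector<std::vector<mat>> pcache(3, std::vector<mat>(nedge));
  auto P_of = [&](int wi, int e) -> const mat& {
    if (pcache[wi][e].is_empty())
      pcache[wi][e] = pmat(eigs[wi], elen(e) * tfac);
    return pcache[wi][e];
  };

  // path from the foreground child up to the root
  std::vector<int> parent_of(ntot + 1, 0);
  std::vector<int> edge_to(ntot + 1, -1);  // edge whose child is the node
  for (int e = 0; e < nedge; ++e) {
    parent_of[edge(e, 1)] = edge(e, 0);
    edge_to[edge(e, 1)] = e;
  }
  const int fg_child = edge(fg_edge - 1, 1);
  std::vector<bool> on_path(ntot + 1, false);
  std::vector<int> path;  // fg_child, its parent, ..., root
  for (int v = fg_child; v != 0; v = parent_of[v]) {
    on_path[v] = true;
    path.push_back(v);
  }

  // tip contribution across an edge
  auto tip_contrib = [&](const mat& P, int tip, mat& C) {
    for (int k = 0; k < npat; ++k) {
      int s = states(tip - 1, k);
      if (s >= 0)
        C.col(k) = P.col(s);
      else
        C.col(k).ones();
    }
  };

  const int bg_of[4] = {0, 1, 0, 1};
  const int fg_of[4] = {0, 1, 2, 2};

  mat logLc(npat, 4);
  for (int b = 0; b < 2; ++b) {  // background generator: w0, then 1
    // shared pass: all subtrees not containing the foreground branch
    std::vector<mat> L(ntot + 1);
    rowvec logsc_shared(npat, fill::zeros);
    for (int e = 0; e < nedge; ++e) {
      int pa = edge(e, 0), ch = edge(e, 1);
      if (on_path[ch]) continue;  // replayed per class
      const mat& P = P_of(b, e);
      mat C(NSTATE, npat);
      if (ch <= ntaxa) {
        tip_contrib(P, ch, C);
      } else {
        rescale(L[ch], logsc_shared);
        C = P * L[ch];
        L[ch].reset();
      }
      if (L[pa].is_empty())
        L[pa] = C;
      else
        L[pa] %= C;
    }
    // stabilize the frozen path partials once per background pass
    if (fg_child > ntaxa) rescale(L[fg_child], logsc_shared);
    for (size_t i = 1; i < path.size(); ++i) {
      if (!L[path[i]].is_empty()) rescale(L[path[i]], logsc_shared);
    }
    // replay the path per class of this background pair
    for (int c = b; c < 4; c += 2) {
      rowvec logsc = logsc_shared;
      mat cur;
      {
        const mat& Pfg = P_of(fg_of[c], fg_edge - 1);
        if (fg_child <= ntaxa) {
          cur.set_size(NSTATE, npat);
          tip_contrib(Pfg, fg_child, cur);
        } else {
          cur = Pfg * L[fg_child];
        }
      }
      for (size_t i = 1; i < path.size(); ++i) {
        int v = path[i];
        if (!L[v].is_empty()) cur %= L[v];
        if (v == root) break;
        rescale(cur, logsc);
        cur = P_of(b, edge_to[v]) * cur;
      }
      for (int k = 0; k < npat; ++k) {
        double lik = dot(pi, cur.col(k));
        logLc(k, c) = std::log(std::max(lik, 1e-300)) + logsc(k);
      }
    }
  }

  vec lp = log(clamp(prop, 1e-300, 1.0));
  double lnL = 0.0;
  mat post;
  if (want_post) post.set_size(npat, 4);
  for (int k = 0; k < npat; ++k) {
    vec z = logLc.row(k).t() + lp;
    double M = z.max();
    double s = accu(exp(z - M));
    double ll = M + std::log(s);
    lnL += weights(k) * ll;
    if (want_post) post.row(k) = exp(z.t() - ll);
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("lnL") = lnL);
  if (want_post) out["posteriors"] = post;
  return out;
}
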