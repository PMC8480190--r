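// MCMC core for Bayesian dating under six clock models, plus the
// heterochronous coalescent simulator. All randomness comes from R's RNG
// (unif_rand / R::r*), so set.seed() in R governs reproducibility.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double CONT_EPS = 1e-9;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

// model codes: 0 sc, 1 rc, 2 arc, 3 csc, 4 crc, 5 carc
// relax = sigma2 (rc/crc) or omega (arc/carc); ignored for strict models.
// Gamma parameters are shape-scale throughout. The negative binomial
// NegBin(r, p) has pmf C(x+r-1, x) p^x (1-p)^r.
static inline double poisson_ll(double x, double m) {
  return x * std::log(m) - m - std::lgamma(x + 1.0);
}

// parametrised by log(p) and log(1-p): p can sit within double rounding of
// 0 or 1 (relaxation near 0, or very large) without cancellation
// the binomial coefficient is -log(x+r) - lbeta(x+1, r): accurate when r is
// huge, where lgamma(x+r) - lgamma(r) cancels badly
static inline double nbinom_ll(double x, double r, double logP,
                               double log1mP) {
  return -std::log(x + r) - R::lbeta(x + 1.0, r) + x * logP + r * log1mP;
}

// below this relaxation the negative binomial is evaluated as its Poisson
// limit (kept identical to the interpreted implementation)
static const double RELAX_EPS = 1e-10;

static inline double gamma_ll(double x, double shape, double scale) {
  double xx = std::max(x, CONT_EPS);
  return (shape - 1.0) * std::log(xx) - xx / scale
       - std::lgamma(shape) - shape * std::log(scale);
}

static inline double branch_ll(int model, double mu, double relax,
                               double l, double x) {
  if (l < 0.0 || !std::isfinite(l)) return NEG_INF;
  if (l == 0.0) return (x <= CONT_EPS) ? 0.0 : NEG_INF;
  double m = mu * l;
  switch (model) {
  case 0:
    return poisson_ll(x, m);
  case 1: {
    if (relax < RELAX_EPS) return poisson_ll(x, m);
    double k = mu * mu / relax, theta = relax / mu;
    double tl = theta * l;
    return nbinom_ll(x, k, std::log(tl) - std::log1p(tl), -std::log1p(tl));
  }
  case 2: {
    if (relax < RELAX_EPS) return poisson_ll(x, m);
    return nbinom_ll(x, m / relax,
                     std::log(relax) - std::log1p(relax), -std::log1p(relax));
  }
  case 3:
    return gamma_ll(x, m, 1.0);
  case 4: {
    if (relax < 1e-12) return gamma_ll(x, m, 1.0);
    return gamma_ll(x, mu * m / (mu + relax * l), 1.0 + relax * l / mu);
  }
  case 5: {
    if (relax < 1e-12) return gamma_ll(x, m, 1.0);
    return gamma_ll(x, m / (1.0 + relax), 1.0 + relax);
  }
  }
  return NEG_INF;
}

// [[Rcpp::export(name = ".branchLLCpp")]]
NumericVector branch_ll_vec(int model, double mu, double relax,
                            NumericVector l, NumericVector x) {
  int n = l.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = branch_ll(model, mu, relax, l[i], x[i]);
  return out;
}

static inline double gamma_logpdf(double x, double shape, double scale) {
  if (x <= 0.0) return NEG_INF;
  return (shape - 1.0) * std::log(x) - x / scale
       - std::lgamma(shape) - shape * std::log(scale);
}

// Heterochronous coalescent: integral of k(k-1)/2 dt over the tree, going
// forward in time; internalSorted and tipsSorted ascending calendar dates.
// log prior = -(n-1) log(alpha) - integral/alpha (up to a constant).
// Coalescences are processed before samplings on ties.
static double coal_integral(const std::vector<double>& internalSorted,
                            const std::vector<double>& tipsSorted) {
  size_t ni = internalSorted.size(), nt = tipsSorted.size();
  size_t i = 0, j = 0;
  // forward in time one lineage exists entering the root event, so that the
  // first coalescence (the root) leaves k = 2
  double k = 1.0, integral = 0.0;
  double prev = std::min(internalSorted[0], tipsSorted[0]);
  while (i < ni || j < nt) {
    double tc = (i < ni) ? internalSorted[i] : R_PosInf;
    double ts = (j < nt) ? tipsSorted[j] : R_PosInf;
    if (ISNAN(tc) || ISNAN(ts)) return R_NaN;
    bool coal = (tc <= ts);
    double t = coal ? tc : ts;
    integral += 0.5 * k * (k - 1.0) * (t - prev);
    prev = t;
    if (coal) { k += 1.0; i++; } else { k -= 1.0; j++; }
  }
  return integral;
}

static inline void replace_sorted(std::vector<double>& v, double oldv,
                                  double newv) {
  v.erase(std::lower_bound(v.begin(), v.end(), oldv));
  v.insert(std::upper_bound(v.begin(), v.end(), newv), newv);
}

struct TreeData {
  int ntip, nnode, nedge;
  std::vector<int> eparent, echild;     // 0-based node indices
  std::vector<double> x;                // substitutions per edge
  std::vector<int> parentEdge;          // -1 for root
  std::vector<std::vector<int> > childEdges;
};

static TreeData build_tree(const IntegerMatrix& edge, int ntip,
                           const NumericVector& x) {
  TreeData td;
  td.ntip = ntip;
  td.nedge = edge.nrow();
  td.nnode = td.nedge + 1;
  td.eparent.resize(td.nedge); td.echild.resize(td.nedge);
  td.x.assign(x.begin(), x.end());
  td.parentEdge.assign(td.nnode, -1);
  td.childEdges.assign(td.nnode, std::vector<int>());
  for (int e = 0; e < td.nedge; e++) {
    td.eparent[e] = edge(e, 0) - 1;
    td.echild[e] = edge(e, 1) - 1;
    td.parentEdge[td.echild[e]] = e;
    td.childEdges[td.eparent[e]].push_back(e);
  }
  return td;
}

struct Sampler {
  const TreeData* td;
  int model;
  bool priorOnly;
  std::vector<double> dates;   // per node
  double mu, relax, alpha;
  std::vector<double> edgeLL;
  double sumLL;
  std::vector<double> sortedInternal, tipsSorted;
  double coalI;                // integral; prior = -ni*log(a) - I/a
  bool coalPrior;

  double edge_ll(int e) const {
    if (priorOnly) return 0.0;
    double l = dates[td->echild[e]] - dates[td->eparent[e]];
    return branch_ll(model, mu, relax, l, td->x[e]);
  }
  void recompute_ll() {
    sumLL = 0.0;
    for (int e = 0; e < td->nedge; e++) { edgeLL[e] = edge_ll(e); sumLL += edgeLL[e]; }
  }
  double total_ll_at(double mu2, double relax2) const {
    if (priorOnly) return 0.0;
    double s = 0.0;
    for (int e = 0; e < td->nedge; e++) {
      double l = dates[td->echild[e]] - dates[td->eparent[e]];
      s += branch_ll(model, mu2, relax2, l, td->x[e]);
      if (s == NEG_INF) return NEG_INF;
    }
    return s;
  }
  double coal_lp(double I, double a) const {
    if (!coalPrior) return 0.0;
    return -((double)sortedInternal.size()) * std::log(a) - I / a;
  }
};

struct Adapt {
  double w;
  int acc, att;
  void init(double w0) { w = w0; acc = 0; att = 0; }
  void tick(bool accepted, bool adapting) {
    att++; if (accepted) acc++;
    if (adapting && att >= 50) {
      double rate = (double)acc / att;
      w *= std::exp(rate - 0.25);
      w = std::min(std::max(w, 1e-8), 1e6);
      acc = 0; att = 0;
    }
  }
};

// One sweep of per-internal-node date proposals.
static void node_moves(Sampler& S, std::vector<Adapt>& wNode, bool adapting) {
  const TreeData& td = *S.td;
  for (int vi = 0; vi < td.nnode - td.ntip; vi++) {
    int v = td.ntip + vi;
    double d0 = S.dates[v];
    double d1 = d0 + wNode[vi].w * (unif_rand() - 0.5) * 2.0;
    // affected edges
    double dll = 0.0;
    bool ok = true;
    int pe = td.parentEdge[v];
    std::vector<int> eds;
    if (pe >= 0) eds.push_back(pe);
    for (size_t c = 0; c < td.childEdges[v].size(); c++)
      eds.push_back(td.childEdges[v][c]);
    std::vector<double> newLL(eds.size());
    S.dates[v] = d1;
    for (size_t ei = 0; ei < eds.size(); ei++) {
      newLL[ei] = S.edge_ll(eds[ei]);
      if (newLL[ei] == NEG_INF) { ok = false; break; }
      dll += newLL[ei] - S.edgeLL[eds[ei]];
    }
    S.dates[v] = d0;
    if (!ok) { wNode[vi].tick(false, adapting); continue; }
    double dprior = 0.0, newI = S.coalI;
    std::vector<double> cand;
    if (S.coalPrior) {
      cand = S.sortedInternal;
      replace_sorted(cand, d0, d1);
      newI = coal_integral(cand, S.tipsSorted);
      dprior = S.coal_lp(newI, S.alpha) - S.coal_lp(S.coalI, S.alpha);
    }
    bool accepted = std::log(unif_rand()) < dll + dprior;
    if (accepted) {
      S.dates[v] = d1;
      for (size_t ei = 0; ei < eds.size(); ei++) {
        S.sumLL += newLL[ei] - S.edgeLL[eds[ei]];
        S.edgeLL[eds[ei]] = newLL[ei];
      }
      if (S.coalPrior) { S.sortedInternal.swap(cand); S.coalI = newI; }
    }
    wNode[vi].tick(accepted, adapting);
  }
}

// Multiplicative scale move for mu or relax (which = 0 -> mu, 1 -> relax).
// A NaN prior shape encodes an improper flat prior on (0, Inf).
static void scale_move(Sampler& S, int which, Adapt& ad, bool adapting,
                       double prShape, double prScale) {
  double cur = (which == 0) ? S.mu : S.relax;
  double prop = cur * std::exp(ad.w * (unif_rand() - 0.5));
  double llNew = (which == 0) ? S.total_ll_at(prop, S.relax)
                              : S.total_ll_at(S.mu, prop);
  double dPrior = ISNAN(prShape) ? 0.0 :
    gamma_logpdf(prop, prShape, prScale) - gamma_logpdf(cur, prShape, prScale);
  double logA = llNew - S.sumLL + dPrior + std::log(prop / cur);
  bool accepted = std::isfinite(llNew) && std::log(unif_rand()) < logA;
  if (accepted) {
    if (which == 0) S.mu = prop; else S.relax = prop;
    S.sumLL = llNew;
    S.recompute_ll();
  }
  ad.tick(accepted, adapting);
}

static void alpha_move(Sampler& S, Adapt& ad, bool adapting, double alphaMean) {
  if (!S.coalPrior) return;
  double prop = S.alpha * std::exp(ad.w * (unif_rand() - 0.5));
  double logA = S.coal_lp(S.coalI, prop) - S.coal_lp(S.coalI, S.alpha)
    + (-prop / alphaMean) - (-S.alpha / alphaMean)   // Exp(mean) prior
    + std::log(prop / S.alpha);
  bool accepted = std::log(unif_rand()) < logA;
  if (accepted) S.alpha = prop;
  ad.tick(accepted, adapting);
}

static double param_logprior(const Sampler& S, bool relaxed,
                             double muShape, double muScale,
                             double relaxShape, double relaxScale,
                             double alphaMean) {
  double lp = gamma_logpdf(S.mu, muShape, muScale);
  if (relaxed && !ISNAN(relaxShape))
    lp += gamma_logpdf(S.relax, relaxShape, relaxScale);
  if (S.coalPrior)
    lp += -S.alpha / alphaMean - std::log(alphaMean)
        + S.coal_lp(S.coalI, S.alpha);
  return lp;
}

static Sampler init_sampler(const TreeData& td, int model, bool priorOnly,
                            bool coalPrior, const NumericVector& initDates,
                            double initMu, double initRelax, double initAlpha) {
  Sampler S;
  S.td = &td; S.model = model; S.priorOnly = priorOnly;
  S.coalPrior = coalPrior;
  S.dates.assign(initDates.begin(), initDates.end());
  S.mu = initMu; S.relax = initRelax; S.alpha = initAlpha;
  S.edgeLL.assign(td.nedge, 0.0);
  S.recompute_ll();
  S.tipsSorted.assign(S.dates.begin(), S.dates.begin() + td.ntip);
  std::sort(S.tipsSorted.begin(), S.tipsSorted.end());
  S.sortedInternal.assign(S.dates.begin() + td.ntip, S.dates.end());
  std::sort(S.sortedInternal.begin(), S.sortedInternal.end());
  S.coalI = coalPrior ? coal_integral(S.sortedInternal, S.tipsSorted) : 0.0;
  return S;
}

// [[Rcpp::export(name = ".mcmcCore")]]
NumericMatrix mcmc_core(IntegerMatrix edge, int ntip, NumericVector x,
                        int model, bool relaxed,
                        double muShape, double muScale,
                        double relaxShape, double relaxScale,
                        double alphaMean, bool coalPrior,
                        int nIter, int thin,
                        NumericVector initDates, double initMu,
                        double initRelax, double initAlpha,
                        bool updateDates, bool priorOnly, double adaptFrac) {
  RNGScope scope;
  TreeData td = build_tree(edge, ntip, x);
  Sampler S = init_sampler(td, model, priorOnly, coalPrior,
                           initDates, initMu, initRelax, initAlpha);
  if (!std::isfinite(S.sumLL))
    stop("initial state has non-finite likelihood");
  int nInternal = td.nnode - ntip;
  int nrec = nIter / thin;
  NumericMatrix out(nrec, 5 + nInternal);
  std::vector<Adapt> wNode(nInternal);
  for (int i = 0; i < nInternal; i++) wNode[i].init(1.0);
  Adapt aMu, aRelax, aAlpha;
  aMu.init(0.5); aRelax.init(1.0); aAlpha.init(1.0);
  int adaptEnd = (int)(adaptFrac * nIter);
  int row = 0;
  for (int it = 1; it <= nIter; it++) {
    bool adapting = it <= adaptEnd;
    if (updateDates) node_moves(S, wNode, adapting);
    scale_move(S, 0, aMu, adapting, muShape, muScale);
    if (relaxed) scale_move(S, 1, aRelax, adapting, relaxShape, relaxScale);
    alpha_move(S, aAlpha, adapting, alphaMean);
    if (it % thin == 0 && row < nrec) {
      out(row, 0) = S.sumLL;
      out(row, 1) = param_logprior(S, relaxed, muShape, muScale,
                                   relaxShape, relaxScale, alphaMean);
      out(row, 2) = S.mu;
      out(row, 3) = relaxed ? S.relax : 0.0;
      out(row, 4) = S.alpha;
      for (int i = 0; i < nInternal; i++) out(row, 5 + i) = S.dates[ntip + i];
      row++;
    }
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Reversible-jump MCMC between the continuous strict clock (csc, omega = 0)
// and the continuous additive relaxed clock (carc, omega > 0). The jump move
// draws omega from its Gamma prior (independence sampler), so prior and
// proposal densities cancel in the acceptance ratio; model prior odds 1:1.
// [[Rcpp::export(name = ".rjmcmcCore")]]
NumericMatrix rjmcmc_core(IntegerMatrix edge, int ntip, NumericVector x,
                          double muShape, double muScale,
                          double relaxShape, double relaxScale,
                          double alphaMean, bool coalPrior,
                          int nIter, int thin,
                          NumericVector initDates, double initMu,
                          double initRelax, double initAlpha,
                          double adaptFrac) {
  RNGScope scope;
  TreeData td = build_tree(edge, ntip, x);
  // start in the relaxed state
  Sampler S = init_sampler(td, 5, false, coalPrior,
                           initDates, initMu, initRelax, initAlpha);
  if (!std::isfinite(S.sumLL))
    stop("initial state has non-finite likelihood");
  int indicator = 1;
  int nInternal = td.nnode - ntip;
  int nrec = nIter / thin;
  NumericMatrix out(nrec, 6 + nInternal);
  std::vector<Adapt> wNode(nInternal);
  for (int i = 0; i < nInternal; i++) wNode[i].init(1.0);
  Adapt aMu, aRelax, aAlpha;
  aMu.init(0.5); aRelax.init(1.0); aAlpha.init(1.0);
  int adaptEnd = (int)(adaptFrac * nIter);
  int row = 0;
  for (int it = 1; it <= nIter; it++) {
    bool adapting = it <= adaptEnd;
    node_moves(S, wNode, adapting);
    scale_move(S, 0, aMu, adapting, muShape, muScale);
    if (indicator == 1) scale_move(S, 1, aRelax, adapting, relaxShape, relaxScale);
    alpha_move(S, aAlpha, adapting, alphaMean);
    // trans-model jump
    if (indicator == 0) {
      double omegaProp = R::rgamma(relaxShape, relaxScale);
      double llNew = S.total_ll_at(S.mu, omegaProp);
      if (std::isfinite(llNew) && std::log(unif_rand()) < llNew - S.sumLL) {
        indicator = 1; S.relax = omegaProp; S.sumLL = llNew; S.recompute_ll();
      }
    } else {
      double llNew = S.total_ll_at(S.mu, 0.0);
      if (std::isfinite(llNew) && std::log(unif_rand()) < llNew - S.sumLL) {
        indicator = 0; S.relax = 0.0; S.sumLL = llNew; S.recompute_ll();
      }
    }
    if (it % thin == 0 && row < nrec) {
      out(row, 0) = S.sumLL;
      out(row, 1) = param_logprior(S, indicator == 1, muShape, muScale,
                                   relaxShape, relaxScale, alphaMean);
      out(row, 2) = S.mu;
      out(row, 3) = indicator == 1 ? S.relax : 0.0;
      out(row, 4) = S.alpha;
      out(row, 5) = indicator;
      for (int i = 0; i < nInternal; i++) out(row, 6 + i) = S.dates[ntip + i];
      row++;
    }
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Heterochronous coalescent simulation: going backwards in time, with k
// active lineages the next coalescence is exponential with rate
// k(k-1)/(2*alpha); lineages activate at their sampling dates.
// Returns the parent (1-based, 0 for root) of every node and all node dates;
// tips are nodes 1..n in input order, internal nodes n+1.. in order of
// creation (most recent coalescence first).
// [[Rcpp::export(name = ".coalSimCore")]]
List coal_sim(NumericVector sampDates, double alpha) {
  RNGScope scope;
  int n = sampDates.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return sampDates[a] > sampDates[b]; });
  std::vector<double> nodeDate(2 * n - 1);
  for (int i = 0; i < n; i++) nodeDate[i] = sampDates[i];
  IntegerVector anc(2 * n - 1, 0);
  std::vector<int> active;
  active.reserve(n);
  int next = 0, created = 0;
  double t = sampDates[ord[0]];
  while (next < n && sampDates[ord[next]] >= t) { active.push_back(ord[next]); next++; }
  while (created < n - 1) {
    int k = (int)active.size();
    double wait = (k >= 2) ? R::rexp(alpha / (0.5 * k * (k - 1.0))) : R_PosInf;
    double tNext = (next < n) ? sampDates[ord[next]] : R_NegInf;
    if (k >= 2 && t - wait >= tNext) {
      t -= wait;
      int i = (int)std::floor(unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int)std::floor(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) j++;
      int node = n + created; created++;
      nodeDate[node] = t;
      anc[active[i]] = node + 1;
      anc[active[j]] = node + 1;
      int hi = std::max(i, j), lo = std::min(i, j);
      active[hi] = active.back(); active.pop_back();
      active[lo] = active.back(); active.pop_back();
      active.push_back(node);
    } else if (next < n) {
      t = tNext;
      while (next < n && sampDates[ord[next]] >= t) { active.push_back(ord[next]); next++; }
    } else {
      stop("coalescent simulation failed (internal error)");
    }
  }
  return List::create(_["anc"] = anc,
                      _["nodeDate"] = NumericVector(nodeDate.begin(), nodeDate.end()));
}

// Exposed for testing the prior against an independent R implementation.
// [[Rcpp::export(name = ".coalLogPriorCpp")]]
double coal_logprior_r(NumericVector internalDates, NumericVector tipDates,
                       double alpha) {
  std::vector<double> in(internalDates.begin(), internalDates.end());
  std::vector<double> tp(tipDates.begin(), tipDates.end());
  std::sort(in.begin(), in.end());
  std::sort(tp.begin(), tp.end());
  double I = coal_integral(in, tp);
  return -((double)in.size()) * std::log(alpha) - I / alpha;
}
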