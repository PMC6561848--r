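#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Count connected components of the subgraph induced by `members`
// (1-based node ids) given the full graph's adjacency list `adj`
// (list of 1-based integer vectors). Isolated members each count as one
// component.
// [[Rcpp::export]]
int cpp_count_components_subset(List adj, IntegerVector members) {
  int n = adj.size();
  std::vector<char> in(n + 1, 0);
  for (int i = 0; i < members.size(); ++i) {
    int v = members[i];
    if (v < 1 || v > n) stop("member id out of range");
    in[v] = 1;
  }
  std::vector<char> seen(n + 1, 0);
  std::vector<int> stack;
  stack.reserve(members.size());
  int comps = 0;
  for (int i = 0; i < members.size(); ++i) {
    int s = members[i];
    if (seen[s]) continue;
    ++comps;
    seen[s] = 1;
    stack.push_back(s);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      IntegerVector nb = adj[v - 1];
      for (int j = 0; j < nb.size(); ++j) {
        int w = nb[j];
        if (in[w] && !seen[w]) {
          seen[w] = 1;
          stack.push_back(w);
        }
      }
    }
  }
  return comps;
}

namespace {

struct Instance {
  int m, n, t;
  std::vector<std::vector<std::vector<int> > > adj; // [t][node], 0-based
  std::vector<const double*> sim;                   // m x n column-major
  std::vector<int> psi0;                            // query -> target
  std::vector<int> qOf;                             // target -> query or -1
  std::vector<char> inImage;
  std::vector<int> image;
  std::vector<double> baseSim;                      // per time point
  double delta;

  double simAt(int ti, int q, int v) const { return sim[ti][v * m + q]; }
};

struct Sol {
  std::vector<int> us, vs;
  double score;
  bool valid;
  Sol() : score(0.0), valid(false) {}
};

// Incremental scorer built around the component structure of a *fixed*
// image (the base image minus a removal set plus an insertion set): the
// fixed part is labelled once per time point, after which each candidate
// gap node v is scored in O(deg(v)) — inserting v merges the d distinct
// fixed components it touches, giving NCC_fixed - d + 1 components (or
// NCC_fixed + 1 when v touches none).
class FixedImageScorer {
public:
  explicit FixedImageScorer(const Instance& ins)
      : ins_(ins), removedStamp_(ins.n, 0), comp_(ins.n, -1),
        compStamp_(ins.n, 0), seenCompStamp_(0), seenComp_(),
        stamp_(0) {}

  // configure the fixed part: image0 - us - uX + vs
  void setFixed(const std::vector<int>& us, const std::vector<int>& vs,
                int uX) {
    ++stamp_;
    for (size_t j = 0; j < us.size(); ++j) removedStamp_[us[j]] = stamp_;
    if (uX >= 0) removedStamp_[uX] = stamp_;
    members_.clear();
    for (size_t k = 0; k < ins_.image.size(); ++k) {
      int x = ins_.image[k];
      if (removedStamp_[x] != stamp_) members_.push_back(x);
    }
    for (size_t k = 0; k < vs.size(); ++k) members_.push_back(vs[k]);
  }

  // label components of the fixed part at time ti; returns their count
  int labelComponents(int ti) {
    const std::vector<std::vector<int> >& A = ins_.adj[ti];
    int comps = 0;
    stack_.clear();
    ++stamp_;
    // re-mark membership under the new stamp
    for (size_t k = 0; k < members_.size(); ++k) {
      compStamp_[members_[k]] = stamp_;
    }
    for (size_t k = 0; k < members_.size(); ++k) {
      int s = members_[k];
      if (isLabelled(s)) continue;
      int id = comps++;
      setLabel(s, id);
      stack_.push_back(s);
      while (!stack_.empty()) {
        int v = stack_.back();
        stack_.pop_back();
        const std::vector<int>& nb = A[v];
        for (size_t j = 0; j < nb.size(); ++j) {
          int w = nb[j];
          if (compStamp_[w] == stamp_ && !isLabelled(w)) {
            setLabel(w, id);
            stack_.push_back(w);
          }
        }
      }
    }
    return comps;
  }

  // components of the fixed part merged by inserting v at time ti
  int touchedComponents(int ti, int v) {
    const std::vector<int>& nb = ins_.adj[ti][v];
    ++seenCompStamp_;
    int d = 0;
    for (size_t j = 0; j < nb.size(); ++j) {
      int w = nb[j];
      if (compStamp_[w] == stamp_) { // member of the fixed part
        int id = comp_[w];
        if ((int)seenComp_.size() <= id) seenComp_.resize(id + 1, 0);
        if (seenComp_[id] != seenCompStamp_) {
          seenComp_[id] = seenCompStamp_;
          ++d;
        }
      }
    }
    return d;
  }

  const std::vector<int>& members() const { return members_; }

private:
  bool isLabelled(int x) {
    ensureLab();
    return labelled_[x] == stamp_;
  }
  void setLabel(int x, int id) {
    ensureLab();
    labelled_[x] = stamp_;
    comp_[x] = id;
  }
  void ensureLab() {
    if (labelled_.empty()) labelled_.assign(ins_.n, 0);
  }

  const Instance& ins_;
  std::vector<int> removedStamp_, comp_, compStamp_, labelled_;
  int seenCompStamp_;
  std::vector<int> seenComp_;
  std::vector<int> members_, stack_;
  int stamp_;
};

bool contains(const std::vector<int>& xs, int x) {
  for (size_t i = 0; i < xs.size(); ++i)
    if (xs[i] == x) return true;
  return false;
}

} // namespace

// Phase II swap-selection dynamic program (1-based ids at the interface).
// [[Rcpp::export]]
List cpp_select_swaps(int n_target, List edges_by_time, List sim_by_time,
                      IntegerVector psi0, NumericVector gap_nodes_num,
                      double delta, int k) {
  Instance ins;
  ins.t = edges_by_time.size();
  ins.m = psi0.size();
  ins.n = n_target;
  ins.delta = delta;
  if (sim_by_time.size() != ins.t) stop("sim/edge time point mismatch");

  ins.adj.resize(ins.t);
  for (int ti = 0; ti < ins.t; ++ti) {
    IntegerMatrix E = edges_by_time[ti];
    ins.adj[ti].assign(ins.n, std::vector<int>());
    for (int e = 0; e < E.nrow(); ++e) {
      int a = E(e, 0) - 1, b = E(e, 1) - 1;
      if (a < 0 || b < 0 || a >= ins.n || b >= ins.n)
        stop("edge endpoint out of range");
      ins.adj[ti][a].push_back(b);
      ins.adj[ti][b].push_back(a);
    }
  }
  std::vector<NumericMatrix> simKeep;
  for (int ti = 0; ti < ins.t; ++ti) {
    NumericMatrix S = sim_by_time[ti];
    if (S.nrow() != ins.m || S.ncol() != ins.n)
      stop("similarity matrix has wrong shape");
    simKeep.push_back(S);
  }
  for (int ti = 0; ti < ins.t; ++ti) ins.sim.push_back(simKeep[ti].begin());

  ins.psi0.resize(ins.m);
  ins.qOf.assign(ins.n, -1);
  ins.inImage.assign(ins.n, 0);
  for (int q = 0; q < ins.m; ++q) {
    int v = psi0[q] - 1;
    if (v < 0 || v >= ins.n) stop("psi0 target id out of range");
    if (ins.inImage[v]) stop("psi0 is not injective");
    ins.psi0[q] = v;
    ins.qOf[v] = q;
    ins.inImage[v] = 1;
    ins.image.push_back(v);
  }
  std::vector<int> gap;
  for (int i = 0; i < gap_nodes_num.size(); ++i) {
    int v = (int)gap_nodes_num[i] - 1;
    if (v < 0 || v >= ins.n || ins.inImage[v]) stop("invalid gap node id");
    gap.push_back(v);
  }
  if (k < 1 || k > (int)gap.size()) stop("k must satisfy 1 <= k <= |F|");

  ins.baseSim.assign(ins.t, 0.0);
  for (int ti = 0; ti < ins.t; ++ti)
    for (int q = 0; q < ins.m; ++q)
      ins.baseSim[ti] += ins.simAt(ti, q, ins.psi0[q]);

  FixedImageScorer scorer(ins);
  std::vector<int> noRem, noAdd;

  // initial score: the objective on the unswapped alignment
  double initScore = 0.0;
  scorer.setFixed(noRem, noAdd, -1);
  for (int ti = 0; ti < ins.t; ++ti) {
    int c0 = scorer.labelComponents(ti);
    initScore += ins.baseSim[ti] - delta * (c0 - 1);
  }

  Sol best;
  best.valid = true;
  best.score = initScore;

  std::vector<Sol> prev(ins.m), cur(ins.m);
  NumericVector iterRaw(k), iterBest(k);
  std::vector<double> vScore(ins.n);

  // iteration 1: for each aligned node u_i, score every single swap
  // (u_i, v): the fixed part is the image without u_i, and candidate v
  // contributes its similarity S_ti(q_i, v) plus the component merge it
  // induces, accumulated over time points
  for (int i = 0; i < ins.m; ++i) {
    int ui = ins.psi0[i];
    int qi = i;
    scorer.setFixed(noRem, noAdd, ui);
    std::fill(vScore.begin(), vScore.end(), 0.0);
    for (int ti = 0; ti < ins.t; ++ti) {
      int c0 = scorer.labelComponents(ti);
      double simFixed = ins.baseSim[ti] - ins.simAt(ti, qi, ui);
      for (size_t g = 0; g < gap.size(); ++g) {
        int v = gap[g];
        int d = scorer.touchedComponents(ti, v);
        int ncc = (d > 0) ? (c0 - d + 1) : (c0 + 1);
        vScore[v] += simFixed + ins.simAt(ti, qi, v) - delta * (ncc - 1);
      }
    }
    Sol s;
    double bs = R_NegInf;
    int bv = -1;
    for (size_t g = 0; g < gap.size(); ++g) { // ascending: ties keep min v
      if (vScore[gap[g]] > bs) {
        bs = vScore[gap[g]];
        bv = gap[g];
      }
    }
    s.us.push_back(ui);
    s.vs.push_back(bv);
    s.score = bs;
    s.valid = true;
    prev[i] = s;
    if (bs > best.score) best = s;
  }
  {
    double raw = R_NegInf;
    for (int i = 0; i < ins.m; ++i) raw = std::max(raw, prev[i].score);
    iterRaw[0] = raw;
    iterBest[0] = std::max(initScore, raw);
  }

  for (int r = 2; r <= k; ++r) {
    for (int i = 0; i < ins.m; ++i) {
      int ui = ins.psi0[i];
      int qi = i;
      Sol bestExt;
      bestExt.score = R_NegInf;
      for (int j = 0; j < ins.m; ++j) {
        if (j == i || !prev[j].valid) continue;
        const Sol& pj = prev[j];
        if ((int)pj.us.size() != r - 1) continue; // carried-forward branch
        if (contains(pj.us, ui)) continue;        // Theta: u_i unswapped
        scorer.setFixed(pj.us, pj.vs, ui);
        // per-time fixed similarity for this removal/insertion set
        std::fill(vScore.begin(), vScore.end(), 0.0);
        for (int ti = 0; ti < ins.t; ++ti) {
          double simFixed = ins.baseSim[ti] - ins.simAt(ti, qi, ui);
          for (size_t sidx = 0; sidx < pj.us.size(); ++sidx) {
            int qs = ins.qOf[pj.us[sidx]];
            simFixed += ins.simAt(ti, qs, pj.vs[sidx]) -
                        ins.simAt(ti, qs, pj.us[sidx]);
          }
          int c0 = scorer.labelComponents(ti);
          for (size_t g = 0; g < gap.size(); ++g) {
            int v = gap[g];
            if (contains(pj.vs, v)) continue;     // Theta: v unused
            int d = scorer.touchedComponents(ti, v);
            int ncc = (d > 0) ? (c0 - d + 1) : (c0 + 1);
            vScore[v] += simFixed + ins.simAt(ti, qi, v) -
                         delta * (ncc - 1);
          }
        }
        for (size_t g = 0; g < gap.size(); ++g) {
          int v = gap[g];
          if (contains(pj.vs, v)) continue;
          if (vScore[v] > bestExt.score) {
            bestExt.us = pj.us;
            bestExt.vs = pj.vs;
            bestExt.us.push_back(ui);
            bestExt.vs.push_back(v);
            bestExt.score = vScore[v];
            bestExt.valid = true;
          }
        }
      }
      if (bestExt.valid) {
        cur[i] = bestExt;
        if (bestExt.score > best.score) best = bestExt;
      } else {
        cur[i] = prev[i]; // no Theta-feasible extension: carry forward
      }
    }
    prev = cur;
    double raw = R_NegInf;
    for (int i = 0; i < ins.m; ++i) raw = std::max(raw, prev[i].score);
    iterRaw[r - 1] = raw;
    iterBest[r - 1] = std::max(iterBest[r - 2], raw);
  }

  int nsel = (int)best.us.size();
  IntegerMatrix swaps(nsel, 2);
  for (int j = 0; j < nsel; ++j) {
    swaps(j, 0) = best.us[j] + 1;
    swaps(j, 1) = best.vs[j] + 1;
  }
  IntegerVector psiOut(ins.m);
  for (int q = 0; q < ins.m; ++q) psiOut[q] = ins.psi0[q] + 1;
  for (int j = 0; j < nsel; ++j) {
    int q = ins.qOf[best.us[j]];
    psiOut[q] = best.vs[j] + 1;
  }
  return List::create(
      _["swaps"] = swaps, _["psi"] = psiOut,
      _["initial_score"] = initScore, _["final_score"] = best.score,
      _["iteration_raw"] = iterRaw, _["iteration_best"] = iterBest,
      _["truncated"] = (nsel < k));
}
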