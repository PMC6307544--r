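// Core engine for Boolean-network holobiont coevolution.
//
// A holobiont is one host network plus PM microbial networks, updated as a
// single synchronous dynamical system.  Regulators are (network, node) pairs
// so edges may cross network boundaries.  Truth tables are indexed with the
// first-listed regulator as the most significant bit.  All randomness flows
// through R's RNG (unif_rand), so results are reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <cmath>

using namespace Rcpp;

// ------------------------------------------------------------------ types --

struct Node {
  std::vector<int> rnet;        // regulator network indices (0-based)
  std::vector<int> rnode;       // regulator node indices (0-based)
  std::vector<unsigned char> table;  // length 2^k, MSB = first regulator
};

struct Net {
  std::vector<Node> nodes;
  std::vector<int> signal;      // 0-based signal node indices
  std::vector<unsigned char> init;
  double mut;                   // accumulated applied mutations (lineage)
};

struct Holo {
  std::vector<Net> nets;        // nets[0] = host
  std::vector<int> niche;       // per net: host -1, microbe j in [0, PG);
                                // empty when no niche partition (control /
                                // non-specialized schemes)
};

typedef std::vector<std::vector<unsigned char>> State;

// -------------------------------------------------------------------- rng --

static inline double ru() { return unif_rand(); }

static inline int ri(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// ---------------------------------------------------------- R conversion --

static Net net_from_list(const List& nl) {
  Net nw;
  List nodes = nl["nodes"];
  nw.nodes.resize(nodes.size());
  for (R_xlen_t i = 0; i < nodes.size(); ++i) {
    List nd = nodes[i];
    IntegerVector rn = nd["reg_net"], rm = nd["reg_node"], tb = nd["table"];
    if ((R_xlen_t)tb.size() != (R_xlen_t)1 << rn.size())
      stop("truth table length must be 2^k");
    Node& out = nw.nodes[i];
    out.rnet.assign(rn.begin(), rn.end());
    out.rnode.assign(rm.begin(), rm.end());
    for (int& v : out.rnet) v -= 1;
    for (int& v : out.rnode) v -= 1;
    out.table.assign(tb.begin(), tb.end());
  }
  IntegerVector sig = nl["signal"], init = nl["init"];
  nw.signal.assign(sig.begin(), sig.end());
  for (int& v : nw.signal) v -= 1;
  nw.init.assign(init.begin(), init.end());
  nw.mut = as<double>(nl["mutation_count"]);
  return nw;
}

static Holo holo_from_list(const List& hl) {
  Holo h;
  List nets = hl["networks"];
  h.nets.reserve(nets.size());
  for (R_xlen_t i = 0; i < nets.size(); ++i)
    h.nets.push_back(net_from_list(nets[i]));
  if (hl.containsElementNamed("niche") && !Rf_isNull(hl["niche"])) {
    IntegerVector ni = hl["niche"];
    if ((size_t)ni.size() != h.nets.size() - 1)
      stop("niche vector must have one entry per microbe");
    h.niche.resize(h.nets.size());
    h.niche[0] = -1;
    for (R_xlen_t j = 0; j < ni.size(); ++j) h.niche[j + 1] = ni[j] - 1;
  }
  // validate regulator references
  for (size_t i = 0; i < h.nets.size(); ++i)
    for (size_t n = 0; n < h.nets[i].nodes.size(); ++n) {
      const Node& nd = h.nets[i].nodes[n];
      for (size_t j = 0; j < nd.rnet.size(); ++j) {
        if (nd.rnet[j] < 0 || nd.rnet[j] >= (int)h.nets.size())
          stop("dangling regulator reference: network index out of range");
        if (nd.rnode[j] < 0 ||
            nd.rnode[j] >= (int)h.nets[nd.rnet[j]].nodes.size())
          stop("dangling regulator reference: node index out of range");
      }
    }
  return h;
}

static List net_to_list(const Net& nw) {
  List nodes(nw.nodes.size());
  for (size_t i = 0; i < nw.nodes.size(); ++i) {
    const Node& nd = nw.nodes[i];
    IntegerVector rn(nd.rnet.size()), rm(nd.rnode.size()), tb(nd.table.size());
    for (size_t j = 0; j < nd.rnet.size(); ++j) {
      rn[j] = nd.rnet[j] + 1;
      rm[j] = nd.rnode[j] + 1;
    }
    for (size_t j = 0; j < nd.table.size(); ++j) tb[j] = nd.table[j];
    nodes[i] = List::create(_["reg_net"] = rn, _["reg_node"] = rm,
                            _["table"] = tb);
  }
  IntegerVector sig(nw.signal.size()), init(nw.init.size());
  for (size_t j = 0; j < nw.signal.size(); ++j) sig[j] = nw.signal[j] + 1;
  for (size_t j = 0; j < nw.init.size(); ++j) init[j] = nw.init[j];
  List out = List::create(_["nodes"] = nodes, _["signal"] = sig,
                          _["init"] = init,
                          _["mutation_count"] = nw.mut);
  out.attr("class") = "bn_network";
  return out;
}

static List holo_to_list(const Holo& h) {
  List nets(h.nets.size());
  for (size_t i = 0; i < h.nets.size(); ++i) nets[i] = net_to_list(h.nets[i]);
  RObject niche = R_NilValue;
  if (!h.niche.empty()) {
    IntegerVector ni(h.nets.size() - 1);
    for (size_t j = 1; j < h.nets.size(); ++j) ni[j - 1] = h.niche[j] + 1;
    niche = ni;
  }
  List out = List::create(_["networks"] = nets, _["niche"] = niche);
  out.attr("class") = "holobiont";
  return out;
}

// ---------------------------------------------------------------- dynamics --

// One synchronous update.  `detached`, when non-null, marks networks whose
// cross-boundary regulator values are read as 0 (in both directions);
// within-network edges are untouched.  Nodes with no regulators freeze.
static void do_step(const Holo& h, const State& cur, State& nxt,
                    const std::vector<unsigned char>* detached) {
  for (size_t i = 0; i < h.nets.size(); ++i) {
    const Net& nw = h.nets[i];
    for (size_t n = 0; n < nw.nodes.size(); ++n) {
      const Node& nd = nw.nodes[n];
      size_t k = nd.rnet.size();
      if (k == 0) { nxt[i][n] = cur[i][n]; continue; }
      unsigned idx = 0;
      for (size_t j = 0; j < k; ++j) {
        int sn = nd.rnet[j];
        unsigned char v = cur[sn][nd.rnode[j]];
        if (detached && sn != (int)i && ((*detached)[sn] || (*detached)[i]))
          v = 0;
        idx = (idx << 1) | v;
      }
      nxt[i][n] = nd.table[idx];
    }
  }
}

// Evaluate every per-task error of one holobiont.
//   tasksH:  T x tm host targets;  tasksM: PM x tm microbial targets
//   initH:   T x N host initial conditions (one per task)
//   scope:   0 = full dynamics; 1 = host-plus-niche (other niches' cross
//            inputs read as 0 while evaluating a task, specialized scheme)
//   task_niche: per task, 0-based niche index (empty when not specialized)
// Fills errH (length T) and errM (PM x T).
static void eval_holo(const Holo& h,
                      const std::vector<std::vector<int>>& tasksH,
                      const std::vector<std::vector<int>>& tasksM,
                      const std::vector<std::vector<unsigned char>>& initH,
                      int tm,
                      const std::vector<unsigned char>* detached,
                      int scope,
                      const std::vector<int>& task_niche,
                      std::vector<double>& errH,
                      std::vector<std::vector<double>>& errM) {
  size_t nn = h.nets.size();
  int T = (int)tasksH.size();
  errH.assign(T, 0.0);
  errM.assign(nn - 1, std::vector<double>(T, 0.0));
  State cur(nn), nxt(nn);
  for (size_t i = 0; i < nn; ++i) {
    cur[i].resize(h.nets[i].nodes.size());
    nxt[i].resize(h.nets[i].nodes.size());
  }
  std::vector<unsigned char> mask;
  for (int tau = 0; tau < T; ++tau) {
    const std::vector<unsigned char>* det = detached;
    if (scope == 1 && !h.niche.empty() && !task_niche.empty()) {
      mask.assign(nn, 0);
      if (detached) mask = *detached;
      for (size_t j = 1; j < nn; ++j)
        if (h.niche[j] != task_niche[tau]) mask[j] = 1;
      det = &mask;
    }
    // initial state: host gets the task's initial condition, each microbe
    // its own fixed one
    for (size_t n = 0; n < cur[0].size(); ++n) cur[0][n] = initH[tau][n];
    for (size_t i = 1; i < nn; ++i) cur[i] = h.nets[i].init;
    for (int t = 1; t <= tm; ++t) {
      do_step(h, cur, nxt, det);
      std::swap(cur, nxt);
      int r = 0;
      for (int s : h.nets[0].signal) r += cur[0][s];
      double d = r - tasksH[tau][t - 1];
      errH[tau] += d * d;
      for (size_t j = 1; j < nn; ++j) {
        int rm = 0;
        for (int s : h.nets[j].signal) rm += cur[j][s];
        double dm = rm - tasksM[j - 1][t - 1];
        errM[j - 1][tau] += dm * dm;
      }
    }
    errH[tau] /= tm;
    for (size_t j = 1; j < nn; ++j) errM[j - 1][tau] /= tm;
  }
}

// Aggregate per-task errors into the holobiont error.
//   mode: 4 or 5 (the two error definitions); specialized scheme instead
//   averages the per-niche errors (each computed like mode 4 within a niche).
// Also reports the host total and per-microbe totals.
static double holo_error(const Holo& h,
                         const std::vector<double>& errH,
                         const std::vector<std::vector<double>>& errM,
                         int mode,
                         const std::vector<int>& task_niche,
                         double& xiH,
                         std::vector<double>& xiM,
                         std::vector<double>& niche_err) {
  int T = (int)errH.size();
  int PM = (int)errM.size();
  xiH = std::accumulate(errH.begin(), errH.end(), 0.0) / T;
  xiM.assign(PM, 0.0);
  niche_err.clear();
  bool specialized = !h.niche.empty() && !task_niche.empty();
  if (!specialized) {
    for (int j = 0; j < PM; ++j)
      xiM[j] = std::accumulate(errM[j].begin(), errM[j].end(), 0.0) / T;
    if (PM == 0) return xiH;
    double s = std::accumulate(xiM.begin(), xiM.end(), 0.0);
    if (mode == 4) return (xiH + s) / (1.0 + PM);
    return 0.5 * (xiH + s / PM);
  }
  int PG = 0;
  for (size_t j = 1; j < h.nets.size(); ++j)
    PG = std::max(PG, h.niche[j] + 1);
  niche_err.assign(PG, 0.0);
  for (int g = 0; g < PG; ++g) {
    std::vector<int> tasks, mics;
    for (int tau = 0; tau < T; ++tau)
      if (task_niche[tau] == g) tasks.push_back(tau);
    for (int j = 0; j < PM; ++j)
      if (h.niche[j + 1] == g) mics.push_back(j);
    int q = (int)tasks.size(), p = (int)mics.size();
    double hm = 0.0;
    for (int tau : tasks) hm += errH[tau];
    hm /= q;
    double ms = 0.0;
    for (int j : mics) {
      double mj = 0.0;
      for (int tau : tasks) mj += errM[j][tau];
      mj /= q;
      xiM[j] = mj;  // microbe total = mean over its niche's tasks
      ms += mj;
    }
    niche_err[g] = (hm + ms) / (1.0 + p);
  }
  return std::accumulate(niche_err.begin(), niche_err.end(), 0.0) / PG;
}

// --------------------------------------------------------------- mutation --

static bool has_reg(const Node& nd, int sn, int sm) {
  for (size_t j = 0; j < nd.rnet.size(); ++j)
    if (nd.rnet[j] == sn && nd.rnode[j] == sm) return true;
  return false;
}

// Networks a new connection involving `src` may reach: the host and all
// microbes in general, restricted to {host} U own niche under the
// specialized wiring constraint.
static int pick_partner(const Holo& h, int src) {
  int PM = (int)h.nets.size() - 1;
  if (PM == 0) return 0;
  if (src == 0 || h.niche.empty()) return ri(PM + 1);
  std::vector<int> cand;
  cand.push_back(0);
  for (size_t j = 1; j < h.nets.size(); ++j)
    if (h.niche[j] == h.niche[src]) cand.push_back((int)j);
  return cand[ri((int)cand.size())];
}

// Truth-table policies when a node's in-degree changes.  The update rule
// itself never specifies them, so both conventions are supported and set
// per entry point (single-threaded).
//   add_fill:    0 = new half gets fresh uniform random bits,
//                1 = new half copies the old table (neutral addition: the
//                    phenotype is unchanged until the table mutates)
//   remove_keep: 0 = keep the half where the removed regulator reads 0,
//                1 = keep the half for a uniformly drawn regulator value
static int g_add_fill = 1;
static int g_remove_keep = 0;

// Insert a new regulator at the front of the list (most significant bit).
// The old table occupies the new-regulator = 0 half contiguously.
static void add_reg(Node& nd, int sn, int sm) {
  nd.rnet.insert(nd.rnet.begin(), sn);
  nd.rnode.insert(nd.rnode.begin(), sm);
  size_t L = nd.table.size();
  nd.table.resize(2 * L);
  if (g_add_fill == 0) {
    for (size_t i = 0; i < L; ++i)
      nd.table[L + i] = (ru() < 0.5) ? 1 : 0;
  } else if (g_add_fill == 2) {
    for (size_t i = 0; i < 2 * L; ++i)
      nd.table[i] = (ru() < 0.5) ? 1 : 0;
  } else {
    for (size_t i = 0; i < L; ++i) nd.table[L + i] = nd.table[i];
  }
}

// Drop regulator at list position j, restricting the table to one half.
static void remove_reg(Node& nd, int j) {
  size_t k = nd.rnet.size();
  int bit = (int)k - 1 - j;  // MSB-first
  unsigned keepv = (g_remove_keep == 1 && ru() < 0.5) ? 1u : 0u;
  std::vector<unsigned char> nt;
  nt.reserve(nd.table.size() / 2);
  for (size_t idx = 0; idx < nd.table.size(); ++idx)
    if (((idx >> bit) & 1) == keepv) nt.push_back(nd.table[idx]);
  nd.table.swap(nt);
  nd.rnet.erase(nd.rnet.begin() + j);
  nd.rnode.erase(nd.rnode.begin() + j);
}

struct OutEdge { int dnet, dnode, jpos; };

static std::vector<OutEdge> outgoing(const Holo& h, int sn, int sm) {
  std::vector<OutEdge> out;
  for (size_t d = 0; d < h.nets.size(); ++d)
    for (size_t m = 0; m < h.nets[d].nodes.size(); ++m) {
      const Node& nd = h.nets[d].nodes[m];
      for (size_t j = 0; j < nd.rnet.size(); ++j)
        if (nd.rnet[j] == sn && nd.rnode[j] == sm)
          out.push_back({(int)d, (int)m, (int)j});
    }
  return out;
}

static const int RETRIES = 5;

// Apply one mutation event.  kind: 0 rewire, 1 add, 2 remove, 3 flip.
// dir: 0 input, 1 output (ignored for flip).  Returns whether the event
// was applied (no-ops do not increment the mutation counter).
static bool apply_event(Holo& h, int tnet, int tnode, int kind, int dir,
                        int kmax) {
  Net& nw = h.nets[tnet];
  Node& nd = nw.nodes[tnode];
  bool applied = false;
  switch (kind) {
  case 0: {  // rewire: move one endpoint of an existing edge
    if (dir == 0) {
      int k = (int)nd.rnet.size();
      if (k == 0) break;
      int j = ri(k);
      for (int r = 0; r < RETRIES; ++r) {
        int pn = pick_partner(h, tnet);
        int pm = ri((int)h.nets[pn].nodes.size());
        if (has_reg(nd, pn, pm)) continue;  // includes the current edge
        nd.rnet[j] = pn;
        nd.rnode[j] = pm;
        applied = true;
        break;
      }
    } else {
      std::vector<OutEdge> outs = outgoing(h, tnet, tnode);
      if (outs.empty()) break;
      OutEdge e = outs[ri((int)outs.size())];
      for (int r = 0; r < RETRIES; ++r) {
        int pn = pick_partner(h, tnet);
        int pm = ri((int)h.nets[pn].nodes.size());
        if (pn == e.dnet && pm == e.dnode) continue;
        Node& dnew = h.nets[pn].nodes[pm];
        if (has_reg(dnew, tnet, tnode)) continue;
        if ((int)dnew.rnet.size() >= kmax) continue;
        remove_reg(h.nets[e.dnet].nodes[e.dnode], e.jpos);
        add_reg(h.nets[pn].nodes[pm], tnet, tnode);
        applied = true;
        break;
      }
    }
    break;
  }
  case 1: {  // add a new input (or output) connection
    if (dir == 0) {
      if ((int)nd.rnet.size() >= kmax) break;
      for (int r = 0; r < RETRIES; ++r) {
        int pn = pick_partner(h, tnet);
        int pm = ri((int)h.nets[pn].nodes.size());
        if (has_reg(nd, pn, pm)) continue;
        add_reg(nd, pn, pm);
        applied = true;
        break;
      }
    } else {
      for (int r = 0; r < RETRIES; ++r) {
        int pn = pick_partner(h, tnet);
        int pm = ri((int)h.nets[pn].nodes.size());
        Node& dnd = h.nets[pn].nodes[pm];
        if ((int)dnd.rnet.size() >= kmax) continue;
        if (has_reg(dnd, tnet, tnode)) continue;
        add_reg(dnd, tnet, tnode);
        applied = true;
        break;
      }
    }
    break;
  }
  case 2: {  // remove one input (or output) connection
    if (dir == 0) {
      int k = (int)nd.rnet.size();
      if (k == 0) break;
      remove_reg(nd, ri(k));
      applied = true;
    } else {
      std::vector<OutEdge> outs = outgoing(h, tnet, tnode);
      if (outs.empty()) break;
      OutEdge e = outs[ri((int)outs.size())];
      remove_reg(h.nets[e.dnet].nodes[e.dnode], e.jpos);
      applied = true;
    }
    break;
  }
  case 3: {  // flip one truth-table entry
    int L = (int)nd.table.size();
    int j = ri(L);
    nd.table[j] ^= 1;
    applied = true;
    break;
  }
  }
  if (applied) nw.mut += 1;
  return applied;
}

struct Ev { int net, node, kind, dir; };

// Per-node Bernoulli mutation sampling followed by sequential application,
// in a fixed network-then-node order.
static void mutate_holo(Holo& h, double muH, double muM, int kmax) {
  std::vector<Ev> evs;
  for (size_t i = 0; i < h.nets.size(); ++i) {
    double mu = (i == 0) ? muH : muM;
    if (mu <= 0) continue;
    for (size_t n = 0; n < h.nets[i].nodes.size(); ++n) {
      if (ru() < mu) {
        int kind = ri(4);
        int dir = (kind == 3) ? 0 : ri(2);
        evs.push_back({(int)i, (int)n, kind, dir});
      }
    }
  }
  for (const Ev& e : evs) apply_event(h, e.net, e.node, e.kind, e.dir, kmax);
}

// ---------------------------------------------------------------- helpers --

static std::vector<std::vector<int>> mat_to_rows(const IntegerMatrix& m) {
  std::vector<std::vector<int>> out(m.nrow(), std::vector<int>(m.ncol()));
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j) out[i][j] = m(i, j);
  return out;
}

static std::vector<std::vector<unsigned char>>
mat_to_rows_u8(const IntegerMatrix& m) {
  std::vector<std::vector<unsigned char>> out(
      m.nrow(), std::vector<unsigned char>(m.ncol()));
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j) out[i][j] = (unsigned char)m(i, j);
  return out;
}

static std::vector<int> task_niche_from_r(const IntegerVector& tn) {
  std::vector<int> out(tn.begin(), tn.end());
  for (int& v : out) v -= 1;
  return out;
}

static std::vector<unsigned char> detached_from_r(const LogicalVector& d,
                                                  size_t nn) {
  std::vector<unsigned char> out(nn, 0);
  if (d.size() == 0) return out;
  if ((size_t)d.size() != nn) stop("detached mask length mismatch");
  for (size_t i = 0; i < nn; ++i) out[i] = d[i] ? 1 : 0;
  return out;
}

static bool any_true(const std::vector<unsigned char>& v) {
  for (unsigned char x : v) if (x) return true;
  return false;
}

// ---------------------------------------------------------------- exports --

// [[Rcpp::export]]
List cpp_step(List holo, List state, LogicalVector detached) {
  Holo h = holo_from_list(holo);
  size_t nn = h.nets.size();
  if ((size_t)state.size() != nn) stop("state must cover every network");
  State cur(nn), nxt(nn);
  for (size_t i = 0; i < nn; ++i) {
    IntegerVector s = state[i];
    if ((size_t)s.size() != h.nets[i].nodes.size())
      stop("state vector length mismatch for network ", i + 1);
    cur[i].assign(s.begin(), s.end());
    nxt[i].resize(h.nets[i].nodes.size());
  }
  std::vector<unsigned char> det = detached_from_r(detached, nn);
  do_step(h, cur, nxt, any_true(det) ? &det : (std::vector<unsigned char>*)0);
  List out(nn);
  for (size_t i = 0; i < nn; ++i) {
    IntegerVector s(nxt[i].size());
    for (size_t n = 0; n < nxt[i].size(); ++n) s[n] = nxt[i][n];
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_trajectory(List holo, IntegerVector host_init, int t_max,
                        LogicalVector detached) {
  Holo h = holo_from_list(holo);
  size_t nn = h.nets.size();
  std::vector<unsigned char> det = detached_from_r(detached, nn);
  std::vector<unsigned char>* dp =
      any_true(det) ? &det : (std::vector<unsigned char>*)0;
  State cur(nn), nxt(nn);
  if ((size_t)host_init.size() != h.nets[0].nodes.size())
    stop("host initial condition length mismatch");
  cur[0].assign(host_init.begin(), host_init.end());
  for (size_t i = 1; i < nn; ++i) cur[i] = h.nets[i].init;
  for (size_t i = 0; i < nn; ++i) nxt[i].resize(h.nets[i].nodes.size());
  List out(nn);
  std::vector<IntegerMatrix> mats;
  for (size_t i = 0; i < nn; ++i) {
    IntegerMatrix m(t_max + 1, (int)h.nets[i].nodes.size());
    for (size_t n = 0; n < cur[i].size(); ++n) m(0, n) = cur[i][n];
    mats.push_back(m);
  }
  for (int t = 1; t <= t_max; ++t) {
    do_step(h, cur, nxt, dp);
    std::swap(cur, nxt);
    for (size_t i = 0; i < nn; ++i)
      for (size_t n = 0; n < cur[i].size(); ++n) mats[i](t, n) = cur[i][n];
  }
  for (size_t i = 0; i < nn; ++i) out[i] = mats[i];
  return out;
}

// [[Rcpp::export]]
List cpp_evaluate(List holo, IntegerMatrix tasksH, IntegerMatrix tasksM,
                  IntegerMatrix initH, int tm, int mode, int scope,
                  IntegerVector task_niche, LogicalVector detached) {
  Holo h = holo_from_list(holo);
  std::vector<std::vector<int>> tH = mat_to_rows(tasksH);
  std::vector<std::vector<int>> tM = mat_to_rows(tasksM);
  std::vector<std::vector<unsigned char>> iH = mat_to_rows_u8(initH);
  std::vector<int> tn = task_niche_from_r(task_niche);
  std::vector<unsigned char> det = detached_from_r(detached, h.nets.size());
  std::vector<unsigned char>* dp =
      any_true(det) ? &det : (std::vector<unsigned char>*)0;
  std::vector<double> errH;
  std::vector<std::vector<double>> errM;
  eval_holo(h, tH, tM, iH, tm, dp, scope, tn, errH, errM);
  double xiH;
  std::vector<double> xiM, nerr;
  double xiL = holo_error(h, errH, errM, mode, tn, xiH, xiM, nerr);
  int T = (int)errH.size(), PM = (int)errM.size();
  NumericMatrix em(PM, T);
  for (int j = 0; j < PM; ++j)
    for (int t = 0; t < T; ++t) em(j, t) = errM[j][t];
  return List::create(
      _["host_per_task"] = NumericVector(errH.begin(), errH.end()),
      _["host_total"] = xiH,
      _["microbial_per_task"] = em,
      _["microbial_totals"] = NumericVector(xiM.begin(), xiM.end()),
      _["niche_errors"] = nerr.empty()
          ? RObject(R_NilValue)
          : RObject(NumericVector(nerr.begin(), nerr.end())),
      _["holobiont_error"] = xiL);
}

// [[Rcpp::export]]
DataFrame cpp_sample_mutations(List holo, double mu_host, double mu_microbe) {
  Holo h = holo_from_list(holo);
  std::vector<int> net, node, kind, dir;
  for (size_t i = 0; i < h.nets.size(); ++i) {
    double mu = (i == 0) ? mu_host : mu_microbe;
    if (mu <= 0) continue;
    for (size_t n = 0; n < h.nets[i].nodes.size(); ++n) {
      if (ru() < mu) {
        int k = ri(4);
        int d = (k == 3) ? NA_INTEGER : ri(2);
        net.push_back((int)i + 1);
        node.push_back((int)n + 1);
        kind.push_back(k);
        dir.push_back(d);
      }
    }
  }
  return DataFrame::create(_["network"] = net, _["node"] = node,
                           _["kind_code"] = kind, _["dir_code"] = dir);
}

// [[Rcpp::export]]
List cpp_apply_mutations(List holo, IntegerVector net, IntegerVector node,
                         IntegerVector kind, IntegerVector dir, int k_max,
                         int add_fill, int remove_keep) {
  g_add_fill = add_fill;
  g_remove_keep = remove_keep;
  Holo h = holo_from_list(holo);
  LogicalVector applied(net.size());
  for (R_xlen_t e = 0; e < net.size(); ++e) {
    int i = net[e] - 1, n = node[e] - 1;
    if (i < 0 || i >= (int)h.nets.size() || n < 0 ||
        n >= (int)h.nets[i].nodes.size())
      stop("mutation event targets a non-existent node");
    int d = (dir[e] == NA_INTEGER) ? 0 : dir[e];
    applied[e] = apply_event(h, i, n, kind[e], d, k_max);
  }
  return List::create(_["holobiont"] = holo_to_list(h),
                      _["applied"] = applied);
}

// [[Rcpp::export]]
int cpp_pick_partner(List holo, int source_network) {
  Holo h = holo_from_list(holo);
  return pick_partner(h, source_network - 1) + 1;
}

// Remove every cross-boundary edge between detached networks and the rest
// (and among detached networks), via the input-removal table policy.
// [[Rcpp::export]]
List cpp_excise(List holo, LogicalVector detached) {
  g_remove_keep = 0;  // excision must match freeze_zero dynamics exactly
  Holo h = holo_from_list(holo);
  std::vector<unsigned char> det = detached_from_r(detached, h.nets.size());
  for (size_t i = 0; i < h.nets.size(); ++i)
    for (size_t n = 0; n < h.nets[i].nodes.size(); ++n) {
      Node& nd = h.nets[i].nodes[n];
      for (int j = (int)nd.rnet.size() - 1; j >= 0; --j) {
        int sn = nd.rnet[j];
        if (sn != (int)i && (det[sn] || det[i])) remove_reg(nd, j);
      }
    }
  return holo_to_list(h);
}

// ----------------------------------------------------------- evolutionary --

struct EvalCache {
  std::vector<double> xiL, xiH, xiM_mean;
};

// Select the n_surv smallest errors.  tie_break: 0 = stable input order,
// 1 = uniform random among ties (a seeded Fisher-Yates permutation applied
// before the stable sort).  Random tie-breaking lets selectively neutral
// mutants replace incumbent copies, which permits drift along neutral
// networks of equal-error genotypes.
static int g_tie_break = 1;

static void select_indices(const std::vector<double>& err, int n_surv,
                           std::vector<int>& keep) {
  std::vector<int> ord(err.size());
  std::iota(ord.begin(), ord.end(), 0);
  if (g_tie_break == 1)
    for (int i = (int)ord.size() - 1; i > 0; --i)
      std::swap(ord[i], ord[ri(i + 1)]);
  std::stable_sort(ord.begin(), ord.end(),
                   [&err](int a, int b) { return err[a] < err[b]; });
  keep.assign(ord.begin(), ord.begin() + n_surv);
}

// Full evolutionary loop: P identical copies of holo0, then per generation
// mutate -> evaluate -> record -> select & replicate.  Records include the
// pre-mutation generation 0.
// [[Rcpp::export]]
List cpp_evolve(List holo0, IntegerMatrix tasksH, IntegerMatrix tasksM,
                IntegerMatrix initH, IntegerVector task_niche, int pop_size,
                int n_survivors, int copies_per_survivor, double mu_host,
                double mu_microbe, double delta_a, int mode, int scope,
                int k_max, int tm, int n_generations,
                bool return_population, int add_fill, int remove_keep,
                int mutate_survivors, int tie_break) {
  g_add_fill = add_fill;
  g_remove_keep = remove_keep;
  g_tie_break = tie_break;
  Holo h0 = holo_from_list(holo0);
  std::vector<std::vector<int>> tH = mat_to_rows(tasksH);
  std::vector<std::vector<int>> tM = mat_to_rows(tasksM);
  std::vector<std::vector<unsigned char>> iH = mat_to_rows_u8(initH);
  std::vector<int> tn = task_niche_from_r(task_niche);
  if (n_survivors * (1 + copies_per_survivor) != pop_size)
    stop("n_survivors * (1 + copies_per_survivor) must equal pop_size");

  std::vector<Holo> pop(pop_size, h0);
  int PM = (int)h0.nets.size() - 1;
  // Two recording points per generation: the full mutated population before
  // selection ("pre"), and the population after selection and replication
  // ("post", the parents of the next generation; free of the fresh
  // mutational load).
  NumericMatrix rec(n_generations + 1, 13);
  colnames(rec) = CharacterVector::create(
      "generation", "xi_h", "xi_m", "xi_l", "p_a", "omega_h", "best_xi_l",
      "pre_xi_h", "pre_xi_m", "pre_xi_l", "pre_p_a", "pre_omega_h",
      "pre_best_xi_l");
  std::vector<double> errH;
  std::vector<std::vector<double>> errM;
  std::vector<double> xiM, nerr;
  std::vector<double> popL(pop_size), popH(pop_size), popM(pop_size),
      popOm(pop_size);

  for (int g = 0; g <= n_generations; ++g) {
    if (g > 0)
      for (int i = 0; i < pop_size; ++i) {
        // after replication individual 0 of each survivor block is the
        // survivor itself; optionally exempt it from mutation
        if (!mutate_survivors && i % (1 + copies_per_survivor) == 0)
          continue;
        mutate_holo(pop[i], mu_host, mu_microbe, k_max);
      }
    for (int i = 0; i < pop_size; ++i) {
      eval_holo(pop[i], tH, tM, iH, tm, 0, scope, tn, errH, errM);
      double xiH;
      double xiL = holo_error(pop[i], errH, errM, mode, tn, xiH, xiM, nerr);
      popL[i] = xiL;
      popH[i] = xiH;
      popM[i] = PM > 0
          ? std::accumulate(xiM.begin(), xiM.end(), 0.0) / PM
          : NA_REAL;
      popOm[i] = pop[i].nets[0].mut;
    }
    rec(g, 0) = g;
    double sH = 0, sM = 0, sL = 0, sOm = 0;
    int nad = 0;
    for (int i = 0; i < pop_size; ++i) {
      sH += popH[i];
      sL += popL[i];
      if (PM > 0) sM += popM[i];
      if (popH[i] <= delta_a) ++nad;
      sOm += popOm[i];
    }
    rec(g, 7) = sH / pop_size;
    rec(g, 8) = PM > 0 ? sM / pop_size : NA_REAL;
    rec(g, 9) = sL / pop_size;
    rec(g, 10) = (double)nad / pop_size;
    rec(g, 11) = sOm / pop_size;
    rec(g, 12) = *std::min_element(popL.begin(), popL.end());
    // post-selection statistics: the n_survivors best, each weighted by
    // its 1 + copies_per_survivor representatives
    std::vector<int> keep;
    select_indices(popL, n_survivors, keep);
    sH = sM = sL = sOm = 0;
    nad = 0;
    for (int s : keep) {
      sH += popH[s];
      sL += popL[s];
      if (PM > 0) sM += popM[s];
      if (popH[s] <= delta_a) ++nad;
      sOm += popOm[s];
    }
    rec(g, 1) = sH / n_survivors;
    rec(g, 2) = PM > 0 ? sM / n_survivors : NA_REAL;
    rec(g, 3) = sL / n_survivors;
    rec(g, 4) = (double)nad / n_survivors;
    rec(g, 5) = sOm / n_survivors;
    rec(g, 6) = *std::min_element(popL.begin(), popL.end());
    if (g < n_generations) {
      std::vector<Holo> next;
      next.reserve(pop_size);
      for (int s : keep) {
        next.push_back(pop[s]);
        for (int c = 0; c < copies_per_survivor; ++c) next.push_back(pop[s]);
      }
      pop.swap(next);
    }
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  List popOut = R_NilValue;
  if (return_population) {
    List pl(pop_size);
    for (int i = 0; i < pop_size; ++i) pl[i] = holo_to_list(pop[i]);
    popOut = pl;
  }
  return List::create(_["records"] = rec, _["population"] = popOut,
                      _["final_xi_l"] = NumericVector(popL.begin(),
                                                      popL.end()),
                      _["final_xi_h"] = NumericVector(popH.begin(),
                                                      popH.end()));
}

// Standalone training of one network on one task until the best individual
// crosses the adaptation threshold (strict <).  Returns the best network
// with its mutation counter reset.
// [[Rcpp::export]]
List cpp_pretrain(List network, IntegerVector task, int pop_size,
                  int n_survivors, int copies_per_survivor, double mu,
                  double delta_a, int max_generations, int k_max, int tm,
                  int add_fill, int remove_keep, int mutate_survivors,
                  int tie_break) {
  g_add_fill = add_fill;
  g_remove_keep = remove_keep;
  g_tie_break = tie_break;
  List hl = List::create(_["networks"] = List::create(network),
                         _["niche"] = R_NilValue);
  Holo h0 = holo_from_list(hl);
  std::vector<std::vector<int>> tH(1, std::vector<int>(task.begin(),
                                                       task.end()));
  std::vector<std::vector<int>> tM;  // no partners
  std::vector<std::vector<unsigned char>> iH(1, h0.nets[0].init);
  std::vector<int> tn;
  std::vector<Holo> pop(pop_size, h0);
  std::vector<double> errH;
  std::vector<std::vector<double>> errM;
  std::vector<double> popE(pop_size);

  for (int g = 0; g <= max_generations; ++g) {
    if (g > 0)
      for (int i = 0; i < pop_size; ++i) {
        if (!mutate_survivors && i % (1 + copies_per_survivor) == 0)
          continue;
        mutate_holo(pop[i], mu, 0.0, k_max);
      }
    int best = 0;
    for (int i = 0; i < pop_size; ++i) {
      eval_holo(pop[i], tH, tM, iH, tm, 0, 0, tn, errH, errM);
      popE[i] = errH[0];
      if (popE[i] < popE[best]) best = i;
    }
    if (popE[best] < delta_a) {
      Net out = pop[best].nets[0];
      out.mut = 0;
      return List::create(_["network"] = net_to_list(out),
                          _["generations"] = g, _["success"] = true,
                          _["best_error"] = popE[best]);
    }
    std::vector<int> keep;
    select_indices(popE, n_survivors, keep);
    std::vector<Holo> next;
    next.reserve(pop_size);
    for (int s : keep) {
      next.push_back(pop[s]);
      for (int c = 0; c < copies_per_survivor; ++c) next.push_back(pop[s]);
    }
    pop.swap(next);
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["network"] = R_NilValue, _["generations"] =
                          max_generations,
                      _["success"] = false, _["best_error"] = NA_REAL);
}
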