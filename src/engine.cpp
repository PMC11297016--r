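// Core Turning Machine engine.
//
// A configuration of a fixed program is encoded by its move-count vector
// (one non-negative integer per monomer, bounded by |initial state|);
// geometry is always derived from it by prefix sums, so state hashing in
// the reachability search is exact integer work.
//
// Conventions (shared with the R layer):
//   * direction indices 0..5 map to the unit vectors
//     (+x, +y, +w, -x, -y, -w) with x=(1,0), y=(0,1), w=(-1,1);
//   * monomer i points at monomer i+1; the last monomer has no direction;
//   * a move at monomer i rotates its direction by +1 (positive state) or
//     -1 (negative state) modulo 6 and rigidly translates every later
//     monomer by the direction two steps around the tuple from the
//     monomer's current direction.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int DX[6] = {1, 0, -1, -1, 0, 1};
static const int DY[6] = {0, 1, 1, 0, -1, -1};

static inline int mod6(int a) { return ((a % 6) + 6) % 6; }

static inline int64_t packxy(int x, int y) {
  return (static_cast<int64_t>(x) << 32) ^ static_cast<uint32_t>(y);
}

// splitmix64 finaliser; the standard library's integer hash is the
// identity, which collapses every point of a grid row into one bucket
static inline uint64_t mixhash(int64_t k) {
  uint64_t x = static_cast<uint64_t>(k) + 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Open-addressing position -> monomer index map, rebuilt after each applied
// move (n is small; rebuild keeps deletion out of the picture).
struct PosMap {
  std::vector<int64_t> key;
  std::vector<int> val;
  size_t mask = 0;

  void build(const std::vector<int>& px, const std::vector<int>& py) {
    size_t cap = 4;
    while (cap < px.size() * 2) cap <<= 1;
    key.assign(cap, INT64_MIN);
    val.assign(cap, -1);
    mask = cap - 1;
    for (size_t i = 0; i < px.size(); ++i) insert(packxy(px[i], py[i]), (int)i);
  }
  void insert(int64_t k, int v) {
    size_t h = mixhash(k) & mask;
    while (key[h] != INT64_MIN) {
      if (key[h] == k) { val[h] = v; return; }  // caller checks duplicates
      h = (h + 1) & mask;
    }
    key[h] = k;
    val[h] = v;
  }
  // returns monomer index at the position, or -1
  int find(int64_t k) const {
    size_t h = mixhash(k) & mask;
    while (key[h] != INT64_MIN) {
      if (key[h] == k) return val[h];
      h = (h + 1) & mask;
    }
    return -1;
  }
};

struct Engine {
  int n;
  std::vector<int> s0;    // initial states
  std::vector<int> d0;    // initial direction indices (last entry unused)
  std::vector<int> mv;    // move counts
  std::vector<int> px, py;
  PosMap pm;

  static int sgn(int s) { return (s > 0) - (s < 0); }

  int curState(int i) const { return s0[i] - sgn(s0[i]) * mv[i]; }
  int curDir(int i) const { return mod6(d0[i] + sgn(s0[i]) * mv[i]); }

  // Rebuilds geometry from the move-count vector.  Returns "" on success or
  // an error message.
  std::string rebuild() {
    px.assign(n, 0);
    py.assign(n, 0);
    for (int i = 0; i < n; ++i) {
      if (mv[i] < 0 || mv[i] > std::abs(s0[i]))
        return "move count out of range at monomer " + std::to_string(i + 1);
    }
    for (int i = 0; i + 1 < n; ++i) {
      int d = curDir(i);
      px[i + 1] = px[i] + DX[d];
      py[i + 1] = py[i] + DY[d];
    }
    pm.build(px, py);
    for (int i = 0; i < n; ++i)
      if (pm.find(packxy(px[i], py[i])) != i)
        return "self-intersecting configuration (repeated position)";
    return "";
  }

  void init(const IntegerVector& states0, const IntegerVector& dirs0,
            const IntegerVector& moves) {
    n = states0.size();
    s0.assign(states0.begin(), states0.end());
    d0.assign(dirs0.begin(), dirs0.end());
    mv.assign(moves.begin(), moves.end());
    std::string err = rebuild();
    if (!err.empty()) stop(err);
  }

  // Is the turning rule applicable to monomer i (0-based)?
  bool applicable(int i) const {
    int s = curState(i);
    if (s == 0) return false;
    if (i == n - 1) return true;  // empty head: pure state change
    int i2 = mod6(curDir(i) + (s > 0 ? 2 : -2));
    int dx = DX[i2], dy = DY[i2];
    // blocked iff translated head meets tail; walk the smaller side
    if (n - 1 - i <= i + 1) {
      for (int j = i + 1; j < n; ++j) {
        int hit = pm.find(packxy(px[j] + dx, py[j] + dy));
        if (hit >= 0 && hit <= i) return false;
      }
    } else {
      for (int l = 0; l <= i; ++l) {
        int hit = pm.find(packxy(px[l] - dx, py[l] - dy));
        if (hit > i) return false;
      }
    }
    return true;
  }

  // Applies the rule at monomer i (assumed applicable) and refreshes
  // geometry incrementally.
  void apply(int i) {
    int s = curState(i);
    if (i < n - 1) {
      int i2 = mod6(curDir(i) + (s > 0 ? 2 : -2));
      int dx = DX[i2], dy = DY[i2];
      for (int j = i + 1; j < n; ++j) {
        px[j] += dx;
        py[j] += dy;
      }
    }
    mv[i] += 1;
    pm.build(px, py);
  }

  std::vector<int> applicableSet() const {
    std::vector<int> out;
    for (int i = 0; i < n; ++i)
      if (applicable(i)) out.push_back(i);
    return out;
  }

  std::string keyOf() const {
    std::string k(n, '\0');
    for (int i = 0; i < n; ++i) k[i] = static_cast<char>(mv[i]);
    return k;
  }
  void setFromKey(const std::string& k) {
    for (int i = 0; i < n; ++i) mv[i] = static_cast<unsigned char>(k[i]);
    rebuild();
  }
};

// [[Rcpp::export(name = ".eng_positions")]]
IntegerMatrix eng_positions(IntegerVector states0, IntegerVector dirs0,
                            IntegerVector moves) {
  Engine e;
  e.init(states0, dirs0, moves);
  IntegerMatrix out(e.n, 2);
  for (int i = 0; i < e.n; ++i) {
    out(i, 0) = e.px[i];
    out(i, 1) = e.py[i];
  }
  return out;
}

// [[Rcpp::export(name = ".eng_applicable_set")]]
IntegerVector eng_applicable_set(IntegerVector states0, IntegerVector dirs0,
                                 IntegerVector moves) {
  Engine e;
  e.init(states0, dirs0, moves);
  std::vector<int> a = e.applicableSet();
  IntegerVector out(a.size());
  for (size_t i = 0; i < a.size(); ++i) out[i] = a[i] + 1;
  return out;
}

// [[Rcpp::export(name = ".eng_rule_applicable")]]
bool eng_rule_applicable(IntegerVector states0, IntegerVector dirs0,
                         IntegerVector moves, int i) {
  Engine e;
  e.init(states0, dirs0, moves);
  if (i < 1 || i > e.n) stop("monomer index out of range");
  return e.applicable(i - 1);
}

// [[Rcpp::export(name = ".eng_apply")]]
IntegerVector eng_apply(IntegerVector states0, IntegerVector dirs0,
                        IntegerVector moves, int i) {
  Engine e;
  e.init(states0, dirs0, moves);
  if (i < 1 || i > e.n) stop("monomer index out of range");
  if (!e.applicable(i - 1))
    stop("BlockedMove: rule not applicable to monomer " + std::to_string(i));
  e.apply(i - 1);
  return IntegerVector(e.mv.begin(), e.mv.end());
}

// Replays a scripted move sequence; returns the first failing position
// (1-based) or 0 if the whole sequence applied.
// [[Rcpp::export(name = ".eng_replay")]]
List eng_replay(IntegerVector states0, IntegerVector dirs0,
                IntegerVector moves, IntegerVector seq) {
  Engine e;
  e.init(states0, dirs0, moves);
  int fail = 0;
  for (int k = 0; k < seq.size(); ++k) {
    int i = seq[k] - 1;
    if (i < 0 || i >= e.n || !e.applicable(i)) {
      fail = k + 1;
      break;
    }
    e.apply(i);
  }
  return List::create(_["moves"] = IntegerVector(e.mv.begin(), e.mv.end()),
                      _["fail_at"] = fail);
}

// Continuous-time dynamics: every applicable move carries an independent
// rate-1 exponential clock.  Simulated by thinning: propose among monomers
// with nonzero state at total rate m; a proposal on a blocked monomer is a
// null event (the holding-time law in each configuration is untouched by
// memorylessness).  Permanent blocking is detected by a full applicability
// scan after a run of rejected proposals.
// [[Rcpp::export(name = ".eng_sample_trajectory")]]
List eng_sample_trajectory(IntegerVector states0, IntegerVector dirs0,
                           int step_cap, bool record) {
  Engine e;
  IntegerVector zero(states0.size());
  e.init(states0, dirs0, zero);

  std::vector<int> stepMon;
  std::vector<double> stepWait;
  double total = 0.0, pending = 0.0;
  int nsteps = 0;
  int terminal = 0;  // 0 target, 1 permanently blocked, 2 cap reached

  int m = 0;  // number of monomers with nonzero state
  for (int i = 0; i < e.n; ++i)
    if (e.curState(i) != 0) ++m;

  int rejections = 0;
  while (true) {
    if (m == 0) { terminal = 0; break; }
    if (nsteps >= step_cap) { terminal = 2; break; }
    pending += exp_rand() / m;
    int pick = (int)(unif_rand() * m);
    if (pick >= m) pick = m - 1;
    // locate pick-th nonzero monomer
    int i = -1, seen = -1;
    for (int j = 0; j < e.n; ++j) {
      if (e.curState(j) != 0 && ++seen == pick) { i = j; break; }
    }
    if (e.applicable(i)) {
      e.apply(i);
      if (e.curState(i) == 0) --m;
      total += pending;
      if (record) {
        stepMon.push_back(i + 1);
        stepWait.push_back(pending);
      }
      pending = 0.0;
      ++nsteps;
      rejections = 0;
    } else {
      if (++rejections >= 4 * m + 8) {
        if (e.applicableSet().empty()) { terminal = 1; break; }
        rejections = 0;
      }
    }
  }

  return List::create(
      _["moves"] = IntegerVector(e.mv.begin(), e.mv.end()),
      _["steps"] = IntegerVector(stepMon.begin(), stepMon.end()),
      _["waits"] = NumericVector(stepWait.begin(), stepWait.end()),
      _["n_steps"] = nsteps, _["total_time"] = total,
      _["terminal"] = terminal);
}

// Exhaustive BFS over reachable move-count vectors.
// [[Rcpp::export(name = ".eng_explore")]]
List eng_explore(IntegerVector states0, IntegerVector dirs0,
                 double state_cap, bool want_path, bool return_vectors) {
  Engine e;
  IntegerVector zero(states0.size());
  e.init(states0, dirs0, zero);
  const int n = e.n;

  std::unordered_map<std::string, int> id;
  std::vector<std::string> keys;
  std::vector<int> predState, predMove;
  std::vector<int> blocked;  // ids of permanently blocked states, BFS order
  bool targetReachable = false, truncated = false;
  int maxAdjDiff = 0;

  std::string k0 = e.keyOf();
  id[k0] = 0;
  keys.push_back(k0);
  if (want_path) { predState.push_back(-1); predMove.push_back(-1); }

  for (size_t head = 0; head < keys.size(); ++head) {
    if ((double)keys.size() > state_cap) { truncated = true; break; }
    e.setFromKey(keys[head]);
    // adjacent move-count gap over monomer pairs that both have a
    // direction (the last monomer has none, so its pair is excluded)
    for (int i = 0; i + 2 < n; ++i) {
      int d = std::abs(e.mv[i] - e.mv[i + 1]);
      if (d > maxAdjDiff) maxAdjDiff = d;
    }
    std::vector<int> acts = e.applicableSet();
    bool anyNonzero = false;
    for (int i = 0; i < n; ++i)
      if (e.curState(i) != 0) { anyNonzero = true; break; }
    if (!anyNonzero) targetReachable = true;
    else if (acts.empty()) blocked.push_back((int)head);
    for (int a : acts) {
      e.mv[a] += 1;
      std::string k(n, '\0');
      for (int i = 0; i < n; ++i) k[i] = (char)e.mv[i];
      e.mv[a] -= 1;
      if (id.find(k) == id.end()) {
        id[k] = (int)keys.size();
        keys.push_back(k);
        if (want_path) {
          predState.push_back((int)head);
          predMove.push_back(a + 1);
        }
      }
    }
  }

  IntegerMatrix wit(blocked.size(), n);
  for (size_t b = 0; b < blocked.size(); ++b)
    for (int i = 0; i < n; ++i)
      wit(b, i) = (unsigned char)keys[blocked[b]][i];

  IntegerVector path;
  if (want_path && !blocked.empty()) {
    std::vector<int> rev;
    for (int cur = blocked[0]; predState[cur] >= 0; cur = predState[cur])
      rev.push_back(predMove[cur]);
    std::reverse(rev.begin(), rev.end());
    path = IntegerVector(rev.begin(), rev.end());
  }

  List out = List::create(
      _["reachable_count"] = (double)keys.size(),
      _["target_reachable"] = targetReachable, _["truncated"] = truncated,
      _["witnesses"] = wit, _["witness_path"] = path,
      _["max_adjacent_diff"] = maxAdjDiff);
  if (return_vectors) {
    IntegerMatrix vecs(keys.size(), n);
    for (size_t s = 0; s < keys.size(); ++s)
      for (int i = 0; i < n; ++i) vecs(s, i) = (unsigned char)keys[s][i];
    out["vectors"] = vecs;
  }
  return out;
}

// Exact expected absorption time by backward induction over the reachable
// DAG (total move count strictly increases along every step, so processing
// states by decreasing total moves is a topological order).
// [[Rcpp::export(name = ".eng_expected_absorption")]]
List eng_expected_absorption(IntegerVector states0, IntegerVector dirs0,
                             double state_cap) {
  Engine e;
  IntegerVector zero(states0.size());
  e.init(states0, dirs0, zero);
  const int n = e.n;

  std::unordered_map<std::string, int> id;
  std::vector<std::string> keys;
  std::string k0 = e.keyOf();
  id[k0] = 0;
  keys.push_back(k0);
  for (size_t head = 0; head < keys.size(); ++head) {
    if ((double)keys.size() > state_cap) stop("StateCapExceeded");
    e.setFromKey(keys[head]);
    for (int a : e.applicableSet()) {
      e.mv[a] += 1;
      std::string k(n, '\0');
      for (int i = 0; i < n; ++i) k[i] = (char)e.mv[i];
      e.mv[a] -= 1;
      if (id.find(k) == id.end()) {
        id[k] = (int)keys.size();
        keys.push_back(k);
      }
    }
  }

  size_t N = keys.size();
  std::vector<int> order(N);
  std::vector<int> tot(N);
  for (size_t s = 0; s < N; ++s) {
    int t = 0;
    for (int i = 0; i < n; ++i) t += (unsigned char)keys[s][i];
    tot[s] = t;
    order[s] = (int)s;
  }
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return tot[a] > tot[b]; });

  std::vector<double> E(N, 0.0), P(N, 0.0);
  bool hasBlocked = false;
  for (int s : order) {
    e.setFromKey(keys[s]);
    std::vector<int> acts = e.applicableSet();
    bool anyNonzero = false;
    for (int i = 0; i < n; ++i)
      if (e.curState(i) != 0) { anyNonzero = true; break; }
    if (acts.empty()) {
      E[s] = 0.0;
      P[s] = anyNonzero ? 0.0 : 1.0;
      if (anyNonzero) hasBlocked = true;
      continue;
    }
    double sumE = 0.0, sumP = 0.0;
    for (int a : acts) {
      e.mv[a] += 1;
      std::string k(n, '\0');
      for (int i = 0; i < n; ++i) k[i] = (char)e.mv[i];
      e.mv[a] -= 1;
      int sid = id[k];
      sumE += E[sid];
      sumP += P[sid];
    }
    double kk = (double)acts.size();
    E[s] = (1.0 + sumE) / kk;
    P[s] = sumP / kk;
  }

  return List::create(_["expected_time"] = E[0], _["p_target"] = P[0],
                      _["reachable_count"] = (double)N,
                      _["has_blocked"] = hasBlocked);
}
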