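// Simulated-annealing modularity search on a simple undirected graph.
//
// Moves: single-node reassignment (to a neighbour's module or a fresh empty
// module), module merges and module splits (random bisection refined by two
// greedy passes). Acceptance min(1, exp(dM/T)); dM == 0 accepted with
// probability 1/2. Uses R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct State {
  int n;
  double L; // undirected edge count
  std::vector<std::vector<int>> adj;
  std::vector<int> deg;
  std::vector<int> memb;           // module id per node
  std::vector<double> modI;        // internal edges per module id
  std::vector<double> modD;        // summed degree per module id
  std::vector<std::vector<int>> members; // node lists per module id
  std::vector<int> posInMod;       // index of node within its member list
  std::vector<int> active;         // active module ids
  std::vector<int> activePos;      // position in `active` (-1 if inactive)
  std::vector<int> freeIds;        // unused module ids

  double M() const {
    double m = 0.0;
    for (int s : active) {
      double ds = modD[s] / (2.0 * L);
      m += modI[s] / L - ds * ds;
    }
    return m;
  }

  void activate(int s) {
    activePos[s] = (int)active.size();
    active.push_back(s);
  }
  void deactivate(int s) {
    int p = activePos[s];
    int last = active.back();
    active[p] = last;
    activePos[last] = p;
    active.pop_back();
    activePos[s] = -1;
    freeIds.push_back(s);
  }
  int freshModule() {
    int s = freeIds.back();
    freeIds.pop_back();
    activate(s);
    return s;
  }
  void removeMember(int i) {
    int s = memb[i];
    std::vector<int> &v = members[s];
    int p = posInMod[i];
    int last = v.back();
    v[p] = last;
    posInMod[last] = p;
    v.pop_back();
  }
  void addMember(int i, int s) {
    posInMod[i] = (int)members[s].size();
    members[s].push_back(i);
    memb[i] = s;
  }
  // links from node i into module s (no self-loops present)
  int kTo(int i, int s) const {
    int k = 0;
    for (int j : adj[i]) if (memb[j] == s) ++k;
    return k;
  }
  // move node i from its module a to module b; kia/kib precomputed
  void applyNodeMove(int i, int b, int kia, int kib) {
    int a = memb[i];
    removeMember(i);
    modI[a] -= kia; modD[a] -= deg[i];
    if (members[a].empty()) deactivate(a);
    addMember(i, b);
    modI[b] += kib; modD[b] += deg[i];
  }
};
// node-move gain: dM = (kib - kia)/L - (2 di^2 + 2 di (dB - dA)) / (4 L^2),
// from (dA-di)^2 - dA^2 + (dB+di)^2 - dB^2 = 2 di^2 + 2 di (dB - dA)

inline bool accept(double dM, double T) {
  if (dM > 0) return true;
  if (dM == 0) return unif_rand() < 0.5;
  if (T <= 0) return false;
  return unif_rand() < std::exp(dM / T);
}

inline int randInt(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

void initState(State &st, int n, const IntegerMatrix &edges) {
  st.n = n;
  st.L = edges.nrow();
  st.adj.assign(n, {});
  st.deg.assign(n, 0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    st.adj[u].push_back(v);
    st.adj[v].push_back(u);
    st.deg[u]++; st.deg[v]++;
  }
  st.memb.resize(n);
  st.modI.assign(2 * n, 0.0);
  st.modD.assign(2 * n, 0.0);
  st.members.assign(2 * n, {});
  st.posInMod.assign(n, 0);
  st.active.clear();
  st.activePos.assign(2 * n, -1);
  st.freeIds.clear();
  for (int s = 2 * n - 1; s >= n; --s) st.freeIds.push_back(s);
  for (int i = 0; i < n; ++i) {
    st.memb[i] = i;
    st.modD[i] = st.deg[i];
    st.members[i] = {i};
    st.posInMod[i] = 0;
    st.activate(i);
  }
}

// propose + maybe apply one node move; returns dM applied (0 if none)
double tryNodeMove(State &st, double T) {
  int i = randInt(st.n);
  if (st.adj[i].empty()) return 0.0;
  int a = st.memb[i];
  int b;
  if (unif_rand() < 0.1) {
    if ((int)st.members[a].size() == 1) return 0.0;
    b = -1; // fresh module sentinel
  } else {
    b = st.memb[st.adj[i][randInt((int)st.adj[i].size())]];
    if (b == a) return 0.0;
  }
  int kia = st.kTo(i, a); // i not its own neighbour (no self-loops)
  int kib = (b >= 0) ? st.kTo(i, b) : 0;
  double dB = (b >= 0) ? st.modD[b] : 0.0;
  double di = st.deg[i];
  double dM = (double)(kib - kia) / st.L -
              (2.0 * di * di + 2.0 * di * (dB - st.modD[a])) /
                (4.0 * st.L * st.L);
  if (!accept(dM, T)) return 0.0;
  if (b < 0) b = st.freshModule();
  st.applyNodeMove(i, b, kia, kib);
  return dM;
}

double tryMerge(State &st, double T) {
  int na = (int)st.active.size();
  if (na < 2) return 0.0;
  int pa = randInt(na), pb = randInt(na - 1);
  if (pb >= pa) ++pb;
  int a = st.active[pa], b = st.active[pb];
  if (st.members[a].size() > st.members[b].size()) std::swap(a, b);
  long eab = 0;
  for (int i : st.members[a])
    for (int j : st.adj[i]) if (st.memb[j] == b) ++eab;
  double dM = (double)eab / st.L -
              st.modD[a] * st.modD[b] / (2.0 * st.L * st.L);
  if (!accept(dM, T)) return 0.0;
  // fold a into b
  std::vector<int> nodes = st.members[a];
  for (int i : nodes) {
    st.removeMember(i);
    st.addMember(i, b);
  }
  st.modI[b] += st.modI[a] + eab;
  st.modD[b] += st.modD[a];
  st.modI[a] = 0.0; st.modD[a] = 0.0;
  st.deactivate(a);
  return dM;
}

double trySplit(State &st, double T) {
  int na = (int)st.active.size();
  if (na < 1) return 0.0;
  int a = st.active[randInt(na)];
  int sz = (int)st.members[a].size();
  if (sz < 2) return 0.0;
  std::vector<int> nodes = st.members[a];
  // tentative side: 0 stays in a, 1 goes to new module c
  std::vector<char> side(sz);
  std::vector<int> indexOf(st.n, -1);
  for (int p = 0; p < sz; ++p) indexOf[nodes[p]] = p;
  int n1 = 0;
  for (int p = 0; p < sz; ++p) {
    side[p] = unif_rand() < 0.5 ? 1 : 0;
    n1 += side[p];
  }
  if (n1 == 0 || n1 == sz) return 0.0;
  // tentative degree sums and internal counts
  auto eval = [&](double &Ia, double &Ic, double &Da, double &Dc) {
    Ia = Ic = Da = Dc = 0.0;
    for (int p = 0; p < sz; ++p) {
      int i = nodes[p];
      if (side[p]) Dc += st.deg[i]; else Da += st.deg[i];
      for (int j : st.adj[i]) {
        int q = indexOf[j];
        if (q > p) { // internal edge counted once
          if (side[p] == 0 && side[q] == 0) Ia += 1.0;
          else if (side[p] == 1 && side[q] == 1) Ic += 1.0;
        }
      }
    }
  };
  // two greedy refinement passes on the bisection, tracked incrementally
  double Ia, Ic, Da, Dc;
  eval(Ia, Ic, Da, Dc);
  for (int pass = 0; pass < 2; ++pass) {
    for (int p = 0; p < sz; ++p) {
      int i = nodes[p];
      int kA = 0, kC = 0;
      for (int j : st.adj[i]) {
        int q = indexOf[j];
        if (q >= 0) { if (side[q]) ++kC; else ++kA; }
      }
      double di = st.deg[i];
      double d;
      if (side[p] == 0) { // move a -> c
        d = (double)(kC - kA) / st.L -
            (2 * di * di + 2 * di * (Dc - Da)) / (4 * st.L * st.L);
        if (d > 0) {
          side[p] = 1;
          Ia -= kA; Ic += kC; Da -= di; Dc += di;
        }
      } else {            // move c -> a
        d = (double)(kA - kC) / st.L -
            (2 * di * di + 2 * di * (Da - Dc)) / (4 * st.L * st.L);
        if (d > 0) {
          side[p] = 0;
          Ic -= kC; Ia += kA; Dc -= di; Da += di;
        }
      }
    }
  }
  n1 = 0;
  for (int p = 0; p < sz; ++p) n1 += side[p];
  if (n1 == 0 || n1 == sz) return 0.0;
  double Ltot = st.L;
  double before = st.modI[a] / Ltot -
                  (st.modD[a] / (2 * Ltot)) * (st.modD[a] / (2 * Ltot));
  double after = Ia / Ltot - (Da / (2 * Ltot)) * (Da / (2 * Ltot)) +
                 Ic / Ltot - (Dc / (2 * Ltot)) * (Dc / (2 * Ltot));
  double dM = after - before;
  if (!accept(dM, T)) return 0.0;
  int c = st.freshModule();
  for (int p = 0; p < sz; ++p) {
    if (side[p]) {
      int i = nodes[p];
      st.removeMember(i);
      st.addMember(i, c);
    }
  }
  st.modI[a] = Ia; st.modD[a] = Da;
  st.modI[c] = Ic; st.modD[c] = Dc;
  return dM;
}

} // namespace

// [[Rcpp::export]]
List anneal_sa_cpp(int n, IntegerMatrix edges, double t0, double cooling,
                   double fmove, double fcollective, double tmin,
                   int stagnation_limit) {
  if (edges.nrow() < 1) stop("annealer needs at least one undirected link");
  State st;
  initState(st, n, edges);

  double Mcur = st.M();

  // calibrate T0 so that typical early uphill/downhill steps are accepted
  // with probability ~0.8
  if (t0 <= 0) {
    double s = 0.0; int cnt = 0;
    for (int t = 0; t < 200; ++t) {
      int i = randInt(n);
      if (st.adj[i].empty()) continue;
      int b = st.memb[st.adj[i][randInt((int)st.adj[i].size())]];
      int a = st.memb[i];
      if (a == b) continue;
      int kia = st.kTo(i, a), kib = st.kTo(i, b);
      double di = st.deg[i];
      double dM = (double)(kib - kia) / st.L -
                  (2 * di * di + 2 * di * (st.modD[b] - st.modD[a])) /
                    (4 * st.L * st.L);
      s += std::fabs(dM); ++cnt;
    }
    double mean = cnt ? s / cnt : 1.0 / st.L;
    t0 = std::max(mean, 1e-9) / 0.223143551; // -log(0.8)
  }

  std::vector<int> best = st.memb;
  double bestM = Mcur;
  double T = t0;
  int stag = 0;
  long nm = (long)std::ceil(fmove * (double)n * (double)n);
  long nc = (long)std::ceil(fcollective * (double)n);
  int iter = 0;
  while (T > tmin && stag < stagnation_limit) {
    double bestBefore = bestM;
    long acc = 0;
    for (long t = 0; t < nm; ++t) {
      double d = tryNodeMove(st, T);
      if (d != 0.0) { Mcur += d; ++acc; }
      if (Mcur > bestM + 1e-12) { bestM = Mcur; best = st.memb; }
    }
    for (long t = 0; t < nc; ++t) {
      if (unif_rand() < 0.5) Mcur += tryMerge(st, T);
      else Mcur += trySplit(st, T);
      if (Mcur > bestM + 1e-12) { bestM = Mcur; best = st.memb; }
    }
    Mcur = st.M(); // kill numerical drift
    // stagnation only counts once the chain has cooled out of the hot
    // phase; while acceptance is high the search is still exploring
    if (bestM > bestBefore + 1e-9) stag = 0;
    else if ((double)acc / (double)nm < 0.3) ++stag;
    T *= cooling;
    if (++iter % 16 == 0) Rcpp::checkUserInterrupt();
  }

  // relabel best membership to dense 1..N_M and recompute M exactly
  std::vector<int> map(2 * n, -1);
  IntegerVector out(n);
  int nmod = 0;
  for (int i = 0; i < n; ++i) {
    if (map[best[i]] < 0) map[best[i]] = nmod++;
    out[i] = map[best[i]] + 1;
  }
  std::vector<double> I(nmod, 0.0), D(nmod, 0.0);
  for (int i = 0; i < n; ++i) D[out[i] - 1] += st.deg[i];
  for (int e = 0; e < edges.nrow(); ++e) {
    if (out[edges(e, 0)] == out[edges(e, 1)]) I[out[edges(e, 0)] - 1] += 1.0;
  }
  double Mfin = 0.0;
  for (int s = 0; s < nmod; ++s) {
    double ds = D[s] / (2.0 * st.L);
    Mfin += I[s] / st.L - ds * ds;
  }
  return List::create(_["membership"] = out, _["M"] = Mfin,
                      _["n_modules"] = nmod, _["t0"] = t0);
}
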