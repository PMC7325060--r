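// Hexagonal-lattice agent-based engine: three-domain lesion state
// (bone / cell-free margin / tumour), clock-gated Monte-Carlo events,
// minimum-distance-path shifts, bone digestion and edge smoothing.
//
// All randomness comes from R's RNG (unif_rand) so that set.seed() on the
// R side makes every run bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const int BONE = 0, MARGIN = 1, TUMOUR = 2;
static const double SQ32 = 0.8660254037844386; // sqrt(3)/2

// axial neighbour offsets, pointy-top orientation
static const int DQ[6] = { 1, -1, 0, 0, 1, -1 };
static const int DR[6] = { 0, 0, 1, -1, -1, 1 };

// status codes
static const int ST_RUNNING = 0, ST_TIME = 1, ST_ERADICATED = 2, ST_ARREST = 3;

struct KParams {
  double alpha1, alpha2;
  double mK, mR, mP0;   // logistic distance effect on mitosis
  double aK, aR, aP0;   // logistic distance effect on apoptosis
  double R0, lambda;    // activity decay
  double delta;         // um per lattice step
  bool   rad;           // regimen: true = Rad223
  int    daughter_mode; // 0 = random clock in [1,24], 1 = zero
};

static KParams parse_params(const List& p) {
  KParams k;
  k.alpha1 = as<double>(p["alpha1"]);
  k.alpha2 = as<double>(p["alpha2"]);
  k.mK = as<double>(p["mit_K"]);  k.mR = as<double>(p["mit_r"]);  k.mP0 = as<double>(p["mit_phi0"]);
  k.aK = as<double>(p["apop_K"]); k.aR = as<double>(p["apop_r"]); k.aP0 = as<double>(p["apop_phi0"]);
  k.R0 = as<double>(p["R0"]);     k.lambda = as<double>(p["lambda"]);
  k.delta = as<double>(p["delta"]);
  k.rad = as<bool>(p["rad"]);
  k.daughter_mode = as<int>(p["daughter_mode"]);
  return k;
}

static inline double logistic_phi(double d, double K, double r, double p0) {
  return K / (1.0 + ((K - p0) / p0) * std::exp(-r * d));
}

static inline double zeta_of(double t, double R0, double lambda) {
  return R0 * std::exp(-lambda * t);
}

static inline double p_mit_of(const KParams& k, double d_um, double t_days) {
  if (!k.rad || k.alpha1 == 0.0) return k.alpha1;
  double phi = logistic_phi(d_um, k.mK, k.mR, k.mP0);
  double z = zeta_of(t_days, k.R0, k.lambda);
  return k.alpha1 / (1.0 + (k.alpha1 / phi - 1.0) * z);
}

static inline double p_apop_of(const KParams& k, double d_um, double t_days) {
  if (!k.rad || k.alpha2 == 0.0) return k.alpha2;
  double phi = logistic_phi(d_um, k.aK, k.aR, k.aP0);
  double z = zeta_of(t_days, k.R0, k.lambda);
  double den = 1.0 - (1.0 - k.alpha2 / phi) * z;
  if (den <= 0.0)
    stop("apoptosis probability denominator <= 0 (phi_apop(d) must stay >= alpha2)");
  return k.alpha2 / den;
}

static inline int ruint(int n) { // uniform integer in [0, n)
  int v = (int)std::floor(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

template <typename T>
static void rshuffle(std::vector<T>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = ruint(i + 1);
    std::swap(v[i], v[j]);
  }
}

struct Sim {
  int N;
  KParams k;
  std::vector<int> lab;    // site -> label
  std::vector<int> cell;   // site -> cell id or -1
  std::vector<int> cpos;   // cell id -> site or -1 (dead)
  std::vector<int> cclk;   // cell id -> clock
  std::vector<int> freeids;
  std::vector<int> alive;  // alive cell ids (swap-remove)
  std::vector<int> apos;   // cell id -> index in alive
  long nT, nM, nB;
  double sx, sy;           // centroid sums over tumour cells (lattice units)
  // bone-interface sites (bone with >= 1 non-bone neighbour), lazily compacted
  std::vector<int> bd;
  std::vector<char> bflag;
  int bstale;
  // bfs scratch
  std::vector<int> stamp, dist;
  std::vector<double> cnt;
  int epoch;
  int status;
  bool border_touch;
  int cap_hits;
  long exec_mit, exec_apop; // per-step counters

  inline int site(int q, int r) const { return r * N + q; }
  inline int sq(int s) const { return s % N; }
  inline int sr(int s) const { return s / N; }
  inline bool ongrid(int q, int r) const { return q >= 0 && q < N && r >= 0 && r < N; }
  inline bool onborder(int s) const {
    int q = sq(s), r = sr(s);
    return q == 0 || r == 0 || q == N - 1 || r == N - 1;
  }
  inline double cx(int s) const { return sq(s) + 0.5 * sr(s); }
  inline double cy(int s) const { return SQ32 * sr(s); }

  Sim(const IntegerMatrix& label, const IntegerMatrix& clock) {
    N = label.nrow();
    if (label.ncol() != N) stop("label matrix must be square");
    lab.assign((size_t)N * N, BONE);
    cell.assign((size_t)N * N, -1);
    nT = nM = nB = 0; sx = sy = 0.0;
    status = ST_RUNNING; border_touch = false; cap_hits = 0;
    exec_mit = exec_apop = 0;
    for (int r = 0; r < N; ++r) for (int q = 0; q < N; ++q) {
      int s = site(q, r);
      int L = label(r, q);
      lab[s] = L;
      if (L == TUMOUR) {
        ++nT; sx += cx(s); sy += cy(s);
        int id = (int)cpos.size();
        cpos.push_back(s); cclk.push_back(clock(r, q));
        apos.push_back((int)alive.size());
        alive.push_back(id);
        cell[s] = id;
      } else if (L == MARGIN) ++nM; else ++nB;
      if (L != BONE && onborder(s)) border_touch = true;
    }
    // bone-interface list
    bflag.assign((size_t)N * N, 0);
    bstale = 0;
    for (int r = 0; r < N; ++r) for (int q = 0; q < N; ++q) {
      int s = site(q, r);
      if (lab[s] != BONE) continue;
      for (int d = 0; d < 6; ++d) {
        int nq = q + DQ[d], nr = r + DR[d];
        if (ongrid(nq, nr) && lab[site(nq, nr)] != BONE) {
          bd.push_back(s); bflag[s] = 1; break;
        }
      }
    }
    stamp.assign((size_t)N * N, 0);
    dist.assign((size_t)N * N, 0);
    cnt.assign((size_t)N * N, 0.0);
    epoch = 0;
  }

  // ---- label bookkeeping -------------------------------------------------
  void set_label(int s, int L) {
    int old = lab[s];
    if (old == L) return;
    if (old == TUMOUR) { --nT; sx -= cx(s); sy -= cy(s); }
    else if (old == MARGIN) --nM;
    else --nB;
    if (L == TUMOUR) { ++nT; sx += cx(s); sy += cy(s); }
    else if (L == MARGIN) ++nM;
    else ++nB;
    lab[s] = L;
    if (L != BONE && onborder(s)) border_touch = true;
    if (old == BONE) {
      // digested bone: interface may recede to its bone neighbours
      ++bstale;
      int q = sq(s), r = sr(s);
      for (int d = 0; d < 6; ++d) {
        int nq = q + DQ[d], nr = r + DR[d];
        if (!ongrid(nq, nr)) continue;
        int ns = site(nq, nr);
        if (lab[ns] == BONE && !bflag[ns]) { bd.push_back(ns); bflag[ns] = 1; }
      }
      if (bstale > (int)bd.size() / 2 && bstale > 256) compact_boundary();
    }
  }

  void compact_boundary() {
    std::vector<int> keep;
    keep.reserve(bd.size());
    for (int s : bd) {
      if (lab[s] != BONE) { bflag[s] = 0; continue; }
      keep.push_back(s);
    }
    bd.swap(keep);
    bstale = 0;
  }

  // ---- cells -------------------------------------------------------------
  int add_cell(int s, int clk) {
    int id;
    if (!freeids.empty()) { id = freeids.back(); freeids.pop_back(); }
    else { id = (int)cpos.size(); cpos.push_back(-1); cclk.push_back(0); apos.push_back(-1); }
    cpos[id] = s; cclk[id] = clk;
    cell[s] = id;
    apos[id] = (int)alive.size();
    alive.push_back(id);
    return id;
  }

  void remove_cell(int id) {
    int s = cpos[id];
    cell[s] = -1;
    cpos[id] = -1;
    int ai = apos[id], last = alive.back();
    alive[ai] = last; apos[last] = ai;
    alive.pop_back();
    freeids.push_back(id);
  }

  void move_cell(int id, int to) {
    cell[cpos[id]] = -1;
    cpos[id] = to;
    cell[to] = id;
  }

  int daughter_clock() {
    return k.daughter_mode == 0 ? 1 + ruint(24) : 0;
  }

  // ---- geometry ----------------------------------------------------------
  // minimum Euclidean distance (lattice units) from site s to any bone site;
  // the nearest bone site always lies on the bone interface, so scanning the
  // maintained interface list equals the exhaustive scan.
  double dmin_lattice(int s) {
    double x0 = cx(s), y0 = cy(s);
    double best = -1.0;
    for (int b : bd) {
      if (lab[b] != BONE) continue;
      double dx = cx(b) - x0, dy = cy(b) - y0;
      double d2 = dx * dx + dy * dy;
      if (best < 0.0 || d2 < best) best = d2;
    }
    if (best < 0.0) stop("state contains no bone sites");
    return std::sqrt(best);
  }

  int non_tumour_neighbours(int s) const {
    int q = sq(s), r = sr(s), n = 0;
    for (int d = 0; d < 6; ++d) {
      int nq = q + DQ[d], nr = r + DR[d];
      if (!ongrid(nq, nr) || lab[site(nq, nr)] != TUMOUR) ++n;
    }
    return n;
  }

  // shortest path (BFS in lattice steps) from `from` to the nearest site
  // satisfying the target predicate; uniform over all tied shortest paths.
  // target_kind: 0 = BONE, 1 = any non-tumour site. Empty result = unreachable.
  std::vector<int> mdp(int from, int target_kind) {
    ++epoch;
    std::vector<int> cur, nxt, targets;
    stamp[from] = epoch; dist[from] = 0; cnt[from] = 1.0;
    cur.push_back(from);
    bool found = false;
    while (!cur.empty() && !found) {
      nxt.clear(); targets.clear();
      for (int s : cur) {
        int q = sq(s), r = sr(s);
        for (int d = 0; d < 6; ++d) {
          int nq = q + DQ[d], nr = r + DR[d];
          if (!ongrid(nq, nr)) continue;
          int ns = site(nq, nr);
          if (stamp[ns] != epoch) {
            stamp[ns] = epoch; dist[ns] = dist[s] + 1; cnt[ns] = cnt[s];
            nxt.push_back(ns);
            bool hit = target_kind == 0 ? (lab[ns] == BONE) : (lab[ns] != TUMOUR);
            if (hit) { targets.push_back(ns); found = true; }
          } else if (dist[ns] == dist[s] + 1) {
            cnt[ns] += cnt[s];
          }
        }
      }
      cur.swap(nxt);
    }
    std::vector<int> path;
    if (!found) return path;
    // pick the target in proportion to its shortest-path count
    double tot = 0.0;
    for (int t : targets) tot += cnt[t];
    double u = unif_rand() * tot, acc = 0.0;
    int t = targets.back();
    for (int s : targets) { acc += cnt[s]; if (u <= acc) { t = s; break; } }
    // walk back sampling predecessors in proportion to their path counts
    path.push_back(t);
    int curs = t;
    while (curs != from) {
      int q = sq(curs), r = sr(curs);
      double ptot = 0.0;
      int preds[6]; int np = 0;
      for (int d = 0; d < 6; ++d) {
        int nq = q + DQ[d], nr = r + DR[d];
        if (!ongrid(nq, nr)) continue;
        int ns = site(nq, nr);
        if (stamp[ns] == epoch && dist[ns] == dist[curs] - 1) {
          preds[np++] = ns; ptot += cnt[ns];
        }
      }
      double v = unif_rand() * ptot, a2 = 0.0;
      int pick = preds[np - 1];
      for (int i = 0; i < np; ++i) { a2 += cnt[preds[i]]; if (v <= a2) { pick = preds[i]; break; } }
      path.push_back(pick);
      curs = pick;
    }
    std::reverse(path.begin(), path.end());
    return path;
  }

  // ---- event execution ----------------------------------------------------
  void digest(int s) {
    int q = sq(s), r = sr(s);
    for (int d = 0; d < 6; ++d) {
      int nq = q + DQ[d], nr = r + DR[d];
      if (!ongrid(nq, nr)) continue;
      int ns = site(nq, nr);
      if (lab[ns] == BONE) set_label(ns, MARGIN);
    }
  }

  void do_mitosis(int id) {
    int s = cpos[id];
    int q = sq(s), r = sr(s);
    int opts[6]; int nopt = 0;
    for (int d = 0; d < 6; ++d) {
      int nq = q + DQ[d], nr = r + DR[d];
      if (!ongrid(nq, nr)) continue;
      int ns = site(nq, nr);
      if (lab[ns] != TUMOUR) opts[nopt++] = ns;
    }
    if (nopt > 0) {
      // edge cell: deploy the daughter on a uniformly chosen non-tumour neighbour
      int tgt = opts[ruint(nopt)];
      set_label(tgt, TUMOUR);
      add_cell(tgt, daughter_clock());
      digest(tgt);
    } else {
      // interior cell: shift the structure outward along a minimum distance
      // path to the nearest bone site
      std::vector<int> path = mdp(s, 0);
      if (path.empty()) { status = ST_ARREST; return; }
      int j = 0;
      while (j + 1 < (int)path.size() && lab[path[j + 1]] == TUMOUR) ++j;
      int out = path[j + 1];
      set_label(out, TUMOUR);
      for (int i = j; i >= 1; --i) move_cell(cell[path[i]], path[i + 1]);
      add_cell(path[1], daughter_clock());
      digest(out);
    }
    ++exec_mit;
  }

  void do_apoptosis(int id) {
    int s = cpos[id];
    int q = sq(s), r = sr(s);
    bool edge = false;
    for (int d = 0; d < 6 && !edge; ++d) {
      int nq = q + DQ[d], nr = r + DR[d];
      if (!ongrid(nq, nr) || lab[site(nq, nr)] != TUMOUR) edge = true;
    }
    if (edge) {
      remove_cell(id);
      set_label(s, MARGIN);
    } else {
      std::vector<int> path = mdp(s, 1);
      if (path.empty()) { status = ST_ARREST; return; } // unreachable in practice
      int kk = (int)path.size() - 1; // path[kk] is the non-tumour terminal
      remove_cell(id);
      for (int i = 1; i < kk; ++i) move_cell(cell[path[i]], path[i - 1]);
      set_label(path[kk - 1], MARGIN);
    }
    ++exec_apop;
  }

  // edge smoothing: a tumour cell with more than three non-tumour neighbours
  // is swapped with the non-tumour neighbour that itself has the fewest
  // non-tumour neighbours (ties: closest to the tumour centroid, then random)
  int smooth() {
    // refresh the centroid sums exactly: accumulated floating-point drift
    // would otherwise break exact geometric ties deterministically and give
    // the swap walk a spurious direction
    sx = sy = 0.0;
    for (int id : alive) { sx += cx(cpos[id]); sy += cy(cpos[id]); }
    int per = 0;
    for (int id : alive) if (non_tumour_neighbours(cpos[id]) >= 1) ++per;
    long cap = 10L * std::max(per, 1);
    long iters = 0;
    bool caphit = false;
    // randomized worklist; a swap can only change the trigger condition of
    // cells adjacent to the two swapped sites, which are re-examined locally
    std::vector<int> work;
    std::vector<char> inq(cpos.size(), 0);
    for (int id : alive) {
      if (non_tumour_neighbours(cpos[id]) > 3) { work.push_back(id); inq[id] = 1; }
    }
    while (!work.empty()) {
      int k = ruint((int)work.size());
      int id = work[k];
      work[k] = work.back();
      work.pop_back();
      inq[id] = 0;
      int s = cpos[id];
      if (s < 0 || non_tumour_neighbours(s) <= 3) continue;
      if (iters >= cap) { caphit = true; break; }
      double cxm = sx / (double)nT, cym = sy / (double)nT;
      int q = sq(s), r = sr(s);
      int best[6]; int nbest = 0;
      int bestScore = 99; double bestDist = 0.0;
      for (int d = 0; d < 6; ++d) {
        int nq = q + DQ[d], nr = r + DR[d];
        if (!ongrid(nq, nr)) continue;
        int ns = site(nq, nr);
        if (lab[ns] == TUMOUR) continue;
        int sc = non_tumour_neighbours(ns);
        double dx = cx(ns) - cxm, dy = cy(ns) - cym;
        double dd = dx * dx + dy * dy;
        double eps = 1e-9 * (1.0 + dd + bestDist);
        if (nbest == 0 || sc < bestScore || (sc == bestScore && dd < bestDist - eps)) {
          bestScore = sc; bestDist = dd; nbest = 0; best[nbest++] = ns;
        } else if (sc == bestScore && std::abs(dd - bestDist) <= eps) {
          best[nbest++] = ns;
        }
      }
      if (nbest == 0) continue; // cell fully boxed in by bone: cannot occur
      int tgt = best[ruint(nbest)];
      set_label(tgt, TUMOUR);
      move_cell(id, tgt);
      set_label(s, MARGIN);
      digest(tgt);
      ++iters;
      // re-examine the moved cell and the tumour neighbours of both sites
      int touched[13]; int ntch = 0;
      touched[ntch++] = tgt;
      for (int d = 0; d < 6; ++d) {
        int nq = sq(s) + DQ[d], nr = sr(s) + DR[d];
        if (ongrid(nq, nr)) touched[ntch++] = site(nq, nr);
      }
      for (int d = 0; d < 6; ++d) {
        int nq = sq(tgt) + DQ[d], nr = sr(tgt) + DR[d];
        if (ongrid(nq, nr)) touched[ntch++] = site(nq, nr);
      }
      for (int i = 0; i < ntch; ++i) {
        int ts = touched[i];
        if (lab[ts] != TUMOUR) continue;
        int tid = cell[ts];
        if (!inq[tid] && non_tumour_neighbours(ts) > 3) {
          work.push_back(tid);
          inq[tid] = 1;
        }
      }
    }
    if (caphit) ++cap_hits;
    return caphit ? 1 : 0;
  }

  // one hourly step; t_hour is the (1-based) hour index after this tick
  void step(int t_hour) {
    if (status != ST_RUNNING) return;
    exec_mit = exec_apop = 0;
    double t_days = t_hour / 24.0;
    std::vector<int> eligible;
    for (int id : alive) {
      if (++cclk[id] >= 24) { cclk[id] = 0; eligible.push_back(id); }
    }
    // assess: one categorical draw per eligible cell, apoptosis band first
    std::vector<std::pair<int, char>> events;
    for (int id : eligible) {
      double d_um = k.rad ? k.delta * dmin_lattice(cpos[id]) : 0.0;
      double pa = p_apop_of(k, d_um, t_days);
      double pm = p_mit_of(k, d_um, t_days);
      double u = unif_rand();
      if (u < pa) events.push_back(std::make_pair(id, 'a'));
      else if (u < pa + pm) events.push_back(std::make_pair(id, 'm'));
    }
    rshuffle(events);
    for (size_t i = 0; i < events.size(); ++i) {
      if (status != ST_RUNNING) break;
      if (events[i].second == 'a') do_apoptosis(events[i].first);
      else do_mitosis(events[i].first);
    }
    if (status != ST_RUNNING) return;
    if (nT > 0) smooth();
    if (nT == 0) { status = ST_ERADICATED; return; }
    if (border_touch) { status = ST_ARREST; return; }
  }

  IntegerMatrix label_matrix() const {
    IntegerMatrix m(N, N);
    for (int r = 0; r < N; ++r) for (int q = 0; q < N; ++q) m(r, q) = lab[site(q, r)];
    return m;
  }

  IntegerMatrix clock_matrix() const {
    IntegerMatrix m(N, N);
    std::fill(m.begin(), m.end(), -1);
    for (int id : alive) {
      int s = cpos[id];
      m(sr(s), sq(s)) = cclk[id];
    }
    return m;
  }
};

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(IntegerMatrix label, IntegerMatrix clock, List params,
             int t_hours, int snapshot_every = 0) {
  Sim sim(label, clock);
  sim.k = parse_params(params);
  IntegerMatrix counts(t_hours + 1, 5); // n_tumour, n_margin, n_bone, mit, apop
  counts(0, 0) = (int)sim.nT; counts(0, 1) = (int)sim.nM; counts(0, 2) = (int)sim.nB;
  List snaps; IntegerVector snap_t;
  if (snapshot_every > 0) { snaps.push_back(sim.label_matrix()); snap_t.push_back(0); }
  int t_end = 0;
  for (int t = 1; t <= t_hours; ++t) {
    sim.step(t);
    counts(t, 0) = (int)sim.nT; counts(t, 1) = (int)sim.nM; counts(t, 2) = (int)sim.nB;
    counts(t, 3) = (int)sim.exec_mit; counts(t, 4) = (int)sim.exec_apop;
    t_end = t;
    if (snapshot_every > 0 && (t % snapshot_every == 0 || sim.status != ST_RUNNING)) {
      snaps.push_back(sim.label_matrix()); snap_t.push_back(t);
    }
    if (sim.status != ST_RUNNING) break;
  }
  if (sim.status == ST_RUNNING) sim.status = ST_TIME;
  return List::create(
    _["counts"] = counts, _["t_end"] = t_end, _["status"] = sim.status,
    _["cap_hits"] = sim.cap_hits,
    _["label"] = sim.label_matrix(), _["clock"] = sim.clock_matrix(),
    _["snapshots"] = snaps, _["snapshot_times"] = snap_t);
}

// [[Rcpp::export]]
List cpp_step(IntegerMatrix label, IntegerMatrix clock, List params, int t_hour) {
  Sim sim(label, clock);
  sim.k = parse_params(params);
  int cap_before = sim.cap_hits;
  sim.step(t_hour);
  return List::create(
    _["label"] = sim.label_matrix(), _["clock"] = sim.clock_matrix(),
    _["status"] = sim.status, _["n_mit"] = (int)sim.exec_mit,
    _["n_apop"] = (int)sim.exec_apop,
    _["cap_hit"] = sim.cap_hits > cap_before,
    _["n_tumour"] = (int)sim.nT, _["n_margin"] = (int)sim.nM, _["n_bone"] = (int)sim.nB);
}

// Event mask for cells whose clock has reached eligibility (clock >= 24);
// the state itself is not modified. status: 0 quiescent, 1 mitotic, 2 apoptotic.
// [[Rcpp::export]]
List cpp_assess(IntegerMatrix label, IntegerMatrix clock, List params, double t_days) {
  Sim sim(label, clock);
  sim.k = parse_params(params);
  std::vector<int> qs, rs, st;
  for (int id : sim.alive) {
    if (sim.cclk[id] < 24) continue;
    int s = sim.cpos[id];
    double d_um = sim.k.rad ? sim.k.delta * sim.dmin_lattice(s) : 0.0;
    double pa = p_apop_of(sim.k, d_um, t_days);
    double pm = p_mit_of(sim.k, d_um, t_days);
    double u = unif_rand();
    int code = 0;
    if (u < pa) code = 2; else if (u < pa + pm) code = 1;
    qs.push_back(sim.sq(s)); rs.push_back(sim.sr(s)); st.push_back(code);
  }
  return List::create(_["q"] = wrap(qs), _["r"] = wrap(rs), _["status"] = wrap(st));
}

// [[Rcpp::export]]
List cpp_execute_mitosis(IntegerMatrix label, IntegerMatrix clock, int q, int r,
                         List params) {
  Sim sim(label, clock);
  sim.k = parse_params(params);
  int s = sim.site(q, r);
  if (sim.lab[s] != TUMOUR) stop("cell at (q, r) is not a tumour cell");
  sim.do_mitosis(sim.cell[s]);
  return List::create(_["label"] = sim.label_matrix(), _["clock"] = sim.clock_matrix(),
                      _["status"] = sim.status);
}

// [[Rcpp::export]]
List cpp_execute_apoptosis(IntegerMatrix label, IntegerMatrix clock, int q, int r) {
  Sim sim(label, clock);
  sim.k.rad = false; sim.k.daughter_mode = 0; // unused by apoptosis
  int s = sim.site(q, r);
  if (sim.lab[s] != TUMOUR) stop("cell at (q, r) is not a tumour cell");
  sim.do_apoptosis(sim.cell[s]);
  return List::create(_["label"] = sim.label_matrix(), _["clock"] = sim.clock_matrix(),
                      _["status"] = sim.status);
}

// [[Rcpp::export]]
List cpp_smooth(IntegerMatrix label, IntegerMatrix clock) {
  Sim sim(label, clock);
  sim.k.rad = false; sim.k.daughter_mode = 0;
  int caphit = 0;
  if (sim.nT > 0) caphit = sim.smooth();
  return List::create(_["label"] = sim.label_matrix(), _["clock"] = sim.clock_matrix(),
                      _["cap_hit"] = caphit == 1);
}

// [[Rcpp::export]]
IntegerMatrix cpp_digest(IntegerMatrix label, int q, int r) {
  IntegerMatrix clock(label.nrow(), label.ncol());
  std::fill(clock.begin(), clock.end(), -1);
  for (int i = 0; i < label.nrow(); ++i) for (int j = 0; j < label.ncol(); ++j)
    if (label(i, j) == TUMOUR) clock(i, j) = 0;
  Sim sim(label, clock);
  int s = sim.site(q, r);
  if (sim.lab[s] != TUMOUR) stop("placed cell at (q, r) is not a tumour cell");
  sim.digest(s);
  return sim.label_matrix();
}

// Minimum Euclidean distance (in lattice units) from (q, r) to any bone site.
// [[Rcpp::export]]
double cpp_min_distance_to_bone(IntegerMatrix label, int q, int r) {
  IntegerMatrix clock(label.nrow(), label.ncol());
  std::fill(clock.begin(), clock.end(), -1);
  Sim sim(label, clock);
  return sim.dmin_lattice(sim.site(q, r));
}

// Shortest lattice path to the nearest target site (0 = bone, 1 = non-tumour);
// ties between shortest paths broken uniformly at random. Returns a matrix of
// (q, r) rows from origin to target, or a 0-row matrix if unreachable.
// [[Rcpp::export]]
IntegerMatrix cpp_min_distance_path(IntegerMatrix label, int q, int r, int target_kind) {
  IntegerMatrix clock(label.nrow(), label.ncol());
  std::fill(clock.begin(), clock.end(), -1);
  Sim sim(label, clock);
  std::vector<int> path = sim.mdp(sim.site(q, r), target_kind);
  IntegerMatrix out((int)path.size(), 2);
  for (int i = 0; i < (int)path.size(); ++i) {
    out(i, 0) = sim.sq(path[i]); out(i, 1) = sim.sr(path[i]);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_event_probs(double d_um, double t_days, List params) {
  KParams k = parse_params(params);
  return NumericVector::create(_["p_mit"] = p_mit_of(k, d_um, t_days),
                               _["p_apop"] = p_apop_of(k, d_um, t_days));
}
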