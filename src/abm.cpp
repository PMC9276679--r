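#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Site classes on the lattice
static const int EMPTY = 0, TUMOUR = 1, IMMUNE = 2;

struct Agent {
  int pos;      // r + c*L, column-major like R matrices
  int cls;      // TUMOUR or IMMUNE
  int prolif;   // remaining proliferation cycles
  bool stem;    // tumour only
  int engcap;   // tumour only: attacks survived before death
  int killcap;  // immune only
  int engstat;  // 1 while engaged in a kill this step
  bool alive;
};

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline int pwrap(int x, int L) { return ((x % L) + L) % L; }

// periodic Chebyshev distance between lattice coordinates
static inline int pcheb(int r1, int c1, int r2, int c2, int L) {
  int dr = std::abs(r1 - r2); dr = std::min(dr, L - dr);
  int dc = std::abs(c1 - c2); dc = std::min(dc, L - dc);
  return std::max(dr, dc);
}

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// free Moore neighbours (periodic) of pos; returns count, fills nb[]
static int free_neighbours(int pos, int L, const std::vector<int> &occ, int *nb) {
  int r = pos % L, c = pos / L, k = 0;
  for (int i = 0; i < 8; ++i) {
    int p = pwrap(r + DR[i], L) + pwrap(c + DC[i], L) * L;
    if (occ[p] < 0) nb[k++] = p;
  }
  return k;
}

// nearest tumour site by periodic Chebyshev ring search; -1 if none within L/2
static int nearest_tumour(int pos, int L, const std::vector<int> &occ,
                          const std::vector<Agent> &agents) {
  int r = pos % L, c = pos / L;
  int dmax = L / 2;
  std::vector<int> hits;
  for (int d = 1; d <= dmax; ++d) {
    hits.clear();
    for (int dr = -d; dr <= d; ++dr) {
      int rr = pwrap(r + dr, L);
      if (dr == -d || dr == d) {
        for (int dc = -d; dc <= d; ++dc) {
          int p = rr + pwrap(c + dc, L) * L;
          if (occ[p] >= 0 && agents[occ[p]].cls == TUMOUR) hits.push_back(p);
        }
      } else {
        int p1 = rr + pwrap(c - d, L) * L, p2 = rr + pwrap(c + d, L) * L;
        if (occ[p1] >= 0 && agents[occ[p1]].cls == TUMOUR) hits.push_back(p1);
        if (occ[p2] >= 0 && agents[occ[p2]].cls == TUMOUR) hits.push_back(p2);
      }
    }
    if (!hits.empty()) return hits[runif_int((int)hits.size())];
  }
  return -1;
}

static void do_move(std::vector<Agent> &agents, std::vector<int> &occ,
                    int ai, int newpos) {
  occ[agents[ai].pos] = -1;
  agents[ai].pos = newpos;
  occ[newpos] = ai;
}

// One biased-random-walk move for an immune agent.
static void immune_move(std::vector<Agent> &agents, std::vector<int> &occ,
                        int ai, int L, double IMrwalk) {
  int nb[8];
  int nfree = free_neighbours(agents[ai].pos, L, occ, nb);
  if (nfree == 0) return;
  if (unif_rand() < IMrwalk) {
    do_move(agents, occ, ai, nb[runif_int(nfree)]);
    return;
  }
  int target = nearest_tumour(agents[ai].pos, L, occ, agents);
  if (target < 0) { // no tumour on the tile: fall back to a random move
    do_move(agents, occ, ai, nb[runif_int(nfree)]);
    return;
  }
  int tr = target % L, tc = target / L;
  int best = L + 1, nbest = 0, cand[8];
  for (int i = 0; i < nfree; ++i) {
    int d = pcheb(nb[i] % L, nb[i] / L, tr, tc, L);
    if (d < best) { best = d; nbest = 0; cand[nbest++] = nb[i]; }
    else if (d == best) cand[nbest++] = nb[i];
  }
  do_move(agents, occ, ai, cand[runif_int(nbest)]);
}

// Stochastic tumour-immune dynamics on a periodic LxL lattice.
//
// grid codes: 0 empty, 1 tumour, 2 immune. Property matrices are aligned with
// the grid. Sequential update over a freshly shuffled agent list per step;
// per-agent action order: death -> proliferation -> (killing, immune) ->
// migration. Agents born within a step first act the following step.
// [[Rcpp::export]]
List abm_run_cpp(IntegerMatrix grid, IntegerMatrix prolif, LogicalMatrix stem,
                 IntegerMatrix engcap, IntegerMatrix killcap,
                 NumericVector par, int n_steps, int steps_per_day,
                 bool record_grids, bool stop_on_eradication) {
  const int L = grid.nrow();
  if (grid.ncol() != L) stop("grid must be square");
  const double IMpprol = par["IMpprol"], IMpkill = par["IMpkill"],
    IMpdeath = par["IMpdeath"], IMrwalk = par["IMrwalk"],
    TUpprol = par["TUpprol"], TUpmig = par["TUpmig"],
    TUpdeath = par["TUpdeath"], TUintmax = par["TUintmax"],
    IMpmax = par["IMpmax"], IMpmig = par["IMpmig"],
    IMinfluxProb = par["IMinfluxProb"], IMinflRate = par["IMinflRate"],
    TUpmax = par["TUpmax"];

  RNGScope rngScope;

  std::vector<Agent> agents;
  std::vector<int> occ(L * L, -1);
  for (int p = 0; p < L * L; ++p) {
    int cls = grid[p];
    if (cls == EMPTY) continue;
    Agent a;
    a.pos = p; a.cls = cls; a.prolif = prolif[p]; a.stem = stem[p];
    a.engcap = engcap[p]; a.killcap = killcap[p]; a.engstat = 0; a.alive = true;
    occ[p] = (int)agents.size();
    agents.push_back(a);
  }

  int n_tumour = 0, n_immune = 0;
  for (size_t i = 0; i < agents.size(); ++i)
    (agents[i].cls == TUMOUR ? n_tumour : n_immune)++;

  std::vector<int> days, cd8s, tums;
  List grids;
  bool terminated_early = false;
  int influx_skipped = 0;

  auto snapshot = [&](int day) {
    days.push_back(day); cd8s.push_back(n_immune); tums.push_back(n_tumour);
    if (record_grids) {
      IntegerMatrix g(L, L);
      for (size_t i = 0; i < agents.size(); ++i)
        if (agents[i].alive) g[agents[i].pos] = agents[i].cls;
      grids.push_back(g);
    }
  };

  if (stop_on_eradication && n_tumour == 0) {
    terminated_early = true;
    snapshot(1);
  }

  std::vector<int> order;
  int nb[8];

  for (int step = 1; step <= n_steps && !terminated_early; ++step) {
    // shuffled schedule over agents alive at step start
    order.clear();
    for (size_t i = 0; i < agents.size(); ++i)
      if (agents[i].alive) order.push_back((int)i);
    for (int i = (int)order.size() - 1; i > 0; --i)
      std::swap(order[i], order[runif_int(i + 1)]);

    for (size_t oi = 0; oi < order.size(); ++oi) {
      int ai = order[oi];
      Agent &a = agents[ai];
      if (!a.alive) continue;

      if (a.cls == TUMOUR) {
        if (unif_rand() < TUpdeath) {
          a.alive = false; occ[a.pos] = -1; --n_tumour; continue;
        }
        if (unif_rand() < TUpprol) {
          if (a.prolif <= 0 && !a.stem) { // exhausted capacity: division kills
            a.alive = false; occ[a.pos] = -1; --n_tumour; continue;
          }
          int nfree = free_neighbours(a.pos, L, occ, nb);
          if (nfree > 0) {
            Agent d;
            d.pos = nb[runif_int(nfree)]; d.cls = TUMOUR;
            if (a.stem) {
              // stem divisions reproduce the baseline stem fraction
              d.stem = unif_rand() < 0.2;
              d.prolif = (int)TUpmax;
            } else {
              a.prolif -= 1;
              d.stem = false; d.prolif = a.prolif;
            }
            d.engcap = 1 + runif_int(std::max(1, (int)TUintmax));
            d.killcap = 0; d.engstat = 0; d.alive = true;
            occ[d.pos] = (int)agents.size();
            agents.push_back(d); ++n_tumour;
          }
        }
        Agent &a2 = agents[ai]; // push_back may have reallocated
        if (a2.engstat == 0 && unif_rand() < TUpmig) {
          int nfree = free_neighbours(a2.pos, L, occ, nb);
          if (nfree > 0) do_move(agents, occ, ai, nb[runif_int(nfree)]);
        }
      } else { // IMMUNE
        if (unif_rand() < IMpdeath) {
          a.alive = false; occ[a.pos] = -1; --n_immune; continue;
        }
        if (unif_rand() < IMpprol) {
          if (a.prolif <= 0) {
            a.alive = false; occ[a.pos] = -1; --n_immune; continue;
          }
          int nfree = free_neighbours(a.pos, L, occ, nb);
          if (nfree > 0) {
            Agent d;
            d.pos = nb[runif_int(nfree)]; d.cls = IMMUNE;
            agents[ai].prolif -= 1;
            d.prolif = agents[ai].prolif;
            d.stem = false; d.engcap = 0; d.killcap = 100;
            d.engstat = 0; d.alive = true;
            occ[d.pos] = (int)agents.size();
            agents.push_back(d); ++n_immune;
          }
        }
        Agent &a2 = agents[ai];
        if (unif_rand() < IMpkill && a2.killcap > 0) {
          int r = a2.pos % L, c = a2.pos / L, ntum = 0, tcand[8];
          for (int i = 0; i < 8; ++i) {
            int p = pwrap(r + DR[i], L) + pwrap(c + DC[i], L) * L;
            if (occ[p] >= 0 && agents[occ[p]].cls == TUMOUR) tcand[ntum++] = p;
          }
          if (ntum > 0) {
            int vi = occ[tcand[runif_int(ntum)]];
            agents[vi].engcap -= 1;
            a2.killcap -= 1;
            a2.engstat = 1;
            if (agents[vi].engcap <= 0) {
              agents[vi].alive = false; occ[agents[vi].pos] = -1; --n_tumour;
            } else {
              agents[vi].engstat = 1;
            }
          }
        }
        Agent &a3 = agents[ai];
        if (a3.engstat == 0) {
          int moves = (int)std::floor(IMpmig);
          if (unif_rand() < IMpmig - std::floor(IMpmig)) ++moves;
          for (int m = 0; m < moves; ++m)
            immune_move(agents, occ, ai, L, IMrwalk);
        }
      }
    }

    // immune influx at the end of the step
    if (unif_rand() < IMinfluxProb) {
      int n_new = (int)std::lround(IMinflRate);
      std::vector<int> freesites;
      freesites.reserve(L * L);
      for (int p = 0; p < L * L; ++p) if (occ[p] < 0) freesites.push_back(p);
      for (int k = 0; k < n_new; ++k) {
        if (freesites.empty()) { ++influx_skipped; break; }
        int j = runif_int((int)freesites.size());
        Agent d;
        d.pos = freesites[j]; d.cls = IMMUNE;
        d.prolif = (int)IMpmax; d.stem = false; d.engcap = 0;
        d.killcap = 100; d.engstat = 0; d.alive = true;
        occ[d.pos] = (int)agents.size();
        agents.push_back(d); ++n_immune;
        freesites[j] = freesites.back(); freesites.pop_back();
      }
    }

    // engagement lasts one step
    for (size_t i = 0; i < agents.size(); ++i) agents[i].engstat = 0;

    if (stop_on_eradication && n_tumour == 0) {
      terminated_early = true;
      snapshot((step + steps_per_day - 1) / steps_per_day);
      break;
    }
    if (step % steps_per_day == 0) snapshot(step / steps_per_day);
  }

  IntegerMatrix gout(L, L), pout(L, L), eout(L, L), kout(L, L);
  LogicalMatrix sout(L, L);
  for (size_t i = 0; i < agents.size(); ++i) {
    if (!agents[i].alive) continue;
    const Agent &a = agents[i];
    gout[a.pos] = a.cls; pout[a.pos] = a.prolif; sout[a.pos] = a.stem;
    eout[a.pos] = a.engcap; kout[a.pos] = a.killcap;
  }

  return List::create(
    _["grid"] = gout, _["prolif"] = pout, _["stem"] = sout,
    _["engcap"] = eout, _["killcap"] = kout,
    _["day"] = wrap(days), _["n_cd8"] = wrap(cd8s), _["n_tumour"] = wrap(tums),
    _["grids"] = grids, _["terminated_early"] = terminated_early,
    _["influx_skipped"] = influx_skipped);
}

// Per-cell Chebyshev pair counts: out[i, j] = number of other cells at
// Chebyshev distance j (1..M) from cell i, with plain (non-periodic) geometry.
// [[Rcpp::export]]
IntegerMatrix chebyshev_pair_counts_cpp(IntegerVector r, IntegerVector c, int M) {
  int n = r.size();
  IntegerMatrix out(n, M);
  for (int i = 0; i < n; ++i) {
    for (int k = i + 1; k < n; ++k) {
      int d = std::max(std::abs(r[i] - r[k]), std::abs(c[i] - c[k]));
      if (d >= 1 && d <= M) { out(i, d - 1)++; out(k, d - 1)++; }
    }
  }
  return out;
}
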