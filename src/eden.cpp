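// Three-dimensional Eden-type lattice simulator of non-interacting
// microlesions with driver mutations and migration.
//
// Each lesion lives on its own integer lattice (lesions never interact).
// Every cell attempts to divide with rate b_n into a uniformly random
// neighbouring site; the attempt succeeds only if that site is empty
// (rejection semantics).  Daughters mutate n -> n+1 with probability pmu
// (capped at nmax).  Cells migrate with rate M (per surface cell by
// default; optionally per cell) and found a new one-cell lesion of the
// migrant's type at the origin of a fresh lattice.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int64_t B21 = 1 << 20;

static inline int64_t pack(int x, int y, int z) {
  return (((int64_t)(x + B21)) << 42) | (((int64_t)(y + B21)) << 21) |
         ((int64_t)(z + B21));
}
static inline void unpack(int64_t k, int &x, int &y, int &z) {
  x = (int)((k >> 42) & 0x1FFFFF) - (int)B21;
  y = (int)((k >> 21) & 0x1FFFFF) - (int)B21;
  z = (int)(k & 0x1FFFFF) - (int)B21;
}

struct Lesion {
  std::unordered_map<int64_t, uint8_t> occ;      // site -> driver count
  std::vector<std::vector<int64_t>> cells;       // per-type site lists
  std::vector<int64_t> surf;                     // surface sites
  std::unordered_map<int64_t, int> surf_ix;      // site -> index in surf
  std::vector<int> count;                        // per-type cell counts
  double birth;
};

struct Sim {
  std::vector<Lesion> les;
  int nmax, ndirs;
  int dirs[26][3];
  std::vector<double> b;       // per-type division rate
  double pmu, M;
  bool migrate_surface, remove_migrant;
  std::vector<long long> type_tot;   // global per-type counts
  long long cells_tot = 0, surf_tot = 0;
};

static void build_dirs(Sim &S, int neighborhood) {
  int m = 0;
  if (neighborhood == 6) {
    int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int i = 0; i < 6; i++) for (int j = 0; j < 3; j++)
      S.dirs[i][j] = d6[i][j];
    m = 6;
  } else {
    for (int dx = -1; dx <= 1; dx++) for (int dy = -1; dy <= 1; dy++)
      for (int dz = -1; dz <= 1; dz++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        S.dirs[m][0] = dx; S.dirs[m][1] = dy; S.dirs[m][2] = dz; m++;
      }
  }
  S.ndirs = m;
}

static bool has_empty_neighbor(const Sim &S, const Lesion &L, int64_t key) {
  int x, y, z; unpack(key, x, y, z);
  for (int d = 0; d < S.ndirs; d++) {
    int64_t nb = pack(x + S.dirs[d][0], y + S.dirs[d][1], z + S.dirs[d][2]);
    if (L.occ.find(nb) == L.occ.end()) return true;
  }
  return false;
}

static void surf_add(Sim &S, Lesion &L, int64_t key) {
  if (L.surf_ix.find(key) != L.surf_ix.end()) return;
  L.surf_ix[key] = (int)L.surf.size();
  L.surf.push_back(key);
  S.surf_tot++;
}

static void surf_remove(Sim &S, Lesion &L, int64_t key) {
  auto it = L.surf_ix.find(key);
  if (it == L.surf_ix.end()) return;
  int ix = it->second;
  int64_t last = L.surf.back();
  L.surf[ix] = last;
  L.surf_ix[last] = ix;
  L.surf.pop_back();
  L.surf_ix.erase(it);
  S.surf_tot--;
}

static void add_cell(Sim &S, Lesion &L, int64_t key, int type) {
  L.occ[key] = (uint8_t)type;
  L.cells[type - 1].push_back(key);
  L.count[type - 1]++;
  S.type_tot[type - 1]++;
  S.cells_tot++;
  if (has_empty_neighbor(S, L, key)) surf_add(S, L, key);
  // neighbours may have lost their last empty neighbour
  int x, y, z; unpack(key, x, y, z);
  for (int d = 0; d < S.ndirs; d++) {
    int64_t nb = pack(x + S.dirs[d][0], y + S.dirs[d][1], z + S.dirs[d][2]);
    if (L.occ.find(nb) != L.occ.end() &&
        L.surf_ix.find(nb) != L.surf_ix.end() &&
        !has_empty_neighbor(S, L, nb))
      surf_remove(S, L, nb);
  }
}

static void remove_cell(Sim &S, Lesion &L, int64_t key) {
  auto it = L.occ.find(key);
  if (it == L.occ.end()) return;
  int type = it->second;
  L.occ.erase(it);
  auto &v = L.cells[type - 1];
  for (size_t i = 0; i < v.size(); i++)
    if (v[i] == key) { v[i] = v.back(); v.pop_back(); break; }
  L.count[type - 1]--;
  S.type_tot[type - 1]--;
  S.cells_tot--;
  surf_remove(S, L, key);
  // neighbours gained an empty neighbour -> they are surface now
  int x, y, z; unpack(key, x, y, z);
  for (int d = 0; d < S.ndirs; d++) {
    int64_t nb = pack(x + S.dirs[d][0], y + S.dirs[d][1], z + S.dirs[d][2]);
    if (L.occ.find(nb) != L.occ.end()) surf_add(S, L, nb);
  }
}

static void new_lesion(Sim &S, int type, double t) {
  Lesion L;
  L.cells.resize(S.nmax);
  L.count.assign(S.nmax, 0);
  L.birth = t;
  S.les.push_back(std::move(L));
  add_cell(S, S.les.back(), pack(0, 0, 0), type);
}

// [[Rcpp::export]]
List run_eden_cpp(NumericVector b_rates, double pmu, double M, int nmax,
                  double t_max, double out_dt, int neighborhood,
                  bool migrate_surface, bool remove_migrant,
                  double max_cells) {
  Sim S;
  S.nmax = nmax;
  S.b = as<std::vector<double>>(b_rates);
  S.pmu = pmu; S.M = M;
  S.migrate_surface = migrate_surface;
  S.remove_migrant = remove_migrant;
  S.type_tot.assign(nmax, 0);
  build_dirs(S, neighborhood);
  RNGScope rngscope;

  new_lesion(S, 1, 0.0);
  double t = 0.0, next_out = 0.0;
  long long n_div = 0, n_att = 0;

  std::vector<double> out_t;
  std::vector<std::vector<long long>> out_counts;
  std::vector<int> out_nles;
  std::vector<double> out_sfrac, out_radius, out_aniso;

  auto record = [&](double tt) {
    out_t.push_back(tt);
    out_counts.push_back(std::vector<long long>(S.type_tot.begin(),
                                                S.type_tot.end()));
    out_nles.push_back((int)S.les.size());
    // lesion-1 surface statistics
    Lesion &L0 = S.les[0];
    long long mut = 0;
    double rsum = 0.0;
    int xmin = 0, xmax = 0, ymin = 0, ymax = 0, zmin = 0, zmax = 0;
    for (int64_t key : L0.surf) {
      int x, y, z; unpack(key, x, y, z);
      if (L0.occ[key] > 1) mut++;
      rsum += std::sqrt((double)x * x + (double)y * y + (double)z * z);
      if (x < xmin) xmin = x; if (x > xmax) xmax = x;
      if (y < ymin) ymin = y; if (y > ymax) ymax = y;
      if (z < zmin) zmin = z; if (z > zmax) zmax = z;
    }
    size_t ns = L0.surf.size();
    out_sfrac.push_back(ns ? (double)mut / ns : 0.0);
    out_radius.push_back(ns ? rsum / ns : 0.0);
    double ext[6] = {(double)xmax, (double)-xmin, (double)ymax,
                     (double)-ymin, (double)zmax, (double)-zmin};
    double emax = ext[0], emin = ext[0];
    for (int i = 1; i < 6; i++) {
      if (ext[i] > emax) emax = ext[i];
      if (ext[i] < emin) emin = ext[i];
    }
    out_aniso.push_back(emin > 0 ? emax / emin : 1.0);
  };

  while (t < t_max) {
    double div_rate = 0.0;
    for (int n = 0; n < nmax; n++) div_rate += S.b[n] * S.type_tot[n];
    double mig_base = S.migrate_surface ? (double)S.surf_tot
                                        : (double)S.cells_tot;
    double mig_rate = M * mig_base;
    double rate = div_rate + mig_rate;
    if (rate <= 0) break;
    t += ::Rf_rexp(1.0 / rate);
    while (next_out <= t && next_out <= t_max) { record(next_out); next_out += out_dt; }
    if (t >= t_max) break;

    if (unif_rand() * rate < div_rate) {
      // division attempt: type prop. to b_n * count, lesion prop. to count
      double u = unif_rand() * div_rate;
      int type = 0;
      for (int n = 0; n < nmax; n++) {
        u -= S.b[n] * S.type_tot[n];
        if (u <= 0) { type = n; break; }
      }
      double v = unif_rand() * S.type_tot[type];
      size_t li = 0;
      for (; li < S.les.size(); li++) {
        v -= S.les[li].count[type];
        if (v <= 0) break;
      }
      if (li >= S.les.size()) li = S.les.size() - 1;
      Lesion &L = S.les[li];
      int64_t key = L.cells[type][(size_t)(unif_rand() * L.count[type])];
      int x, y, z; unpack(key, x, y, z);
      int d = (int)(unif_rand() * S.ndirs);
      int64_t target = pack(x + S.dirs[d][0], y + S.dirs[d][1],
                            z + S.dirs[d][2]);
      n_att++;
      if (L.occ.find(target) == L.occ.end()) {
        int ctype = type + 1;     // 1-based daughter type
        if (S.pmu > 0 && ctype < nmax && unif_rand() < S.pmu) ctype++;
        add_cell(S, L, target, ctype);
        n_div++;
        if (S.cells_tot > (long long)max_cells)
          stop("site count exceeded max_cells; shorten t_max or raise the cap");
      }
    } else {
      // migration: uniform over eligible cells
      if (S.migrate_surface) {
        double v = unif_rand() * S.surf_tot;
        size_t li = 0;
        for (; li < S.les.size(); li++) {
          v -= (double)S.les[li].surf.size();
          if (v <= 0) break;
        }
        if (li >= S.les.size()) li = S.les.size() - 1;
        Lesion &L = S.les[li];
        if (!L.surf.empty()) {
          int64_t key = L.surf[(size_t)(unif_rand() * L.surf.size())];
          int mtype = L.occ[key];
          if (S.remove_migrant && S.cells_tot > 1) remove_cell(S, L, key);
          new_lesion(S, mtype, t);
        }
      } else {
        double v = unif_rand() * S.cells_tot;
        size_t li = 0; int mtype = 1;
        for (; li < S.les.size(); li++) {
          long long tot = 0;
          for (int n = 0; n < nmax; n++) tot += S.les[li].count[n];
          v -= (double)tot;
          if (v <= 0) break;
        }
        if (li >= S.les.size()) li = S.les.size() - 1;
        Lesion &L = S.les[li];
        long long tot = 0;
        for (int n = 0; n < nmax; n++) tot += L.count[n];
        double vv = unif_rand() * tot;
        int64_t key = -1;
        for (int n = 0; n < nmax; n++) {
          vv -= L.count[n];
          if (vv <= 0 && L.count[n] > 0) {
            key = L.cells[n][(size_t)(unif_rand() * L.count[n])];
            mtype = n + 1;
            break;
          }
        }
        if (key >= 0) {
          if (S.remove_migrant && S.cells_tot > 1) remove_cell(S, L, key);
          new_lesion(S, mtype, t);
        }
      }
    }
  }
  while (next_out <= t_max) { record(next_out); next_out += out_dt; }

  size_t nt = out_t.size();
  NumericMatrix counts(nt, nmax);
  for (size_t i = 0; i < nt; i++)
    for (int n = 0; n < nmax; n++) counts(i, n) = (double)out_counts[i][n];
  return List::create(
    _["time"] = wrap(out_t),
    _["counts"] = counts,
    _["n_lesions"] = wrap(out_nles),
    _["surf_mutant_frac"] = wrap(out_sfrac),
    _["radius"] = wrap(out_radius),
    _["anisotropy"] = wrap(out_aniso),
    _["n_divisions"] = (double)n_div,
    _["n_attempts"] = (double)n_att,
    _["final_cells"] = (double)S.cells_tot);
}
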