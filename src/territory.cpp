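#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Sum of x over the disk of cells whose center lies within `radius_cells`
// (Euclidean, in cell units) of each cell's center; out-of-grid treated as 0.
// [[Rcpp::export]]
NumericMatrix cpp_focal_disk_sum(NumericMatrix x, double radius_cells) {
  int nr = x.nrow(), nc = x.ncol();
  int r = (int)std::floor(radius_cells);
  std::vector<std::pair<int,int>> off;
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      if ((double)(di*di + dj*dj) <= radius_cells * radius_cells + 1e-9)
        off.push_back({di, dj});
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double s = 0.0;
      for (auto &o : off) {
        int ii = i + o.first, jj = j + o.second;
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) s += x(ii, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// Keep only the rook-connected component of `id`'s cells containing
// `origin` (0-based linear index); pruned cells become unowned. Returns the
// summed prey of pruned cells (callers subtract it from the owner's total).
static double prune_component(IntegerMatrix owner, NumericMatrix prey,
                              int id, int origin) {
  int nr = owner.nrow(), nc = owner.ncol(), n = nr * nc;
  std::vector<int> cells;
  for (int k = 0; k < n; ++k) if (owner[k] == id) cells.push_back(k);
  if (cells.empty()) return 0.0;
  std::vector<char> keep(n, 0);
  std::vector<int> stack;
  if (owner[origin] != id) {
    // origin lost (should not happen: origins are never contested)
    double lost = 0.0;
    for (int k : cells) { lost += prey[k]; owner[k] = 0; }
    return lost;
  }
  keep[origin] = 1; stack.push_back(origin);
  while (!stack.empty()) {
    int k = stack.back(); stack.pop_back();
    int i = k % nr, j = k / nr;
    const int ni[4] = {i - 1, i + 1, i, i};
    const int nj[4] = {j, j, j - 1, j + 1};
    for (int t = 0; t < 4; ++t) {
      if (ni[t] < 0 || ni[t] >= nr || nj[t] < 0 || nj[t] >= nc) continue;
      int kk = ni[t] + nj[t] * nr;
      if (owner[kk] == id && !keep[kk]) { keep[kk] = 1; stack.push_back(kk); }
    }
  }
  double lost = 0.0;
  for (int k : cells) if (!keep[k]) { lost += prey[k]; owner[k] = 0; }
  return lost;
}

// [[Rcpp::export]]
double cpp_prune_component(IntegerMatrix owner, NumericMatrix prey,
                           int id, int origin0) {
  return prune_component(owner, prey, id, origin0);
}

// Greedy monthly territory expansion for one female. Modifies `owner` in
// place. Repeatedly annexes the frontier cell (rook-adjacent to her
// territory, inside the mask) with the highest effective prey; ties are
// broken uniformly at random. Unowned cells are annexed outright. A cell
// owned by a *younger* female (ties: larger id is subordinate) is contested
// with probability `contest_p`; on success the cell transfers and the
// subordinate's territory is pruned to the component containing her origin.
// A failed contest removes the cell from this month's candidates. A
// subordinate's origin cell is never contested. Expansion stops after
// `max_add` acquisitions or once utilized prey reaches `stop_util`.
//
// fem_id/fem_age/fem_origin describe all settled females (origin as 0-based
// linear index). Returns the number of cells added, the owner's new prey
// sum, and per-loser prey losses.
// [[Rcpp::export]]
List cpp_expand_territory(IntegerMatrix owner, NumericMatrix prey,
                          LogicalMatrix mask,
                          int id, double age, int origin0,
                          IntegerVector fem_id, NumericVector fem_age,
                          IntegerVector fem_origin0,
                          double prey_sum, double util_frac, double stop_util,
                          int max_add, double contest_p,
                          int max_cells_total) {
  int nr = owner.nrow(), nc = owner.ncol(), n = nr * nc;
  std::unordered_map<int, double> ageof;
  std::unordered_map<int, int> originof;
  for (int i = 0; i < fem_id.size(); ++i) {
    ageof[fem_id[i]] = fem_age[i];
    originof[fem_id[i]] = fem_origin0[i];
  }
  // state flags: 0 untouched, 1 in frontier, 2 dead (blocked/annexed/own)
  std::vector<char> flag(n, 0);
  std::vector<int> frontier;
  frontier.reserve(512);

  auto push_neighbors = [&](int k) {
    int i = k % nr, j = k / nr;
    const int ni[4] = {i - 1, i + 1, i, i};
    const int nj[4] = {j, j, j - 1, j + 1};
    for (int t = 0; t < 4; ++t) {
      if (ni[t] < 0 || ni[t] >= nr || nj[t] < 0 || nj[t] >= nc) continue;
      int kk = ni[t] + nj[t] * nr;
      if (flag[kk] || !mask[kk] || owner[kk] == id) continue;
      flag[kk] = 1;
      frontier.push_back(kk);
    }
  };
  // collect the territory by flood fill from the origin (territories are
  // rook-connected by construction), pushing frontier as we go
  int ncells = 0;
  {
    std::vector<int> stack;
    std::vector<char> seen(n, 0);
    if (owner[origin0] == id) { seen[origin0] = 1; stack.push_back(origin0); }
    while (!stack.empty()) {
      int k = stack.back(); stack.pop_back();
      ++ncells;
      push_neighbors(k);
      int i = k % nr, j = k / nr;
      const int ni[4] = {i - 1, i + 1, i, i};
      const int nj[4] = {j, j, j - 1, j + 1};
      for (int t = 0; t < 4; ++t) {
        if (ni[t] < 0 || ni[t] >= nr || nj[t] < 0 || nj[t] >= nc) continue;
        int kk = ni[t] + nj[t] * nr;
        if (owner[kk] == id && !seen[kk]) { seen[kk] = 1; stack.push_back(kk); }
      }
    }
  }

  std::unordered_map<int, double> losses;
  int added = 0;
  RNGScope scope;
  while (added < max_add && util_frac * prey_sum < stop_util &&
         ncells + added < max_cells_total) {
    // best live frontier candidate; uniform tie-break by reservoir sampling
    double best = -1.0; int pick = -1; int nties = 0;
    for (size_t t = 0; t < frontier.size(); ++t) {
      int k = frontier[t];
      if (flag[k] != 1) continue;
      if (owner[k] == id) { flag[k] = 2; continue; }
      double v = prey[k];
      if (v > best) { best = v; pick = k; nties = 1; }
      else if (v == best) { if (unif_rand() * (++nties) < 1.0) pick = k; }
    }
    if (pick < 0) break;
    int holder = owner[pick];
    if (holder == 0) {
      owner[pick] = id;
      prey_sum += prey[pick];
      ++added;
      flag[pick] = 2;
      push_neighbors(pick);
    } else {
      // contest: only against a strictly subordinate (younger, ties by id)
      double ha = ageof.count(holder) ? ageof[holder] : -1.0;
      bool dominant = (age > ha) || (age == ha && id < holder);
      bool is_origin = originof.count(holder) && originof[holder] == pick;
      if (!dominant || is_origin) { flag[pick] = 2; continue; }
      if (unif_rand() < contest_p) {
        owner[pick] = id;
        double lost = prey[pick];
        prey_sum += prey[pick];
        ++added;
        flag[pick] = 2;
        push_neighbors(pick);
        lost += prune_component(owner, prey, holder, originof[holder]);
        losses[holder] += lost;
      } else {
        flag[pick] = 2; // failed contest: cell stays with holder this month
      }
    }
  }
  IntegerVector lid(losses.size());
  NumericVector lloss(losses.size());
  int i = 0;
  for (auto &kv : losses) { lid[i] = kv.first; lloss[i] = kv.second; ++i; }
  return List::create(_["added"] = added, _["prey_sum"] = prey_sum,
                      _["loser_id"] = lid, _["loser_loss"] = lloss);
}

// Females with at least one territory cell within `radius_m` of (row0,col0)
// (1-based indices): per-female minimum cell-center distance, ascending.
// [[Rcpp::export]]
List cpp_females_in_radius(IntegerMatrix owner, int row0, int col0,
                           double radius_m, double cell_size) {
  int nr = owner.nrow(), nc = owner.ncol();
  int rad = (int)std::ceil(radius_m / cell_size);
  std::unordered_map<int, double> dmin;
  for (int i = std::max(1, row0 - rad); i <= std::min(nr, row0 + rad); ++i)
    for (int j = std::max(1, col0 - rad); j <= std::min(nc, col0 + rad); ++j) {
      int id = owner(i - 1, j - 1);
      if (id <= 0) continue;
      double d = std::sqrt((double)((i - row0) * (i - row0) +
                                    (j - col0) * (j - col0))) * cell_size;
      if (d > radius_m) continue;
      auto it = dmin.find(id);
      if (it == dmin.end() || d < it->second) dmin[id] = d;
    }
  std::vector<std::pair<double, int>> v;
  for (auto &kv : dmin) v.push_back({kv.second, kv.first});
  std::sort(v.begin(), v.end());
  IntegerVector ids(v.size());
  NumericVector dist(v.size());
  for (size_t t = 0; t < v.size(); ++t) { ids[t] = v[t].second; dist[t] = v[t].first; }
  return List::create(_["id"] = ids, _["dist_m"] = dist);
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance in cell units from every cell to the nearest site cell.
// All-zero input gives R_PosInf everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_edt(IntegerMatrix site) {
  int nr = site.nrow(), nc = site.ncol();
  const double INF = 1e20;
  NumericMatrix g(nr, nc);
  // 1D pass down/up each column: row distance to nearest site
  for (int j = 0; j < nc; ++j) {
    double d = INF;
    for (int i = 0; i < nr; ++i) {
      d = site(i, j) ? 0.0 : (d >= INF ? INF : d + 1.0);
      g(i, j) = d;
    }
    d = INF;
    for (int i = nr - 1; i >= 0; --i) {
      d = site(i, j) ? 0.0 : (d >= INF ? INF : d + 1.0);
      if (d < g(i, j)) g(i, j) = d;
    }
  }
  // 1D squared-distance transform along each row (lower envelope of parabolas)
  NumericMatrix out(nr, nc);
  std::vector<int> v(nc);
  std::vector<double> z(nc + 1), f(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      f[j] = g(i, j) >= INF ? INF : g(i, j) * g(i, j);
    }
    int k = 0;
    v[0] = 0; z[0] = -INF; z[1] = INF;
    for (int q = 1; q < nc; ++q) {
      if (f[q] >= INF && f[v[k]] >= INF) { // both empty columns
        // parabola from q only matters if finite; skip by treating as +INF
      }
      double s;
      while (true) {
        s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
            (2.0 * q - 2.0 * v[k]);
        if (s <= z[k]) { --k; } else break;
      }
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < nc; ++q) {
      while (z[k + 1] < q) ++k;
      double dq = (double)(q - v[k]);
      double val = dq * dq + f[v[k]];
      out(i, q) = val >= INF ? R_PosInf : std::sqrt(val);
    }
  }
  return out;
}
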