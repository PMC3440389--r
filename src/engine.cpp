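#include <Rcpp.h>
using namespace Rcpp;

// Agent behavioural states
enum State { IDLE = 0, SEARCHING = 1, FEEDING = 2, DISSATISFIED = 3,
             RECRUITING = 4, UNLOADING = 5 };

// 8 compass directions, multiples of 45 deg; step length exactly 1 cell
static const double SQ = 0.7071067811865476;
static const double DIRX[8] = {1, SQ, 0, -SQ, -1, -SQ, 0, SQ};
static const double DIRY[8] = {0, SQ, 1, SQ, 0, -SQ, -1, -SQ};

static inline int rint_n(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Grid {
  const int *region;
  const double *scent;
  double *pher;
  int nx, ny, x0, y0;

  inline int cell_i(double x) const { return (int)std::floor(x) - x0; }
  inline int cell_j(double y) const { return (int)std::floor(y) - y0; }
  inline bool inside(int i, int j) const {
    return i >= 0 && j >= 0 && i < nx && j < ny;
  }
  inline int reg(int i, int j) const {
    return inside(i, j) ? region[i + (size_t)nx * j] : 0;
  }
  inline bool walkable_at(double x, double y) const {
    return reg(cell_i(x), cell_j(y)) > 0;
  }
};

// Pick among the three forward directions (heading, heading +/- 45 deg) the
// walkable destination cell with the greatest field value, provided it
// exceeds `threshold`; ties broken uniformly at random. Returns the absolute
// direction index 0..7, or -1 if no candidate qualifies.
static int sense_forward_impl(const Grid &g, const double *field,
                              double x, double y, int heading,
                              double threshold) {
  int best[3]; int nbest = 0; double bestval = R_NegInf;
  for (int t = -1; t <= 1; ++t) {
    int d = ((heading + t) % 8 + 8) % 8;
    int i = g.cell_i(x + DIRX[d]);
    int j = g.cell_j(y + DIRY[d]);
    if (g.reg(i, j) <= 0) continue;
    double v = field[i + (size_t)g.nx * j];
    if (ISNAN(v) || v <= threshold) continue;
    if (v > bestval) { bestval = v; best[0] = d; nbest = 1; }
    else if (v == bestval) best[nbest++] = d;
  }
  if (nbest == 0) return -1;
  return best[rint_n(nbest)];
}

// Directions whose one-step destination stays walkable.
static int admissible_dirs(const Grid &g, double x, double y, int out[8]) {
  int n = 0;
  for (int d = 0; d < 8; ++d)
    if (g.walkable_at(x + DIRX[d], y + DIRY[d])) out[n++] = d;
  return n;
}

// Greedy step toward a target point: among the three forward walkable cells
// pick the one whose centre is nearest the target (ties random); if none of
// the forward cells is walkable, fall back to a uniform admissible step.
static int toward_target(const Grid &g, double x, double y, int heading,
                         double tx, double ty) {
  int best[3]; int nbest = 0; double bestval = R_NegInf;
  for (int t = -1; t <= 1; ++t) {
    int d = ((heading + t) % 8 + 8) % 8;
    int i = g.cell_i(x + DIRX[d]);
    int j = g.cell_j(y + DIRY[d]);
    if (g.reg(i, j) <= 0) continue;
    double cx = i + g.x0 + 0.5, cy = j + g.y0 + 0.5;
    double v = -std::sqrt((cx - tx) * (cx - tx) + (cy - ty) * (cy - ty));
    if (v > bestval) { bestval = v; best[0] = d; nbest = 1; }
    else if (v == bestval) best[nbest++] = d;
  }
  if (nbest > 0) return best[rint_n(nbest)];
  int adm[8]; int n = admissible_dirs(g, x, y, adm);
  return n > 0 ? adm[rint_n(n)] : -1;
}

// [[Rcpp::export]]
int cpp_sense_forward(IntegerMatrix region, NumericMatrix field,
                      int x0, int y0, double x, double y,
                      int heading, double threshold) {
  Grid g{region.begin(), nullptr, nullptr,
         region.nrow(), region.ncol(), x0, y0};
  return sense_forward_impl(g, field.begin(), x, y, heading, threshold);
}

// [[Rcpp::export]]
IntegerVector cpp_admissible_dirs(IntegerMatrix region, int x0, int y0,
                                  double x, double y) {
  Grid g{region.begin(), nullptr, nullptr,
         region.nrow(), region.ncol(), x0, y0};
  int adm[8]; int n = admissible_dirs(g, x, y, adm);
  return IntegerVector(adm, adm + n);
}

// Full simulation run. Region codes: 1 nest, 2 stem, 3 left arm, 4 right
// arm, 5 patch 1, 6 patch 2. Within each time step the state groups are
// updated asynchronously in sequence (forward: idle, searching, feeding,
// dissatisfied, recruiting, unloading; or reversed); each agent acts at most
// once per step. Deposits land before the global decay of the step.
// [[Rcpp::export]]
List cpp_run_sim(IntegerMatrix region, NumericMatrix scent,
                 int x0, int y0,
                 int colony, int steps,
                 IntegerVector thresholds, IntegerVector patch_from,
                 double deposit_amount, double decay_rate,
                 double diffusion_rate, double detection_threshold,
                 double p_leave, int drinking_time, int unloading_time,
                 double nest_cx, double nest_cy,
                 NumericVector patch_cx, NumericVector patch_cy,
                 bool reversed_order, bool routed, double p_nest,
                 bool nest_resets, bool diss_off_patch,
                 IntegerVector trace_ids) {
  int nx = region.nrow(), ny = region.ncol();
  NumericMatrix pher(nx, ny);
  Grid g{region.begin(), scent.begin(), pher.begin(), nx, ny, x0, y0};
  const double *scentp = scent.begin();
  double *pherp = pher.begin();
  double keep = (100.0 - decay_rate) / 100.0;

  // agent arrays
  std::vector<double> ax(colony, nest_cx), ay(colony, nest_cy);
  std::vector<int> st(colony, IDLE), hd(colony), tm(colony, 0),
      fp(colony, 0), goal(colony, 0), upd(colony, -1);
  for (int i = 0; i < colony; ++i) hd[i] = rint_n(8);

  int feed_count[3] = {0, 0, 0};
  int thr[3] = {0, thresholds[0], thresholds[1]};
  int from[3] = {0, patch_from[0], patch_from[1]};

  // arm / patch cell index lists for per-step summaries
  std::vector<int> arm_cells[2];
  std::vector<int> walk_cells;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int r = region[i + (size_t)nx * j];
      if (r > 0) walk_cells.push_back(i + nx * j);
      if (r == 3) arm_cells[0].push_back(i + nx * j);
      if (r == 4) arm_cells[1].push_back(i + nx * j);
    }
  // 8-neighbour offsets for diffusion (walls absorb: shares sent toward
  // non-walkable cells are lost)
  std::vector<double> pher_buf((size_t)nx * ny, 0.0);
  const int noff[8][2] = {{1,0},{1,1},{0,1},{-1,1},{-1,0},{-1,-1},{0,-1},{1,-1}};

  NumericMatrix series(steps, 11); // n1 n2 pher1 pher2 idle srch feed diss recr unld crowd_ok
  std::vector<bool> traced(colony, false);
  for (int k = 0; k < trace_ids.size(); ++k) {
    int id = trace_ids[k] - 1;
    if (id >= 0 && id < colony) traced[id] = true;
  }
  int ntr = 0; for (int i = 0; i < colony; ++i) ntr += traced[i];
  NumericMatrix trace(ntr > 0 ? (size_t)steps * ntr : 0, 5);
  size_t trow = 0;

  const int fwd[6] = {IDLE, SEARCHING, FEEDING, DISSATISFIED, RECRUITING,
                      UNLOADING};

  int commit_nest = 0, commit_other = 0;
  auto commit_goal = [&](int i, int at_patch, int t) {
    int other = 3 - at_patch;
    bool other_free = (t >= from[other]) && (feed_count[other] < thr[other]);
    if (!other_free) goal[i] = 1;           // both crowded -> nest
    else {
      goal[i] = (unif_rand() < p_nest) ? 1 : 1 + other;
      if (goal[i] == 1) ++commit_nest; else ++commit_other;
    }
  };

  // resolve a patch-region entry (crossing from outside the patch region)
  // for searching/dissatisfied agents; movement within the region does not
  // re-trigger, so an agent inside a patch when it opens must leave and
  // re-enter before it can feed
  auto try_feed = [&](int i, int t, int reg_before) -> bool {
    int r = g.reg(g.cell_i(ax[i]), g.cell_j(ay[i]));
    if (r != 5 && r != 6) return false;
    if (r == reg_before) return false;      // still inside: no new arrival
    int p = r - 4;
    if (t < from[p]) return false;          // patch not yet open: walk on
    if (feed_count[p] < thr[p]) {
      st[i] = FEEDING; tm[i] = drinking_time; fp[i] = p; ++feed_count[p];
    } else if (st[i] != DISSATISFIED) {
      st[i] = DISSATISFIED;
      if (routed) commit_goal(i, p, t);
    }
    return true;
  };

  auto move_dir = [&](int i, int d) {
    ax[i] += DIRX[d]; ay[i] += DIRY[d]; hd[i] = d;
  };

  auto random_step = [&](int i) {
    int adm[8]; int n = admissible_dirs(g, ax[i], ay[i], adm);
    if (n == 0) { hd[i] = (hd[i] + 4) % 8; return false; }
    move_dir(i, adm[rint_n(n)]);
    return true;
  };

  bool ceiling_ok = true;

  for (int t = 1; t <= steps; ++t) {
    for (int gi = 0; gi < 6; ++gi) {
      int group = reversed_order ? fwd[5 - gi] : fwd[gi];
      for (int i = 0; i < colony; ++i) {
        if (st[i] != group || upd[i] == t) continue;
        upd[i] = t;
        switch (group) {
        case IDLE:
          if (unif_rand() < p_leave) { st[i] = SEARCHING; hd[i] = rint_n(8); }
          break;
        case SEARCHING: {
          int rb = g.reg(g.cell_i(ax[i]), g.cell_j(ay[i]));
          int d = sense_forward_impl(g, pherp, ax[i], ay[i], hd[i],
                                     detection_threshold);
          if (d >= 0) move_dir(i, d);
          else if (!random_step(i)) break;
          if (!try_feed(i, t, rb) && nest_resets && rb != 1 &&
              g.reg(g.cell_i(ax[i]), g.cell_j(ay[i])) == 1)
            st[i] = IDLE;  // re-entered the nest empty: back to the idle pool
          break;
        }
        case FEEDING:
          if (--tm[i] == 0) {
            st[i] = RECRUITING; --feed_count[fp[i]]; fp[i] = 0;
          }
          break;
        case DISSATISFIED:
          if (!routed) {
            int rb = g.reg(g.cell_i(ax[i]), g.cell_j(ay[i]));
            if (random_step(i) && !try_feed(i, t, rb)) {
              int rn = g.reg(g.cell_i(ax[i]), g.cell_j(ay[i]));
              if (nest_resets && rb != 1 && rn == 1) st[i] = IDLE;
              else if (diss_off_patch && rn != 5 && rn != 6)
                st[i] = SEARCHING;  // left the patch: ordinary forager again
            }
          } else {
            double tx, ty;
            if (goal[i] == 1) { tx = nest_cx; ty = nest_cy; }
            else { tx = patch_cx[goal[i] - 2]; ty = patch_cy[goal[i] - 2]; }
            int d = toward_target(g, ax[i], ay[i], hd[i], tx, ty);
            if (d >= 0) move_dir(i, d);
            int r = g.reg(g.cell_i(ax[i]), g.cell_j(ay[i]));
            if (goal[i] == 1) {
              if (r == 1) { st[i] = SEARCHING; goal[i] = 0; }
            } else {
              int p = goal[i] - 1;
              if (r == 4 + p) {
                if (t >= from[p] && feed_count[p] < thr[p]) {
                  st[i] = FEEDING; tm[i] = drinking_time; fp[i] = p;
                  ++feed_count[p]; goal[i] = 0;
                } else commit_goal(i, p, t);
              }
            }
          }
          break;
        case RECRUITING: {
          int d = sense_forward_impl(g, scentp, ax[i], ay[i], hd[i],
                                     R_NegInf);
          if (d >= 0) move_dir(i, d);
          else if (!random_step(i)) break;
          int ci = g.cell_i(ax[i]), cj = g.cell_j(ay[i]);
          pherp[ci + (size_t)nx * cj] += deposit_amount;
          if (g.reg(ci, cj) == 1) { st[i] = UNLOADING; tm[i] = unloading_time; }
          break;
        }
        case UNLOADING:
          if (--tm[i] == 0) st[i] = IDLE;
          break;
        }
      }
    }

    // diffusion then global evaporation, once per step, after all deposits
    if (diffusion_rate > 0) {
      for (size_t c = 0; c < walk_cells.size(); ++c)
        pher_buf[walk_cells[c]] = 0.0;
      for (size_t c = 0; c < walk_cells.size(); ++c) {
        int k = walk_cells[c];
        int i = k % nx, j = k / nx;
        double share = diffusion_rate * pherp[k] / 8.0;
        pher_buf[k] += (1.0 - diffusion_rate) * pherp[k];
        for (int d = 0; d < 8; ++d) {
          int ii = i + noff[d][0], jj = j + noff[d][1];
          if (ii >= 0 && jj >= 0 && ii < nx && jj < ny &&
              region[ii + (size_t)nx * jj] > 0)
            pher_buf[ii + (size_t)nx * jj] += share;
        }
      }
      for (size_t c = 0; c < walk_cells.size(); ++c)
        pherp[walk_cells[c]] = pher_buf[walk_cells[c]];
    }
    if (decay_rate > 0) {
      size_t ncell = (size_t)nx * ny;
      for (size_t k = 0; k < ncell; ++k) pherp[k] *= keep;
    }

    // record
    double psum[2] = {0, 0};
    for (int a = 0; a < 2; ++a)
      for (size_t k = 0; k < arm_cells[a].size(); ++k)
        psum[a] += pherp[arm_cells[a][k]];
    int cnt[6] = {0, 0, 0, 0, 0, 0};
    for (int i = 0; i < colony; ++i) ++cnt[st[i]];
    series(t - 1, 0) = feed_count[1];
    series(t - 1, 1) = feed_count[2];
    series(t - 1, 2) = psum[0];
    series(t - 1, 3) = psum[1];
    for (int s = 0; s < 6; ++s) series(t - 1, 4 + s) = cnt[s];
    bool ok = (t < from[1] ? feed_count[1] == 0 : feed_count[1] <= thr[1]) &&
              (t < from[2] ? feed_count[2] == 0 : feed_count[2] <= thr[2]);
    if (!ok) ceiling_ok = false;
    series(t - 1, 10) = ok ? 1 : 0;

    if (ntr > 0)
      for (int i = 0; i < colony; ++i)
        if (traced[i]) {
          trace(trow, 0) = t; trace(trow, 1) = i + 1;
          trace(trow, 2) = ax[i]; trace(trow, 3) = ay[i];
          trace(trow, 4) = st[i]; ++trow;
        }
  }

  return List::create(_["series"] = series, _["pheromone"] = pher,
                      _["trace"] = trace, _["ceiling_ok"] = ceiling_ok,
                      _["routed_commits"] = IntegerVector::create(
                          _["nest"] = commit_nest, _["other"] = commit_other));
}
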