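#include <Rcpp.h>
using namespace Rcpp;

// Nearest-seed assignment of every grid cell to a field (grid-based Voronoi
// tessellation).  Coordinates are 0-based: x = column, y = row, origin
// top-left.  Distances are Euclidean between cell centres; because all cells
// share the same half-cell offset this reduces to integer squared distance on
// the (x, y) indices, so ties are detected exactly and broken toward the
// lowest field id.
// [[Rcpp::export]]
IntegerMatrix cpp_assign_fields(IntegerVector seed_x, IntegerVector seed_y,
                                int width, int height) {
  int ns = seed_x.size();
  if (ns < 1) stop("at least one field seed is required");
  IntegerMatrix field(height, width);
  for (int y = 0; y < height; ++y) {
    for (int x = 0; x < width; ++x) {
      long best = -1;
      int best_id = 0;
      for (int s = 0; s < ns; ++s) {
        long dx = (long)x - seed_x[s];
        long dy = (long)y - seed_y[s];
        long d2 = dx * dx + dy * dy;
        if (best < 0 || d2 < best) {  // strict: first (lowest) id wins ties
          best = d2;
          best_id = s;
        }
      }
      field(y, x) = best_id;
    }
  }
  return field;
}

// Habitat-biased correlated random walk on a habitat grid (0 = crop,
// 1 = wild).  Headings are absolute directions 0=N, 1=E, 2=S, 3=W (N is
// decreasing y).  Relative directions are derived from the heading by
// clockwise rotation: forward = heading, right = +90, backward = +180,
// left = +270.  Unadjusted probabilities p are (pF, pB, pS, pS) for
// (forward, backward, left, right); moving into a cell of a different
// habitat multiplies the preference by r; off-grid directions get
// preference 0.  If all four preferences vanish the walker stays in place
// for that timestep.
//
// Uses R's RNG stream: one uniform draw for the initial heading (when
// init_heading < 0) and exactly one per timestep, so trajectories are
// reproducible from set.seed() and can be mirrored step-for-step by a plain
// R implementation.
// [[Rcpp::export]]
List cpp_simulate_walk(IntegerMatrix habitat, int nest_x, int nest_y,
                       double pF, double pS, double pB, double r,
                       int T, int init_heading, bool keep_path) {
  int height = habitat.nrow(), width = habitat.ncol();
  if (nest_x < 0 || nest_x >= width || nest_y < 0 || nest_y >= height)
    stop("nest coordinates fall outside the grid");
  if (T < 1) stop("T must be >= 1");

  static const int DX[4] = {0, 1, 0, -1};  // N E S W
  static const int DY[4] = {-1, 0, 1, 0};
  const double p_rel[4] = {pF, pB, pS, pS};  // forward, backward, left, right
  // relative index -> heading offset (clockwise quarter turns)
  static const int ROT[4] = {0, 2, 3, 1};

  int heading = init_heading;
  if (heading < 0) {
    heading = (int)(4.0 * unif_rand());
    if (heading > 3) heading = 3;
  }
  const int heading0 = heading;

  int x = nest_x, y = nest_y;
  int cur_hab = habitat(y, x);
  double max_d2 = 0.0;
  int n_switch = 0, n_wild = 0, border_steps = 0, n_stay = 0;

  IntegerVector px, py, phead, phab, pswitch, pmoved;
  if (keep_path) {
    px = IntegerVector(T); py = IntegerVector(T); phead = IntegerVector(T);
    phab = IntegerVector(T); pswitch = IntegerVector(T); pmoved = IntegerVector(T);
  }

  for (int t = 0; t < T; ++t) {
    double m[4];
    double total = 0.0;
    bool on_border = false;
    for (int k = 0; k < 4; ++k) {
      int dir = (heading + ROT[k]) % 4;
      int nx = x + DX[dir], ny = y + DY[dir];
      if (nx < 0 || nx >= width || ny < 0 || ny >= height) {
        m[k] = 0.0;
        on_border = true;
      } else {
        m[k] = (habitat(ny, nx) == cur_hab) ? p_rel[k] : r * p_rel[k];
      }
      total += m[k];
    }
    if (on_border) ++border_steps;

    bool moved = false, switched = false;
    if (total > 0.0) {
      double u = unif_rand() * total;
      int k = 0;
      double acc = m[0];
      while (k < 3 && u >= acc) acc += m[++k];
      int dir = (heading + ROT[k]) % 4;
      x += DX[dir];
      y += DY[dir];
      int new_hab = habitat(y, x);
      switched = (new_hab != cur_hab);
      if (switched) ++n_switch;
      cur_hab = new_hab;
      heading = dir;
      moved = true;
    } else {
      ++n_stay;
    }

    double ddx = (double)(x - nest_x), ddy = (double)(y - nest_y);
    double d2 = ddx * ddx + ddy * ddy;
    if (d2 > max_d2) max_d2 = d2;
    if (cur_hab == 1) ++n_wild;

    if (keep_path) {
      px[t] = x; py[t] = y; phead[t] = heading; phab[t] = cur_hab;
      pswitch[t] = switched ? 1 : 0; pmoved[t] = moved ? 1 : 0;
    }
  }

  List out = List::create(
    _["max_distance"] = std::sqrt(max_d2),
    _["n_switches"] = n_switch,
    _["prop_wild"] = (double)n_wild / (double)T,
    _["border_steps"] = border_steps,
    _["stay_steps"] = n_stay,
    _["init_heading"] = heading0,
    _["final_x"] = x,
    _["final_y"] = y);
  if (keep_path) {
    out["path"] = DataFrame::create(
      _["t"] = seq_len(T), _["x"] = px, _["y"] = py, _["heading"] = phead,
      _["habitat"] = phab, _["switched"] = pswitch, _["moved"] = pmoved);
  }
  return out;
}
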