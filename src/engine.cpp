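#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Compiled session engine. This performs the identical synchronous update
// as the pure-R step_world(), consuming the same RNG stream in the same
// order (2 * n uniforms per tick, plus 2 per target spawn), so the two
// implementations can be cross-checked tick-for-tick.

static inline double wrap1(double v, double L) {
  return v - std::floor(v / L) * L;
}

// minimum-image reduction into [-L/2, L/2), tie toward -L/2
static inline double mi(double d, double L) {
  return d - std::floor(d / L + 0.5) * L;
}

// mirror of R's `^` dispatch for doubles (y == 2 short-circuits to x * x)
static inline double r_pow(double x, double y) {
  if (y == 2.0) return x * x;
  if (x == 1.0 || y == 0.0) return 1.0;
  return std::pow(x, y);
}

// [[Rcpp::export]]
List advance_world_cpp(List world, List params, List cond, List rule,
                       int n_ticks, bool record,
                       Nullable<Function> controller, int cslot) {
  const int n = as<int>(params["n_agents"]);
  const double L = as<double>(params["L"]);
  const double d_v = as<double>(rule["d_v"]);
  const double s = as<double>(rule["s"]);
  const double rep_exp = as<double>(rule["rep_exp"]);
  const double att_exp = as<double>(rule["att_exp"]);
  const double cutoff = as<double>(rule["cutoff_factor"]) * d_v;
  const double speed = as<double>(rule["speed"]);
  const bool flock_on = as<bool>(cond["flocking_on"]);
  const bool dist_on = as<bool>(cond["distancing_on"]);
  const double target_units = as<double>(params["target_units"]);
  const double rate = as<double>(params["consumption_rate"]);
  const double arrival_radius = as<double>(params["arrival_radius"]);
  const double deg = M_PI / 180.0;

  std::vector<double> x = as<std::vector<double>>(world["x"]);
  std::vector<double> y = as<std::vector<double>>(world["y"]);
  std::vector<double> h = as<std::vector<double>>(world["heading"]);
  std::vector<int> flagged = as<std::vector<int>>(world["flagged"]);
  std::vector<int> consuming = as<std::vector<int>>(world["consuming"]);
  std::vector<double> consumed = as<std::vector<double>>(world["consumed"]);
  double tick = as<double>(world["tick"]);
  double target_ax = as<double>(world["target_ax"]);
  double target_ay = as<double>(world["target_ay"]);
  double units = as<double>(world["units"]);
  double trial_index = as<double>(world["trial_index"]);
  double trial_start = as<double>(world["trial_start"]);
  double detect_tick = as<double>(world["detect_tick"]);     // NA allowed
  double arrival_tick = as<double>(world["arrival_tick"]);
  double first_detector = as<double>(world["first_detector"]);

  List wtr = world["trials"];
  std::vector<double> tr_index = as<std::vector<double>>(wtr["index"]);
  std::vector<double> tr_start = as<std::vector<double>>(wtr["start"]);
  std::vector<double> tr_detect = as<std::vector<double>>(wtr["detect"]);
  std::vector<double> tr_arrival = as<std::vector<double>>(wtr["arrival"]);
  std::vector<double> tr_end = as<std::vector<double>>(wtr["end"]);
  std::vector<double> tr_fd = as<std::vector<double>>(wtr["first_detector"]);

  NumericMatrix log_x, log_y, log_h;
  IntegerMatrix log_mask;
  IntegerVector log_trial, log_tick, log_flag, log_cons;
  if (record) {
    log_x = NumericMatrix(n_ticks, n);
    log_y = NumericMatrix(n_ticks, n);
    log_h = NumericMatrix(n_ticks, n);
    log_mask = IntegerMatrix(n_ticks, n);
    log_trial = IntegerVector(n_ticks);
    log_tick = IntegerVector(n_ticks);
    log_flag = IntegerVector(n_ticks);
    log_cons = IntegerVector(n_ticks);
  }

  std::vector<double> dist(n * n, 0.0);
  std::vector<double> td(n), newx(n), newy(n), newh(n);
  std::vector<int> see(n);
  const bool has_ctrl = controller.isNotNull() && cslot >= 1;

  for (int t = 0; t < n_ticks; ++t) {
    // snapshot distances
    for (int i = 0; i < n; ++i) {
      dist[i * n + i] = 0.0;
      for (int j = 0; j < n; ++j) {
        if (i == j) continue;
        double dx = mi(x[j] - x[i], L);
        double dy = mi(y[j] - y[i], L);
        dist[i * n + j] = std::sqrt(dx * dx + dy * dy);
      }
    }
    double tcx = wrap1(target_ax + 1.0, L);
    double tcy = wrap1(target_ay + 1.0, L);
    for (int i = 0; i < n; ++i) {
      double dx = mi(tcx - x[i], L);
      double dy = mi(tcy - y[i], L);
      td[i] = std::sqrt(dx * dx + dy * dy);
      see[i] = td[i] < d_v;
    }

    // flags + detection
    bool any_see = false;
    int first_seer = -1;
    for (int i = 0; i < n; ++i) {
      if (see[i]) {
        flagged[i] = 1;
        if (!any_see) { any_see = true; first_seer = i; }
      }
    }
    if (ISNAN(detect_tick) && any_see) {
      detect_tick = tick;
      first_detector = first_seer + 1;  // 1-based id
    }

    // arrivals
    bool newly_arrived = false;
    for (int i = 0; i < n; ++i) {
      if (!consuming[i] && td[i] <= arrival_radius) {
        consuming[i] = 1;
        flagged[i] = 1;
        newly_arrived = true;
      }
    }
    if (newly_arrived && ISNAN(arrival_tick)) arrival_tick = tick;

    // movement (fixed 2n draws per tick keeps the stream aligned)
    std::vector<double> u(2 * n);
    for (int k = 0; k < 2 * n; ++k) u[k] = R::runif(0.0, 1.0);

    for (int i = 0; i < n; ++i) {
      newx[i] = x[i];
      newy[i] = y[i];
      newh[i] = h[i];
      if (consuming[i]) continue;

      double cue_x = NA_REAL, cue_y = NA_REAL;
      if (see[i]) {
        cue_x = tcx;
        cue_y = tcy;
      } else {
        double best = R_PosInf;
        for (int j = 0; j < n; ++j) {
          if (j != i && flagged[j] && dist[i * n + j] < d_v &&
              dist[i * n + j] < best) {
            best = dist[i * n + j];
            cue_x = x[j];
            cue_y = y[j];
          }
        }
      }

      double vx, vy;
      if (!ISNAN(cue_x)) {
        double dx = mi(cue_x - x[i], L);
        double dy = mi(cue_y - y[i], L);
        double nrm = std::sqrt(dx * dx + dy * dy);
        if (nrm == 0.0) {
          double ang = h[i] * deg;
          vx = std::cos(ang) * speed;
          vy = std::sin(ang) * speed;
        } else {
          vx = dx * (speed / nrm);
          vy = dy * (speed / nrm);
        }
      } else if (has_ctrl && i == cslot - 1) {
        // controlled slot: policy heading replaces self-direction; no
        // flocking/distancing pull on this agent
        IntegerVector vis;
        for (int j = 0; j < n; ++j)
          if (j != i && dist[i * n + j] < d_v) vis.push_back(j + 1);
        NumericVector vx_(vis.size()), vy_(vis.size()), vh_(vis.size());
        LogicalVector vf_(vis.size()), vc_(vis.size());
        for (int k = 0; k < vis.size(); ++k) {
          int j = vis[k] - 1;
          vx_[k] = x[j]; vy_[k] = y[j]; vh_[k] = h[j];
          vf_[k] = flagged[j] != 0; vc_[k] = consuming[j] != 0;
        }
        List obs = List::create(
          _["tick"] = tick,
          _["self"] = List::create(
            _["id"] = i + 1, _["x"] = x[i], _["y"] = y[i],
            _["heading"] = h[i], _["flagged"] = flagged[i] != 0,
            _["consuming"] = consuming[i] != 0),
          _["neighbors"] = List::create(
            _["id"] = vis, _["x"] = vx_, _["y"] = vy_, _["heading"] = vh_,
            _["flagged"] = vf_, _["consuming"] = vc_),
          _["target"] = see[i]
            ? RObject(NumericVector::create(tcx, tcy))
            : RObject(R_NilValue));
        Function ctrl(controller.get());
        PutRNGstate();
        double hdes = as<double>(ctrl(obs));
        GetRNGstate();
        double ang = hdes * deg;
        vx = std::cos(ang) * speed;
        vy = std::sin(ang) * speed;
      } else {
        double theta_n = u[2 * i] * 180.0 - u[2 * i + 1] * 180.0;
        double ang = (h[i] + theta_n) * deg;
        vx = std::cos(ang);
        vy = std::sin(ang);
        if (flock_on) {
          for (int j = 0; j < n; ++j) {
            if (j != i && dist[i * n + j] < d_v) {
              double a = h[j] * deg;
              vx += std::cos(a);
              vy += std::sin(a);
            }
          }
        }
        if (dist_on) {
          for (int j = 0; j < n; ++j) {
            if (j != i && dist[i * n + j] < cutoff) {
              double dx = mi(x[j] - x[i], L);
              double dy = mi(y[j] - y[i], L);
              double d = dist[i * n + j];
              if (d < 1e-6) d = 1e-6;
              double mag = r_pow(s / d, rep_exp) - r_pow(s / d, att_exp);
              vx -= mag * (dx / d);
              vy -= mag * (dy / d);
            }
          }
        }
        double nrm = std::sqrt(vx * vx + vy * vy);
        if (nrm == 0.0) {
          double ang2 = h[i] * deg;
          vx = std::cos(ang2) * speed;
          vy = std::sin(ang2) * speed;
        } else {
          vx = vx * (speed / nrm);
          vy = vy * (speed / nrm);
        }
      }

      newx[i] = wrap1(x[i] + vx, L);
      newy[i] = wrap1(y[i] + vy, L);
      double hh = std::atan2(vy, vx) * 180.0 / M_PI;
      newh[i] = hh - std::floor(hh / 360.0) * 360.0;
    }
    x = newx;
    y = newy;
    h = newh;

    // consumption
    int k = 0;
    for (int i = 0; i < n; ++i) k += consuming[i];
    if (k > 0 && units > 0) {
      double per = std::min(rate, units / k);
      units -= per * k;
      for (int i = 0; i < n; ++i)
        if (consuming[i]) consumed[i] += per;
    }

    tick += 1.0;
    int trial_of_tick = (int)trial_index;

    if (record) {
      int fm = 0, cm = 0;
      for (int i = 0; i < n; ++i) {
        log_x(t, i) = x[i];
        log_y(t, i) = y[i];
        log_h(t, i) = h[i];
        if (flagged[i]) fm |= (1 << i);
        if (consuming[i]) cm |= (1 << i);
        int m = 0;
        for (int j = 0; j < n; ++j) {
          if (i == j) continue;
          double dx = mi(x[j] - x[i], L);
          double dy = mi(y[j] - y[i], L);
          if (std::sqrt(dx * dx + dy * dy) < d_v) m |= (1 << j);
        }
        log_mask(t, i) = m;
      }
      log_trial[t] = trial_of_tick;
      log_tick[t] = (int)tick;
      log_flag[t] = fm;
      log_cons[t] = cm;
    }

    if (k > 0 && units <= 1e-9) {
      tr_index.push_back(trial_index);
      tr_start.push_back(trial_start);
      tr_detect.push_back(detect_tick);
      tr_arrival.push_back(arrival_tick);
      tr_end.push_back(tick);
      tr_fd.push_back(first_detector);
      target_ax = std::floor(R::runif(0.0, 1.0) * L);
      target_ay = std::floor(R::runif(0.0, 1.0) * L);
      units = target_units;
      for (int i = 0; i < n; ++i) { flagged[i] = 0; consuming[i] = 0; }
      trial_index += 1.0;
      trial_start = tick;
      detect_tick = NA_REAL;
      arrival_tick = NA_REAL;
      first_detector = NA_REAL;
    }

  }

  List new_world = List::create(
    _["tick"] = tick, _["x"] = x, _["y"] = y, _["heading"] = h,
    _["flagged"] = LogicalVector(flagged.begin(), flagged.end()),
    _["consuming"] = LogicalVector(consuming.begin(), consuming.end()),
    _["target_ax"] = target_ax, _["target_ay"] = target_ay,
    _["units"] = units, _["consumed"] = consumed,
    _["trial_index"] = trial_index, _["trial_start"] = trial_start,
    _["detect_tick"] = detect_tick, _["arrival_tick"] = arrival_tick,
    _["first_detector"] = first_detector,
    _["trials"] = List::create(
      _["index"] = tr_index, _["start"] = tr_start,
      _["detect"] = tr_detect, _["arrival"] = tr_arrival,
      _["end"] = tr_end, _["first_detector"] = tr_fd));

  List log = R_NilValue;
  if (record) {
    log = List::create(_["x"] = log_x, _["y"] = log_y,
                       _["heading"] = log_h, _["mask"] = log_mask,
                       _["trial"] = log_trial, _["tick"] = log_tick,
                       _["flagged"] = log_flag, _["consuming"] = log_cons);
  }
  return List::create(_["world"] = new_world, _["log"] = log);
}

// Single-pass grouped coverage: stamps each position's vision disk into a
// bit-mask grid (one bit per group, groups are 1-based and at most 30) and
// returns the per-group unique-pixel counts plus the union count. Exact:
// a pixel counts when its centre lies strictly within radius r (minimum
// image) of some position of the group.
// [[Rcpp::export]]
List coverage_by_group_cpp(NumericVector x, NumericVector y,
                           IntegerVector group, int n_groups,
                           int L, double r) {
  std::vector<int> grid(L * L, 0);
  int R = (int)std::ceil(r) + 1;
  double r2 = r * r;
  double Ld = (double)L;
  std::vector<double> ddy2(2 * R + 1);
  std::vector<int> iyv(2 * R + 1);
  for (int p = 0; p < x.size(); ++p) {
    int bit = 1 << (group[p] - 1);
    int ix0 = (int)std::floor(x[p]);
    int iy0 = (int)std::floor(y[p]);
    for (int dy = -R; dy <= R; ++dy) {
      double ddy = mi(iy0 + dy + 0.5 - y[p], Ld);
      ddy2[dy + R] = ddy * ddy;
      iyv[dy + R] = ((iy0 + dy) % L + L) % L;
    }
    for (int dx = -R; dx <= R; ++dx) {
      double ddx = mi(ix0 + dx + 0.5 - x[p], Ld);
      double dx2 = ddx * ddx;
      if (dx2 > r2) continue;
      int *row = grid.data() + ((ix0 + dx) % L + L) % L * L;
      double lim = r2 - dx2;
      for (int k = 0; k <= 2 * R; ++k) {
        if (ddy2[k] < lim) row[iyv[k]] |= bit;
      }
    }
  }
  IntegerVector counts(n_groups, 0);
  int uni = 0;
  for (int c = 0; c < L * L; ++c) {
    int v = grid[c];
    if (v) ++uni;
    while (v) {
      int b = v & (-v);
      int idx = 0;
      int t = b;
      while (t >>= 1) ++idx;
      ++counts[idx];
      v &= v - 1;
    }
  }
  return List::create(_["per_group"] = counts, _["union"] = uni);
}

// Exact vision-disk rasterization: marks every pixel whose centre
// (ix + 0.5, iy + 0.5) lies strictly within radius r (minimum image) of any
// of the supplied positions. Returns an L x L logical grid, pixel (ix, iy)
// at linear index ix * L + iy.
// [[Rcpp::export]]
LogicalVector coverage_grid_cpp(NumericVector x, NumericVector y,
                                int L, double r) {
  LogicalVector grid(L * L, false);
  int R = (int)std::ceil(r) + 1;
  double r2 = r * r;
  double Ld = (double)L;
  for (int p = 0; p < x.size(); ++p) {
    int ix0 = (int)std::floor(x[p]);
    int iy0 = (int)std::floor(y[p]);
    for (int dx = -R; dx <= R; ++dx) {
      double cx = ix0 + dx + 0.5;
      double ddx = mi(cx - x[p], Ld);
      if (ddx * ddx > r2) continue;
      int ix = ((ix0 + dx) % L + L) % L;
      for (int dy = -R; dy <= R; ++dy) {
        double cy = iy0 + dy + 0.5;
        double ddy = mi(cy - y[p], Ld);
        if (ddx * ddx + ddy * ddy < r2) {
          int iy = ((iy0 + dy) % L + L) % L;
          grid[ix * L + iy] = true;
        }
      }
    }
  }
  return grid;
}
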