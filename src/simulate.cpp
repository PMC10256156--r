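#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Fenwick tree over origin alive-flags, used to sample an unfired,
// unpassivated origin uniformly in O(log n).
struct Fenwick {
  int n;
  std::vector<int> t;
  Fenwick(int n_) : n(n_), t(n_ + 1, 0) {}
  void add(int i, int d) { for (++i; i <= n; i += i & -i) t[i] += d; }
  int total() const { int s = 0; for (int i = n; i > 0; i -= i & -i) s += t[i]; return s; }
  // index of the k-th alive origin (k is 1-based)
  int kth(int k) const {
    int pos = 0, bit = 1;
    while ((bit << 1) <= n) bit <<= 1;
    for (; bit; bit >>= 1)
      if (pos + bit <= n && t[pos + bit] < k) { pos += bit; k -= t[pos]; }
    return pos; // 0-based
  }
};

struct Interval {
  double lo, hi;
  bool lo_alive, hi_alive;
  int l_idx, r_idx; // next origin index (segment-local) left of lo / right of hi
};

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector origin_pos, IntegerVector origin_seg,
              NumericVector seg_len_kb, double v, double kon,
              int n_factors, double tau, double max_events) {
  const int n_or = origin_pos.size();
  const int n_seg = seg_len_kb.size();
  if (v <= 0 || kon <= 0 || n_factors < 1)
    stop("fork speed, reaction rate and factor count must be positive");

  // origins are expected sorted by (segment, position)
  std::vector<int> seg_start(n_seg + 1, 0);
  for (int i = 0; i < n_or; ++i) seg_start[origin_seg[i] + 1]++;
  for (int s = 0; s < n_seg; ++s) seg_start[s + 1] += seg_start[s];
  for (int s = 0; s < n_seg; ++s)
    if (seg_start[s + 1] == seg_start[s])
      stop("unreplicable segment: no potential origin drawn in segment %d", s + 1);

  // progressive factor activation: the k-th factor becomes available at
  // t_k = -tau * log(1 - k/N_F); the asymptotic last factor is capped at
  // the time the expected deficit drops below one half.
  std::vector<double> arrival(n_factors);
  for (int k = 1; k <= n_factors; ++k) {
    if (tau <= 0) arrival[k - 1] = 0.0;
    else if (k < n_factors)
      arrival[k - 1] = -tau * std::log(1.0 - (double)k / n_factors);
    else
      arrival[k - 1] = -tau * std::log(0.5 / n_factors);
  }

  Fenwick bit(n_or);
  std::vector<char> alive(n_or, 1);
  for (int i = 0; i < n_or; ++i) bit.add(i, 1);
  int n_po = n_or;

  std::vector<std::vector<Interval> > iv(n_seg);
  int unfinished = n_seg;
  std::vector<char> seg_done(n_seg, 0);

  double t = 0.0;
  int inits = 0, merges = 0, retired = 0;
  int arrived = 0;

  std::vector<double> fire_t, fire_pos;
  std::vector<int> fire_seg, fire_or;
  std::vector<double> tr_t;
  std::vector<int> tr_free;

  RNGScope scope;
  const double INF = R_PosInf;
  double n_events = 0;

  auto engaged = [&]() { return inits - merges - retired / 2; };
  auto passivate_interval = [&](int s, Interval &I) {
    int base = seg_start[s];
    int cnt = seg_start[s + 1] - base;
    while (I.r_idx < cnt && origin_pos[base + I.r_idx] <= I.hi) {
      int gi = base + I.r_idx;
      if (alive[gi]) { alive[gi] = 0; bit.add(gi, -1); --n_po; }
      ++I.r_idx;
    }
    while (I.l_idx >= 0 && origin_pos[base + I.l_idx] >= I.lo) {
      int gi = base + I.l_idx;
      if (alive[gi]) { alive[gi] = 0; bit.add(gi, -1); --n_po; }
      --I.l_idx;
    }
  };

  tr_t.push_back(0.0);
  tr_free.push_back(0);

  while (unfinished > 0) {
    if (++n_events > max_events) stop("event budget exceeded");

    int avail = arrived;
    while (avail < n_factors && arrival[avail] <= t) ++avail;
    arrived = avail;
    int free_f = arrived - engaged();
    if (free_f < 0) free_f = 0;

    // next deterministic factor arrival
    double dt_arr = (arrived < n_factors) ? arrival[arrived] - t : INF;
    if (dt_arr < 0) dt_arr = 0;

    // candidate initiation
    double a = kon * (double)n_po * (double)free_f;
    double dt_a = (a > 0) ? exp_rand() / a : INF;

    // earliest fork-fork or fork-boundary encounter
    double dt_e = INF;
    int e_seg = -1, e_j = -1;  // e_j: -1 left boundary, m right boundary, else merge j/j+1
    for (int s = 0; s < n_seg; ++s) {
      if (seg_done[s]) continue;
      std::vector<Interval> &V = iv[s];
      int m = (int)V.size();
      if (m == 0) continue;
      if (V[0].lo_alive) {
        double d = std::max(0.0, V[0].lo / v);
        if (d < dt_e) { dt_e = d; e_seg = s; e_j = -1; }
      }
      if (V[m - 1].hi_alive) {
        double d = std::max(0.0, (seg_len_kb[s] - V[m - 1].hi) / v);
        if (d < dt_e) { dt_e = d; e_seg = s; e_j = m; }
      }
      for (int j = 0; j + 1 < m; ++j) {
        double gap = V[j + 1].lo - V[j].hi;
        double sp = v * ((V[j].hi_alive ? 1 : 0) + (V[j + 1].lo_alive ? 1 : 0));
        if (sp > 0) {
          double d = std::max(0.0, gap / sp);
          if (d < dt_e) { dt_e = d; e_seg = s; e_j = j; }
        }
      }
    }

    // encounter wins ties so a factor is recycled before the redraw
    double dt;
    int ev;  // 0 encounter, 1 arrival, 2 initiation
    if (dt_e <= dt_a && dt_e <= dt_arr) { dt = dt_e; ev = 0; }
    else if (dt_arr <= dt_a)            { dt = dt_arr; ev = 1; }
    else                                { dt = dt_a; ev = 2; }
    if (!R_FINITE(dt)) stop("stalled simulation: no possible event");

    // advance all alive fork ends
    t += dt;
    for (int s = 0; s < n_seg; ++s) {
      if (seg_done[s]) continue;
      for (size_t j = 0; j < iv[s].size(); ++j) {
        Interval &I = iv[s][j];
        if (I.lo_alive) I.lo -= v * dt;
        if (I.hi_alive) I.hi += v * dt;
      }
    }

    // passivate origins swept during this advance before any firing choice
    for (int s = 0; s < n_seg; ++s) {
      if (seg_done[s]) continue;
      for (size_t j = 0; j < iv[s].size(); ++j) passivate_interval(s, iv[s][j]);
    }

    if (ev == 0) {
      std::vector<Interval> &V = iv[e_seg];
      int m = (int)V.size();
      if (e_j == -1) {
        V[0].lo = 0.0; V[0].lo_alive = false; ++retired;
      } else if (e_j == m) {
        V[m - 1].hi = seg_len_kb[e_seg]; V[m - 1].hi_alive = false; ++retired;
      } else {
        // passivate any origin still alive in the closing gap before the
        // merged interval adopts the outer passivation pointers
        int base = seg_start[e_seg];
        for (int k = V[e_j].r_idx; k <= V[e_j + 1].l_idx; ++k) {
          int gi = base + k;
          if (k >= 0 && gi < seg_start[e_seg + 1] && alive[gi]) {
            alive[gi] = 0; bit.add(gi, -1); --n_po;
          }
        }
        V[e_j].hi = V[e_j + 1].hi;
        V[e_j].hi_alive = V[e_j + 1].hi_alive;
        V[e_j].r_idx = V[e_j + 1].r_idx;
        V.erase(V.begin() + e_j + 1);
        ++merges;
      }
    } else if (ev == 2 && n_po > 0) {
      // fire one origin chosen uniformly among the alive ones
      int k = 1 + (int)std::floor(unif_rand() * n_po);
      if (k > n_po) k = n_po;
      int gi = bit.kth(k);
      int s = origin_seg[gi];
      double p = origin_pos[gi];
      alive[gi] = 0; bit.add(gi, -1); --n_po;
      ++inits;
      fire_t.push_back(t); fire_pos.push_back(p);
      fire_seg.push_back(s); fire_or.push_back(gi);
      Interval I;
      I.lo = p; I.hi = p; I.lo_alive = true; I.hi_alive = true;
      int base = seg_start[s];
      int loc = gi - base;
      I.l_idx = loc - 1; I.r_idx = loc + 1;
      // locate insertion point among sorted intervals
      std::vector<Interval> &V = iv[s];
      size_t j = 0;
      while (j < V.size() && V[j].lo < p) ++j;
      V.insert(V.begin() + j, I);
    }
    // ev == 1 (factor arrival): nothing to do beyond the time advance

    // passivate origins swept by the moving forks
    for (int s = 0; s < n_seg; ++s) {
      if (seg_done[s]) continue;
      for (size_t j = 0; j < iv[s].size(); ++j) passivate_interval(s, iv[s][j]);
      if (iv[s].size() == 1 && !iv[s][0].lo_alive && !iv[s][0].hi_alive) {
        seg_done[s] = 1; --unfinished;
      }
    }

    {
      int av2 = arrived;
      while (av2 < n_factors && arrival[av2] <= t) ++av2;
      tr_t.push_back(t);
      tr_free.push_back(std::max(0, av2 - engaged()));
    }
  }

  return List::create(
    _["fire_t"] = fire_t, _["fire_pos"] = fire_pos,
    _["fire_seg"] = IntegerVector(fire_seg.begin(), fire_seg.end()),
    _["fire_origin"] = IntegerVector(fire_or.begin(), fire_or.end()),
    _["ffree_t"] = tr_t, _["ffree_n"] = tr_free,
    _["inits"] = inits, _["merges"] = merges, _["retired"] = retired,
    _["t_end"] = t);
}

// Deterministic fork propagation: given fired origins (position kb, firing
// time min) in one segment, return per-bin replication time and fork sign
// (+1 rightward, -1 leftward, 0 initiation or termination in the bin).
// First-passage time at x is min over fired origins i of t_i + |x - x_i|/v.
// [[Rcpp::export(name = ".propagate_forks")]]
List propagate_forks(NumericVector pos, NumericVector tfire,
                     double seg_len_kb, int n_bins, double bin_kb, double v) {
  const int n = pos.size();
  if (n < 1) stop("no fired origins in segment");
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return pos[a] < pos[b]; });

  NumericVector rt(n_bins);
  IntegerVector sign(n_bins);
  std::vector<double> Lt(n_bins), Rt(n_bins);
  const double INF = R_PosInf;

  // best wave from the left:  min over x_i <= x of (t_i - x_i/v) + x/v
  {
    double cur = INF;
    int k = 0;
    for (int b = 0; b < n_bins; ++b) {
      double x = (b + 0.5) * bin_kb;
      while (k < n && pos[ord[k]] <= x) {
        double c = tfire[ord[k]] - pos[ord[k]] / v;
        if (c < cur) cur = c;
        ++k;
      }
      Lt[b] = (cur < INF) ? cur + x / v : INF;
    }
  }
  // best wave from the right
  {
    double cur = INF;
    int k = n - 1;
    for (int b = n_bins - 1; b >= 0; --b) {
      double x = (b + 0.5) * bin_kb;
      while (k >= 0 && pos[ord[k]] >= x) {
        double c = tfire[ord[k]] + pos[ord[k]] / v;
        if (c < cur) cur = c;
        --k;
      }
      Rt[b] = (cur < INF) ? cur - x / v : INF;
    }
  }

  std::vector<char> has_origin(n_bins, 0);
  for (int i = 0; i < n; ++i) {
    int b = (int)std::floor(pos[i] / bin_kb);
    if (b >= 0 && b < n_bins) has_origin[b] = 1;
  }

  for (int b = 0; b < n_bins; ++b) {
    rt[b] = std::min(Lt[b], Rt[b]);
    if (has_origin[b]) sign[b] = 0;
    else if (Lt[b] < Rt[b]) sign[b] = 1;
    else if (Rt[b] < Lt[b]) sign[b] = -1;
    else sign[b] = 0; // exact tie: both waves arrive together
  }
  // termination: bin containing the meeting point of converging waves
  for (int b = 0; b + 1 < n_bins; ++b) {
    if (!R_FINITE(Lt[b]) || !R_FINITE(Rt[b]) ||
        !R_FINITE(Lt[b + 1]) || !R_FINITE(Rt[b + 1])) continue;
    double d0 = Lt[b] - Rt[b], d1 = Lt[b + 1] - Rt[b + 1];
    if (d0 < 0 && d1 > 0) {
      double x0 = (b + 0.5) * bin_kb;
      double xm = x0 + bin_kb * (-d0) / (d1 - d0);
      int bm = (int)std::floor(xm / bin_kb);
      if (bm >= 0 && bm < n_bins && !has_origin[bm]) sign[bm] = 0;
    }
  }
  return List::create(_["rt"] = rt, _["sign"] = sign);
}
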