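// Event-driven discrete molecular dynamics over piecewise-constant pair
// potentials. Beads move ballistically between events; events are boundary
// crossings of step potentials (shell crossings, hard-core bounces, bond
// walls), Andersen thermostat kicks, frame recordings and queue resyncs.
//
// Scheduling: binary heap keyed by (time, kind, i, j) with lazy
// invalidation via per-bead collision counters. Pair events are predicted
// only up to a rolling horizon (the next resync); a resync event re-predicts
// every pair, so no event can be missed while the heap stays small.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding; self-contained so that seeded runs
// are bit-identical across platforms and standard libraries.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; } // [0, 1)
  double unif_pos() { double u; do { u = unif(); } while (u <= 0.0); return u; }
  double norm() { // Box-Muller (cosine branch only, deterministic stream)
    double u1 = unif_pos(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  double expo(double rate) { return -std::log(unif_pos()) / rate; }
};

enum EvKind { EV_PAIR = 0, EV_FRAME = 1, EV_KICK = 2, EV_RESYNC = 3, EV_END = 4 };

struct Ev {
  double t;
  int kind;
  int p;        // pair index (EV_PAIR)
  int i, j;     // beads (tie-breaking)
  int boundary; // threshold index (0-based)
  int dir;      // +1 outward, -1 inward
  uint64_t ci, cj; // collision counters at scheduling time
};

struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.kind != b.kind) return a.kind > b.kind;
    if (a.i != b.i) return a.i > b.i;
    return a.j > b.j;
  }
};

const double GRAZE_TOL = 1e-12; // |discriminant| below this: no crossing
const double T_EPS = 1e-12;    // smallest admissible event delay

struct Engine {
  int n;
  std::vector<double> px, py, pz, vx, vy, vz, mass, speed;
  std::vector<int> pi, pj, ppot, region;
  std::vector<std::vector<double>> thr, en;
  // flattened tables for the hot prediction path
  std::vector<double> thr_flat, thr2_flat;
  std::vector<int> pot_off, pot_K;
  std::vector<std::vector<int>> bead_pairs;
  std::vector<uint64_t> cc;
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> heap;
  double t_now, horizon;
  double pe;
  long long n_events;

  void flatten_tables() {
    pot_off.resize(thr.size());
    pot_K.resize(thr.size());
    for (size_t q = 0; q < thr.size(); ++q) {
      pot_off[q] = (int)thr_flat.size();
      pot_K[q] = (int)thr[q].size();
      for (double d : thr[q]) {
        thr_flat.push_back(d);
        thr2_flat.push_back(d * d);
      }
    }
  }

  void update_speed(int k) {
    speed[k] = std::sqrt(vx[k] * vx[k] + vy[k] * vy[k] + vz[k] * vz[k]);
  }

  double pair_r2(int p) const {
    double dx = px[pi[p]] - px[pj[p]];
    double dy = py[pi[p]] - py[pj[p]];
    double dz = pz[pi[p]] - pz[pj[p]];
    return dx * dx + dy * dy + dz * dz;
  }

  void init_shells() {
    int P = (int)pi.size();
    region.assign(P, 0);
    pe = 0.0;
    for (int p = 0; p < P; ++p) {
      const std::vector<double>& th = thr[ppot[p]];
      double r = std::sqrt(pair_r2(p));
      int s = 0;
      while (s < (int)th.size() && r >= th[s]) ++s;
      region[p] = s;
      double e = en[ppot[p]][s];
      if (!R_FINITE(e)) {
        stop("pair %d-%d starts in a forbidden region (distance %.6f A)",
             pi[p] + 1, pj[p] + 1, r);
      }
      pe += e;
    }
  }

  // Predict the next boundary crossing of pair p and push it if it falls
  // inside the scheduling horizon. A conservative distance bound (relative
  // speed times time-to-horizon) skips the quadratic for far pairs; this
  // affects speed only, never which events occur.
  void predict(int p) {
    int a = pi[p], b = pj[p];
    double rx = px[a] - px[b], ry = py[a] - py[b], rz = pz[a] - pz[b];
    double rr = rx * rx + ry * ry + rz * rz;
    int q = ppot[p];
    int s = region[p];
    int K = pot_K[q];
    const double* th = &thr_flat[pot_off[q]];
    const double* th2 = &thr2_flat[pot_off[q]];
    if (s == K) { // outermost shell: only the inner boundary is reachable
      double reach = (speed[a] + speed[b]) * (horizon - t_now);
      double lim = th[s - 1] + reach;
      if (rr > lim * lim) return; // cannot get there before the next resync
    }
    double wx = vx[a] - vx[b], wy = vy[a] - vy[b], wz = vz[a] - vz[b];
    double rv = rx * wx + ry * wy + rz * wz;
    double vv = wx * wx + wy * wy + wz * wz;
    if (vv <= 0.0) return;
    double best = R_PosInf;
    int bbound = -1, bdir = 0;
    if (s > 0 && rv < 0.0) { // approaching the inner boundary
      double disc = rv * rv - vv * (rr - th2[s - 1]);
      if (disc >= GRAZE_TOL) {
        double t = (-rv - std::sqrt(disc)) / vv;
        if (t > T_EPS && t < best) { best = t; bbound = s - 1; bdir = -1; }
      }
    }
    if (s < K) { // the outer boundary is always eventually reached unless receding
      double disc = rv * rv - vv * (rr - th2[s]);
      if (disc > 0.0) {
        double t = (-rv + std::sqrt(disc)) / vv;
        if (t > T_EPS && t < best) { best = t; bbound = s; bdir = +1; }
      }
    }
    if (bbound >= 0 && t_now + best <= horizon) {
      Ev e{t_now + best, EV_PAIR, p, a, b, bbound, bdir, cc[a], cc[b]};
      heap.push(e);
    }
  }

  void predict_bead(int bead, int skip_other = -1) {
    for (int q : bead_pairs[bead]) {
      if (skip_other >= 0 && (pi[q] == skip_other || pj[q] == skip_other))
        continue;
      predict(q);
    }
  }

  void predict_all() {
    for (int p = 0; p < (int)pi.size(); ++p) predict(p);
  }

  void advance(double t) {
    double dt = t - t_now;
    if (dt <= 0.0) { t_now = t; return; }
    for (int k = 0; k < n; ++k) {
      px[k] += vx[k] * dt; py[k] += vy[k] * dt; pz[k] += vz[k] * dt;
    }
    t_now = t;
  }

  double kinetic() const {
    double ke = 0.0;
    for (int k = 0; k < n; ++k) {
      ke += 0.5 * mass[k] * (vx[k] * vx[k] + vy[k] * vy[k] + vz[k] * vz[k]);
    }
    return ke;
  }
};

} // namespace

// [[Rcpp::export(name = ".dmd_run_cpp")]]
List dmd_run_cpp(NumericMatrix positions, NumericMatrix velocities,
                 NumericVector masses, IntegerVector pair_i,
                 IntegerVector pair_j, IntegerVector pair_pot, List pot_thr,
                 List pot_en, double temperature, double t_span,
                 double thermostat_rate, double frame_interval,
                 double resync_interval, double seed, bool record_events,
                 double start_time) {
  Engine E;
  E.n = positions.nrow();
  E.px.resize(E.n); E.py.resize(E.n); E.pz.resize(E.n);
  E.vx.resize(E.n); E.vy.resize(E.n); E.vz.resize(E.n);
  E.mass.resize(E.n);
  for (int k = 0; k < E.n; ++k) {
    E.px[k] = positions(k, 0); E.py[k] = positions(k, 1); E.pz[k] = positions(k, 2);
    E.vx[k] = velocities(k, 0); E.vy[k] = velocities(k, 1); E.vz[k] = velocities(k, 2);
    E.mass[k] = masses[k];
  }
  int P = pair_i.size();
  E.pi.resize(P); E.pj.resize(P); E.ppot.resize(P);
  E.bead_pairs.assign(E.n, {});
  for (int p = 0; p < P; ++p) {
    E.pi[p] = pair_i[p] - 1; E.pj[p] = pair_j[p] - 1; E.ppot[p] = pair_pot[p] - 1;
    E.bead_pairs[E.pi[p]].push_back(p);
    E.bead_pairs[E.pj[p]].push_back(p);
  }
  int nt = pot_thr.size();
  E.thr.resize(nt); E.en.resize(nt);
  for (int q = 0; q < nt; ++q) {
    E.thr[q] = as<std::vector<double>>(pot_thr[q]);
    E.en[q] = as<std::vector<double>>(pot_en[q]);
  }
  E.cc.assign(E.n, 0);
  E.t_now = start_time;
  E.n_events = 0;
  double t_end = start_time + t_span;
  E.flatten_tables();
  E.speed.resize(E.n);
  for (int k = 0; k < E.n; ++k) E.update_speed(k);
  E.init_shells();

  Xoshiro rng((uint64_t)seed);

  // frame bookkeeping
  int nf = (frame_interval > 0.0) ? (int)std::floor(t_span / frame_interval + 1e-9) : 0;
  NumericVector fpos(std::max(nf, 0) * (double)E.n * 3.0);
  NumericVector fpe(std::max(nf, 0)), fke(std::max(nf, 0)), ft(std::max(nf, 0));
  int frame_idx = 0;
  for (int f = 1; f <= nf; ++f) {
    Ev e{start_time + f * frame_interval, EV_FRAME, -1, -1, -1, -1, 0, 0, 0};
    E.heap.push(e);
  }
  { Ev e{t_end, EV_END, -1, -1, -1, -1, 0, 0, 0}; E.heap.push(e); }
  if (thermostat_rate > 0.0) {
    Ev e{E.t_now + rng.expo(thermostat_rate * E.n), EV_KICK, -1, -1, -1, -1, 0, 0, 0};
    E.heap.push(e);
  }
  double next_resync = start_time + resync_interval;
  { Ev e{next_resync, EV_RESYNC, -1, -1, -1, -1, 0, 0, 0}; E.heap.push(e); }
  E.horizon = next_resync;
  E.predict_all();

  std::vector<double> ev_t; std::vector<int> ev_i, ev_j, ev_b, ev_d, ev_x;

  while (!E.heap.empty()) {
    Ev ev = E.heap.top();
    E.heap.pop();
    if (ev.kind == EV_PAIR) {
      if (E.cc[ev.i] != ev.ci || E.cc[ev.j] != ev.cj) continue; // stale
      E.advance(ev.t);
      int p = ev.p;
      int a = E.pi[p], b = E.pj[p];
      double rx = E.px[a] - E.px[b], ry = E.py[a] - E.py[b], rz = E.pz[a] - E.pz[b];
      double rn = std::sqrt(rx * rx + ry * ry + rz * rz);
      double nx = rx / rn, ny = ry / rn, nz = rz / rn;
      double vr = (E.vx[a] - E.vx[b]) * nx + (E.vy[a] - E.vy[b]) * ny +
                  (E.vz[a] - E.vz[b]) * nz;
      double mu = E.mass[a] * E.mass[b] / (E.mass[a] + E.mass[b]);
      int s = E.region[p];
      int snew = (ev.dir > 0) ? s + 1 : s - 1;
      double eold = E.en[E.ppot[p]][s];
      double enew = E.en[E.ppot[p]][snew];
      double vrn;
      int crossed = 0;
      if (!R_FINITE(enew)) {
        vrn = -vr; // hard core / bond wall: always reflect
      } else {
        double dU = enew - eold;
        if (0.5 * mu * vr * vr > dU) {
          double sgn = (vr >= 0.0) ? 1.0 : -1.0;
          vrn = sgn * std::sqrt(vr * vr - 2.0 * dU / mu);
          E.region[p] = snew;
          E.pe += dU;
          crossed = 1;
        } else {
          vrn = -vr;
        }
      }
      double dvr = vrn - vr;
      E.vx[a] += (mu / E.mass[a]) * dvr * nx;
      E.vy[a] += (mu / E.mass[a]) * dvr * ny;
      E.vz[a] += (mu / E.mass[a]) * dvr * nz;
      E.vx[b] -= (mu / E.mass[b]) * dvr * nx;
      E.vy[b] -= (mu / E.mass[b]) * dvr * ny;
      E.vz[b] -= (mu / E.mass[b]) * dvr * nz;
      E.update_speed(a); E.update_speed(b);
      E.cc[a]++; E.cc[b]++;
      E.n_events++;
      if (record_events) {
        ev_t.push_back(ev.t); ev_i.push_back(a + 1); ev_j.push_back(b + 1);
        ev_b.push_back(ev.boundary + 1); ev_d.push_back(ev.dir);
        ev_x.push_back(crossed);
      }
      E.predict_bead(a);
      E.predict_bead(b, a);
    } else if (ev.kind == EV_FRAME) {
      E.advance(ev.t);
      for (int k = 0; k < E.n; ++k) {
        fpos[frame_idx + nf * (k + 0 * E.n)] = E.px[k];
        fpos[frame_idx + nf * (k + 1 * E.n)] = E.py[k];
        fpos[frame_idx + nf * (k + 2 * E.n)] = E.pz[k];
      }
      fpe[frame_idx] = E.pe;
      fke[frame_idx] = E.kinetic();
      ft[frame_idx] = ev.t;
      ++frame_idx;
    } else if (ev.kind == EV_KICK) {
      E.advance(ev.t);
      int bead = (int)(rng.unif() * E.n);
      if (bead >= E.n) bead = E.n - 1;
      double sd = std::sqrt(temperature / E.mass[bead]);
      E.vx[bead] = sd * rng.norm();
      E.vy[bead] = sd * rng.norm();
      E.vz[bead] = sd * rng.norm();
      E.update_speed(bead);
      E.cc[bead]++;
      E.predict_bead(bead);
      Ev nx{E.t_now + rng.expo(thermostat_rate * E.n), EV_KICK,
            -1, -1, -1, -1, 0, 0, 0};
      if (nx.t <= t_end) E.heap.push(nx);
    } else if (ev.kind == EV_RESYNC) {
      E.advance(ev.t);
      next_resync = ev.t + resync_interval;
      E.horizon = next_resync;
      if (ev.t < t_end) {
        Ev nx{std::min(next_resync, t_end + resync_interval), EV_RESYNC,
              -1, -1, -1, -1, 0, 0, 0};
        E.heap.push(nx);
        E.predict_all();
      }
    } else { // EV_END
      E.advance(t_end);
      break;
    }
  }

  NumericMatrix opos(E.n, 3), ovel(E.n, 3);
  for (int k = 0; k < E.n; ++k) {
    opos(k, 0) = E.px[k]; opos(k, 1) = E.py[k]; opos(k, 2) = E.pz[k];
    ovel(k, 0) = E.vx[k]; ovel(k, 1) = E.vy[k]; ovel(k, 2) = E.vz[k];
  }
  if (nf > 0) fpos.attr("dim") = IntegerVector::create(nf, E.n, 3);
  List out = List::create(
      _["positions"] = opos, _["velocities"] = ovel, _["time"] = t_end,
      _["frame_times"] = ft, _["frame_positions"] = fpos, _["frame_pe"] = fpe,
      _["frame_ke"] = fke, _["pe"] = E.pe, _["ke"] = E.kinetic(),
      _["n_events"] = (double)E.n_events);
  if (record_events) {
    out["events"] = DataFrame::create(
        _["time"] = ev_t, _["i"] = ev_i, _["j"] = ev_j,
        _["boundary"] = ev_b, _["dir"] = ev_d, _["crossed"] = ev_x);
  }
  return out;
}
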