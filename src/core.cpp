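// Fixed-point, multiplier-less simulator core.
//
// Everything on the hot path is integer arithmetic: states are saturating
// signed integers of configurable width (default 16 bit), all multiplicative
// coefficients are signed powers of two applied with the corrected shift
// operator, and every random draw comes from a counter-based generator keyed
// by (seed, purpose, id, tick, lane) so that runs are reproducible and
// independent of how neurons are partitioned across cores.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int PURPOSE_NOISE = 1;
static const int PURPOSE_BLANKOUT = 2;
static const int PURPOSE_ROUND = 3;

static const int64_t ACC_MAX = 2147483647LL;
static const int64_t ACC_MIN = -2147483647LL - 1;

// ---------------------------------------------------------------------------
// counter-based RNG (splitmix64 finaliser chain)

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t rng64(int seed, int purpose, int a, int b, int c) {
  uint64_t u = 0x9E3779B97F4A7C15ULL * (uint64_t)(uint32_t)(seed + 0x5851F42D);
  u = mix64(u ^ (uint64_t)(uint32_t)purpose);
  u = mix64(u ^ (uint64_t)(uint32_t)a);
  u = mix64(u ^ (uint64_t)(uint32_t)b);
  u = mix64(u ^ (uint64_t)(uint32_t)c);
  return u;
}

// ---------------------------------------------------------------------------
// fixed-point primitives

static inline int64_t sat_width(int64_t v, int64_t smin, int64_t smax) {
  if (v > smax) return smax;
  if (v < smin) return smin;
  return v;
}

// corrected signed shift: x * 2^e with truncation toward zero on downshifts
// and saturation on upshifts.  First argument is always the shift exponent.
static inline int64_t shift_mult64(int e, int64_t x, int64_t smin, int64_t smax) {
  if (x == 0 || e == 0) return sat_width(x, smin, smax);
  if (e > 0) {
    // e <= 15 and |x| <= 2^31 so the product fits in 64 bits
    return sat_width(x << e, smin, smax);
  }
  int64_t m = (x < 0) ? -x : x;
  m >>= (-e);
  return sat_width((x < 0) ? -m : m, smin, smax);
}

// leak increment: sign-applied shift with a guaranteed one-LSB decay toward
// zero whenever the coefficient opposes the sign of x but the shifted
// magnitude truncates to zero.
static inline int64_t leak_inc(int sgn, int e, int64_t x,
                               int64_t smin, int64_t smax) {
  if (sgn == 0 || x == 0) return 0;
  int64_t v = shift_mult64(e, x, smin, smax);
  int sx = (x > 0) ? 1 : -1;
  // a negative-signed coefficient always contributes against the sign of x
  // (v carries x's sign); if its magnitude truncates to zero on a nonzero
  // state, decay by one LSB instead so states reach rest exactly
  if (sgn < 0 && v == 0) return -sx;
  return (sgn > 0) ? v : -v;
}

static inline bool blankout_draw(int seed, int syn, int tick,
                                 int p_num, int p_den_exp) {
  if (p_den_exp <= 0) return p_num > 0; // den 2^0 = 1: p is 0 or 1
  uint64_t u = rng64(seed, PURPOSE_BLANKOUT, syn, tick, 0);
  uint64_t mask = ((uint64_t)1 << p_den_exp) - 1;
  return (u & mask) < (uint64_t)p_num;
}

static inline int64_t rround(int64_t delta, int r, int seed, int id, int tick) {
  if (r <= 0 || delta == 0) return delta;
  int64_t m = delta < 0 ? -delta : delta;
  int64_t base = m >> r;
  uint64_t p = (uint64_t)m & (((uint64_t)1 << r) - 1);
  if (p > 0) {
    uint64_t u = rng64(seed, PURPOSE_ROUND, id, tick, 0) & (((uint64_t)1 << r) - 1);
    if (u < p) base += 1;
  }
  return delta < 0 ? -base : base;
}

// zero-mean integer noise with variance ~= 2^v, as the sum of four uniform
// integer draws; a uniform on [-a, a] has variance (a^2+a)/3, so the four
// half-widths are chosen from two adjacent integers {a, a+1} (m of the
// larger) to bring the total variance as close to 2^v as the grid allows.
// The configuration is packed as a*8 + m.
static inline int noise_config(int var_exp) {
  double target = std::ldexp(3.0, var_exp); // 3 * 2^v = sum of (a_i^2 + a_i)
  double a0 = (-1.0 + std::sqrt(1.0 + target)) / 2.0; // 4 equal widths
  long a = (long)std::floor(a0);
  if (a < 0) a = 0;
  long best_a = a, best_m = 0;
  double best_err = 1e300;
  for (long aa = (a > 0 ? a - 1 : 0); aa <= a + 1; ++aa) {
    for (long m = 0; m <= 4; ++m) {
      double var3 = (4 - m) * (double)(aa * (aa + 1)) +
                    m * (double)((aa + 1) * (aa + 2));
      double err = std::fabs(var3 - target);
      if (err < best_err) { best_err = err; best_a = aa; best_m = m; }
    }
  }
  return (int)(best_a * 8 + best_m);
}

static inline int noise_draw(int seed, int id, int tick, int comp, int packed) {
  int a = packed / 8, m = packed % 8;
  if (a <= 0 && m <= 0) return 0;
  int s = 0;
  for (int call = 0; call < 2; ++call) {
    uint64_t u = rng64(seed, PURPOSE_NOISE, id, tick, comp * 2 + call);
    uint32_t lane[2] = { (uint32_t)(u & 0xFFFFFFFFULL), (uint32_t)(u >> 32) };
    for (int j = 0; j < 2; ++j) {
      int ai = (call * 2 + j < m) ? a + 1 : a;
      s += (int)(lane[j] % (uint64_t)(2 * ai + 1)) - ai;
    }
  }
  return s;
}

// ---------------------------------------------------------------------------
// R-visible primitive wrappers (vectorised over x / keys)

// [[Rcpp::export]]
IntegerVector fx_shift_cpp(IntegerVector e, IntegerVector x, int bits) {
  int64_t smax = ((int64_t)1 << (bits - 1)) - 1;
  int64_t smin = -((int64_t)1 << (bits - 1));
  R_xlen_t n = std::max(e.size(), x.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int ei = e[i % e.size()];
    int xi = x[i % x.size()];
    out[i] = (int)shift_mult64(ei, xi, smin, smax);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector fx_leak_cpp(IntegerVector sgn, IntegerVector e, IntegerVector x,
                          int bits) {
  int64_t smax = ((int64_t)1 << (bits - 1)) - 1;
  int64_t smin = -((int64_t)1 << (bits - 1));
  R_xlen_t n = std::max(std::max(sgn.size(), e.size()), x.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = (int)leak_inc(sgn[i % sgn.size()], e[i % e.size()],
                           x[i % x.size()], smin, smax);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector fx_round_cpp(IntegerVector delta, int r, int seed,
                           IntegerVector id, IntegerVector tick) {
  R_xlen_t n = std::max(std::max(delta.size(), id.size()), tick.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = (int)rround(delta[i % delta.size()], r, seed,
                         id[i % id.size()], tick[i % tick.size()]);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector fx_noise_cpp(int var_exp, int seed, IntegerVector id,
                           IntegerVector tick, IntegerVector comp) {
  int a = noise_config(var_exp);
  R_xlen_t n = std::max(std::max(id.size(), tick.size()), comp.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = noise_draw(seed, id[i % id.size()], tick[i % tick.size()],
                        comp[i % comp.size()], a);
  }
  return out;
}

// [[Rcpp::export]]
int fx_noise_halfwidth_cpp(int var_exp) { return noise_config(var_exp) / 8; }

// [[Rcpp::export]]
int fx_noise_config_cpp(int var_exp) { return noise_config(var_exp); }

// [[Rcpp::export]]
IntegerVector fx_blankout_cpp(int p_num, int p_den_exp, int seed,
                              IntegerVector id, IntegerVector tick) {
  R_xlen_t n = std::max(id.size(), tick.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = blankout_draw(seed, id[i % id.size()], tick[i % tick.size()],
                           p_num, p_den_exp) ? 1 : 0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// simulator

struct PlastC {
  int type;               // 0 = stdp, 1 = state
  int mod, gate, gmin, gmax;
  int wmin, wmax, rbits, on_dropped;
  int tca, tac;
  std::vector<int> ca_exp, ac_exp;
  int ca_sign, ac_sign, state_exp;
};

struct GroupC {
  int k;
  std::vector<int> a_sign, a_exp; // k x k, column-major (index i + k*j)
  std::vector<int> b, theta, reset_en, xr, x_min, noise_a, gain_exp;
  int refr;
  bool has_derived;
  int dv, dca, dth, dmod, v_lth, eta_p, eta_m, eta_h_exp, eta_h_sign, ca_target;
};

// [[Rcpp::export]]
List sim_run_cpp(List cfg, List state, IntegerMatrix events, int n_ticks,
                 int seed, IntegerVector watch, bool record_spikes) {
  const int n_neurons = as<int>(cfg["n_neurons"]);
  const int n_ext = as<int>(cfg["n_ext"]);
  const int n_pre = n_neurons + n_ext;
  const int k_max = as<int>(cfg["k_max"]);
  const int bits = as<int>(cfg["state_bits"]);
  const int max_delay = as<int>(cfg["max_delay"]);
  const int learn_period = as<int>(cfg["learn_period"]);
  const int learn_freeze = as<int>(cfg["learn_freeze"]);
  const int64_t smax = ((int64_t)1 << (bits - 1)) - 1;
  const int64_t smin = -((int64_t)1 << (bits - 1));

  IntegerVector group_of = cfg["group_of"];
  IntegerVector core_of = cfg["core_of"];
  const int n_cores = as<int>(cfg["n_cores"]);

  // groups
  List groupsL = cfg["groups"];
  std::vector<GroupC> groups(groupsL.size());
  for (int g = 0; g < (int)groupsL.size(); ++g) {
    List gl = groupsL[g];
    GroupC &G = groups[g];
    G.k = as<int>(gl["k"]);
    IntegerMatrix as_ = gl["a_sign"], ae_ = gl["a_exp"];
    G.a_sign.assign(as_.begin(), as_.end());
    G.a_exp.assign(ae_.begin(), ae_.end());
    G.b = as<std::vector<int> >(gl["b"]);
    G.theta = as<std::vector<int> >(gl["theta"]);
    G.reset_en = as<std::vector<int> >(gl["reset_en"]);
    G.xr = as<std::vector<int> >(gl["xr"]);
    G.x_min = as<std::vector<int> >(gl["x_min"]);
    G.noise_a = as<std::vector<int> >(gl["noise_a"]);
    G.gain_exp = as<std::vector<int> >(gl["gain_exp"]);
    G.refr = as<int>(gl["refr"]);
    G.has_derived = gl.containsElementNamed("derived") &&
                    !Rf_isNull(gl["derived"]);
    if (G.has_derived) {
      List d = gl["derived"];
      G.dv = as<int>(d["v"]); G.dca = as<int>(d["ca"]);
      G.dth = as<int>(d["th"]); G.dmod = as<int>(d["mod"]);
      G.v_lth = as<int>(d["v_lth"]);
      G.eta_p = as<int>(d["eta_p"]); G.eta_m = as<int>(d["eta_m"]);
      G.eta_h_exp = as<int>(d["eta_h_exp"]);
      G.eta_h_sign = as<int>(d["eta_h_sign"]);
      G.ca_target = as<int>(d["ca_target"]);
    }
  }

  // plasticity configs
  List plastL = cfg["plast"];
  std::vector<PlastC> plast(plastL.size());
  for (int p = 0; p < (int)plastL.size(); ++p) {
    List pl = plastL[p];
    PlastC &P = plast[p];
    P.type = as<int>(pl["type"]);
    P.mod = as<int>(pl["mod"]);
    P.gate = as<int>(pl["gate"]);
    P.gmin = as<int>(pl["gmin"]); P.gmax = as<int>(pl["gmax"]);
    P.wmin = as<int>(pl["wmin"]); P.wmax = as<int>(pl["wmax"]);
    P.rbits = as<int>(pl["rbits"]);
    P.on_dropped = as<int>(pl["on_dropped"]);
    P.tca = as<int>(pl["tca"]); P.tac = as<int>(pl["tac"]);
    P.ca_exp = as<std::vector<int> >(pl["ca_exp"]);
    P.ac_exp = as<std::vector<int> >(pl["ac_exp"]);
    P.ca_sign = as<int>(pl["ca_sign"]); P.ac_sign = as<int>(pl["ac_sign"]);
    P.state_exp = as<int>(pl["state_exp"]);
  }

  // synapse table (CSR by pre)
  List syn = cfg["syn"];
  IntegerVector s_pre = syn["pre"], s_post = syn["post"], s_tgt = syn["tgt"],
                s_widx = syn["widx"], s_pl = syn["pl"], s_delay = syn["delay"],
                s_bon = syn["bo_num"], s_bod = syn["bo_den"];
  IntegerVector row_ptr = cfg["row_ptr"];
  IntegerVector max_tca_of = cfg["max_tca_of"];
  IntegerVector has_pl = cfg["has_pl"];
  IntegerVector has_stdp = cfg["has_stdp"];

  // mutable state (cloned: sim_run is a pure function of (cfg, state, seed))
  IntegerMatrix x = clone(as<IntegerMatrix>(state["x"]));
  IntegerVector refr = clone(as<IntegerVector>(state["refr"]));
  IntegerVector last_spike = clone(as<IntegerVector>(state["last_spike"]));
  IntegerVector pending = clone(as<IntegerVector>(state["pending"]));
  IntegerMatrix acc = clone(as<IntegerMatrix>(state["acc"]));
  IntegerVector w = clone(as<IntegerVector>(state["w"]));
  double synops = as<double>(state["synops"]);
  int tick0 = as<int>(state["tick"]);

  // delivery ring buffer: due tick -> synapse rows
  const int ring_n = 2 * max_delay + 4;
  std::vector<std::vector<int> > ring(ring_n);
  IntegerMatrix future = state["future"];
  for (int i = 0; i < future.nrow(); ++i) {
    int due = future(i, 0);
    if (due >= tick0) ring[due % ring_n].push_back(future(i, 1));
    // deliveries already past due are dropped (cannot happen via sim_run)
  }

  // outputs
  std::vector<int> raster_t, raster_n;
  const int n_watch = watch.size();
  IntegerVector traces(n_watch > 0 ? (R_xlen_t)n_ticks * n_watch * k_max : 0);

  std::vector<int> spiked;   // neurons spiking this tick (ascending id)
  std::vector<int> xold(k_max);

  int ev_ptr = 0;
  const int n_ev = events.nrow();

  // per-core neuron lists (ascending id within core)
  std::vector<std::vector<int> > core_members(n_cores);
  for (int n = 0; n < n_neurons; ++n) core_members[core_of[n]].push_back(n);

  for (int step = 0; step < n_ticks; ++step) {
    int tick = tick0 + step;
    bool learn_open = (learn_period <= 0) ||
                      ((tick % learn_period) >= learn_freeze);

    // ---- external events arriving this tick: schedule deliveries
    int ev_lo = ev_ptr;
    while (ev_ptr < n_ev && events(ev_ptr, 0) == tick) {
      int ch = events(ev_ptr, 1);
      int evd = events(ev_ptr, 2);
      int pre = n_neurons + ch;
      for (int r = row_ptr[pre]; r < row_ptr[pre + 1]; ++r) {
        int due = tick + s_delay[r] + evd;
        ring[due % ring_n].push_back(r);
      }
      ++ev_ptr;
    }
    int ev_hi = ev_ptr;

    // ---- stage 1: integrate + spike detection, core by core
    spiked.clear();
    for (int c = 0; c < n_cores; ++c) {
      for (size_t idx = 0; idx < core_members[c].size(); ++idx) {
        int n = core_members[c][idx];
        const GroupC &G = groups[group_of[n]];
        bool clamped = refr[n] > 0;
        if (clamped) refr[n] -= 1;
        for (int i = 0; i < G.k; ++i) xold[i] = x(n, i);
        for (int i = 0; i < G.k; ++i) {
          if (i == 0 && clamped) {
            x(n, 0) = G.xr[0];
            acc(n, 0) = 0;
            continue;
          }
          int64_t s = (int64_t)xold[i] + G.b[i] + acc(n, i);
          for (int j = 0; j < G.k; ++j) {
            int sg = G.a_sign[i + G.k * j];
            if (sg != 0)
              s += leak_inc(sg, G.a_exp[i + G.k * j], xold[j], smin, smax);
          }
          if (G.noise_a[i] > 0)
            s += noise_draw(seed, n, tick, i, G.noise_a[i]);
          int64_t lo = G.x_min[i] > smin ? (int64_t)G.x_min[i] : smin;
          x(n, i) = (int)sat_width(s, lo, smax);
          acc(n, i) = 0;
        }
        if (!clamped && x(n, 0) >= G.theta[0]) {
          spiked.push_back(n);
          if (record_spikes) { raster_t.push_back(tick); raster_n.push_back(n); }
        }
      }
    }

    // ---- route internal spikes (available at tick + 1 + delay)
    for (size_t si = 0; si < spiked.size(); ++si) {
      int n = spiked[si];
      for (int r = row_ptr[n]; r < row_ptr[n + 1]; ++r) {
        int due = tick + 1 + s_delay[r];
        ring[due % ring_n].push_back(r);
      }
    }

    // ---- stage 2a: accumulate deliveries due now
    {
      std::vector<int> &due = ring[tick % ring_n];
      for (size_t di = 0; di < due.size(); ++di) {
        int r = due[di];
        if (s_bod[r] >= 0) { // blank-out configured
          if (!blankout_draw(seed, r, tick, s_bon[r], s_bod[r])) continue;
        }
        int post = s_post[r], tgt = s_tgt[r];
        const GroupC &G = groups[group_of[post]];
        int64_t inc = shift_mult64(G.gain_exp[tgt], w[s_widx[r]], smin, smax);
        int64_t v = sat_width((int64_t)acc(post, tgt) + inc, ACC_MIN, ACC_MAX);
        acc(post, tgt) = (int)v;
        synops += 1.0;
      }
      due.clear();
    }

    // ---- stage 2b: plasticity (forward-table, pre-sensitive)
    if (learn_open && plast.size() > 0) {
      // eager timer expiries: commit causal-only updates
      for (int p = 0; p < n_pre; ++p) {
        if (!pending[p] || max_tca_of[p] <= 0) continue;
        if (tick != last_spike[p] + max_tca_of[p] + 1) continue;
        int lp = last_spike[p];
        for (int r = row_ptr[p]; r < row_ptr[p + 1]; ++r) {
          if (s_pl[r] < 0) continue;
          const PlastC &P = plast[s_pl[r]];
          if (P.type != 0) continue;
          int post = s_post[r];
          int tp = last_spike[post];
          int dtc = tp - lp;
          if (tp < lp || dtc > P.tca) continue;
          if (P.gate >= 0 &&
              (x(post, P.gate) < P.gmin || x(post, P.gate) > P.gmax)) continue;
          if (!P.on_dropped && s_bod[r] >= 0) {
            int del = (p < n_neurons) ? lp + 1 + s_delay[r] : lp + s_delay[r];
            if (!blankout_draw(seed, r, del, s_bon[r], s_bod[r])) continue;
          }
          int64_t eps = P.ca_sign *
            shift_mult64(P.ca_exp[dtc], x(post, P.mod), smin, smax);
          if (eps != 0) {
            int64_t d = rround(eps, P.rbits, seed, r, tick);
            int64_t nw = sat_width((int64_t)w[s_widx[r]] + d, P.wmin, P.wmax);
            w[s_widx[r]] = (int)nw;
          }
        }
        pending[p] = 0;
      }

      // triggers: internal spikes (ascending id), then external events
      for (int phase = 0; phase < 2; ++phase) {
        int lim = (phase == 0) ? (int)spiked.size() : (ev_hi - ev_lo);
        for (int q = 0; q < lim; ++q) {
          int p = (phase == 0) ? spiked[q]
                               : n_neurons + events(ev_lo + q, 1);
          if (!has_pl[p]) continue;
          int lp = last_spike[p];
          bool pend = pending[p] != 0;
          for (int r = row_ptr[p]; r < row_ptr[p + 1]; ++r) {
            if (s_pl[r] < 0) continue;
            const PlastC &P = plast[s_pl[r]];
            int post = s_post[r];
            bool gate_ok = P.gate < 0 ||
              (x(post, P.gate) >= P.gmin && x(post, P.gate) <= P.gmax);
            int64_t delta = 0;
            if (P.type == 0) {
              if (pend) { // causal commit for the previous pre spike
                int tp = last_spike[post];
                int dtc = tp - lp;
                if (tp >= lp && dtc <= P.tca && gate_ok) {
                  bool ok = true;
                  if (!P.on_dropped && s_bod[r] >= 0) {
                    int del = (p < n_neurons) ? lp + 1 + s_delay[r]
                                              : lp + s_delay[r];
                    ok = blankout_draw(seed, r, del, s_bon[r], s_bod[r]);
                  }
                  if (ok)
                    delta += P.ca_sign *
                      shift_mult64(P.ca_exp[dtc], x(post, P.mod), smin, smax);
                }
              }
              int tp = last_spike[post];
              int dta = tick - tp;
              if (dta >= 1 && dta <= P.tac && gate_ok) {
                bool ok = true;
                if (!P.on_dropped && s_bod[r] >= 0) {
                  int del = (p < n_neurons) ? tick + 1 + s_delay[r]
                                            : tick + s_delay[r];
                  ok = blankout_draw(seed, r, del, s_bon[r], s_bod[r]);
                }
                if (ok)
                  delta += P.ac_sign *
                    shift_mult64(P.ac_exp[dta], x(post, P.mod), smin, smax);
              }
            } else { // state rule: update on every pre spike
              if (gate_ok) {
                bool ok = true;
                if (!P.on_dropped && s_bod[r] >= 0) {
                  int del = (p < n_neurons) ? tick + 1 + s_delay[r]
                                            : tick + s_delay[r];
                  ok = blankout_draw(seed, r, del, s_bon[r], s_bod[r]);
                }
                if (ok)
                  delta = shift_mult64(P.state_exp, x(post, P.mod), smin, smax);
              }
            }
            if (delta != 0) {
              int64_t d = rround(delta, P.rbits, seed, r, tick);
              int64_t nw = sat_width((int64_t)w[s_widx[r]] + d, P.wmin, P.wmax);
              w[s_widx[r]] = (int)nw;
            }
          }
          pending[p] = 0; // committed (or nothing to commit)
        }
      }
    }

    // ---- timer refresh for everything that fired this tick
    for (size_t si = 0; si < spiked.size(); ++si) {
      int n = spiked[si];
      last_spike[n] = tick;
      pending[n] = has_stdp[n];
    }
    for (int e = ev_lo; e < ev_hi; ++e) {
      int p = n_neurons + events(e, 1);
      last_spike[p] = tick;
      pending[p] = has_stdp[p];
    }

    // ---- stage 2c: derived (modulator) components, then conditional resets
    for (int n = 0; n < n_neurons; ++n) {
      const GroupC &G = groups[group_of[n]];
      if (G.has_derived) {
        int th = (x(n, G.dv) > G.v_lth) ? G.eta_p : G.eta_m;
        x(n, G.dth) = th;
        int64_t hom = 0;
        if (G.eta_h_sign != 0) {
          int64_t dca = (int64_t)G.ca_target - x(n, G.dca);
          hom = G.eta_h_sign * shift_mult64(G.eta_h_exp, dca, smin, smax);
        }
        x(n, G.dmod) = (int)sat_width((int64_t)th + hom, smin, smax);
      }
    }
    for (size_t si = 0; si < spiked.size(); ++si) {
      int n = spiked[si];
      refr[n] = groups[group_of[n]].refr;
    }
    for (int n = 0; n < n_neurons; ++n) {
      const GroupC &G = groups[group_of[n]];
      for (int i = 0; i < G.k; ++i) {
        if (G.reset_en[i] && x(n, i) >= G.theta[i]) x(n, i) = G.xr[i];
      }
    }

    // ---- record watched traces (end-of-tick state)
    if (n_watch > 0) {
      for (int wi = 0; wi < n_watch; ++wi) {
        int n = watch[wi];
        for (int i = 0; i < k_max; ++i)
          traces[(R_xlen_t)step + (R_xlen_t)n_ticks * (wi + (R_xlen_t)n_watch * i)] =
            x(n, i);
      }
    }
  }

  // dump remaining scheduled deliveries for chunked continuation
  std::vector<int> fut_due, fut_row;
  for (int s = 0; s < ring_n; ++s) {
    int due_mod = s;
    for (size_t i = 0; i < ring[s].size(); ++i) {
      // reconstruct absolute due tick: it is the unique tick in
      // [tick0+n_ticks, tick0+n_ticks+ring_n) congruent to s mod ring_n
      int base = tick0 + n_ticks;
      int due = base + ((due_mod - base) % ring_n + ring_n) % ring_n;
      fut_due.push_back(due);
      fut_row.push_back(ring[s][i]);
    }
  }
  IntegerMatrix future_out(fut_due.size(), 2);
  for (size_t i = 0; i < fut_due.size(); ++i) {
    future_out(i, 0) = fut_due[i];
    future_out(i, 1) = fut_row[i];
  }

  IntegerMatrix raster(raster_t.size(), 2);
  for (size_t i = 0; i < raster_t.size(); ++i) {
    raster(i, 0) = raster_t[i];
    raster(i, 1) = raster_n[i];
  }

  List new_state = List::create(
    _["x"] = x, _["refr"] = refr, _["last_spike"] = last_spike,
    _["pending"] = pending, _["acc"] = acc, _["w"] = w,
    _["synops"] = synops, _["tick"] = tick0 + n_ticks,
    _["future"] = future_out);

  List out = List::create(_["raster"] = raster, _["state"] = new_state,
                          _["n_ticks"] = n_ticks);
  if (n_watch > 0) {
    traces.attr("dim") = IntegerVector::create(n_ticks, n_watch, k_max);
    out["traces"] = traces;
  }
  return out;
}
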