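// Direct-method Gillespie engine shared by the three lattice models.
//
// State encoding: occ[i] per bin (0-based internally, 1-based in the API):
//   simple model    : 0 = empty, 1 = RNAP
//   backtrack model : 0 = empty, 1 = mobile RNAP (mRNAP), 2 = backtracked (bRNAP)
//   obstacle model  : 0 = empty, 1 = bound obstacle
// At most one condensin; cond = 1-based bin or 0 (absent), dir = +1/-1.
// All rates are in events/s with lengths in bins (speeds pre-converted by R).
//
// Randomness goes through R's RNG so set.seed() governs every draw.

#include <Rcpp.h>
using namespace Rcpp;

enum EvType {
  EV_INIT = 1,    // RNAP initiation at bin 1
  EV_STEP = 2,    // RNAP hop i -> i+1 (may push condensin, may walk off at N)
  EV_TERM = 3,    // RNAP unbinding in the termination zone
  EV_TO_B = 4,    // mRNAP -> bRNAP
  EV_TO_M = 5,    // bRNAP -> mRNAP
  EV_OBIND = 6,   // obstacle binding
  EV_OUNBIND = 7, // obstacle unbinding
  EV_CSTEP = 8,   // condensin hop into a free bin (or off the lattice)
  EV_CBYPASS = 9  // condensin bypass of a blocking RNAP/obstacle
};

struct Par {
  int model;          // 1 simple, 2 backtrack, 3 obstacle
  int n_bins;
  int term_start;     // 1-based first termination-zone bin
  double gamma_init, gamma_term;
  double v_rnap;      // bins/s
  double v_c;         // bins/s
  double v_jump;      // bins/s: simple-model bypass, or obstacle v_slow
  double k_on;
  double v_jump_m, v_jump_b; // bins/s, backtrack bypass rates
  double k_off;
  bool mobile_term;   // backtrack reduction switch: mobile RNAPs may unbind
  bool hop_over;      // bypass lands past the contiguous block, no exchange
  std::vector<double> kback; // per-bin mRNAP -> bRNAP rate
  std::vector<double> kbind; // per-bin obstacle binding rate
};

static Par parse_par(const List& p) {
  Par P;
  P.model = as<int>(p["model"]);
  P.n_bins = as<int>(p["n_bins"]);
  P.term_start = as<int>(p["term_start"]);
  P.gamma_init = as<double>(p["gamma_init"]);
  P.gamma_term = as<double>(p["gamma_term"]);
  P.v_rnap = as<double>(p["v_rnap"]);
  P.v_c = as<double>(p["v_c"]);
  P.v_jump = as<double>(p["v_jump"]);
  P.k_on = as<double>(p["k_on"]);
  P.v_jump_m = as<double>(p["v_jump_m"]);
  P.v_jump_b = as<double>(p["v_jump_b"]);
  P.k_off = as<double>(p["k_off"]);
  P.mobile_term = as<bool>(p["mobile_term"]);
  P.hop_over = as<bool>(p["hop_over"]);
  P.kback = as< std::vector<double> >(p["kback"]);
  P.kbind = as< std::vector<double> >(p["kbind"]);
  if ((int)P.kback.size() != P.n_bins || (int)P.kbind.size() != P.n_bins)
    stop("kback/kbind must have length n_bins");
  return P;
}

struct Chan {
  double rate;
  int type;
  int site; // 1-based bin of the acting particle
};

// Build the full channel list for a state.  Suppressed channels (exclusion,
// blocked pushes, zero rates) are simply not emitted.
static void enumerate_channels(const Par& P, const std::vector<int>& occ,
                               int cond, int dir, std::vector<Chan>& out) {
  out.clear();
  const int N = P.n_bins;

  if (P.model == 1 || P.model == 2) {
    // Initiation at the TSS (bin 1), excluded by a resident RNAP; a condensin
    // sitting on bin 1 is pushed to bin 2, so bin 2 must be RNAP-free.
    if (occ[0] == 0 && P.gamma_init > 0) {
      bool ok = true;
      if (cond == 1) ok = (N >= 2 && occ[1] == 0);
      if (ok) out.push_back({P.gamma_init, EV_INIT, 1});
    }
    for (int i = 0; i < N; ++i) {
      const int s = occ[i];
      if (s == 0) continue;
      const int bin = i + 1;
      const bool mobile = (P.model == 1) || (s == 1);
      if (mobile && P.v_rnap > 0) {
        bool ok;
        if (bin == N) {
          ok = true; // steps off the lattice and is removed
        } else if (occ[i + 1] != 0) {
          ok = false; // excluded
        } else if (cond == bin + 1) {
          // push: condensin must be displaceable one bin toward 3'
          ok = (bin + 2 > N) || (occ[i + 2] == 0);
        } else {
          ok = true;
        }
        if (ok) out.push_back({P.v_rnap, EV_STEP, bin});
      }
      if (P.model == 1) {
        if (bin >= P.term_start && P.gamma_term > 0)
          out.push_back({P.gamma_term, EV_TERM, bin});
      } else if (s == 1) { // mRNAP
        if (P.kback[i] > 0) out.push_back({P.kback[i], EV_TO_B, bin});
        if (P.mobile_term && bin >= P.term_start && P.gamma_term > 0)
          out.push_back({P.gamma_term, EV_TERM, bin});
      } else { // bRNAP
        if (P.k_on > 0) out.push_back({P.k_on, EV_TO_M, bin});
        if (bin >= P.term_start && P.gamma_term > 0)
          out.push_back({P.gamma_term, EV_TERM, bin});
      }
    }
  } else {
    // Obstacles bind/unbind independently of the condensin.
    for (int i = 0; i < N; ++i) {
      if (occ[i] == 0) {
        if (P.kbind[i] > 0) out.push_back({P.kbind[i], EV_OBIND, i + 1});
      } else {
        if (P.k_off > 0) out.push_back({P.k_off, EV_OUNBIND, i + 1});
      }
    }
  }

  if (cond > 0 && P.v_c > 0) {
    const int j = cond + dir;
    if (j < 1 || j > N) {
      out.push_back({P.v_c, EV_CSTEP, cond}); // exits the lattice
    } else if (occ[j - 1] == 0) {
      out.push_back({P.v_c, EV_CSTEP, cond});
    } else {
      double r;
      if (P.model == 2) r = (occ[j - 1] == 1) ? P.v_jump_m : P.v_jump_b;
      else r = P.v_jump; // simple bypass rate, or obstacle v_slow
      if (r > 0) out.push_back({r, EV_CBYPASS, cond});
    }
  }
}

// Apply a channel; returns true when the condensin leaves the lattice.
static bool apply_channel(const Par& P, std::vector<int>& occ, int& cond,
                          int dir, const Chan& c) {
  const int N = P.n_bins;
  switch (c.type) {
  case EV_INIT:
    if (cond == 1) cond = 2; // push validated at enumeration time
    occ[0] = 1;
    break;
  case EV_STEP: {
    const int i = c.site;
    occ[i - 1] = 0;
    if (i == N) break;      // walked off the 3' boundary
    if (cond == i + 1) {    // push condensin one bin toward 3'
      if (i + 2 > N) { occ[i] = 1; cond = 0; return true; }
      cond = i + 2;
    }
    occ[i] = 1;
    break;
  }
  case EV_TERM:
    occ[c.site - 1] = 0;
    break;
  case EV_TO_B:
    occ[c.site - 1] = 2;
    break;
  case EV_TO_M:
    occ[c.site - 1] = 1;
    break;
  case EV_OBIND:
    occ[c.site - 1] = 1;
    break;
  case EV_OUNBIND:
    occ[c.site - 1] = 0;
    break;
  case EV_CSTEP: {
    const int j = cond + dir;
    if (j < 1 || j > N) { cond = 0; return true; }
    cond = j;
    break;
  }
  case EV_CBYPASS: {
    const int j = cond + dir;
    if (P.model == 3) {
      cond = j;             // obstacle is neither pushed nor displaced
    } else if (P.hop_over) {
      int f = j;            // first free bin beyond the contiguous block
      while (f >= 1 && f <= N && occ[f - 1] != 0) f += dir;
      if (f < 1 || f > N) { cond = 0; return true; }
      cond = f;
    } else {
      occ[cond - 1] = occ[j - 1]; // position exchange with the blocking RNAP
      occ[j - 1] = 0;
      cond = j;
    }
    break;
  }
  default:
    stop("unknown event type");
  }
  return false;
}

// [[Rcpp::export]]
List cpp_enumerate(List par, IntegerVector occ, int cond_bin, int cond_dir) {
  Par P = parse_par(par);
  std::vector<int> o = as< std::vector<int> >(occ);
  if ((int)o.size() != P.n_bins) stop("occ must have length n_bins");
  std::vector<Chan> ch;
  enumerate_channels(P, o, cond_bin, cond_dir, ch);
  const int m = ch.size();
  IntegerVector type(m), site(m);
  NumericVector rate(m);
  for (int k = 0; k < m; ++k) {
    type[k] = ch[k].type; site[k] = ch[k].site; rate[k] = ch[k].rate;
  }
  return List::create(_["type"] = type, _["site"] = site, _["rate"] = rate);
}

// General event loop.
//   t_max       : stop once simulated time reaches t_max (R_PosInf to disable)
//   stop_on_exit: stop when the condensin leaves the lattice
//   max_events  : stop after this many events (<0 to disable)
//   n_blocks    : if > 0, accumulate per-bin occupancy time into n_blocks
//                 equal time blocks over [0, t_max] (requires finite t_max)
//   track_states: accumulate time per occupancy bitmask (n_bins <= 20,
//                 RNAP/obstacle presence only) for exact-CTMC comparisons
//   wait_entry  : if the condensin's entry bin is occupied, run the lattice
//                 dynamics without the condensin until the bin frees, then
//                 insert it (waiting time reported separately)
// [[Rcpp::export]]
List cpp_run(List par, IntegerVector occ0, int cond_bin, int cond_dir,
             double t_max, bool stop_on_exit, double max_events,
             int n_blocks, bool track_states, bool wait_entry) {
  Par P = parse_par(par);
  const int N = P.n_bins;
  std::vector<int> occ = as< std::vector<int> >(occ0);
  if ((int)occ.size() != N) stop("occ0 must have length n_bins");
  if (n_blocks > 0 && !R_FINITE(t_max))
    stop("occupancy blocks require a finite t_max");
  if (track_states && N > 20) stop("track_states requires n_bins <= 20");

  int cond = cond_bin, pending = 0;
  if (wait_entry && cond > 0 && occ[cond - 1] != 0) {
    pending = cond; cond = 0;
  }

  NumericVector residence(N);
  NumericMatrix occ_blocks(std::max(n_blocks, 0), n_blocks > 0 ? N : 0);
  NumericMatrix occb_blocks(std::max(n_blocks, 0), n_blocks > 0 ? N : 0);
  NumericVector state_time(track_states ? (1 << N) : 0);
  const double block_len = n_blocks > 0 ? t_max / n_blocks : 0.0;

  double t = 0.0, wait_time = 0.0, events_done = 0.0;
  bool exited = false, absorbing = false;
  std::vector<Chan> ch;
  ch.reserve(4 * N);

  // Accumulate the interval [t0, t0+dt) into all time-weighted collectors.
  auto accumulate = [&](double t0, double dt) {
    if (dt <= 0) return;
    if (cond > 0) residence[cond - 1] += dt;
    if (track_states) {
      int idx = 0;
      for (int i = 0; i < N; ++i) if (occ[i] != 0) idx |= (1 << i);
      state_time[idx] += dt;
    }
    if (n_blocks > 0) {
      double a = t0, b = std::min(t0 + dt, t_max);
      while (a < b) {
        int blk = (int)(a / block_len);
        if (blk >= n_blocks) blk = n_blocks - 1;
        double edge = std::min(b, (blk + 1) * block_len);
        double w = edge - a;
        for (int i = 0; i < N; ++i) {
          if (occ[i] != 0) occ_blocks(blk, i) += w;
          if (occ[i] == 2) occb_blocks(blk, i) += w;
        }
        a = edge;
      }
    }
  };

  while (true) {
    if (R_FINITE(t_max) && t >= t_max) break;
    if (max_events >= 0 && events_done >= max_events) break;

    enumerate_channels(P, occ, cond, cond_dir, ch);
    double total = 0.0;
    for (size_t k = 0; k < ch.size(); ++k) total += ch[k].rate;

    if (total <= 0.0) {
      if (R_FINITE(t_max)) { accumulate(t, t_max - t); t = t_max; break; }
      absorbing = true;
      break;
    }

    double dt = exp_rand() / total;
    double t_next = t + dt;
    if (R_FINITE(t_max) && t_next > t_max) {
      accumulate(t, t_max - t);
      t = t_max;
      break;
    }

    // choose the channel proportionally to its propensity
    double u = unif_rand() * total, acc = 0.0;
    size_t pick = ch.size() - 1;
    for (size_t k = 0; k < ch.size(); ++k) {
      acc += ch[k].rate;
      if (u <= acc) { pick = k; break; }
    }

    accumulate(t, dt);
    if (pending > 0) wait_time += dt;
    t = t_next;
    events_done += 1.0;

    bool left = apply_channel(P, occ, cond, cond_dir, ch[pick]);
    if (pending > 0 && occ[pending - 1] == 0) {
      cond = pending; pending = 0; // insert the condensin at its entry bin
    }
    if (left) {
      exited = true;
      if (stop_on_exit) break;
    }
    if (events_done >= 1e12) stop("event budget exceeded (runaway simulation)");
  }

  return List::create(
    _["occ"] = IntegerVector(occ.begin(), occ.end()),
    _["cond_bin"] = cond,
    _["time"] = t,
    _["n_events"] = events_done,
    _["residence"] = residence,
    _["wait_time"] = wait_time,
    _["occ_blocks"] = occ_blocks,
    _["occb_blocks"] = occb_blocks,
    _["state_time"] = state_time,
    _["exited"] = exited,
    _["absorbing"] = absorbing);
}
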