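#include <Rcpp.h>
using namespace Rcpp;

// Closed-loop stepper for the delayed feedback controller.
//
// Parameter vector layout (10 doubles):
//   0 omega_f, 1 omega_r, 2 tau_s, 3 thr, 4 omega_s, 5 omega_m,
//   6 tau_m, 7 omega_i, 8 delta_t (s, sensory delay), 9 swim_speed (mm/s)
//
// Reafference condition encoding (one row, 8 doubles):
//   0 kind (0 = gain, 1 = lag, 2 = gain_drop)
//   1 gain
//   2 lag in samples (-1 encodes infinite lag)
//   3 shunted flag (0/1)
//   4..7 gain-drop profile digits for the four 75 ms segments
//
// Per-step update order (exponential Euler, see the methods vignette):
//   u      = shown grating delta_t earlier (pre-trial buffer = first command)
//   s_in   = omega_f * max(u, 0) - omega_r * max(-u, 0)
//   V     <- clip[0,1]( V * es + s_in * (1 - es) ),   es = exp(-dt / tau_s)
//   D      = max(0, V + omega_s * b_prev - omega_i * M)
//   b      = D >= thr
//   M     <- clip[0,1]( M * em + omega_m * b * (1 - em) )
//   vel    = swim_speed * b
// and the reafference for the current sample is produced from vel according
// to the condition of the bout that generated it (lagged streams are
// scheduled into the future; shunted streams are cancelled at bout offset).

// [[Rcpp::export]]
List sim_trial_cpp(NumericVector params, NumericVector base_cmd, double dt,
                   NumericMatrix cond_seq, int seg_samp,
                   double V0 = 0.0, double M0 = 0.0) {
  const int n = base_cmd.size();
  const double wf = params[0], wr = params[1], tau_s = params[2],
               thr = params[3], ws = params[4], wm = params[5],
               tau_m = params[6], wi = params[7], delay_s = params[8],
               swim = params[9];
  const int d = (int)std::lround(delay_s / dt);
  const double es = std::exp(-dt / tau_s), em = std::exp(-dt / tau_m);

  NumericVector V(n), M(n), D(n), shown(n), vel(n);
  IntegerVector b(n), bout_id(n);
  std::vector<double> reaff(n, 0.0); // accumulated reafference stream
  std::vector<int> src(n, 0);        // source bout of lag-scheduled samples

  std::vector<int> onsets, offsets, conds;
  double Vc = V0, Mc = M0;
  int b_prev = 0, nbouts = 0, cur_cond = -1, cur_onset = -1;
  const int ncond = cond_seq.nrow();

  for (int t = 0; t < n; ++t) {
    double u = (t - d >= 0) ? shown[t - d] : base_cmd[0];
    double s_in = wf * std::max(u, 0.0) - wr * std::max(-u, 0.0);
    Vc = Vc * es + s_in * (1.0 - es);
    if (Vc < 0.0) Vc = 0.0; else if (Vc > 1.0) Vc = 1.0;
    double Dc = Vc + ws * b_prev - wi * Mc;
    if (Dc < 0.0) Dc = 0.0;
    int bc = (Dc >= thr) ? 1 : 0;
    Mc = Mc * em + wm * bc * (1.0 - em);
    if (Mc < 0.0) Mc = 0.0; else if (Mc > 1.0) Mc = 1.0;

    if (bc == 1 && b_prev == 0) { // bout onset: draw next condition
      ++nbouts;
      cur_cond = std::min(nbouts - 1, ncond - 1);
      cur_onset = t;
      onsets.push_back(t);
      conds.push_back(cur_cond);
    }
    if (bc == 0 && b_prev == 1) { // bout offset at t - 1
      offsets.push_back(t - 1);
      if ((int)cond_seq(cur_cond, 0) == 1 && cond_seq(cur_cond, 3) > 0.5) {
        // shunted lag: cancel this bout's reafference scheduled past offset
        int lag = (int)cond_seq(cur_cond, 2);
        if (lag > 0) {
          int hi = std::min(n - 1, (t - 1) + lag);
          for (int j = t; j <= hi; ++j)
            if (src[j] == nbouts) { reaff[j] = 0.0; src[j] = 0; }
        }
      }
    }

    if (bc == 1) { // emit reafference from the current sample
      double v = swim;
      int kind = (int)cond_seq(cur_cond, 0);
      if (kind == 0) {
        reaff[t] += cond_seq(cur_cond, 1) * v;
      } else if (kind == 1) {
        int lag = (int)cond_seq(cur_cond, 2);
        if (lag == 0) {
          reaff[t] += v;
        } else if (lag > 0 && t + lag < n) {
          reaff[t + lag] += v;
          src[t + lag] = nbouts;
        } // infinite lag (-1): never arrives
      } else {
        int k = (t - cur_onset) / seg_samp;
        double g = (k < 4) ? cond_seq(cur_cond, 4 + k) : 1.0;
        reaff[t] += g * v;
      }
    }

    shown[t] = base_cmd[t] - reaff[t];
    V[t] = Vc; M[t] = Mc; D[t] = Dc; b[t] = bc; vel[t] = swim * bc;
    bout_id[t] = bc ? nbouts : 0;
    b_prev = bc;
  }
  if (b_prev == 1) offsets.push_back(n - 1); // bout open at trial end

  return List::create(
    _["V"] = V, _["M"] = M, _["D"] = D, _["b"] = b, _["vel"] = vel,
    _["shown"] = shown, _["bout_id"] = bout_id,
    _["onset"] = wrap(onsets), _["offset"] = wrap(offsets),
    _["cond_index"] = wrap(conds));
}

// Model test trial battery: for each condition row, run one short trial
// (static lead-in then constant forward grating), with the first bout under
// normal reafference and the second under the probed condition. Returns
// bout-2 and interbout-2 durations in ms (NA when no third bout starts).

// [[Rcpp::export]]
NumericMatrix model_trial_table_cpp(NumericVector params, NumericMatrix conds,
                                    double dt, double static_s,
                                    double moving_s, double base_velocity,
                                    int seg_samp) {
  const int n_static = (int)std::lround(static_s / dt);
  const int n_mov = (int)std::lround(moving_s / dt);
  const int n = n_static + n_mov;
  NumericVector base(n);
  for (int t = n_static; t < n; ++t) base[t] = base_velocity;

  NumericMatrix out(conds.nrow(), 2);
  NumericMatrix normal(1, 8); // gain 1
  normal(0, 0) = 0.0; normal(0, 1) = 1.0;

  for (int i = 0; i < conds.nrow(); ++i) {
    NumericMatrix seq(3, 8);
    for (int j = 0; j < 8; ++j) {
      seq(0, j) = normal(0, j);
      seq(1, j) = conds(i, j);
      seq(2, j) = normal(0, j);
    }
    List res = sim_trial_cpp(params, base, dt, seq, seg_samp);
    IntegerVector on = res["onset"], off = res["offset"];
    if (on.size() >= 3) {
      out(i, 0) = (off[1] - on[1] + 1) * dt * 1000.0;
      out(i, 1) = (on[2] - off[1] - 1) * dt * 1000.0;
    } else {
      out(i, 0) = NA_REAL;
      out(i, 1) = NA_REAL;
    }
  }
  return out;
}
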