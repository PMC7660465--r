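#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Event kind codes, kept in sync with event_kinds() in R/simulator.R:
//   1 operant_response, 2 others_response, 3 reinforcer_operant,
//   4 reinforcer_others, 5 enter_choice, 6 enter_operant, 7 enter_others
//
// Agent codes: 1 dual, 2 no_choice, 3 no_cost, 4 two_state
// Schedule codes (operant behavior): 1 VI, 2 FR, 3 tandem VT VR
//
// The loop consumes R's RNG stream in a fixed order per step: (1) the
// choice draw when the Choice state resolves (skipped by the no_choice
// agent, whose choice is deterministic), (2) the response-emission draw
// while engaged, (3) the stay/leave draw after a response (skipped by the
// no_cost agent, whose stay probability is identically zero).

// [[Rcpp::export]]
List run_session_cpp(int agent_code, List par, int schedule_code,
                     NumericVector interval_table, int ratio_requirement,
                     int max_reinforcers, double extinction_duration,
                     bool record_qtrace) {
  const double alpha_rft = as<double>(par["alpha_rft"]);
  const double alpha_ext = as<double>(par["alpha_ext"]);
  const double beta      = as<double>(par["beta"]);
  const double w_pref    = as<double>(par["w_pref"]);
  const double w_cost    = as<double>(par["w_cost"]);
  const double r_op      = as<double>(par["r_operant"]);
  const double r_oth     = as<double>(par["r_others"]);
  const double p_resp    = as<double>(par["response_prob"]);
  const double dt        = as<double>(par["dt"]);

  std::vector<double> ev_t;  std::vector<int> ev_k;
  ev_t.reserve(1 << 20);     ev_k.reserve(1 << 20);
  std::vector<double> tr_t, tr_qp_op, tr_qp_oth, tr_qc_op, tr_qc_oth;

  // states: 0 Choice, 1 Operant, 2 Others; the two-state agent has no
  // Choice state and starts engaged in the operant behavior
  int state = (agent_code == 4) ? 1 : 0;
  double Qp[2] = {0.0, 0.0};   // [0] Operant, [1] Others
  double Qc[2] = {0.0, 0.0};
  // responses emitted to obtain a reinforcer: reset at every reinforcer
  // and, for the three-state agents, at each Choice-state resolution (the
  // two-state agent has no Choice state, so only reinforcers reset it)
  long   x = 1;
  int    rewards = 0;
  double t = 0.0;

  const int n_iv = interval_table.size();
  int cursor = 0; double elapsed = 0.0; bool armed = false;
  int vr_left = 0; int fr_count = 0;

  const bool has_ext = extinction_duration > 0.0;
  bool in_ext = false; double ext_start = NA_REAL;
  long ext_steps = 0;
  const long ext_steps_max =
      has_ext ? (long)std::lround(extinction_duration / dt) : 0L;

  RNGScope scope;

  for (;;) {
    if (!in_ext && rewards >= max_reinforcers) {
      if (has_ext) { in_ext = true; ext_start = t; }
      else break;
    }
    if (in_ext && ext_steps >= ext_steps_max) break;

    t += dt;
    if (in_ext) ext_steps++;

    // VI/VT interval clock runs in session time regardless of the agent's
    // state; an armed reinforcer is held until collected, and the next
    // interval starts at delivery
    if ((schedule_code == 1 || schedule_code == 3) && !armed && n_iv > 0) {
      elapsed += dt;
      if (elapsed >= interval_table[cursor] - 1e-9) {
        armed = true;
        vr_left = (schedule_code == 3) ? ratio_requirement : 0;
      }
    }

    if (state == 0) {           // Choice state resolves within the step
      int pick;
      if (agent_code == 2) {    // no-choice knockout: operant only
        pick = 1;
      } else {
        double p_op = 1.0 / (1.0 + std::exp(-beta * (Qp[0] - Qp[1])));
        pick = (unif_rand() <= p_op) ? 1 : 2;
      }
      state = pick;
      // the choice knockout's pass through Choice is inert bookkeeping:
      // its response counter runs on until the next reinforcer
      if (agent_code != 2) x = 1;
      ev_t.push_back(t); ev_k.push_back(pick == 1 ? 6 : 7);
    }

    if (state == 1 && unif_rand() <= p_resp) {        // operant response
      ev_t.push_back(t); ev_k.push_back(1);
      x += 1;

      // stay/leave decision precedes the reward check
      int next_state;
      if (agent_code == 3) {
        next_state = 0;         // no-cost knockout: always back to Choice
      } else if (agent_code == 4) {
        double s_op  = w_pref * Qp[0] + w_cost * Qc[0];
        double s_oth = w_pref * Qp[1] + w_cost * Qc[1];
        double p_stay = 1.0 / (1.0 + std::exp(-(s_op - s_oth)));
        next_state = (unif_rand() <= p_stay) ? 1 : 2;
      } else {
        double s = w_pref * Qp[0] + w_cost * Qc[0];
        double p_stay = (s <= 0.0) ? 0.0 : std::exp(-1.0 / s);
        next_state = (unif_rand() <= p_stay) ? 1 : 0;
      }

      bool delivered = false;
      if (!in_ext) {
        if (schedule_code == 2) {
          if (++fr_count >= ratio_requirement) { delivered = true; fr_count = 0; }
        } else if (armed) {
          if (schedule_code == 1 || vr_left == 0) delivered = true;
          else vr_left--;
        }
      }

      if (delivered) {
        ev_t.push_back(t); ev_k.push_back(3);
        Qp[0] += alpha_rft * (r_op - Qp[0]);
        Qc[0] += alpha_rft * (std::log((double)x) - Qc[0]);
        rewards++;
        x = 1;
        if (schedule_code != 2) {
          armed = false; elapsed = 0.0;
          cursor = (cursor + 1) % n_iv;
        }
        if (record_qtrace) {
          tr_t.push_back(t);
          tr_qp_op.push_back(Qp[0]);  tr_qp_oth.push_back(Qp[1]);
          tr_qc_op.push_back(Qc[0]);  tr_qc_oth.push_back(Qc[1]);
        }
      } else if (next_state != 1) {
        Qp[0] += alpha_ext * (0.0 - Qp[0]);   // left the bout unreinforced
      }

      if (next_state != 1) {
        state = next_state;
        ev_t.push_back(t); ev_k.push_back(next_state == 0 ? 5 : 7);
        if (agent_code == 4) x = 1;   // no Choice state to reset it
      }
    } else if (state == 2 && unif_rand() <= p_resp) { // other behavior
      ev_t.push_back(t); ev_k.push_back(2);
      x += 1;
      Qp[1] += alpha_rft * (r_oth - Qp[1]);
      Qc[1] += alpha_rft * (std::log((double)x) - Qc[1]);
      ev_t.push_back(t); ev_k.push_back(4);           // FR 1 delivery
      x = 1;

      int next_state;
      if (agent_code == 3) {
        next_state = 0;
      } else if (agent_code == 4) {
        double s_op  = w_pref * Qp[0] + w_cost * Qc[0];
        double s_oth = w_pref * Qp[1] + w_cost * Qc[1];
        double p_stay = 1.0 / (1.0 + std::exp(-(s_oth - s_op)));
        next_state = (unif_rand() <= p_stay) ? 2 : 1;
      } else {
        double s = w_pref * Qp[1] + w_cost * Qc[1];
        double p_stay = (s <= 0.0) ? 0.0 : std::exp(-1.0 / s);
        next_state = (unif_rand() <= p_stay) ? 2 : 0;
      }
      if (next_state != 2) {
        state = next_state;
        ev_t.push_back(t); ev_k.push_back(next_state == 0 ? 5 : 6);
        if (agent_code == 4) x = 1;
      }
    }
  }

  return List::create(
      _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["kind"] = IntegerVector(ev_k.begin(), ev_k.end()),
      _["n_reinforcers_operant"] = rewards,
      _["extinction_start"] = ext_start,
      _["q_final"] = NumericVector::create(
          _["q_pref_operant"] = Qp[0], _["q_pref_others"] = Qp[1],
          _["q_cost_operant"] = Qc[0], _["q_cost_others"] = Qc[1]),
      _["qtrace_time"] = NumericVector(tr_t.begin(), tr_t.end()),
      _["qtrace_qp_op"] = NumericVector(tr_qp_op.begin(), tr_qp_op.end()),
      _["qtrace_qp_oth"] = NumericVector(tr_qp_oth.begin(), tr_qp_oth.end()),
      _["qtrace_qc_op"] = NumericVector(tr_qc_op.begin(), tr_qc_op.end()),
      _["qtrace_qc_oth"] = NumericVector(tr_qc_oth.begin(), tr_qc_oth.end()));
}
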