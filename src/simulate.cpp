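#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Internal codes shared with the R level:
//   cues    1 = VISUAL_1, 2 = VISUAL_2, 3 = ODOUR_1, 4 = ODOUR_2, 5 = END_OF_TRIAL
//   actions 0 = NO_LICK, 1 = LICK
//   blocks  0 = VISUAL, 1 = ODOUR
// Randomness comes from a fast local generator seeded from R's RNG, so
// set.seed() at the R level fully determines a run.

static const int CUE_V1 = 1, CUE_V2 = 2, CUE_O1 = 3, CUE_O2 = 4, CUE_EOT = 5;
static const double BELIEF_FLOOR = 1e-9;

// Fast local RNG (xoshiro256++), seeded from R's RNG so that set.seed()
// fully determines a run while the hot loop avoids per-draw R API calls.
struct FastRng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit FastRng() {
    // two R uniforms give 2 x 53 bits of seed entropy
    uint64_t seed = (uint64_t)(unif_rand() * 9007199254740992.0);
    seed ^= (uint64_t)(unif_rand() * 9007199254740992.0) << 11;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double norm() {  // Box-Muller with cached spare
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double th = 6.283185307179586 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

struct AgentPars {
  int kind;                 // 0 basic, 1 belief
  double epsilon, epsilon_prime, alpha, zeta, beta;
  double factor_visual, factor_odour;
  bool eps_prime_odour_only;
  bool has_eps_prime;
};

static inline int pick_action(const double q0, const double q1, double eps,
                              FastRng &rng) {
  if (eps > 0.0 && rng.unif() < eps) return rng.unif() < 0.5 ? 1 : 0;
  if (q1 > q0) return 1;
  if (q0 > q1) return 0;
  return rng.unif() < 0.5 ? 1 : 0;  // tie broken uniformly
}

// [[Rcpp::export]]
List cpp_simulate(List env_cfg, List agent_cfg, int n_steps,
                  List init_state, bool record_steps, bool record_trace) {
  // ---- environment configuration ----
  const double p_irr = as<double>(env_cfg["pIrrelevantVisual"]);
  const double acc_thr = as<double>(env_cfg["blockAccuracyThreshold"]);
  const int acc_win = as<int>(env_cfg["blockAccuracyWindow"]);
  const int ign_win = as<int>(env_cfg["ignoreWindow"]);
  const int variant = as<int>(env_cfg["transitionVariantCode"]);  // 1 or 2
  const int max_block = as<int>(env_cfg["maxBlockTrials"]);
  const int forced_trials = as<int>(env_cfg["forcedTrials"]);     // 0 => until-3-correct rule
  int block = as<int>(env_cfg["firstBlockCode"]);                 // 0 visual, 1 odour

  // ---- agent configuration ----
  AgentPars ap;
  ap.kind = as<int>(agent_cfg["kindCode"]);
  ap.epsilon = as<double>(agent_cfg["epsilon"]);
  ap.has_eps_prime = !Rf_isNull(agent_cfg["epsilonPrime"]) &&
    !NumericVector::is_na(as<double>(agent_cfg["epsilonPrime"]));
  ap.epsilon_prime = ap.has_eps_prime ? as<double>(agent_cfg["epsilonPrime"]) : ap.epsilon;
  ap.alpha = as<double>(agent_cfg["alpha"]);
  ap.zeta = as<double>(agent_cfg["zeta"]);
  ap.beta = as<double>(agent_cfg["beta"]);
  ap.factor_visual = as<double>(agent_cfg["silencingFactorVisual"]);
  ap.factor_odour = as<double>(agent_cfg["silencingFactorOdour"]);
  ap.eps_prime_odour_only = as<bool>(agent_cfg["epsilonPrimeOdourOnly"]);

  // ---- agent state (two Q tables of 4 cues x 2 actions; basic agent uses table 0) ----
  double Q[2][4][2];
  NumericVector q_init = as<NumericVector>(init_state["q"]);  // length 16, table-major
  {
    int i = 0;
    for (int t = 0; t < 2; ++t)
      for (int s = 0; s < 4; ++s)
        for (int a = 0; a < 2; ++a) Q[t][s][a] = q_init[i++];
  }
  NumericVector b_init = as<NumericVector>(init_state["belief"]);
  double b0 = b_init[0], b1 = b_init[1];
  int prev_assumed = as<int>(init_state["prevAssumed"]);

  FastRng rng;  // seeded from R's RNG state

  // ---- environment bookkeeping ----
  int block_index = 0, trial_in_block = 0, global_trial = 0, steps_done = 0;
  bool in_transition = false;       // session starts outside a transition period
  int trans_count = 0;
  bool first_irr_shown = false;
  std::vector<int> rel_correct_hist; // per-trial relevant-stimulus correctness, current block
  std::vector<int> irr_hist;         // -1 no irrelevant cue, 0 licked, 1 ignored

  // ---- output buffers ----
  std::vector<int> o_trial, o_block_index, o_block_type, o_trial_in_block,
    o_irr_cue, o_final_cue, o_switched, o_forced_end;
  std::vector<int> o_has_irr, o_irr_forced, o_licked_irr, o_final_forced,
    o_licked_final, o_licked_eot, o_rel_correct, o_strict_correct, o_transition;
  std::vector<double> o_reward;

  std::vector<int> s_trial, s_block_index, s_block_type, s_step, s_cue, s_action,
    s_forced, s_transition;
  std::vector<double> s_reward, s_delta;

  std::vector<int> t_trial, t_assumed, t_detected, t_first_of_block;
  std::vector<double> t_b0, t_chi0, t_chi1, t_chin0, t_chin1, t_xi;

  // pending SARSA pair (updated once the next state-action is known)
  bool have_prev = false;
  int prev_s = 0, prev_a = 0, prev_tbl = 0;
  double prev_r = 0.0;
  size_t prev_step_row = 0;

  while (steps_done < n_steps) {
    // assumed block for this trial (constant within a trial: belief updates at trial end)
    int assumed = 0;
    if (ap.kind == 1) {
      if (b0 > b1) assumed = 0;
      else if (b1 > b0) assumed = 1;
      else assumed = prev_assumed;
    }

    bool forcing = in_transition;
    if (forced_trials > 0) forcing = trial_in_block < forced_trials;
    const bool trans_at_start = forcing;

    // ---- choose the trial's cue sequence ----
    int cues[3];
    bool forced_flag[3] = {false, false, false};
    int n_cue = 0;
    cues[n_cue++] = CUE_EOT;
    bool has_irr = false, irr_forced = false;
    int irr_cue = 0;
    if (block == 0) {  // visual block: EOT then the visual grating (reward step)
      int cv;
      if (forcing) { cv = CUE_V1; forced_flag[n_cue] = true; }
      else cv = rng.unif() < 0.5 ? CUE_V1 : CUE_V2;
      cues[n_cue++] = cv;
    } else {           // odour block: EOT, optional irrelevant grating, odour
      has_irr = rng.unif() < p_irr;
      if (has_irr) {
        int cv;
        if (forcing) {
          irr_forced = true;
          forced_flag[n_cue] = true;
          if (variant == 1 && !first_irr_shown) cv = CUE_V2; else cv = CUE_V1;
        } else cv = rng.unif() < 0.5 ? CUE_V1 : CUE_V2;
        irr_cue = cv;
        cues[n_cue++] = cv;
        first_irr_shown = true;
      }
      cues[n_cue++] = rng.unif() < 0.5 ? CUE_O1 : CUE_O2;
    }
    const int final_cue = cues[n_cue - 1];
    const bool final_forced = (block == 0) ? forced_flag[1] : false;

    // ---- play the trial ----
    int licked_eot = 0, licked_irr = 0, licked_final = 0;
    double reward_sum = 0.0;
    for (int k = 0; k < n_cue; ++k) {
      const int s = cues[k];
      const bool is_final = (k == n_cue - 1);
      double q0 = 0.0, q1 = 0.0;
      if (s != CUE_EOT) { q0 = Q[assumed][s - 1][0]; q1 = Q[assumed][s - 1][1]; }
      double eps = ap.epsilon;
      if (s == CUE_V2 && ap.has_eps_prime &&
          (!ap.eps_prime_odour_only || block == 1)) eps = ap.epsilon_prime;
      const int a = pick_action(q0, q1, eps, rng);

      double r;
      if (is_final) {
        if (a == 1) r = (s == CUE_V1 || s == CUE_O1) ? 1.0 : -1.0;
        else r = 0.0;
      } else {
        r = (a == 1) ? -1.0 : 0.0;  // needless lick
      }

      // SARSA update of the pending pair, bootstrap from the current state-action
      const double q_next = (s == CUE_EOT) ? 0.0 : Q[assumed][s - 1][a];
      if (have_prev) {
        const double q_cur = (prev_s == CUE_EOT) ? 0.0 : Q[prev_tbl][prev_s - 1][prev_a];
        const double delta = prev_r + q_next - q_cur;
        if (prev_s != CUE_EOT && ap.alpha > 0.0)
          Q[prev_tbl][prev_s - 1][prev_a] = q_cur + ap.alpha * delta;
        if (record_steps) s_delta[prev_step_row] = delta;
      }
      prev_s = s; prev_a = a; prev_r = r; prev_tbl = assumed; have_prev = true;

      if (s == CUE_EOT && a == 1) licked_eot = 1;
      if (!is_final && s != CUE_EOT && a == 1) licked_irr = 1;
      if (is_final) licked_final = a;
      reward_sum += r;

      if (record_steps) {
        s_trial.push_back(global_trial); s_block_index.push_back(block_index);
        s_block_type.push_back(block); s_step.push_back(k);
        s_cue.push_back(s); s_action.push_back(a);
        s_reward.push_back(r); s_forced.push_back(forced_flag[k] ? 1 : 0);
        s_transition.push_back(trans_at_start ? 1 : 0);
        s_delta.push_back(NA_REAL);
        prev_step_row = s_delta.size() - 1;
      }
      ++steps_done;
    }

    const int rel_correct = (final_cue == CUE_V1 || final_cue == CUE_O1)
      ? licked_final : 1 - licked_final;
    const int strict_correct = rel_correct && !licked_eot && !licked_irr;

    // ---- belief update at trial end (belief agent only) ----
    if (ap.kind == 1) {
      const int detected = (final_cue == CUE_V1 || final_cue == CUE_V2) ? 0 : 1;
      const double d0 = detected == 0 ? 1.0 : 0.0, d1 = 1.0 - d0;
      const double chi0 = d0 - b0, chi1 = d1 - b1;
      const double fac = detected == 0 ? ap.factor_visual : ap.factor_odour;
      const double xi = rng.norm();
      const double scale = fac * (1.0 + ap.beta * xi);
      const double chin0 = chi0 * scale, chin1 = chi1 * scale;
      double n0 = b0 + ap.zeta * chin0, n1 = b1 + ap.zeta * chin1;
      if (n0 < BELIEF_FLOOR) n0 = BELIEF_FLOOR;
      if (n1 < BELIEF_FLOOR) n1 = BELIEF_FLOOR;
      if (n0 <= BELIEF_FLOOR && n1 <= BELIEF_FLOOR) { n0 = 0.5; n1 = 0.5; }
      const double tot = n0 + n1;
      if (record_trace) {
        t_trial.push_back(global_trial); t_b0.push_back(b0);
        t_assumed.push_back(assumed); t_detected.push_back(detected);
        t_chi0.push_back(chi0); t_chi1.push_back(chi1);
        t_chin0.push_back(chin0); t_chin1.push_back(chin1); t_xi.push_back(xi);
        t_first_of_block.push_back(trial_in_block == 0 ? 1 : 0);
      }
      b0 = n0 / tot; b1 = n1 / tot;
      prev_assumed = assumed;
    }

    // ---- transition-period counter ----
    if (in_transition && forced_trials == 0) {
      if (block == 0) {  // odour->visual: three consecutive correct licks to forced V1
        trans_count = licked_final ? trans_count + 1 : 0;
      } else if (has_irr) {  // visual->odour: three consecutive correct ignores
        trans_count = licked_irr ? 0 : trans_count + 1;
      }
      if (trans_count >= 3) in_transition = false;
    }
    if (forced_trials > 0 && in_transition && trial_in_block + 1 >= forced_trials)
      in_transition = false;

    // ---- block-switch criteria ----
    rel_correct_hist.push_back(rel_correct);
    irr_hist.push_back(has_irr ? (licked_irr ? 0 : 1) : -1);
    bool switched = false, forced_end = false;
    const int n_in_block = (int) rel_correct_hist.size();
    if (n_in_block >= acc_win) {
      int nc = 0;
      for (int i = n_in_block - acc_win; i < n_in_block; ++i) nc += rel_correct_hist[i];
      bool ok = ((double) nc / acc_win) > acc_thr;
      if (ok && block == 1) {
        const int lo = std::max(0, n_in_block - ign_win);
        for (int i = lo; i < n_in_block; ++i)
          if (irr_hist[i] == 0) { ok = false; break; }
      }
      switched = ok;
    }
    if (!switched && n_in_block >= max_block) { switched = true; forced_end = true; }

    // ---- record the trial ----
    o_trial.push_back(global_trial); o_block_index.push_back(block_index);
    o_block_type.push_back(block); o_trial_in_block.push_back(trial_in_block);
    o_transition.push_back(trans_at_start ? 1 : 0);
    o_has_irr.push_back(has_irr ? 1 : 0); o_irr_cue.push_back(irr_cue);
    o_irr_forced.push_back(irr_forced ? 1 : 0); o_licked_irr.push_back(licked_irr);
    o_final_cue.push_back(final_cue); o_final_forced.push_back(final_forced ? 1 : 0);
    o_licked_final.push_back(licked_final); o_licked_eot.push_back(licked_eot);
    o_rel_correct.push_back(rel_correct); o_strict_correct.push_back(strict_correct);
    o_reward.push_back(reward_sum);
    o_switched.push_back(switched ? 1 : 0); o_forced_end.push_back(forced_end ? 1 : 0);

    ++global_trial;
    ++trial_in_block;
    if (switched) {
      block = 1 - block;
      ++block_index;
      trial_in_block = 0;
      in_transition = true;
      trans_count = 0;
      first_irr_shown = false;
      rel_correct_hist.clear();
      irr_hist.clear();
    }
  }

  // ---- pack results ----
  List trials = List::create(
    _["trial"] = wrap(o_trial), _["block_index"] = wrap(o_block_index),
    _["block_type"] = wrap(o_block_type), _["trial_in_block"] = wrap(o_trial_in_block),
    _["transition_phase"] = wrap(o_transition), _["has_irrelevant"] = wrap(o_has_irr),
    _["irrelevant_cue"] = wrap(o_irr_cue), _["irrelevant_forced"] = wrap(o_irr_forced),
    _["licked_irrelevant"] = wrap(o_licked_irr), _["final_cue"] = wrap(o_final_cue),
    _["final_forced"] = wrap(o_final_forced), _["licked_final"] = wrap(o_licked_final),
    _["licked_eot"] = wrap(o_licked_eot), _["relevant_correct"] = wrap(o_rel_correct),
    _["correct"] = wrap(o_strict_correct), _["reward"] = wrap(o_reward),
    _["switched_after"] = wrap(o_switched), _["block_cap_hit"] = wrap(o_forced_end));

  NumericVector q_out(16);
  {
    int i = 0;
    for (int t = 0; t < 2; ++t)
      for (int s = 0; s < 4; ++s)
        for (int a = 0; a < 2; ++a) q_out[i++] = Q[t][s][a];
  }
  List state = List::create(_["q"] = q_out,
                            _["belief"] = NumericVector::create(b0, b1),
                            _["prevAssumed"] = prev_assumed);

  List out = List::create(_["trials"] = trials, _["state"] = state,
                          _["n_steps"] = steps_done);
  if (record_steps)
    out["steps"] = List::create(
      _["trial"] = wrap(s_trial), _["block_index"] = wrap(s_block_index),
      _["block_type"] = wrap(s_block_type), _["step"] = wrap(s_step),
      _["cue"] = wrap(s_cue), _["action"] = wrap(s_action),
      _["reward"] = wrap(s_reward), _["forced"] = wrap(s_forced),
      _["transition_phase"] = wrap(s_transition), _["delta"] = wrap(s_delta));
  if (record_trace && ap.kind == 1)
    out["trace"] = List::create(
      _["trial"] = wrap(t_trial), _["p_visual"] = wrap(t_b0),
      _["assumed_block"] = wrap(t_assumed), _["detected_block"] = wrap(t_detected),
      _["chi_1"] = wrap(t_chi0), _["chi_2"] = wrap(t_chi1),
      _["chi_noisy_1"] = wrap(t_chin0), _["chi_noisy_2"] = wrap(t_chin1),
      _["xi"] = wrap(t_xi), _["first_of_block"] = wrap(t_first_of_block));
  return out;
}

// Causal moving average: mean over the trailing `width` samples (history-limited
// at the start of the trace).
// [[Rcpp::export]]
NumericVector cpp_causal_moving_average(NumericVector x, int width) {
  const int n = x.size();
  NumericVector out(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += x[i];
    if (i >= width) acc -= x[i - width];
    out[i] = acc / std::min(i + 1, width);
  }
  return out;
}

// Running minimum over the trailing `width` samples (inclusive of the current
// one, history-limited at the start); monotonic-deque, O(n).
// [[Rcpp::export]]
NumericVector cpp_running_min(NumericVector x, int width) {
  const int n = x.size();
  NumericVector out(n);
  std::deque<int> q;
  for (int i = 0; i < n; ++i) {
    while (!q.empty() && x[q.back()] >= x[i]) q.pop_back();
    q.push_back(i);
    if (q.front() <= i - width) q.pop_front();
    out[i] = x[q.front()];
  }
  return out;
}
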