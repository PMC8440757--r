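// Fast presentation loop: one image (plus rest period) of the two-layer
// winner-take-all network. Mirrors the R reference implementation in
// present_image()/step_network() exactly -- same RNG call order, same
// floating-point evaluation order -- so that the two engines produce
// bit-identical trajectories (asserted in the test suite).

#include <Rcpp.h>
using namespace Rcpp;

// one S-STDP update of neuron j's afferents; advances the device counters
// with the same uniform-draw order as the R implementation
static void post_spike_update_stochastic(
    IntegerMatrix W, IntegerMatrix M, IntegerMatrix Nd,
    const NumericMatrix& Pk, const NumericMatrix& Qk,
    IntegerMatrix n_pot, IntegerMatrix n_dep,
    int j, const LogicalVector& in_win,
    int k_pot, int k_dep, bool reset_on_complete) {
  const int n_in = W.nrow();
  // potentiation trials: in-window afferents
  for (int i = 0; i < n_in; ++i) {
    if (!in_win[i]) continue;
    n_pot(i, j) += 1;
    Nd(i, j) = 0;                       // opposite counters reset
  }
  for (int i = 0; i < n_in; ++i) {      // RNG draws in ascending row order
    if (!in_win[i]) continue;
    int m = M(i, j);
    if (m < k_pot) {
      double pr = Pk(i + (R_xlen_t)j * n_in, m);
      if (unif_rand() < pr) {
        M(i, j) = m + 1;
        if (m + 1 == k_pot) {
          W(i, j) = 1;
          if (reset_on_complete) M(i, j) = 0;
        }
      }
    }
  }
  // depression trials: all other afferents
  for (int i = 0; i < n_in; ++i) {
    if (in_win[i]) continue;
    n_dep(i, j) += 1;
    M(i, j) = 0;
  }
  for (int i = 0; i < n_in; ++i) {
    if (in_win[i]) continue;
    int m = Nd(i, j);
    if (m < k_dep) {
      double pr = Qk(i + (R_xlen_t)j * n_in, m);
      if (unif_rand() < pr) {
        Nd(i, j) = m + 1;
        if (m + 1 == k_dep) {
          W(i, j) = 0;
          if (reset_on_complete) Nd(i, j) = 0;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_present")]]
List cpp_present(List state, List params, Nullable<LogicalMatrix> spikes_in_,
                 int n_pres, int n_rest, bool plasticity) {
  // neuron state (cloned: the R caller keeps its copy untouched)
  NumericVector v_e = clone(as<NumericVector>(state["v_e"]));
  NumericVector v_i = clone(as<NumericVector>(state["v_i"]));
  NumericVector g_e_e = clone(as<NumericVector>(state["g_e_e"]));
  NumericVector g_i_e = clone(as<NumericVector>(state["g_i_e"]));
  NumericVector g_e_i = clone(as<NumericVector>(state["g_e_i"]));
  NumericVector theta = clone(as<NumericVector>(state["theta"]));
  NumericVector refrac_e = clone(as<NumericVector>(state["refrac_e"]));
  NumericVector refrac_i = clone(as<NumericVector>(state["refrac_i"]));
  NumericVector last_pre = clone(as<NumericVector>(state["last_pre"]));
  double t_now = as<double>(state["t_now"]);

  const bool det_rule = as<bool>(params["deterministic"]);
  const int k_pot = as<int>(params["k_pot"]);
  const int k_dep = as<int>(params["k_dep"]);
  const bool reset_on_complete = as<bool>(params["reset_on_complete"]);
  const double eta_plus = as<double>(params["eta_plus"]);
  const double eta_minus = as<double>(params["eta_minus"]);
  const double w_min = as<double>(params["w_min"]);
  const double w_max = as<double>(params["w_max"]);
  const double win_T = as<double>(params["window_T"]);

  const double dt = as<double>(params["dt"]);
  const double v_rest_e = as<double>(params["v_rest_e"]);
  const double v_reset_e = as<double>(params["v_reset_e"]);
  const double v_thresh_e = as<double>(params["v_thresh_e"]);
  const double refrac_e_ms = as<double>(params["refrac_e"]);
  const double v_rest_i = as<double>(params["v_rest_i"]);
  const double v_reset_i = as<double>(params["v_reset_i"]);
  const double v_thresh_i = as<double>(params["v_thresh_i"]);
  const double refrac_i_ms = as<double>(params["refrac_i"]);
  const double E_exc = as<double>(params["E_exc"]);
  const double E_inh = as<double>(params["E_inh"]);
  const double w_ei = as<double>(params["w_ei"]);
  const double w_ie = as<double>(params["w_ie"]);
  const double g_unit = as<double>(params["g_unit"]);
  const double theta_plus = as<double>(params["theta_plus"]);
  const double dec_ge = as<double>(params["dec_ge"]);
  const double dec_gi = as<double>(params["dec_gi"]);
  const double dec_th = as<double>(params["dec_th"]);
  const double ce_m = as<double>(params["ce_m"]);
  const double ci_m = as<double>(params["ci_m"]);

  const int n_exc = v_e.size();
  List ps = state["ps"];
  // weights: integer for stochastic rules, double for the deterministic one
  IntegerMatrix Wi, M, Nd;
  NumericMatrix Wd, Pk, Qk;
  IntegerMatrix n_pot = clone(as<IntegerMatrix>(ps["n_pot_trials"]));
  IntegerMatrix n_dep = clone(as<IntegerMatrix>(ps["n_dep_trials"]));
  if (det_rule) {
    Wd = clone(as<NumericMatrix>(ps["W"]));
  } else {
    Wi = clone(as<IntegerMatrix>(ps["W"]));
    M = clone(as<IntegerMatrix>(ps["M"]));
    Nd = clone(as<IntegerMatrix>(ps["Nd"]));
    Pk = as<NumericMatrix>(ps["Pk"]);
    Qk = as<NumericMatrix>(ps["Qk"]);
  }
  const int n_in = det_rule ? Wd.nrow() : Wi.nrow();

  LogicalMatrix spikes_in;
  bool has_input = spikes_in_.isNotNull();
  if (has_input) spikes_in = LogicalMatrix(spikes_in_);

  IntegerVector counts(n_exc);
  LogicalVector in_win(n_in);
  std::vector<int> fired, fired_i;
  RNGScope rngScope;

  for (int step = 0; step < n_pres + n_rest; ++step) {
    for (int j = 0; j < n_exc; ++j) g_e_e[j] *= dec_ge;
    if (step < n_pres && has_input) {
      bool any_spike = false;
      for (int i = 0; i < n_in; ++i)
        if (spikes_in(step, i)) { last_pre[i] = t_now; any_spike = true; }
      if (any_spike) {
        // column sums over the spiking rows, ascending row order
        for (int j = 0; j < n_exc; ++j) {
          double add = 0.0;
          if (det_rule)
            for (int i = 0; i < n_in; ++i) {
              if (spikes_in(step, i)) add += Wd(i, j);
            }
          else
            for (int i = 0; i < n_in; ++i) {
              if (spikes_in(step, i)) add += (double)Wi(i, j);
            }
          g_e_e[j] += g_unit * add;
        }
      }
    }
    for (int j = 0; j < n_exc; ++j) { g_i_e[j] *= dec_gi; g_e_i[j] *= dec_ge; }

    // excitatory membrane update
    fired.clear();
    for (int j = 0; j < n_exc; ++j) {
      if (refrac_e[j] <= 0) {
        double dv = (v_rest_e - v_e[j] + g_e_e[j] * (E_exc - v_e[j]) +
                     g_i_e[j] * (E_inh - v_e[j])) * ce_m;
        v_e[j] += dv;
        if (v_e[j] >= v_thresh_e + theta[j]) fired.push_back(j);
      }
    }
    for (size_t f = 0; f < fired.size(); ++f) {
      int j = fired[f];
      counts[j] += 1;
      v_e[j] = v_reset_e;
      refrac_e[j] = refrac_e_ms;
    }
    if (!fired.empty() && plasticity) {
      for (size_t f = 0; f < fired.size(); ++f)
        theta[fired[f]] += theta_plus;
      for (int i = 0; i < n_in; ++i) {
        double d = t_now - last_pre[i];
        in_win[i] = (d > 0.0) && (d < win_T);
      }
      for (size_t f = 0; f < fired.size(); ++f) {
        int j = fired[f];
        if (det_rule) {
          for (int i = 0; i < n_in; ++i) {
            n_pot(i, j) += in_win[i] ? 1 : 0;
            n_dep(i, j) += in_win[i] ? 0 : 1;
            if (in_win[i]) Wd(i, j) += eta_plus * (w_max - Wd(i, j));
            else Wd(i, j) -= eta_minus * (Wd(i, j) - w_min);
          }
        } else {
          post_spike_update_stochastic(Wi, M, Nd, Pk, Qk, n_pot, n_dep,
                                       j, in_win, k_pot, k_dep,
                                       reset_on_complete);
        }
      }
    }
    for (size_t f = 0; f < fired.size(); ++f) g_e_i[fired[f]] += w_ei;
    for (int j = 0; j < n_exc; ++j) theta[j] *= dec_th;

    // inhibitory membrane update
    fired_i.clear();
    for (int j = 0; j < n_exc; ++j) {
      if (refrac_i[j] <= 0) {
        double dvi = (v_rest_i - v_i[j] + g_e_i[j] * (E_exc - v_i[j])) * ci_m;
        v_i[j] += dvi;
        if (v_i[j] >= v_thresh_i) fired_i.push_back(j);
      }
    }
    if (!fired_i.empty()) {
      double inh = w_ie * (double)fired_i.size();
      for (size_t f = 0; f < fired_i.size(); ++f) {
        int j = fired_i[f];
        v_i[j] = v_reset_i;
        refrac_i[j] = refrac_i_ms;
      }
      for (int j = 0; j < n_exc; ++j) g_i_e[j] += inh;
      for (size_t f = 0; f < fired_i.size(); ++f)
        g_i_e[fired_i[f]] -= w_ie;
    }

    for (int j = 0; j < n_exc; ++j) {
      refrac_e[j] -= dt;
      refrac_i[j] -= dt;
    }
    t_now += dt;
  }

  for (int j = 0; j < n_exc; ++j)
    if (!R_finite(v_e[j]))
      stop("non-finite membrane potential: simulation diverged");

  return List::create(
    _["v_e"] = v_e, _["v_i"] = v_i,
    _["g_e_e"] = g_e_e, _["g_i_e"] = g_i_e, _["g_e_i"] = g_e_i,
    _["theta"] = theta, _["refrac_e"] = refrac_e, _["refrac_i"] = refrac_i,
    _["last_pre"] = last_pre, _["t_now"] = t_now,
    _["W"] = det_rule ? (SEXP)Wd : (SEXP)Wi,
    _["M"] = M, _["Nd"] = Nd,
    _["n_pot_trials"] = n_pot, _["n_dep_trials"] = n_dep,
    _["counts"] = counts);
}
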