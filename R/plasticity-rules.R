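#' Synaptic update rule configuration
#'
#' Bundles the parameters of one S-STDP update rule. Three families exist:
#' \describe{
#'   \item{deterministic}{continuous weights with the linear
#'     weight-dependent update \code{dw = eta_plus * (w_max - w)} for
#'     potentiation and \code{dw = -eta_minus * (w - w_min)} for
#'     depression.}
#'   \item{stochastic, k = 1 (conventional)}{binary weights flipped with
#'     constant probabilities p (0 to 1) and q (1 to 0) per fire.}
#'   \item{stochastic, k >= 2 (sigmoidal)}{binary weights backed by
#'     serial-memristor devices; the cumulative flip probability grows
#'     sigmoidally with repeated same-direction trials.}
#' }
#' Mixed modes use different device lengths for the two directions (e.g.
#' sigmoidal potentiation with conventional depression).
#'
#' @param rule \code{"deterministic"} or \code{"stochastic"}.
#' @param k potentiation device length (stochastic; 1 = conventional).
#' @param p,q per-pulse SET probabilities of the potentiation and
#'   depression devices (stochastic).
#' @param k_dep depression device length (defaults to \code{k}).
#' @param eta_plus,eta_minus learning rates (deterministic).
#' @param w_min,w_max continuous weight bounds (deterministic).
#' @param window_T S-STDP coincidence window in ms: an afferent is
#'   potentiated iff its last presynaptic spike arrived within
#'   \code{window_T} before the postsynaptic fire.
#' @param reset_on_complete passed to the device model (see
#'   \code{\link{binary_synapse}}).
#' @return An object of class \code{rule_config}.
#' @seealso \code{\link{rule_preset}} for the named parameter sets.
#' @export
rule_config <- function(rule = c("stochastic", "deterministic"),
                        k = 1, p = 0.04, q = 0.008, k_dep = k,
                        eta_plus = 0.04, eta_minus = 0.008,
                        w_min = 0, w_max = 1,
                        window_T = 20, reset_on_complete = FALSE) {
  rule <- match.arg(rule)
  if (rule == "stochastic") {
    if (k < 1 || k != round(k) || k_dep < 1 || k_dep != round(k_dep))
      stop("device lengths must be integers >= 1")
    if (p <= 0 || p >= 1 || q <= 0 || q >= 1)
      stop("'p' and 'q' must be in (0, 1)")
  } else {
    if (eta_plus <= 0 || eta_plus > 1 || eta_minus <= 0 || eta_minus > 1)
      stop("learning rates must be in (0, 1]")
    if (w_min >= w_max) stop("need w_min < w_max")
  }
  if (window_T <= 0) stop("'window_T' must be positive (ms)")
  structure(list(rule = rule, k = as.integer(k), p = p, q = q,
                 k_dep = as.integer(k_dep),
                 eta_plus = eta_plus, eta_minus = eta_minus,
                 w_min = w_min, w_max = w_max,
                 window_T = window_T,
                 reset_on_complete = isTRUE(reset_on_complete)),
            class = "rule_config")
}

#' Named update-rule presets
#'
#' The parameter sets used throughout the benchmark experiments:
#' \tabular{lll}{
#'   \code{"deterministic"} \tab continuous \tab eta+ = 0.04, eta- = 0.008 \cr
#'   \code{"conventional"} \tab k = 1 \tab p = 0.04, q = 0.008 \cr
#'   \code{"sigmoidal_k2"} \tab k = 2 \tab p = 0.13, q = 0.03 \cr
#'   \code{"sigmoidal_k3"} \tab k = 3 \tab p = 0.13, q = 0.03 \cr
#'   \code{"sigmoidal_k4"} \tab k = 4 \tab p = 0.2, q = 0.08 \cr
#'   \code{"sigmoidal_k5"} \tab k = 5 \tab p = 0.29, q = 0.12 \cr
#'   \code{"sigmoidal_pot_k3"} \tab mixed \tab sigmoidal potentiation
#'     (k = 3, p = 0.13), conventional depression (q = 0.008) \cr
#'   \code{"sigmoidal_dep_k3"} \tab mixed \tab conventional potentiation
#'     (p = 0.04), sigmoidal depression (k = 3, q = 0.03)
#' }
#'
#' @param name preset name (see above).
#' @param ... overrides forwarded to \code{\link{rule_config}} (e.g.
#'   \code{window_T}).
#' @return A \code{\link{rule_config}}.
#' @export
rule_preset <- function(name, ...) {
  presets <- list(
    deterministic    = list(rule = "deterministic", eta_plus = 0.04, eta_minus = 0.008),
    conventional     = list(rule = "stochastic", k = 1, p = 0.04, q = 0.008),
    sigmoidal_k2     = list(rule = "stochastic", k = 2, p = 0.13, q = 0.03),
    sigmoidal_k3     = list(rule = "stochastic", k = 3, p = 0.13, q = 0.03),
    sigmoidal_k4     = list(rule = "stochastic", k = 4, p = 0.2,  q = 0.08),
    sigmoidal_k5     = list(rule = "stochastic", k = 5, p = 0.29, q = 0.12),
    sigmoidal_pot_k3 = list(rule = "stochastic", k = 3, p = 0.13, k_dep = 1, q = 0.008),
    sigmoidal_dep_k3 = list(rule = "stochastic", k = 1, p = 0.04, k_dep = 3, q = 0.03)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; valid: ",
         paste(names(presets), collapse = ", "))
  do.call(rule_config, utils::modifyList(presets[[name]], list(...)))
}

#' Deterministic linear weight-dependent S-STDP update
#'
#' Potentiation moves a continuous weight towards its upper bound by a
#' fraction \code{eta_plus} of the remaining headroom; depression moves it
#' towards the lower bound by a fraction \code{eta_minus}. The bounds are
#' fixed points, so repeated updates approach them exponentially.
#'
#' @param w continuous weight(s) in [w_min, w_max]; vectorised.
#' @param potentiate logical; TRUE for potentiation, FALSE for depression.
#' @param cfg a deterministic \code{\link{rule_config}}.
#' @return Updated weight(s), guaranteed inside the bounds.
#' @export
apply_deterministic <- function(w, potentiate, cfg) {
  stopifnot(inherits(cfg, "rule_config"), cfg$rule == "deterministic")
  if (any(w < cfg$w_min - 1e-12) || any(w > cfg$w_max + 1e-12))
    stop("weight outside [w_min, w_max]")
  if (isTRUE(potentiate)) w + cfg$eta_plus * (cfg$w_max - w)
  else w - cfg$eta_minus * (w - cfg$w_min)
}

#' Stochastic S-STDP update of a single binary synapse
#'
#' Routes one update trial to the synapse's potentiation or depression
#' device. For k = 1 devices this flips the weight with the constant
#' per-fire probabilities p and q (conventional stochastic S-STDP); for
#' k >= 2 the flip probability depends on the accumulated same-direction
#' trial count (sigmoidal).
#'
#' @param syn a \code{\link{binary_synapse}}.
#' @param potentiate logical direction flag.
#' @return The updated synapse.
#' @export
apply_stochastic <- function(syn, potentiate) {
  if (isTRUE(potentiate)) potentiation_trial(syn) else depression_trial(syn)
}

# ---------------------------------------------------------------------------
# Vectorised afferent state: all plastic synapses of a layer in matrix form.
# Rows index presynaptic inputs, columns postsynaptic excitatory neurons.
# ---------------------------------------------------------------------------

#' Create the plastic afferent-synapse state of a layer
#'
#' Matrix-form container for all input-to-excitatory synapses under one
#' update rule. Stochastic rules store the binary weight matrix plus the
#' m- and n-counter matrices and the (possibly variability-scattered)
#' per-element SET probabilities; the deterministic rule stores a
#' continuous weight matrix.
#'
#' @param n_in number of presynaptic inputs.
#' @param n_out number of postsynaptic excitatory neurons.
#' @param cfg a \code{\link{rule_config}}.
#' @param var a \code{\link{variability_spec}} (stochastic rules only).
#' @param init_density for binary weights, the Bernoulli probability of
#'   initialising a weight at 1; for continuous weights the mean of the
#'   uniform initial distribution.
#' @return An object of class \code{plastic_synapses}.
#' @export
plastic_synapses <- function(n_in, n_out, cfg, var = variability_spec(),
                             init_density = 0.5) {
  stopifnot(inherits(cfg, "rule_config"))
  ps <- list(cfg = cfg, n_in = n_in, n_out = n_out,
             n_pot_trials = matrix(0L, n_in, n_out),
             n_dep_trials = matrix(0L, n_in, n_out))
  if (cfg$rule == "deterministic") {
    ps$W <- matrix(stats::runif(n_in * n_out, 0, 2 * init_density),
                   n_in, n_out)
    ps$W <- pmin(pmax(ps$W, cfg$w_min), cfg$w_max)
  } else {
    ps$W <- matrix(as.integer(stats::runif(n_in * n_out) < init_density),
                   n_in, n_out)
    ps$M  <- matrix(0L, n_in, n_out)   # potentiation-device set counts
    ps$Nd <- matrix(0L, n_in, n_out)   # depression-device set counts
    # per-element SET probabilities, stage-major: [synapse, stage]
    ps$Pk <- matrix(sample_element_probs(n_in * n_out * cfg$k, cfg$p, var),
                    n_in * n_out, cfg$k)
    ps$Qk <- matrix(sample_element_probs(n_in * n_out * cfg$k_dep, cfg$q, var),
                    n_in * n_out, cfg$k_dep)
  }
  class(ps) <- "plastic_synapses"
  ps
}

# advance the devices of the given linear synapse indices by one trial.
# counters/probs given by value; returns list(count, flipped_index)
.advance_devices <- function(idx, count, k, prob_mat) {
  cnt <- count[idx]
  active <- cnt < k
  flipped <- integer(0)
  if (any(active)) {
    ia <- idx[active]
    ca <- cnt[active]
    pr <- prob_mat[cbind(ia, ca + 1L)]
    succ <- stats::runif(length(ia)) < pr
    if (any(succ)) {
      count[ia[succ]] <- ca[succ] + 1L
      flipped <- ia[succ][ca[succ] + 1L == k]
    }
  }
  list(count = count, flipped = flipped)
}

#' Apply one postsynaptic-fire S-STDP update to a neuron's afferents
#'
#' Implements the simplified-STDP rule at the moment postsynaptic neuron
#' \code{j} fires: every afferent whose most recent presynaptic spike fell
#' within the coincidence window (\code{in_window}) receives a
#' potentiation trial, and every other afferent -- including those that
#' never spiked -- receives a depression trial. Each afferent is updated
#' exactly once per fire.
#'
#' @param ps a \code{\link{plastic_synapses}} state.
#' @param j column index of the firing neuron.
#' @param in_window logical vector (length \code{n_in}): TRUE where
#'   \code{0 < t_post - t_pre < window_T}.
#' @return The updated \code{plastic_synapses}.
#' @export
on_post_spike <- function(ps, j, in_window) {
  stopifnot(inherits(ps, "plastic_synapses"),
            length(in_window) == ps$n_in)
  cfg <- ps$cfg
  ps$n_pot_trials[in_window, j] <- ps$n_pot_trials[in_window, j] + 1L
  ps$n_dep_trials[!in_window, j] <- ps$n_dep_trials[!in_window, j] + 1L
  if (cfg$rule == "deterministic") {
    w <- ps$W[, j]
    w[in_window] <- w[in_window] + cfg$eta_plus * (cfg$w_max - w[in_window])
    w[!in_window] <- w[!in_window] - cfg$eta_minus * (w[!in_window] - cfg$w_min)
    ps$W[, j] <- w
    return(ps)
  }
  off <- (j - 1L) * ps$n_in
  pot_idx <- off + which(in_window)
  dep_idx <- off + which(!in_window)
  if (length(pot_idx)) {
    ps$Nd[pot_idx] <- 0L                       # opposite counters reset
    adv <- .advance_devices(pot_idx, ps$M, cfg$k, ps$Pk)
    ps$M <- adv$count
    if (length(adv$flipped)) {
      ps$W[adv$flipped] <- 1L
      if (cfg$reset_on_complete) ps$M[adv$flipped] <- 0L
    }
  }
  if (length(dep_idx)) {
    ps$M[dep_idx] <- 0L
    adv <- .advance_devices(dep_idx, ps$Nd, cfg$k_dep, ps$Qk)
    ps$Nd <- adv$count
    if (length(adv$flipped)) {
      ps$W[adv$flipped] <- 0L
      if (cfg$reset_on_complete) ps$Nd[adv$flipped] <- 0L
    }
  }
  ps
}
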