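#' Stateful serial-memristor switching device
#'
#' One switching device of \code{k} binary memristors in series. Pulses
#' arrive at the input terminal, so elements SET strictly in order: the
#' set elements always form a prefix, summarised by \code{set_count}. The
#' device is ON (conducting) when \code{set_count == k}. Each element may
#' carry its own per-pulse SET probability (device-to-device variability);
#' with variability disabled all equal the nominal \code{p}.
#'
#' @param k device length (number of serial memristors, >= 1).
#' @param p nominal per-pulse SET probability.
#' @param per_p optional vector of k per-element probabilities.
#' @return An object of class \code{switch_device}.
#' @export
switch_device <- function(k, p, per_p = NULL) {
  if (length(k) != 1L || k < 1 || k != round(k)) stop("'k' must be an integer >= 1")
  if (is.null(per_p)) per_p <- rep(p, k)
  if (length(per_p) != k || any(per_p < 0) || any(per_p > 1))
    stop("'per_p' must be k probabilities")
  structure(list(k = as.integer(k), set_count = 0L, per_p = per_p),
            class = "switch_device")
}

device_is_on <- function(dev) dev$set_count == dev$k

# one pulse: attempt to SET the first unset element (if any)
device_pulse <- function(dev) {
  if (dev$set_count < dev$k) {
    if (stats::runif(1) < dev$per_p[dev$set_count + 1L])
      dev$set_count <- dev$set_count + 1L
  }
  dev
}

device_reset <- function(dev) { dev$set_count <- 0L; dev }

#' Binary synapse backed by a pair of switching devices
#'
#' A binary synapse holds a potentiation device (the m-counters), a
#' depression device (the n-counters) and a latched binary weight. The
#' weight flips to 1 on the trial at which the potentiation device turns
#' ON, and to 0 when the depression device turns ON; a completed device
#' stays ON until the first opposite-direction trial resets it (the latch
#' reading of the hardware, exposed via \code{reset_on_complete} for the
#' alternative immediate-reset convention).
#'
#' @param k device length shared by both devices, or use \code{k_dep} for
#'   a mixed-mode synapse.
#' @param p per-pulse SET probability of the potentiation device.
#' @param q per-pulse SET probability of the depression device.
#' @param k_dep depression device length (defaults to \code{k}).
#' @param weight initial binary weight (0 or 1).
#' @param pot_per_p,dep_per_p optional per-element probability vectors
#'   (from \code{\link{sample_device}} under variability).
#' @param reset_on_complete if TRUE, a device that completes and flips the
#'   latch is immediately re-initialised to all-HRS.
#' @return An object of class \code{binary_synapse}.
#' @export
binary_synapse <- function(k, p, q, k_dep = k, weight = 0L,
                           pot_per_p = NULL, dep_per_p = NULL,
                           reset_on_complete = FALSE) {
  if (!weight %in% c(0L, 1L)) stop("'weight' must be 0 or 1")
  structure(list(
    pot = switch_device(k, p, pot_per_p),
    dep = switch_device(k_dep, q, dep_per_p),
    weight = as.integer(weight),
    reset_on_complete = isTRUE(reset_on_complete)
  ), class = "binary_synapse")
}

#' Apply one potentiation trial to a binary synapse
#'
#' The per-trial semantics of the synaptic update algorithm: all
#' depression counters are reset to 0, then a single SET attempt is made
#' on the first unset element of the potentiation device. If that attempt
#' completes the device, the weight latches to 1.
#'
#' Uses R's global random number stream; seed with \code{set.seed()} for
#' reproducibility.
#'
#' @param syn a \code{\link{binary_synapse}}.
#' @return The updated synapse.
#' @export
potentiation_trial <- function(syn) {
  stopifnot(inherits(syn, "binary_synapse"))
  syn$dep <- device_reset(syn$dep)
  was_on <- device_is_on(syn$pot)
  syn$pot <- device_pulse(syn$pot)
  if (!was_on && device_is_on(syn$pot)) {
    syn$weight <- 1L
    if (syn$reset_on_complete) syn$pot <- device_reset(syn$pot)
  }
  syn
}

#' Apply one depression trial to a binary synapse
#'
#' Mirror of \code{\link{potentiation_trial}}: potentiation counters are
#' reset, the depression device receives one SET attempt, and the weight
#' latches to 0 when the depression device completes.
#'
#' @inheritParams potentiation_trial
#' @return The updated synapse.
#' @export
depression_trial <- function(syn) {
  stopifnot(inherits(syn, "binary_synapse"))
  syn$pot <- device_reset(syn$pot)
  was_on <- device_is_on(syn$dep)
  syn$dep <- device_pulse(syn$dep)
  if (!was_on && device_is_on(syn$dep)) {
    syn$weight <- 0L
    if (syn$reset_on_complete) syn$dep <- device_reset(syn$dep)
  }
  syn
}

#' Log-normal device-to-device variability specification
#'
#' SET time constants scatter across devices as
#' \code{tau = tau0 * exp(sigma * r)} with standard-normal \code{r}. The
#' draw is made once per memristor at construction (quenched disorder);
#' cycle-to-cycle variability is already captured by the exponential SET
#' statistics.
#'
#' @param sigma log-normal standard deviation (>= 0; 0 disables).
#' @param tau0 nominal SET time constant (arbitrary units, > 0).
#' @return An object of class \code{variability_spec}.
#' @export
variability_spec <- function(sigma = 0, tau0 = 1) {
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (!is.finite(tau0) || tau0 <= 0) stop("'tau0' must be > 0")
  structure(list(sigma = sigma, tau0 = tau0), class = "variability_spec")
}

#' Draw a switching device with log-normal element variability
#'
#' The pulse width is fixed so that the nominal element satisfies
#' \code{1 - exp(-delta_t / tau0) = p_nominal}; each of the k elements then
#' draws its own \code{tau_i = tau0 * exp(sigma * r_i)} and gets
#' \code{per_p_i = 1 - exp(-delta_t / tau_i)}. With \code{sigma = 0} all
#' per-element probabilities equal \code{p_nominal}.
#'
#' @param k device length.
#' @param p_nominal nominal per-pulse SET probability in (0, 1).
#' @param var a \code{\link{variability_spec}}.
#' @return A \code{\link{switch_device}} with frozen per-element
#'   probabilities.
#' @export
sample_device <- function(k, p_nominal, var = variability_spec()) {
  stopifnot(inherits(var, "variability_spec"))
  per_p <- sample_element_probs(k, p_nominal, var)
  switch_device(k, p_nominal, per_p = per_p)
}

# vector of n per-element SET probabilities under log-normal tau scatter
sample_element_probs <- function(n, p_nominal, var) {
  if (p_nominal <= 0 || p_nominal >= 1) stop("'p_nominal' must be in (0, 1)")
  if (var$sigma == 0) return(rep(p_nominal, n))
  delta_t <- -log1p(-p_nominal) * var$tau0   # so that p(tau0) = p_nominal
  tau <- var$tau0 * exp(var$sigma * stats::rnorm(n))
  -expm1(-delta_t / tau)
}

#' Serialise synapse state to a plain list
#'
#' Counters and weight of a synapse as a named list of integers/numerics,
#' suitable for JSON checkpointing; \code{restore_synapse_state} inverts
#' it.
#'
#' @param syn a \code{\link{binary_synapse}}.
#' @return A named list with m-counters, n-counters, weight and the
#'   per-element probabilities.
#' @export
synapse_state <- function(syn) {
  list(m = syn$pot$set_count, n = syn$dep$set_count, weight = syn$weight,
       k_pot = syn$pot$k, k_dep = syn$dep$k,
       pot_per_p = syn$pot$per_p, dep_per_p = syn$dep$per_p,
       reset_on_complete = syn$reset_on_complete)
}

#' @rdname synapse_state
#' @param state a list produced by \code{synapse_state}.
#' @export
restore_synapse_state <- function(state) {
  syn <- binary_synapse(k = state$k_pot, p = state$pot_per_p[1],
                        q = state$dep_per_p[1], k_dep = state$k_dep,
                        weight = state$weight,
                        pot_per_p = state$pot_per_p,
                        dep_per_p = state$dep_per_p,
                        reset_on_complete = state$reset_on_complete)
  syn$pot$set_count <- as.integer(state$m)
  syn$dep$set_count <- as.integer(state$n)
  syn
}
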