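#' Poisson rate-coding encoder specification
#'
#' Pixel intensities are converted to Poisson spike rates by dividing by
#' \code{rate_divisor}: with 8-bit intensities and the default divisor 4
#' the rates span 0 to 63.75 Hz. Each image is presented for
#' \code{presentation_ms}, followed by a silent \code{rest_ms} during
#' which input rates are zero and the network relaxes.
#'
#' @param pixels number of input pixels (one input node each).
#' @param rate_divisor intensity-to-Hz divisor.
#' @param presentation_ms duration of each image presentation (ms).
#' @param rest_ms silent inter-image period (ms).
#' @return An object of class \code{encoder_spec}.
#' @export
encoder_spec <- function(pixels = 784, rate_divisor = 4,
                         presentation_ms = 350, rest_ms = 150) {
  if (pixels < 1 || rate_divisor <= 0 || presentation_ms <= 0 || rest_ms < 0)
    stop("invalid encoder specification")
  structure(list(pixels = as.integer(pixels), rate_divisor = rate_divisor,
                 presentation_ms = presentation_ms, rest_ms = rest_ms),
            class = "encoder_spec")
}

#' Encode an image as Poisson spike trains
#'
#' Draws independent Poisson processes, one per pixel, at rate
#' \code{intensity / rate_divisor} Hz for the presentation duration, on a
#' clock grid of width \code{dt}. The per-step spike probability is
#' \code{rate * dt}, so the empirical rate of a pixel converges exactly to
#' its intensity divided by the divisor.
#'
#' @param image numeric vector (or matrix) of non-negative intensities.
#' @param spec an \code{\link{encoder_spec}}.
#' @param dt clock step in ms.
#' @return Logical matrix \code{n_steps x pixels}; TRUE marks a spike.
#' @export
encode_image <- function(image, spec, dt = 0.5) {
  img <- as.vector(image)
  if (length(img) != spec$pixels) stop("image size does not match encoder")
  if (any(img < 0)) stop("negative intensity")
  rate_hz <- img / spec$rate_divisor
  p_step <- rate_hz * dt / 1000
  if (any(p_step > 1)) stop("rate too high for this dt")
  n_steps <- round(spec$presentation_ms / dt)
  matrix(stats::runif(n_steps * spec$pixels) <
           rep(p_step, each = n_steps), n_steps, spec$pixels)
}

#' Network constants for the two-layer winner-take-all circuit
#'
#' Conductance-based leaky integrate-and-fire parameters for the
#' excitatory/inhibitory neuron pairs, following the standard two-layer
#' digit-learning design: adaptive-threshold excitatory neurons, fast
#' inhibitory partners, exponential conductance decay, and fixed
#' non-plastic excitatory-to-inhibitory pairing plus
#' all-to-all-minus-pair inhibition. All voltages in mV, times in ms,
#' conductances in units of the leak conductance.
#'
#' @param dt integration step (<= 0.5 ms for stability).
#' @param v_rest_e,v_reset_e,v_thresh_e resting, reset and base threshold
#'   potentials of excitatory neurons.
#' @param tau_m_e,refrac_e membrane time constant and refractory period of
#'   excitatory neurons.
#' @param v_rest_i,v_reset_i,v_thresh_i,tau_m_i,refrac_i the same for
#'   inhibitory neurons.
#' @param E_exc,E_inh excitatory and inhibitory reversal potentials.
#' @param tau_ge,tau_gi conductance decay time constants.
#' @param theta_plus adaptive-threshold increment per excitatory spike.
#' @param tau_theta adaptive-threshold decay time constant.
#' @param w_ei fixed excitatory-to-paired-inhibitory weight.
#' @param w_ie fixed inhibitory-to-excitatory (lateral) weight.
#' @param g_unit conductance quantum of one binary plastic synapse; a
#'   continuous weight w contributes \code{w * g_unit}.
#' @param init_density initial plastic-weight density (see
#'   \code{\link{plastic_synapses}}).
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(dt = 0.5,
                           v_rest_e = -65, v_reset_e = -65, v_thresh_e = -52,
                           tau_m_e = 100, refrac_e = 5,
                           v_rest_i = -60, v_reset_i = -45, v_thresh_i = -40,
                           tau_m_i = 10, refrac_i = 2,
                           E_exc = 0, E_inh = -100,
                           tau_ge = 1, tau_gi = 2,
                           theta_plus = 0.05, tau_theta = 1e5,
                           w_ei = 10.4, w_ie = 8,
                           g_unit = 1, init_density = 0.5) {
  if (dt <= 0 || dt > 0.5) stop("'dt' must be in (0, 0.5] ms")
  structure(as.list(environment()), class = "network_config")
}

#' Construct a two-layer winner-take-all spiking network
#'
#' Builds the full network state: \code{n_input} Poisson input nodes
#' all-to-all connected through plastic synapses (under the given update
#' rule) to \code{n_exc} excitatory neurons, each paired with one
#' inhibitory neuron that laterally inhibits all other excitatory neurons.
#' Uses R's global RNG for weight initialisation and any variability
#' draws; seed with \code{set.seed()}.
#'
#' @param n_input number of input nodes (pixels).
#' @param n_exc number of excitatory/inhibitory pairs.
#' @param rule a \code{\link{rule_config}}.
#' @param enc an \code{\link{encoder_spec}} (its \code{pixels} must equal
#'   \code{n_input}).
#' @param cfg a \code{\link{network_config}}.
#' @param var a \code{\link{variability_spec}} for device-to-device
#'   scatter of the stochastic synapses.
#' @return An object of class \code{snn_network}.
#' @export
snn_network <- function(n_input, n_exc, rule = rule_preset("sigmoidal_k3"),
                        enc = encoder_spec(pixels = n_input),
                        cfg = network_config(),
                        var = variability_spec()) {
  if (enc$pixels != n_input) stop("encoder pixel count must equal n_input")
  net <- list(
    n_input = as.integer(n_input), n_exc = as.integer(n_exc),
    rule = rule, enc = enc, cfg = cfg,
    ps = plastic_synapses(n_input, n_exc, rule, var,
                          init_density = cfg$init_density),
    v_e = rep(cfg$v_rest_e, n_exc), v_i = rep(cfg$v_rest_i, n_exc),
    g_e_e = numeric(n_exc),  # excitatory conductance on exc neurons
    g_i_e = numeric(n_exc),  # inhibitory conductance on exc neurons
    g_e_i = numeric(n_exc),  # excitatory conductance on inh neurons
    theta = numeric(n_exc),
    refrac_e = numeric(n_exc), refrac_i = numeric(n_exc),
    last_pre = rep(-Inf, n_input),
    t_now = 0,
    images_seen = 0L
  )
  class(net) <- "snn_network"
  net
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf(
    "Two-layer WTA spiking network: %d inputs -> %d exc/inh pairs, rule %s%s\n",
    x$n_input, x$n_exc, x$rule$rule,
    if (x$rule$rule == "stochastic")
      sprintf(" (k = %d/%d, p = %g, q = %g)", x$rule$k, x$rule$k_dep,
              x$rule$p, x$rule$q) else ""))
  cat(sprintf("  images presented: %d, weight sum: %.1f\n",
              x$images_seen, sum(x$ps$W)))
  invisible(x)
}

#' Advance the network by one clock step
#'
#' One step of clock-driven integration: conductance decay plus input
#' spike arrivals, leaky integrate-and-fire updates of both populations,
#' adaptive-threshold homeostasis, delivery of lateral inhibition, and --
#' when plasticity is enabled -- one S-STDP update per excitatory spike
#' (simultaneously firing neurons are processed in index order).
#'
#' This is the reference single-step API; \code{\link{present_image}} runs
#' the same dynamics in an optimised loop.
#'
#' @param net an \code{\link{snn_network}}.
#' @param input_spikes logical vector of input spikes this step (length
#'   \code{n_input}), or NULL for silence.
#' @param plasticity logical; apply synaptic updates on excitatory fires.
#' @return A list with \code{net} (updated) and \code{fired} (integer
#'   indices of excitatory neurons that fired).
#' @export
step_network <- function(net, input_spikes = NULL, plasticity = TRUE) {
  if (any(!is.finite(net$v_e)) || any(!is.finite(net$v_i)))
    stop("non-finite membrane potential: simulation diverged; ",
         "dump: v_e range [", min(net$v_e), ", ", max(net$v_e), "]")
  cfg <- net$cfg
  dt <- cfg$dt
  dec_ge <- exp(-dt / cfg$tau_ge); dec_gi <- exp(-dt / cfg$tau_gi)
  dec_th <- exp(-dt / cfg$tau_theta)

  # input arrivals
  net$g_e_e <- net$g_e_e * dec_ge
  if (!is.null(input_spikes) && any(input_spikes)) {
    net$last_pre[input_spikes] <- net$t_now
    net$g_e_e <- net$g_e_e +
      cfg$g_unit * colSums(net$ps$W[input_spikes, , drop = FALSE])
  }
  net$g_i_e <- net$g_i_e * dec_gi
  net$g_e_i <- net$g_e_i * dec_ge

  # excitatory membrane update
  free_e <- net$refrac_e <= 0
  dv <- (cfg$v_rest_e - net$v_e + net$g_e_e * (cfg$E_exc - net$v_e) +
           net$g_i_e * (cfg$E_inh - net$v_e)) * (dt / cfg$tau_m_e)
  net$v_e <- ifelse(free_e, net$v_e + dv, net$v_e)
  fired <- which(free_e & net$v_e >= cfg$v_thresh_e + net$theta)
  if (length(fired)) {
    net$v_e[fired] <- cfg$v_reset_e
    net$refrac_e[fired] <- cfg$refrac_e
    if (plasticity) {
      # homeostatic adaptation is part of learning; frozen in recognition
      net$theta[fired] <- net$theta[fired] + cfg$theta_plus
      dtpre <- net$t_now - net$last_pre
      in_win <- dtpre > 0 & dtpre < net$rule$window_T
      for (j in fired) net$ps <- on_post_spike(net$ps, j, in_win)
    }
    # paired inhibitory neurons receive the fixed exc->inh weight
    net$g_e_i[fired] <- net$g_e_i[fired] + cfg$w_ei
  }
  net$theta <- net$theta * dec_th

  # inhibitory membrane update
  free_i <- net$refrac_i <= 0
  dvi <- (cfg$v_rest_i - net$v_i + net$g_e_i * (cfg$E_exc - net$v_i)) *
    (dt / cfg$tau_m_i)
  net$v_i <- ifelse(free_i, net$v_i + dvi, net$v_i)
  fired_i <- which(free_i & net$v_i >= cfg$v_thresh_i)
  if (length(fired_i)) {
    net$v_i[fired_i] <- cfg$v_reset_i
    net$refrac_i[fired_i] <- cfg$refrac_i
    # lateral inhibition to all excitatory neurons except the pair
    add <- rep(cfg$w_ie * length(fired_i), net$n_exc)
    add[fired_i] <- add[fired_i] - cfg$w_ie
    net$g_i_e <- net$g_i_e + add
  }

  net$refrac_e <- net$refrac_e - dt
  net$refrac_i <- net$refrac_i - dt
  net$t_now <- net$t_now + dt
  list(net = net, fired = fired)
}

#' Present one image (plus rest period) to the network
#'
#' Encodes the image as Poisson spike trains, runs the network for the
#' presentation duration and the silent rest period, and returns the
#' per-excitatory-neuron spike counts. Identical dynamics to
#' \code{\link{step_network}}, in a loop optimised for the training and
#' evaluation drivers.
#'
#' @param net an \code{\link{snn_network}}.
#' @param image intensity vector (length \code{n_input}), or NULL for a
#'   silent presentation.
#' @param plasticity logical; enable S-STDP updates.
#' @param engine \code{"cpp"} (compiled loop, default) or \code{"r"} (the
#'   reference implementation); both produce bit-identical trajectories
#'   from the same RNG state.
#' @return A list with \code{net} and \code{counts} (integer spike count
#'   per excitatory neuron during the presentation).
#' @export
present_image <- function(net, image, plasticity = TRUE,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cfg <- net$cfg
  dt <- cfg$dt
  spikes_in <- if (is.null(image)) NULL else encode_image(image, net$enc, dt)
  n_pres <- round(net$enc$presentation_ms / dt)
  n_rest <- round(net$enc$rest_ms / dt)
  if (engine == "cpp")
    return(present_image_cpp(net, spikes_in, n_pres, n_rest, plasticity,
                             !is.null(image)))
  counts <- integer(net$n_exc)

  # locals for speed
  v_e <- net$v_e; v_i <- net$v_i
  g_e_e <- net$g_e_e; g_i_e <- net$g_i_e; g_e_i <- net$g_e_i
  theta <- net$theta
  refrac_e <- net$refrac_e; refrac_i <- net$refrac_i
  last_pre <- net$last_pre
  t_now <- net$t_now
  ps <- net$ps
  W <- ps$W
  dec_ge <- exp(-dt / cfg$tau_ge); dec_gi <- exp(-dt / cfg$tau_gi)
  dec_th <- exp(-dt / cfg$tau_theta)
  ce_m <- dt / cfg$tau_m_e; ci_m <- dt / cfg$tau_m_i
  thr_i <- cfg$v_thresh_i
  win_T <- net$rule$window_T
  g_unit <- cfg$g_unit

  for (step in seq_len(n_pres + n_rest)) {
    g_e_e <- g_e_e * dec_ge
    if (step <= n_pres && !is.null(spikes_in)) {
      s <- spikes_in[step, ]
      if (any(s)) {
        last_pre[s] <- t_now
        g_e_e <- g_e_e + g_unit * colSums(W[s, , drop = FALSE])
      }
    }
    g_i_e <- g_i_e * dec_gi
    g_e_i <- g_e_i * dec_ge

    free_e <- refrac_e <= 0
    dv <- (cfg$v_rest_e - v_e + g_e_e * (cfg$E_exc - v_e) +
             g_i_e * (cfg$E_inh - v_e)) * ce_m
    v_e[free_e] <- v_e[free_e] + dv[free_e]
    fired <- which(free_e & v_e >= cfg$v_thresh_e + theta)
    if (length(fired)) {
      counts[fired] <- counts[fired] + 1L
      v_e[fired] <- cfg$v_reset_e
      refrac_e[fired] <- cfg$refrac_e
      if (plasticity) {
        theta[fired] <- theta[fired] + cfg$theta_plus
        dtpre <- t_now - last_pre
        in_win <- dtpre > 0 & dtpre < win_T
        for (j in fired) ps <- on_post_spike(ps, j, in_win)
        W <- ps$W
      }
      g_e_i[fired] <- g_e_i[fired] + cfg$w_ei
    }
    theta <- theta * dec_th

    free_i <- refrac_i <= 0
    dvi <- (cfg$v_rest_i - v_i + g_e_i * (cfg$E_exc - v_i)) * ci_m
    v_i[free_i] <- v_i[free_i] + dvi[free_i]
    fired_i <- which(free_i & v_i >= thr_i)
    if (length(fired_i)) {
      v_i[fired_i] <- cfg$v_reset_i
      refrac_i[fired_i] <- cfg$refrac_i
      g_i_e <- g_i_e + cfg$w_ie * length(fired_i)
      g_i_e[fired_i] <- g_i_e[fired_i] - cfg$w_ie
    }

    refrac_e <- refrac_e - dt
    refrac_i <- refrac_i - dt
    t_now <- t_now + dt
  }
  if (any(!is.finite(v_e)))
    stop("non-finite membrane potential: simulation diverged")

  net$v_e <- v_e; net$v_i <- v_i
  net$g_e_e <- g_e_e; net$g_i_e <- g_i_e; net$g_e_i <- g_e_i
  net$theta <- theta
  net$refrac_e <- refrac_e; net$refrac_i <- refrac_i
  net$last_pre <- last_pre
  net$t_now <- t_now
  net$ps <- ps
  net$images_seen <- net$images_seen + !is.null(image)
  list(net = net, counts = counts)
}

# marshal network state into the compiled presentation loop and back
present_image_cpp <- function(net, spikes_in, n_pres, n_rest, plasticity,
                              had_image) {
  cfg <- net$cfg
  rule <- net$rule
  params <- list(
    deterministic = rule$rule == "deterministic",
    k_pot = rule$k, k_dep = rule$k_dep,
    reset_on_complete = rule$reset_on_complete,
    eta_plus = rule$eta_plus, eta_minus = rule$eta_minus,
    w_min = rule$w_min, w_max = rule$w_max, window_T = rule$window_T,
    dt = cfg$dt, v_rest_e = cfg$v_rest_e, v_reset_e = cfg$v_reset_e,
    v_thresh_e = cfg$v_thresh_e, refrac_e = cfg$refrac_e,
    v_rest_i = cfg$v_rest_i, v_reset_i = cfg$v_reset_i,
    v_thresh_i = cfg$v_thresh_i, refrac_i = cfg$refrac_i,
    E_exc = cfg$E_exc, E_inh = cfg$E_inh,
    w_ei = cfg$w_ei, w_ie = cfg$w_ie, g_unit = cfg$g_unit,
    theta_plus = cfg$theta_plus,
    dec_ge = exp(-cfg$dt / cfg$tau_ge), dec_gi = exp(-cfg$dt / cfg$tau_gi),
    dec_th = exp(-cfg$dt / cfg$tau_theta),
    ce_m = cfg$dt / cfg$tau_m_e, ci_m = cfg$dt / cfg$tau_m_i)
  out <- .cpp_present(net, params, spikes_in, n_pres, n_rest, plasticity)
  for (f in c("v_e", "v_i", "g_e_e", "g_i_e", "g_e_i", "theta",
              "refrac_e", "refrac_i", "last_pre", "t_now"))
    net[[f]] <- out[[f]]
  net$ps$W <- out$W
  if (rule$rule != "deterministic") {
    net$ps$M <- out$M
    net$ps$Nd <- out$Nd
  }
  net$ps$n_pot_trials <- out$n_pot_trials
  net$ps$n_dep_trials <- out$n_dep_trials
  net$images_seen <- net$images_seen + had_image
  list(net = net, counts = out$counts)
}

#' Train the network on a labelled dataset (unsupervised)
#'
#' Presents every image of the dataset in order with plasticity enabled
#' (labels are never used during training), logging per-image spike counts
#' and the per-neuron afferent weight sums. Deterministic given the state
#' of R's RNG.
#'
#' @param net an \code{\link{snn_network}}.
#' @param dataset a dataset list with \code{images} (rows = images) and
#'   \code{labels}, as from \code{\link{generate_dataset}}.
#' @param plasticity logical; FALSE freezes all weights (the recognition
#'   phase).
#' @param engine simulation engine, see \code{\link{present_image}}.
#' @return A list with \code{net}, \code{counts} (images x neurons spike
#'   count matrix) and \code{weight_sums} (images x neurons afferent
#'   weight-sum trace, recorded after each presentation).
#' @export
train_network <- function(net, dataset, plasticity = TRUE,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  n <- nrow(dataset$images)
  if (n == 0) stop("empty dataset")
  counts <- matrix(0L, n, net$n_exc)
  wsums <- matrix(0, n, net$n_exc)
  for (i in seq_len(n)) {
    res <- present_image(net, dataset$images[i, ], plasticity = plasticity,
                         engine = engine)
    net <- res$net
    counts[i, ] <- res$counts
    wsums[i, ] <- colSums(net$ps$W)
  }
  list(net = net, counts = counts, weight_sums = wsums)
}

#' Save / load a network checkpoint
#'
#' Serialises the full network state -- neuron variables, plastic weights,
#' device counters and per-element probabilities -- as plain JSON so runs
#' can be resumed or inspected.
#'
#' @param net an \code{\link{snn_network}}.
#' @param path destination JSON path.
#' @return \code{path} invisibly (\code{save_checkpoint});
#'   the restored network (\code{load_checkpoint}).
#' @export
save_checkpoint <- function(net, path) {
  x <- net
  x$last_pre[!is.finite(x$last_pre)] <- NA_real_  # JSON has no -Inf
  jsonlite::write_json(unclass_deep(x), path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- raw
  net$rule <- do.call(rule_config, raw$rule)
  net$enc <- do.call(encoder_spec, raw$enc)
  net$cfg <- do.call(network_config, raw$cfg)
  ps <- raw$ps
  ps$cfg <- net$rule
  for (f in c("W", "M", "Nd", "n_pot_trials", "n_dep_trials"))
    if (!is.null(ps[[f]])) storage.mode(ps[[f]]) <- "integer"
  if (net$rule$rule == "deterministic") storage.mode(ps$W) <- "double"
  class(ps) <- "plastic_synapses"
  net$ps <- ps
  net$last_pre[is.na(net$last_pre)] <- -Inf
  class(net) <- "snn_network"
  net
}

# strip S3 classes recursively for JSON round-tripping
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
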