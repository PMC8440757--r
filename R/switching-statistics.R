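#' Switching model for a serial binary-memristor device
#'
#' Constructs the stateless probabilistic description of a switching device
#' made of \code{k} binary memristors in series. Each memristor SETs
#' (high-resistance to low-resistance) on a voltage pulse as a Poissonian
#' event with per-pulse probability \code{p}; the device conducts only once
#' all \code{k} elements have SET, so the pulse count at which the device
#' turns ON follows a negative binomial law NB(k, p) -- the discrete
#' counterpart of a gamma distribution with shape \code{k}.
#'
#' Exactly one of \code{p} or \code{lambda} must be given; the other is
#' derived through \code{lambda = -log(1 - p)}, the dimensionless rate that
#' equals the pulse-width to SET-time ratio \code{delta_t / tau}.
#'
#' @param k integer number of serially connected memristors (>= 1).
#' @param p per-pulse SET probability of a single memristor, in (0, 1).
#' @param lambda dimensionless SET rate; alternative parameterisation.
#' @return An object of class \code{gamma_switch_model} with fields
#'   \code{k}, \code{p}, \code{lambda}.
#' @examples
#' m <- gamma_switch_model(k = 3, p = 0.13)
#' m$lambda
#' @export
gamma_switch_model <- function(k, p = NULL, lambda = NULL) {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    stop("'k' must be a single integer >= 1")
  if (is.null(p) == is.null(lambda))
    stop("give exactly one of 'p' or 'lambda'")
  if (is.null(p)) {
    if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
      stop("'lambda' must be a single positive number")
    p <- 1 - exp(-lambda)
  } else {
    if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
      stop("'p' must be a single probability in (0, 1)")
    lambda <- lambda_from_p(p)
  }
  structure(list(k = as.integer(k), p = p, lambda = lambda),
            class = "gamma_switch_model")
}

#' @export
print.gamma_switch_model <- function(x, ...) {
  cat(sprintf("Serial-memristor switch model: k = %d, p = %.6g, lambda = %.6g\n",
              x$k, x$p, x$lambda))
  invisible(x)
}

#' Dimensionless SET rate from a per-pulse probability
#'
#' \code{lambda = -log(1 - p)}, approximately \code{p} for small \code{p}.
#'
#' @param p per-pulse SET probability in (0, 1).
#' @return The rate \code{-log(1 - p)}.
#' @export
lambda_from_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie in the open interval (0, 1)")
  -log1p(-p)
}

#' Per-pulse SET probability from pulse width and SET time constant
#'
#' A memristor with exponential SET-time statistics SETs during a voltage
#' pulse of width \code{delta_t} with probability
#' \code{1 - exp(-delta_t / tau)}.
#'
#' @param delta_t pulse width (same units as \code{tau}).
#' @param tau characteristic SET time constant.
#' @return SET probability in (0, 1).
#' @export
p_from_pulse <- function(delta_t, tau) {
  if (any(!is.finite(delta_t)) || any(delta_t <= 0))
    stop("'delta_t' must be positive")
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("'tau' must be positive")
  -expm1(-delta_t / tau)
}

#' Exact cumulative ON probability of the serial device (negative binomial)
#'
#' Probability that the k-th SET success occurs at or before pulse \code{N},
#' i.e. that at least \code{k} of \code{N} independent Bernoulli(p) trials
#' succeed. This is the exact discrete law realised by the per-trial update
#' algorithm (one SET attempt per pulse, elements SET in order), and the
#' reference implementation against which the continuous gamma
#' approximation is compared.
#'
#' @param model a \code{\link{gamma_switch_model}}.
#' @param N integer vector of pulse counts (>= 0).
#' @return Probabilities in [0, 1], one per element of \code{N}.
#' @export
cdf_negative_binomial <- function(model, N) {
  stopifnot(inherits(model, "gamma_switch_model"))
  if (any(!is.finite(N)) || any(N < 0) || any(N != round(N)))
    stop("'N' must be non-negative integers")
  out <- numeric(length(N))
  pos <- N >= model$k
  # P(>= k successes in N trials): upper binomial tail
  out[pos] <- stats::pbinom(model$k - 1, N[pos], model$p, lower.tail = FALSE)
  out
}

#' Discretised-gamma cumulative ON probability
#'
#' The continuous-time approximation of the device's ON probability after
#' \code{N} pulses: the gamma(shape k) CDF discretised as
#' \deqn{P_k(N) = \frac{\lambda^k}{(k-1)!} \sum_{n=0}^{N-1} n^{k-1} e^{-\lambda n},}
#' with \code{0^0 = 1} for \code{k = 1}. For \code{k = 1} and small
#' \code{lambda} this reduces to \code{1 - exp(-lambda N)}. It is an
#' approximation of \code{\link{cdf_negative_binomial}}, accurate for small
#' \code{p}; it is not clamped to [0, 1].
#'
#' @inheritParams cdf_negative_binomial
#' @param N integer vector of pulse counts (>= 1).
#' @return Approximate probabilities, one per element of \code{N}.
#' @export
cdf_gamma_discretised <- function(model, N) {
  stopifnot(inherits(model, "gamma_switch_model"))
  if (any(!is.finite(N)) || any(N < 1) || any(N != round(N)))
    stop("'N' must be integers >= 1 (the sum runs over n = 0..N-1)")
  k <- model$k
  lam <- model$lambda
  nmax <- max(N)
  n <- 0:(nmax - 1)
  terms <- if (k == 1L) exp(-lam * n) else n^(k - 1) * exp(-lam * n)
  csum <- cumsum(terms)
  lam^k / factorial(k - 1) * csum[N]
}

#' Density of the underlying gamma switching-time law
#'
#' Helper for plotting the continuous switching-time distribution of the
#' serial device: gamma density with shape \code{k} and scale \code{tau}.
#' Not used in the learning path.
#'
#' @param x switching times (>= 0).
#' @param k shape (number of serial memristors).
#' @param tau per-element SET time constant (scale).
#' @return Density values.
#' @export
gamma_switch_density <- function(x, k, tau = 1) {
  stats::dgamma(x, shape = k, scale = tau)
}

#' Expected binary weight under repeated potentiation trials
#'
#' Starting from \code{w = 0}, the expected weight after \code{N}
#' potentiation trials equals the cumulative ON probability of the
#' potentiation device: \code{<w> = P_k(N)}. For \code{k = 1} the curve is
#' exponential-saturating (steep start); for \code{k >= 2} it is sigmoidal,
#' starting gently and accelerating -- the property that stabilises
#' memories during learning.
#'
#' @param model a \code{\link{gamma_switch_model}} for the potentiation
#'   device (parameters \code{k}, \code{p}).
#' @param N integer vector of trial counts (>= 0).
#' @param method \code{"exact"} (negative binomial, default) or
#'   \code{"gamma"} (discretised continuous approximation).
#' @return Expected weights in [0, 1].
#' @export
expected_weight_potentiation <- function(model, N, method = c("exact", "gamma")) {
  method <- match.arg(method)
  if (method == "exact") {
    cdf_negative_binomial(model, N)
  } else {
    out <- numeric(length(N))
    out[N >= 1] <- cdf_gamma_discretised(model, N[N >= 1])
    out
  }
}

#' Expected binary weight under repeated depression trials
#'
#' Starting from \code{w = 1}, the expected weight after \code{N}
#' depression trials is \code{<w> = 1 - Q_k(N)}, the mirror image of
#' \code{\link{expected_weight_potentiation}} with the depression device's
#' parameters (\code{q}, \code{mu = -log(1 - q)}).
#'
#' @param model a \code{\link{gamma_switch_model}} for the depression
#'   device (its \code{p} plays the role of \code{q}).
#' @inheritParams expected_weight_potentiation
#' @return Expected weights in [0, 1].
#' @export
expected_weight_depression <- function(model, N, method = c("exact", "gamma")) {
  1 - expected_weight_potentiation(model, N, method = method)
}

#' Log-normal device-to-device sigma spanning a multiplicative range
#'
#' SET times of oxide memristors scatter over a multiplicative
#' \code{total_range} in the literature, of which a factor
#' \code{cycle_range} is cycle-to-cycle (already captured by the
#' exponential SET statistics). The residual device-to-device range is
#' \code{total_range / cycle_range}; assuming log-normal SET times
#' \code{tau = tau0 * exp(sigma * r)} with standard-normal \code{r}, the
#' sigma whose \code{[-nsigma, +nsigma]} section covers that multiplicative
#' range is \code{log(device_range) / (2 * nsigma)}.
#'
#' @param total_range total multiplicative SET-time scattering (e.g. 1e4).
#' @param cycle_range cycle-to-cycle multiplicative factor (e.g. 50).
#' @param nsigma half-width of the covering section in sigma units
#'   (default 3).
#' @return The log-normal standard deviation sigma.
#' @examples
#' sigma_for_variability_range(1e4, 50)  # 0.883...
#' @export
sigma_for_variability_range <- function(total_range, cycle_range, nsigma = 3) {
  if (!is.finite(total_range) || !is.finite(cycle_range) ||
      cycle_range <= 1 || total_range <= cycle_range)
    stop("need total_range > cycle_range > 1")
  if (!is.finite(nsigma) || nsigma <= 0)
    stop("'nsigma' must be positive")
  device_range <- total_range / cycle_range
  log(device_range) / (2 * nsigma)
}

#' Export expected-weight curves as a data frame
#'
#' Tabulates the cumulative switching probability / expected-weight curves
#' for a set of device lengths at a common rate, in long format suitable
#' for CSV export or plotting.
#'
#' @param k integer vector of device lengths.
#' @param p per-pulse SET probability shared by all curves.
#' @param N_max largest trial count (curves run over N = 0..N_max).
#' @param direction \code{"potentiation"} or \code{"depression"}.
#' @param method passed to the expected-weight functions.
#' @return A data frame with columns \code{k}, \code{N}, \code{value}.
#' @export
expected_weight_curves <- function(k, p, N_max = 200,
                                   direction = c("potentiation", "depression"),
                                   method = "exact") {
  direction <- match.arg(direction)
  fn <- if (direction == "potentiation") expected_weight_potentiation
        else expected_weight_depression
  N <- 0:N_max
  do.call(rbind, lapply(k, function(kk) {
    m <- gamma_switch_model(k = kk, p = p)
    data.frame(k = kk, N = N, value = fn(m, N, method = method))
  }))
}
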