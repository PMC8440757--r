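---
title: "Sigmoidal stochastic S-STDP with serial-memristor binary synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sigmoidal stochastic S-STDP with serial-memristor binary synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigstdp)
```

## The model

Simplified STDP (S-STDP) replaces the exponential timing kernel of standard
spike timing-dependent plasticity with a rectangular window: when a
postsynaptic neuron fires at time $t_{post}$, every afferent synapse whose
most recent presynaptic spike satisfies $0 < t_{post} - t_{pre} < T$ is
potentiated, and **all** other afferents are depressed. Because each fire
potentiates the in-window set and depresses the rest, the sum of afferent
weights is driven towards a stationary value set by the
potentiation/depression balance — synaptic normalisation is inherent in the
rule rather than an extra mechanism.

For binary synapses ($w \in \{0, 1\}$) the update is stochastic: a
potentiation trial flips $0 \to 1$ with probability $p$ and a depression
trial flips $1 \to 0$ with probability $q$. With constant $p$ and $q$
("conventional" stochastic S-STDP) the expected weight after $N$
same-direction trials is exponential-saturating,

$$\langle w \rangle = 1 - (1-p)^N = 1 - e^{-\lambda N}, \qquad
  \lambda = -\ln(1 - p),$$

so most of the change happens in the first few trials. That steep start is
exactly what makes memories fragile: a handful of postsynaptic fires driven
by a new stimulus is enough to overwrite a learned weight pattern.

The package implements the alternative studied here: make the *cumulative*
flip probability sigmoidal in $N$, so that a weight resists the first few
opposing trials and then commits. The physical realisation is a switching
device of $k$ binary memristors in series. Each voltage pulse can SET only
the first still-unset element (the pulse only reaches it through already
conducting predecessors), with per-pulse probability
$p = 1 - e^{-\Delta t / \tau}$, and the device conducts only when all $k$
elements have SET. The pulse count at which the device turns ON therefore
follows a negative binomial law $\mathrm{NB}(k, p)$ — the discrete
counterpart of a gamma distribution with shape $k$ — and the cumulative ON
probability

$$P_k(N) = \Pr[\text{at least } k \text{ successes in } N
  \text{ Bernoulli}(p) \text{ trials}]$$

is sigmoidal in $N$ for every $k \ge 2$ (`cdf_negative_binomial()`). The
continuous approximation

$$P_k(N) \approx \frac{\lambda^k}{(k-1)!} \sum_{n=0}^{N-1} n^{k-1}
  e^{-\lambda n}$$

is provided as `cdf_gamma_discretised()`; it converges to the exact
discrete law as $p \to 0$ and is used only in convergence checks, never in
the learning path. A synapse (`binary_synapse`) pairs one such device for
potentiation (counters $m_1 \dots m_k$) with one for depression
($n_1 \dots n_k$) and a latched binary weight: a potentiation trial resets
all $n_i$, attempts one SET on the first unset $m_i$, and latches $w = 1$
on the trial that completes the device; depression mirrors this.

### Why the latch

The two devices reset each other on every opposite-direction trial. If the
weight were read directly off $m_k$, a single depression trial would zero a
learned weight instantly, contradicting the requirement that depression
take of order $k/q$ trials. The package therefore treats the weight as a
separate latched bit — set when the potentiation device completes, cleared
when the depression device completes — which matches the paired-device
synaptic circuit the model describes. A completed device stays ON until the
first opposite-direction trial re-initialises it; the alternative
convention (immediate re-initialisation on latch flip) is available via
`reset_on_complete` in `rule_config()` and changes none of the headline
behaviour, because a completed device's further same-direction trials are
no-ops either way.

## Update-rule presets

`rule_preset()` exposes the parameter sets used throughout the benchmark
comparisons; all were chosen as the best-performing combinations for their
rule family:

| preset | rule | parameters |
|---|---|---|
| `deterministic` | continuous, linear weight-dependent | $\eta_+ = 0.04$, $\eta_- = 0.008$ |
| `conventional` | stochastic, $k=1$ | $p = 0.04$, $q = 0.008$ |
| `sigmoidal_k2`, `sigmoidal_k3` | stochastic | $p = 0.13$, $q = 0.03$ |
| `sigmoidal_k4` | stochastic | $p = 0.2$, $q = 0.08$ |
| `sigmoidal_k5` | stochastic | $p = 0.29$, $q = 0.12$ |
| `sigmoidal_pot_k3` / `sigmoidal_dep_k3` | mixed | sigmoidal one direction, conventional the other |

The deterministic rule moves a continuous weight by
$\Delta w = \eta_+ (w_{max} - w)$ or $-\eta_- (w - w_{min})$; repeated
updates follow exactly the same exponential trajectory as the $k = 1$
stochastic rule's expected weight, which is why those two are the matched
baselines for the sigmoidal model.

## The coincidence window T

The S-STDP window $T$ is a free parameter of the rule (`window_T`, ms).
`rule_config()` defaults to the conventional short coincidence window of
20 ms; the packaged benchmark recipes set it to 100 ms. The choice
matters through one mechanism:
an afferent driven at rate $r$ is in-window at a postsynaptic fire with
probability $\approx 1 - e^{-rT}$, and every *out-of-window* fire delivers
a depression trial that resets the potentiation device's progress. Small
$T$ (20 ms) leaves even strongly driven pixels out of window on a third of
fires, which stalls the $k \ge 2$ devices far more than the $k = 1$ rule
and biases any rule comparison; $T = 100$ ms puts pixels at the encoder's
upper rate range reliably in window while still depressing weakly driven
ones. Sensitivity is easy to explore (`rule_preset(name, window_T = ...)`);
orderings among rules reported by the experiment recipes are stable for
$T$ between 50 and 100 ms, with absolute accuracies a few points lower at
50 ms.

## The two-layer winner-take-all network

`snn_network()` builds the standard two-layer unsupervised digit-learning
circuit: $n_{input}$ Poisson input nodes (one per pixel, rate =
intensity / 4 Hz, so 8-bit images span 0–63.75 Hz; 350 ms per image
followed by a 150 ms silent rest), all-to-all plastic synapses onto
$n_{exc}$ excitatory conductance-based LIF neurons, each paired with one
inhibitory neuron that inhibits every *other* excitatory neuron
(winner-take-all). Excitatory↔inhibitory connections are fixed. Neuron
constants follow the conductance-LIF design that this family of
digit-learning networks standardised (rest −65 mV, threshold −52 mV,
membrane constants 100 ms / 10 ms, refractory 5 ms / 2 ms, reversal
potentials 0 / −100 mV, conductance decays 1 ms / 2 ms, pairing weight
10.4); all live in `network_config()` and are overridable. Excitatory
spikes trigger the S-STDP update; an afferent that has never spiked is
treated as out-of-window and depressed.

Two constants are deliberately adapted to the 40-neuron operating point
rather than copied from the 400-neuron reference design:

* **Lateral inhibition `w_ie = 8`** gives winner-take-*most* competition
  (the winner claims ~25% of the spikes of a presentation). With the
  reference value 17 at this scale, a single neuron fires per image and
  losing neurons are never updated — every rule's memories then look
  perfectly stable and the update rules become indistinguishable. Soft
  competition keeps non-winning neurons participating in plasticity,
  which is the regime in which memory stability is actually exercised.
* **Adaptive threshold with a real steady state.** Each excitatory spike
  increments the neuron's threshold offset $\theta$ by `theta_plus`
  (0.05 mV) and $\theta$ decays with `tau_theta` = 100 s, so sustained
  training drives $\theta$ to a stable equilibrium instead of growing
  without bound. With an effectively non-decaying $\theta$, thresholds
  inflate until the network falls silent under the long continued-training
  protocols used here.

$\theta$ adaptation, like the synaptic updates, runs only during
learning; recognition passes (`plasticity = FALSE`) leave the whole
learned state untouched.

Integration is clock-driven at $dt = 0.5$ ms with exact exponential
conductance decay; per-step input spikes are Bernoulli with probability
$r \, dt$. Simultaneously firing neurons apply their plasticity in neuron
index order (ties are rare at this $dt$ and the order is documented rather
than randomised, keeping runs bit-reproducible).

## Evaluation protocols

All protocols run with frozen synapses ("learning and recognition phases
are separate"):

* **Assignment** (`assign_digits`): each neuron's *memorised label* is the
  label of the single evaluation image for which it fired most; ties break
  to the earliest presentation; silent neurons stay unassigned and never
  count as retaining or representative. (The class-averaged alternative
  reading of "fires most frequently" is deliberately not the default: the
  per-image argmax is what the protocol text states.)
* **Recognition accuracy** (`recognition_accuracy`): per test image, the
  most active neuron is the representative; success iff its memorised
  label equals the image label; images that elicit no spikes count as
  failures.
* **Memory maintenance** (`memory_maintenance`): train for initialisation,
  assign, keep training through a checkpoint schedule in one continuing
  run, re-assign at each checkpoint; retention = number of neurons whose
  memorised label is unchanged from the initial assignment.
* **Sequential overwrite** (`sequential_overwrite_benchmark`): train
  phase-by-phase on single classes and count, after each phase, how many
  neurons still memorise each earlier class. The full-scale protocol is
  6,000 images of one digit, then 3,000 of a second, then 3,000 of a
  third; the scaled preset keeps the 2:1:1 ratio at 60/30/30.

## The synthetic pattern generator

`synthetic_pattern_spec()` / `generate_dataset()` provide a five-class,
10×10, graded-intensity pattern set (bar, cross, diagonal, blob, ring)
standing in for the 28×28 handwritten-digit benchmark, with the identical
statistical role: intensities in [0, 255] drive Poisson rates through the
same encoder. Intra-class variability is multiplicative log-normal pixel
noise (amplitude 0.25) plus ±1-pixel translation — enough that the classes
are non-trivial (a shift-aware nearest-prototype classifier scores ≥ 95%,
not 100%, on typical draws) while keeping winner-take-all specialisation
achievable with tens of neurons. What the fixtures do *not* emulate:
within-class style diversity (every image of a class is one jittered
prototype), class imbalance, and the 7.8× higher input dimensionality of
real digits. Passing the scaled benchmarks therefore demonstrates the
rule orderings under controlled conditions, not absolute accuracy on real
handwriting.

Real digit data in IDX containers can be used instead via `read_idx()`
(gzip accepted); `dataset_to_idx()` exports the synthetic sets to the same
format so both paths are uniform.

## Scaled benchmark conditions

The packaged experiment recipes (`run_experiment()`) run the full
protocols at desk scale: 100 inputs → 40 excitatory neurons, 1,200
initialisation samples, maintenance checkpoints at 600/1,200/2,400 extra
samples, 100-image evaluation sets, and five replicate seeds where a
median or majority is reported. The sample counts keep the per-neuron
training dose (30 initialisation samples per neuron, extra training up to
2× initialisation) in the same regime as the full-scale protocol
(10,000 samples over 400 neurons, extra training to 15×); recognition
accuracy for all rule families is evaluated at the final checkpoint,
i.e. after sustained training, which is where the update rules differ.
The architecture itself supports the full 784 → 400/1,600/6,400 sizes
unchanged. The sequential-overwrite preset trains 1,600/800/800
single-class samples, preserving the full protocol's 2:1:1 phase ratio at
a per-neuron dose (40/20/20) about twice the full-scale one — the
smallest dose at which the last phase fully converts the network under
the conventional rule, so the overwrite-versus-coexistence contrast is
observable. Device variability studies
sweep the log-normal $\sigma$ over 0–2; the literature-derived estimate
for real oxide memristors is
$\sigma = \ln\!\big(10^4 / 50\big)/6 \approx 0.88$
(`sigma_for_variability_range()`): a total SET-time scattering of four
orders of magnitude, of which a factor 50 is cycle-to-cycle, leaves a
multiplicative device-to-device range of 200 to be covered by the
$\pm 3\sigma$ section.

## Numerical choices and degenerate inputs

* `cdf_negative_binomial()` evaluates the binomial upper tail through
  `stats::pbinom`, exact to machine precision for the small $k$ used here;
  the test suite checks it against exhaustive $2^N$ enumeration.
* The discretised gamma sum is evaluated as written, including its
  $N - 1$ upper limit; the off-by-one relative to the discrete law is part
  of the approximation error budget (max deviation < 0.05 for
  $p \le 0.05$, $k \le 4$) and the function is deliberately not clamped
  to [0, 1].
* Variability draws are quenched: per-memristor $\tau_i$ once at
  construction, never per trial. The median of the per-element
  probabilities equals the nominal $p$ (log-normal median property), so
  variability widens but does not bias the device statistics.
* Binary weights initialise as independent Bernoulli(0.5); the
  deterministic rule initialises uniformly on [0, 1] (mean 0.5) so all
  rules start at the same expected afferent weight sum.
* Degenerate inputs error early: empty datasets, non-increasing
  maintenance schedules, out-of-bounds probabilities, negative
  intensities, truncated IDX files, non-finite membrane potentials.

## Known limitations

* The clock-driven simulator has two engines — a compiled loop (default)
  and a pure-R reference — that produce bit-identical trajectories; a
  350 ms presentation over 100×40 synapses takes ~7 ms of wall time.
  Full-scale (784×6,400, 150,000-sample) replications remain outside the
  scope of the packaged recipes; the scaled protocols above are the
  supported regime.
* The inhibitory delivery delay (one clock step) and inhibition strength
  approximate the deferred reference design; they are configuration keys,
  not fitted values.
* The memristor model assumes exponential SET statistics per element;
  non-exponential short-pulse kinetics and RESET-side stochasticity are
  out of scope.
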