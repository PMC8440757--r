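test_that("trial semantics: resets, certain and impossible SETs, latch behaviour", {
  set.seed(1)
  # certain SET completes the device and latches the weight
  syn <- binary_synapse(k = 2, p = 1 - 1e-12, q = 0.5)
  syn$pot$set_count <- 1L
  syn$dep$set_count <- 1L
  syn <- potentiation_trial(syn)
  expect_equal(syn$pot$set_count, 2L)
  expect_equal(syn$weight, 1L)
  expect_equal(syn$dep$set_count, 0L)   # opposite counters reset

  # impossible SET leaves the device untouched (except the n-reset)
  syn2 <- binary_synapse(k = 3, p = 1e-12, q = 0.5)
  syn2$dep$set_count <- 2L
  syn2 <- potentiation_trial(syn2)
  expect_equal(syn2$pot$set_count, 0L)
  expect_equal(syn2$weight, 0L)
  expect_equal(syn2$dep$set_count, 0L)

  # k = 1 certain depression flips a set weight in one trial
  syn3 <- binary_synapse(k = 1, p = 0.5, q = 1 - 1e-12, weight = 1L)
  syn3 <- depression_trial(syn3)
  expect_equal(syn3$weight, 0L)

  # an ON device stays ON across same-direction trials (latch), and the
  # first opposite trial resets it
  syn4 <- binary_synapse(k = 2, p = 1 - 1e-12, q = 1e-12)
  syn4 <- potentiation_trial(potentiation_trial(syn4))
  expect_equal(syn4$pot$set_count, 2L)
  syn4 <- potentiation_trial(syn4)            # no change beyond n-reset
  expect_equal(syn4$pot$set_count, 2L)
  expect_equal(syn4$weight, 1L)
  syn4 <- depression_trial(syn4)
  expect_equal(syn4$pot$set_count, 0L)
  expect_equal(syn4$weight, 1L)               # weight latched until dep completes
})

test_that("alternating trials with k = 2 never complete either device", {
  # each direction resets the other's progress; single successes never
  # accumulate to k = 2, so the weight never flips even with p = q = 1
  syn <- binary_synapse(k = 2, p = 1 - 1e-12, q = 1 - 1e-12, weight = 0L)
  for (i in 1:10) {
    syn <- potentiation_trial(syn)
    expect_lte(syn$pot$set_count, 1L)
    syn <- depression_trial(syn)
    expect_lte(syn$dep$set_count, 1L)
    expect_equal(syn$weight, 0L)
  }
})

test_that("prefix invariant holds under randomised trial sequences", {
  set.seed(7)
  for (rep in 1:30) {
    k <- sample(1:4, 1)
    syn <- binary_synapse(k = k, p = runif(1, 0.1, 0.9),
                          q = runif(1, 0.1, 0.9))
    for (trial in 1:50) {
      syn <- if (runif(1) < 0.5) potentiation_trial(syn)
             else depression_trial(syn)
      expect_gte(syn$pot$set_count, 0L)
      expect_lte(syn$pot$set_count, k)
      expect_gte(syn$dep$set_count, 0L)
      expect_lte(syn$dep$set_count, k)
      # the two devices never hold progress simultaneously after a trial
      expect_true(syn$pot$set_count == 0L || syn$dep$set_count == 0L)
    }
  }
})

test_that("Monte-Carlo ON fraction matches the exact discrete law", {
  set.seed(11)
  n_dev <- 20000
  for (par in list(c(2, 0.5), c(3, 0.13))) {
    k <- par[1]; p <- par[2]
    mdl <- gamma_switch_model(k, p = p)
    rc <- rule_config("stochastic", k = k, p = p, q = 0.5)
    ps <- plastic_synapses(n_dev, 1, rc, init_density = 0)
    checks <- c(1, 5, 10, 25)
    for (N in 1:25) {
      ps <- on_post_spike(ps, 1, rep(TRUE, n_dev))
      if (N %in% checks) {
        exact <- cdf_negative_binomial(mdl, N)
        se <- sqrt(max(exact * (1 - exact), 1e-9) / n_dev)
        expect_lt(abs(mean(ps$W) - exact), 3 * se + 1e-9)
      }
    }
  }
})

test_that("device ON-times are negative-binomial distributed (goodness of fit)", {
  set.seed(13)
  n_dev <- 20000
  k <- 3; p <- 0.3
  rc <- rule_config("stochastic", k = k, p = p, q = 0.5)
  ps <- plastic_synapses(n_dev, 1, rc, init_density = 0)
  on_at <- rep(NA_integer_, n_dev)
  for (N in 1:120) {
    before <- ps$W
    ps <- on_post_spike(ps, 1, rep(TRUE, n_dev))
    newly <- which(before == 0L & ps$W == 1L)
    on_at[newly] <- N
    if (!anyNA(on_at)) break
  }
  obs <- on_at[!is.na(on_at)]
  # bin ON-times; expected from the NB pmf (failures before the k-th success)
  breaks <- c(k:24, Inf)
  ecounts <- table(cut(obs, c(breaks[1] - 1, breaks)))
  probs <- diff(c(0, stats::pnbinom(breaks - k, size = k, prob = p)))
  keep <- probs * length(obs) >= 5
  chi <- sum((as.numeric(ecounts[keep]) - probs[keep] * length(obs))^2 /
               (probs[keep] * length(obs)))
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("weight flips require >= k uninterrupted same-direction trials", {
  set.seed(17)
  k <- 3
  syn <- binary_synapse(k = k, p = 0.6, q = 0.6)
  pot_streak <- 0; dep_streak <- 0
  for (trial in 1:400) {
    pot <- runif(1) < 0.5
    w_before <- syn$weight
    if (pot) { pot_streak <- pot_streak + 1; dep_streak <- 0
               syn <- potentiation_trial(syn) }
    else     { dep_streak <- dep_streak + 1; pot_streak <- 0
               syn <- depression_trial(syn) }
    if (syn$weight > w_before) expect_gte(pot_streak, k)
    if (syn$weight < w_before) expect_gte(dep_streak, k)
  }
})

test_that("variability draws have the log-normal median and sigma = 0 collapses", {
  dev0 <- sample_device(4, 0.2, variability_spec(sigma = 0))
  expect_equal(dev0$per_p, rep(0.2, 4))
  # delta_t recovery: with delta_t = -ln(1 - p) * tau0 the nominal element
  # gets back exactly p_nominal
  expect_equal(p_from_pulse(-log(1 - 0.2) * 2.5, 2.5), 0.2, tolerance = 1e-12)
  set.seed(19)
  pp <- sigstdp:::sample_element_probs(1e5, 0.2, variability_spec(sigma = 1))
  expect_true(all(pp > 0 & pp < 1))
  # median of exp(sigma r) is 1, so the median per-element p is p_nominal
  expect_lt(abs(stats::median(pp) - 0.2), 0.005)
  expect_error(sample_device(3, 1.5, variability_spec(1)), "0, 1")
  expect_error(variability_spec(sigma = -1))
})

test_that("synapse state round-trips through its serialised form", {
  set.seed(23)
  syn <- binary_synapse(k = 3, p = 0.4, q = 0.2, k_dep = 2,
                        pot_per_p = c(0.3, 0.4, 0.5), dep_per_p = c(0.2, 0.25))
  syn <- potentiation_trial(potentiation_trial(syn))
  st <- synapse_state(syn)
  syn2 <- restore_synapse_state(st)
  expect_equal(syn2$pot$set_count, syn$pot$set_count)
  expect_equal(syn2$dep$set_count, syn$dep$set_count)
  expect_equal(syn2$weight, syn$weight)
  expect_equal(syn2$pot$per_p, syn$pot$per_p)
  expect_equal(syn2$dep$per_p, syn$dep$per_p)
})
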