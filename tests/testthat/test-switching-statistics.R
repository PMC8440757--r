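test_that("lambda/p conversions match their closed forms and reject bad input", {
  # frozen from a high-precision evaluation of -ln(0.96)
  expect_equal(lambda_from_p(0.04), 0.04082199452025513, tolerance = 1e-14)
  expect_equal(lambda_from_p(1 - exp(-1)), 1, tolerance = 1e-12)
  expect_lt(lambda_from_p(1e-9), 1.1e-9)          # lambda ~ p for small p
  expect_gt(lambda_from_p(0.5), lambda_from_p(0.3))  # monotone
  expect_error(lambda_from_p(0), "interval")
  expect_error(lambda_from_p(1), "interval")

  expect_equal(p_from_pulse(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(p_from_pulse(log(2), 1), 0.5, tolerance = 1e-12)
  expect_lt(p_from_pulse(1e-8, 1), 1e-7)
  expect_error(p_from_pulse(-1, 1), "positive")
  expect_error(p_from_pulse(1, 0), "positive")

  m <- gamma_switch_model(k = 2, p = 0.3)
  expect_equal(m$lambda, -log(0.7), tolerance = 1e-14)
  m2 <- gamma_switch_model(k = 2, lambda = m$lambda)
  expect_equal(m2$p, 0.3, tolerance = 1e-14)
  expect_error(gamma_switch_model(k = 0, p = 0.5))
  expect_error(gamma_switch_model(k = 2.5, p = 0.5))
  expect_error(gamma_switch_model(k = 2, p = 0.5, lambda = 1))
})

test_that("exact device CDF matches brute-force enumeration and its k = 1 form", {
  # hand-enumerable cases
  expect_equal(cdf_negative_binomial(gamma_switch_model(1, p = 0.5), 2), 0.75)
  expect_equal(cdf_negative_binomial(gamma_switch_model(2, p = 0.5), 2), 0.25)
  expect_equal(cdf_negative_binomial(gamma_switch_model(2, p = 0.5), 3), 0.5)
  # exhaustive enumeration over all 2^N outcome sequences
  for (k in 1:4) for (p in c(0.3, 0.5)) {
    m <- gamma_switch_model(k, p = p)
    for (N in 0:8)
      expect_equal(cdf_negative_binomial(m, N),
                   enumerate_on_probability(k, p, N), tolerance = 1e-12)
  }
  # k = 1 closed form 1 - (1-p)^N
  for (p in c(0.04, 0.3, 0.9)) {
    m <- gamma_switch_model(1, p = p)
    N <- 0:60
    expect_equal(cdf_negative_binomial(m, N), 1 - (1 - p)^N,
                 tolerance = 1e-12)
  }
  expect_error(cdf_negative_binomial(gamma_switch_model(1, p = 0.5), -1))
})

test_that("both CDFs are monotone, bounded, and agree in the small-p limit", {
  for (k in 1:4) for (p in c(0.01, 0.05, 0.3)) {
    m <- gamma_switch_model(k, p = p)
    N <- 1:2000
    nb <- cdf_negative_binomial(m, N)
    expect_true(all(diff(nb) >= 0))
    expect_true(all(nb >= 0 & nb <= 1))
    expect_gt(nb[2000], 0.999)  # tends to 1
    ga <- cdf_gamma_discretised(m, N)
    expect_true(all(diff(ga) >= -1e-15))
    if (p <= 0.05) expect_lt(max(abs(ga - nb)), 0.05)
    if (p <= 0.01) expect_lt(max(abs(ga - nb)), 0.01)
  }
})

test_that("discretised gamma sum reproduces its closed forms", {
  # single-summand cases
  expect_equal(cdf_gamma_discretised(gamma_switch_model(2, lambda = 0.7), 1), 0)
  expect_equal(cdf_gamma_discretised(gamma_switch_model(1, lambda = 0.04), 1),
               0.04)
  # frozen high-precision evaluation of the k = 3, lambda = 0.13 sum at N = 50
  expect_equal(cdf_gamma_discretised(gamma_switch_model(3, lambda = 0.13), 50),
               0.95486749132172765, tolerance = 1e-12)
  # ... close to the exact discrete law at matched p = 1 - exp(-0.13)
  expect_equal(cdf_negative_binomial(gamma_switch_model(3, p = 0.121904569), 50),
               0.95256463493035665, tolerance = 1e-9)
  expect_lt(abs(0.95486749132172765 - 0.95256463493035665), 0.05)
  # k = 1 reduces to ~ 1 - exp(-lambda N) for small lambda
  m <- gamma_switch_model(1, lambda = 0.04)
  N <- 1:100
  expect_lt(max(abs(cdf_gamma_discretised(m, N) - (1 - exp(-0.04 * N)))), 0.05)
  expect_error(cdf_gamma_discretised(m, 0), "N")
})

test_that("expected weight curves are exponential for k = 1 and sigmoidal for k >= 2", {
  m1 <- gamma_switch_model(1, lambda = 0.04)
  N <- 0:300
  w1 <- expected_weight_potentiation(m1, N)
  expect_equal(w1[1], 0)
  expect_equal(w1, 1 - exp(-0.04 * N), tolerance = 0.05)
  # steep start for k = 1: concave everywhere (negative second difference)
  d2 <- diff(diff(w1))
  expect_lt(d2[1], 0)
  expect_true(all(d2 < 1e-12))

  for (k in 2:4) {
    mk <- gamma_switch_model(k, lambda = 0.04)
    wk <- expected_weight_potentiation(mk, N)
    expect_equal(wk[1], 0)
    expect_true(all(diff(wk) >= 0))
    d2k <- diff(diff(wk))
    # gentle start: curvature is zero until N = k - 1, then positive --
    # the first non-zero second difference is positive, unlike k = 1
    first_nz <- which(abs(d2k) > 1e-15)[1]
    expect_equal(first_nz, max(k - 1, 1))
    expect_gt(d2k[first_nz], 0)
    expect_lt(min(d2k), 0)         # ... then concave: an inflection at N > 1
    inflection <- which(d2k < 0)[1]
    expect_gt(inflection, 1)
    # the k >= 2 curve lies below k = 1 early and crosses 0.5 later
    expect_true(all(wk[2:50] < w1[2:50]))
    expect_gt(which(wk >= 0.5)[1], which(w1 >= 0.5)[1])
  }
})

test_that("depression is the exact mirror of potentiation", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(1:5, 1)
    q <- runif(1, 0.01, 0.9)
    N <- sample(0:200, 5)
    m <- gamma_switch_model(k, p = q)
    expect_equal(expected_weight_depression(m, N),
                 1 - expected_weight_potentiation(m, N), tolerance = 1e-15)
  }
  m <- gamma_switch_model(1, p = 1 - exp(-0.008))
  N <- 0:500
  expect_equal(expected_weight_depression(m, N), exp(-0.008 * N),
               tolerance = 0.01)
  expect_equal(expected_weight_depression(m, 0), 1)
})

test_that("variability sigma spans the multiplicative device range", {
  # total scattering 1e4, cycle-to-cycle factor 50 -> device range 200
  expect_equal(1e4 / 50, 200)
  sg <- sigma_for_variability_range(1e4, 50, nsigma = 3)
  expect_equal(sg, log(200) / 6, tolerance = 1e-14)
  expect_equal(round(sg, 2), 0.88)
  expect_equal(sigma_for_variability_range(exp(6) * 2, 2, nsigma = 3), 1,
               tolerance = 1e-12)
  expect_lt(sigma_for_variability_range(2 * (1 + 1e-9), 2), 1e-9)
  expect_error(sigma_for_variability_range(10, 50), "range")
})

test_that("curve export tabulates one row per (k, N)", {
  cv <- expected_weight_curves(c(1, 3), 0.13, N_max = 50)
  expect_equal(nrow(cv), 2 * 51)
  expect_named(cv, c("k", "N", "value"))
  expect_true(all(cv$value >= 0 & cv$value <= 1))
  dens <- gamma_switch_density(c(0.5, 1), k = 2, tau = 1)
  expect_equal(dens, c(0.5 * exp(-0.5), exp(-1)), tolerance = 1e-12)
})
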