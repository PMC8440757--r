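test_that("encoder converts intensities to Poisson rates at intensity/4 Hz", {
  spec <- encoder_spec(pixels = 3, presentation_ms = 4000)
  set.seed(47)
  img <- c(0, 100, 255)
  sp <- encode_image(img, spec, dt = 0.5)
  expect_equal(dim(sp), c(8000, 3))
  expect_equal(sum(sp[, 1]), 0)                 # zero intensity -> silence
  # empirical rates over 4 s within 4 SE of intensity/4 Hz
  for (j in 2:3) {
    rate <- img[j] / 4
    n_exp <- rate * 4
    expect_lt(abs(sum(sp[, j]) - n_exp), 4 * sqrt(n_exp))
  }
  # max-intensity pixel: 63.75 Hz -> 22.31 expected spikes per 350 ms
  spec350 <- encoder_spec(pixels = 1, presentation_ms = 350)
  counts <- replicate(200, sum(encode_image(255, spec350)))
  expect_lt(abs(mean(counts) - 63.75 * 0.350), 3 * sd(counts) / sqrt(200))
  expect_error(encode_image(c(-1, 0, 0), spec), "negative")
  expect_error(encode_image(c(0, 0), spec), "size")
})

test_that("silent network decays to rest and strong drive triggers lateral inhibition", {
  set.seed(53)
  net <- snn_network(10, 4, rule = rule_preset("conventional"))
  net$v_e <- rep(-55, 4)  # displaced from rest
  for (i in 1:400) {
    st <- step_network(net, NULL, plasticity = FALSE)
    net <- st$net
    expect_length(st$fired, 0)
  }
  expect_equal(net$v_e, rep(-65, 4), tolerance = 0.1)

  # drive only neuron 1's afferents: it fires, the others get inhibited
  net2 <- snn_network(10, 4, rule = rule_preset("conventional"))
  net2$ps$W[] <- 0L
  net2$ps$W[, 1] <- 1L
  fired_any <- FALSE; inhibited <- FALSE
  for (i in 1:700) {
    st <- step_network(net2, rep(TRUE, 10), plasticity = FALSE)
    net2 <- st$net
    if (1 %in% st$fired) fired_any <- TRUE
    if (any(net2$g_i_e[2:4] > 0)) inhibited <- TRUE
  }
  expect_true(fired_any)
  expect_true(inhibited)
  expect_true(all(net2$v_e[2:4] < -64))  # pushed below rest by inhibition
})

test_that("two-neuron circuit specialises to orthogonal patterns (and not without inhibition)", {
  pats <- orthogonal_patterns()
  # quickly imprinting k = 1 rule so specialisation resolves within a few
  # presentation cycles
  fast_rule <- rule_config("stochastic", k = 1, p = 0.2, q = 0.05)
  run_one <- function(seed, w_ie) {
    set.seed(seed)
    enc <- encoder_spec(pixels = 100, presentation_ms = 150, rest_ms = 50)
    cfg <- network_config(w_ie = w_ie, theta_plus = 0.3)
    net <- snn_network(100, 2, rule = fast_rule, enc = enc, cfg = cfg)
    for (i in 1:10) {
      net <- present_image(net, pats$a)$net
      net <- present_image(net, pats$b)$net
    }
    ca <- present_image(net, pats$a, plasticity = FALSE)
    cb <- present_image(ca$net, pats$b, plasticity = FALSE)
    pref_a <- which.max(ca$counts + c(0, -0.5))   # deterministic tie-break
    pref_b <- which.max(cb$counts + c(0, -0.5))
    sum(ca$counts) > 0 && sum(cb$counts) > 0 && pref_a != pref_b
  }
  with_inh <- mean(vapply(1:20, function(s) run_one(s, w_ie = 17), logical(1)))
  expect_gte(with_inh, 0.9)
  # negative control: no lateral inhibition, no winner-take-all
  no_inh <- mean(vapply(1:20, function(s) run_one(s, w_ie = 0), logical(1)))
  expect_lt(no_inh, with_inh)
})

test_that("homeostatic threshold prevents a runaway winner", {
  set.seed(59)
  pats <- orthogonal_patterns()
  enc <- encoder_spec(pixels = 100, presentation_ms = 150, rest_ms = 50)
  net <- snn_network(100, 4, rule = rule_preset("conventional"), enc = enc,
                     cfg = network_config(theta_plus = 0.3))
  total <- integer(4)
  for (i in 1:14) {
    r <- present_image(net, if (i %% 2) pats$a else pats$b)
    net <- r$net
    total <- total + r$counts
  }
  expect_gt(sum(total), 0)
  expect_lt(max(total) / sum(total), 0.9)  # no single neuron takes all spikes
  # refractory bound: spikes per presentation can never exceed duration/refractory
  expect_lt(max(total) / 14, 150 / net$cfg$refrac_e)
})

test_that("training is reproducible and leaves weights untouched when frozen", {
  spec <- toy_spec()
  d <- generate_dataset(spec, 2, seed = 61)
  mk <- function(seed) {
    set.seed(seed)
    snn_network(100, 6, rule = rule_preset("sigmoidal_k3"))
  }
  net <- mk(62)
  W0 <- net$ps$W
  frozen <- train_network(net, d, plasticity = FALSE)
  expect_identical(frozen$net$ps$W, W0)         # bit-identical

  set.seed(63); r1 <- train_network(mk(62), d)
  set.seed(63); r2 <- train_network(mk(62), d)
  expect_identical(r1$net$ps$W, r2$net$ps$W)    # same seed, same weights
  expect_identical(r1$counts, r2$counts)
  expect_error(train_network(net, list(images = matrix(0, 0, 100))), "empty")
})

test_that("step-wise and batched presentation produce the same dynamics", {
  spec <- toy_spec()
  d <- generate_dataset(spec, 1, seed = 67)
  set.seed(68)
  net_a <- snn_network(100, 5, rule = rule_preset("conventional"),
                       enc = encoder_spec(pixels = 100, presentation_ms = 50,
                                          rest_ms = 10))
  set.seed(68)
  net_b <- snn_network(100, 5, rule = rule_preset("conventional"),
                       enc = encoder_spec(pixels = 100, presentation_ms = 50,
                                          rest_ms = 10))
  set.seed(69)
  res <- present_image(net_a, d$images[1, ])
  set.seed(69)
  sp <- encode_image(d$images[1, ], net_b$enc, net_b$cfg$dt)
  counts <- integer(5)
  for (s in 1:nrow(sp)) {
    st <- step_network(net_b, sp[s, ])
    net_b <- st$net
    counts[st$fired] <- counts[st$fired] + 1L
  }
  for (s in 1:round(10 / net_b$cfg$dt)) net_b <- step_network(net_b, NULL)$net
  expect_equal(res$counts, counts)
  expect_equal(res$net$v_e, net_b$v_e, tolerance = 1e-10)
  expect_identical(res$net$ps$W, net_b$ps$W)
})

test_that("network checkpoints round-trip through JSON", {
  spec <- toy_spec()
  d <- generate_dataset(spec, 1, seed = 71)
  set.seed(72)
  net <- snn_network(100, 4, rule = rule_preset("sigmoidal_k3"),
                     enc = encoder_spec(pixels = 100, presentation_ms = 50,
                                        rest_ms = 0))
  net <- present_image(net, d$images[1, ])$net
  path <- tempfile(fileext = ".json")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_equal(net2$ps$W, net$ps$W)
  expect_equal(net2$ps$M, net$ps$M)
  expect_equal(net2$v_e, net$v_e, tolerance = 1e-12)
  expect_equal(net2$theta, net$theta, tolerance = 1e-12)
  expect_equal(net2$last_pre, net$last_pre)
  # restored network keeps simulating identically
  set.seed(73); a <- present_image(net, d$images[1, ])
  set.seed(73); b <- present_image(net2, d$images[1, ])
  expect_equal(a$counts, b$counts)
  unlink(path)
})
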