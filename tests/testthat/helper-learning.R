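# Shared scaled-down learning benchmark, computed once and reused by the
# acceptance tests: the maintenance/accuracy comparison across the three
# rule families (5 seeds) and the sequential-overwrite contrast (3 seeds),
# at the package's frozen study conditions (100 inputs -> 40 neurons,
# 1200-sample initialisation, checkpoints +600/+1200/+2400, 100-image
# evaluation sets, window_T = 100 ms).

benchmark_rule_run <- function(preset, seed) {
  set.seed(seed)
  spec <- synthetic_pattern_spec()
  init <- generate_dataset(spec, 240, seed = seed * 10 + 1)
  extra <- generate_dataset(spec, 480, seed = seed * 10 + 4)
  ev <- generate_dataset(spec, 20, seed = seed * 10 + 2)
  te <- generate_dataset(spec, 20, seed = seed * 10 + 3)
  net <- snn_network(100, 40, rule = rule_preset(preset, window_T = 100))
  tr <- train_network(net, init)
  net <- tr$net
  a0 <- assign_digits(net, ev)
  retained <- c(40L)
  prev <- 0L
  a1 <- a0
  for (cp in c(600, 1200, 2400)) {
    idx <- (prev + 1L):cp
    net <- train_network(net, list(images = extra$images[idx, , drop = FALSE],
                                   labels = extra$labels[idx]))$net
    a1 <- assign_digits(net, ev)
    retained <- c(retained, sum(!is.na(a0$labels) & !is.na(a1$labels) &
                                  a0$labels == a1$labels))
    prev <- cp
  }
  acc <- recognition_accuracy(net, a1, te)
  list(retained = retained, accuracy = acc, init_weight_sums = tr$weight_sums)
}

benchmark_overwrite_run <- function(preset, seed) {
  set.seed(seed)
  spec <- synthetic_pattern_spec()
  ev <- generate_dataset(spec, 20, seed = seed * 10 + 2)
  net <- snn_network(100, 40, rule = rule_preset(preset, window_T = 100))
  make_data <- function(label, n) {
    d <- generate_dataset(spec, n, seed = seed * 100 + label)
    keep <- which(d$labels == label)[seq_len(n)]
    list(images = d$images[keep, , drop = FALSE], labels = d$labels[keep])
  }
  sequential_overwrite_benchmark(
    net, phases = list(list(label = 1, n = 1600), list(label = 2, n = 800),
                       list(label = 3, n = 800)),
    make_data, ev)$class_counts
}

learning_suite <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    rules <- c("sigmoidal_k3", "deterministic", "conventional")
    runs <- lapply(rules, function(r)
      lapply(1:5, function(s) benchmark_rule_run(r, s)))
    names(runs) <- rules
    overwrite <- list(
      sigmoidal_k3 = lapply(1:3, function(s)
        benchmark_overwrite_run("sigmoidal_k3", s)),
      conventional = lapply(1:3, function(s)
        benchmark_overwrite_run("conventional", s)))
    cache <<- list(runs = runs, overwrite = overwrite)
    cache
  }
})

# per-neuron weight-sum variance averaged over neurons, for a quarter of
# the training trace
quarter_variance <- function(wsums, which_quarter) {
  n <- nrow(wsums)
  q <- n %/% 4
  rows <- if (which_quarter == "first") 1:q else (n - q + 1):n
  mean(apply(wsums[rows, , drop = FALSE], 2, stats::var))
}
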