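#' Experiment configuration
#'
#' Validated bundle of everything one reproducible experiment needs: the
#' update-rule preset, network and encoder sizes, the training schedule,
#' device variability, and seeding. All fields are checked before any
#' simulation starts, and the configuration is embedded in every results
#' bundle so outputs are self-describing.
#'
#' @param recipe one of \code{"train_evaluate"},
#'   \code{"maintenance_comparison"}, \code{"overwrite_benchmark"},
#'   \code{"sigma_sweep"}, \code{"device_curves"}.
#' @param rule name of a \code{\link{rule_preset}}, or a vector of names
#'   for comparison recipes.
#' @param n_exc excitatory neuron count.
#' @param grid_size,n_classes,n_per_class_train synthetic-pattern
#'   generator shape (input count is \code{grid_size^2}).
#' @param init_samples initialisation training sample count.
#' @param extra_checkpoints strictly increasing cumulative extra-training
#'   sample counts for maintenance curves.
#' @param overwrite_phases list of \code{list(label=, n=)} for the
#'   sequential-overwrite recipe.
#' @param n_eval evaluation images per assignment/accuracy pass.
#' @param sigma device-to-device log-normal sigma (or vector, for the
#'   sigma sweep).
#' @param window_T S-STDP window (ms), forwarded to the rule.
#' @param presentation_ms,rest_ms encoder timing.
#' @param seed master seed; expanded deterministically into per-component
#'   streams.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param net_cfg a \code{\link{network_config}}.
#' @return An object of class \code{experiment_config}.
#' @export
experiment_config <- function(recipe = "train_evaluate",
                              rule = "sigmoidal_k3",
                              n_exc = 40, grid_size = 10, n_classes = 5,
                              n_per_class_train = 240,
                              init_samples = 1200,
                              extra_checkpoints = c(600, 1200, 2400),
                              overwrite_phases = list(
                                list(label = 1, n = 1600),
                                list(label = 2, n = 800),
                                list(label = 3, n = 800)),
                              n_eval = 100, sigma = 0, window_T = 100,
                              presentation_ms = 350, rest_ms = 150,
                              seed = 1L, out_dir = NULL,
                              net_cfg = network_config()) {
  recipes <- c("train_evaluate", "maintenance_comparison",
               "overwrite_benchmark", "sigma_sweep", "device_curves")
  if (!recipe %in% recipes)
    stop("invalid recipe '", recipe, "'; valid: ",
         paste(recipes, collapse = ", "))
  valid_rules <- c("deterministic", "conventional", "sigmoidal_k2",
                   "sigmoidal_k3", "sigmoidal_k4", "sigmoidal_k5",
                   "sigmoidal_pot_k3", "sigmoidal_dep_k3")
  if (!all(rule %in% valid_rules))
    stop("invalid rule preset; valid: ", paste(valid_rules, collapse = ", "))
  if (any(diff(c(0, extra_checkpoints)) <= 0))
    stop("'extra_checkpoints' must be strictly increasing")
  if (any(sigma < 0)) stop("'sigma' must be >= 0")
  if (n_exc < 2 || grid_size < 4 || n_classes < 2)
    stop("network/generator sizes too small")
  stopifnot(init_samples >= n_classes, n_eval >= n_classes)
  cfg <- as.list(environment())
  cfg$recipes <- NULL; cfg$valid_rules <- NULL
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "experiment_config")
}

#' Deterministic per-component seed streams
#'
#' Expands one master seed into independent 31-bit seeds for the named
#' components (data generation, network construction, training,
#' evaluation, ...), so a component can be re-seeded without touching the
#' others.
#'
#' @param seed master seed (integer).
#' @param component character tag.
#' @param index optional extra index (e.g. replicate number).
#' @return A single integer seed in [0, 2^31).
#' @export
component_seed <- function(seed, component, index = 0L) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 16807 + index * 69621) %%
               2147483647)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass_deep(cfg))),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            4294967296)
}

build_toy_world <- function(cfg, rule_name, sigma = 0, seed = cfg$seed) {
  spec <- synthetic_pattern_spec(grid_size = cfg$grid_size,
                                 n_classes = cfg$n_classes)
  enc <- encoder_spec(pixels = cfg$grid_size^2,
                      presentation_ms = cfg$presentation_ms,
                      rest_ms = cfg$rest_ms)
  set.seed(component_seed(seed, "network"))
  net <- snn_network(cfg$grid_size^2, cfg$n_exc,
                     rule = rule_preset(rule_name, window_T = cfg$window_T),
                     enc = enc, cfg = cfg$net_cfg,
                     var = variability_spec(sigma = sigma))
  list(spec = spec, net = net)
}

#' Run a named experiment recipe
#'
#' Executes one of the packaged experiment recipes on the synthetic
#' pattern fixtures, fully deterministically given the configuration
#' seed:
#' \describe{
#'   \item{device_curves}{expected-weight curves for the configured rules
#'     (no network simulation).}
#'   \item{train_evaluate}{unsupervised training followed by assignment
#'     and recognition accuracy.}
#'   \item{maintenance_comparison}{memory-maintenance curves for each
#'     rule in \code{cfg$rule} at matched checkpoints.}
#'   \item{overwrite_benchmark}{sequential single-class training phases
#'     with per-phase assignment survival and weight maps.}
#'   \item{sigma_sweep}{train/evaluate at each device variability sigma.}
#' }
#' If \code{cfg$out_dir} is set, curves are written as CSV and the
#' configuration (with its hash and seed) as JSON alongside.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @return A results list; always contains \code{config} and
#'   \code{config_hash}.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  res <- switch(cfg$recipe,
    device_curves = recipe_device_curves(cfg),
    train_evaluate = recipe_train_evaluate(cfg),
    maintenance_comparison = recipe_maintenance(cfg),
    overwrite_benchmark = recipe_overwrite(cfg),
    sigma_sweep = recipe_sigma_sweep(cfg))
  res$config <- cfg
  res$config_hash <- config_hash(cfg)
  if (!is.null(cfg$out_dir)) write_results_bundle(res, cfg)
  res
}

recipe_device_curves <- function(cfg) {
  curves <- lapply(cfg$rule, function(rn) {
    rc <- rule_preset(rn)
    if (rc$rule == "deterministic") {
      N <- 0:200
      data.frame(rule = rn, direction = "potentiation", N = N,
                 value = 1 - (1 - rc$eta_plus)^N)
    } else {
      rbind(cbind(rule = rn, direction = "potentiation",
                  expected_weight_curves(rc$k, rc$p)),
            cbind(rule = rn, direction = "depression",
                  expected_weight_curves(rc$k_dep, rc$q,
                                         direction = "depression")))
    }
  })
  list(curves = do.call(rbind, lapply(curves, function(d)
    d[, c("rule", "direction", "N", "value")])))
}

recipe_train_evaluate <- function(cfg, rule_name = cfg$rule[1],
                                  sigma = cfg$sigma[1], seed = cfg$seed) {
  w <- build_toy_world(cfg, rule_name, sigma = sigma, seed = seed)
  train <- generate_dataset(w$spec, ceiling(cfg$init_samples / cfg$n_classes),
                            seed = component_seed(seed, "train-data"))
  train <- dataset_head(train, cfg$init_samples)
  evald <- generate_dataset(w$spec, ceiling(cfg$n_eval / cfg$n_classes),
                            seed = component_seed(seed, "eval-data"))
  testd <- generate_dataset(w$spec, ceiling(cfg$n_eval / cfg$n_classes),
                            seed = component_seed(seed, "test-data"))
  set.seed(component_seed(seed, "training"))
  tr <- train_network(w$net, train)
  assignment <- assign_digits(tr$net, evald)
  acc <- recognition_accuracy(tr$net, assignment, testd)
  list(net = tr$net, assignment = assignment, accuracy = acc,
       weight_sums = tr$weight_sums, counts = tr$counts)
}

recipe_maintenance <- function(cfg) {
  curves <- list()
  for (rn in cfg$rule) {
    w <- build_toy_world(cfg, rn, sigma = cfg$sigma[1])
    init <- generate_dataset(w$spec,
                             ceiling(cfg$init_samples / cfg$n_classes),
                             seed = component_seed(cfg$seed, "train-data"))
    init <- dataset_head(init, cfg$init_samples)
    extra <- generate_dataset(w$spec,
                              ceiling(max(cfg$extra_checkpoints) / cfg$n_classes),
                              seed = component_seed(cfg$seed, "extra-data"))
    evald <- generate_dataset(w$spec, ceiling(cfg$n_eval / cfg$n_classes),
                              seed = component_seed(cfg$seed, "eval-data"))
    set.seed(component_seed(cfg$seed, "training"))
    curves[[rn]] <- memory_maintenance(w$net, init, extra, evald,
                                       cfg$extra_checkpoints)
  }
  list(curves = curves)
}

recipe_overwrite <- function(cfg) {
  out <- list()
  for (rn in cfg$rule) {
    w <- build_toy_world(cfg, rn)
    evald <- generate_dataset(w$spec, ceiling(cfg$n_eval / cfg$n_classes),
                              seed = component_seed(cfg$seed, "eval-data"))
    make_data <- function(label, n) {
      d <- generate_dataset(w$spec, n,
                            seed = component_seed(cfg$seed, "phase", label))
      keep <- which(d$labels == label)[seq_len(n)]
      list(images = d$images[keep, , drop = FALSE], labels = d$labels[keep])
    }
    set.seed(component_seed(cfg$seed, "training"))
    out[[rn]] <- sequential_overwrite_benchmark(w$net, cfg$overwrite_phases,
                                                make_data, evald)
  }
  list(benchmarks = out)
}

recipe_sigma_sweep <- function(cfg) {
  acc <- vapply(cfg$sigma, function(sg)
    recipe_train_evaluate(cfg, sigma = sg)$accuracy, numeric(1))
  list(sweep = data.frame(sigma = cfg$sigma, accuracy = acc))
}

dataset_head <- function(d, n) {
  list(images = d$images[seq_len(n), , drop = FALSE],
       labels = d$labels[seq_len(n)], grid = d$grid, spec = d$spec)
}

write_results_bundle <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- paste0(cfg$recipe, "-seed", cfg$seed, "-", config_hash(cfg))
  jsonlite::write_json(unclass_deep(cfg),
                       file.path(cfg$out_dir, paste0(tag, "-config.json")),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  if (!is.null(res$curves) && is.data.frame(res$curves))
    utils::write.csv(res$curves,
                     file.path(cfg$out_dir, paste0(tag, "-curves.csv")),
                     row.names = FALSE)
  if (!is.null(res$curves) && is.list(res$curves) && !is.data.frame(res$curves)) {
    flat <- do.call(rbind, lapply(names(res$curves), function(rn)
      cbind(rule = rn, as.data.frame(res$curves[[rn]]))))
    utils::write.csv(flat,
                     file.path(cfg$out_dir, paste0(tag, "-curves.csv")),
                     row.names = FALSE)
  }
  if (!is.null(res$sweep))
    utils::write.csv(res$sweep,
                     file.path(cfg$out_dir, paste0(tag, "-sweep.csv")),
                     row.names = FALSE)
  if (!is.null(res$benchmarks)) {
    flat <- do.call(rbind, lapply(names(res$benchmarks), function(rn)
      cbind(rule = rn, phase = seq_len(nrow(res$benchmarks[[rn]]$class_counts)),
            as.data.frame(res$benchmarks[[rn]]$class_counts))))
    utils::write.csv(flat,
                     file.path(cfg$out_dir, paste0(tag, "-survivors.csv")),
                     row.names = FALSE)
  }
  invisible(tag)
}
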