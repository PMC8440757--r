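#' Present a dataset with frozen synapses and collect spike counts
#'
#' The recognition-phase primitive: every image is presented with
#' plasticity disabled and the per-neuron spike counts are recorded.
#'
#' @param net an \code{\link{snn_network}}.
#' @param dataset a dataset list (\code{images}, \code{labels}).
#' @return A list with \code{net} and the \code{counts} matrix
#'   (images x neurons).
#' @export
recognition_pass <- function(net, dataset) {
  res <- train_network(net, dataset, plasticity = FALSE)
  list(net = res$net, counts = res$counts)
}

#' Assign a memorised class label to every excitatory neuron
#'
#' Presents the evaluation images with plasticity disabled; each neuron's
#' memorised label is the label of the single image for which it fired
#' most, ties broken by the earliest presentation. A neuron that never
#' fires is left unassigned (NA) and never counts as retaining or
#' representative.
#'
#' @param net an \code{\link{snn_network}}.
#' @param dataset evaluation dataset (\code{images}, \code{labels}).
#' @param counts optional precomputed spike-count matrix from
#'   \code{\link{recognition_pass}} (skips re-presentation).
#' @return An object of class \code{assignment_table}: list with
#'   \code{labels} (integer per neuron, NA = unassigned), \code{counts},
#'   and \code{eval_labels}.
#' @export
assign_digits <- function(net, dataset, counts = NULL) {
  if (is.null(counts)) counts <- recognition_pass(net, dataset)$counts
  best_img <- max.col(t(counts), ties.method = "first")  # per neuron
  labels <- dataset$labels[best_img]
  labels[colSums(counts) == 0L] <- NA_integer_
  structure(list(labels = labels, counts = counts,
                 eval_labels = dataset$labels),
            class = "assignment_table")
}

#' Recognition accuracy on a test set
#'
#' For each test image the representative neuron is the one firing most
#' (ties to the lowest neuron index); recognition succeeds iff that
#' neuron's memorised label equals the image label. Images for which no
#' neuron fires, or whose representative is unassigned, count as
#' failures.
#'
#' @param net an \code{\link{snn_network}}.
#' @param assignment an \code{\link{assign_digits}} table.
#' @param dataset test dataset.
#' @param counts optional precomputed spike-count matrix.
#' @return Fraction of successful recognitions in [0, 1].
#' @export
recognition_accuracy <- function(net, assignment, dataset, counts = NULL) {
  stopifnot(inherits(assignment, "assignment_table"))
  if (is.null(counts)) counts <- recognition_pass(net, dataset)$counts
  rep_neuron <- max.col(counts, ties.method = "first")
  predicted <- assignment$labels[rep_neuron]
  predicted[rowSums(counts) == 0L] <- NA_integer_
  mean(!is.na(predicted) & predicted == dataset$labels)
}

#' Memory-maintenance curve under continued training
#'
#' The stability protocol: train the network on \code{init_data} for
#' initialisation, assign a memorised label to every neuron, then continue
#' training through the checkpoints of \code{extra_schedule} (cumulative
#' extra-sample counts), re-assigning after each. The retention at a
#' checkpoint is the number of neurons whose memorised label is unchanged
#' from the initial assignment; at zero extra training all \code{n_exc}
#' neurons trivially retain. One continuing run is used, with plasticity
#' frozen during assignment passes.
#'
#' @param net a freshly constructed \code{\link{snn_network}}.
#' @param init_data initialisation training dataset.
#' @param extra_data dataset supplying the extra training samples (must
#'   contain at least \code{max(extra_schedule)} images).
#' @param eval_data evaluation dataset for the assignment passes.
#' @param extra_schedule strictly increasing cumulative extra-sample
#'   counts.
#' @return An object of class \code{maintenance_curve}: data frame with
#'   columns \code{extra_training} and \code{retained}, plus attributes
#'   \code{n_exc} and \code{initial_assignment}.
#' @export
memory_maintenance <- function(net, init_data, extra_data, eval_data,
                               extra_schedule) {
  if (any(diff(c(0, extra_schedule)) <= 0))
    stop("'extra_schedule' must be strictly increasing")
  if (max(extra_schedule) > nrow(extra_data$images))
    stop("not enough extra training images for the schedule")
  net <- train_network(net, init_data)$net
  init_assign <- assign_digits(net, eval_data)
  retained <- c(net$n_exc, integer(length(extra_schedule)))
  prev <- 0L
  for (s in seq_along(extra_schedule)) {
    idx <- (prev + 1L):extra_schedule[s]
    chunk <- list(images = extra_data$images[idx, , drop = FALSE],
                  labels = extra_data$labels[idx])
    net <- train_network(net, chunk)$net
    cur <- assign_digits(net, eval_data)
    retained[s + 1L] <- sum(!is.na(init_assign$labels) &
                              !is.na(cur$labels) &
                              init_assign$labels == cur$labels)
    prev <- extra_schedule[s]
  }
  out <- data.frame(extra_training = c(0L, extra_schedule),
                    retained = retained)
  attr(out, "n_exc") <- net$n_exc
  attr(out, "initial_assignment") <- init_assign$labels
  attr(out, "final_net") <- net
  class(out) <- c("maintenance_curve", "data.frame")
  out
}

#' Sequential class-overwrite benchmark
#'
#' Trains the network phase by phase on single classes (e.g. many samples
#' of one class, then fewer of a second, then a third) and, after each
#' phase, assigns memorised labels and snapshots the weight matrix. With
#' the conventional constant-probability rule earlier memories are
#' overwritten by the last class; with the sigmoidal rule neurons holding
#' earlier classes survive.
#'
#' @param net a freshly constructed \code{\link{snn_network}}.
#' @param phases list of \code{list(label =, n =)} entries: the class
#'   trained in each phase and its sample count.
#' @param make_data function(label, n) returning a dataset of n images of
#'   that class (e.g. a closure over \code{\link{generate_dataset}}).
#' @param eval_data evaluation dataset covering all phase classes.
#' @return A list with \code{class_counts} (matrix: phases x classes,
#'   neurons memorising each class after each phase), \code{weights}
#'   (list of weight-matrix snapshots) and \code{assignments}.
#' @export
sequential_overwrite_benchmark <- function(net, phases, make_data, eval_data) {
  n_classes <- max(eval_data$labels)
  class_counts <- matrix(0L, length(phases), n_classes,
                         dimnames = list(NULL, paste0("class", 1:n_classes)))
  weights <- vector("list", length(phases))
  assignments <- vector("list", length(phases))
  for (ph in seq_along(phases)) {
    d <- make_data(phases[[ph]]$label, phases[[ph]]$n)
    net <- train_network(net, d)$net
    a <- assign_digits(net, eval_data)
    assignments[[ph]] <- a$labels
    tab <- table(factor(a$labels, levels = 1:n_classes))
    class_counts[ph, ] <- as.integer(tab)
    weights[[ph]] <- net$ps$W
  }
  list(class_counts = class_counts, weights = weights,
       assignments = assignments, net = net)
}

#' Tile per-neuron afferent weights into one intensity map
#'
#' Renders the plastic weight matrix as a grid of panels, one panel per
#' neuron, each panel being that neuron's afferent weights reshaped to the
#' input pixel grid -- the standard visual readout of what each neuron has
#' memorised. A 5 x 5 grid of 28 x 28 panels contains 19,600 pixels.
#'
#' @param W weight matrix, \code{n_pixels x n_neurons}.
#' @param pixel_shape c(rows, cols) of one input image.
#' @param grid_cols panels per row of the tiling (default: square-ish).
#' @param neurons which neuron columns to render (default all).
#' @return A numeric matrix of the tiled map, with attribute
#'   \code{"panels"} = number of panels.
#' @export
render_weight_map <- function(W, pixel_shape, grid_cols = NULL,
                              neurons = seq_len(ncol(W))) {
  if (nrow(W) != prod(pixel_shape))
    stop("nrow(W) must equal prod(pixel_shape)")
  n <- length(neurons)
  if (is.null(grid_cols)) grid_cols <- ceiling(sqrt(n))
  grid_rows <- ceiling(n / grid_cols)
  out <- matrix(0, grid_rows * pixel_shape[1], grid_cols * pixel_shape[2])
  for (idx in seq_len(n)) {
    r <- (idx - 1) %/% grid_cols
    cc <- (idx - 1) %% grid_cols
    panel <- matrix(W[, neurons[idx]], pixel_shape[1], pixel_shape[2])
    out[r * pixel_shape[1] + seq_len(pixel_shape[1]),
        cc * pixel_shape[2] + seq_len(pixel_shape[2])] <- panel
  }
  attr(out, "panels") <- n
  out
}
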