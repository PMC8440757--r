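#' Specification of a synthetic graded-intensity pattern set
#'
#' Defines a small labelled image set that plays the statistical role of a
#' handwritten-digit benchmark for the spiking network: per-class 2-D
#' intensity prototypes on a square grid, with per-image multiplicative
#' pixel noise and integer translation jitter. Pixel intensities live in
#' [0, 255] and drive Poisson input rates through the encoder.
#'
#' The default prototypes are five clearly distinguishable shapes on a
#' 10 x 10 grid: a horizontal bar, a cross, a diagonal stripe, an
#' off-centre blob and a ring. Prototypes must be pairwise distinguishable
#' (normalised cross-correlation below \code{max_ncc}); degenerate sets
#' are rejected.
#'
#' @param grid_size side length of the square image grid.
#' @param prototypes optional list of \code{grid_size x grid_size}
#'   intensity matrices, one per class; defaults to the built-in shapes.
#' @param n_classes number of classes (only used with default prototypes;
#'   must be <= 5).
#' @param jitter multiplicative per-pixel noise amplitude: each pixel is
#'   scaled by \code{exp(jitter * z)} with standard-normal \code{z}.
#' @param translate logical; jitter each image by an integer shift drawn
#'   uniformly from \{-1, 0, 1\} in each axis.
#' @param intensity_max upper intensity clip (255).
#' @param max_ncc distinguishability bound on pairwise normalised
#'   cross-correlation of prototypes.
#' @param seed RNG seed used by \code{\link{generate_dataset}}.
#' @return An object of class \code{synthetic_pattern_spec}.
#' @export
synthetic_pattern_spec <- function(grid_size = 10, prototypes = NULL,
                                   n_classes = 5, jitter = 0.25,
                                   translate = TRUE, intensity_max = 255,
                                   max_ncc = 0.8, seed = 1L) {
  if (is.null(prototypes)) {
    if (n_classes > 5) stop("built-in prototypes support at most 5 classes")
    prototypes <- default_prototypes(grid_size)[seq_len(n_classes)]
  }
  g <- grid_size
  if (!all(vapply(prototypes, function(m) all(dim(m) == c(g, g)), logical(1))))
    stop("all prototypes must be grid_size x grid_size matrices")
  if (any(vapply(prototypes, function(m) sum(m) == 0, logical(1))))
    stop("degenerate (all-zero) prototype")
  nc <- length(prototypes)
  for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
    va <- as.vector(prototypes[[a]]); vb <- as.vector(prototypes[[b]])
    ncc <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
    if (ncc >= max_ncc)
      stop(sprintf("prototypes %d and %d not distinguishable (ncc = %.2f)",
                   a, b, ncc))
  }
  structure(list(grid_size = g, prototypes = prototypes,
                 n_classes = nc, jitter = jitter,
                 translate = isTRUE(translate),
                 intensity_max = intensity_max, seed = as.integer(seed)),
            class = "synthetic_pattern_spec")
}

#' Built-in class prototype shapes
#'
#' The five default intensity prototypes (bar, cross, diagonal, blob,
#' ring) on a \code{g x g} grid, as used by
#' \code{\link{synthetic_pattern_spec}}.
#'
#' @param g grid side length (>= 8).
#' @return Named list of five \code{g x g} intensity matrices.
#' @export
default_prototypes <- function(g = 10) {
  stopifnot(g >= 8)
  mid <- ceiling(g / 2)
  ij <- expand.grid(i = 1:g, j = 1:g)
  mk <- function(v) matrix(v, g, g)
  # the bar is the cross's horizontal arm: a deliberately correlated class
  # pair (ncc ~ 0.75) so that classification requires sharp weight maps
  bar <- mk(ifelse(ij$i %in% c(mid, mid + 1), 220, 0))
  cross <- mk(ifelse(ij$i %in% c(mid, mid + 1) | ij$j %in% c(mid, mid + 1),
                     200, 0))
  diagonal <- mk(ifelse(abs(ij$i - ij$j) <= 1, 220, 0))
  cb <- c(g - 2.5, 3.5)  # blob centre: lower-left quadrant
  d2 <- (ij$i - cb[1])^2 + (ij$j - cb[2])^2
  blob <- mk(255 * exp(-d2 / (2 * 1.6^2)))
  blob[blob < 20] <- 0
  cc <- (g + 1) / 2
  r <- sqrt((ij$i - cc)^2 + (ij$j - cc)^2)
  ring <- mk(ifelse(abs(r - (g / 2 - 1.3)) <= 0.9, 210, 0))
  list(bar = bar, cross = cross, diagonal = diagonal, blob = blob, ring = ring)
}

# shift a matrix by (di, dj), zero-filling
shift_matrix <- function(m, di, dj) {
  g <- nrow(m)
  out <- matrix(0, g, ncol(m))
  src_i <- seq_len(g) - di; src_j <- seq_len(ncol(m)) - dj
  ok_i <- src_i >= 1 & src_i <= g
  ok_j <- src_j >= 1 & src_j <= ncol(m)
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

#' Generate a labelled synthetic pattern dataset
#'
#' Draws \code{n_per_class} jittered instances of each class prototype,
#' shuffles the presentation order, and returns flattened images. Fully
#' deterministic given \code{seed}.
#'
#' @param spec a \code{\link{synthetic_pattern_spec}}.
#' @param n_per_class images per class.
#' @param seed RNG seed (defaults to \code{spec$seed}).
#' @return A list with \code{images} (matrix, one row per image, pixels
#'   column-major), \code{labels} (integer class per image, 1-based),
#'   \code{grid} (c(rows, cols)), and \code{spec}.
#' @export
generate_dataset <- function(spec, n_per_class, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_pattern_spec"))
  set.seed(seed)
  g <- spec$grid_size
  n <- n_per_class * spec$n_classes
  images <- matrix(0, n, g * g)
  labels <- rep(seq_len(spec$n_classes), each = n_per_class)
  for (idx in seq_len(n)) {
    proto <- spec$prototypes[[labels[idx]]]
    if (spec$translate) {
      sh <- sample(-1:1, 2, replace = TRUE)
      proto <- shift_matrix(proto, sh[1], sh[2])
    }
    img <- proto * exp(spec$jitter * matrix(stats::rnorm(g * g), g, g))
    img[img > spec$intensity_max] <- spec$intensity_max
    images[idx, ] <- as.vector(img)
  }
  ord <- sample.int(n)
  list(images = images[ord, , drop = FALSE], labels = labels[ord],
       grid = c(g, g), spec = spec)
}

#' Nearest-prototype classification of a pattern set
#'
#' Sanity-check classifier: assigns each image the class of the prototype
#' with the highest normalised cross-correlation, maximised over the same
#' +/-1-pixel shift set the generator draws from. Used to verify the
#' separability of generated datasets.
#'
#' @param dataset a dataset from \code{\link{generate_dataset}}.
#' @return Fraction of images classified to their true class.
#' @export
nearest_prototype_accuracy <- function(dataset) {
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  templates <- lapply(dataset$spec$prototypes, function(pr) {
    v <- vapply(seq_len(nrow(shifts)), function(s)
      as.vector(shift_matrix(pr, shifts$di[s], shifts$dj[s])),
      numeric(length(pr)))
    sweep(v, 2, pmax(sqrt(colSums(v^2)), 1e-12), "/")
  })
  score <- vapply(templates, function(tm)
    apply(dataset$images %*% tm, 1, max), numeric(nrow(dataset$images)))
  pred <- max.col(score, ties.method = "first")
  mean(pred == dataset$labels)
}

# ---------------------------------------------------------------------------
# IDX container format (the classic big-endian digit-image format)
# ---------------------------------------------------------------------------

#' Read an IDX-format array file
#'
#' Reads the big-endian IDX container used by the standard
#' handwritten-digit distribution: unsigned-byte image tensors (magic
#' 0x00000803) and label vectors (magic 0x00000801). Gzip-compressed
#' files are accepted transparently.
#'
#' @param path file path (plain or gzip).
#' @return For image files, an array of dimension \code{c(n, rows, cols)}
#'   with intensities 0-255; for label files, an integer vector.
#' @export
read_idx <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, integer(), n = 1, size = 4, endian = "big")
  if (length(magic) != 1 || bitwAnd(magic, bitwNot(0xFFL)) != 0x0800L)
    stop("not an IDX file (bad magic number)")
  ndim <- bitwAnd(magic, 0xFFL)
  dims <- readBin(con, integer(), n = ndim, size = 4, endian = "big")
  if (length(dims) != ndim || any(dims < 0)) stop("truncated IDX header")
  total <- prod(dims)
  raw <- readBin(con, integer(), n = total, size = 1, signed = FALSE)
  if (length(raw) != total) stop("truncated IDX data section")
  if (ndim == 1) return(as.integer(raw))
  # stored row-major: last index varies fastest
  aperm(array(raw, dim = rev(dims)), rev(seq_len(ndim)))
}

#' Write an array in IDX format
#'
#' Inverse of \code{\link{read_idx}}: writes an unsigned-byte IDX file.
#' A path ending in \code{.gz} is gzip-compressed.
#'
#' @param x integer vector (labels) or 3-d array \code{c(n, rows, cols)}
#'   (images), values 0-255.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
write_idx <- function(x, path) {
  if (any(x < 0) || any(x > 255)) stop("IDX unsigned-byte values must be 0-255")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  ndim <- length(dims)
  writeBin(as.integer(0x0800L + ndim), con, size = 4, endian = "big")
  writeBin(as.integer(dims), con, size = 4, endian = "big")
  flat <- if (ndim == 1) as.integer(x)
          else as.integer(aperm(x, rev(seq_len(ndim))))
  writeBin(as.raw(flat), con)
  invisible(path)
}

#' Convert a generated dataset to IDX image/label pairs
#'
#' Exports a synthetic dataset in the same container format as the real
#' digit benchmark so every downstream path is format-uniform.
#'
#' @param dataset a dataset from \code{\link{generate_dataset}}.
#' @param image_path,label_path destination paths.
#' @return Invisibly, the two paths.
#' @export
dataset_to_idx <- function(dataset, image_path, label_path) {
  g <- dataset$grid
  n <- nrow(dataset$images)
  arr <- array(0L, dim = c(n, g[1], g[2]))
  for (i in seq_len(n))
    arr[i, , ] <- matrix(as.integer(round(dataset$images[i, ])), g[1], g[2])
  write_idx(arr, image_path)
  write_idx(as.integer(dataset$labels), label_path)
  invisible(c(image_path, label_path))
}
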