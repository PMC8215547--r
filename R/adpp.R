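# Adaptive pre-processing: filter-and-pool image compression, binarization
# to a target mean count of active pixels, and the f statistic that links
# sparsity, input density, mean weight and threshold to the expected
# hidden-layer firing fraction.

#' Pooling configuration
#'
#' @param filter_size,stride,padding average-pooling geometry (pixels;
#'   padding is zero-filled)
#' @return list of class `pool_config`
#' @export
pool_config <- function(filter_size = 2, stride = 2, padding = 0) {
  if (filter_size < 1 || stride < 1 || padding < 0)
    stop("invalid pooling configuration")
  structure(list(filter_size = filter_size, stride = stride,
                 padding = padding), class = "pool_config")
}

#' Output side length of the pooling stage
#'
#' `floor((original - filter_size + 2*padding)/stride) + 1`.
#'
#' @param original input side length (pixels)
#' @param cfg a [pool_config()]
#' @return compressed side length
#' @export
compressed_size <- function(original, cfg = pool_config()) {
  out <- floor((original - cfg$filter_size + 2 * cfg$padding) /
                 cfg$stride) + 1
  if (out < 1) stop("invalid pooling configuration: non-positive output size")
  out
}

#' Average-pool a grayscale image
#'
#' Each output pixel is the mean of its receptive field; zero padding
#' contributes zeros to the mean.
#'
#' @param image square grayscale matrix with values in [0, 1]
#' @param cfg a [pool_config()]
#' @return pooled matrix of side [compressed_size()]
#' @export
average_pool <- function(image, cfg = pool_config()) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix")
  n <- nrow(image)
  if (cfg$padding > 0) {
    padded <- matrix(0, n + 2 * cfg$padding, n + 2 * cfg$padding)
    padded[cfg$padding + seq_len(n), cfg$padding + seq_len(n)] <- image
    image <- padded
  }
  out_n <- compressed_size(n, cfg)
  f <- cfg$filter_size
  out <- matrix(0, out_n, out_n)
  for (i in seq_len(out_n)) {
    for (j in seq_len(out_n)) {
      r0 <- (i - 1) * cfg$stride; c0 <- (j - 1) * cfg$stride
      out[i, j] <- mean(image[r0 + seq_len(f), c0 + seq_len(f)])
    }
  }
  out
}

# pool a n x 28 x 28 array to n x side x side
.pool_array <- function(images, cfg) {
  n <- dim(images)[1]
  side <- compressed_size(dim(images)[2], cfg)
  out <- array(0, c(n, side, side))
  for (i in seq_len(n)) out[i, , ] <- average_pool(images[i, , ], cfg)
  out
}

#' Binarize a grayscale image
#'
#' A pixel is active ("black", i.e. digit ink) iff its value strictly
#' exceeds the threshold.
#'
#' @param image grayscale matrix (or n x side x side array)
#' @param threshold binarization threshold
#' @return list with `binary` (same shape, 0/1) and `nin_b` (count of
#'   active pixels; a vector when given an array)
#' @export
binarize <- function(image, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  b <- 1 * (image > threshold)
  nin_b <- if (length(dim(image)) == 3) apply(b, 1, sum) else sum(b)
  list(binary = b, nin_b = nin_b)
}

#' Adaptive pre-processing configuration
#'
#' @param target_nin_b target mean number of active pixels per compressed
#'   image
#' @param tolerance acceptable deviation of the achieved mean
#' @param bracket threshold search bracket
#' @return list of class `adpp_config`
#' @export
adpp_config <- function(target_nin_b = 20, tolerance = 1,
                        bracket = c(0, 1)) {
  if (target_nin_b < 0) stop("target_nin_b must be >= 0")
  structure(list(target_nin_b = target_nin_b, tolerance = tolerance,
                 bracket = bracket), class = "adpp_config")
}

#' Tune the binarization threshold to a target input density
#'
#' Bisection on the (monotone non-increasing) mean active-pixel count as a
#' function of the threshold, applied after pooling the whole dataset.
#'
#' @param images n x 28 x 28 grayscale array (raw images)
#' @param cfg an [adpp_config()]
#' @param pool a [pool_config()]
#' @return list with `threshold`, `achieved` (mean active count) and
#'   `pooled` (the pooled array, for reuse)
#' @export
tune_threshold <- function(images, cfg = adpp_config(),
                           pool = pool_config()) {
  if (dim(images)[1] < 1) stop("dataset is empty")
  pooled <- .pool_array(images, pool)
  mean_count <- function(thr) mean(binarize(pooled, thr)$nin_b)
  lo <- cfg$bracket[1]; hi <- cfg$bracket[2]
  c_lo <- mean_count(lo); c_hi <- mean_count(hi)
  if (cfg$target_nin_b > c_lo + cfg$tolerance ||
      cfg$target_nin_b < c_hi - cfg$tolerance)
    stop(sprintf(paste0("tuning failure: target %.1f outside achievable ",
                        "range [%.1f, %.1f]"), cfg$target_nin_b, c_hi, c_lo))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (mean_count(mid) > cfg$target_nin_b) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  cand <- c(lo, hi)
  ach <- vapply(cand, mean_count, numeric(1))
  pick <- which.min(abs(ach - cfg$target_nin_b))
  list(threshold = cand[pick], achieved = ach[pick], pooled = pooled)
}

#' Full pre-processing chain
#'
#' Pools, tunes the binarization threshold to the target density, and
#' returns flattened binary input vectors.
#'
#' @param dataset a `labeled_image_set` (see [generate_synthetic_digits()])
#' @param cfg an [adpp_config()]
#' @param pool a [pool_config()]
#' @return list with `X` (n x side^2 binary matrix), `y` (1-based labels),
#'   `threshold`, `achieved`, `side`
#' @export
preprocess_dataset <- function(dataset, cfg = adpp_config(),
                               pool = pool_config()) {
  tt <- tune_threshold(dataset$images, cfg, pool)
  b <- binarize(tt$pooled, tt$threshold)$binary
  side <- dim(b)[2]
  X <- matrix(aperm(b, c(1, 3, 2)), dim(b)[1], side * side)
  list(X = X, y = dataset$labels + 1L, threshold = tt$threshold,
       achieved = tt$achieved, side = side)
}

#' The f statistic
#'
#' `f = sparsity * nin_b * meanW / vth`: the expected hidden pre-activation
#' in threshold units. When f = 1 the average hidden neuron sits at its
#' threshold, and about half of the hidden layer is expected to fire.
#'
#' @param sparsity realized connection probability
#' @param nin_b mean number of active input pixels
#' @param meanW mean biological-layer weight over masked connections
#' @param vth mean hidden threshold (> 0)
#' @return f
#' @export
f_statistic <- function(sparsity, nin_b, meanW, vth) {
  if (!is.finite(vth) || vth <= 0) stop("vth must be positive")
  sparsity * nin_b * meanW / vth
}

#' Hidden-layer firing fraction at a given input density
#'
#' Builds a sparse threshold layer, feeds random binary inputs with exactly
#' `nin_b` active pixels, and reports the dataset-mean fraction of firing
#' hidden neurons. With `nin_b` chosen so that f = 1 this measures the
#' half-firing prediction.
#'
#' @param n_inputs number of random binary input vectors
#' @param n_in,n_hidden layer sizes
#' @param sparsity connection probability
#' @param w_spec weight distribution ([gaussian_spec()], truncated at zero)
#' @param vth threshold (same for all hidden neurons)
#' @param nin_b number of active pixels per input; `NULL` solves f = 1 for
#'   the realized mean weight and rounds to the nearest integer
#' @return list with `nf_hidden` (mean firing fraction), `nin_b`, `f`
#'   (realized f at that integer density) and `mean_w`
#' @export
half_firing_experiment <- function(n_inputs = 1000, n_in = 196,
                                   n_hidden = 100, sparsity = 0.4,
                                   w_spec = gaussian_spec(9e-4, 9e-4,
                                                          "weight"),
                                   vth = 0.0066, nin_b = NULL) {
  mask <- matrix(rbinom(n_in * n_hidden, 1, sparsity), n_in, n_hidden)
  W <- matrix(.rtrunc0(n_in * n_hidden, w_spec$mean, w_spec$sd),
              n_in, n_hidden) * mask
  mean_w <- mean(W[mask == 1])
  if (is.null(nin_b))
    nin_b <- round(vth / (mean(mask) * mean_w))
  X <- matrix(0L, n_inputs, n_in)
  for (i in seq_len(n_inputs))
    X[i, sample.int(n_in, nin_b)] <- 1L
  xn <- X %*% W
  nf <- mean(sweep(xn, 2, rep(vth, n_hidden), `>`))
  list(nf_hidden = nf, nin_b = nin_b,
       f = f_statistic(mean(mask), nin_b, mean_w, vth), mean_w = mean_w)
}
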