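# The computational hybrid network: a sparse threshold layer with
# non-negative, range-clamped weights (the "biological" layer), a dense
# unconstrained softmax layer (the "hardware" layer), and cross-entropy
# training through a windowed straight-through estimator.

#' Normal distribution specification
#'
#' @param mean mean
#' @param sd standard deviation (>= 0)
#' @param units free-text units tag (e.g. "threshold", "weight")
#' @return object of class `gaussian_spec`
#' @export
gaussian_spec <- function(mean, sd, units = "") {
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0")
  structure(list(mean = mean, sd = sd, units = units),
            class = "gaussian_spec")
}

#' @export
print.gaussian_spec <- function(x, ...) {
  cat(sprintf("N(%g, %g) [%s]\n", x$mean, x$sd, x$units))
  invisible(x)
}

#' Initialize the biological and hardware layers
#'
#' The biological layer has i.i.d. Bernoulli(sparsity) connectivity,
#' non-negative weights (normal draws truncated at zero), and per-neuron
#' thresholds; the initial weights are frozen as the reference for the
#' 0.5x-2x clamp. The hardware layer is dense and unconstrained.
#'
#' @param n_in,n_hidden,n_out layer sizes
#' @param sparsity connection probability in (0, 1]
#' @param vth_spec,w_spec,hw_spec [gaussian_spec()]s for thresholds,
#'   biological weights and hardware weights
#' @param clamp_lo,clamp_hi multiplicative clamp bounds on the biological
#'   weights relative to their initial values
#' @return list with elements `bio` (mask, W, W0, vth, clamp bounds) and
#'   `hw` (W), of class `lnn_layers`
#' @export
init_layers <- function(n_in, n_hidden, n_out = 10, sparsity = 0.4,
                        vth_spec = gaussian_spec(0.0066, 0.0019, "threshold"),
                        w_spec = gaussian_spec(0.0009, 0.0009, "weight"),
                        hw_spec = gaussian_spec(0.0009, 0.0009, "weight"),
                        clamp_lo = 0.5, clamp_hi = 2) {
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  mask <- matrix(rbinom(n_in * n_hidden, 1, sparsity), n_in, n_hidden)
  W <- matrix(.rtrunc0(n_in * n_hidden, w_spec$mean, w_spec$sd),
              n_in, n_hidden) * mask
  vth <- .rtrunc0(n_hidden, vth_spec$mean, vth_spec$sd)
  hw <- matrix(rnorm(n_hidden * n_out, hw_spec$mean, hw_spec$sd),
               n_hidden, n_out)
  structure(list(
    bio = list(mask = mask, W = W, W0 = W, vth = vth,
               clamp_lo = clamp_lo, clamp_hi = clamp_hi),
    hw = list(W = hw)), class = "lnn_layers")
}

#' @export
print.lnn_layers <- function(x, ...) {
  cat(sprintf("hybrid layers: %d-%d-%d, realized sparsity %.3f\n",
              nrow(x$bio$mask), ncol(x$bio$mask), ncol(x$hw$W),
              mean(x$bio$mask)))
  cat(sprintf("  bio weights in [%g, %g], clamp [%gx, %gx] of init\n",
              min(x$bio$W[x$bio$mask == 1]), max(x$bio$W),
              x$bio$clamp_lo, x$bio$clamp_hi))
  invisible(x)
}

.as_input_matrix <- function(x, n_in) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != n_in) stop("input size mismatch")
  if (!all(X %in% c(0, 1))) stop("inputs must be binary (0/1)")
  X
}

#' Forward pass through the biological threshold layer
#'
#' @param x binary input vector or n x n_in matrix
#' @param layer the `bio` component of [init_layers()]
#' @return list with `h` (binary hidden outputs; a neuron fires iff its
#'   pre-activation strictly exceeds its threshold) and `xn`
#'   (pre-activations)
#' @export
bio_forward <- function(x, layer) {
  X <- .as_input_matrix(x, nrow(layer$mask))
  xn <- X %*% (layer$W * layer$mask)
  h <- 1 * (sweep(xn, 2, layer$vth, `>`))
  if (!is.matrix(x)) { h <- as.vector(h); xn <- as.vector(xn) }
  list(h = h, xn = xn)
}

#' Softmax output of the hardware layer
#'
#' @param h binary hidden vector or n x n_hidden matrix
#' @param layer the `hw` component of [init_layers()]
#' @return probability vector (or matrix), rows summing to one
#' @export
hw_forward <- function(h, layer) {
  H <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  logits <- H %*% layer$W
  p <- .softmax(logits)
  if (is.matrix(h)) p else as.vector(p)
}

.softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

#' Cross-entropy loss
#'
#' @param p probability vector, or n x K matrix
#' @param y class index (1-based) or vector of indices
#' @return mean negative log-likelihood; probabilities are floored at the
#'   machine minimum so the loss stays finite
#' @export
cross_entropy <- function(p, y) {
  P <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  py <- P[cbind(seq_len(nrow(P)), y)]
  mean(-log(pmax(py, .Machine$double.xmin)))
}

#' Windowed straight-through estimator mask
#'
#' The gradient of the hard threshold activation is passed as one only where
#' the pre-activation lies strictly inside the estimator range; an unbounded
#' range recovers the constant-one straight-through estimator.
#'
#' @param xn pre-activation vector or matrix
#' @param est_range `c(lo, hi)` with `lo < hi`, or `NULL` for the unbounded
#'   estimator
#' @return binary mask shaped like `xn`
#' @export
ste_mask <- function(xn, est_range = NULL) {
  if (is.null(est_range)) {
    out <- xn
    out[] <- 1
    return(out)
  }
  if (est_range[1] >= est_range[2]) stop("est_range must satisfy lo < hi")
  1 * (xn > est_range[1] & xn < est_range[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training configuration
#'
#' @param lr_bio,lr_hw learning rates for the two layers
#' @param est_range straight-through estimator window (`NULL` = unbounded)
#' @param epochs,batch_size training schedule
#' @param dropout dropout rate on the hidden activations during training
#' @param adaptive_lr if `TRUE`, both rates are multiplied by `lr_decay`
#'   whenever the epoch-mean loss fails to improve by at least 1% over
#'   `plateau` epochs
#' @param lr_decay,plateau adaptive learning-rate parameters
#' @return list of class `train_config`
#' @export
train_config <- function(lr_bio = 5e-6, lr_hw = 0.008,
                         est_range = c(0, 0.0075), epochs = 100,
                         batch_size = 32, dropout = 0,
                         adaptive_lr = FALSE, lr_decay = 0.1,
                         plateau = 5) {
  if (lr_bio <= 0 || lr_hw <= 0) stop("learning rates must be positive")
  if (!is.null(est_range) && est_range[1] >= est_range[2])
    stop("est_range must satisfy lo < hi")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  structure(list(lr_bio = lr_bio, lr_hw = lr_hw, est_range = est_range,
                 epochs = epochs, batch_size = batch_size, dropout = dropout,
                 adaptive_lr = adaptive_lr, lr_decay = lr_decay,
                 plateau = plateau), class = "train_config")
}

# clamp the biological weights to [lo*W0, hi*W0] on masked entries
.clamp_bio <- function(bio) {
  bio$W <- pmin(pmax(bio$W, bio$clamp_lo * bio$W0), bio$clamp_hi * bio$W0)
  bio$W <- bio$W * bio$mask
  bio
}

#' One training step on a batch
#'
#' Forward through both layers, softmax/cross-entropy gradient for the
#' hardware layer, straight-through (windowed) gradient for the biological
#' layer, followed by the biological weight clamp. The hidden activations
#' used for the gradients can optionally be passed in (`h_override`), which
#' is how the biophysical backend trains: its simulated hidden responses
#' replace the threshold-layer outputs while the pre-activations still
#' define the estimator window.
#'
#' @param X,y batch inputs (binary matrix) and 1-based class labels
#' @param layers an `lnn_layers` object
#' @param cfg a [train_config()]
#' @param h_override optional hidden activation matrix replacing the
#'   computational forward pass
#' @return list with updated `layers` and the batch `loss`
#' @export
train_step <- function(X, y, layers, cfg, h_override = NULL) {
  fw <- bio_forward(X, layers$bio)
  h <- if (is.null(h_override)) fw$h else h_override
  if (cfg$dropout > 0) {
    keep <- matrix(rbinom(length(h), 1, 1 - cfg$dropout), nrow(h), ncol(h))
    h <- h * keep / (1 - cfg$dropout)
  }
  p <- hw_forward(h, layers$hw)
  loss <- cross_entropy(p, y)
  if (!is.finite(loss)) stop("training diverged: non-finite loss")
  n <- nrow(X)
  Y <- matrix(0, n, ncol(layers$hw$W))
  Y[cbind(seq_len(n), y)] <- 1
  dlogit <- (p - Y) / n
  grad_hw <- t(h) %*% dlogit
  dh <- dlogit %*% t(layers$hw$W)
  dxn <- dh * ste_mask(fw$xn, cfg$est_range)
  grad_bio <- (t(X) %*% dxn) * layers$bio$mask
  layers$hw$W <- layers$hw$W - cfg$lr_hw * grad_hw
  layers$bio$W <- layers$bio$W - cfg$lr_bio * grad_bio
  layers$bio <- .clamp_bio(layers$bio)
  list(layers = layers, loss = loss)
}

#' Evaluate the hybrid network
#'
#' @param X,y dataset (binary inputs, 1-based labels)
#' @param layers an `lnn_layers` object
#' @param h_override optional hidden activations (biophysical backend)
#' @return list with `accuracy` (argmax prediction, ties to the lowest
#'   index) and `nf_hidden` (mean fraction of firing hidden neurons)
#' @export
evaluate_net <- function(X, y, layers, h_override = NULL) {
  h <- if (is.null(h_override)) bio_forward(X, layers$bio)$h else h_override
  p <- hw_forward(h, layers$hw)
  pred <- apply(p, 1, which.max)
  list(accuracy = mean(pred == y), nf_hidden = mean(h))
}

#' Train the hybrid network
#'
#' Mini-batch gradient descent with the straight-through estimator and the
#' biological weight clamp; optionally decays both learning rates on loss
#' plateaus. `hidden_fn`, if given, computes the hidden activations for a
#' binary input matrix (the biophysical backend) in place of the threshold
#' layer.
#'
#' @param X,y training data (binary matrix, 1-based labels)
#' @param layers an `lnn_layers` object
#' @param cfg a [train_config()]
#' @param X_test,y_test optional held-out data (defaults to the training
#'   set, matching the small-dataset experiments where train = test)
#' @param hidden_fn optional function(X, layers) -> hidden activation matrix
#' @param verbose print per-epoch progress?
#' @return list with final `layers` and a `history` data.frame (epoch,
#'   loss, train_acc, test_acc, nf_hidden, lr_bio, lr_hw)
#' @export
train_network <- function(X, y, layers, cfg, X_test = X, y_test = y,
                          hidden_fn = NULL, verbose = FALSE) {
  n <- nrow(X)
  hist <- data.frame()
  lr_bio <- cfg$lr_bio; lr_hw <- cfg$lr_hw
  best_loss <- Inf; stall <- 0
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    cfg_ep <- cfg; cfg_ep$lr_bio <- lr_bio; cfg_ep$lr_hw <- lr_hw
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      hov <- if (is.null(hidden_fn)) NULL else
        hidden_fn(X[b, , drop = FALSE], layers)
      st <- train_step(X[b, , drop = FALSE], y[b], layers, cfg_ep,
                       h_override = hov)
      layers <- st$layers
      losses <- c(losses, st$loss)
    }
    ep_loss <- mean(losses)
    hov_tr <- if (is.null(hidden_fn)) NULL else hidden_fn(X, layers)
    ev_tr <- evaluate_net(X, y, layers, h_override = hov_tr)
    same_split <- identical(X, X_test) && identical(y, y_test)
    ev_te <- if (same_split) ev_tr else {
      hov_te <- if (is.null(hidden_fn)) NULL else hidden_fn(X_test, layers)
      evaluate_net(X_test, y_test, layers, h_override = hov_te)
    }
    hist <- rbind(hist, data.frame(
      epoch = ep, loss = ep_loss, train_acc = ev_tr$accuracy,
      test_acc = ev_te$accuracy, nf_hidden = ev_tr$nf_hidden,
      lr_bio = lr_bio, lr_hw = lr_hw))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  nf %.3f",
                      ep, ep_loss, ev_tr$accuracy, ev_tr$nf_hidden))
    if (cfg$adaptive_lr) {
      if (ep_loss < best_loss * 0.99) {
        best_loss <- ep_loss; stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= cfg$plateau) {
          lr_bio <- lr_bio * cfg$lr_decay
          lr_hw <- lr_hw * cfg$lr_decay
          stall <- 0
        }
      }
    }
  }
  list(layers = layers, history = hist)
}

#' Save / load hybrid-layer checkpoints
#'
#' Checkpoints are stored as a flat JSON container holding the mask, the
#' current and initial biological weights, thresholds, clamp bounds, and the
#' hardware weights.
#'
#' @param layers an `lnn_layers` object
#' @param file path
#' @return `save_layers` the path invisibly; `load_layers` the restored
#'   `lnn_layers`
#' @export
save_layers <- function(layers, file) {
  b <- layers$bio
  jsonlite::write_json(list(
    n_in = nrow(b$mask), n_hidden = ncol(b$mask), n_out = ncol(layers$hw$W),
    mask = as.vector(b$mask), W = as.vector(b$W), W0 = as.vector(b$W0),
    vth = b$vth, clamp_lo = b$clamp_lo, clamp_hi = b$clamp_hi,
    hw_W = as.vector(layers$hw$W)), file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname save_layers
#' @export
load_layers <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(
    bio = list(mask = matrix(j$mask, j$n_in, j$n_hidden),
               W = matrix(j$W, j$n_in, j$n_hidden),
               W0 = matrix(j$W0, j$n_in, j$n_hidden),
               vth = j$vth, clamp_lo = j$clamp_lo, clamp_hi = j$clamp_hi),
    hw = list(W = matrix(j$hw_W, j$n_hidden, j$n_out))),
    class = "lnn_layers")
}
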