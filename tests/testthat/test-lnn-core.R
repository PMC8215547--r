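# The computational hybrid network: initialization, forward passes, the
# straight-through estimator, the clamp, training and evaluation.

test_that("layer initialization respects sparsity and sign constraints", {
  set.seed(10)
  ly <- init_layers(196, 100, sparsity = 1)
  expect_true(all(ly$bio$mask == 1))
  set.seed(11)
  ly <- init_layers(196, 100, sparsity = 0.4,
                    w_spec = gaussian_spec(9e-4, 9e-4))
  n <- length(ly$bio$mask)
  expect_lt(abs(mean(ly$bio$mask) - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  expect_true(all(ly$bio$W >= 0))
  expect_true(all(ly$bio$W[ly$bio$mask == 0] == 0))
  expect_identical(ly$bio$W, ly$bio$W0)
  expect_true(all(ly$bio$vth > 0))
  expect_error(init_layers(10, 5, sparsity = 0), "sparsity")
  expect_error(gaussian_spec(1, -1), "sd")
})

test_that("bio_forward uses a strict threshold rule", {
  layer <- list(mask = matrix(1, 2, 2),
                W = matrix(c(0.5, 0, 0, 0.3), 2, 2),
                W0 = matrix(c(0.5, 0, 0, 0.3), 2, 2),
                vth = c(0.4, 0.3), clamp_lo = 0.5, clamp_hi = 2)
  expect_equal(bio_forward(c(0, 0), layer)$h, c(0, 0))
  # first unit: 0.5 > 0.4 fires; second: 0.3 == 0.3 does not (strict)
  fw <- bio_forward(c(1, 1), layer)
  expect_equal(fw$h, c(1, 0))
  expect_equal(fw$xn, c(0.5, 0.3))
  expect_error(bio_forward(c(0.5, 1), layer), "binary")
})

test_that("hw_forward is a shift-invariant softmax", {
  layer <- list(W = matrix(0, 4, 10))
  p <- hw_forward(rep(1, 4), layer)
  expect_equal(p, rep(0.1, 10))
  set.seed(12)
  layer$W <- matrix(rnorm(40), 4, 10)
  p <- hw_forward(c(1, 0, 1, 0), layer)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  layer2 <- layer; layer2$W <- layer$W + 3  # shifts every logit equally
  expect_equal(hw_forward(c(1, 0, 1, 0), layer2), p, tolerance = 1e-12)
})

test_that("cross entropy behaves like a proper loss", {
  expect_equal(cross_entropy(c(1, 0, 0), 1), 0)
  expect_equal(cross_entropy(rep(0.1, 10), 3), log(10))
  p1 <- c(0.2, 0.8); p2 <- c(0.1, 0.9)
  expect_gt(cross_entropy(p1, 2), cross_entropy(p2, 2))
  expect_true(is.finite(cross_entropy(c(0, 1), 1)))  # floored, not -Inf
})

test_that("the estimator window gates the surrogate gradient", {
  expect_equal(ste_mask(c(-1, 0, 0.5, 3), NULL), rep(1, 4))
  expect_equal(as.vector(ste_mask(c(0.01, 0.005, 0, 0.0075),
                                  c(0, 0.0075))),
               c(0, 1, 0, 0))
  expect_error(ste_mask(1, c(1, 0)), "lo < hi")
})

test_that("training respects the weight clamp and mask conservation", {
  set.seed(13)
  ly <- init_layers(20, 8, sparsity = 0.5,
                    w_spec = gaussian_spec(9e-4, 9e-4))
  X <- matrix(rbinom(60 * 20, 1, 0.4), 60, 20)
  y <- sample(1:10, 60, replace = TRUE)
  cfg <- train_config(lr_bio = 1, lr_hw = 0.05, est_range = NULL,
                      epochs = 1, batch_size = 10)
  # enormous bio learning rate: every update must land on the clamp bounds
  for (i in 1:5) {
    st <- train_step(X, y, ly, cfg)
    ly <- st$layers
    on <- ly$bio$mask == 1
    expect_true(all(ly$bio$W[on] >= 0.5 * ly$bio$W0[on] - 1e-15))
    expect_true(all(ly$bio$W[on] <= 2 * ly$bio$W0[on] + 1e-15))
    expect_true(all(ly$bio$W[!on] == 0))
    expect_true(all(ly$bio$W >= 0))
  }
  # a masked-out estimator leaves the biological weights unchanged
  cfg2 <- train_config(lr_bio = 1, lr_hw = 0.05, est_range = c(-2, -1),
                       epochs = 1)
  W_before <- ly$bio$W
  st <- train_step(X, y, ly, cfg2)
  expect_identical(st$layers$bio$W, W_before)
})

test_that("hardware gradient matches central finite differences", {
  set.seed(14)
  n_h <- 4
  ly <- init_layers(6, n_h, n_out = 3, sparsity = 1,
                    w_spec = gaussian_spec(1e-3, 0),
                    vth_spec = gaussian_spec(2e-3, 0),
                    hw_spec = gaussian_spec(0, 0.5))
  X <- matrix(rbinom(5 * 6, 1, 0.5), 5, 6)
  y <- c(1, 2, 3, 1, 2)
  h <- bio_forward(X, ly$bio)$h
  loss_at <- function(W) {
    lyw <- ly; lyw$hw$W <- W
    cross_entropy(hw_forward(h, lyw$hw), y)
  }
  # analytic gradient as used by train_step
  p <- hw_forward(h, ly$hw)
  Y <- matrix(0, 5, 3); Y[cbind(1:5, y)] <- 1
  grad <- t(h) %*% ((p - Y) / 5)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(4, 2))) {
    Wp <- ly$hw$W; Wp[idx[1], idx[2]] <- Wp[idx[1], idx[2]] + eps
    Wm <- ly$hw$W; Wm[idx[1], idx[2]] <- Wm[idx[1], idx[2]] - eps
    fd <- (loss_at(Wp) - loss_at(Wm)) / (2 * eps)
    expect_equal(grad[idx[1], idx[2]], fd, tolerance = 1e-5)
  }
})

test_that("evaluation reports accuracy and hidden firing fraction", {
  ly <- list(bio = list(mask = matrix(1, 2, 2),
                        W = matrix(c(1, 0, 0, 1), 2, 2),
                        W0 = matrix(c(1, 0, 0, 1), 2, 2),
                        vth = c(0.5, 0.5), clamp_lo = 0.5, clamp_hi = 2),
             hw = list(W = matrix(c(1, 0, 0, 1), 2, 2)))
  ev <- evaluate_net(matrix(c(1, 0), 1, 2), 1, ly)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$nf_hidden, 0.5)
  ev0 <- evaluate_net(matrix(0, 3, 2), c(1, 1, 1), ly)
  expect_equal(ev0$nf_hidden, 0)
  # ties break to the lowest class index
  expect_equal(ev0$accuracy, 1)
})

test_that("a separable toy problem is learned under the constraints", {
  # four binary patterns, two classes, identity-like bio layer
  X <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 0, 1, 1), c(0, 1, 0, 1))
  y <- c(1, 1, 2, 2)
  set.seed(15)
  # identity-wired biological layer (h = x), so the hardware layer sees the
  # patterns themselves; a separating readout exists under the constraints
  ly <- structure(list(
    bio = list(mask = diag(4), W = diag(4) * 1e-3, W0 = diag(4) * 1e-3,
               vth = rep(5e-4, 4), clamp_lo = 0.5, clamp_hi = 2),
    hw = list(W = matrix(rnorm(8, 0, 0.01), 4, 2))), class = "lnn_layers")
  cfg <- train_config(lr_bio = 1e-6, lr_hw = 0.5, est_range = NULL,
                      epochs = 200, batch_size = 4)
  res <- train_network(X, y, ly, cfg)
  expect_equal(res$history$train_acc[200], 1)
})

test_that("training is reproducible from a fixed seed", {
  run <- function() {
    set.seed(16)
    ds <- generate_synthetic_digits(60, seed = 17)
    pp <- preprocess_dataset(ds, adpp_config(20))
    ly <- init_layers(196, 30)
    cfg <- train_config(epochs = 5)
    train_network(pp$X, pp$y, ly, cfg)
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$layers$bio$W, b$layers$bio$W)
})

test_that("checkpoints round-trip through the JSON container", {
  set.seed(18)
  ly <- init_layers(12, 6, n_out = 4)
  f <- tempfile(fileext = ".json")
  save_layers(ly, f)
  ly2 <- load_layers(f)
  expect_equal(ly2$bio$W, ly$bio$W)
  expect_equal(ly2$bio$mask, ly$bio$mask)
  expect_equal(ly2$hw$W, ly$hw$W)
  expect_equal(ly2$bio$vth, ly$bio$vth)
})

test_that("divergent training surfaces as an error", {
  ly <- init_layers(4, 4, n_out = 2, sparsity = 1,
                    hw_spec = gaussian_spec(0, 1))
  ly$hw$W[1, 1] <- NaN
  X <- matrix(1, 2, 4); y <- c(1, 2)
  expect_error(train_step(X, y, ly, train_config()), "diverged")
})
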