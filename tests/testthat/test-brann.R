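test_that("initialisation is seeded, shaped, and Nguyen-Widrow scaled", {
  p1 <- init_network(21, 10, 4, seed = 7)
  p2 <- init_network(21, 10, 4, seed = 7)
  expect_identical(p1, p2)
  expect_false(isTRUE(all.equal(p1$w1, init_network(21, 10, 4, seed = 8)$w1)))
  expect_equal(dim(p1$w1), c(10, 21))
  expect_length(p1$b1, 10)
  expect_equal(dim(p1$w2), c(4, 10))
  expect_length(p1$b2, 4)
  magnitude <- 0.7 * 10^(1 / 21)
  expect_equal(sqrt(rowSums(p1$w1^2)), rep(magnitude, 10), tolerance = 1e-9)
})

test_that("forward pass computes w2 tanh(w1 x + b1) + b2", {
  p <- init_network(3, 4, 2, seed = 1)
  zero <- list(w1 = matrix(0, 4, 3), b1 = rep(0, 4),
               w2 = matrix(0, 2, 4), b2 = rep(0, 2))
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(forward(zero, x), matrix(0, 10, 2))
  # small-argument linearisation: tanh(eps * x1) ~ eps * x1
  lin <- list(w1 = rbind(c(1e-4, 0, 0)), b1 = 0, w2 = matrix(1e4), b2 = 0)
  expect_equal(as.numeric(forward(lin, x)), x[, 1], tolerance = 1e-6)
  # direct evaluation
  y <- forward(p, x)
  h <- tanh(x %*% t(p$w1) + matrix(p$b1, 10, 4, byrow = TRUE))
  expect_equal(y, h %*% t(p$w2) + matrix(p$b2, 10, 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_error(forward(p, matrix(0, 2, 5)), "columns")
})

test_that("the backpropagated Jacobian matches central finite differences", {
  set.seed(4)
  n_in <- 3; n_hidden <- 4; n_out <- 2; n <- 25
  p <- init_network(n_in, n_hidden, n_out, seed = 5)
  x <- matrix(runif(n * n_in, -1, 1), n, n_in)
  t <- matrix(runif(n * n_out, -1, 1), n, n_out)
  acc <- dairyheat:::.br_accumulate(p, x, t, chunk_size = 7)
  w0 <- dairyheat:::.pack_weights(p)
  sse <- function(w) {
    q <- dairyheat:::.unpack_weights(w, n_in, n_hidden, n_out)
    sum((forward(q, x) - t)^2)
  }
  # gradient of E_D is 2 J'e; compare against central differences
  h <- 1e-6
  fd <- vapply(seq_along(w0), function(i) {
    e <- rep(0, length(w0)); e[i] <- h
    (sse(w0 + e) - sse(w0 - e)) / (2 * h)
  }, numeric(1))
  grad <- 2 * acc$jte
  expect_equal(grad, fd, tolerance = 1e-6 * max(1, max(abs(fd))))
  expect_lt(max(abs(grad - fd)) / max(abs(fd)), 1e-6)
  # chunking must not change the accumulation
  acc2 <- dairyheat:::.br_accumulate(p, x, t, chunk_size = 1000)
  expect_equal(acc$jtj, acc2$jtj, tolerance = 1e-12)
  expect_equal(acc$e_d, sse(w0), tolerance = 1e-10)
})

test_that("a noiseless linear map is recovered to near machine loss", {
  set.seed(10)
  x <- matrix(runif(200 * 4, -1, 1), 200, 4)
  cmat <- matrix(c(0.5, -0.3, 0.2, 0.1, -0.4, 0.25, 0.05, -0.15), 4, 2)
  t <- x %*% cmat
  split <- split_rows(200, 0.7, seed = 2)
  model <- train_brann(x[split$train, ], t[split$train, ],
                       train_config(n_hidden = 6, max_epochs = 300, seed = 3))
  pred <- forward(model, x[split$test, ])
  m <- regression_metrics(pred, t[split$test, ])
  expect_lt(m$mse, 1e-4)
  expect_gt(m$r, 0.999)
})

test_that("with observation noise the evidence framework prunes unused capacity", {
  # gamma counts well-determined parameters; on a noisy linear problem an
  # oversized tanh network needs far fewer than it has (noiseless data
  # instead drive beta to infinity and gamma toward N_w, since with no
  # noise every parameter direction the data touch is well determined)
  set.seed(13)
  x <- matrix(runif(400 * 4, -1, 1), 400, 4)
  t <- x %*% matrix(c(0.5, -0.3, 0.2, 0.1, -0.4, 0.25, 0.05, -0.15), 4, 2) +
    matrix(rnorm(800, 0, 0.1), 400, 2)
  small <- train_brann(x, t, train_config(n_hidden = 8, max_epochs = 100,
                                          seed = 14))
  wide <- train_brann(x, t, train_config(n_hidden = 15, max_epochs = 100,
                                         seed = 14))
  # gamma tracks the problem's effective complexity, not the capacity:
  # it stays put while N_w nearly doubles
  expect_lt(abs(wide$gamma - small$gamma), 0.25 * small$n_w)
  expect_lt(wide$gamma, 0.5 * wide$n_w)
  expect_gt(wide$gamma, 0)
})

test_that("destroying the input-target association gives near-zero test correlation", {
  set.seed(11)
  n <- 2000
  x <- matrix(runif(n * 5, -1, 1), n, 5)
  t <- x %*% matrix(runif(10, -1, 1), 5, 2)
  t <- t[sample(n), , drop = FALSE]  # permute rows: no signal left
  split <- split_rows(n, 0.7, seed = 4)
  model <- train_brann(x[split$train, ], t[split$train, ],
                       train_config(n_hidden = 5, max_epochs = 30, seed = 5))
  m <- regression_metrics(forward(model, x[split$test, ]), t[split$test, ])
  expect_lt(abs(m$r), 0.1)
})

test_that("training state keeps the Bayesian-regularization invariants", {
  set.seed(12)
  x <- matrix(runif(300 * 3, -1, 1), 300, 3)
  t <- cbind(sin(2 * x[, 1]) + 0.1 * rnorm(300),
             x[, 2] * x[, 3] + 0.1 * rnorm(300))
  model <- train_brann(x, t, train_config(n_hidden = 6, max_epochs = 60,
                                          seed = 6))
  h <- model$history
  expect_gt(nrow(h), 5)
  # accepted steps never increase the objective under that epoch's alpha/beta
  expect_true(all(h$f_after <= h$f_before + 1e-9))
  expect_true(all(h$gamma >= 0 & h$gamma <= model$n_w))
  expect_true(all(h$beta > 0))
  expect_true(all(h$alpha >= 0))
  expect_true(all(is.finite(h$f_after)))
})

test_that("models serialize to JSON and restore bit-comparable predictions", {
  farm <- tiny_farm(n_cows = 4, n_days = 40)
  model <- fit_milk_model(farm$fm, seed = 2,
                          config = train_config(max_epochs = 10))
  tmp <- tempfile(fileext = ".json")
  write_brann_json(model, tmp)
  back <- read_brann_json(tmp)
  expect_equal(back$w1, model$w1, tolerance = 1e-12)
  expect_equal(predict_targets(back, farm$fm),
               predict_targets(model, farm$fm), tolerance = 1e-12)
  expect_identical(back$signature, model$signature)
  unlink(tmp)
})

test_that("a trained model refuses a feature matrix with a different signature", {
  farm <- tiny_farm(n_cows = 3, n_days = 20)
  model <- fit_milk_model(farm$fm, seed = 2,
                          config = train_config(max_epochs = 5))
  impostor <- farm$fm
  impostor$signature <- "not|the|same"
  expect_error(predict_targets(model, impostor), "signature")
  expect_error(build_report(model, impostor), "signature")
})
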