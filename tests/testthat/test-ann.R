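# The deep tanh network: gradients, forward-pass correctness, determinism,
# training behavior and estimate validation.

micro_net <- function(seed = 1) {
  withr::with_seed(seed, list(
    W = list(matrix(rnorm(6, sd = 0.5), 3, 2),
             matrix(rnorm(2, sd = 0.5), 2, 1)),
    b = list(rnorm(2, sd = 0.2), rnorm(1, sd = 0.2))))
}

test_that("analytic gradients match central finite differences", {
  net <- micro_net(1)
  x <- c(0.3, -0.8, 0.5)
  y <- 0.4
  g <- mlp_gradients(net$W, net$b, x, y)
  fd <- finite_diff_grads(net$W, net$b, x, y)
  for (l in 1:2) {
    expect_lt(max(abs(g$dW[[l]] - fd$dW[[l]])), 1e-5)
    expect_lt(max(abs(as.numeric(g$db[[l]]) - fd$db[[l]])), 1e-5)
  }
})

test_that("the forward pass equals a hand-computed tanh cascade", {
  W <- list(matrix(c(0.1, -0.2, 0.3, 0.4), 2, 2), matrix(c(0.5, -0.6), 2, 1))
  b <- list(c(0.05, -0.05), 0.1)
  X <- rbind(c(1, 2), c(-0.5, 0.3))
  acts <- mlp_forward(W, b, X)
  h <- tanh(X %*% W[[1]] + matrix(b[[1]], 2, 2, byrow = TRUE))
  out <- tanh(h %*% W[[2]] + b[[2]])
  expect_equal(acts[[2]], h, tolerance = 1e-12)
  expect_equal(acts[[3]], out, tolerance = 1e-12)
})

test_that("training is bit-reproducible under a fixed seed", {
  tab <- generate_table(generator_config(n_participants = 60, seed = 2))
  spec <- network_spec(outputs = "tas_ddf", hidden = c(8, 8, 8),
                       epochs = 30, epoch_window = c(20, 30), seed = 5)
  n1 <- train_network(tab$data, spec)
  n2 <- train_network(tab$data, spec)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$estimates, n2$estimates)
  expect_identical(n1$train_idx, n2$train_idx)
})

test_that("hidden activations are tanh-bounded and deterministic per row", {
  tab <- generate_table(generator_config(n_participants = 50, seed = 3))
  dat <- tab$data
  dat[50, ] <- dat[49, ]  # duplicated participant
  net <- train_network(dat, network_spec(outputs = "tas_dif",
                                         hidden = c(10, 10, 10),
                                         epochs = 40,
                                         epoch_window = c(30, 40),
                                         seed = 4))
  uh <- extract_upper_hidden(net)
  expect_equal(dim(uh), c(50, 10))
  expect_true(all(abs(uh) < 1))
  expect_equal(uh[50, ], uh[49, ], tolerance = 1e-12)
})

test_that("an untrained network scores near the target variance baseline", {
  tab <- generate_table(generator_config(n_participants = 80, seed = 6))
  spec <- network_spec(outputs = "tas_eot", epochs = 0, seed = 9)
  net <- train_network(tab$data, spec)
  # compare the raw-scale MSE of random-init estimates to outcome variance
  mse <- mean((net$estimates$tas_eot - tab$data$tas_eot)^2)
  v <- var(tab$data$tas_eot)
  expect_lt(mse, 3 * v)
  expect_gt(mse, v / 3)
})

test_that("a teacher tanh network is learned to low held-out error", {
  dat <- withr::with_seed(15, {
    X <- matrix(rnorm(300 * 5), 300, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    w <- c(0.8, -0.6, 0.4, 0.5, -0.3)
    data.frame(X, y = tanh(X %*% w) + rnorm(300, sd = 0.02))
  })
  spec <- network_spec(outputs = "y", hidden = c(10, 10, 10),
                       epochs = 600, epoch_window = c(500, 600), seed = 8)
  net <- train_network(dat, spec, predictors = paste0("x", 1:5))
  best <- min(net$log$test_mse[500:600])
  expect_lt(best, 0.05)
})

test_that("weight decay keeps weights bounded on a pure-noise problem", {
  dat <- withr::with_seed(33, {
    X <- matrix(rnorm(100 * 6), 100, 6,
                dimnames = list(NULL, paste0("x", 1:6)))
    data.frame(X, y = rnorm(100))
  })
  spec <- network_spec(outputs = "y", hidden = c(10, 10, 10),
                       epochs = 300, epoch_window = c(200, 300),
                       weight_decay = 1e-3, seed = 2)
  net <- train_network(dat, spec, predictors = paste0("x", 1:6))
  norms <- vapply(net$final_weights, function(w) sqrt(sum(w^2)), numeric(1))
  expect_true(all(is.finite(norms)))
  expect_lt(max(norms), 20)
})

test_that("batch mode runs and differs from online updates", {
  tab <- generate_table(generator_config(n_participants = 40, seed = 12))
  s_on <- network_spec(outputs = "tas_ddf", hidden = c(6, 6, 6),
                       epochs = 20, epoch_window = c(10, 20), seed = 3)
  s_ba <- network_spec(outputs = "tas_ddf", hidden = c(6, 6, 6),
                       epochs = 20, epoch_window = c(10, 20), seed = 3,
                       mode = "batch")
  n_on <- train_network(tab$data, s_on)
  n_ba <- train_network(tab$data, s_ba)
  expect_false(identical(n_on$weights, n_ba$weights))
  expect_true(all(is.finite(n_ba$log$train_mse)))
})

test_that("estimate validation reports the perfect and broken extremes", {
  tab <- generate_table(generator_config(n_participants = 60, seed = 18))
  net <- train_network(tab$data,
                       network_spec(outputs = "tas_ddf", hidden = c(8, 8, 8),
                                    epochs = 30, epoch_window = c(20, 30),
                                    seed = 6))
  # perfect estimates
  net_perfect <- net
  net_perfect$estimates$tas_ddf <- tab$data$tas_ddf
  # summary.lm warns on an exactly perfect fit; that is the case under test
  v <- suppressWarnings(validate_estimates(net_perfect, tab$data))$tas_ddf
  expect_equal(v$adj_r_squared, 1, tolerance = 1e-10)
  expect_equal(v$coefficients$std_beta, 1, tolerance = 1e-10)
  # shuffled estimates carry no information
  net_broken <- net
  net_broken$estimates$tas_ddf <- withr::with_seed(1, sample(tab$data$tas_ddf))
  v2 <- validate_estimates(net_broken, tab$data)$tas_ddf
  expect_lt(v2$adj_r_squared, 0.1)
  # collapsed estimates are an error
  net_const <- net
  net_const$estimates$tas_ddf <- rep(17, 60)
  expect_error(validate_estimates(net_const, tab$data), "collapsed")
})

test_that("three-output networks sum their subscale estimates to a total", {
  tab <- generate_table(generator_config(n_participants = 50, seed = 21))
  net <- train_network(tab$data, network_spec(hidden = c(8, 8, 8),
                                              epochs = 20,
                                              epoch_window = c(10, 20),
                                              seed = 2))
  expect_true("tas_total" %in% names(net$estimates))
  expect_equal(net$estimates$tas_total,
               net$estimates$tas_ddf + net$estimates$tas_dif +
                 net$estimates$tas_eot)
})
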