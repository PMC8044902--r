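# Deep tanh backpropagation networks.  The reference architecture is five
# layers (17 x 30 x 30 x 30 x out, out = 3 for the joint subscale network
# and 1 for single-subscale networks), online updates with momentum 0.1 and
# weight decay 1e-4, and a seeded 70/30 train/test split; the retained
# weights are those minimizing held-out error inside the epoch window.

#' Specify a deep tanh network
#'
#' @param outputs outcome column names the network estimates (3 subscales
#'   jointly, or a single one).
#' @param hidden hidden layer widths (default three layers of 30).
#' @param learning_rate online learning rate (default 0.05; 0.001 is a
#'   common conservative alternative).
#' @param momentum momentum coefficient on the update velocity.
#' @param weight_decay L2 shrinkage applied inside each update.
#' @param epochs total training epochs.
#' @param epoch_window inclusive epoch range within which the
#'   test-error-minimizing weights are kept (overfitting guard).
#' @param train_fraction fraction of rows in the training split.
#' @param target_margin targets are affinely mapped into
#'   \[-target_margin, target_margin\] (tanh output range).
#' @param mode `"online"` (per-row updates in a seeded shuffled order) or
#'   `"batch"` (one averaged-gradient update per epoch).
#' @param seed integer seed controlling the split, the weight
#'   initialization and the visit order.
#' @return A `network_spec` list.
#' @export
network_spec <- function(outputs = c("tas_ddf", "tas_dif", "tas_eot"),
                         hidden = c(30, 30, 30),
                         learning_rate = 0.05, momentum = 0.1,
                         weight_decay = 1e-4, epochs = 600,
                         epoch_window = c(500, 600),
                         train_fraction = 0.7, target_margin = 0.9,
                         mode = c("online", "batch"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(all(hidden > 0), train_fraction > 0, train_fraction < 1,
            epochs >= 0, target_margin > 0, target_margin < 1)
  epoch_window <- c(max(1, epoch_window[1]), min(epochs, epoch_window[2]))
  if (epochs > 0 && epoch_window[1] > epoch_window[2]) {
    epoch_window <- c(1, epochs)
  }
  structure(list(outputs = outputs, hidden = hidden,
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, epochs = epochs,
                 epoch_window = epoch_window,
                 train_fraction = train_fraction,
                 target_margin = target_margin, mode = mode, seed = seed),
            class = "network_spec")
}

init_layers <- function(sizes) {
  L <- length(sizes) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    r <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -r, r),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

# Affine map of z-scale targets into [-m, m] using train-split min/max.
make_target_map <- function(y_train, margin) {
  lo <- apply(y_train, 2, min)
  hi <- apply(y_train, 2, max)
  span <- pmax(hi - lo, 1e-12)
  list(lo = lo, hi = hi, margin = margin, span = span)
}

apply_target_map <- function(y, map) {
  sweep(sweep(y, 2, map$lo), 2, map$span, "/") * 2 * map$margin - map$margin
}

invert_target_map <- function(s, map) {
  sweep(sweep((s + map$margin) / (2 * map$margin), 2, map$span, "*"),
        2, map$lo, "+")
}

#' Train a deep tanh network on a scored dataset
#'
#' Standardizes the 17 predictors and the target outcome(s) to z scores,
#' maps targets into the tanh codomain, splits rows 70/30 (seeded,
#' unstratified), initializes weights uniformly at random, and runs
#' backpropagation with momentum and weight decay.  The weights kept are
#' those with the lowest held-out error inside `spec$epoch_window`; the
#' per-epoch error curves are recorded.
#'
#' @param data a scored dataset (see [scored_dataset()]).
#' @param spec a [network_spec()].
#' @param predictors predictor columns (default: the 17 canonical ones).
#' @return A `trained_network`: weights, train/test indices, per-epoch
#'   error log, the N x 30 upper-hidden-layer activation matrix, and
#'   network estimates mapped back to the raw outcome scale (including a
#'   `tas_total` column summing the three subscale estimates when the
#'   network has three outputs).
#' @export
train_network <- function(data, spec, predictors = predictor_names()) {
  stopifnot(inherits(spec, "network_spec"))
  assert_cols(data, c(predictors, spec$outputs), "network data")
  if (anyNA(data[, c(predictors, spec$outputs)])) {
    stop("network training requires complete data", call. = FALSE)
  }
  n <- nrow(data)
  X <- as.matrix(z_view(data, predictors))
  y_raw <- as.matrix(data[, spec$outputs, drop = FALSE])
  y_mean <- colMeans(y_raw)
  y_sd <- apply(y_raw, 2, sd)
  Yz <- sweep(sweep(y_raw, 2, y_mean), 2, y_sd, "/")

  sizes <- c(ncol(X), spec$hidden, length(spec$outputs))
  local_seed(spec$seed, {
    ntr <- max(2, round(spec$train_fraction * n))
    train_idx <- sort(sample.int(n, ntr))
    test_idx <- setdiff(seq_len(n), train_idx)
    layers <- init_layers(sizes)
    tmap <- make_target_map(Yz[train_idx, , drop = FALSE],
                            spec$target_margin)
    S <- apply_target_map(Yz, tmap)
    if (spec$epochs > 0) {
      order_mat <- t(vapply(seq_len(spec$epochs),
                            function(e) sample.int(ntr) - 1L,
                            integer(ntr)))
      fit <- mlp_train_cpp(layers$W, layers$b,
                           X[train_idx, , drop = FALSE],
                           S[train_idx, , drop = FALSE],
                           X[test_idx, , drop = FALSE],
                           S[test_idx, , drop = FALSE],
                           spec$learning_rate, spec$momentum,
                           spec$weight_decay, order_mat,
                           spec$epoch_window[1], spec$epoch_window[2],
                           identical(spec$mode, "batch"))
    } else {
      fit <- list(W = layers$W, b = layers$b,
                  W_final = layers$W, b_final = layers$b,
                  train_mse = numeric(0), test_mse = numeric(0),
                  best_epoch = 0L)
    }
    acts <- mlp_forward_cpp(fit$W, fit$b, X)
    upper <- acts[[length(acts) - 1L]]
    est_scaled <- acts[[length(acts)]]
    est_z <- invert_target_map(est_scaled, tmap)
    est_raw <- sweep(sweep(est_z, 2, y_sd, "*"), 2, y_mean, "+")
    colnames(est_raw) <- spec$outputs
    estimates <- tibble::as_tibble(est_raw)
    if (length(spec$outputs) == 3L) {
      estimates$tas_total <- rowSums(est_raw)
    }
    log <- tibble::tibble(epoch = seq_along(fit$train_mse),
                          train_mse = as.numeric(fit$train_mse),
                          test_mse = as.numeric(fit$test_mse))
    structure(list(spec = spec, predictors = predictors,
                   weights = fit$W, biases = fit$b,
                   final_weights = fit$W_final, final_biases = fit$b_final,
                   best_epoch = fit$best_epoch,
                   train_idx = train_idx, test_idx = test_idx,
                   target_map = tmap, y_mean = y_mean, y_sd = y_sd,
                   log = log, upper_hidden = upper,
                   estimates = estimates, n = n),
              class = "trained_network")
  })
}

#' @export
print.trained_network <- function(x, ...) {
  sizes <- c(length(x$predictors), x$spec$hidden, length(x$spec$outputs))
  cat(sprintf("Deep tanh network %s, %d epochs (best epoch %d)\n",
              paste(sizes, collapse = " x "), x$spec$epochs, x$best_epoch))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("final train MSE %.4f, test MSE %.4f (scaled targets)\n",
                last$train_mse, last$test_mse))
  }
  invisible(x)
}

#' Upper-hidden-layer activations
#'
#' Deterministic forward pass returning the activations of the deepest
#' hidden layer (one row per participant, one column per hidden unit) --
#' the representation on which participant subgroups are clustered.
#'
#' @param net a `trained_network`.
#' @param newdata optional data frame to propagate instead of the training
#'   data's stored activations.
#' @return An N x 30 (by default) numeric matrix.
#' @export
extract_upper_hidden <- function(net, newdata = NULL) {
  stopifnot(inherits(net, "trained_network"))
  if (is.null(newdata)) return(net$upper_hidden)
  X <- as.matrix(z_view(newdata, net$predictors))
  acts <- mlp_forward_cpp(net$weights, net$biases, X)
  acts[[length(acts) - 1L]]
}

#' Analytic gradients of the network loss for one sample
#'
#' Exposes the backpropagation gradients of the per-sample loss
#' 0.5 * ||output - target||^2 with respect to every weight and bias, for
#' verification against finite differences.
#'
#' @param W,b lists of layer weight matrices and bias vectors.
#' @param x input row vector; `y` target row vector.
#' @return A list with `loss`, `dW`, `db`.
#' @export
mlp_gradients <- function(W, b, x, y) {
  mlp_grad_cpp(W, b, as.numeric(x), as.numeric(y))
}

#' Forward pass through a layer stack
#'
#' @param W,b lists of layer weight matrices and bias vectors.
#' @param X input matrix (rows = samples).
#' @return A list of activation matrices, from the input (unchanged) to
#'   the output layer.
#' @export
mlp_forward <- function(W, b, X) {
  mlp_forward_cpp(W, b, as.matrix(X))
}

#' Validate network estimates against actual outcomes
#'
#' Enter-method simple regression of each actual outcome on the network's
#' estimate of it, reporting adjusted R-squared, the omnibus F and the
#' standardized beta -- the accuracy check used for backprop estimates of
#' questionnaire outcomes.
#'
#' @param net a `trained_network`.
#' @param data the scored dataset holding the actual outcomes.
#' @return A named list of `regression_result`s, one per network output.
#' @export
validate_estimates <- function(net, data) {
  stopifnot(inherits(net, "trained_network"))
  outs <- net$spec$outputs
  assert_cols(data, outs, "validation data")
  if (nrow(data) != net$n) {
    stop("validation data must align with the training rows", call. = FALSE)
  }
  res <- lapply(outs, function(oc) {
    est <- net$estimates[[oc]]
    if (sd(est) < 1e-10) {
      stop(sprintf("network estimates for %s are constant (collapsed)", oc),
           call. = FALSE)
    }
    df <- data.frame(actual = data[[oc]], estimate = est)
    enter_regression(df, "actual", "estimate")
  })
  names(res) <- outs
  res
}
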