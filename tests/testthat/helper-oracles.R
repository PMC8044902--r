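# Independent reference implementations used as oracles.  Each is written
# from first principles (no shared code with the package internals beyond
# base R) so that agreement is informative.

# --- Ward agglomeration by exhaustive O(N^3) search -------------------------
# At every stage, merge the pair of clusters whose union increases the total
# within-cluster sum of squares the least; record that increase.
brute_force_ward_heights <- function(X) {
  X <- as.matrix(X)
  clusters <- lapply(seq_len(nrow(X)), identity)
  ss <- function(rows) {
    if (length(rows) == 1) return(0)
    M <- X[rows, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_delta <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq((i + 1), length(clusters))) {
        delta <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (delta < best_delta) {
          best_delta <- delta
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_delta)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# --- Gaussian AIC from scratch ---------------------------------------------
# Matches the standard lm log-likelihood AIC: parameters counted as the
# regression coefficients (incl. intercept) plus the error variance.
oracle_aic <- function(X, y) {
  n <- length(y)
  fit <- qr(cbind(1, X))
  res <- qr.resid(fit, y)
  rss <- sum(res^2)
  k <- ncol(X) + 2
  n * (log(2 * pi) + log(rss / n) + 1) + 2 * k
}

# Greedy backward elimination replicated by exhaustive single-removal scans.
# Returns the sequence of dropped variables and the final retained set.
oracle_backward_path <- function(data, outcome, predictors) {
  current <- predictors
  dropped <- character(0)
  repeat {
    if (!length(current)) break
    y <- data[[outcome]]
    aic_now <- oracle_aic(as.matrix(data[, current, drop = FALSE]), y)
    cand <- vapply(current, function(v) {
      rest <- setdiff(current, v)
      X <- if (length(rest)) as.matrix(data[, rest, drop = FALSE])
           else matrix(nrow = length(y), ncol = 0)
      oracle_aic(X, y)
    }, numeric(1))
    best <- which.min(cand)
    if (cand[best] >= aic_now) break
    dropped <- c(dropped, current[best])
    current <- setdiff(current, current[best])
  }
  list(dropped = dropped, retained = current)
}

# --- Finite-difference gradients -------------------------------------------
mlp_loss_at <- function(W, b, x, y) {
  out <- mlp_forward(W, b, matrix(x, nrow = 1))
  pred <- out[[length(out)]]
  0.5 * sum((pred - y)^2)
}

finite_diff_grads <- function(W, b, x, y, h = 1e-6) {
  dW <- lapply(seq_along(W), function(l) {
    g <- W[[l]]
    for (i in seq_along(W[[l]])) {
      Wp <- W; Wp[[l]][i] <- W[[l]][i] + h
      Wm <- W; Wm[[l]][i] <- W[[l]][i] - h
      g[i] <- (mlp_loss_at(Wp, b, x, y) - mlp_loss_at(Wm, b, x, y)) / (2 * h)
    }
    g
  })
  db <- lapply(seq_along(b), function(l) {
    g <- b[[l]]
    for (i in seq_along(b[[l]])) {
      bp <- b; bp[[l]][i] <- b[[l]][i] + h
      bm <- b; bm[[l]][i] <- b[[l]][i] - h
      g[i] <- (mlp_loss_at(W, bp, x, y) - mlp_loss_at(W, bm, x, y)) / (2 * h)
    }
    g
  })
  list(dW = dW, db = db)
}

# --- Small simulation helpers ----------------------------------------------
# Rejection rate of the omnibus F test under a population f-squared, with
# regressors redrawn every replicate (raw-data Monte Carlo, independent of
# the noncentral-F route).
mc_rejection_rate <- function(n, u, f2, alpha, reps, seed) {
  beta <- rep(sqrt(f2 / u), u)
  withr::with_seed(seed, {
    rej <- logical(reps)
    for (r in seq_len(reps)) {
      X <- matrix(rnorm(n * u), n, u)
      y <- as.vector(X %*% beta) + rnorm(n)
      fit <- lm.fit(cbind(1, X), y)
      rss <- sum(fit$residuals^2)
      tss <- sum((y - mean(y))^2)
      fstat <- ((tss - rss) / u) / (rss / (n - u - 1))
      rej[r] <- fstat > qf(1 - alpha, u, n - u - 1)
    }
    mean(rej)
  })
}
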