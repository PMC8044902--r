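# Simple mediation (x -> m -> y) with percentile-bootstrap confidence
# intervals for the indirect effect a*b.  Path estimates come from three
# OLS fits (m ~ x; y ~ x + m; y ~ x); the bootstrap re-estimates a and b
# on case resamples with closed-form OLS so that thousands of resamples
# stay cheap.

lm_path_row <- function(fit, term) {
  ct <- summary(fit)$coefficients
  tibble::tibble(term = term, b = ct[term, 1], se = ct[term, 2],
                 t = ct[term, 3], df = fit$df.residual, p = ct[term, 4])
}

# Closed-form a (from m ~ x) and b (coefficient of m in y ~ x + m) for
# every bootstrap column at once.  X, M, Y are n x B matrices of resampled
# cases.
boot_ab <- function(X, M, Y) {
  n <- nrow(X)
  cm <- function(A) colMeans(A)
  mx <- cm(X); mm <- cm(M); my <- cm(Y)
  s_xx <- cm(X * X) - mx^2
  s_mm <- cm(M * M) - mm^2
  s_xm <- cm(X * M) - mx * mm
  s_xy <- cm(X * Y) - mx * my
  s_my <- cm(M * Y) - mm * my
  a <- s_xm / s_xx
  det <- s_xx * s_mm - s_xm^2
  b <- (s_xx * s_my - s_xm * s_xy) / det
  list(a = a, b = b)
}

#' Simple mediation with a bootstrap CI for the indirect effect
#'
#' Estimates the four paths of a single-mediator model by OLS --
#' `a` (x to m), `b` (m to y given x), `c` (total effect of x on y) and
#' `c'` (direct effect given m) -- and the indirect effect `a*b` with a
#' percentile (default) or bias-corrected case-resampling bootstrap CI.
#' The verdict follows the usual logic: no mediation if the CI covers
#' zero; full mediation if the CI excludes zero, the total effect is
#' significant and the direct effect is not; partial mediation if both the
#' CI excludes zero and the direct effect stays significant.
#'
#' @param x,m,y numeric vectors (predictor, mediator, outcome), n >= 10.
#' @param n_boot number of bootstrap resamples (5000 in typical use).
#' @param level CI level (default 0.95).
#' @param seed integer seed for the resampling stream.
#' @param ci_type `"percentile"` or `"bc"` (bias corrected).
#' @param alpha significance level for the path t tests in the verdict.
#' @return A `mediation_result` list: `paths` (a/b/c/c-prime rows with B,
#'   SE, t, df, p), `indirect`, `ci`, `n_boot`, `seed`, `verdict`.
#' @export
mediate <- function(x, m, y, n_boot = 5000, level = 0.95, seed = 1,
                    ci_type = c("percentile", "bc"), alpha = 0.05) {
  ci_type <- match.arg(ci_type)
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  if (n < 10) stop("mediation needs at least 10 cases", call. = FALSE)
  if (sd(x) == 0 || sd(m) == 0) {
    stop("x and m must have positive variance", call. = FALSE)
  }
  dat <- data.frame(x = x, m = m, y = y)
  fit_a <- lm(m ~ x, data = dat)
  fit_b <- lm(y ~ x + m, data = dat)
  fit_c <- lm(y ~ x, data = dat)
  paths <- rbind(
    within(lm_path_row(fit_a, "x"), term <- "a"),
    within(lm_path_row(fit_b, "m"), term <- "b"),
    within(lm_path_row(fit_c, "x"), term <- "c"),
    within(lm_path_row(fit_b, "x"), term <- "c_prime"))
  a_hat <- paths$b[paths$term == "a"]
  b_hat <- paths$b[paths$term == "b"]
  indirect <- a_hat * b_hat

  boot <- local_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    ab <- boot_ab(matrix(x[idx], n), matrix(m[idx], n), matrix(y[idx], n))
    ab$a * ab$b
  })
  boot <- boot[is.finite(boot)]
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (ci_type == "bc") {
    z0 <- stats::qnorm(mean(boot < indirect))
    zq <- stats::qnorm(probs)
    probs <- stats::pnorm(2 * z0 + zq)
  }
  ci <- unname(quantile(boot, probs, names = FALSE))

  excludes_zero <- ci[1] > 0 || ci[2] < 0
  c_sig <- paths$p[paths$term == "c"] < alpha
  cp_sig <- paths$p[paths$term == "c_prime"] < alpha
  verdict <- if (!excludes_zero) "none"
             else if (cp_sig) "partial"
             else if (c_sig) "full"
             else "partial"
  structure(list(paths = tibble::as_tibble(paths), indirect = indirect,
                 ci = ci, level = level, n_boot = n_boot, seed = seed,
                 ci_type = ci_type, n = n, verdict = verdict),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Simple mediation (n = %d, %d bootstrap resamples)\n",
              x$n, x$n_boot))
  print(x$paths, ...)
  cat(sprintf("Indirect effect a*b = %.3f, %d%% CI [%.3f, %.3f] -> %s mediation\n",
              x$indirect, round(100 * x$level), x$ci[1], x$ci[2], x$verdict))
  invisible(x)
}

#' The four mediation analyses of the alexithymia pipeline
#'
#' Runs the standard quartet on a scored dataset: interoceptive emotional
#' awareness and attention regulation each as predictor, self-as-context
#' and psychological inflexibility (AAQ-II) each as mediator, with the
#' TAS-20 total as outcome.
#'
#' @param data a scored dataset.
#' @param n_boot,level,seed,ci_type passed to [mediate()]; each analysis
#'   draws its own child seed from `seed`.
#' @return A named list of four `mediation_result`s, in the order
#'   emotional-awareness/SAC, attention-regulation/SAC,
#'   emotional-awareness/AAQ, attention-regulation/AAQ.
#' @export
mediation_suite <- function(data, n_boot = 5000, level = 0.95, seed = 1,
                            ci_type = "percentile") {
  combos <- list(
    emoaw_sac = c(x = "maia_emotional_awareness", m = "sacs"),
    attreg_sac = c(x = "maia_attention_regulation", m = "sacs"),
    emoaw_aaq = c(x = "maia_emotional_awareness", m = "aaq"),
    attreg_aaq = c(x = "maia_attention_regulation", m = "aaq"))
  assert_cols(data, c(unique(unlist(combos)), "tas_total"),
              "mediation data")
  out <- lapply(seq_along(combos), function(i) {
    cb <- combos[[i]]
    mediate(data[[cb[["x"]]]], data[[cb[["m"]]]], data[["tas_total"]],
            n_boot = n_boot, level = level,
            seed = child_seed(seed, i), ci_type = ci_type)
  })
  names(out) <- names(combos)
  out
}
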