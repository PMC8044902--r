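# Ordinary-least-squares machinery: Enter-method regression summaries,
# AIC-guided backward stepwise elimination, and the noncentral-F power
# analytics for the omnibus R^2 test.

summarize_lm <- function(fit, data, outcome, predictors) {
  sm <- summary(fit)
  ct <- sm$coefficients
  keep <- setdiff(rownames(ct), "(Intercept)")
  sd_y <- sd(data[[outcome]])
  std_beta <- vapply(keep, function(v) {
    ct[v, 1] * sd(data[[v]]) / sd_y
  }, numeric(1))
  coefs <- tibble::tibble(
    term = keep,
    b = ct[keep, 1], se = ct[keep, 2],
    std_beta = unname(std_beta),
    t = ct[keep, 3], p = ct[keep, 4])
  fstat <- sm$fstatistic
  structure(list(
    outcome = outcome,
    retained = keep,
    coefficients = coefs,
    intercept = unname(coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_value = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    df = if (is.null(fstat)) c(0, fit$df.residual) else unname(fstat[2:3]),
    aic = AIC(fit),
    n = nrow(data),
    fit = fit), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Regression: %s ~ %s\n", x$outcome,
              if (length(x$retained)) paste(x$retained, collapse = " + ")
              else "1"))
  cat(sprintf("R^2 = %.3f, adjusted R^2 = %.3f, F(%d, %d) = %.2f, AIC = %.1f\n",
              x$r_squared, x$adj_r_squared, x$df[1], x$df[2],
              x$f_value, x$aic))
  print(x$coefficients, ...)
  invisible(x)
}

check_full_rank <- function(data, outcome, predictors) {
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (nrow(X) <= ncol(X) + 1) {
    stop("model not estimable: need n > number of predictors + 1",
         call. = FALSE)
  }
  q <- qr(cbind(1, X))
  if (q$rank < ncol(X) + 1) {
    dropped <- predictors[q$pivot[seq(q$rank + 1, ncol(X) + 1)] - 1]
    stop("design is rank deficient; collinear set includes: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Enter-method multiple regression
#'
#' Plain OLS with every listed predictor entered simultaneously, summarized
#' the way questionnaire studies report it: unstandardized B with SE,
#' standardized beta (B scaled by SD_x / SD_y), t and two-sided p per
#' coefficient, R-squared, adjusted R-squared, the omnibus F with its
#' degrees of freedom, and the Gaussian AIC.
#'
#' @param data a data frame.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor columns.
#' @return A `regression_result`.
#' @export
enter_regression <- function(data, outcome, predictors) {
  assert_cols(data, c(outcome, predictors), "regression data")
  check_full_rank(data, outcome, predictors)
  f <- stats::reformulate(predictors, response = outcome)
  fit <- lm(f, data = data)
  summarize_lm(fit, data, outcome, predictors)
}

#' Backward stepwise regression by AIC
#'
#' Starts from the full model and, at each step, removes the single
#' predictor whose deletion lowers the Gaussian AIC the most; stops when no
#' deletion lowers AIC (so a variable is retained only while it pays for
#' its own complexity).  An alternative `criterion = "p"` removes the
#' least-significant predictor while its p-value exceeds `p_remove`, the
#' classic significance-to-stay rule.
#'
#' @param data a data frame.
#' @param outcome outcome column name.
#' @param predictors starting predictor set (default: the 17 canonical
#'   predictors present in `data`).
#' @param criterion `"aic"` (default) or `"p"`.
#' @param p_remove removal threshold for `criterion = "p"`.
#' @return A `regression_result` for the final model, with an
#'   `elimination` tibble tracing each accepted step (variable dropped,
#'   AIC before and after).
#' @export
backward_stepwise <- function(data, outcome, predictors = NULL,
                              criterion = c("aic", "p"), p_remove = 0.10) {
  criterion <- match.arg(criterion)
  predictors <- predictors %||% intersect(predictor_names(), names(data))
  assert_cols(data, c(outcome, predictors), "regression data")
  check_full_rank(data, outcome, predictors)

  current <- predictors
  fit_model <- function(preds) {
    f <- if (length(preds)) stats::reformulate(preds, response = outcome)
         else stats::as.formula(paste(outcome, "~ 1"))
    lm(f, data = data)
  }
  fit <- fit_model(current)
  trace <- list()
  repeat {
    if (!length(current)) break
    if (criterion == "aic") {
      aic_now <- AIC(fit)
      cand <- vapply(current, function(v) {
        AIC(fit_model(setdiff(current, v)))
      }, numeric(1))
      best <- which.min(cand)
      if (cand[best] >= aic_now) break
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = length(trace) + 1L, dropped = current[best],
        aic_before = aic_now, aic_after = cand[best])
      current <- setdiff(current, current[best])
      fit <- fit_model(current)
    } else {
      ct <- summary(fit)$coefficients
      keep <- setdiff(rownames(ct), "(Intercept)")
      pv <- ct[keep, 4]
      worst <- which.max(pv)
      if (pv[worst] <= p_remove) break
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = length(trace) + 1L, dropped = keep[worst],
        aic_before = AIC(fit), aic_after = NA_real_)
      current <- setdiff(current, keep[worst])
      fit <- fit_model(current)
      trace[[length(trace)]]$aic_after <- AIC(fit)
    }
  }
  res <- summarize_lm(fit, data, outcome, current)
  res$elimination <- if (length(trace)) do.call(rbind, trace) else
    tibble::tibble(step = integer(), dropped = character(),
                   aic_before = numeric(), aic_after = numeric())
  res$start_predictors <- predictors
  res
}

# Power of the omnibus F test for R^2 > 0 in fixed-effects multiple
# regression, under noncentrality lambda = f2 * n (the total-sample
# convention of standard power software).
power_f2 <- function(u, f2, alpha, n) {
  v <- n - u - 1
  if (v < 1) return(NA_real_)
  fcrit <- qf(1 - alpha, u, v)
  pf(fcrit, u, v, ncp = f2 * n, lower.tail = FALSE)
}

#' A priori sample size for a multiple-regression F test
#'
#' Smallest integer n such that the omnibus test of R-squared deviating
#' from zero, with `u` predictors, effect size Cohen's f-squared `f2`, and
#' significance level `alpha`, reaches the target `power` under the
#' noncentral F distribution with noncentrality f2 * n.
#'
#' @param u number of predictors.
#' @param f2 Cohen's f-squared (medium = 0.15).
#' @param alpha significance level.
#' @param power target power, in (0, 1).
#' @return The required sample size (integer).
#' @export
required_n <- function(u, f2, alpha = 0.05, power = 0.80) {
  stopifnot(u >= 1, alpha > 0, alpha < 1, power > 0, power < 1)
  if (f2 <= 0) stop("f2 must be positive for a finite sample size",
                    call. = FALSE)
  n <- u + 2
  while (TRUE) {
    pw <- power_f2(u, f2, alpha, n)
    if (!is.na(pw) && pw >= power) return(as.integer(n))
    n <- n + 1
    if (n > 1e7) stop("no feasible n below 1e7; check the specification",
                      call. = FALSE)
  }
}

#' Post-hoc power of a multiple-regression F test
#'
#' Noncentral-F tail probability of the omnibus R-squared test at the
#' achieved sample size, with noncentrality f2 * n.
#'
#' @inheritParams required_n
#' @param n achieved sample size (must exceed u + 1).
#' @return The power (unrounded probability).
#' @export
achieved_power <- function(u, f2, alpha = 0.05, n) {
  stopifnot(u >= 1, n > u + 1, alpha > 0, alpha < 1, f2 >= 0)
  power_f2(u, f2, alpha, n)
}
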