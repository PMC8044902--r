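#' Skewness and excess kurtosis
#'
#' `type = "spss"` (default) gives the bias-corrected estimators most
#' statistics packages print (G1 and G2, with a normal distribution at 0
#' excess kurtosis); `type = "moment"` gives the raw moment ratios g1 and
#' g2.  A Bernoulli(0.5) variable has excess kurtosis close to -2 under
#' either convention.
#'
#' @param x numeric vector (length >= 4 for the bias-corrected kurtosis).
#' @param type `"spss"` or `"moment"`.
#' @return A single number; `NA` for zero-variance input.
#' @export
skewness <- function(x, type = c("spss", "moment")) {
  type <- match.arg(type)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  if (type == "moment") return(g1)
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' @rdname skewness
#' @export
kurtosis <- function(x, type = c("spss", "moment")) {
  type <- match.arg(type)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g2 <- mean((x - m)^4) / m2^2 - 3
  if (type == "moment") return(g2)
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Descriptive statistics with normality screening
#'
#' Per-variable mean, sample SD, range, skewness and excess kurtosis, with
#' a normality flag using the plus/minus 2 rule of thumb on both shape
#' statistics.  Zero-variance columns are flagged (`degenerate`), not
#' fatal.
#'
#' @param data a data frame of numeric variables.
#' @param type shape-statistic convention, see [skewness()].
#' @return A tibble, one row per variable.
#' @export
describe <- function(data, type = c("spss", "moment")) {
  type <- match.arg(type)
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  if (nrow(data) < 3) stop("need at least 3 rows", call. = FALSE)
  rows <- lapply(num, function(v) {
    x <- data[[v]]
    sk <- skewness(x, type)
    ku <- kurtosis(x, type)
    tibble::tibble(
      variable = v, mean = mean(x), sd = sd(x),
      min = min(x), max = max(x),
      skewness = sk, kurtosis = ku,
      degenerate = sd(x) == 0,
      normal_ok = !is.na(sk) && !is.na(ku) && abs(sk) <= 2 && abs(ku) <= 2)
  })
  do.call(rbind, rows)
}

#' Collinearity diagnostics: correlations and variance inflation factors
#'
#' Computes the predictor correlation matrix and per-predictor VIFs.
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the others;
#' a perfectly collinear predictor gets `Inf`.  Pairs with |r| >= `r_flag`
#' and predictors with VIF >= `vif_flag` are flagged, mirroring the usual
#' screening thresholds of 0.8 and 10.
#'
#' @param data data frame containing the predictors.
#' @param predictors predictor column names (default: all 17 canonical
#'   predictors present in `data`).
#' @param r_flag,vif_flag flagging thresholds.
#' @return A list with `correlations`, `vif` (tibble), `flagged_pairs`
#'   (tibble of offending correlations) and `ok` (no flags raised).
#' @export
collinearity <- function(data, predictors = NULL, r_flag = 0.8,
                         vif_flag = 10) {
  predictors <- predictors %||% intersect(predictor_names(), names(data))
  if (length(predictors) < 2) stop("need at least 2 predictors", call. = FALSE)
  X <- as.matrix(data[, predictors, drop = FALSE])
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("VIF undefined: n must exceed the number of predictors",
                   call. = FALSE)
  R <- cor(X)
  vifs <- vapply(seq_len(p), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  vif_tab <- tibble::tibble(predictor = predictors, vif = vifs,
                            flagged = vifs >= vif_flag)
  pairs <- which(abs(R) >= r_flag & upper.tri(R), arr.ind = TRUE)
  flagged_pairs <- tibble::tibble(
    var1 = predictors[pairs[, 1]], var2 = predictors[pairs[, 2]],
    r = R[pairs])
  list(correlations = R, vif = vif_tab, flagged_pairs = flagged_pairs,
       ok = !any(vif_tab$flagged) && nrow(flagged_pairs) == 0L)
}

#' Numeric residual diagnostics for a fitted regression
#'
#' Replaces visual P-P and residual scatter inspection with numbers:
#' skewness and excess kurtosis of the residuals (normality), and a
#' Breusch-Pagan test statistic (homoscedasticity) via
#' [lmtest::bptest()].
#'
#' @param fit an `lm` fit.
#' @return A tibble with one row of residual summaries.
#' @export
residual_diagnostics <- function(fit) {
  r <- residuals(fit)
  bp <- lmtest::bptest(fit)
  tibble::tibble(
    resid_skewness = skewness(r),
    resid_kurtosis = kurtosis(r),
    resid_normal_ok = abs(skewness(r)) <= 2 && abs(kurtosis(r)) <= 2,
    bp_statistic = unname(bp$statistic),
    bp_df = unname(bp$parameter),
    bp_p = unname(bp$p.value))
}
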