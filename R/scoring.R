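#' Default scoring map for the six questionnaires
#'
#' Defines, per instrument, the item identifiers, the admissible per-item
#' response range, the subscale-to-item assignment, the reverse-keyed items,
#' the aggregation rule (sum or mean of keyed items) and a post-aggregation
#' multiplier.  The shipped defaults follow the published instrument manuals:
#'
#' * TAS-20: 20 items on 1--5; subscales DIF (7 items), DDF (5), EOT (8);
#'   items 4, 5, 10, 18, 19 reverse keyed; total = DIF + DDF + EOT.
#' * DASS-21: 21 items on 0--3; depression/anxiety/stress, 7 items each,
#'   summed and doubled (the conventional x2 to the 42-item metric).
#' * AAQ-II: 7 items on 1--7, summed; higher = more inflexibility.
#' * SACS: 11 items on a 7-point scale, summed.
#' * MAIA-2: 32 items on 0--5 across eight subscales, each scored as the
#'   item mean; items 5--9 reverse keyed.
#' * PANAS-SF: 10 items on 1--5; positive and negative affect, 5 items each,
#'   summed.
#'
#' All scoring functions take an explicit map, so analyses never silently
#' depend on these defaults.
#'
#' @param dass_multiplier multiplier applied to DASS-21 subscale sums
#'   (default 2, the short-form-to-full-scale convention).
#' @param dass_range per-item response range for the DASS-21.
#' @return A named list of instrument definitions, class `scoring_map`.
#' @export
default_scoring_map <- function(dass_multiplier = 2, dass_range = c(0, 3)) {
  map <- list(
    tas = list(
      items = sprintf("tas_%02d", 1:20), range = c(1, 5),
      reverse = c(4, 5, 10, 18, 19),
      subscales = list(
        tas_dif = c(1, 3, 6, 7, 9, 13, 14),
        tas_ddf = c(2, 4, 11, 12, 17),
        tas_eot = c(5, 8, 10, 15, 16, 18, 19, 20)),
      aggregate = "sum", multiplier = 1, total = "tas_total"),
    dass = list(
      items = sprintf("das_%02d", 1:21), range = dass_range,
      reverse = integer(0),
      subscales = list(
        das_depression = c(3, 5, 10, 13, 16, 17, 21),
        das_anxiety    = c(2, 4, 7, 9, 15, 19, 20),
        das_stress     = c(1, 6, 8, 11, 12, 14, 18)),
      aggregate = "sum", multiplier = dass_multiplier, total = NULL),
    aaq = list(
      items = sprintf("aaq_%02d", 1:7), range = c(1, 7),
      reverse = integer(0),
      subscales = list(aaq = 1:7),
      aggregate = "sum", multiplier = 1, total = NULL),
    sacs = list(
      items = sprintf("sacs_%02d", 1:11), range = c(1, 7),
      reverse = integer(0),
      subscales = list(sacs = 1:11),
      aggregate = "sum", multiplier = 1, total = NULL),
    maia = list(
      items = sprintf("maia_%02d", 1:32), range = c(0, 5),
      reverse = 5:9,
      subscales = list(
        maia_noticing = 1:4,
        maia_not_distracting = 5:7,
        maia_not_worrying = 8:10,
        maia_attention_regulation = 11:17,
        maia_emotional_awareness = 18:22,
        maia_self_regulation = 23:26,
        maia_body_listening = 27:29,
        maia_trusting = 30:32),
      aggregate = "mean", multiplier = 1, total = NULL),
    panas = list(
      items = sprintf("panas_%02d", 1:10), range = c(1, 5),
      reverse = integer(0),
      subscales = list(
        panas_pa = c(1, 3, 5, 9, 10),
        panas_na = c(2, 4, 6, 7, 8)),
      aggregate = "sum", multiplier = 1, total = NULL)
  )
  structure(map, class = "scoring_map")
}

expected_item_counts <- c(tas = 20, dass = 21, aaq = 7, sacs = 11,
                          maia = 32, panas = 10)

validate_scoring_map <- function(map) {
  if (!inherits(map, "scoring_map")) {
    stop("`map` must be a scoring_map (see default_scoring_map()).",
         call. = FALSE)
  }
  for (nm in names(map)) {
    inst <- map[[nm]]
    n_items <- length(inst$items)
    if (nm %in% names(expected_item_counts) &&
        n_items != expected_item_counts[[nm]]) {
      stop(sprintf("instrument '%s' must have %d items, got %d",
                   nm, expected_item_counts[[nm]], n_items), call. = FALSE)
    }
    assigned <- as.integer(sort(unlist(inst$subscales, use.names = FALSE)))
    if (!identical(assigned, seq_len(n_items))) {
      stop(sprintf(
        "instrument '%s': subscales must partition items 1..%d exactly",
        nm, n_items), call. = FALSE)
    }
    if (length(inst$reverse) && !all(inst$reverse %in% seq_len(n_items))) {
      stop(sprintf("instrument '%s': reverse keys outside item range", nm),
           call. = FALSE)
    }
  }
  invisible(map)
}

# Reverse-keyed response on a bounded Likert range: x' = min + max - x.
reverse_key <- function(x, range) range[1] + range[2] - x

#' Score item-level questionnaire responses
#'
#' Converts per-item responses into instrument subscale scores, applying
#' reverse keying, aggregation (sum or item mean) and any multiplier, and
#' derives the TAS-20 total as the sum of its three subscales.  Demographic
#' columns (`age`, `gender`) pass through untouched when present.
#'
#' @param items a data frame of per-item responses; column names must match
#'   the item identifiers in `map`.
#' @param map a `scoring_map`, e.g. [default_scoring_map()].
#' @return A tibble of subscale scores (one row per participant).
#' @export
score_instruments <- function(items, map = default_scoring_map()) {
  validate_scoring_map(map)
  out <- list()
  if ("age" %in% names(items)) out$age <- items$age
  if ("gender" %in% names(items)) out$gender <- items$gender
  for (nm in names(map)) {
    inst <- map[[nm]]
    present <- inst$items %in% names(items)
    if (!any(present)) next
    if (!all(present)) {
      stop(sprintf("instrument '%s': missing item column(s) %s", nm,
                   paste(inst$items[!present], collapse = ", ")),
           call. = FALSE)
    }
    resp <- as.matrix(items[, inst$items, drop = FALSE])
    bad <- which(resp < inst$range[1] | resp > inst$range[2] | is.na(resp),
                 arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf(
        "instrument '%s': out-of-range response at row %d, item '%s'",
        nm, bad[1, 1], inst$items[bad[1, 2]]), call. = FALSE)
    }
    if (length(inst$reverse)) {
      resp[, inst$reverse] <- reverse_key(resp[, inst$reverse, drop = FALSE],
                                          inst$range)
    }
    for (sub in names(inst$subscales)) {
      idx <- inst$subscales[[sub]]
      agg <- if (identical(inst$aggregate, "mean")) {
        rowMeans(resp[, idx, drop = FALSE])
      } else {
        rowSums(resp[, idx, drop = FALSE])
      }
      out[[sub]] <- agg * inst$multiplier
    }
    if (!is.null(inst$total)) {
      out[[inst$total]] <- Reduce(`+`, out[names(inst$subscales)])
    }
  }
  tibble::as_tibble(out)
}

#' Classify a TAS-20 total score
#'
#' Applies the published TAS-20 cut-offs: totals of 51 or less indicate the
#' absence of alexithymia, 52--60 possible alexithymia, and 61 or more the
#' presence of alexithymia.
#'
#' @param total numeric vector of TAS-20 totals, each in \[20, 100\].
#' @return A factor with levels `absence`, `possible`, `presence`.
#' @export
classify_alexithymia <- function(total) {
  if (any(is.na(total)) || any(total < 20 | total > 100)) {
    stop("TAS-20 totals must lie in [20, 100]", call. = FALSE)
  }
  cls <- ifelse(total >= 61, "presence",
                ifelse(total >= 52, "possible", "absence"))
  factor(cls, levels = c("absence", "possible", "presence"))
}

#' Validate a scored dataset
#'
#' Checks that all 17 predictor columns and the 4 alexithymia outcome
#' columns are present and that the TAS-20 total equals the sum of its
#' three subscales.
#'
#' @param data a data frame of subscale-level scores.
#' @return The data as a tibble, invisibly classed `scored_dataset`.
#' @export
scored_dataset <- function(data) {
  assert_cols(data, c(predictor_names(), outcome_names()), "scored dataset")
  if (max(abs(data$tas_total -
              (data$tas_ddf + data$tas_dif + data$tas_eot))) > 1e-8) {
    stop("tas_total must equal tas_ddf + tas_dif + tas_eot", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  class(out) <- c("scored_dataset", class(out))
  out
}

#' Standardized (z-score) view of a scored dataset
#'
#' Centers and scales every predictor and outcome column to mean 0, SD 1
#' (sample SD).  Constant columns are left centered at 0.
#'
#' @param data a scored dataset (or any numeric data frame).
#' @param cols columns to standardize; defaults to all numeric columns.
#' @return A tibble of z scores with the same column names.
#' @export
z_view <- function(data, cols = NULL) {
  cols <- cols %||% names(data)[vapply(data, is.numeric, logical(1))]
  out <- data[, cols, drop = FALSE]
  for (cc in cols) {
    x <- out[[cc]]
    s <- sd(x)
    out[[cc]] <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  tibble::as_tibble(out)
}
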