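# Item-level expansion of subscale targets.
#
# The analyses only need subscale scores, but the scoring module is easier
# to trust when it can be exercised against item-level responses whose
# subscale scores are known in advance.  `items_for_target()` solves the
# small integer-allocation problem (deterministically, lowest item first);
# `generate_item_level()` applies it to a whole generated table.

# Distribute an aggregate target over k items each in [lo, hi].
# `target` is on the keyed (post-reverse) scale; returns keyed item values.
items_for_target <- function(target, k, lo, hi) {
  s <- round(target)
  s <- min(max(s, k * lo), k * hi)
  vals <- rep(lo, k)
  rem <- s - k * lo
  i <- 1
  while (rem > 0) {
    add <- min(hi - lo, rem)
    vals[i] <- lo + add
    rem <- rem - add
    i <- i + 1
  }
  vals
}

#' Generate item-level questionnaire responses
#'
#' Generates a subscale-level table from `config`, then expands each
#' subscale score into per-item Likert responses consistent with the
#' scoring map: summed subscales are reproduced exactly (after feasibility
#' rounding), mean-scored subscales to within one item step, and
#' reverse-keyed items are inverted so that scoring the items recovers the
#' targets.
#'
#' @param config a [generator_config()]; its bounds are always applied so
#'   targets are feasible on the instrument ranges.
#' @param map a `scoring_map` (defaults must match the instrument item
#'   counts: TAS-20 20, DASS-21 21, AAQ-II 7, SACS 11, MAIA-2 32,
#'   PANAS-SF 10).
#' @return A list with `items` (tibble of age, gender and per-item
#'   responses) and `targets` (the subscale table the items encode).
#' @export
generate_item_level <- function(config, map = default_scoring_map()) {
  validate_scoring_map(map)
  if (!config$apply_bounds) {
    stop("item-level generation requires apply_bounds = TRUE", call. = FALSE)
  }
  tab <- generate_table(config)
  targets <- tab$data
  items <- tibble::tibble(age = targets$age, gender = targets$gender)
  for (nm in names(map)) {
    inst <- map[[nm]]
    resp <- matrix(NA_real_, nrow(targets), length(inst$items),
                   dimnames = list(NULL, inst$items))
    for (sub in names(inst$subscales)) {
      if (!sub %in% names(targets)) {
        stop(sprintf("no generated column for subscale '%s'", sub),
             call. = FALSE)
      }
      idx <- inst$subscales[[sub]]
      k <- length(idx)
      tgt <- targets[[sub]] / inst$multiplier
      if (identical(inst$aggregate, "mean")) tgt <- tgt * k
      for (r in seq_len(nrow(targets))) {
        resp[r, idx] <- items_for_target(tgt[r], k,
                                         inst$range[1], inst$range[2])
      }
    }
    # Values so far are on the keyed scale; invert the reverse-keyed items
    # so that scoring (which re-reverses them) reproduces the targets.
    if (length(inst$reverse)) {
      resp[, inst$reverse] <- reverse_key(resp[, inst$reverse, drop = FALSE],
                                          inst$range)
    }
    items <- tibble::as_tibble(cbind(items, resp))
  }
  list(items = items, targets = targets)
}

#' Variable scales restricted to item-feasible subscale ranges
#'
#' Returns [default_variable_scales()] with each subscale's min/max
#' replaced by the range actually attainable by summing (or averaging)
#' items under `map`, so that every generated target is exactly
#' representable at item level.
#'
#' @param map a `scoring_map`.
#' @return A scales data frame for [generator_config()].
#' @export
item_feasible_scales <- function(map = default_scoring_map()) {
  sc <- default_variable_scales()
  rownames(sc) <- sc$variable
  for (nm in names(map)) {
    inst <- map[[nm]]
    for (sub in names(inst$subscales)) {
      if (!sub %in% rownames(sc)) next
      k <- length(inst$subscales[[sub]])
      if (identical(inst$aggregate, "mean")) {
        lo <- inst$range[1]; hi <- inst$range[2]
      } else {
        lo <- k * inst$range[1] * inst$multiplier
        hi <- k * inst$range[2] * inst$multiplier
      }
      sc[sub, "min"] <- lo
      sc[sub, "max"] <- hi
    }
  }
  sc
}
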