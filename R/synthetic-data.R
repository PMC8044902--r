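#' Per-variable measurement scales for the synthetic generator
#'
#' Location, spread, admissible range, and rounding behaviour for each of
#' the 17 predictors and 3 alexithymia subscales, calibrated to the
#' marginal summaries typical of adult community samples on these
#' instruments (questionnaire sums rounded to integers; MAIA-2 subscales
#' are item means and stay continuous).  `unit_scales()` replaces every
#' scale with mean 0 / SD 1 and no bounds, which is convenient for method
#' studies where clipping and rounding would only obscure planted effects.
#'
#' @return A data frame with columns `variable`, `mean`, `sd`, `min`,
#'   `max`, `round`.
#' @export
default_variable_scales <- function() {
  tab <- rbind(
    c("age",                        29.0, 9.8,  18, 61, 1),
    c("das_depression",             20.1, 10.9,  0, 42, 1),
    c("das_anxiety",                14.8, 10.0,  0, 42, 1),
    c("das_stress",                 20.3, 9.7,   0, 40, 1),
    c("aaq",                        31.7, 8.7,   7, 49, 1),
    c("sacs",                       46.0, 12.0, 11, 77, 1),
    c("maia_noticing",              2.78, 1.08,  0, 5,  0),
    c("maia_not_distracting",       2.04, 1.06,  0, 5,  0),
    c("maia_not_worrying",          2.30, 1.03,  0, 5,  0),
    c("maia_attention_regulation",  2.16, 1.00,  0, 5,  0),
    c("maia_emotional_awareness",   2.65, 1.25,  0, 5,  0),
    c("maia_self_regulation",       2.15, 1.14,  0, 5,  0),
    c("maia_body_listening",        1.83, 1.29,  0, 5,  0),
    c("maia_trusting",              2.20, 1.38,  0, 5,  0),
    c("panas_pa",                   25.1, 7.7,  10, 50, 1),
    c("panas_na",                   27.7, 9.3,  10, 50, 1),
    c("tas_ddf",                    17.2, 4.1,   5, 25, 1),
    c("tas_dif",                    23.0, 5.5,   7, 35, 1),
    c("tas_eot",                    20.8, 4.1,   8, 40, 1))
  out <- data.frame(variable = tab[, 1],
                    mean = as.numeric(tab[, 2]), sd = as.numeric(tab[, 3]),
                    min = as.numeric(tab[, 4]), max = as.numeric(tab[, 5]),
                    round = as.numeric(tab[, 6]) == 1,
                    stringsAsFactors = FALSE)
  out
}

#' @rdname default_variable_scales
#' @export
unit_scales <- function() {
  sc <- default_variable_scales()
  sc$mean <- 0; sc$sd <- 1; sc$min <- -Inf; sc$max <- Inf; sc$round <- FALSE
  sc
}

# Continuous predictors (everything except gender, which is Bernoulli).
continuous_predictors <- function() setdiff(predictor_names(), "gender")

#' Default predictor correlation structure
#'
#' A two-factor model: a general-distress factor loading on the DASS
#' subscales, psychological inflexibility and negative affect (negatively
#' on positive affect and self-as-context), and an interoceptive-awareness
#' factor loading on the MAIA-2 subscales and self-as-context.  The factor
#' construction guarantees a positive-definite matrix while reproducing the
#' broad sign pattern seen between these instruments (distress measures
#' inter-correlate positively, interoception correlates negatively with
#' distress and positively with self-as-context).
#'
#' @return A 16x16 correlation matrix over the continuous predictors.
#' @export
default_predictor_correlation <- function() {
  vars <- continuous_predictors()
  L <- matrix(0, length(vars), 2, dimnames = list(vars, c("distress", "intero")))
  L[c("das_depression", "das_anxiety", "das_stress"), 1] <- c(0.75, 0.70, 0.72)
  L["aaq", 1] <- 0.60
  L["panas_na", 1] <- 0.70
  L["panas_pa", 1] <- -0.35
  L["sacs", ] <- c(-0.40, 0.45)
  maia <- grep("^maia_", vars, value = TRUE)
  L[maia, 2] <- 0.55
  L[c("maia_not_distracting", "maia_not_worrying"), 1] <- -0.25
  L["maia_attention_regulation", 1] <- -0.20
  L["panas_pa", 2] <- 0.30
  sigma <- L %*% t(L)
  diag(sigma) <- 1
  sigma
}

#' Specify a latent participant group
#'
#' @param weight mixing probability of the group.
#' @param mean_profile named numeric vector of standardized (z-scale) mean
#'   shifts over the continuous predictors; omitted variables default to 0.
#' @param covariance correlation-scale covariance of the continuous
#'   predictors within the group; defaults to
#'   [default_predictor_correlation()].
#' @param p_male probability that `gender == 1` within the group.
#' @return A `group_spec` list.
#' @export
group_spec <- function(weight = 1, mean_profile = NULL, covariance = NULL,
                       p_male = 0.5) {
  vars <- continuous_predictors()
  mu <- setNames(numeric(length(vars)), vars)
  if (!is.null(mean_profile)) {
    bad <- setdiff(names(mean_profile), vars)
    if (length(bad)) {
      stop("unknown predictor(s) in mean_profile: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    mu[names(mean_profile)] <- mean_profile
  }
  structure(list(weight = weight, mean_profile = mu,
                 covariance = covariance %||% default_predictor_correlation(),
                 p_male = p_male),
            class = "group_spec")
}

#' Planted outcome model for one alexithymia subscale
#'
#' @param linear_coefs named numeric vector of z-scale slopes on predictors.
#' @param group_offsets numeric vector, one z-scale intercept shift per
#'   latent group (recycled to the number of groups).
#' @param interactions list of `list(predictor=, group=, coef=)` entries:
#'   an extra slope `coef` on `predictor` active only inside `group`.
#' @param noise_sd residual SD on the z scale.
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(linear_coefs = NULL, group_offsets = 0,
                         interactions = list(), noise_sd = 0.8) {
  structure(list(linear_coefs = linear_coefs %||% numeric(0),
                 group_offsets = group_offsets,
                 interactions = interactions, noise_sd = noise_sd),
            class = "outcome_spec")
}

#' Default planted outcome model
#'
#' Linear z-scale effects with the sign pattern questionnaire studies of
#' alexithymia typically report: inflexibility and distress raise the
#' subscales, interoceptive attention regulation / not-distracting and
#' positive affect lower them, age raises externally oriented thinking.
#' No group offsets or interactions by default.
#'
#' @return A named list of three [outcome_spec()]s.
#' @export
default_outcome_model <- function() {
  list(
    tas_ddf = outcome_spec(c(aaq = 0.25, maia_not_distracting = -0.30,
                             maia_attention_regulation = -0.25,
                             panas_pa = -0.20, gender = 0.10),
                           noise_sd = 0.80),
    tas_dif = outcome_spec(c(das_depression = 0.20, das_anxiety = 0.20,
                             aaq = 0.20, maia_not_distracting = -0.25,
                             maia_attention_regulation = -0.20),
                           noise_sd = 0.75),
    tas_eot = outcome_spec(c(age = 0.15, das_anxiety = 0.25,
                             maia_emotional_awareness = -0.30, sacs = -0.15),
                           noise_sd = 0.85))
}

#' Build a synthetic-data generator configuration
#'
#' Bundles everything the generator needs: sample size, seed, latent group
#' mixture, per-subscale outcome models, an optional planted mediation
#' path, and the measurement scales used to map latent z scores onto
#' instrument ranges.  The same configuration and seed always reproduce the
#' same table.
#'
#' @param n_participants number of rows to generate (>= 2).
#' @param seed integer seed; one RNG stream per table.
#' @param groups list of [group_spec()]s; weights must sum to 1.
#' @param outcome_model named list of [outcome_spec()]s for `tas_ddf`,
#'   `tas_dif`, `tas_eot`.
#' @param mediation optional `list(x=, m=, a=, b=, c_direct=, noise_sd=)`
#'   planting `m = a x + e` and adding `b m + c_direct x` to the TAS total
#'   (spread equally over the three subscales).
#' @param scales per-variable measurement scales
#'   ([default_variable_scales()] or [unit_scales()]).
#' @param apply_bounds clip and round generated values to instrument
#'   ranges?  Disable to study planted effects without truncation bias.
#' @return A validated `generator_config`.
#' @export
generator_config <- function(n_participants = 230, seed = 1,
                             groups = list(group_spec()),
                             outcome_model = default_outcome_model(),
                             mediation = NULL,
                             scales = default_variable_scales(),
                             apply_bounds = TRUE) {
  cfg <- structure(list(n_participants = n_participants, seed = seed,
                        groups = groups, outcome_model = outcome_model,
                        mediation = mediation, scales = scales,
                        apply_bounds = apply_bounds),
                   class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 2) {
    stop("n_participants must be at least 2", call. = FALSE)
  }
  w <- vapply(cfg$groups, function(g) g$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) {
    stop("group weights must sum to 1", call. = FALSE)
  }
  for (i in seq_along(cfg$groups)) {
    cv <- cfg$groups[[i]]$covariance
    ok <- tryCatch({ chol(cv); TRUE }, error = function(e) FALSE)
    if (!ok) {
      stop(sprintf("covariance for group %d is not positive semi-definite", i),
           call. = FALSE)
    }
  }
  if (!all(c("tas_ddf", "tas_dif", "tas_eot") %in% names(cfg$outcome_model))) {
    stop("outcome_model must define tas_ddf, tas_dif and tas_eot",
         call. = FALSE)
  }
  if (!is.null(cfg$mediation)) {
    need <- c("x", "m", "a", "b", "c_direct", "noise_sd")
    if (!all(need %in% names(cfg$mediation))) {
      stop("mediation spec needs fields: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(cfg)
}

# Map a z-scale column to its instrument scale, with optional clip/round.
scale_to_instrument <- function(z, scale_row, apply_bounds) {
  x <- scale_row$mean + scale_row$sd * z
  if (apply_bounds) {
    x <- pmin(pmax(x, scale_row$min), scale_row$max)
    if (isTRUE(scale_row$round)) x <- round(x)
  }
  x
}

#' Generate a synthetic participant table
#'
#' Draws latent group labels from the configured mixture, correlated
#' continuous predictors from each group's Gaussian profile, Bernoulli
#' gender, and the three alexithymia subscales from the planted linear,
#' group-offset, interaction and mediation structure; then maps every
#' variable onto its instrument scale.  The TAS total is the sum of the
#' three subscales.
#'
#' @param config a [generator_config()].
#' @return A list with elements `data` (scored-dataset tibble), `labels`
#'   (hidden group id per row), and `truth` (the full configuration plus
#'   derived quantities), classed `participant_table`.
#' @export
generate_table <- function(config) {
  validate_generator_config(config)
  vars <- continuous_predictors()
  n <- config$n_participants
  G <- length(config$groups)
  local_seed(config$seed, {
    w <- vapply(config$groups, function(g) g$weight, numeric(1))
    labels <- sample.int(G, n, replace = TRUE, prob = w)
    Z <- matrix(0, n, length(vars), dimnames = list(NULL, vars))
    gender <- integer(n)
    for (g in seq_len(G)) {
      idx <- which(labels == g)
      if (!length(idx)) next
      gs <- config$groups[[g]]
      eps <- matrix(rnorm(length(idx) * length(vars)), length(idx))
      Z[idx, ] <- sweep(eps %*% chol(gs$covariance), 2, gs$mean_profile, "+")
      gender[idx] <- rbinom(length(idx), 1, gs$p_male)
    }
    z_gender <- 2 * (gender - 0.5)  # +/-1 coding on the z scale
    Zfull <- cbind(Z, gender = z_gender)

    med <- config$mediation
    if (!is.null(med)) {
      zx <- Zfull[, med$x]
      zm <- med$a * zx + rnorm(n, 0, med$noise_sd)
      Z[, med$m] <- zm
      Zfull[, med$m] <- zm
    }

    Y <- matrix(0, n, 3, dimnames = list(NULL, outcome_names(total = FALSE)))
    for (oc in colnames(Y)) {
      spec <- config$outcome_model[[oc]]
      y <- rnorm(n, 0, spec$noise_sd)
      cf <- spec$linear_coefs
      if (length(cf)) {
        bad <- setdiff(names(cf), colnames(Zfull))
        if (length(bad)) stop("unknown predictor(s) in linear_coefs: ",
                              paste(bad, collapse = ", "), call. = FALSE)
        y <- y + Zfull[, names(cf), drop = FALSE] %*% cf
      }
      offs <- rep_len(spec$group_offsets, G)
      y <- y + offs[labels]
      for (it in spec$interactions) {
        y <- y + it$coef * Zfull[, it$predictor] * (labels == it$group)
      }
      if (!is.null(med)) y <- y + (med$b * Zfull[, med$m] +
                                     med$c_direct * Zfull[, med$x]) / 3
      Y[, oc] <- y
    }

    sc <- config$scales
    rownames(sc) <- sc$variable
    data <- tibble::tibble(.rows = n)
    for (v in predictor_names()) {
      data[[v]] <- if (v == "gender") gender else {
        scale_to_instrument(Z[, v], sc[v, ], config$apply_bounds)
      }
    }
    for (oc in colnames(Y)) {
      data[[oc]] <- scale_to_instrument(Y[, oc], sc[oc, ], config$apply_bounds)
    }
    data$tas_total <- data$tas_ddf + data$tas_dif + data$tas_eot

    structure(list(data = scored_dataset(data),
                   labels = labels,
                   truth = list(config = config,
                                group_sizes = tabulate(labels, G))),
              class = "participant_table")
  })
}

#' Well-separated latent group specifications
#'
#' Builds `n_groups` group specs whose mean profiles sit at the vertices of
#' a regular simplex in predictor space, scaled so every pairwise
#' Mahalanobis distance (under the shared covariance) equals `distance`.
#'
#' @param n_groups number of groups.
#' @param distance target pairwise Mahalanobis distance.
#' @param covariance shared within-group covariance.
#' @param weights mixing weights (default equal).
#' @return A list of [group_spec()]s.
#' @export
separated_group_specs <- function(n_groups = 3, distance = 8,
                                  covariance = default_predictor_correlation(),
                                  weights = NULL) {
  vars <- continuous_predictors()
  p <- length(vars)
  stopifnot(n_groups >= 2, n_groups <= p)
  # Orthogonal sign directions (Sylvester/Hadamard construction) spread the
  # separation across every predictor, so per-variable shifts stay small
  # and survive instrument-range clipping.
  H <- matrix(1, 1, 1)
  while (ncol(H) < p) H <- rbind(cbind(H, H), cbind(H, -H))
  U <- H[1 + seq_len(n_groups), seq_len(p), drop = FALSE] / sqrt(p)
  U <- sweep(U, 2, colMeans(U))
  # Distinct Hadamard rows are pairwise equidistant; scale in whitened
  # coordinates and map through chol(covariance) so that every pairwise
  # Mahalanobis distance equals `distance` exactly.
  d12 <- sqrt(sum((U[1, ] - U[2, ])^2))
  centers <- (U * (distance / d12)) %*% chol(covariance)
  weights <- weights %||% rep(1 / n_groups, n_groups)
  lapply(seq_len(n_groups), function(g) {
    group_spec(weight = weights[g],
               mean_profile = setNames(centers[g, ], vars),
               covariance = covariance)
  })
}

# Squared Mahalanobis distance between two profile vectors under sigma.
mahalanobis_sq <- function(a, b, sigma) {
  d <- a - b
  as.numeric(d %*% solve(sigma, d))
}

#' Canonical planted-structure study configurations
#'
#' Three ready-made generator configurations used throughout the package's
#' validation studies:
#'
#' * `subgroup_study_config()`: three well-separated latent groups
#'   (pairwise Mahalanobis distance 8 across all predictors) whose
#'   alexithymia subscale profiles point in orthogonal directions (each
#'   group elevated on its own subscale, lowered on the others) -- the
#'   ground truth for hidden-layer subgroup recovery.
#' * `interaction_study_config()`: the same separated groups, each with a
#'   different predictor driving one subscale (group-specific slopes), the
#'   nonlinearity a purely linear model cannot represent.
#' * `mediation_study_config()`: a single homogeneous group on unit scales
#'   with independent predictors and pure-noise subscales, plus a planted
#'   mediation path `m = a x + e`, `y += b m + c_direct x`, so the OLS
#'   estimands equal the planted path values exactly.
#'
#' @param n_participants sample size.
#' @param seed generator seed.
#' @param n_groups,distance see [separated_group_specs()].
#' @param a,b,c_direct,noise_sd planted mediation paths and mediator noise.
#' @return A [generator_config()].
#' @export
subgroup_study_config <- function(n_participants = 230, seed = 1,
                                  n_groups = 3, distance = 8) {
  om <- default_outcome_model()
  base <- c(1.5, -1.0, -0.5)
  outs <- outcome_names(total = FALSE)
  for (i in seq_along(outs)) {
    offs <- base[((seq_len(n_groups) - i) %% 3) + 1]
    om[[outs[i]]]$group_offsets <- offs
    om[[outs[i]]]$noise_sd <- 0.4
  }
  generator_config(n_participants = n_participants, seed = seed,
                   groups = separated_group_specs(n_groups, distance),
                   outcome_model = om)
}

#' @rdname subgroup_study_config
#' @param outcome the subscale carrying the group-specific slopes.
#' @export
interaction_study_config <- function(n_participants = 230, seed = 1,
                                     outcome = "tas_ddf") {
  om <- default_outcome_model()
  om[[outcome]]$interactions <- list(
    list(predictor = "das_anxiety", group = 1, coef = 1.2),
    list(predictor = "aaq", group = 2, coef = -1.2),
    list(predictor = "sacs", group = 3, coef = 1.2))
  om[[outcome]]$group_offsets <- c(-0.8, 0.3, 0.8)
  om[[outcome]]$noise_sd <- 0.5
  generator_config(n_participants = n_participants, seed = seed,
                   groups = separated_group_specs(3, 8),
                   outcome_model = om)
}

#' @rdname subgroup_study_config
#' @export
mediation_study_config <- function(n_participants = 230, seed = 1,
                                   a = 0.5, b = 0.5, c_direct = 0.2,
                                   noise_sd = 1) {
  vars <- continuous_predictors()
  om <- list(tas_ddf = outcome_spec(noise_sd = 0.8),
             tas_dif = outcome_spec(noise_sd = 0.8),
             tas_eot = outcome_spec(noise_sd = 0.8))
  generator_config(
    n_participants = n_participants, seed = seed,
    groups = list(group_spec(covariance = diag(length(vars)))),
    outcome_model = om,
    mediation = list(x = "maia_emotional_awareness", m = "sacs",
                     a = a, b = b, c_direct = c_direct,
                     noise_sd = noise_sd),
    scales = unit_scales(), apply_bounds = FALSE)
}

#' Write a participant table and its ground truth to disk
#'
#' The table goes to a header-labelled CSV (one participant per row); the
#' planted parameters go to a YAML sidecar.
#'
#' @param x a `participant_table` from [generate_table()].
#' @param csv_path output CSV path.
#' @param truth_path output YAML path; defaults to `<csv>.truth.yaml`.
#' @return Invisibly, the CSV path.
#' @export
write_participant_table <- function(x, csv_path,
                                    truth_path = paste0(csv_path,
                                                        ".truth.yaml")) {
  stopifnot(inherits(x, "participant_table"))
  df <- cbind(x$data, group = x$labels)
  utils::write.csv(df, csv_path, row.names = FALSE)
  truth <- serialize_truth(x$truth)
  yaml::write_yaml(truth, truth_path)
  invisible(csv_path)
}

serialize_truth <- function(truth) {
  cfg <- truth$config
  list(
    n_participants = cfg$n_participants,
    seed = cfg$seed,
    group_weights = vapply(cfg$groups, `[[`, numeric(1), "weight"),
    group_sizes = truth$group_sizes,
    mean_profiles = lapply(cfg$groups, function(g) as.list(g$mean_profile)),
    outcome_model = lapply(cfg$outcome_model, function(o) {
      list(linear_coefs = as.list(o$linear_coefs),
           group_offsets = o$group_offsets,
           interactions = o$interactions, noise_sd = o$noise_sd)
    }),
    mediation = cfg$mediation,
    apply_bounds = cfg$apply_bounds)
}

#' Read a participant table written by [write_participant_table()]
#'
#' @param csv_path the CSV path.
#' @return A tibble (including the `group` column when present).
#' @export
read_participant_table <- function(csv_path) {
  tibble::as_tibble(utils::read.csv(csv_path, check.names = FALSE))
}
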