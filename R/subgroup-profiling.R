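# Two-stage subgroup discovery: Ward agglomeration (squared Euclidean
# distance) chooses the number of clusters from the agglomeration schedule
# and supplies centroids; K-means (Lloyd, seeded exactly at those
# centroids, no random restarts) refines the memberships.  Each group is
# then profiled against all other groups combined with Cohen's d (and an
# odds-ratio conversion for binary variables).

#' Ward clustering of activation rows
#'
#' Full agglomerative merge tree under Ward's criterion with squared
#' Euclidean distances.  Reported merge heights are the increase in total
#' within-cluster sum of squares at each merge.  The number of clusters is
#' chosen at the largest relative jump between successive merge heights
#' (the agglomeration-schedule elbow), bounded by `k_max`, unless `k` is
#' given explicitly.
#'
#' @param activations numeric matrix, one row per participant (N >= 4).
#' @param k optional fixed number of clusters (overrides the elbow).
#' @param k_max largest k the elbow may select.
#' @return A list: `k`, `labels` (cut at k), `centroids` (k x p),
#'   `schedule` (tibble of merge heights), `tree` (the `hclust` object).
#' @export
ward_cluster <- function(activations, k = NULL, k_max = 6) {
  A <- as.matrix(activations)
  n <- nrow(A)
  if (n < 4) stop("Ward clustering needs at least 4 rows", call. = FALSE)
  # ward.D on squared distances follows the classic Ward recurrence whose
  # heights are twice the within-SS increase; halve to report SS units.
  tree <- hclust(dist(A)^2, method = "ward.D")
  heights <- tree$height / 2
  schedule <- tibble::tibble(step = seq_along(heights), height = heights)
  if (is.null(k)) {
    k <- select_k_elbow(heights, n, k_max)
    if (k == 1L) {
      warning("no separation in the agglomeration schedule; k = 1",
              call. = FALSE)
    }
  }
  labels <- if (k == 1L) rep(1L, n) else cutree(tree, k = k)
  centroids <- centroid_matrix(A, labels, k)
  list(k = as.integer(k), labels = as.integer(labels),
       centroids = centroids, schedule = schedule, tree = tree)
}

# Elbow on the agglomeration schedule: the merge with the largest height
# ratio to its predecessor marks where dissimilar clusters start fusing;
# cutting just before it leaves k = n - step + 1 clusters.
select_k_elbow <- function(heights, n, k_max) {
  tol <- max(heights) * 1e-10
  if (max(heights) <= 0) return(1L)
  steps <- seq_along(heights)
  ks <- n - steps + 1L
  ok <- ks >= 2 & ks <= k_max & c(0, heights[-length(heights)]) > tol
  if (!any(ok)) return(1L)
  ratios <- ifelse(ok, heights / c(NA, heights[-length(heights)]), -Inf)
  best <- which.max(ratios)
  as.integer(n - best + 1L)
}

centroid_matrix <- function(A, labels, k) {
  cen <- matrix(NA_real_, k, ncol(A))
  for (g in seq_len(k)) {
    cen[g, ] <- colMeans(A[labels == g, , drop = FALSE])
  }
  cen
}

within_ss <- function(A, labels, centroids) {
  sum(vapply(seq_len(nrow(centroids)), function(g) {
    rows <- A[labels == g, , drop = FALSE]
    if (!nrow(rows)) return(0)
    sum(sweep(rows, 2, centroids[g, ])^2)
  }, numeric(1)))
}

#' K-means refinement from fixed centroid seeds
#'
#' Lloyd's algorithm started exactly at the supplied centroids (no random
#' restarts): assign each row to its nearest centroid by squared Euclidean
#' distance, recompute centroids, and repeat until the assignment is a
#' fixed point or the centroid shift falls below `tol`.  If a cluster
#' empties during iteration, its centroid is re-seeded at the point
#' farthest from its current centroid and the event is logged.
#'
#' @param activations numeric matrix of rows to cluster.
#' @param k number of clusters; must match `nrow(seeds)`.
#' @param seeds k x p matrix of starting centroids (typically the Ward
#'   centroids).
#' @param tol convergence tolerance on the centroid shift.
#' @param max_iter iteration cap.
#' @return A `cluster_assignment` list: `k`, `labels`, `ward_centroids`
#'   (the seeds), `kmeans_centroids`, `iterations`, `wss` (final
#'   within-cluster SS), `events` (re-seeding log).
#' @export
kmeans_refine <- function(activations, k, seeds, tol = 1e-8,
                          max_iter = 100) {
  A <- as.matrix(activations)
  seeds <- as.matrix(seeds)
  if (nrow(seeds) != k) stop("k must match the number of seed centroids",
                             call. = FALSE)
  cen <- seeds
  events <- character(0)
  labels <- integer(nrow(A))
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist_to_centroids(A, cen)
    new_labels <- max.col(-d2, ties.method = "first")
    for (g in seq_len(k)) {
      if (!any(new_labels == g)) {
        # farthest point from the empty cluster's centroid becomes its seed
        far <- which.max(d2[, g])
        new_labels[far] <- g
        events <- c(events,
                    sprintf("iteration %d: cluster %d emptied; re-seeded at row %d",
                            it, g, far))
      }
    }
    new_cen <- centroid_matrix(A, new_labels, k)
    shift <- max(abs(new_cen - cen))
    converged <- identical(new_labels, labels) || shift < tol
    labels <- new_labels
    cen <- new_cen
    if (converged) break
  }
  structure(list(k = as.integer(k), labels = labels,
                 ward_centroids = seeds, kmeans_centroids = cen,
                 iterations = it, wss = within_ss(A, labels, cen),
                 events = events),
            class = "cluster_assignment")
}

sq_dist_to_centroids <- function(A, cen) {
  an <- rowSums(A^2)
  cn <- rowSums(cen^2)
  outer(an, cn, "+") - 2 * A %*% t(cen)
}

#' Two-stage clustering: Ward then seeded K-means
#'
#' @inheritParams ward_cluster
#' @return The `cluster_assignment` from [kmeans_refine()], with the Ward
#'   `schedule`, `tree` and selected `k` attached.
#' @export
two_stage_cluster <- function(activations, k = NULL, k_max = 6) {
  wd <- ward_cluster(activations, k = k, k_max = k_max)
  if (wd$k == 1L) {
    asg <- structure(list(k = 1L, labels = rep(1L, nrow(activations)),
                          ward_centroids = wd$centroids,
                          kmeans_centroids = wd$centroids,
                          iterations = 0L,
                          wss = within_ss(as.matrix(activations),
                                          rep(1L, nrow(activations)),
                                          wd$centroids),
                          events = character(0)),
                     class = "cluster_assignment")
  } else {
    asg <- kmeans_refine(activations, wd$k, wd$centroids)
  }
  asg$schedule <- wd$schedule
  asg$tree <- wd$tree
  asg$ward_labels <- wd$labels
  asg
}

#' Cohen's d for one group against the rest
#'
#' d = (mean_g - mean_rest) / sqrt((SD_g^2 + SD_rest^2) / 2), the pooled-SD
#' two-sample form with the remaining groups combined as the comparison.
#'
#' @param x numeric vector; `in_group` logical vector of membership.
#' @return A single number (NA when either side has fewer than 2 cases or
#'   both SDs are 0).
#' @export
cohens_d_vs_rest <- function(x, in_group) {
  g <- x[in_group]
  r <- x[!in_group]
  if (length(g) < 2 || length(r) < 2) return(NA_real_)
  sp <- sqrt((var(g) + var(r)) / 2)
  if (sp == 0) return(if (mean(g) == mean(r)) 0 else NA_real_)
  (mean(g) - mean(r)) / sp
}

#' Odds-ratio effect size for a binary variable, as Cohen's d
#'
#' Computes the odds ratio of `x == 1` for the group versus the rest
#' (Haldane 0.5 correction when any cell is empty) and converts it to a
#' standardized mean difference.  The default conversion is Chinn's
#' d = ln(OR) / 1.81; `literal = TRUE` instead divides the raw odds ratio
#' by 1.81 (for auditing against reports that applied the rule verbatim).
#'
#' @param x binary (0/1) vector; `in_group` logical membership.
#' @param literal use OR / 1.81 instead of ln(OR) / 1.81.
#' @return A list with `odds_ratio` and `d`.
#' @export
odds_ratio_d <- function(x, in_group, literal = FALSE) {
  a <- sum(x == 1 & in_group); b <- sum(x == 0 & in_group)
  c <- sum(x == 1 & !in_group); d <- sum(x == 0 & !in_group)
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5
                              c <- c + 0.5; d <- d + 0.5 }
  or <- (a / b) / (c / d)
  list(odds_ratio = or, d = or_to_d(or, literal))
}

#' @rdname odds_ratio_d
#' @param or an odds ratio.
#' @export
or_to_d <- function(or, literal = FALSE) {
  if (literal) or / 1.81 else log(or) / 1.81
}

cohen_flag <- function(d, report_min = 0.35, salient_min = 0.5,
                       large_min = 0.8) {
  if (is.na(d)) return(NA_character_)
  ad <- abs(d)
  if (ad >= large_min) "large"
  else if (ad >= salient_min) "medium"
  else if (ad >= report_min) "small"
  else "suppressed"
}

#' Effect-size profile of discovered subgroups
#'
#' For every (group, predictor) pair, the standardized difference between
#' the group and all other groups combined: Cohen's d for continuous
#' variables, ln(OR)/1.81 for binary ones.  Effects are flagged by Cohen's
#' bands: |d| of at least 0.8 is large, 0.5 medium (the salience
#' threshold), 0.35 small; smaller entries are suppressed in the rendered
#' table.
#'
#' @param data the scored dataset (profiles use the original variable
#'   scales).
#' @param assignment a `cluster_assignment` (or any integer label vector).
#' @param variables columns to profile (default: the 17 predictors).
#' @param binary names of variables treated as binary (default `gender`).
#' @param or_literal see [odds_ratio_d()].
#' @return A `cluster_profile`: tibble with group, n, variable, d, flag.
#' @export
profile_groups <- function(data, assignment,
                           variables = predictor_names(),
                           binary = "gender", or_literal = FALSE) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  if (length(labels) != nrow(data)) {
    stop("assignment must cover every row of the data", call. = FALSE)
  }
  assert_cols(data, variables, "profile data")
  groups <- sort(unique(labels))
  rows <- list()
  for (g in groups) {
    ing <- labels == g
    if (sum(ing) < 2) {
      warning(sprintf("group %d has fewer than 2 members; d undefined", g),
              call. = FALSE)
    }
    for (v in variables) {
      d <- if (v %in% binary) {
        odds_ratio_d(data[[v]], ing, literal = or_literal)$d
      } else {
        cohens_d_vs_rest(data[[v]], ing)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, n = sum(ing), variable = v, d = d,
        flag = cohen_flag(d))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_profile", class(out))
  out
}

#' Render a cluster profile as a wide predictor-by-group table
#'
#' One row per variable, one column per group (headed by its size); cells
#' show d to two decimals, with sub-threshold effects shown as `--`.
#'
#' @param profile a `cluster_profile`.
#' @return A tibble in report layout.
#' @export
format_profile_table <- function(profile) {
  groups <- sort(unique(profile$group))
  vars <- unique(profile$variable)
  out <- tibble::tibble(variable = vars)
  for (g in groups) {
    sub <- profile[profile$group == g, ]
    n_g <- sub$n[1]
    cell <- ifelse(is.na(sub$d), "NA",
                   ifelse(sub$flag == "suppressed", "--",
                          sprintf("%.2f", sub$d)))
    out[[sprintf("group%d (n=%d)", g, n_g)]] <- cell[match(vars, sub$variable)]
  }
  out
}

#' Train, cluster and profile the four-network suite
#'
#' The standard analysis runs four deep networks -- one estimating the
#' three alexithymia subscales jointly and one per subscale -- then, for
#' each, clusters the upper-hidden-layer activations (Ward then seeded
#' K-means) and profiles the resulting participant groups.
#'
#' @param data a scored dataset.
#' @param specs list of four [network_spec()]s; defaults to the reference
#'   architecture with outputs (DDF+DIF+EOT), DDF, DIF, EOT.
#' @param k_max upper bound for elbow-selected k.
#' @param cluster_on `"upper_hidden"` (default) clusters network
#'   activations; `"z_scores"` clusters the standardized predictors
#'   directly.
#' @param seed base seed; network i uses child seed i unless its spec sets
#'   one explicitly.
#' @return A list of four elements, each with `network`, `assignment`,
#'   `profile`, and `table` (the formatted report).
#' @export
run_networks_suite <- function(data, specs = NULL, k_max = 6,
                               cluster_on = c("upper_hidden", "z_scores"),
                               seed = 1) {
  cluster_on <- match.arg(cluster_on)
  if (is.null(specs)) {
    outs <- list(c("tas_ddf", "tas_dif", "tas_eot"),
                 "tas_ddf", "tas_dif", "tas_eot")
    specs <- lapply(seq_along(outs), function(i) {
      network_spec(outputs = outs[[i]], seed = child_seed(seed, i))
    })
  }
  n_out <- vapply(specs, function(s) length(s$outputs), integer(1))
  if (!identical(n_out, c(3L, 1L, 1L, 1L))) {
    stop("the four specs must have 3, 1, 1 and 1 outputs", call. = FALSE)
  }
  lapply(specs, function(sp) {
    net <- train_network(data, sp)
    feats <- if (cluster_on == "upper_hidden") extract_upper_hidden(net)
             else as.matrix(z_view(data, predictor_names()))
    asg <- two_stage_cluster(feats, k_max = k_max)
    prof <- profile_groups(data, asg)
    list(network = net, assignment = asg, profile = prof,
         table = format_profile_table(prof))
  })
}
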