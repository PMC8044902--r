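# Ward agglomeration, seeded K-means refinement and effect-size profiling.

two_clouds <- function(n_per = 15, gap = 20, seed = 1) {
  withr::with_seed(seed, rbind(
    matrix(rnorm(n_per * 2), n_per, 2),
    matrix(rnorm(n_per * 2, mean = gap), n_per, 2)))
}

test_that("Ward merge heights match the brute-force oracle exactly", {
  for (s in 1:4) {
    X <- withr::with_seed(200 + s, matrix(rnorm(15 * 3), 15, 3))
    wd <- ward_cluster(X)
    expect_equal(wd$schedule$height, brute_force_ward_heights(X),
                 tolerance = 1e-8, label = sprintf("heights (seed %d)", s))
  }
})

test_that("two distant clouds produce k = 2 with one dominant merge jump", {
  X <- two_clouds()
  wd <- ward_cluster(X)
  expect_equal(wd$k, 2L)
  h <- wd$schedule$height
  expect_gt(h[length(h)] / h[length(h) - 1], 50)
  expect_equal(sort(table(wd$labels), decreasing = TRUE)[[1]], 15)
})

test_that("identical points collapse to one cluster with a warning", {
  X <- matrix(1, 10, 3)
  expect_warning(wd <- ward_cluster(X), "k = 1")
  expect_equal(wd$k, 1L)
  expect_true(all(wd$schedule$height == 0))
})

test_that("K-means at an optimal fixed point converges immediately", {
  X <- two_clouds()
  truth <- rep(1:2, each = 15)
  seeds <- rbind(colMeans(X[1:15, ]), colMeans(X[16:30, ]))
  asg <- kmeans_refine(X, 2, seeds)
  expect_lte(asg$iterations, 2)
  expect_equal(adjusted_rand(asg$labels, truth), 1)
  expect_equal(asg$kmeans_centroids, seeds, tolerance = 1e-12)
})

test_that("the Lloyd objective is non-increasing over iterations", {
  X <- withr::with_seed(31, matrix(rnorm(120 * 4), 120, 4))
  seeds <- X[1:4, ]
  wss <- vapply(1:6, function(mi) {
    kmeans_refine(X, 4, seeds, max_iter = mi)$wss
  }, numeric(1))
  expect_true(all(diff(wss) <= 1e-9))
})

test_that("seeded K-means agrees with the reference Lloyd implementation", {
  X <- withr::with_seed(17, matrix(rnorm(200 * 5), 200, 5))
  seeds <- X[c(3, 50, 120), ]
  ours <- kmeans_refine(X, 3, seeds)
  ref <- kmeans(X, centers = seeds, algorithm = "Lloyd", iter.max = 100)
  expect_equal(adjusted_rand(ours$labels, ref$cluster), 1)
  expect_equal(ours$wss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("K-means never increases within-SS relative to the Ward cut", {
  X <- withr::with_seed(23, matrix(rnorm(150 * 6), 150, 6))
  wd <- ward_cluster(X, k = 4)
  ward_wss <- alexnn:::within_ss(X, wd$labels, wd$centroids)
  asg <- kmeans_refine(X, 4, wd$centroids)
  expect_lte(asg$wss, ward_wss + 1e-9)
})

test_that("an emptied cluster is re-seeded and logged", {
  X <- two_clouds()
  # a seed stranded far from all data must empty on the first assignment
  seeds <- rbind(colMeans(X), c(1e4, 1e4))
  asg <- kmeans_refine(X, 2, seeds)
  expect_gte(length(asg$events), 1)
  expect_true(all(tabulate(asg$labels, 2) > 0))
})

test_that("adjusted Rand agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  withr::with_seed(6, {
    for (i in 1:5) {
      a <- sample(1:3, 40, replace = TRUE)
      b <- sample(1:4, 40, replace = TRUE)
      expect_equal(adjusted_rand(a, b),
                   unname(mclust::adjustedRandIndex(a, b)),
                   tolerance = 1e-12)
    }
  })
  expect_equal(adjusted_rand(rep(1:2, 10), rep(1:2, 10)), 1)
})

test_that("effect-size profiles honor the null, unit and conversion identities", {
  labels <- rep(1:2, each = 3)
  dat <- data.frame(same = rep(5, 6),
                    unit = c(0, 1, 2, -1, 0, 1),
                    gender = c(1, 1, 0, 1, 0, 0))
  prof <- profile_groups(dat, labels, variables = c("same", "unit", "gender"))
  expect_equal(prof$d[prof$group == 1 & prof$variable == "same"], 0)
  expect_equal(prof$d[prof$group == 1 & prof$variable == "unit"], 1)
  expect_equal(or_to_d(1), 0)
  expect_equal(or_to_d(exp(1.81)), 1)
  expect_equal(or_to_d(exp(1.81), literal = TRUE), exp(1.81) / 1.81)
})

test_that("profiles flag by Cohen band and suppress small effects", {
  expect_equal(alexnn:::cohen_flag(0.9), "large")
  expect_equal(alexnn:::cohen_flag(-0.6), "medium")
  expect_equal(alexnn:::cohen_flag(0.4), "small")
  expect_equal(alexnn:::cohen_flag(0.1), "suppressed")
  tab <- generate_table(subgroup_study_config(n_participants = 120, seed = 4))
  prof <- profile_groups(tab$data, tab$labels)
  ft <- format_profile_table(prof)
  expect_equal(nrow(ft), 17)
  expect_equal(ncol(ft), 1 + length(unique(tab$labels)))
  expect_true(any(ft[[2]] == "--"))
})

test_that("group/rest partition means reconstruct the overall mean", {
  tab <- generate_table(subgroup_study_config(n_participants = 90, seed = 10))
  labels <- tab$labels
  for (v in c("aaq", "sacs", "das_anxiety")) {
    x <- tab$data[[v]]
    parts <- vapply(sort(unique(labels)), function(g) {
      sum(labels == g) * mean(x[labels == g])
    }, numeric(1))
    expect_equal(sum(parts), length(x) * mean(x), tolerance = 1e-9)
  }
})

test_that("profile d values are invariant to affine rescaling", {
  tab <- generate_table(subgroup_study_config(n_participants = 90, seed = 11))
  p1 <- profile_groups(tab$data, tab$labels)
  scaled <- tab$data
  scaled$aaq <- 10 + 3 * scaled$aaq
  p2 <- profile_groups(scaled, tab$labels)
  expect_equal(p2$d[p2$variable == "aaq"], p1$d[p1$variable == "aaq"],
               tolerance = 1e-9)
})

test_that("tiny groups yield undefined d with a warning", {
  dat <- data.frame(x = rnorm(10), gender = rbinom(10, 1, 0.5))
  labels <- c(1, rep(2, 9))
  expect_warning(prof <- profile_groups(dat, labels, variables = "x",
                                        binary = character(0)),
                 "fewer than 2")
  expect_true(is.na(prof$d[prof$group == 1]))
})
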