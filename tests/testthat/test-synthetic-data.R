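# The generator: determinism, validation, bounds, and recovery of planted
# linear, mediated and group structure.

test_that("identical configuration and seed reproduce the table exactly", {
  cfg <- generator_config(n_participants = 50, seed = 123)
  t1 <- generate_table(cfg)
  t2 <- generate_table(cfg)
  expect_identical(t1$data, t2$data)
  expect_identical(t1$labels, t2$labels)
  t3 <- generate_table(generator_config(n_participants = 50, seed = 124))
  expect_false(identical(t1$data, t3$data))
})

test_that("invalid configurations are rejected up front", {
  expect_error(generator_config(n_participants = 1), "at least 2")
  bad_cov <- diag(16); bad_cov[1, 2] <- bad_cov[2, 1] <- 2  # not PSD
  expect_error(
    generator_config(groups = list(group_spec(covariance = bad_cov))),
    "positive semi-definite")
  expect_error(
    generator_config(groups = list(group_spec(weight = 0.5))),
    "sum to 1")
  expect_error(group_spec(mean_profile = c(nonexistent = 1)), "unknown")
})

test_that("generated values respect instrument bounds and rounding", {
  cfg <- generator_config(n_participants = 400, seed = 5)
  tab <- generate_table(cfg)
  sc <- default_variable_scales()
  for (i in seq_len(nrow(sc))) {
    v <- tab$data[[sc$variable[i]]]
    expect_gte(min(v), sc$min[i])
    expect_lte(max(v), sc$max[i])
    if (sc$round[i]) expect_equal(v, round(v))
  }
  expect_true(all(tab$data$gender %in% 0:1))
  expect_equal(tab$data$tas_total,
               tab$data$tas_ddf + tab$data$tas_dif + tab$data$tas_eot)
})

test_that("null model yields vanishing predictor-outcome correlation", {
  om <- list(tas_ddf = outcome_spec(noise_sd = 1),
             tas_dif = outcome_spec(noise_sd = 1),
             tas_eot = outcome_spec(noise_sd = 1))
  cfg <- generator_config(
    n_participants = 4000, seed = 31,
    groups = list(group_spec(covariance = diag(16))),
    outcome_model = om, scales = unit_scales(), apply_bounds = FALSE)
  tab <- generate_table(cfg)
  cors <- vapply(predictor_names(), function(p) {
    cor(tab$data[[p]], tab$data$tas_ddf)
  }, numeric(1))
  expect_lt(max(abs(cors)), 0.05)
})

test_that("OLS on generated data recovers planted linear coefficients", {
  coefs <- c(das_anxiety = 0.4, aaq = 0.3, maia_not_distracting = -0.35)
  om <- list(tas_ddf = outcome_spec(coefs, noise_sd = 0.3),
             tas_dif = outcome_spec(noise_sd = 1),
             tas_eot = outcome_spec(noise_sd = 1))
  cfg <- generator_config(
    n_participants = 5000, seed = 77,
    groups = list(group_spec(covariance = diag(16))),
    outcome_model = om, scales = unit_scales(), apply_bounds = FALSE)
  tab <- generate_table(cfg)
  fit <- enter_regression(tab$data, "tas_ddf", names(coefs))
  for (nm in names(coefs)) {
    row <- fit$coefficients[fit$coefficients$term == nm, ]
    expect_lt(abs(row$b - coefs[[nm]]), 2 * row$se)
  }
})

test_that("planted mediation is recovered by products of OLS path fits", {
  # mediator noise large enough that x and m are not near-collinear, so
  # the b path is well identified at n = 10,000
  cfg <- mediation_study_config(n_participants = 10000, seed = 11,
                                a = 1, b = 1, c_direct = 0, noise_sd = 0.5)
  tab <- generate_table(cfg)
  a_hat <- coef(lm(sacs ~ maia_emotional_awareness, tab$data))[2]
  b_hat <- coef(lm(tas_total ~ maia_emotional_awareness + sacs,
                   tab$data))[3]
  expect_lt(abs(a_hat * b_hat - 1), 0.1)
})

test_that("cluster recovery improves monotonically with profile separation", {
  aris <- vapply(c(1, 3, 8), function(d) {
    cfg <- generator_config(n_participants = 200, seed = 99,
                            groups = separated_group_specs(3, distance = d))
    tab <- generate_table(cfg)
    Z <- as.matrix(z_view(tab$data, alexnn:::predictor_names()))
    asg <- two_stage_cluster(Z, k = 3)
    adjusted_rand(asg$labels, tab$labels)
  }, numeric(1))
  expect_true(all(diff(aris) >= 0))
  expect_equal(aris[3], 1)
})

test_that("well-separated profiles meet the pairwise Mahalanobis target", {
  gs <- separated_group_specs(3, distance = 8)
  for (i in 1:2) for (j in (i + 1):3) {
    d <- sqrt(alexnn:::mahalanobis_sq(gs[[i]]$mean_profile,
                                      gs[[j]]$mean_profile,
                                      gs[[i]]$covariance))
    expect_equal(d, 8, tolerance = 1e-8)
  }
})

test_that("tables round-trip through CSV with a YAML truth sidecar", {
  cfg <- generator_config(n_participants = 20, seed = 3)
  tab <- generate_table(cfg)
  csv <- tempfile(fileext = ".csv")
  write_participant_table(tab, csv)
  back <- read_participant_table(csv)
  expect_equal(back$tas_total, tab$data$tas_total)
  expect_equal(back$group, tab$labels)
  truth <- yaml::read_yaml(paste0(csv, ".truth.yaml"))
  expect_equal(truth$seed, 3)
  expect_equal(truth$n_participants, 20)
  unlink(c(csv, paste0(csv, ".truth.yaml")))
})
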