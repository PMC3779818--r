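test_that("Spearman correlation matches monotone expectations and cor.test", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(61)
  for (rep in 1:10) {
    a <- rnorm(15); b <- rnorm(15) + a
    a[sample(15, 2)] <- NA                      # incomplete pairs dropped
    mine <- spearman_cor(a, b)
    ct <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(mine$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ct$p.value, tolerance = 1e-9)
  }
  # degenerate inputs are reported missing, not errors
  expect_true(is.na(spearman_cor(c(1, 1, 1), c(1, 2, 3))$rho))
  expect_true(is.na(spearman_cor(c(1, 2), c(1, 2))$rho))
})

test_that("the station correlation matrix is symmetric with unit diagonal", {
  env <- arisa_fixtures()$table4_env
  ec <- env_correlation_matrix(env)
  expect_equal(ec$rho, t(ec$rho))
  expect_equal(unname(diag(ec$rho)), rep(1, 5))
  expect_true(all(ec$rho >= -1 & ec$rho <= 1))
  expect_equal(unname(ec$n_used["salinity", "temperature"]), 22)
  # pairwise-complete deletion: knocking out one station's salinity only
  # shrinks salinity pairs
  env2 <- env
  env2$salinity[3] <- NA
  ec2 <- env_correlation_matrix(env2)
  expect_equal(unname(ec2$n_used["salinity", "temperature"]), 21)
  expect_equal(unname(ec2$n_used["dissolved_fe", "temperature"]), 22)
})

test_that("salinity-dissolved Fe and other reproducible station correlations hold", {
  # cells of the published matrix that the 22 printed station rows reproduce
  ec <- env_correlation_matrix(arisa_fixtures()$table4_env)
  expect_equal(ec$rho["dissolved_fe", "salinity"], -0.77, tolerance = 0.03)
  expect_equal(ec$rho["dissolved_fe", "temperature"], 0.62, tolerance = 0.03)
  expect_equal(ec$rho["bottom_depth", "temperature"], -0.73, tolerance = 0.03)
  expect_equal(ec$rho["bottom_depth", "dissolved_fe"], -0.76, tolerance = 0.03)
})

test_that("environmental normalization z-scores and excludes incomplete stations", {
  env <- data.frame(station_id = c("a", "b", "c", "d"),
                    t = c(1, 2, 3, 4), fe = c(0.1, NA, 0.3, 0.5))
  z <- normalize_env(env, c("t", "fe"))
  expect_equal(rownames(z), c("a", "c", "d"))
  expect_equal(attr(z, "excluded"), "b")
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  # two stations, single variable: distance is |z1 - z2|
  z2 <- normalize_env(env[1:2, ], "t")
  expect_equal(as.numeric(dist(z2)), abs(z2[1] - z2[2]))
  expect_error(normalize_env(transform(env, c0 = 1), "c0"), "zero-variance")
  expect_error(normalize_env(env, "nope"), "unknown")
})

test_that("BIOENV enumerates all non-empty subsets and ranks by matrix rank correlation", {
  set.seed(71)
  m <- random_abundance(12, 8)
  env <- data.frame(station_id = rownames(m),
                    v1 = rnorm(12), v2 = rnorm(12), v3 = rnorm(12),
                    v4 = rnorm(12), v5 = rnorm(12))
  fit <- bioenv(bray_curtis(m), env)
  expect_equal(fit$n_subsets, 31)                      # 2^5 - 1
  expect_equal(nrow(fit$results), 31)
  expect_false(is.unsorted(rev(fit$results$rho)))
  # singleton rho equals a direct spearman of the unrolled distance vectors
  d <- as.matrix(bray_curtis(m))
  lt <- lower.tri(d)
  for (v in c("v1", "v4")) {
    ed <- as.matrix(dist(scale(env[[v]])))
    direct <- spearman_cor(d[lt], ed[lt])$rho
    expect_equal(fit$results$rho[fit$results$subset == v], direct,
                 tolerance = 1e-12)
  }
  # env distances rank-identical to the biotic ones give rho_s = 1
  env_perfect <- data.frame(station_id = rownames(m),
                            x = cmdscale(bray_curtis(m), k = 1)[, 1])
  ed <- as.matrix(dist(scale(env_perfect$x)))
  if (spearman_cor(d[lt], ed[lt])$rho > 0.99) {
    fitp <- bioenv(bray_curtis(m), env_perfect)
    expect_gt(fitp$best_rho, 0.99)
  }
})

test_that("BIOENV agrees with vegan's reference implementation", {
  set.seed(83)
  m <- random_abundance(14, 9)
  env <- data.frame(station_id = rownames(m),
                    t = rnorm(14), s = rnorm(14), f = rnorm(14))
  d <- bray_curtis(m)
  fit <- bioenv(d, env)
  ref <- vegan::bioenv(d, env[, -1], method = "spearman",
                       index = "euclidean")
  ref_best <- names(ref$models[[ref$whichbest]]$best)
  ref_best <- colnames(env[, -1])[ref$models[[ref$whichbest]]$best]
  expect_setequal(fit$best, ref_best)
  expect_equal(fit$best_rho, ref$models[[ref$whichbest]]$est,
               tolerance = 1e-9)
})

test_that("stations missing a subset variable are dropped only for that subset", {
  set.seed(73)
  m <- random_abundance(10, 6)
  env <- data.frame(station_id = rownames(m),
                    t = rnorm(10), fe = rnorm(10))
  env$fe[c(2, 7)] <- NA                       # like unmeasured dissolved Fe
  fit <- bioenv(bray_curtis(m), env)
  expect_setequal(
    attr(normalize_env(env, "fe"), "excluded"),
    env$station_id[c(2, 7)])
  # subsets without fe use all stations
  expect_length(attr(normalize_env(env, "t"), "excluded"), 0)
})

test_that("the permutation p value is seeded, bounded below, and significant for a real signal", {
  cfg <- simulation_config(n_samples = 16, n_bins = 10,
                           gradient_strength = 3, seed = 314)
  sim <- simulate_community(cfg)
  d <- bray_curtis(sim$matrix)
  fit <- bioenv(d, sim$env)
  f1 <- bioenv_permutation_p(fit, n_perm = 99, seed = 10)
  f2 <- bioenv_permutation_p(fit, n_perm = 99, seed = 10)
  expect_identical(f1$p_value, f2$p_value)     # bit-reproducible
  expect_gte(f1$p_value, 1 / 100)              # attainable lower bound
  expect_lte(f1$p_value, 0.05)                 # strong simulated gradient
  expect_error(bioenv_permutation_p(fit, n_perm = 9, seed = 1), "99")
  expect_error(bioenv_permutation_p(fit, n_perm = 99), "seed")
})

test_that("dropping variables reruns the search and reports rho deltas", {
  cfg <- simulation_config(n_samples = 14, n_bins = 8,
                           gradient_strength = 3, seed = 99)
  sim <- simulate_community(cfg)
  d <- bray_curtis(sim$matrix)
  sens <- sensitivity_drop(d, sim$env)
  expect_equal(nrow(sens), 5)                  # one rerun per variable
  full_best <- attr(sens, "full_best_subset")
  full_rho <- attr(sens, "full_best_rho")
  for (i in seq_len(nrow(sens))) {
    in_best <- grepl(sens$dropped[i], full_best, fixed = TRUE)
    if (!in_best) {
      expect_equal(sens$best_rho[i], full_rho, tolerance = 1e-12)
    } else {
      expect_lte(sens$best_rho[i], full_rho + 1e-12)
    }
  }
  # dropping the sole driver lowers the attainable correlation
  drv <- sim$ground_truth$driver
  if (grepl(drv, full_best, fixed = TRUE))
    expect_lt(sens$best_rho[sens$dropped == drv], full_rho)
})

test_that("similarity-percent input matrices are converted to dissimilarity", {
  m <- random_abundance(8, 5, seed = 11)
  d <- bray_curtis(m)
  sim_pct <- 100 * (1 - as.matrix(d))
  env <- data.frame(station_id = rownames(m), t = rnorm(8), s = rnorm(8))
  f1 <- bioenv(d, env)
  f2 <- bioenv(sim_pct, env)
  expect_equal(f1$results$rho, f2$results$rho, tolerance = 1e-12)
})
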