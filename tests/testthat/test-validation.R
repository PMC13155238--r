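test_that("randomized-quantile residuals are bounded and calibrated for a
           well-specified fixed-effects fit", {
  sim <- simulate_count_frame(n_countries = 8, n_species = 40,
                              beta = c(LIG = 0, COR = 0.5, TER = -0.3),
                              species_sigma = 0, country_sigma = 0, seed = 71)
  d <- as.data.frame(sim$frame)
  d$substrateCategory <- stats::relevel(factor(d$substrateCategory), "LIG")
  fit <- ztnb_glm(y ~ substrateCategory, d, offset = d$log_offset)
  rd <- quantile_residuals(fit, S = 150, seed = 5)
  expect_true(all(rd$residuals >= 0 & rd$residuals <= 1))
  expect_gt(rd$ks$p_value, 0.01)
  expect_gt(rd$dispersion$p_value, 0.05)
  expect_lt(abs(rd$dispersion$statistic - 1), 0.25)
  expect_warning(quantile_residuals(fit, S = 20, seed = 1), "coarse")
})

test_that("the dispersion test flags underdispersed simulations against an
           overdispersed fit", {
  # observed data Poisson-like (k huge), fitted object claims k = 0.5:
  # simulated variance exceeds observed, two-sided p should be small
  withr::with_seed(81, {
    n <- 400
    mu <- exp(stats::runif(n, 0, 2))
    fake <- structure(list(mu = mu, k = 0.5, y = rztnb(n, mu, 1e6)),
                      class = "ztnb_glm")
    rd <- quantile_residuals(fake, S = 200, seed = 6)
    expect_lt(rd$dispersion$statistic, 1)
    expect_lt(rd$dispersion$p_value, 0.05)
  })
})

test_that("GLMM residuals stay in bounds on the fixture archive", {
  fit <- suppressWarnings(fit_substrate_model(fixture_frame()))
  rd <- quantile_residuals(fit, S = 100, seed = 7)
  expect_true(all(rd$residuals >= 0 & rd$residuals <= 1))
  expect_equal(rd$n_sim, 100)
})

test_that("Poisson deviance and calibration slope behave as estimators", {
  y <- c(2, 5, 1, 7, 3)
  expect_equal(2 * sum(y * log(y / y) - (y - y)), 0) # deviance 0 at y = mu
  mu <- c(1.5, 6, 2, 5, 2.5)
  dev <- 2 * sum(y * log(y / mu) - (y - mu))
  expect_gt(dev, 0)
  # slope invariance to rescaling predictions
  withr::with_seed(91, {
    yy <- rpois(300, lambda = exp(stats::runif(300, 0, 2))) + 1
    mm <- exp(stats::runif(300, 0, 2))
    s1 <- calibration_slope(yy, mm)
    s2 <- calibration_slope(yy, mm * 100)
    expect_equal(s1$slope, s2$slope, tolerance = 1e-8)
  })
  # constant predictions are degenerate
  expect_warning(out <- calibration_slope(c(1, 2, 3), rep(2, 3)),
                 "constant")
  expect_true(out$degenerate)
})

test_that("robust standard errors match a brute-force sandwich on a small toy", {
  withr::with_seed(101, {
    y <- rpois(10, 4) + 1
    mu <- exp(stats::rnorm(10, 1.2, 0.4))
  })
  m <- stats::glm(y ~ log(mu), family = stats::poisson())
  X <- stats::model.matrix(m)
  fitted_mu <- stats::fitted(m)
  bread <- solve(t(X) %*% (X * fitted_mu))
  meat <- t(X) %*% (X * (y - fitted_mu)^2)
  expect_equal(unname(sandwich::vcovHC(m, type = "HC0")),
               unname(bread %*% meat %*% bread), tolerance = 1e-6)
})

test_that("LOCO-CV is well calibrated on data the model can represent", {
  sim <- simulate_count_frame(n_countries = 8, n_species = 80,
                              beta = c(LIG = 0, COR = 0.5, TER = -0.3,
                                       XYL = 1),
                              species_sigma = 0, country_sigma = 0,
                              exposure_range = c(200, 3000), seed = 55)
  cv <- loco_cv(sim$frame, engine = "ztnb")
  expect_equal(nrow(cv$folds), 8)
  expect_equal(cv$calibration$slope, 1, tolerance = 0.12)
  expect_false(cv$calibration$degenerate)
  expect_true(cv$calibration$conf.low < 1 & 1 < cv$calibration$conf.high)
  expect_true(all(cv$folds$deviance >= 0))
  # decile table conserves the held-out records and their mean
  expect_equal(sum(cv$deciles$n), nrow(cv$heldout))
  expect_equal(sum(cv$deciles$mean_observed * cv$deciles$n) /
                 sum(cv$deciles$n), mean(cv$heldout$y))
})

test_that("constructed miscalibration (square-root shrunken predictions) is
           detected as slope > 1", {
  sim <- simulate_count_frame(n_countries = 8, n_species = 80,
                              beta = c(LIG = 0, COR = 0.5, TER = -0.3),
                              species_sigma = 0, country_sigma = 0,
                              exposure_range = c(200, 3000), seed = 56)
  cv <- loco_cv(sim$frame, engine = "ztnb")
  shrunk <- calibration_slope(cv$heldout$y, cv$heldout$mu^0.5)
  expect_gt(shrunk$conf.low, 1)
  expect_equal(shrunk$slope, 2 * cv$calibration$slope, tolerance = 0.2)
})

test_that("the mixed-model LOCO engine carries taxon modes but zeroes unseen
           levels", {
  sim <- simulate_count_frame(n_countries = 5, n_species = 15,
                              beta = c(LIG = 0, COR = 0.4),
                              species_sigma = 0.5, country_sigma = 0.2,
                              seed = 57)
  cv <- suppressWarnings(loco_cv(sim$frame, engine = "glmm"))
  expect_equal(nrow(cv$folds), 5)
  expect_true(is.finite(cv$mean$rmse))
  expect_true(is.finite(cv$calibration$slope))
})

test_that("sensitivity variants: no rare substrates makes V3 a no-op and rare
           ones are excluded", {
  sim <- simulate_count_frame(n_countries = 8, n_species = 25,
                              beta = c(LIG = 0, COR = 0.4, TER = -0.2),
                              exposure_range = c(200, 1000), seed = 61)
  sv <- suppressWarnings(sensitivity_variants(sim$frame,
                                              rarity_threshold = 100))
  v3 <- sv[sv$variant == "V3", ]
  expect_equal(v3$delta_log_rr, rep(0, nrow(v3)), tolerance = 1e-6)
  expect_true(all(sv$delta_log_rr[sv$variant == "V1"] == 0))
  # plant a rare substrate: it disappears from V3 output
  rare_rows <- tibble::tibble(
    country = sprintf("C%02d", 1:8), substrateCategory = "SAX",
    species = "Species_001", y = 2, exposure = 50, log_offset = log(50))
  frame2 <- dplyr::bind_rows(sim$frame, rare_rows)
  sv2 <- suppressWarnings(sensitivity_variants(frame2,
                                               rarity_threshold = 100))
  expect_false("SAX" %in% sv2$substrateCategory[sv2$variant == "V3"])
  expect_true("SAX" %in% sv2$substrateCategory[sv2$variant == "V2"])
})

test_that("strong taxon-level slopes separate V1 from V2", {
  # species differ in their substrate response: the slopes and no-slopes
  # variants disagree more than numerical noise
  withr::with_seed(63, {
    countries <- sprintf("C%02d", 1:8)
    species <- sprintf("Species_%03d", 1:30)
    subs <- c("LIG", "COR")
    g <- tidyr::expand_grid(country = countries, substrateCategory = subs,
                            species = species)
    g$exposure <- round(exp(stats::runif(nrow(g), log(200), log(1000))))
    slope <- stats::setNames(stats::rnorm(30, 0.5, 1.2), species)
    mu <- exp(-5 + ifelse(g$substrateCategory == "COR",
                          slope[g$species], 0)) * g$exposure
    g$y <- stats::rnbinom(nrow(g), size = 1.5, mu = mu)
    g <- g[g$y > 0, ]
    g$log_offset <- log(g$exposure)
  })
  sv <- suppressWarnings(sensitivity_variants(g, rarity_threshold = 10))
  d12 <- abs(sv$delta_log_rr[sv$variant == "V2" &
                               sv$substrateCategory == "COR"])
  expect_gt(d12, 0.05)
})

test_that("pH mode concordance: stable modes agree across resolutions,
           planted cohorts correlate", {
  withr::with_seed(65, {
    sp_modes <- stats::setNames(stats::runif(8, 4, 9), paste0("sp", 1:8))
    rec <- purrr::map_dfr(names(sp_modes), function(s) {
      tibble::tibble(species = s,
                     pH = pmin(pmax(stats::rnorm(40, sp_modes[s], 0.35),
                                    3.1), 9.9))
    })
  })
  pc <- ph_mode_concordance(rec, resolutions = c(0.01, 0.1), min_records = 5)
  expect_equal(nrow(pc$modes), 8)
  expect_gt(pc$pearson, 0.9)
  expect_gt(pc$spearman, 0.9)
  expect_lt(max(abs(pc$modes$mode_fine - sp_modes[pc$modes$species])), 1)
  # two records at opposite ends: sparse flag
  sparse <- tibble::tibble(species = "s", pH = c(3.5, 9.5))
  pc2 <- suppressMessages(
    ph_mode_concordance(sparse, min_records = 2))
  expect_true(all(pc2$modes$sparse))
  expect_true(is.na(pc2$pearson))
})
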