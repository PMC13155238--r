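fit_quietly <- function(...) suppressWarnings(fit_substrate_model(...))

test_that("with zero random-effect variance the GLMM matches the plain
           ZTNB regression", {
  sim <- simulate_count_frame(
    n_countries = 6, n_species = 30,
    beta = stats::setNames(c(0, 0.4, -0.3, 0.8), c("LIG", "COR", "TER", "XYL")),
    species_sigma = 0, country_sigma = 0, seed = 17)
  fit <- fit_quietly(sim$frame, reference = "LIG")
  d <- as.data.frame(sim$frame)
  d$substrateCategory <- stats::relevel(factor(d$substrateCategory), "LIG")
  oracle <- ztnb_glm(y ~ substrateCategory, d, offset = d$log_offset)
  b_glmm <- glmmTMB::fixef(fit$fit)$cond
  expect_equal(unname(b_glmm[names(oracle$coefficients)]),
               unname(oracle$coefficients), tolerance = 1e-3)
  expect_equal(glmmTMB::sigma(fit$fit), oracle$k, tolerance = 0.02)
})

test_that("adding a constant to every offset shifts only the intercept", {
  sim <- simulate_count_frame(n_countries = 6, n_species = 25,
                              beta = c(LIG = 0, COR = 0.5, TER = -0.2),
                              seed = 23)
  f1 <- fit_quietly(sim$frame)
  shifted <- dplyr::mutate(sim$frame, log_offset = log_offset + 2)
  f2 <- fit_quietly(shifted)
  b1 <- glmmTMB::fixef(f1$fit)$cond
  b2 <- glmmTMB::fixef(f2$fit)$cond
  expect_equal(unname(b2[1]), unname(b1[1]) - 2, tolerance = 1e-3)
  expect_equal(unname(b2[-1]), unname(b1[-1]), tolerance = 1e-3)
})

test_that("the effort model recovers simulated contrasts within Wald error", {
  beta <- stats::setNames(c(0, 0.3, log(2), -0.4, 1),
                          c("LIG", "COR", "FOL", "RAM", "XYL"))
  sim <- simulate_count_frame(n_countries = 16, n_species = 50, beta = beta,
                              seed = 3)
  fit <- fit_quietly(sim$frame)
  td <- tidy(fit) %>%
    dplyr::filter(startsWith(term, "substrateCategory")) %>%
    dplyr::mutate(substrateCategory = sub("substrateCategory", "", term),
                  truth = beta[substrateCategory])
  expect_true(all(abs(td$estimate - td$truth) < 3.5 * td$std.error))
  # rate ratio of the doubled substrate is near 2 and its CI covers 2
  rr <- rate_ratios(fit)
  fol <- rr[rr$substrateCategory == "FOL", ]
  expect_true(fol$conf.low < 2 & 2 < fol$conf.high)
  expect_equal(fol$rate_ratio, 2, tolerance = 0.35)
})

test_that("rate ratios: reference row is exactly 1 and CI/p duality holds", {
  sim <- simulate_count_frame(n_countries = 8, n_species = 30,
                              beta = c(LIG = 0, COR = 1.2, TER = 0.02),
                              seed = 41)
  fit <- fit_quietly(sim$frame)
  rr <- rate_ratios(fit)
  ref <- rr[rr$substrateCategory == "LIG", ]
  expect_equal(ref$rate_ratio, 1)
  expect_true(is.na(ref$conf.low))
  non_ref <- rr[rr$substrateCategory != "LIG", ]
  excludes_one <- non_ref$conf.low > 1 | non_ref$conf.high < 1
  expect_equal(excludes_one, non_ref$p.value < 0.05)
  expect_error(rate_ratios(structure(list(), class = "lm")), "substrate_model")
})

test_that("pairwise contrasts: two-substrate case equals the rate ratio and
           adjustment is monotone", {
  sim <- simulate_count_frame(n_countries = 8, n_species = 25,
                              beta = c(LIG = 0, COR = 0.6), seed = 13)
  fit <- fit_quietly(sim$frame)
  emm <- emm_pairwise(fit)
  rr <- rate_ratios(fit)
  ratio <- emm$contrasts$ratio[1] # LIG / COR
  expect_equal(1 / ratio, rr$rate_ratio[rr$substrateCategory == "COR"],
               tolerance = 1e-6)
  # three substrates: adjusted p >= unadjusted p for every pair
  sim3 <- simulate_count_frame(n_countries = 8, n_species = 25,
                               beta = c(LIG = 0, COR = 0.4, TER = -0.2),
                               seed = 14)
  fit3 <- fit_quietly(sim3$frame)
  adj <- emm_pairwise(fit3)$contrasts
  raw <- summary(emmeans::contrast(
    emmeans::emmeans(fit3$fit, ~substrateCategory, offset = 0,
                     type = "response", component = "cond"),
    method = "pairwise", adjust = "none"))
  expect_true(all(adj$p.value >= raw$p.value - 1e-10))
})

test_that("single-step max-|z| adjustment matches a Monte-Carlo null", {
  sim <- simulate_count_frame(n_countries = 10, n_species = 25,
                              beta = c(LIG = 0, COR = 0.25, TER = -0.1),
                              seed = 19)
  fit <- fit_quietly(sim$frame)
  emm <- emmeans::emmeans(fit$fit, ~substrateCategory, offset = 0,
                          component = "cond")
  ctr <- emmeans::contrast(emm, "pairwise", adjust = "tukey")
  s <- summary(ctr)
  V <- stats::vcov(ctr)
  R <- stats::cov2cor(V)
  z_obs <- abs(s$estimate / s$SE)
  Z <- withr::with_seed(77, {
    abs(matrix(stats::rnorm(1e5 * nrow(R)), ncol = nrow(R)) %*% chol(R))
  })
  maxZ <- apply(Z, 1, max)
  p_mc <- vapply(z_obs, function(z) mean(maxZ >= z), numeric(1))
  expect_equal(s$p.value, p_mc, tolerance = 0.02)
})

test_that("bootstrap ranks: dominant substrate pins rank 1 and the weakest
           collapses at the bottom", {
  beta <- c(LIG = 0, COR = 1.2, TER = 1.5, XYL = 3)
  sim <- simulate_count_frame(n_countries = 6, n_species = 20, beta = beta,
                              species_sigma = 0.2, country_sigma = 0.2,
                              exposure_range = c(100, 1000), seed = 29)
  fit <- fit_quietly(sim$frame)
  rk <- bootstrap_ranks(fit, B = 20, rarity_threshold = 50, seed = 6)
  expect_lte(attr(rk, "failure_rate"), 0.3)
  xyl <- rk[rk$substrateCategory == "XYL", ]
  expect_equal(xyl$median_rank, 1)
  expect_equal(xyl$rank_95_high, 1)
  # reference-lowest pattern: LIG collapses at the bottom rank
  lig <- rk[rk$substrateCategory == "LIG", ]
  expect_equal(lig$median_rank, 4)
  expect_equal(lig$rank_95_low, 4)
  # interval nesting and range invariants
  expect_true(all(rk$rank_95_low <= rk$rank_50_low))
  expect_true(all(rk$rank_50_high <= rk$rank_95_high))
  expect_true(all(rk$median_rank >= 1 & rk$median_rank <= nrow(rk)))
  expect_true(all(rk$weighted_median_rank >= 1 &
                    rk$weighted_median_rank <= nrow(rk)))
})

test_that("rarity threshold excludes sparse substrates from ranking", {
  frame <- fixture_frame()
  fit <- fit_quietly(frame)
  totals <- frame %>%
    dplyr::group_by(substrateCategory) %>%
    dplyr::summarise(n = sum(y))
  thr <- sort(totals$n, decreasing = TRUE)[4] # keep exactly 4 substrates
  rk <- bootstrap_ranks(fit, B = 4, rarity_threshold = thr, seed = 2)
  expect_equal(nrow(rk), 4)
  expect_setequal(rk$substrateCategory, totals$substrateCategory[totals$n >= thr])
})

make_order_frame <- function(dev, seed) {
  withr::with_seed(seed, {
    countries <- sprintf("C%02d", 1:12)
    orders <- sprintf("Order_%02d", 1:10)
    subs <- c("LIG", "COR", "TER")
    beta <- c(LIG = 0, COR = 0.3, TER = -0.2)
    g <- tidyr::expand_grid(country = countries, substrateCategory = subs,
                            order = orders)
    g$exposure <- round(exp(stats::runif(nrow(g), log(500), log(3000))))
    o_eff <- stats::setNames(stats::rnorm(10, 0, 0.4), orders)
    c_eff <- stats::setNames(stats::rnorm(12, 0, 0.2), countries)
    extra <- ifelse(g$order == "Order_01" & g$substrateCategory == "COR",
                    dev, 0)
    mu <- exp(-5.5 + beta[g$substrateCategory] + o_eff[g$order] +
                c_eff[g$country] + extra) * g$exposure
    g$y <- stats::rnbinom(nrow(g), size = 2, mu = mu)
    g <- g[g$y > 0, ]
    g$log_offset <- log(g$exposure)
    g
  })
}

test_that("order-level random slopes recover a planted deviation and shrink
           to zero without one", {
  frame <- make_order_frame(dev = 1.3, seed = 51)
  dv <- suppressWarnings(order_deviations(frame, reference = "LIG"))
  planted <- dv[dv$order == "Order_01" & dv$substrateCategory == "COR", ]
  expect_gt(planted$deviation, 0.4)
  expect_true(planted$excludes_zero)
  others <- dv[!(dv$order == "Order_01" & dv$substrateCategory == "COR"), ]
  expect_lt(mean(abs(others$deviation)), abs(planted$deviation))
  # partial pooling keeps deviations roughly centred across orders
  expect_lt(abs(mean(dv$deviation[dv$substrateCategory == "COR"])),
            abs(planted$deviation))

  flat <- make_order_frame(dev = 0, seed = 52)
  dv0 <- suppressWarnings(order_deviations(flat, reference = "LIG"))
  expect_lt(max(abs(dv0$deviation)), 0.6)
  expect_lt(mean(abs(dv0$deviation)), 0.25)
})

test_that("model accessors are tidy and consistent", {
  sim <- simulate_count_frame(n_countries = 6, n_species = 20,
                              beta = c(LIG = 0, COR = 0.5), seed = 61)
  fit <- fit_quietly(sim$frame)
  td <- tidy(fit, exponentiate = TRUE)
  expect_true(all(c("term", "estimate", "conf.low") %in% names(td)))
  gl <- glance(fit)
  expect_gt(gl$k, 0)
  expect_equal(gl$nobs, nrow(sim$frame))
  expect_error(fit_substrate_model(sim$frame, reference = "ZZZ"),
               "not present")
  bad <- dplyr::mutate(sim$frame, y = y - y[1] * (dplyr::row_number() == 1))
  expect_error(fit_substrate_model(dplyr::mutate(sim$frame,
                                                 log_offset = Inf)),
               "finite")
})
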