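test_that("site construction defines sites, efforts and the retention rule", {
  M <- build_sites(toy_site_data(), min_sites = 1)
  expect_equal(nrow(M$sites), 6)
  expect_setequal(M$sites$site,
                  c("A:G1", "A:G2", "B:G1", "B:G2", "C:G1", "C:G2"))
  expect_equal(M$sites$effort[M$sites$site == "A:G1"], 5)
  expect_true(all(M$X %in% c(0, 1)))
  # taxa in fewer than min_sites sites are dropped
  M3 <- build_sites(toy_site_data(), min_sites = 5)
  expect_false("sp1" %in% colnames(M3$X)) # sp1 occupies 4 sites
  expect_true("sp2" %in% colnames(M3$X))  # sp2 occupies 5 sites
})

test_that("weighted IndVal components match a hand-computed oracle", {
  M <- build_sites(toy_site_data(), min_sites = 1)
  # hand computation for sp1 in G1: presences A:G1 (w 5), B:G1 (w 4), C:G1 (w 6)
  # all G1 sites hold sp1 -> m_G1 = 1; G2: B:G2 only (w 6 of w 3+6+2=11)
  m_g1 <- (5 * 1 + 4 * 1 + 6 * 1) / (5 + 4 + 6)
  m_g2 <- (3 * 0 + 6 * 1 + 2 * 0) / (3 + 6 + 2)
  out <- indval_E(M, "sp1", "G1")
  expect_equal(out$A, m_g1 / (m_g1 + m_g2))
  expect_equal(out$B, m_g1)
  expect_equal(out$stat, sqrt(out$A * out$B))
  # unweighted variant: equal site weights
  out_u <- indval_E(M, "sp1", "G1", weighted = FALSE)
  expect_equal(out_u$B, 1)
  expect_equal(out_u$A, 1 / (1 + 1 / 3))
  expect_true(all(c(out$A, out$B, out$stat) >= 0 &
                    c(out$A, out$B, out$stat) <= 1))
})

test_that("perfect planted indicator attains statistic 1 everywhere", {
  M <- build_sites(perfect_indicator_data(), min_sites = 3)
  out <- indval_E(M, "perfect", "FOC")
  expect_equal(out$A, 1)
  expect_equal(out$B, 1)
  expect_equal(out$stat, 1)
  # ubiquitous filler is indifferent: A = 1 / number of groups
  filler <- indval_E(M, "filler", "FOC", weighted = FALSE)
  expect_equal(filler$A, 0.5)
})

test_that("blocked permutation p-values match exhaustive enumeration on a
           2-block toy", {
  # 2 blocks x 2 sites; within-block label swaps give 4 equally likely
  # permutations; enumerate the exact null exceedance probability
  toy <- tibble::tribble(
    ~country, ~substrateCategory, ~species, ~y,
    "A", "G1", "t", 2, "A", "G1", "f", 1, "A", "G2", "f", 1,
    "B", "G1", "t", 1, "B", "G1", "f", 2, "B", "G2", "f", 3
  )
  M <- build_sites(toy, min_sites = 1)
  obs <- indval_E(M, "t", "G1")$stat
  perms <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE))
  exceed <- mean(apply(perms, 1, function(sw) {
    s <- M$sites
    if (sw[1]) s$group[s$block == "A"] <- rev(s$group[s$block == "A"])
    if (sw[2]) s$group[s$block == "B"] <- rev(s$group[s$block == "B"])
    g1 <- s$group == "G1"
    mg1 <- sum(s$effort[g1] * M$X[g1, "t"]) / sum(s$effort[g1])
    mg2 <- sum(s$effort[!g1] * M$X[!g1, "t"]) / sum(s$effort[!g1])
    stat <- sqrt(mg1 / (mg1 + mg2) * mg1)
    isTRUE(stat >= obs - 1e-12)
  }))
  res <- blocked_permutation_test(M, n_perm = 999, seed = 5)
  p_t <- res$p_value[res$taxon == "t"]
  expected_p <- (1 + 999 * exceed) / 1000
  expect_lt(abs(p_t - expected_p), 3 * sqrt(exceed * (1 - exceed) / 999) + 1e-6)
})

test_that("label-invariant statistics give p near 1 and planted indicators
           hit the resolution floor", {
  M <- build_sites(perfect_indicator_data(), min_sites = 3)
  res <- blocked_permutation_test(M, n_perm = 999, seed = 9)
  # the filler taxon is identical across sites: permutation cannot beat it
  expect_gt(res$p_value[res$taxon == "filler"], 0.95)
  # perfect indicator: only label layouts reproducing FOC alignment tie it
  expect_lt(res$p_value[res$taxon == "perfect"], 0.05)
  all_p <- blocked_permutation_test(M, n_perm = 99, seed = 2, focal = "all")
  expect_true(all(all_p$p_value >= 1 / 100 - 1e-12))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  withr::with_seed(31, {
    for (i in 1:20) {
      p <- stats::runif(sample(2:10, 1))
      expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
    }
  })
  # and the adjusted column produced by the permutation test obeys the oracle
  M <- build_sites(fixture_frame(), min_sites = 3)
  res <- blocked_permutation_test(M, n_perm = 49, seed = 3)
  expect_equal(res$p_adj, bh_oracle(res$p_value))
  expect_true(all(res$p_adj >= res$p_value - 1e-12))
})

test_that("stratified bootstrap intervals behave on degenerate and planted
           cases", {
  M <- build_sites(perfect_indicator_data(), min_sites = 3)
  ci <- bootstrap_ci(M, B = 200, seed = 11)
  pf <- ci[ci$taxon == "perfect", ]
  # every site of FOC holds the taxon: the statistic is constant under
  # resampling, the interval collapses to the point
  expect_equal(pf$conf.low, 1)
  expect_equal(pf$conf.high, 1)
  frame <- fixture_frame()
  M2 <- build_sites(frame, min_sites = 3)
  ci2 <- bootstrap_ci(M2, B = 100, seed = 12)
  ok <- !is.na(ci2$conf.low)
  expect_true(any(ok))
  expect_true(all(ci2$conf.low[ok] >= 0 & ci2$conf.high[ok] <= 1))
  expect_true(all(ci2$conf.low[ok] <= ci2$conf.high[ok] + 1e-12))
})

test_that("bootstrap intervals cover the observed statistic in well-behaved
           cases", {
  M <- build_sites(fixture_frame(), min_sites = 4)
  ci <- bootstrap_ci(M, B = 150, seed = 13)
  ok <- !is.na(ci$conf.low)
  covered <- mean(ci$conf.low[ok] <= ci$stat[ok] + 1e-9 &
                    ci$stat[ok] <= ci$conf.high[ok] + 1e-9)
  expect_gt(covered, 0.9)
})

test_that("blocked K-fold held-out metrics: perfect alignment gives A=B=1,
           single-country taxa are unavailable", {
  M <- build_sites(perfect_indicator_data(), min_sites = 3)
  ho <- blocked_kfold(M, K = 3, seed = 21)
  pf <- ho[ho$taxon == "perfect", ]
  expect_equal(pf$heldout_A, 1)
  expect_equal(pf$heldout_B, 1)
  # taxon present in one country only: never in both partitions
  dat <- dplyr::bind_rows(
    perfect_indicator_data(),
    tibble::tibble(country = c("B1", "B1", "B1"),
                   substrateCategory = "OTH", species = "lonely", y = 1))
  M2 <- build_sites(dat, min_sites = 1)
  ho2 <- blocked_kfold(M2, K = 3, seed = 22)
  expect_true(is.na(ho2$heldout_A[ho2$taxon == "lonely"]))
  expect_error(blocked_kfold(M, K = 99), "number of blocks")
})

test_that("held-out metrics degrade under label noise relative to in-sample", {
  withr::with_seed(41, {
    blocks <- paste0("B", 1:10)
    base <- tidyr::expand_grid(country = blocks,
                               substrateCategory = c("FOC", "OTH"),
                               species = "filler", y = 3)
    noisy <- tibble::tibble(
      country = blocks,
      substrateCategory = ifelse(stats::runif(10) < 0.2, "OTH", "FOC"),
      species = "noisy", y = 2)
    M <- build_sites(dplyr::bind_rows(base, noisy), min_sites = 1)
    insample <- indval_E(M, "noisy", "FOC")
    ho <- blocked_kfold(M, K = 5, seed = 42)
    hv <- ho[ho$taxon == "noisy", ]
    expect_lte(hv$heldout_A + hv$heldout_B,
               insample$A + insample$B + 0.35)
  })
})

test_that("presence scores reproduce printed-margin worked examples", {
  cases <- tibble::tribble(
    ~taxon, ~n_focal, ~n_total, ~n_sites, ~A, ~B, ~score,
    "Reticularia", 15, 33, 16, 0.45, 0.94, 0.43,
    "Paradiacheopsis", 12, 23, 15, 0.52, 0.80, 0.42,
    "Liceales", 4, 5, 16, 0.80, 0.25, 0.20,
    "Ceratiomyxales", 14, 37, 16, 0.38, 0.88, 0.33,
    "Hemitrichiaceae", 15, 52, 15, 0.29, 1.00, 0.29
  )
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    M <- build_sites(margin_site_data(cs$taxon, cs$n_focal, cs$n_total,
                                      cs$n_sites), min_sites = 1)
    ps <- presence_score(M, all_groups = TRUE)
    row <- ps[ps$taxon == cs$taxon & ps$group == "FOC", ]
    expect_equal(row$n_focal, cs$n_focal)
    expect_equal(row$n_total, cs$n_total)
    expect_equal(row$n_sites, cs$n_sites)
    expect_equal(round_half_up(row$A, 2), cs$A)
    expect_equal(round_half_up(row$B, 2), cs$B)
    expect_equal(round_half_up(row$score, 2), cs$score)
  }
})

test_that("presence-score invariants: A sums to 1, score bounded by min(A, B)", {
  M <- build_sites(fixture_frame(), min_sites = 3)
  ps <- presence_score(M, all_groups = TRUE)
  sums <- ps %>%
    dplyr::group_by(taxon) %>%
    dplyr::summarise(sA = sum(A), total = sum(n_focal), n_tot = n_total[1])
  expect_equal(sums$sA, rep(1, nrow(sums)))
  expect_equal(sums$total, sums$n_tot)
  expect_true(all(ps$score <= pmin(ps$A, ps$B) + 1e-12))
  # best-group view maximises the score with deterministic tie-breaks
  best <- presence_score(M)
  for (tx in best$taxon[1:5]) {
    expect_equal(best$score[best$taxon == tx],
                 max(ps$score[ps$taxon == tx]))
  }
})

test_that("unweighted group-equalised IndVal reduces to presence quantities on
           equal-weight balanced toys", {
  # equal efforts and equal group sizes: B (occupancy) matches presence B
  dat <- dplyr::bind_rows(
    tidyr::expand_grid(country = paste0("B", 1:4),
                       substrateCategory = c("G1", "G2"),
                       species = "filler", y = 2),
    tibble::tibble(country = paste0("B", 1:3), substrateCategory = "G1",
                   species = "t", y = 2)
  )
  M <- build_sites(dat, min_sites = 1)
  iv <- indval_E(M, "t", "G1", weighted = FALSE)
  ps <- presence_score(M, all_groups = TRUE)
  pr <- ps[ps$taxon == "t" & ps$group == "G1", ]
  expect_equal(iv$B, pr$B)
  expect_equal(iv$A, 1) # group-equalised: absent from G2
})

test_that("pH screening produces stratum summaries and screening labels", {
  sim <- fixture_sim()
  scr <- ph_screening(sim$archive, n_perm = 49, n_boot = 50, seed = 17)
  expect_s3_class(scr, "myx_ph_screening")
  expect_equal(scr$label, "screening")
  ss <- scr$stratum_summary
  expect_true(all(c("records", "species", "singletons", "goods_coverage")
                  %in% names(ss)))
  expect_equal(ss$goods_coverage,
               round_half_up(1 - ss$singletons / ss$records, 2))
  expect_true(all(ss$singletons <= ss$species))
  if (nrow(scr$indicators) > 0) {
    expect_true(all(scr$indicators$rank %in% c("species", "genus", "family")))
    expect_true(all(scr$indicators$p_adj >= scr$indicators$p_value - 1e-12))
  }
  empty <- sim$archive[0, ]
  expect_warning(ph_screening(empty), "no records")
})

test_that("pH-indifferent taxa yield few discoveries under screening", {
  # pH bands assigned independently of taxa: BH-adjusted discoveries at 5%
  # should be rare
  sim <- fixture_sim()
  scr <- ph_screening(sim$archive, n_perm = 99, n_boot = 50, seed = 23)
  if (nrow(scr$indicators) > 0) {
    expect_lt(mean(scr$indicators$p_adj < 0.05, na.rm = TRUE), 0.2)
  }
})
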