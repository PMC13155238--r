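#' Good's coverage
#'
#' Sample completeness in the simple Good-Turing form: one minus the
#' proportion of records belonging to singleton species,
#' `1 - f1 / n`. Used for descriptive stratum summaries (e.g. substrate x pH
#' band tables); coverage-based standardisation uses the f1/f2-adjusted
#' estimator inside [coverage_at_m()] instead.
#'
#' @param n Total number of records in the stratum (>= 1; 0 gives `NA`).
#' @param f1 Number of singleton species (`0 <= f1 <= n`).
#' @return Coverage in \[0, 1\]; `NA` for empty strata.
#' @export
#' @examples
#' goods_coverage(36, 19) # 0.472...
goods_coverage <- function(n, f1) {
  assert_that(all(f1 >= 0 & f1 <= n, na.rm = TRUE),
              "f1 must satisfy 0 <= f1 <= n")
  out <- 1 - f1 / n
  out[n == 0] <- NA_real_
  out
}

check_abundance <- function(x) {
  x <- x[!is.na(x)]
  assert_that(length(x) > 0 && all(x >= 1) && all(x == floor(x)),
              "abundance vectors must contain positive integer counts")
  x
}

#' Hill numbers of order 0, 1 and 2
#'
#' Effective species numbers from an abundance vector: order 0 is richness,
#' order 1 is the exponential of Shannon entropy (natural log), order 2 the
#' inverse Simpson concentration.
#'
#' @param x Vector of positive integer counts (one entry per observed taxon).
#' @param q Diversity order(s), each one of 0, 1, 2.
#' @return Numeric vector of Hill numbers, one per `q`.
#' @export
#' @examples
#' hill_number(c(8, 2), q = c(0, 1, 2))
hill_number <- function(x, q = c(0, 1, 2)) {
  x <- check_abundance(x)
  assert_that(all(q %in% c(0, 1, 2)), "q must be 0, 1 or 2")
  p <- x / sum(x)
  vapply(q, function(qq) {
    switch(as.character(qq),
           "0" = length(x),
           "1" = exp(-sum(p * log(p))),
           "2" = 1 / sum(p^2))
  }, numeric(1))
}

# E[f_k(m)]: expected number of species represented exactly k times in a
# hypergeometric subsample of size m (k = 1..m)
expected_freq_counts <- function(x, m) {
  n <- sum(x)
  lcnm <- lchoose(n, m)
  vapply(seq_len(m), function(k) {
    ok <- x >= k & (n - x) >= (m - k)
    sum(exp(lchoose(x[ok], k) + lchoose(n - x[ok], m - k) - lcnm))
  }, numeric(1))
}

#' Rarefied Hill numbers (interpolation)
#'
#' Expected diversity of a hypergeometric subsample of size `m` drawn without
#' replacement from the observed records. Order 0 uses the exact
#' interpolation `S - sum_i C(n - x_i, m) / C(n, m)`. Orders 1 and 2 are
#' computed from the expected abundance-frequency counts `E[f_k(m)]` of the
#' subsample: `q1 = exp(sum_k E[f_k] * (-(k/m) log(k/m)))` and
#' `q2 = 1 / sum_k E[f_k] (k/m)^2`, i.e. the Hill transform of the *expected*
#' entropy/concentration, which is the standard interpolation construction.
#' Only interpolation is supported: `m > n` is an error, and `m = n` returns
#' the observed values.
#'
#' @inheritParams hill_number
#' @param m Subsample size, `1 <= m <= sum(x)`.
#' @return Numeric vector of rarefied Hill numbers, one per `q`.
#' @export
#' @examples
#' rarefy_hill(c(2, 1), m = 2, q = 0) # 5/3 by exhaustive enumeration
rarefy_hill <- function(x, m, q = c(0, 1, 2)) {
  x <- check_abundance(x)
  n <- sum(x)
  assert_that(m >= 1 && m == floor(m), "m must be a positive integer")
  if (m > n) stop("m exceeds the sample size: extrapolation is not supported")
  if (m == n) return(hill_number(x, q))
  efk <- NULL
  vapply(q, function(qq) {
    if (qq == 0) {
      length(x) - sum(exp(lchoose(n - x, m) - lchoose(n, m)))
    } else {
      if (is.null(efk)) efk <<- expected_freq_counts(x, m)
      k <- seq_len(m)
      if (qq == 1) exp(sum(efk * (-(k / m) * log(k / m)))) else
        1 / sum(efk * (k / m)^2)
    }
  }, numeric(1))
}

#' Estimated sample coverage at subsample size m
#'
#' Expected proportion of individuals in the assemblage belonging to species
#' detected in a subsample of size `m` (the coverage estimator used for
#' coverage-based standardisation). For `m < n` the exact interpolated form
#' `1 - sum_i (x_i / n) C(n - x_i, m) / C(n - 1, m)` is used; at `m = n` the
#' f1/f2-adjusted Good-Turing estimate
#' `1 - (f1 / n) * ((n - 1) f1 / ((n - 1) f1 + 2 f2))`.
#'
#' @inheritParams rarefy_hill
#' @return Estimated coverage in \[0, 1\].
#' @export
coverage_at_m <- function(x, m) {
  x <- check_abundance(x)
  n <- sum(x)
  assert_that(m >= 1 && m == floor(m), "m must be a positive integer")
  if (m > n) stop("m exceeds the sample size: extrapolation is not supported")
  if (m < n) {
    return(1 - sum((x / n) * exp(lchoose(n - x, m) - lchoose(n - 1, m))))
  }
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(1)
  # Good-Turing adjustment; the f2 = 0 fallback keeps the estimator finite
  A <- if (f2 > 0) {
    (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  } else {
    (n - 1) * (f1 - 1) / ((n - 1) * (f1 - 1) + 2)
  }
  1 - (f1 / n) * A
}

# multinomial bootstrap of an abundance vector; "chao" augments the empirical
# proportions with an estimated unseen-species component before resampling
boot_abundance <- function(x, variant = c("multinomial", "chao")) {
  variant <- match.arg(variant)
  n <- sum(x)
  if (variant == "multinomial") {
    p <- x / n
  } else {
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    chat <- coverage_at_m(x, n)
    lambda <- if (f1 > 0) (1 - chat) / sum((x / n) * (1 - x / n)^n) else 0
    p_seen <- (x / n) * (1 - lambda * (1 - x / n)^n)
    f0 <- if (f2 > 0) ceiling((n - 1) / n * f1^2 / (2 * f2)) else
      ceiling((n - 1) / n * f1 * (f1 - 1) / 2)
    p <- if (f0 > 0 && (1 - sum(p_seen)) > 0) {
      c(p_seen, rep((1 - sum(p_seen)) / f0, f0))
    } else p_seen
  }
  draw <- stats::rmultinom(1, n, p)[, 1]
  draw[draw > 0]
}

#' Coverage-standardised Hill numbers with bootstrap intervals
#'
#' Finds the smallest subsample size `m` whose estimated coverage reaches the
#' target `C_star`, and reports rarefied Hill numbers at that size with
#' symmetric bootstrap intervals (estimate +/- 1.96 bootstrap SDs, from
#' multinomial resampling of the n records; the multinomial bootstrap loses
#' rare species systematically, so percentile bounds would sit below the
#' point estimate -- the symmetric form keeps the estimate inside its
#' interval. An unseen-species-adjusted resampling scheme is available via
#' `boot_variant = "chao"`). When even the full
#' sample does not attain `C_star`, the boundary estimate at `m = n` is
#' returned with `coverage_short = TRUE` and a warning.
#'
#' @inheritParams hill_number
#' @param C_star Target coverage in \[0, 1\].
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param boot_variant `"multinomial"` (default) or `"chao"`.
#' @param seed Integer seed for the bootstrap.
#' @return Tibble with one row per order: `q`, `m`, `coverage`, `estimate`,
#'   `lower`, `upper`, `n_boot`, `coverage_short`.
#' @export
standardise_by_coverage <- function(x, C_star = 0.90, q = c(0, 1, 2),
                                    n_boot = 200,
                                    boot_variant = "multinomial", seed = 1) {
  x <- check_abundance(x)
  assert_that(C_star >= 0 && C_star <= 1, "C_star must lie in [0, 1]")
  n <- sum(x)
  cov_m <- vapply(seq_len(n), function(m) coverage_at_m(x, m), numeric(1))
  short <- max(cov_m) < C_star
  if (short) {
    warning("target coverage ", C_star,
            " unreachable by interpolation; reporting the m = n boundary estimate")
    m_star <- n
  } else {
    m_star <- which(cov_m >= C_star)[1]
  }
  est <- rarefy_hill(x, m_star, q)
  boots <- withr::with_seed(seed, {
    replicate(n_boot, {
      xb <- boot_abundance(x, boot_variant)
      mb <- min(m_star, sum(xb))
      rarefy_hill(xb, mb, q)
    })
  })
  boots <- matrix(boots, nrow = length(q))
  bsd <- apply(boots, 1, stats::sd)
  tibble::tibble(
    q = q, m = m_star, coverage = cov_m[m_star], estimate = est,
    lower = pmax(est - 1.96 * bsd, 1),
    upper = est + 1.96 * bsd,
    n_boot = n_boot, coverage_short = short
  )
}

#' Rarefied Hill numbers at a common sample size, with bootstrap intervals
#'
#' @inheritParams standardise_by_coverage
#' @param m Common subsample size (default 27, the smallest substrate total
#'   in the motivating archive).
#' @return Tibble with one row per order: `q`, `m`, `estimate`, `lower`,
#'   `upper`, `n_boot`.
#' @export
rarefied_hill_ci <- function(x, m = 27, q = c(0, 1, 2), n_boot = 200,
                             boot_variant = "multinomial", seed = 1) {
  x <- check_abundance(x)
  est <- rarefy_hill(x, m, q)
  boots <- withr::with_seed(seed, {
    replicate(n_boot, {
      xb <- boot_abundance(x, boot_variant)
      rarefy_hill(xb, min(m, sum(xb)), q)
    })
  })
  boots <- matrix(boots, nrow = length(q))
  bsd <- apply(boots, 1, stats::sd)
  tibble::tibble(
    q = q, m = m, estimate = est,
    lower = pmax(est - 1.96 * bsd, 1),
    upper = est + 1.96 * bsd,
    n_boot = n_boot
  )
}

#' Evenness and dominance summaries
#'
#' Shannon entropy (natural log), Pielou's evenness `J = q1D / q0D`
#' (equivalently `exp(H') / S`, bounded in (0, 1\]) and the Gini-Simpson
#' index `1 - D = 1 - sum p^2`. With `m` supplied, all three are derived from
#' the rarefied Hill numbers at that common sample size; otherwise from the
#' observed vector. A single-species vector has `J = 1` by convention.
#'
#' @inheritParams rarefy_hill
#' @param m Optional common sample size for rarefied evenness.
#' @return Tibble with columns `shannon`, `pielou_J`, `gini_simpson`.
#' @export
#' @examples
#' evenness_suite(c(8, 2))
evenness_suite <- function(x, m = NULL) {
  h <- if (is.null(m)) hill_number(x, c(0, 1, 2)) else rarefy_hill(x, m, c(0, 1, 2))
  tibble::tibble(
    shannon = log(h[2]),
    pielou_J = h[2] / h[1],
    gini_simpson = 1 - 1 / h[3]
  )
}

#' Per-substrate abundance vectors from a count frame
#'
#' Pools record counts over countries to give one named abundance vector per
#' substrate class.
#'
#' @param frame A count frame from [aggregate_counts()].
#' @return Named list of integer abundance vectors.
#' @export
substrate_abundances <- function(frame) {
  frame %>%
    dplyr::group_by(.data$substrateCategory, .data$species) %>%
    dplyr::summarise(y = sum(.data$y), .groups = "drop") %>%
    split(.$substrateCategory) %>%
    purrr::map(~stats::setNames(.x$y, .x$species))
}

#' Substrate-level diversity panel
#'
#' Computes, per substrate class: observed records / richness / singletons
#' and Good's coverage; rarefied Hill numbers, evenness and dominance at a
#' common sample size `m`; and coverage-standardised Hill numbers at target
#' coverage `C_star`. Substrates with fewer than `m` records are reported at
#' their own total (flagged via `m_used`).
#'
#' @param frame A count frame from [aggregate_counts()].
#' @param m Common sample size (default 27).
#' @param C_star Target coverage (default 0.90).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @return Tidy tibble, one row per substrate x panel x order, with columns
#'   `substrateCategory`, `panel` (`"size"` or `"coverage"`), `q`, `m_used`,
#'   `estimate`, `lower`, `upper`, plus per-substrate descriptive columns.
#' @export
substrate_diversity <- function(frame, m = 27, C_star = 0.90, n_boot = 200,
                                seed = 1) {
  vecs <- substrate_abundances(frame)
  seeds <- derive_seeds(seed, 2 * length(vecs))
  purrr::imap_dfr(vecs, function(x, sub) {
    i <- match(sub, names(vecs))
    mm <- min(m, sum(x))
    size_panel <- rarefied_hill_ci(x, mm, n_boot = n_boot, seed = seeds[2 * i - 1]) %>%
      dplyr::mutate(panel = "size") %>%
      dplyr::rename(m_used = "m")
    cov_panel <- standardise_by_coverage(x, C_star, n_boot = n_boot,
                                         seed = seeds[2 * i]) %>%
      dplyr::mutate(panel = "coverage") %>%
      dplyr::select(-"coverage", -"coverage_short") %>%
      dplyr::rename(m_used = "m")
    ev <- evenness_suite(x, mm)
    dplyr::bind_rows(size_panel, cov_panel) %>%
      dplyr::mutate(
        substrateCategory = sub,
        records = sum(x), richness = length(x), singletons = sum(x == 1),
        goods_coverage = goods_coverage(sum(x), sum(x == 1)),
        shannon_at_m = ev$shannon, pielou_J_at_m = ev$pielou_J,
        gini_simpson_at_m = ev$gini_simpson
      )
  }) %>%
    dplyr::relocate("substrateCategory", "panel", "q", "m_used")
}
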