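#' Simulation-based randomized-quantile residual diagnostics
#'
#' For each observation, `S` response values are simulated from the fitted
#' model and the residual is the randomized position of the observed count in
#' its simulated distribution -- Uniform(0, 1) under a correctly specified
#' model. A simulation-based dispersion test compares the variance of the
#' observed counts with the variances of the simulated response vectors
#' (statistic = observed/mean simulated variance; two-sided empirical p with
#' the add-one convention), and a Kolmogorov-Smirnov statistic summarises
#' uniformity of the residuals.
#'
#' @param fit A `substrate_model` or `ztnb_glm` fit.
#' @param S Number of simulations per observation (default 250; below 50 a
#'   warning is issued).
#' @param seed Integer seed.
#' @return Object of class `residual_diagnostics`: list with `residuals`
#'   (vector in \[0, 1\]), `dispersion` (statistic, `p_value`), `ks`
#'   (statistic, `p_value`), `n_sim`.
#' @export
quantile_residuals <- function(fit, S = 250, seed = 1) {
  if (S < 50) warning("S < 50 simulations gives coarse residuals")
  if (inherits(fit, "substrate_model")) {
    y <- fit$data$y
    sims <- withr::with_seed(seed, {
      as.matrix(stats::simulate(fit$fit, nsim = S))
    })
  } else if (inherits(fit, "ztnb_glm")) {
    y <- fit$y
    sims <- withr::with_seed(seed, {
      matrix(rztnb(length(fit$mu) * S, rep(fit$mu, S), fit$k),
             ncol = S)
    })
  } else {
    stop("unsupported fit class")
  }
  res <- withr::with_seed(seed + 1, {
    u <- stats::runif(length(y))
    vapply(seq_along(y), function(i) {
      lo <- sum(sims[i, ] < y[i])
      ties <- sum(sims[i, ] == y[i])
      (lo + u[i] * (1 + ties)) / (S + 1)
    }, numeric(1))
  })
  v_obs <- stats::var(y)
  v_sim <- apply(sims, 2, stats::var)
  p_disp <- min(1, 2 * min((1 + sum(v_sim >= v_obs)) / (S + 1),
                           (1 + sum(v_sim <= v_obs)) / (S + 1)))
  ks <- suppressWarnings(stats::ks.test(res, "punif"))
  structure(
    list(residuals = res,
         dispersion = list(statistic = v_obs / mean(v_sim), p_value = p_disp),
         ks = list(statistic = unname(ks$statistic), p_value = ks$p.value),
         n_sim = S),
    class = "residual_diagnostics"
  )
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat("Randomized-quantile residual diagnostics (", x$n_sim, "simulations )\n")
  cat("  dispersion ratio:", format(x$dispersion$statistic, digits = 3),
      " p =", format(x$dispersion$p_value, digits = 3), "\n")
  cat("  KS uniformity:", format(x$ks$statistic, digits = 3),
      " p =", format(x$ks$p_value, digits = 3), "\n")
  invisible(x)
}

# manual population-level prediction for held-out cells: fixed effects, plus
# taxon BLUPs where the taxon was seen in training, country effect at 0
predict_heldout <- function(beta, taxon_blup, heldout, reference, levels_sub) {
  sub <- as.character(heldout$substrateCategory)
  bnames <- paste0("substrateCategory", sub)
  bsub <- ifelse(sub == reference, 0,
                 unname(beta[bnames]))
  if (any(is.na(bsub))) {
    stop("held-out substrate level absent from training fit")
  }
  blup <- taxon_blup[as.character(heldout$.taxon)]
  blup[is.na(blup)] <- 0
  exp(unname(beta["(Intercept)"]) + bsub + blup + heldout$log_offset)
}

# conditional (zero-truncated) mean E[y | y > 0] = mu / (1 - p0): held-out
# rows exist only where a count was recorded, so this is the mean the
# predictions must be compared against
ztnb_conditional_mean <- function(mu, k) {
  p0 <- exp(k * (log(k) - log(k + mu)))
  mu / (1 - p0)
}

#' Calibration slope of held-out counts on log predictions
#'
#' Poisson GLM of observed counts on the log of predicted means, with robust
#' Eicker-Huber-White (HC0) standard errors. A slope of 1 indicates perfect
#' calibration; slopes below 1 indicate over-dispersion of predictions
#' relative to outcomes (typical for blocked extrapolation), above 1
#' under-confident (shrunken) predictions. The slope is invariant to
#' rescaling all predictions by a constant (absorbed by the intercept).
#'
#' @param y Observed counts.
#' @param mu Predicted means (> 0).
#' @param conf_level Interval level (default 0.95).
#' @return Tibble with `slope`, `conf.low`, `conf.high`, `degenerate`.
#' @export
calibration_slope <- function(y, mu, conf_level = 0.95) {
  assert_that(length(y) == length(mu) && all(mu > 0),
              "y and mu must have equal length and mu must be positive")
  if (stats::sd(log(mu)) < 1e-10) {
    warning("predictions are constant; calibration slope undefined")
    return(tibble::tibble(slope = NA_real_, conf.low = NA_real_,
                          conf.high = NA_real_, degenerate = TRUE))
  }
  m <- stats::glm(y ~ log(mu), family = stats::poisson())
  vc <- sandwich::vcovHC(m, type = "HC0")
  qz <- stats::qnorm(1 - (1 - conf_level) / 2)
  sl <- unname(stats::coef(m)[2])
  se <- sqrt(vc[2, 2])
  tibble::tibble(slope = sl, conf.low = sl - qz * se,
                 conf.high = sl + qz * se, degenerate = FALSE)
}

#' Leave-one-country-out cross-validation of the effort model
#'
#' The primary predictive check: each fold holds out one country, the model
#' is refitted on the rest, and held-out cells are predicted at the
#' population level for country (a held-out country has no estimated effect,
#' so its random effect is set to the population mean, 0) while taxon
#' conditional modes are carried over where the taxon was seen in training.
#' Reports per-fold and mean RMSE and Poisson deviance
#' `2 sum(y log(y / mu) - (y - mu))`, a pooled calibration slope from a
#' Poisson GLM of held-out counts on `log(mu_hat)` with robust
#' Eicker-Huber-White standard errors (1 = perfect calibration), and a
#' decile calibration table with the number of observations per decile.
#'
#' @param frame A count frame from [aggregate_counts()].
#' @param reference Reference substrate code.
#' @param taxon Taxon column name (default `"species"`).
#' @param engine `"glmm"` (mixed model per fold) or `"ztnb"` (fixed-effects
#'   zero-truncated NB regression per fold; fast, no conditional modes).
#' @param conf_level Interval level for the calibration slope.
#' @return Object of class `cv_report`: list with `folds` (per-fold tibble),
#'   `mean` (tibble of mean RMSE/deviance and per-fold mean slope),
#'   `calibration` (pooled slope, robust conf.low/conf.high, `degenerate`
#'   flag), `deciles` (tibble `decile`, `mean_predicted`, `mean_observed`,
#'   `n`), `heldout` (pooled predictions tibble).
#' @export
loco_cv <- function(frame, reference = "LIG", taxon = "species",
                    engine = c("glmm", "ztnb"), conf_level = 0.95) {
  engine <- match.arg(engine)
  countries <- sort(unique(as.character(frame$country)))
  assert_that(length(countries) >= 2, "need at least two countries for LOCO-CV")
  d <- as.data.frame(frame)
  d$.taxon <- factor(d[[taxon]])
  pooled <- list()
  folds <- purrr::map_dfr(countries, function(cc) {
    train <- d[d$country != cc, ]
    held <- d[d$country == cc, ]
    if (nrow(held) == 0 || nrow(train) == 0) {
      warning("fold ", cc, " has no rows; skipped")
      return(tibble::tibble())
    }
    held$substrateCategory <- as.character(held$substrateCategory)
    keep <- held$substrateCategory %in% unique(as.character(train$substrateCategory))
    held <- held[keep, ]
    if (nrow(held) == 0) return(tibble::tibble())
    if (engine == "glmm") {
      f <- fit_substrate_model(train, reference = reference, taxon = taxon,
                               require_convergence = FALSE)
      beta <- glmmTMB::fixef(f$fit)$cond
      re <- glmmTMB::ranef(f$fit)$cond$.taxon
      blup <- stats::setNames(re[["(Intercept)"]], rownames(re))
      k_hat <- glmmTMB::sigma(f$fit)
    } else {
      train$substrateCategory <- stats::relevel(factor(train$substrateCategory),
                                                ref = reference)
      f <- ztnb_glm(y ~ substrateCategory, train, offset = train$log_offset)
      beta <- f$coefficients
      blup <- numeric(0)
      k_hat <- f$k
    }
    mu <- ztnb_conditional_mean(
      predict_heldout(beta, blup, held, reference, NULL), k_hat)
    pooled[[cc]] <<- tibble::tibble(country = cc, y = held$y, mu = mu)
    tibble::tibble(
      country = cc, n = nrow(held),
      rmse = sqrt(mean((held$y - mu)^2)),
      deviance = 2 * sum(held$y * log(held$y / mu) - (held$y - mu)),
      slope = tryCatch(
        unname(stats::coef(stats::glm(held$y ~ log(mu),
                                      family = stats::poisson()))[2]),
        error = function(e) NA_real_)
    )
  })
  po <- dplyr::bind_rows(pooled)
  calib <- as.list(calibration_slope(po$y, po$mu, conf_level))
  breaks <- unique(stats::quantile(po$mu, seq(0, 1, 0.1)))
  po$decile <- cut(po$mu, breaks = breaks, include.lowest = TRUE,
                   labels = FALSE)
  deciles <- po %>%
    dplyr::group_by(.data$decile) %>%
    dplyr::summarise(mean_predicted = mean(.data$mu),
                     mean_observed = mean(.data$y),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(folds = folds,
         mean = tibble::tibble(rmse = mean(folds$rmse),
                               deviance = mean(folds$deviance),
                               slope_foldmean = mean(folds$slope, na.rm = TRUE)),
         calibration = calib, deciles = deciles, heldout = po,
         engine = engine),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Leave-one-country-out cross-validation (", nrow(x$folds), "folds,",
      x$engine, "engine )\n")
  cat("  mean RMSE:", format(x$mean$rmse, digits = 4),
      " mean Poisson deviance:", format(x$mean$deviance, digits = 5), "\n")
  cat("  pooled calibration slope:", format(x$calibration$slope, digits = 3),
      " [", format(x$calibration$conf.low, digits = 3), ",",
      format(x$calibration$conf.high, digits = 3), "]\n")
  invisible(x)
}

#' Sensitivity of substrate contrasts to model specification
#'
#' Refits the effort model under four variants -- V1: baseline with taxon
#' random substrate slopes; V2: intercepts only; V3: as V1 after excluding
#' substrates below the rarity threshold; V4: as V1 with rows of rare
#' substrates down-weighted by `min(1, substrate total / threshold)` -- and
#' reports the change in log rate ratio per substrate relative to V1.
#' Intervals combine the Wald standard errors of the two fits
#' (`sqrt(se_V1^2 + se_v^2)`); a parametric bootstrap (simulate from V1,
#' refit both) is used instead when `B > 0`.
#'
#' @param frame A count frame from [aggregate_counts()].
#' @param reference Reference substrate code.
#' @param rarity_threshold Record total defining a rare substrate (default
#'   100).
#' @param B Parametric-bootstrap replicates for the intervals (default 0 =
#'   Wald combination).
#' @param seed Integer seed (bootstrap only).
#' @param conf_level Interval level.
#' @return Tibble: `variant`, `substrateCategory`, `log_rr`, `delta_log_rr`
#'   (vs V1; 0 for V1 itself), `conf.low`, `conf.high`, `converged`.
#' @export
sensitivity_variants <- function(frame, reference = "LIG",
                                 rarity_threshold = 100, B = 0, seed = 1,
                                 conf_level = 0.95) {
  totals <- frame %>%
    dplyr::group_by(.data$substrateCategory) %>%
    dplyr::summarise(n = sum(.data$y), .groups = "drop")
  rare <- totals$substrateCategory[totals$n < rarity_threshold]
  fits <- list(
    V1 = function(fr) fit_substrate_model(fr, reference, taxon_slopes = TRUE,
                                          require_convergence = FALSE),
    V2 = function(fr) fit_substrate_model(fr, reference, taxon_slopes = FALSE,
                                          require_convergence = FALSE),
    V3 = function(fr) fit_substrate_model(
      dplyr::filter(fr, !.data$substrateCategory %in% rare), reference,
      taxon_slopes = TRUE, require_convergence = FALSE),
    V4 = function(fr) fit_substrate_model(
      fr, reference, taxon_slopes = TRUE,
      weights = pmin(1, totals$n[match(fr$substrateCategory,
                                       totals$substrateCategory)] /
                      rarity_threshold),
      require_convergence = FALSE)
  )
  coefs <- purrr::imap(fits, function(f, nm) {
    fit <- tryCatch(f(frame), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    td <- tidy(fit) %>%
      dplyr::filter(startsWith(.data$term, "substrateCategory")) %>%
      dplyr::mutate(substrateCategory = sub("^substrateCategory", "", .data$term))
    list(td = td, converged = fit$converged, fit = fit)
  })
  assert_that(!is.null(coefs$V1), "baseline variant V1 failed to fit")
  base <- coefs$V1$td
  qz <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- purrr::imap_dfr(coefs, function(cf, nm) {
    if (is.null(cf)) {
      return(tibble::tibble(variant = nm, substrateCategory = NA_character_,
                            log_rr = NA_real_, delta_log_rr = NA_real_,
                            conf.low = NA_real_, conf.high = NA_real_,
                            converged = FALSE))
    }
    cf$td %>%
      dplyr::left_join(dplyr::select(base, "substrateCategory",
                                     base_est = "estimate",
                                     base_se = "std.error"),
                       by = "substrateCategory") %>%
      dplyr::transmute(
        variant = nm, substrateCategory = .data$substrateCategory,
        log_rr = .data$estimate,
        delta_log_rr = .data$estimate - .data$base_est,
        se_delta = if (nm == "V1") 0 else
          sqrt(.data$std.error^2 + .data$base_se^2),
        conf.low = .data$delta_log_rr - qz * .data$se_delta,
        conf.high = .data$delta_log_rr + qz * .data$se_delta,
        converged = cf$converged
      ) %>%
      dplyr::select(-"se_delta")
  })
  if (B > 0 && !is.null(coefs$V1$fit)) {
    out <- sensitivity_boot_ci(out, coefs, frame, reference, rare,
                               rarity_threshold, B, seed, conf_level)
  }
  out
}

# parametric-bootstrap intervals for the sensitivity deltas
sensitivity_boot_ci <- function(out, coefs, frame, reference, rare,
                                rarity_threshold, B, seed, conf_level) {
  seeds <- derive_seeds(seed, B)
  v1fit <- coefs$V1$fit
  grab <- function(fit) {
    b <- glmmTMB::fixef(fit$fit)$cond
    b <- b[startsWith(names(b), "substrateCategory")]
    stats::setNames(unname(b), sub("^substrateCategory", "", names(b)))
  }
  deltas <- purrr::map(seq_len(B), function(b) {
    tryCatch({
      ys <- withr::with_seed(seeds[b], stats::simulate(v1fit$fit)[[1]])
      fr <- frame
      fr$y <- ys
      fr <- fr[fr$y > 0, ]
      v1b <- fit_substrate_model(fr, reference, taxon_slopes = TRUE,
                                 require_convergence = FALSE)
      purrr::imap_dfr(list(
        V2 = fit_substrate_model(fr, reference, taxon_slopes = FALSE,
                                 require_convergence = FALSE),
        V3 = fit_substrate_model(
          dplyr::filter(fr, !.data$substrateCategory %in% rare), reference,
          taxon_slopes = TRUE, require_convergence = FALSE)
      ), function(vf, nm) {
        d <- grab(vf) - grab(v1b)[names(grab(vf))]
        tibble::tibble(variant = nm, substrateCategory = names(d), delta = d)
      })
    }, error = function(e) NULL)
  })
  dd <- dplyr::bind_rows(deltas)
  if (nrow(dd) == 0) return(out)
  alpha <- (1 - conf_level) / 2
  ci <- dd %>%
    dplyr::group_by(.data$variant, .data$substrateCategory) %>%
    dplyr::summarise(boot.low = stats::quantile(.data$delta, alpha, names = FALSE),
                     boot.high = stats::quantile(.data$delta, 1 - alpha,
                                                 names = FALSE),
                     .groups = "drop")
  out %>%
    dplyr::left_join(ci, by = c("variant", "substrateCategory")) %>%
    dplyr::mutate(conf.low = dplyr::coalesce(.data$boot.low, .data$conf.low),
                  conf.high = dplyr::coalesce(.data$boot.high, .data$conf.high)) %>%
    dplyr::select(-"boot.low", -"boot.high")
}

#' Concordance of per-species modal pH across binning resolutions
#'
#' Estimates each species' modal pH on two binning grids (default 0.01 and
#' 0.1 pH units) via Poisson spline fits to binned counts with a log offset
#' equal to the total measured records per bin, and summarises agreement of
#' the paired modes with Pearson and Spearman correlations. Species whose
#' occupied bins cannot support the spline fall back to the maximum-share bin
#' and are flagged sparse, as are modes at the edge of the species' observed
#' pH range.
#'
#' @param records Occurrence tibble with `pH` and `species`.
#' @param resolutions Two bin widths in pH units (default `c(0.01, 0.1)`).
#' @param min_records Minimum measured pH records per species (default 5).
#' @param df Spline degrees of freedom (default 3).
#' @return Object of class `ph_concordance`: list with `modes` (tibble
#'   `species`, `n`, `mode_fine`, `mode_coarse`, `sparse`, `boundary`),
#'   `pearson`, `spearman` (NA when fewer than 3 species are eligible).
#' @export
ph_mode_concordance <- function(records, resolutions = c(0.01, 0.1),
                                min_records = 5, df = 3) {
  measured <- records %>%
    dplyr::filter(!is.na(.data$pH), !is.na(.data$species)) %>%
    dplyr::select("species", "pH")
  eligible <- measured %>%
    dplyr::count(.data$species) %>%
    dplyr::filter(.data$n >= min_records)
  mode_at <- function(res) {
    lo <- floor(min(measured$pH) / res) * res
    hi <- ceiling(max(measured$pH) / res) * res
    edges <- seq(lo, hi, by = res)
    bin <- pmin(findInterval(measured$pH, edges, rightmost.closed = TRUE),
                length(edges) - 1)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    expo <- tabulate(bin, nbins = length(mids))
    purrr::map_dfr(eligible$species, function(sp) {
      ybin <- tabulate(bin[measured$species == sp], nbins = length(mids))
      use <- expo > 0
      occ <- mids[use][ybin[use] > 0]
      dom <- range(occ)
      df_use <- min(df, length(unique(occ)) - 2)
      if (df_use < 1) {
        m <- mids[use][which.max(ybin[use] / expo[use])]
        return(tibble::tibble(species = sp, mode = m, sparse = TRUE,
                              boundary = m <= dom[1] || m >= dom[2]))
      }
      x <- mids[use]
      knots <- if (df_use > 1) {
        stats::quantile(occ, seq_len(df_use - 1) / df_use, names = FALSE)
      } else NULL
      X <- cbind(1, splines::ns(x, knots = knots, Boundary.knots = range(x)))
      m <- tryCatch({
        beta <- poisson_ridge(X, ybin[use], log(expo[use]), ridge = 1e-6)
        dense <- seq(dom[1], dom[2], length.out = 256)
        Xd <- cbind(1, splines::ns(dense, knots = knots,
                                   Boundary.knots = range(x)))
        dense[which.max(drop(Xd %*% beta))]
      }, error = function(e) mids[use][which.max(ybin[use] / expo[use])])
      tibble::tibble(species = sp, mode = m, sparse = FALSE,
                     boundary = abs(m - dom[1]) < res || abs(m - dom[2]) < res)
    })
  }
  fine <- mode_at(min(resolutions))
  coarse <- mode_at(max(resolutions))
  modes <- eligible %>%
    dplyr::left_join(dplyr::rename(fine, mode_fine = "mode",
                                   sparse_fine = "sparse",
                                   boundary_fine = "boundary"),
                     by = "species") %>%
    dplyr::left_join(dplyr::rename(coarse, mode_coarse = "mode",
                                   sparse_coarse = "sparse",
                                   boundary_coarse = "boundary"),
                     by = "species") %>%
    dplyr::mutate(sparse = .data$sparse_fine | .data$sparse_coarse,
                  boundary = .data$boundary_fine | .data$boundary_coarse) %>%
    dplyr::select("species", "n", "mode_fine", "mode_coarse", "sparse",
                  "boundary")
  if (nrow(modes) < 3) {
    message("fewer than 3 eligible species; correlations not computed")
    pe <- sp <- NA_real_
  } else {
    pe <- stats::cor(modes$mode_fine, modes$mode_coarse, method = "pearson")
    sp <- stats::cor(modes$mode_fine, modes$mode_coarse, method = "spearman")
  }
  structure(list(modes = modes, pearson = pe, spearman = sp),
            class = "ph_concordance")
}

#' @export
print.ph_concordance <- function(x, ...) {
  cat("Per-species modal pH concordance across binning resolutions\n")
  cat("  species:", nrow(x$modes), " Pearson r:", format(x$pearson, digits = 3),
      " Spearman rho:", format(x$spearman, digits = 3), "\n")
  invisible(x)
}
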