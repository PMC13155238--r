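#' Build an effort-weighted site x taxon matrix
#'
#' Sites are observed (block, group) combinations -- country x substrate for
#' substrate indicators, country x pH band for pH screening. Each site carries
#' its total record count as an effort weight; the matrix holds presence
#' (default) or record counts per taxon. Taxa occurring in fewer than
#' `min_sites` sites are dropped: their specificity and fidelity are
#' inherently unstable at this resolution.
#'
#' @param data Tibble with one row per (block, group, taxon) holding a
#'   positive count: a count frame from [aggregate_counts()] works directly
#'   for substrate sites.
#' @param group Name of the grouping column (default `"substrateCategory"`).
#' @param taxon Name of the taxon column (default `"species"`).
#' @param block Name of the block column (default `"country"`).
#' @param min_sites Minimum number of occupied sites for a taxon to be
#'   retained (default 3).
#' @param presence Store presence/absence (default) rather than counts.
#' @return Object of class `site_taxon_matrix`: list with `sites` (tibble:
#'   `site`, `block`, `group`, `effort`), `X` (site x taxon matrix) and the
#'   retention threshold.
#' @export
build_sites <- function(data, group = "substrateCategory", taxon = "species",
                        block = "country", min_sites = 3, presence = TRUE) {
  assert_that(nrow(data) > 0, "data must be non-empty")
  d <- tibble::tibble(
    block = as.character(data[[block]]),
    group = as.character(data[[group]]),
    taxon = as.character(data[[taxon]]),
    y = if ("y" %in% names(data)) data$y else 1L
  ) %>%
    dplyr::filter(!is.na(.data$block), !is.na(.data$group), !is.na(.data$taxon)) %>%
    dplyr::group_by(.data$block, .data$group, .data$taxon) %>%
    dplyr::summarise(y = sum(.data$y), .groups = "drop") %>%
    dplyr::mutate(site = paste(.data$block, .data$group, sep = ":"))
  sites <- d %>%
    dplyr::group_by(.data$site, .data$block, .data$group) %>%
    dplyr::summarise(effort = sum(.data$y), .groups = "drop") %>%
    dplyr::arrange(.data$site)
  X <- matrix(0, nrow(sites), dplyr::n_distinct(d$taxon),
              dimnames = list(sites$site, sort(unique(d$taxon))))
  X[cbind(match(d$site, sites$site), match(d$taxon, colnames(X)))] <- d$y
  if (presence) X <- (X > 0) * 1
  occ <- colSums(X > 0)
  X <- X[, occ >= min_sites, drop = FALSE]
  structure(list(sites = sites, X = X, min_sites = min_sites,
                 presence = presence),
            class = "site_taxon_matrix")
}

#' @export
print.site_taxon_matrix <- function(x, ...) {
  cat("Site x taxon matrix:", nrow(x$X), "sites (",
      dplyr::n_distinct(x$sites$block), "blocks x",
      dplyr::n_distinct(x$sites$group), "groups ),",
      ncol(x$X), "retained taxa\n")
  invisible(x)
}

# A, B and sqrt(A * B) for every taxon x group.
# m_g = weighted mean presence of the taxon over sites of group g (weights =
# site efforts, or equal when weighted = FALSE); A = m_g / sum_g m_g
# (group-equalised specificity), B = weighted within-group occupancy.
indval_components <- function(M, weighted = TRUE, weighted_B = weighted,
                              sites = NULL, X = NULL) {
  sites <- sites %||% M$sites
  X <- X %||% M$X
  groups <- sort(unique(sites$group))
  w <- if (weighted) sites$effort else rep(1, nrow(sites))
  wB <- if (weighted_B) sites$effort else rep(1, nrow(sites))
  mg <- matrix(0, length(groups), ncol(X),
               dimnames = list(groups, colnames(X)))
  mgB <- mg
  for (g in groups) {
    j <- sites$group == g
    mg[g, ] <- colSums(X[j, , drop = FALSE] * w[j]) / sum(w[j])
    mgB[g, ] <- colSums(X[j, , drop = FALSE] * wB[j]) / sum(wB[j])
  }
  tot <- colSums(mg)
  A <- sweep(mg, 2, ifelse(tot > 0, tot, NA_real_), "/")
  B <- mgB
  list(A = A, B = B, stat = sqrt(A * B))
}

#' Effort-weighted indicator value (IndVal E)
#'
#' Specificity `A`, fidelity `B` and the indicator statistic
#' `sqrt(A * B)` of a taxon for a focal group on an effort-weighted site x
#' taxon presence matrix. With `m_g` the effort-weighted mean presence of the
#' taxon over sites of group `g`, specificity is group-equalised,
#' `A = m_focal / sum_g m_g`, and fidelity is the effort-weighted
#' within-group occupancy, `B = m_focal`. All three lie in \[0, 1\]. Setting
#' `weighted = FALSE` recovers the classic unweighted IndVal components;
#' `weighted_B = FALSE` keeps weights in A only.
#'
#' @param M A [build_sites()] matrix.
#' @param taxon Taxon name (must be retained in `M`).
#' @param group Focal group label.
#' @param weighted Use site efforts as weights (default `TRUE`).
#' @param weighted_B Use weights in the fidelity component too (default
#'   follows `weighted`).
#' @return Tibble with one row: `taxon`, `group`, `A`, `B`, `stat`.
#' @export
indval_E <- function(M, taxon, group, weighted = TRUE, weighted_B = weighted) {
  assert_that(taxon %in% colnames(M$X),
              paste("taxon", taxon, "not retained in the site matrix"))
  comp <- indval_components(M, weighted, weighted_B)
  assert_that(group %in% rownames(comp$A), paste("unknown group", group))
  tibble::tibble(taxon = taxon, group = group,
                 A = comp$A[group, taxon], B = comp$B[group, taxon],
                 stat = comp$stat[group, taxon])
}

# best group per taxon with deterministic tie-breaks: larger stat, then
# larger B, then lexicographic group label
best_group <- function(comp) {
  vapply(seq_len(ncol(comp$stat)), function(j) {
    s <- comp$stat[, j]
    s[is.na(s)] <- -Inf
    top <- which(s == max(s))
    if (length(top) > 1) {
      b <- comp$B[top, j]
      top <- top[b == max(b)]
    }
    rownames(comp$stat)[min(top)]
  }, character(1))
}

#' Country-blocked permutation test for indicator statistics
#'
#' Permutes group labels among sites *within each block* (country), leaving
#' the block structure intact, and compares the observed statistic of every
#' taxon x group combination with its permutation distribution. P-values use
#' the add-one convention `p = (1 + #[perm >= obs]) / (1 + n_perm)`, so the
#' resolution floor is `1 / (1 + n_perm)`. Benjamini-Hochberg adjustment is
#' applied across taxa (at each taxon's focal group when `focal = "best"`,
#' or across the full taxon x group grid).
#'
#' @param M A [build_sites()] matrix.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param weighted,weighted_B Passed to the statistic.
#' @param focal `"best"` (default): test each taxon at its maximising group;
#'   `"all"`: return the full taxon x group grid.
#' @return Tibble: `taxon`, `group`, `A`, `B`, `stat`, `p_value`, `p_adj`.
#' @export
blocked_permutation_test <- function(M, n_perm = 999, seed = 1,
                                     weighted = TRUE, weighted_B = weighted,
                                     focal = c("best", "all")) {
  focal <- match.arg(focal)
  sites <- M$sites
  single <- names(which(table(sites$block) == 1))
  if (length(single) > 0) {
    message("block(s) with a single site contribute no permutation variability: ",
            paste(single, collapse = ", "))
  }
  obs <- indval_components(M, weighted, weighted_B)
  exceed <- array(0, dim = dim(obs$stat))
  withr::with_seed(seed, {
    for (r in seq_len(n_perm)) {
      perm_group <- sites$group
      for (b in unique(sites$block)) {
        j <- which(sites$block == b)
        perm_group[j] <- perm_group[j][sample.int(length(j))]
      }
      ps <- sites
      ps$group <- perm_group
      pc <- indval_components(M, weighted, weighted_B, sites = ps, X = M$X)
      exceed <- exceed + (pc$stat >= obs$stat - 1e-12 &
                            !is.na(pc$stat) & !is.na(obs$stat))
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  grid <- tibble::tibble(
    taxon = rep(colnames(obs$stat), each = nrow(obs$stat)),
    group = rep(rownames(obs$stat), ncol(obs$stat)),
    A = as.vector(obs$A), B = as.vector(obs$B), stat = as.vector(obs$stat),
    p_value = as.vector(p)
  )
  if (focal == "best") {
    bg <- best_group(obs)
    grid <- grid %>%
      dplyr::inner_join(tibble::tibble(taxon = colnames(obs$stat), group = bg),
                        by = c("taxon", "group"))
  }
  grid %>% dplyr::mutate(p_adj = stats::p.adjust(.data$p_value, method = "BH"))
}

#' Stratified bootstrap confidence intervals for indicator statistics
#'
#' Resamples sites with replacement *within each group* (so the group layout
#' is preserved) and reports percentile 95% intervals of the indicator
#' statistic per taxon x group. A bound is reported as `NA` when the taxon
#' was lost from the resampled matrix (absent from every drawn site) in more
#' than half of the replicates, mirroring the not-estimable convention.
#'
#' @inheritParams blocked_permutation_test
#' @param B Number of bootstrap replicates (default 1000).
#' @param conf_level Interval level (default 0.95).
#' @return Tibble: `taxon`, `group`, `stat`, `conf.low`, `conf.high`,
#'   `n_valid` (replicates where the taxon survived).
#' @export
bootstrap_ci <- function(M, B = 1000, seed = 1, conf_level = 0.95,
                         weighted = TRUE, weighted_B = weighted,
                         focal = c("best", "all")) {
  focal <- match.arg(focal)
  sites <- M$sites
  obs <- indval_components(M, weighted, weighted_B)
  draws <- array(NA_real_, dim = c(B, dim(obs$stat)))
  withr::with_seed(seed, {
    for (r in seq_len(B)) {
      idx <- unlist(lapply(split(seq_len(nrow(sites)), sites$group),
                           function(j) j[sample.int(length(j), length(j),
                                                    replace = TRUE)]))
      bs <- sites[idx, ]
      pc <- indval_components(M, weighted, weighted_B, sites = bs,
                              X = M$X[idx, , drop = FALSE])
      draws[r, , ] <- pc$stat
    }
  })
  alpha <- (1 - conf_level) / 2
  grid <- tibble::tibble(
    taxon = rep(colnames(obs$stat), each = nrow(obs$stat)),
    group = rep(rownames(obs$stat), ncol(obs$stat)),
    stat = as.vector(obs$stat)
  )
  n_valid <- apply(draws, c(2, 3), function(v) sum(!is.na(v)))
  qfun <- function(p) apply(draws, c(2, 3), function(v) {
    ok <- v[!is.na(v)]
    if (length(ok) < B / 2) NA_real_ else
      stats::quantile(ok, p, names = FALSE)
  })
  out <- dplyr::bind_cols(grid, tibble::tibble(
    conf.low = as.vector(qfun(alpha)),
    conf.high = as.vector(qfun(1 - alpha)),
    n_valid = as.vector(n_valid)
  ))
  if (focal == "best") {
    bg <- best_group(obs)
    out <- dplyr::inner_join(out,
                             tibble::tibble(taxon = colnames(obs$stat), group = bg),
                             by = c("taxon", "group"))
  }
  out
}

#' Country-blocked K-fold held-out specificity and fidelity
#'
#' Partitions blocks (countries) into K folds. Per fold, each taxon's best
#' group is chosen on the training sites (ties broken by larger training
#' fidelity, then lexicographic group label), and specificity A and fidelity
#' B are recomputed on the held-out sites for that group. Estimates are
#' averaged across folds in which the taxon occurs in both partitions; a
#' taxon never estimable under the blocked folds gets `NA`.
#'
#' @inheritParams blocked_permutation_test
#' @param K Number of folds (5 for substrate indicators, 3 for pH bands).
#' @return Tibble: `taxon`, `heldout_A`, `heldout_B`, `n_folds` (folds where
#'   estimable).
#' @export
blocked_kfold <- function(M, K = 5, seed = 1, weighted = TRUE,
                          weighted_B = weighted) {
  blocks <- sort(unique(M$sites$block))
  assert_that(K <= length(blocks), "K must not exceed the number of blocks")
  fold_of <- withr::with_seed(seed, {
    stats::setNames(sample(rep(seq_len(K), length.out = length(blocks))), blocks)
  })
  res <- purrr::map(seq_len(K), function(k) {
    test <- M$sites$block %in% names(fold_of)[fold_of == k]
    if (!any(test) || all(test)) return(NULL)
    tr_sites <- M$sites[!test, ]; tr_X <- M$X[!test, , drop = FALSE]
    te_sites <- M$sites[test, ]; te_X <- M$X[test, , drop = FALSE]
    tr <- indval_components(M, weighted, weighted_B, sites = tr_sites, X = tr_X)
    bg <- best_group(tr)
    te <- indval_components(M, weighted, weighted_B, sites = te_sites, X = te_X)
    purrr::map_dfr(seq_along(bg), function(j) {
      taxon <- colnames(tr$stat)[j]
      in_train <- sum(tr_X[, j]) > 0
      in_test <- sum(te_X[, j]) > 0
      g_ok <- bg[j] %in% rownames(te$A)
      if (!in_train || !in_test || !g_ok) {
        return(tibble::tibble(taxon = taxon, A = NA_real_, B = NA_real_))
      }
      tibble::tibble(taxon = taxon, A = te$A[bg[j], j], B = te$B[bg[j], j])
    })
  })
  dplyr::bind_rows(res) %>%
    dplyr::group_by(.data$taxon) %>%
    dplyr::summarise(
      heldout_A = if (all(is.na(.data$A))) NA_real_ else
        mean(.data$A, na.rm = TRUE),
      heldout_B = if (all(is.na(.data$B))) NA_real_ else
        mean(.data$B, na.rm = TRUE),
      n_folds = sum(!is.na(.data$A)), .groups = "drop")
}

#' Presence-based indicator scores (A x B) for higher taxa
#'
#' Descriptive indicator scores on a presence basis: for each taxon and
#' group, specificity `A` is the share of the taxon's occupied sites that
#' fall in the group (`presences in group / total presences`), fidelity `B`
#' is the occupancy of the group (`presences in group / number of sites in
#' the group`), and the score is `A x B` (range 0-1). The group with the
#' maximum score is reported per taxon (all groups with `all_groups = TRUE`).
#' No inferential testing accompanies this summary. Display values are
#' conventionally rounded to two decimals with [round_half_up()]; full
#' precision is returned.
#'
#' @param M A [build_sites()] presence matrix.
#' @param all_groups Return every taxon x group row instead of the maximising
#'   group only.
#' @return Tibble: `taxon`, `group`, `n_focal`, `n_total`, `n_sites`, `A`,
#'   `B`, `score`, sorted by decreasing score.
#' @export
#' @examples
#' # 15 presences in the focal class out of 33 overall, 16 focal sites:
#' # A = 0.45, B = 0.94, score = 0.43
presence_score <- function(M, all_groups = FALSE) {
  P <- (M$X > 0) * 1
  groups <- sort(unique(M$sites$group))
  n_in_group <- t(vapply(groups, function(g) {
    colSums(P[M$sites$group == g, , drop = FALSE])
  }, numeric(ncol(P))))
  sites_per_group <- vapply(groups, function(g) sum(M$sites$group == g),
                            numeric(1))
  total <- colSums(P)
  out <- tibble::tibble(
    taxon = rep(colnames(P), each = length(groups)),
    group = rep(unname(groups), ncol(P)),
    n_focal = as.vector(unname(n_in_group)),
    n_total = rep(unname(total), each = length(groups)),
    n_sites = rep(unname(sites_per_group), ncol(P))
  ) %>%
    dplyr::mutate(A = .data$n_focal / .data$n_total,
                  B = .data$n_focal / .data$n_sites,
                  score = .data$A * .data$B)
  if (!all_groups) {
    out <- out %>%
      dplyr::group_by(.data$taxon) %>%
      dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$B),
                     .data$group, .by_group = TRUE) %>%
      dplyr::slice(1) %>%
      dplyr::ungroup()
  }
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' Full indicator table for a site matrix
#'
#' Combines the indicator statistic at each taxon's best group with the
#' country-blocked permutation test (BH-adjusted), stratified bootstrap
#' intervals, and blocked K-fold held-out specificity/fidelity.
#'
#' @inheritParams blocked_permutation_test
#' @param n_boot Bootstrap replicates (default 1000).
#' @param K Folds for held-out validation (default 5).
#' @return Tibble: `taxon`, `group`, `A`, `B`, `stat`, `conf.low`,
#'   `conf.high`, `p_value`, `p_adj`, `heldout_A`, `heldout_B`, sorted by
#'   decreasing statistic.
#' @export
indicator_table <- function(M, n_perm = 999, n_boot = 1000, K = 5, seed = 1,
                            weighted = TRUE, weighted_B = weighted) {
  seeds <- derive_seeds(seed, 3)
  perm <- blocked_permutation_test(M, n_perm, seed = seeds[1],
                                   weighted = weighted, weighted_B = weighted_B)
  ci <- bootstrap_ci(M, n_boot, seed = seeds[2], weighted = weighted,
                     weighted_B = weighted_B) %>%
    dplyr::select("taxon", "group", "conf.low", "conf.high")
  ho <- blocked_kfold(M, K, seed = seeds[3], weighted = weighted,
                      weighted_B = weighted_B)
  perm %>%
    dplyr::left_join(ci, by = c("taxon", "group")) %>%
    dplyr::left_join(ho, by = "taxon") %>%
    dplyr::arrange(dplyr::desc(.data$stat))
}

#' pH-band screening of indicator associations
#'
#' Uses only records with measured pH and non-missing species and substrate.
#' Produces (i) a stratum summary per substrate x pH band (records, species,
#' singletons, Good's coverage) and (ii) indicator tables over country x
#' pH-band sites at species, genus and family ranks with three-fold blocked
#' validation. The site grid behind these outputs is sparse and unbalanced,
#' so the result is labelled screening evidence: it ranks candidates and
#' prioritises systematic pH co-measurement, it does not support confirmatory
#' inference.
#'
#' @param records Occurrence tibble with `pH`, `species`, `genus`, `family`,
#'   `substrateCategory`, `country` columns.
#' @param min_sites Minimum occupied sites per taxon (default 3).
#' @param K Folds for blocked validation (default 3).
#' @param n_perm,n_boot Resampling sizes.
#' @param seed Integer seed.
#' @return List of class `myx_ph_screening`: `stratum_summary` (tibble) and
#'   `indicators` (tibble with a `rank` column over species/genus/family),
#'   plus a `label` attribute fixed at `"screening"`.
#' @export
ph_screening <- function(records, min_sites = 3, K = 3, n_perm = 199,
                         n_boot = 200, seed = 1) {
  measured <- records %>%
    dplyr::filter(!is.na(.data$pH), !is.na(.data$species),
                  !is.na(.data$substrateCategory)) %>%
    dplyr::mutate(ph_band = band_ph(.data$pH))
  if (nrow(measured) == 0) {
    warning("no records with measured pH, species and substrate; empty screening output")
    return(structure(list(stratum_summary = tibble::tibble(),
                          indicators = tibble::tibble(), label = "screening"),
                     class = "myx_ph_screening"))
  }
  stratum_summary <- measured %>%
    dplyr::group_by(.data$substrateCategory, .data$ph_band) %>%
    dplyr::summarise(
      records = dplyr::n(),
      species = dplyr::n_distinct(.data$species),
      singletons = sum(table(.data$species) == 1),
      goods_coverage = round_half_up(
        goods_coverage(dplyr::n(), sum(table(.data$species) == 1)), 2),
      .groups = "drop")

  ranks <- c("species", "genus", "family")
  seeds <- derive_seeds(seed, length(ranks))
  indicators <- purrr::map_dfr(seq_along(ranks), function(i) {
    rk <- ranks[i]
    if (!rk %in% names(measured)) return(tibble::tibble())
    counts <- measured %>%
      dplyr::filter(!is.na(.data[[rk]])) %>%
      dplyr::count(.data$country, .data$ph_band, .data[[rk]], name = "y")
    M <- build_sites(counts, group = "ph_band", taxon = rk,
                     min_sites = min_sites)
    if (ncol(M$X) == 0 || dplyr::n_distinct(M$sites$block) < K) {
      return(tibble::tibble())
    }
    indicator_table(M, n_perm = n_perm, n_boot = n_boot, K = K,
                    seed = seeds[i]) %>%
      dplyr::mutate(rank = rk, .before = 1)
  })
  structure(list(stratum_summary = stratum_summary, indicators = indicators,
                 label = "screening"),
            class = "myx_ph_screening")
}

#' @export
print.myx_ph_screening <- function(x, ...) {
  cat("pH-band indicator screening (exploratory output)\n")
  cat("Stratum summary:\n")
  print(x$stratum_summary)
  if (nrow(x$indicators) > 0) {
    cat("Top screening candidates:\n")
    print(utils::head(dplyr::arrange(x$indicators, dplyr::desc(.data$stat)), 10))
  }
  invisible(x)
}
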