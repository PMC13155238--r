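#' Run configuration for the end-to-end analysis
#'
#' Assembles the configuration consumed by [run_pipeline()]. Either `input`
#' (path to an occurrence CSV/TSV) or `simulate` (a list of
#' [generator_config()] arguments) must be supplied. Defaults follow the
#' standard analysis settings: dead wood (LIG) reference, rarity threshold
#' 100 records, common sample size m = 27, target coverage 0.90 (sensitivity
#' 0.85), five-fold blocked validation for substrate indicators and
#' three-fold for pH bands.
#'
#' @param input Path to an occurrence table, or `NULL` when simulating.
#' @param simulate List of [generator_config()] arguments, or `NULL`.
#' @param vocab Path to a YAML substrate vocabulary (`NULL` = built-in).
#' @param out_dir Output directory (created if needed).
#' @param reference Reference substrate code.
#' @param rarity_threshold Rarity rule for rankings (records).
#' @param m Common sample size for rarefaction.
#' @param coverage,coverage_sensitivity Target coverages.
#' @param K_substrate,K_ph Blocked-validation folds.
#' @param n_perm,n_boot,rank_B,elevation_B Resampling sizes; defaults are
#'   moderate so a full run stays interactive, raise them for production.
#' @param min_sites Minimum occupied sites per indicator taxon.
#' @param cv_engine LOCO-CV engine (`"ztnb"` fast default or `"glmm"`).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL, vocab = NULL,
                       out_dir = "myxindic-run", reference = "LIG",
                       rarity_threshold = 100, m = 27, coverage = 0.90,
                       coverage_sensitivity = 0.85, K_substrate = 5, K_ph = 3,
                       n_perm = 199, n_boot = 200, rank_B = 100,
                       elevation_B = 100, min_sites = 3,
                       cv_engine = "ztnb", seed = 1) {
  assert_that(!is.null(input) || !is.null(simulate),
              "provide either an input path or a simulate block")
  if (!is.null(input)) {
    assert_that(file.exists(input), paste("input file not found:", input))
  }
  if (!is.null(vocab)) {
    assert_that(file.exists(vocab), paste("vocabulary file not found:", vocab))
  }
  assert_that(rarity_threshold > 0 && m > 0 && n_perm > 0 && n_boot > 0,
              "thresholds and resampling sizes must be positive")
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(x, path, row.names = FALSE, na = "")
  path
}

#' Run the full effort-aware substrate-affinity analysis
#'
#' Executes the pipeline stages in dependency order: ingest or simulate;
#' harmonise verbatim substrate descriptors where no harmonised code is
#' present; quality flags and completeness; aggregation to the count frame;
#' substrate diversity standardisation; the zero-truncated NB effort model
#' with rate ratios and bootstrap ranks; effort-weighted indicator analysis
#' and presence scores; pH screening; elevational profiling; and validation
#' (residual diagnostics and leave-one-country-out calibration). Every stage
#' output is written as plain CSV (plus JSON for scalar summaries), and a
#' run manifest records the configuration, seeds, package versions, per-stage
#' status/timing and a content hash per output file. A failed stage halts its
#' downstream dependents but leaves independent stages running.
#'
#' @param config A [run_config()] (or path to its YAML form).
#' @return Invisibly, a list with `results` (per-stage R objects), `manifest`
#'   and `ok` (logical: all stages succeeded).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 10)
  status <- list()
  outputs <- character(0)
  results <- list()

  stage <- function(name, deps, expr) {
    if (!all(purrr::map_lgl(deps, ~isTRUE(status[[.x]]$ok)))) {
      status[[name]] <<- list(ok = FALSE, error = "skipped: upstream failure",
                              seconds = 0)
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    res <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    res$seconds <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    status[[name]] <<- res[setdiff(names(res), "value")]
    if (res$ok) results[[name]] <<- res$value
    invisible(NULL)
  }

  stage("ingest", character(0), {
    if (!is.null(config$input)) {
      read_archive(config$input)
    } else {
      sim <- generate_archive(do.call(generator_config,
                                      c(config$simulate,
                                        list(seed = seeds[1]))))
      outputs <<- c(outputs, write_stage_csv(sim$archive, config$out_dir,
                                             "archive"))
      sim$archive
    }
  })

  stage("harmonise", "ingest", {
    vocab <- if (is.null(config$vocab)) default_substrate_vocabulary() else
      read_substrate_vocabulary(config$vocab)
    archive <- results$ingest
    if (!"substrateCategory" %in% names(archive) &&
        "microhabitat" %in% names(archive)) {
      archive$substrateCategory <- harmonise_substrate(archive$microhabitat,
                                                       vocab)
    }
    archive
  })

  stage("qc", "harmonise", {
    qc <- quality_flags(results$harmonise)
    outputs <<- c(outputs, write_stage_csv(qc$completeness, config$out_dir,
                                           "completeness"))
    qc
  })

  stage("aggregate", "harmonise", {
    frame <- aggregate_counts(results$harmonise,
                              rare_substrate_threshold = config$rarity_threshold)
    outputs <<- c(outputs, write_stage_csv(frame, config$out_dir,
                                           "count_frame"))
    frame
  })

  stage("diversity", "aggregate", {
    div <- substrate_diversity(results$aggregate, m = config$m,
                               C_star = config$coverage,
                               n_boot = config$n_boot, seed = seeds[2])
    outputs <<- c(outputs, write_stage_csv(div, config$out_dir, "diversity"))
    div
  })

  stage("model", "aggregate", {
    fit <- fit_substrate_model(results$aggregate, reference = config$reference)
    rr <- rate_ratios(fit)
    rk <- bootstrap_ranks(fit, B = config$rank_B,
                          rarity_threshold = config$rarity_threshold,
                          seed = seeds[3])
    outputs <<- c(outputs, write_stage_csv(rr, config$out_dir, "rate_ratios"),
                  write_stage_csv(rk, config$out_dir, "rank_summary"))
    list(fit = fit, rate_ratios = rr, ranks = rk)
  })

  stage("indicators", "aggregate", {
    M <- build_sites(results$aggregate, min_sites = config$min_sites)
    tab <- indicator_table(M, n_perm = config$n_perm, n_boot = config$n_boot,
                           K = config$K_substrate, seed = seeds[4])
    ps <- presence_score(M)
    outputs <<- c(outputs, write_stage_csv(tab, config$out_dir, "indicators"),
                  write_stage_csv(ps, config$out_dir, "presence_scores"))
    list(sites = M, table = tab, presence = ps)
  })

  stage("ph_screening", "harmonise", {
    scr <- ph_screening(results$harmonise, min_sites = config$min_sites,
                        K = config$K_ph, n_perm = config$n_perm,
                        n_boot = config$n_boot, seed = seeds[5])
    if (nrow(scr$stratum_summary) > 0) {
      outputs <<- c(outputs,
                    write_stage_csv(scr$stratum_summary, config$out_dir,
                                    "ph_strata"),
                    write_stage_csv(scr$indicators, config$out_dir,
                                    "ph_indicators"))
    }
    scr
  })

  stage("elevation", "harmonise", {
    el <- elevation_profiles(results$harmonise, B = config$elevation_B,
                             seed = seeds[6])
    if (nrow(el$modes) > 0) {
      outputs <<- c(outputs, write_stage_csv(el$modes, config$out_dir,
                                             "elevation_modes"))
    }
    el
  })

  stage("validation", "model", {
    resid <- quantile_residuals(results$model$fit, S = 250, seed = seeds[7])
    cv <- loco_cv(results$aggregate, reference = config$reference,
                  engine = config$cv_engine)
    outputs <<- c(outputs, write_stage_csv(cv$folds, config$out_dir,
                                           "cv_folds"))
    val_path <- file.path(config$out_dir, "validation.json")
    jsonlite::write_json(
      list(dispersion = resid$dispersion, ks = resid$ks,
           calibration = cv$calibration, cv_mean = as.list(cv$mean)),
      val_path, auto_unbox = TRUE, digits = NA)
    outputs <<- c(outputs, val_path)
    list(residuals = resid, cv = cv)
  })

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config[setdiff(names(config), c("input", "out_dir"))],
    versions = list(myxindic = as.character(utils::packageVersion("myxindic")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    stages = status,
    outputs = purrr::map(stats::setNames(outputs, basename(outputs)),
                         ~list(path = .x,
                               md5 = unname(tools::md5sum(.x))))
  )
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ok <- all(purrr::map_lgl(status, "ok"))
  if (!ok) {
    failed <- names(status)[!purrr::map_lgl(status, "ok")]
    warning("pipeline stages failed: ", paste(failed, collapse = ", "))
  }
  invisible(list(results = results, manifest = manifest, ok = ok))
}
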