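# Shared fixtures, built in code at load time. Sizes are kept small so the
# whole suite stays interactive; statistical checks that need larger samples
# build their own data locally.

suppressPackageStartupMessages({
  library(dplyr)
})

# a moderate synthetic archive exercising every optional field
fixture_archive <- function(seed = 7) {
  generate_archive(generator_config(
    n_countries = 8, n_species = 60, target_total = 6000,
    frac_with_ph = 0.08, frac_with_elevation = 0.5, seed = seed,
    planted_indicators = c(Planted_lig = "LIG", Planted_cor = "COR")
  ))
}

.fix_env <- new.env()

fixture_frame <- function() {
  if (is.null(.fix_env$frame)) {
    .fix_env$sim <- fixture_archive()
    .fix_env$frame <- aggregate_counts(.fix_env$sim$archive)
  }
  .fix_env$frame
}

fixture_sim <- function() {
  invisible(fixture_frame())
  .fix_env$sim
}

# a tiny site x taxon layout with known hand-computable weighted components
toy_site_data <- function() {
  tibble::tribble(
    ~country, ~substrateCategory, ~species, ~y,
    "A", "G1", "sp1", 4,
    "A", "G1", "sp2", 1,
    "A", "G2", "sp2", 3,
    "B", "G1", "sp1", 2,
    "B", "G1", "sp2", 2,
    "B", "G2", "sp1", 1,
    "B", "G2", "sp2", 5,
    "C", "G1", "sp1", 6,
    "C", "G2", "sp2", 2
  )
}

# site data where one taxon is a perfect indicator of group "FOC" and every
# site also holds a ubiquitous filler taxon (so all sites exist)
perfect_indicator_data <- function(n_blocks = 6) {
  blocks <- paste0("B", seq_len(n_blocks))
  dplyr::bind_rows(
    tidyr::expand_grid(country = blocks,
                       substrateCategory = c("FOC", "OTH"),
                       species = "filler", y = 3),
    tibble::tibble(country = blocks, substrateCategory = "FOC",
                   species = "perfect", y = 2)
  )
}

# presence layout reproducing a given (n_focal, n_total, n_sites_focal)
# margin for one taxon: n_focal presences among the focal-group sites and
# (n_total - n_focal) presences on extra sites of another group
margin_site_data <- function(taxon, n_focal, n_total, n_sites_focal) {
  n_other <- n_total - n_focal
  n_sites_other <- max(n_other, 3)
  focal_sites <- tibble::tibble(
    country = paste0("F", seq_len(n_sites_focal)),
    substrateCategory = "FOC", species = "filler", y = 1)
  other_sites <- tibble::tibble(
    country = paste0("O", seq_len(n_sites_other)),
    substrateCategory = "OTH", species = "filler", y = 1)
  pres <- dplyr::bind_rows(
    tibble::tibble(country = paste0("F", seq_len(n_focal)),
                   substrateCategory = "FOC", species = taxon, y = 1),
    if (n_other > 0) tibble::tibble(country = paste0("O", seq_len(n_other)),
                                    substrateCategory = "OTH",
                                    species = taxon, y = 1)
  )
  dplyr::bind_rows(focal_sites, other_sites, pres)
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
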