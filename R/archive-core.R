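#' Consolidated ten-class substrate vocabulary
#'
#' Returns the controlled vocabulary used to harmonise verbatim microhabitat
#' descriptors into the consolidated ten-class substrate scheme: corticolous
#' (COR, bark), lignicolous (LIG, dead wood), ramicolous (RAM, twigs),
#' foliicolous (FOL, leaves/needles), bryophilous (BRY, mosses), herbaceous
#' (HER), terricolous (TER, soil/litter), saxicolous (SAX, rock), xylophilous
#' (XYL, processed wood) and miscellaneous (MSC, explicitly indeterminate).
#'
#' Each class carries an ordered list of case-folded keyword patterns
#' (regular expressions). Harmonisation is conservative: a descriptor is
#' assigned a class only when patterns of exactly one class match; descriptors
#' matching several classes (e.g. "moss on rotten log") stay unassigned.
#' MSC patterns fire only on wording that explicitly signals an indeterminate
#' substrate. The default rule set is an English reading of the class
#' definitions and is replaceable: load an alternative with
#' [read_substrate_vocabulary()].
#'
#' @return A tibble with columns `code`, `category`, `definition`, `patterns`
#'   (list column of regular expressions).
#' @export
#' @examples
#' default_substrate_vocabulary()$code
default_substrate_vocabulary <- function() {
  tibble::tribble(
    ~code, ~category, ~definition, ~patterns,
    "COR", "Corticolous",
    "Bark of living or recently dead woody plants (outer periderm of trunks, stems and large branches).",
    list(c("\\bbark\\b", "periderm", "corticolous")),
    "LIG", "Lignicolous",
    "Structural xylem in any stage of decay: logs, stumps and dead or fallen trunks.",
    list(c("\\blogs?\\b", "\\bstumps?\\b", "dead wood", "deadwood",
           "decay(ing|ed)? wood", "rott(en|ing) wood", "coarse woody debris",
           "(dead|fallen|decay(ing|ed)?|rott(en|ing)) trunk", "\\bxylem\\b",
           "lignicolous")),
    "RAM", "Ramicolous",
    "Fine woody twigs and branches (<2 cm), attached or fallen.",
    list(c("\\btwigs?\\b", "\\bbranch(es|lets?)?\\b", "ramicolous")),
    "FOL", "Foliicolous",
    "Photosynthetic foliar organs (leaves, needles), alive or recently abscised.",
    list(c("\\bleaf\\b", "\\bleaves\\b", "\\bneedles?\\b", "foliage",
           "foliicolous")),
    "BRY", "Bryophilous",
    "Living moss gametophytes and moss-covered substrata.",
    list(c("\\bmoss(es)?\\b", "bryophyte", "sphagnum", "liverwort",
           "bryophilous")),
    "HER", "Herbaceous",
    "Aerial parts of non-woody vascular plants (grasses, forbs, ferns, dwarf shrubs).",
    list(c("herbaceous", "\\bherbs?\\b", "\\bgrass(es)?\\b", "\\bferns?\\b",
           "\\bforbs?\\b", "dwarf shrub")),
    "TER", "Terricolous",
    "Upper soil horizons, humus layers and surface litter on the forest floor.",
    list(c("\\bsoil\\b", "humus", "forest floor", "\\blitter\\b",
           "terricolous")),
    "SAX", "Saxicolous",
    "Exposed mineral substrata: rocks, stones and boulders.",
    list(c("\\brocks?\\b", "\\bstones?\\b", "boulder", "saxicolous")),
    "XYL", "Xylophilous (anthropogenic)",
    "Anthropogenically processed wood (sawn timber, boards, constructions) weathering outdoors.",
    list(c("sawn", "timber", "\\bboards?\\b", "\\bplanks?\\b",
           "processed wood", "wooden (construction|fence|post|bench)",
           "xylophilous")),
    "MSC", "Miscellaneous",
    "Explicitly indeterminate or unspecified substrata, including unspecified decaying organic matter.",
    list(c("unspecified substrate", "indeterminate substrate",
           "unknown substrate", "substrate not specified",
           "unspecified decaying organic matter", "miscellaneous substrate"))
  ) %>%
    dplyr::mutate(patterns = purrr::map(.data$patterns, unlist))
}

#' Read or write a substrate vocabulary as YAML
#'
#' @param path File path.
#' @param vocab A vocabulary tibble as returned by
#'   [default_substrate_vocabulary()].
#' @return `read_substrate_vocabulary()` returns a vocabulary tibble;
#'   `write_substrate_vocabulary()` returns `path` invisibly.
#' @export
read_substrate_vocabulary <- function(path) {
  raw <- yaml::read_yaml(path)
  tibble::tibble(
    code = purrr::map_chr(raw, "code"),
    category = purrr::map_chr(raw, "category"),
    definition = purrr::map_chr(raw, "definition"),
    patterns = purrr::map(raw, ~as.character(.x$patterns))
  )
}

#' @rdname read_substrate_vocabulary
#' @export
write_substrate_vocabulary <- function(vocab, path) {
  yaml::write_yaml(purrr::pmap(vocab, function(code, category, definition, patterns) {
    list(code = code, category = category, definition = definition,
         patterns = as.character(patterns))
  }), path)
  invisible(path)
}

fold_text <- function(x) {
  x <- tolower(trimws(x))
  # diacritic-insensitive matching on the controlled vocabulary
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  ifelse(is.na(out), x, out)
}

#' Harmonise verbatim microhabitat descriptors to substrate codes
#'
#' Maps free-text microhabitat descriptors to the consolidated ten-class
#' substrate scheme under conservative decision rules: a code is assigned only
#' when the descriptor matches the keyword patterns of exactly one class;
#' descriptors matching zero or several classes remain unassigned (`NA`).
#' Matching is case- and diacritic-insensitive and idempotent (codes map to
#' themselves). Unmappable text is a value, not an error; the verbatim
#' descriptor should always be retained alongside the harmonised code.
#'
#' @param descriptor Character vector of verbatim microhabitat descriptors.
#' @param vocab Substrate vocabulary tibble (default
#'   [default_substrate_vocabulary()]).
#' @return Character vector of substrate codes, `NA` where no unambiguous
#'   mapping exists.
#' @export
#' @examples
#' harmonise_substrate(c("bark of living oak trunk", "decaying log",
#'                       "moss on rotten log"))
harmonise_substrate <- function(descriptor, vocab = default_substrate_vocabulary()) {
  txt <- fold_text(as.character(descriptor))
  # bare codes pass through unchanged (idempotence)
  is_code <- toupper(trimws(as.character(descriptor))) %in% vocab$code
  hits <- matrix(FALSE, length(txt), nrow(vocab))
  for (j in seq_len(nrow(vocab))) {
    pats <- vocab$patterns[[j]]
    hit_j <- rep(FALSE, length(txt))
    for (p in pats) hit_j <- hit_j | stringr::str_detect(txt, p)
    hits[, j] <- hit_j
  }
  n_hit <- rowSums(hits)
  out <- rep(NA_character_, length(txt))
  one <- which(n_hit == 1 & !is.na(txt))
  out[one] <- vocab$code[apply(hits[one, , drop = FALSE], 1, which)]
  out[is_code] <- toupper(trimws(as.character(descriptor)))[is_code]
  out
}

#' Quality-flag an occurrence table and summarise completeness
#'
#' Computes per-field missingness counts and percentages, applies range checks
#' (year bounds, latitude/longitude, pH in \[0, 14\], elevation minimum not
#' above maximum), and returns the table with flag columns added. Records with
#' missing species or substrate are flagged but retained: substrate-resolved
#' analyses subset on completeness downstream, no record is dropped here.
#'
#' @param records Occurrence tibble with Darwin-Core-style columns (any of
#'   `country`, `year`, `species`, `genus`, `family`, `order`, `microhabitat`,
#'   `substrateCategory`, `decimalLatitude`, `decimalLongitude`,
#'   `minimumElevationInMeters`, `maximumElevationInMeters`, `pH`).
#' @param year_bounds Integer vector of length 2 giving plausible year limits.
#' @return A list of class `myx_qc` with elements `records` (input plus
#'   `flag_*` logical columns) and `completeness` (tibble: `field`,
#'   `n_missing`, `pct_missing` to two decimals, plus attributes `n_records`
#'   and `n_species`).
#' @export
quality_flags <- function(records, year_bounds = c(1857, 2025)) {
  assert_that(is.data.frame(records), "records must be a data frame")
  records <- tibble::as_tibble(records)
  fields <- intersect(
    c("country", "year", "species", "genus", "family", "order", "microhabitat",
      "substrateCategory", "decimalLatitude", "decimalLongitude",
      "minimumElevationInMeters", "maximumElevationInMeters", "pH"),
    names(records)
  )
  n <- nrow(records)
  miss_n <- function(x) sum(is.na(x) | (is.character(x) & !is.na(x) & trimws(x) == ""))
  completeness <- tibble::tibble(
    field = fields,
    n_missing = purrr::map_int(fields, ~miss_n(records[[.x]])),
    pct_missing = round_half_up(100 * .data$n_missing / max(n, 1), 2)
  )
  attr(completeness, "n_records") <- n
  attr(completeness, "n_species") <-
    if ("species" %in% fields) dplyr::n_distinct(stats::na.omit(records$species)) else NA_integer_

  rng <- function(x, lo, hi) !is.na(x) & (x < lo | x > hi)
  flagged <- records
  if ("year" %in% fields) {
    flagged$flag_year_range <- rng(records$year, year_bounds[1], year_bounds[2])
  }
  if (all(c("decimalLatitude", "decimalLongitude") %in% fields)) {
    flagged$flag_coord_range <- rng(records$decimalLatitude, -90, 90) |
      rng(records$decimalLongitude, -180, 180)
  }
  if ("pH" %in% fields) flagged$flag_ph_range <- rng(records$pH, 0, 14)
  if (all(c("minimumElevationInMeters", "maximumElevationInMeters") %in% fields)) {
    flagged$flag_elevation_order <-
      !is.na(records$minimumElevationInMeters) &
      !is.na(records$maximumElevationInMeters) &
      records$minimumElevationInMeters > records$maximumElevationInMeters
  }
  if ("species" %in% fields) flagged$flag_missing_species <- is.na(records$species)
  if ("substrateCategory" %in% fields) {
    flagged$flag_missing_substrate <- is.na(records$substrateCategory)
  }
  structure(list(records = flagged, completeness = completeness),
            class = "myx_qc")
}

#' @export
print.myx_qc <- function(x, ...) {
  cat("Occurrence archive quality summary:",
      attr(x$completeness, "n_records"), "records,",
      attr(x$completeness, "n_species"), "unique species\n")
  print(x$completeness)
  invisible(x)
}

#' Midpoint elevation from bound columns
#'
#' The derived analysis elevation is the mean of the minimum and maximum
#' elevation bounds, and is only defined where both are available. Inverted
#' bounds (minimum above maximum) are treated as unusable and return `NA`.
#'
#' @param min_elev,max_elev Numeric vectors of elevation bounds in metres.
#' @return Numeric vector of midpoints in metres (`NA` where undefined).
#' @export
#' @examples
#' elevation_mid(c(100, 300, 462), c(200, NA, 462))
elevation_mid <- function(min_elev, max_elev) {
  mid <- (min_elev + max_elev) / 2
  mid[!is.na(min_elev) & !is.na(max_elev) & min_elev > max_elev] <- NA_real_
  mid
}

#' Discretise measured pH into three bands
#'
#' Bands follow the screening convention: acid (pH at most 5.00), mid
#' (5.01 to 7.00) and alkaline (7.01 and above). Values are banded on the
#' measured scale, so pH 5.00 is acid and pH 7.00 is mid.
#'
#' @param ph Numeric vector of pH values in \[0, 14\] (NA allowed).
#' @return Factor with levels `acid`, `mid`, `alkaline`.
#' @export
#' @examples
#' band_ph(c(5, 7, 7.01))
band_ph <- function(ph) {
  assert_that(all(is.na(ph) | (ph >= 0 & ph <= 14)), "pH must lie in [0, 14]")
  factor(
    dplyr::case_when(is.na(ph) ~ NA_character_,
                     ph <= 5 ~ "acid",
                     ph <= 7 ~ "mid",
                     TRUE ~ "alkaline"),
    levels = c("acid", "mid", "alkaline")
  )
}

#' Aggregate occurrences into a country x substrate x species count frame
#'
#' Builds the analysis frame for effort-aware modelling: records with
#' non-missing species and substrate are counted per
#' (country, substrateCategory, species) cell. Only observed combinations
#' appear (`y >= 1` on every row); absences are never imputed as zeros. Each
#' row also carries the total records of its country x substrate cell
#' (`cell_total`), the leave-one-out exposure `exposure = cell_total - y`
#' (records of all other species in the cell), and the log offset
#' `log(exposure + offset_constant)`. Rows with near-zero exposure and
#' substrates with few total records are flagged, not dropped: their model
#' estimates are treated as descriptive downstream.
#'
#' @param records Occurrence tibble with `country`, `substrateCategory` and
#'   `species` columns.
#' @param offset_constant Small constant added inside the log offset so it
#'   stays finite at zero exposure (default 1).
#' @param low_exposure_threshold Exposure below which a row is flagged
#'   (default 5 records).
#' @param rare_substrate_threshold Substrate record total below which all its
#'   rows are flagged rare (default 100, the pre-declared rarity rule).
#' @return A tibble of class `count_frame` with columns `country`,
#'   `substrateCategory`, `species`, `y`, `cell_total`, `exposure`,
#'   `log_offset`, `low_exposure`, `rare_substrate`.
#' @export
aggregate_counts <- function(records, offset_constant = 1,
                             low_exposure_threshold = 5,
                             rare_substrate_threshold = 100) {
  assert_that(offset_constant > 0, "offset_constant must be positive")
  frame <- records %>%
    dplyr::filter(!is.na(.data$species), !is.na(.data$substrateCategory)) %>%
    dplyr::count(.data$country, .data$substrateCategory, .data$species,
                 name = "y") %>%
    dplyr::group_by(.data$country, .data$substrateCategory) %>%
    dplyr::mutate(cell_total = sum(.data$y)) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$substrateCategory) %>%
    dplyr::mutate(substrate_total = sum(.data$y)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      exposure = .data$cell_total - .data$y,
      log_offset = log(.data$exposure + offset_constant),
      low_exposure = .data$exposure < low_exposure_threshold,
      rare_substrate = .data$substrate_total < rare_substrate_threshold
    ) %>%
    dplyr::select(-"substrate_total") %>%
    dplyr::arrange(.data$country, .data$substrateCategory, .data$species)
  class(frame) <- c("count_frame", class(frame))
  attr(frame, "offset_constant") <- offset_constant
  frame
}
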