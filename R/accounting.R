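#' Bundled study-level catalog of published stalk-lodging QTL reports
#'
#' The study-level compilation of 44 published maize stalk-lodging QTL
#' mapping experiments (some contributing several crosses, 55 rows in all):
#' cross, number of reported QTLs, population type and size, and traits.
#' Summing `n_qtls` gives the catalog size the accounting ratios are
#' computed over.
#'
#' @return Tibble with `study_no`, `cross`, `n_qtls`, `population_type`,
#'   `population_size`, `traits`.
#' @export
load_study_catalog <- function() {
  path <- system.file("extdata", "study_catalog.tsv", package = "maizeMQTL",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    study_no = readr::col_integer(), cross = readr::col_character(),
    n_qtls = readr::col_integer(), population_type = readr::col_character(),
    population_size = readr::col_integer(),
    traits = readr::col_character()), progress = FALSE)
}

#' Bundled headline accounting counts
#'
#' Numerator/denominator counts behind the headline percentages of the
#' published compilation (projection and exclusion rates, LOD-bin and
#' minor-effect shares, GWAS-validation rate, gene-confidence-tier shares),
#' together with the number of decimals each percentage is reported to.
#'
#' @return Tibble `quantity`, `numerator`, `denominator`, `digits`.
#' @export
load_printed_accounting <- function() {
  path <- system.file("extdata", "printed_accounting.tsv",
                      package = "maizeMQTL", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    quantity = readr::col_character(), numerator = readr::col_integer(),
    denominator = readr::col_integer(), digits = readr::col_integer()),
    progress = FALSE)
}

#' Recompute the headline accounting percentages
#'
#' Applies the reporting rounding rule (half-up at the stated number of
#' decimals) to each numerator/denominator pair from
#' [load_printed_accounting()].
#'
#' @param accounting Optional accounting tibble; defaults to the bundled one.
#' @return The tibble with a `pct` column added.
#' @export
recompute_accounting <- function(accounting = load_printed_accounting()) {
  accounting$pct <- pct_of(accounting$numerator, accounting$denominator,
                           accounting$digits)
  accounting
}
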