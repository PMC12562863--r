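#' @importFrom rlang .data
#' @importFrom stats dnorm rnorm runif rpois rlnorm setNames approx
#' @importFrom utils head tail
NULL

# Trait codes handled by the pipeline and their functional categories:
# stalk morphology (SM), stalk strength (SS), stalk chemical composition (SC),
# stalk anatomical structure (SA).
.TRAIT_CATEGORY <- c(
  PH = "SM", EH = "SM", IL = "SM", SD = "SM",
  RPR = "SS", SBS = "SS",
  DF = "SC", Cel = "SC", Hem = "SC", Lig = "SC", SSC = "SC",
  Vb = "SA"
)

#' Trait-to-category lookup for stalk-lodging traits
#'
#' Maps the twelve stalk-lodging trait codes to their functional categories:
#' stalk morphology (SM: PH, EH, IL, SD), stalk strength (SS: RPR, SBS),
#' stalk chemical composition (SC: DF, Cel, Hem, Lig, SSC) and stalk
#' anatomical structure (SA: Vb).
#'
#' @param trait Character vector of trait codes.
#' @return Character vector of category codes; errors on unknown traits.
#' @export
trait_category <- function(trait) {
  unknown <- setdiff(unique(trait), names(.TRAIT_CATEGORY))
  if (length(unknown) > 0) {
    stop("unknown trait code(s): ", paste(unknown, collapse = ", "))
  }
  unname(.TRAIT_CATEGORY[trait])
}

# Population types routed to the F2-derived CI formula vs the inbred-line
# formula. DH lines are fully homozygous like RILs; F2:3 and IF2 retain the
# F2 recombination structure. Exposed so users can override the routing.
.DEFAULT_ROUTING <- list(
  f2  = c("F2", "BC", "F2:3", "IF2"),
  ril = c("RIL", "DH")
)

#' Formula class of a mapping population type
#'
#' @param population_type Character vector of population types.
#' @param routing List with elements `f2` and `ril` naming the population
#'   types routed to each confidence-interval formula.
#' @return Character vector, `"f2"` or `"ril"`.
#' @export
population_formula_class <- function(population_type, routing = .DEFAULT_ROUTING) {
  out <- rep(NA_character_, length(population_type))
  out[population_type %in% routing$f2] <- "f2"
  out[population_type %in% routing$ril] <- "ril"
  if (anyNA(out)) {
    bad <- unique(population_type[is.na(out)])
    stop("population type(s) with no formula routing: ",
         paste(bad, collapse = ", "))
  }
  out
}

#' Expected 95% confidence-interval width of a QTL
#'
#' Estimates the width (in cM) of a QTL's 95% confidence interval from the
#' mapping population size N and the proportion of phenotypic variance
#' explained R-squared, using the empirical formulas
#' `530 / (N * R2)` for F2/backcross-derived populations and
#' `163 / (N * R2)` for recombinant-inbred-line-like populations.
#'
#' @param population_type Character vector (F2, BC, F2:3, IF2, RIL, DH).
#' @param population_size Integer vector, N >= 2.
#' @param r2 Numeric vector in (0, 1].
#' @param routing Population-type routing, see [population_formula_class()].
#' @return Confidence-interval width in cM (strictly positive, decreasing in
#'   both N and R2).
#' @export
#' @examples
#' estimate_ci_width("RIL", 163, 1.0)   # 1 cM
#' estimate_ci_width("F2", 282, 0.10)
estimate_ci_width <- function(population_type, population_size, r2,
                              routing = .DEFAULT_ROUTING) {
  if (any(r2 <= 0, na.rm = TRUE)) stop("r2 must be > 0")
  if (any(r2 > 1, na.rm = TRUE)) stop("r2 must be <= 1")
  if (any(population_size < 2, na.rm = TRUE)) stop("population_size must be >= 2")
  cls <- population_formula_class(population_type, routing)
  numerator <- ifelse(cls == "f2", 530, 163)
  numerator / (population_size * r2)
}

#' Phenotypic variance explained from a LOD score
#'
#' Converts a QTL peak LOD score to the proportion of phenotypic variance it
#' explains via `R2 = 1 - 10^(-2 * LOD / N)`, with N the population size.
#'
#' @param lod Numeric vector of LOD scores, >= 0.
#' @param population_size Integer vector, N >= 2.
#' @return R-squared in `[0, 1)`.
#' @export
#' @examples
#' estimate_r2_from_lod(3, 200)
estimate_r2_from_lod <- function(lod, population_size) {
  if (any(lod < 0, na.rm = TRUE)) stop("lod must be >= 0")
  if (any(population_size < 2, na.rm = TRUE)) stop("population_size must be >= 2")
  1 - 10^(-2 * lod / population_size)
}

#' LOD score implied by a phenotypic variance explained
#'
#' Inverse of [estimate_r2_from_lod()]: `LOD = -(N / 2) * log10(1 - R2)`.
#' Used by the synthetic generator to keep LOD and R2 mutually consistent.
#'
#' @param r2 Numeric vector in `[0, 1)`.
#' @param population_size Integer vector, N >= 2.
#' @return LOD scores, >= 0.
#' @export
lod_from_r2 <- function(r2, population_size) {
  if (any(r2 < 0 | r2 >= 1, na.rm = TRUE)) stop("r2 must be in [0, 1)")
  -(population_size / 2) * log10(1 - r2)
}

#' Assemble a QTL catalog tibble
#'
#' Light constructor that normalizes column types and fills derived columns
#' (trait category). Missing values are `NA`, never sentinel numbers.
#'
#' @param df Data frame with at least `study_id`, `trait`, `chromosome`;
#'   optionally `qtl_id`, `peak_cm`, `ci_lower_cm`, `ci_upper_cm`, `lod`,
#'   `r2`, `population_type`, `population_size`, `flank_lower`, `flank_upper`.
#' @return A tibble with the full QTLRecord column set.
#' @export
as_qtl_catalog <- function(df) {
  mandatory <- c("study_id", "trait", "chromosome")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("QTL table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  fill_col <- function(name, proto) {
    if (name %in% names(df)) df[[name]] else rep(proto, n)
  }
  out <- tibble::tibble(
    qtl_id = as.character(fill_col("qtl_id", NA_character_)),
    study_id = as.character(df$study_id),
    trait = as.character(df$trait),
    chromosome = as.character(df$chromosome),
    peak_cm = as.numeric(fill_col("peak_cm", NA_real_)),
    ci_lower_cm = as.numeric(fill_col("ci_lower_cm", NA_real_)),
    ci_upper_cm = as.numeric(fill_col("ci_upper_cm", NA_real_)),
    lod = as.numeric(fill_col("lod", NA_real_)),
    r2 = as.numeric(fill_col("r2", NA_real_)),
    population_type = as.character(fill_col("population_type", NA_character_)),
    population_size = as.integer(fill_col("population_size", NA_integer_)),
    flank_lower = as.character(fill_col("flank_lower", NA_character_)),
    flank_upper = as.character(fill_col("flank_upper", NA_character_))
  )
  out$trait_category <- trait_category(out$trait)
  if (all(is.na(out$qtl_id))) {
    out$qtl_id <- sprintf("Q%04d", seq_len(n))
  }
  extras <- setdiff(names(df), names(out))
  for (e in extras) out[[e]] <- df[[e]]
  out
}

#' Validate QTL-record invariants
#'
#' Checks interval ordering, peak containment, value ranges and the
#' trait-category mapping; errors with offending `qtl_id`s on violation.
#'
#' @param records QTL catalog tibble.
#' @return Invisibly, `records`.
#' @export
validate_qtl_records <- function(records) {
  bad <- function(cond) records$qtl_id[which(cond)]
  problems <- list(
    "ci_lower_cm > ci_upper_cm" =
      bad(records$ci_lower_cm > records$ci_upper_cm),
    "peak outside CI" =
      bad(records$peak_cm < records$ci_lower_cm |
            records$peak_cm > records$ci_upper_cm),
    "r2 outside (0, 1)" = bad(records$r2 <= 0 | records$r2 >= 1),
    "negative lod" = bad(records$lod < 0),
    "population_size < 2" = bad(records$population_size < 2)
  )
  problems <- problems[vapply(problems, length, integer(1)) > 0]
  if (length(problems) > 0) {
    msg <- paste(names(problems),
                 vapply(problems, paste, character(1), collapse = ","),
                 sep = ": ", collapse = "; ")
    stop("invalid QTL record(s): ", msg)
  }
  stopifnot(identical(records$trait_category, trait_category(records$trait)))
  invisible(records)
}

#' Impute missing positional and effect fields of a QTL catalog
#'
#' Applies the curation rules in order, never overwriting present values:
#' a missing peak becomes the midpoint of the flanking markers' positions on
#' the record's study map; a missing R-squared is estimated from LOD via
#' [estimate_r2_from_lod()]; a missing confidence interval becomes
#' `peak +/- width / 2` with the width from [estimate_ci_width()].
#' Records that still lack the information needed downstream are retained
#' and flagged `usable = FALSE` with a `reason`, never dropped silently.
#'
#' @param records QTL catalog tibble (see [as_qtl_catalog()]).
#' @param study_maps Optional genetic-map table (see [read_map_table()]) whose
#'   `map_name` matches `study_id`; needed only to resolve flanking markers.
#' @param routing Population-type routing for the CI formulas.
#' @return The catalog with imputed fields plus `usable` and `reason` columns.
#' @export
impute_qtl_catalog <- function(records, study_maps = NULL,
                               routing = .DEFAULT_ROUTING) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  usable <- rep(TRUE, n)
  reason <- rep(NA_character_, n)

  marker_pos <- function(study, chrom, marker) {
    if (is.null(study_maps) || is.na(marker)) return(NA_real_)
    hit <- study_maps[study_maps$map_name == study &
                        study_maps$chromosome == chrom &
                        study_maps$marker == marker, ]
    if (nrow(hit) == 0) NA_real_ else hit$position_cm[[1]]
  }

  for (i in seq_len(n)) {
    rec <- records[i, ]
    # peak: midpoint between flanking markers when absent
    if (is.na(rec$peak_cm)) {
      lo <- marker_pos(rec$study_id, rec$chromosome, rec$flank_lower)
      hi <- marker_pos(rec$study_id, rec$chromosome, rec$flank_upper)
      if (!is.na(lo) && !is.na(hi)) {
        records$peak_cm[i] <- (lo + hi) / 2
      } else {
        usable[i] <- FALSE
        reason[i] <- "no peak and flanking markers unresolvable"
        next
      }
    }
    # r2 from LOD when absent
    if (is.na(records$r2[i])) {
      if (!is.na(rec$lod) && !is.na(rec$population_size)) {
        records$r2[i] <- estimate_r2_from_lod(rec$lod, rec$population_size)
      } else if (is.na(rec$ci_lower_cm) || is.na(rec$ci_upper_cm)) {
        usable[i] <- FALSE
        reason[i] <- "no r2, no lod, and no reported CI"
        next
      }
    }
    # CI from the population-size formula when absent
    if (is.na(records$ci_lower_cm[i]) || is.na(records$ci_upper_cm[i])) {
      r2i <- records$r2[i]
      if (is.na(r2i) || r2i <= 0 || is.na(rec$population_type) ||
          is.na(rec$population_size)) {
        usable[i] <- FALSE
        reason[i] <- "cannot estimate CI width"
        next
      }
      width <- estimate_ci_width(rec$population_type, rec$population_size,
                                 r2i, routing)
      records$ci_lower_cm[i] <- records$peak_cm[i] - width / 2
      records$ci_upper_cm[i] <- records$peak_cm[i] + width / 2
    }
  }

  records$usable <- usable
  records$reason <- reason
  n_bad <- sum(!usable)
  if (n_bad > 0) {
    message(n_bad, " of ", n, " records flagged unusable during imputation")
  }
  records
}

# Bin edges used by the descriptive catalog summary (LOD and R2 percent).
.LOD_BREAKS <- c(-Inf, 3, 6, 9, 12, Inf)
.LOD_LABELS <- c("<3", "3-6", "6-9", "9-12", ">=12")
.R2_BREAKS <- c(-Inf, 5, 10, 15, 20, Inf)
.R2_LABELS <- c("<5", "5-10", "10-15", "15-20", ">=20")

#' Descriptive distribution summary of a QTL catalog
#'
#' Counts and percentage shares of LOD bins (`<3, 3-6, 6-9, 9-12, >=12`),
#' R-squared-percent bins (`<5, 5-10, 10-15, 15-20, >=20`), trait-category
#' shares and per-trait counts. Percentages are over the full catalog,
#' rounded half-up (1 d.p. for the bins, 2 d.p. for categories).
#'
#' @param records Imputed QTL catalog.
#' @return List of tibbles: `lod_bins`, `r2_bins`, `categories`, `traits`.
#' @export
summarize_catalog <- function(records) {
  empty <- function(labels) {
    tibble::tibble(bin = labels, n = 0L, pct = NA_real_)
  }
  if (nrow(records) == 0) {
    return(list(lod_bins = empty(.LOD_LABELS), r2_bins = empty(.R2_LABELS),
                categories = tibble::tibble(category = character(), n = integer(),
                                            pct = numeric()),
                traits = tibble::tibble(trait = character(), n = integer())))
  }
  total <- nrow(records)
  bin_table <- function(x, breaks, labels, digits = 1) {
    b <- cut(x, breaks = breaks, labels = labels, right = FALSE)
    counts <- as.integer(table(b))
    tibble::tibble(bin = labels, n = counts,
                   pct = pct_of(counts, total, digits))
  }
  lod_bins <- bin_table(records$lod, .LOD_BREAKS, .LOD_LABELS)
  r2_bins <- bin_table(100 * records$r2, .R2_BREAKS, .R2_LABELS)
  cat_tab <- table(factor(records$trait_category, levels = c("SM", "SS", "SC", "SA")))
  categories <- tibble::tibble(
    category = names(cat_tab),
    n = as.integer(cat_tab),
    pct = pct_of(as.integer(cat_tab), total, 2)
  )
  trait_tab <- sort(table(records$trait), decreasing = TRUE)
  traits <- tibble::tibble(trait = names(trait_tab), n = as.integer(trait_tab))
  list(lod_bins = lod_bins, r2_bins = r2_bins, categories = categories,
       traits = traits)
}

#' Read / write a QTL catalog table
#'
#' Tab-separated UTF-8 with a header; one row per QTL; empty fields are
#' missing values. Unknown columns are preserved. The pair round-trips:
#' `read_qtl_table(write_qtl_table(x, p))` reproduces `x`'s field values in
#' the original row order.
#'
#' @param path File path.
#' @return [read_qtl_table()]: a QTL catalog tibble.
#' @export
read_qtl_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  mandatory <- c("study_id", "trait", "chromosome")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("QTL table ", path, " (header line 1) is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- intersect(c("peak_cm", "ci_lower_cm", "ci_upper_cm", "lod", "r2"),
                        names(df))
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  if ("population_size" %in% names(df)) {
    df$population_size <- as.integer(df$population_size)
  }
  as_qtl_catalog(df)
}

#' @rdname read_qtl_table
#' @param records QTL catalog tibble.
#' @export
write_qtl_table <- function(records, path) {
  readr::write_tsv(records, path, na = "", progress = FALSE)
  invisible(path)
}
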