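#' Convert genetic positions to physical coordinates on the reference map
#'
#' Piecewise-linear interpolation between the reference-map markers that
#' carry physical (bp) positions on the chromosome. Query positions are
#' clamped into the anchored cM span first: consensus 95% CIs legitimately
#' overhang the mapped ends of a chromosome, and the clamp reads them as
#' truncated at the chromosome boundary rather than discarding the locus.
#'
#' @param chromosome Chromosome id.
#' @param cm Numeric vector of genetic positions (cM).
#' @param ref_map Reference map tibble with `position_bp` on some markers.
#' @return Numeric vector of bp positions (`NA` when the chromosome has
#'   fewer than two bp-anchored markers).
#' @export
genetic_to_physical <- function(chromosome, cm, ref_map) {
  anchors <- ref_map[ref_map$chromosome == chromosome &
                       !is.na(ref_map$position_bp), ]
  anchors <- anchors[order(anchors$position_cm), ]
  if (nrow(anchors) < 2) return(rep(NA_real_, length(cm)))
  cm <- pmin(pmax(cm, anchors$position_cm[1]),
             anchors$position_cm[nrow(anchors)])
  stats::approx(anchors$position_cm, anchors$position_bp, xout = cm,
                ties = "ordered")$y
}

#' Attach physical intervals to MQTLs
#'
#' Interpolates each MQTL's 95% CI bounds and consensus peak from cM to bp
#' (see [genetic_to_physical()]). MQTLs on chromosomes without two
#' bp-anchored markers are flagged `no_physical`.
#'
#' @param mqtls MQTL tibble from [run_meta_analysis()].
#' @param ref_map Reference map tibble.
#' @return `mqtls` with `start_bp`, `end_bp`, `peak_bp`, `no_physical`.
#' @export
mqtl_physical_intervals <- function(mqtls, ref_map) {
  n <- nrow(mqtls)
  start_bp <- end_bp <- peak_bp <- rep(NA_real_, n)
  for (chrom in unique(mqtls$chromosome)) {
    idx <- which(mqtls$chromosome == chrom)
    start_bp[idx] <- genetic_to_physical(chrom, mqtls$ci95_lower_cm[idx], ref_map)
    end_bp[idx] <- genetic_to_physical(chrom, mqtls$ci95_upper_cm[idx], ref_map)
    peak_bp[idx] <- genetic_to_physical(chrom, mqtls$consensus_cm[idx], ref_map)
  }
  mqtls$start_bp <- round(start_bp)
  mqtls$end_bp <- round(end_bp)
  mqtls$peak_bp <- round(peak_bp)
  mqtls$no_physical <- is.na(start_bp) | is.na(end_bp)
  mqtls
}

#' Read a GWAS marker-trait-association table
#'
#' TSV with columns `mta_id`, `study_id`, `trait`, `chromosome`,
#' `position_bp` (1-based).
#'
#' @param path File path.
#' @return MTA tibble.
#' @export
read_mta_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    mta_id = readr::col_character(), study_id = readr::col_character(),
    trait = readr::col_character(), chromosome = readr::col_character(),
    position_bp = readr::col_double()), progress = FALSE)
  if (any(df$position_bp < 1)) stop("MTA position_bp must be >= 1")
  df
}

#' Co-localize GWAS MTAs with MQTL physical intervals
#'
#' An MTA validates an MQTL when it lies within `window_bp` of the MQTL's
#' physical interval on the same chromosome:
#' `start_bp - window <= position <= end_bp + window`, bounds inclusive.
#' Trait identity is not required by default (positional overlap only);
#' `match_trait = TRUE` additionally requires the MTA trait to be among the
#' MQTL's member traits.
#'
#' @param mqtls MQTLs with physical intervals
#'   (see [mqtl_physical_intervals()]).
#' @param mtas MTA tibble.
#' @param window_bp Flanking window, default 500 kb each side.
#' @param match_trait Require trait agreement (default `FALSE`).
#' @return List: `mqtls` with `n_mtas`, `mta_ids`, `is_mta_validated`;
#'   `pairs` (one row per MQTL-MTA hit).
#' @export
colocalize_mtas <- function(mqtls, mtas, window_bp = 500000,
                            match_trait = FALSE) {
  n <- nrow(mqtls)
  n_mtas <- integer(n)
  mta_ids <- character(n)
  pairs <- list()
  for (i in seq_len(n)) {
    if (isTRUE(mqtls$no_physical[i])) next
    hits <- mtas[mtas$chromosome == mqtls$chromosome[i] &
                   mtas$position_bp >= mqtls$start_bp[i] - window_bp &
                   mtas$position_bp <= mqtls$end_bp[i] + window_bp, ]
    if (match_trait && nrow(hits) > 0) {
      member_traits <- strsplit(mqtls$traits[i], ",")[[1]]
      hits <- hits[hits$trait %in% member_traits, ]
    }
    n_mtas[i] <- nrow(hits)
    mta_ids[i] <- paste(hits$mta_id, collapse = ",")
    if (nrow(hits) > 0) {
      pairs[[length(pairs) + 1]] <-
        tibble::tibble(mqtl_id = mqtls$mqtl_id[i], mta_id = hits$mta_id)
    }
  }
  mqtls$n_mtas <- n_mtas
  mqtls$mta_ids <- mta_ids
  mqtls$is_mta_validated <- n_mtas > 0
  list(mqtls = mqtls, pairs = dplyr::bind_rows(pairs))
}

#' Breeder's-MQTL filter
#'
#' Flags MQTLs compact and well-supported enough for direct use in
#' marker-assisted selection: at least `min_qtls` initial QTLs, physical
#' span strictly under `max_bp` and 95% CI width strictly under `max_cm`.
#' MQTLs without a physical interval fail with reason `no_physical`.
#'
#' @param mqtls MQTLs with physical intervals.
#' @param max_bp Physical-span bound, default 1 Mb (strict).
#' @param max_cm Genetic-width bound, default 4 cM (strict).
#' @param min_qtls Minimum member count, default 2.
#' @return `mqtls` with `is_breeder` and `breeder_reason` columns.
#' @export
breeder_filter <- function(mqtls, max_bp = 1e6, max_cm = 4, min_qtls = 2) {
  span_bp <- mqtls$end_bp - mqtls$start_bp + 1
  width_cm <- mqtls$ci95_upper_cm - mqtls$ci95_lower_cm
  no_phys <- (if ("no_physical" %in% names(mqtls)) mqtls$no_physical else FALSE) |
    is.na(span_bp)
  ok <- !no_phys & mqtls$n_initial_qtls >= min_qtls &
    span_bp < max_bp & width_cm < max_cm
  reason <- dplyr::case_when(
    no_phys ~ "no_physical",
    mqtls$n_initial_qtls < min_qtls ~ "too_few_qtls",
    !(span_bp < max_bp) ~ "physical_span",
    !(width_cm < max_cm) ~ "genetic_width",
    TRUE ~ NA_character_
  )
  mqtls$is_breeder <- ok
  mqtls$breeder_reason <- reason
  mqtls
}

#' Gene-search windows of MTA-supported MQTLs
#'
#' An MQTL co-localizing with strictly more than `threshold` MTAs gets a
#' gene-search window: the whole physical interval when it spans under
#' 1 Mb, otherwise a 1 Mb region centred on the consensus peak (500 kb
#' flanking each side).
#'
#' @param mqtls MQTLs with physical intervals and `n_mtas`
#'   (see [colocalize_mtas()]).
#' @param threshold MTA-count threshold (strict `>`), default 3.
#' @param flank_bp Half-width of the peak-centred window, default 500 kb.
#' @return `mqtls` with `has_mta_window`, `window_start_bp`,
#'   `window_end_bp`.
#' @export
mta_mqtl_windows <- function(mqtls, threshold = 3, flank_bp = 500000) {
  n <- nrow(mqtls)
  ws <- we <- rep(NA_real_, n)
  has <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (isTRUE(mqtls$no_physical[i])) next
    if (mqtls$n_mtas[i] > threshold) {
      has[i] <- TRUE
      if (mqtls$end_bp[i] - mqtls$start_bp[i] + 1 < 1e6) {
        ws[i] <- mqtls$start_bp[i]
        we[i] <- mqtls$end_bp[i]
      } else {
        ws[i] <- max(1, mqtls$peak_bp[i] - flank_bp)
        we[i] <- mqtls$peak_bp[i] + flank_bp
      }
    }
  }
  mqtls$has_mta_window <- has
  mqtls$window_start_bp <- ws
  mqtls$window_end_bp <- we
  mqtls
}

#' Core-MQTL set
#'
#' The non-redundant union of the breeder's MQTLs and the MTA-supported
#' MQTLs (each MQTL counted once).
#'
#' @param mqtls MQTLs with `is_breeder` and `has_mta_window` computed.
#' @return `mqtls` with `is_core`.
#' @export
core_mqtl_set <- function(mqtls) {
  mqtls$is_core <- mqtls$is_breeder | mqtls$has_mta_window
  mqtls
}

#' GWAS-validation rate of an MQTL set
#'
#' @param mqtls MQTLs with `is_mta_validated`.
#' @return Tibble with `n_validated`, `n_mqtls` and `validated_pct`
#'   (1 d.p., half-up).
#' @export
validation_rate <- function(mqtls) {
  nv <- sum(mqtls$is_mta_validated)
  tibble::tibble(n_validated = nv, n_mqtls = nrow(mqtls),
                 validated_pct = pct_of(nv, nrow(mqtls), 1))
}

#' Export MQTL intervals (or gene windows) as BED
#'
#' Converts the internal 1-based closed bp intervals to BED's 0-based
#' half-open convention (`start - 1`, `end`).
#'
#' @param mqtls MQTLs with physical intervals.
#' @param what `"interval"` (default) or `"window"`.
#' @return Tibble with `chrom`, `start`, `end`, `name` in BED semantics.
#' @export
mqtl_to_bed <- function(mqtls, what = c("interval", "window")) {
  what <- match.arg(what)
  if (what == "interval") {
    keep <- !mqtls$no_physical
    tibble::tibble(chrom = mqtls$chromosome[keep],
                   start = mqtls$start_bp[keep] - 1,
                   end = mqtls$end_bp[keep],
                   name = mqtls$mqtl_id[keep])
  } else {
    keep <- mqtls$has_mta_window
    tibble::tibble(chrom = mqtls$chromosome[keep],
                   start = mqtls$window_start_bp[keep] - 1,
                   end = mqtls$window_end_bp[keep],
                   name = mqtls$mqtl_id[keep])
  }
}
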