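#' Read a genetic-map table
#'
#' TSV with columns `map_name`, `chromosome`, `marker`, `position_cm` and
#' optional `position_bp`. Reference and study maps share the format; a file
#' may carry several maps distinguished by `map_name`.
#'
#' @param path File path.
#' @return Tibble sorted by map, chromosome and cM position.
#' @export
read_map_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    map_name = readr::col_character(),
    chromosome = readr::col_character(),
    marker = readr::col_character(),
    position_cm = readr::col_double(),
    .default = readr::col_double()
  ), progress = FALSE)
  needed <- c("map_name", "chromosome", "marker", "position_cm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("map table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"position_bp" %in% names(df)) df$position_bp <- NA_real_
  dplyr::arrange(df, .data$map_name, .data$chromosome, .data$position_cm)
}

#' @rdname read_map_table
#' @param map Genetic-map tibble.
#' @export
write_map_table <- function(map, path) {
  readr::write_tsv(map, path, na = "", progress = FALSE)
  invisible(path)
}

#' Common markers of a study map and the reference map
#'
#' Markers shared by exact name on one chromosome, ordered by study-map
#' position. A marker is flagged `consistent = FALSE` when its order on the
#' reference map contradicts its study-map order against any other shared
#' marker; inconsistent markers are dropped from anchoring by the projection
#' functions (local marker-order disagreements between maps are real and are
#' treated conservatively).
#'
#' @param study_map,ref_map Genetic-map tibbles (single map each).
#' @param chromosome Chromosome id.
#' @return Tibble with `marker`, `study_cm`, `ref_cm`, `consistent`.
#' @export
find_common_markers <- function(study_map, ref_map, chromosome) {
  s <- study_map[study_map$chromosome == chromosome, c("marker", "position_cm")]
  r <- ref_map[ref_map$chromosome == chromosome, c("marker", "position_cm")]
  names(s)[2] <- "study_cm"
  names(r)[2] <- "ref_cm"
  common <- dplyr::inner_join(s, r, by = "marker")
  common <- dplyr::arrange(common, .data$study_cm)
  m <- nrow(common)
  consistent <- rep(TRUE, m)
  if (m >= 2) {
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i == j) next
        ds <- common$study_cm[i] - common$study_cm[j]
        dr <- common$ref_cm[i] - common$ref_cm[j]
        if (ds * dr < 0) consistent[i] <- FALSE
      }
    }
  }
  common$consistent <- consistent
  common
}

#' Project a cM position between maps by common-marker interval scaling
#'
#' Homothetic projection: within each interval bounded by consecutive
#' consistent common markers, positions map linearly so that the shared
#' markers coincide on both maps. Positions outside the span of the common
#' markers are not extrapolated.
#'
#' @param p_cm Numeric vector of study-map positions.
#' @param anchors Tibble from [find_common_markers()] (inconsistent rows are
#'   ignored), or any tibble with `study_cm`, `ref_cm`.
#' @return Tibble with `value` (reference cM, `NA` when not projectable) and
#'   `status` (`"projected"`, `"out_of_range"` or `"no_anchor"`).
#' @export
project_position <- function(p_cm, anchors) {
  if ("consistent" %in% names(anchors)) {
    anchors <- anchors[anchors$consistent, ]
  }
  anchors <- anchors[order(anchors$study_cm), ]
  n <- length(p_cm)
  out <- tibble::tibble(value = rep(NA_real_, n),
                        status = rep("no_anchor", n))
  if (nrow(anchors) < 2) return(out)
  o <- anchors$study_cm
  r <- anchors$ref_cm
  lo <- o[1]; hi <- o[length(o)]
  for (i in seq_len(n)) {
    p <- p_cm[i]
    if (is.na(p)) next
    if (p < lo || p > hi) {
      out$status[i] <- "out_of_range"
      next
    }
    at <- which(o == p)
    if (length(at) > 0) {
      # p sits on a common marker; coincident study positions with
      # diverging reference positions collapse to their midpoint
      rs <- range(r[at])
      out$value[i] <- if (rs[1] == rs[2]) rs[1] else mean(rs)
      out$status[i] <- "projected"
      next
    }
    k <- findInterval(p, o, rightmost.closed = TRUE)
    o1 <- o[k]; o2 <- o[k + 1]
    r1 <- r[k]; r2 <- r[k + 1]
    if (o2 > o1) {
      out$value[i] <- r1 + (p - o1) * (r2 - r1) / (o2 - o1)
    } else {
      # zero-length study interval: collapse to the shared point
      out$value[i] <- if (r1 == r2) r1 else (r1 + r2) / 2
    }
    out$status[i] <- "projected"
  }
  out
}

#' Project an imputed QTL catalog onto the reference map
#'
#' Each record's peak and both confidence-interval bounds are projected
#' independently (piecewise-linearly, each with its own flanking common
#' markers). A record whose peak cannot be projected is excluded with status
#' `excluded_out_of_range` or `excluded_no_anchor`. A CI bound that
#' individually falls outside the common-marker span is clamped to the
#' reference chromosome ends; bounds are re-ordered if projection inverts
#' them. The positional standard deviation fed to the mixture model is
#' `(CI width) / 3.92`, reading the interval as a 95% CI under normality.
#'
#' @param records Imputed, usable QTL catalog (see [impute_qtl_catalog()]).
#' @param study_maps Map table holding every study map (`map_name` matches
#'   `study_id`).
#' @param ref_map Reference map tibble (single map).
#' @param sd_floor Lower clamp for the derived positional sd, in cM.
#' @return The catalog with `status`, `ref_peak_cm`, `ref_ci_lower_cm`,
#'   `ref_ci_upper_cm`, `position_sd_cm`, `n_anchors` columns.
#' @export
project_qtl_catalog <- function(records, study_maps, ref_map, sd_floor = 0.01) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  status <- rep(NA_character_, n)
  ref_peak <- ref_lo <- ref_hi <- sd_cm <- rep(NA_real_, n)
  n_anchors <- rep(0L, n)

  ref_span <- dplyr::summarise(
    dplyr::group_by(ref_map, .data$chromosome),
    lo = min(.data$position_cm), hi = max(.data$position_cm), .groups = "drop")

  anchor_cache <- list()
  get_anchors <- function(study, chrom) {
    key <- paste(study, chrom, sep = "\r")
    if (is.null(anchor_cache[[key]])) {
      sm <- study_maps[study_maps$map_name == study, ]
      anchor_cache[[key]] <<- find_common_markers(sm, ref_map, chrom)
    }
    anchor_cache[[key]]
  }

  for (i in seq_len(n)) {
    rec <- records[i, ]
    span <- ref_span[ref_span$chromosome == rec$chromosome, ]
    if (nrow(span) == 0) {
      status[i] <- "excluded_no_anchor"
      next
    }
    anchors <- get_anchors(rec$study_id, rec$chromosome)
    anchors_ok <- anchors[anchors$consistent, ]
    n_anchors[i] <- nrow(anchors_ok)
    pr <- project_position(c(rec$peak_cm, rec$ci_lower_cm, rec$ci_upper_cm),
                           anchors_ok)
    if (pr$status[1] != "projected") {
      status[i] <- if (pr$status[1] == "out_of_range")
        "excluded_out_of_range" else "excluded_no_anchor"
      next
    }
    peak <- pr$value[1]
    lo <- if (pr$status[2] == "projected") pr$value[2] else span$lo
    hi <- if (pr$status[3] == "projected") pr$value[3] else span$hi
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
    lo <- min(lo, peak)
    hi <- max(hi, peak)
    status[i] <- "projected"
    ref_peak[i] <- peak
    ref_lo[i] <- lo
    ref_hi[i] <- hi
    sd_cm[i] <- max((hi - lo) / 3.92, sd_floor)
  }

  records$status <- status
  records$ref_peak_cm <- ref_peak
  records$ref_ci_lower_cm <- ref_lo
  records$ref_ci_upper_cm <- ref_hi
  records$position_sd_cm <- sd_cm
  records$n_anchors <- n_anchors
  records
}

#' Place a SNP marker on the reference map via physical position
#'
#' Interpolates the marker's genome (bp) coordinate linearly between the
#' nearest reference-map markers that carry physical positions on the same
#' chromosome.
#'
#' @param chromosome Chromosome id.
#' @param position_bp Physical position (1-based bp).
#' @param ref_map Reference map tibble with `position_bp` on some markers.
#' @return List with `value` (cM or `NA`) and `status`.
#' @export
project_snp_marker <- function(chromosome, position_bp, ref_map) {
  anchors <- ref_map[ref_map$chromosome == chromosome &
                       !is.na(ref_map$position_bp), ]
  anchors <- anchors[order(anchors$position_bp), ]
  if (nrow(anchors) < 2) return(list(value = NA_real_, status = "no_anchor"))
  if (position_bp < anchors$position_bp[1] ||
      position_bp > anchors$position_bp[nrow(anchors)]) {
    return(list(value = NA_real_, status = "out_of_range"))
  }
  cm <- stats::approx(anchors$position_bp, anchors$position_cm,
                      xout = position_bp, ties = "ordered")$y
  list(value = cm, status = "projected")
}

#' Projection accounting of a projected catalog
#'
#' @param projected Output of [project_qtl_catalog()].
#' @return Tibble with counts per status and the projected percentage
#'   (1 d.p., half-up).
#' @export
projection_report <- function(projected) {
  total <- nrow(projected)
  n_proj <- sum(projected$status == "projected")
  tibble::tibble(
    n_usable = total,
    n_projected = n_proj,
    n_excluded_out_of_range = sum(projected$status == "excluded_out_of_range"),
    n_excluded_no_anchor = sum(projected$status == "excluded_no_anchor"),
    projected_pct = pct_of(n_proj, total, 1)
  )
}
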