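#' Run the full meta-QTL pipeline
#'
#' Executes curation -> projection -> per-chromosome meta-analysis ->
#' physical reconciliation and GWAS validation -> candidate-gene scoring on
#' a set of in-memory input tables (such as a [simulate_dataset()] result,
#' or tables read with the `read_*` functions). Deterministic given `seed`.
#'
#' The candidate-gene set is the union of (i) genes inside breeder's-MQTL
#' physical intervals, (ii) genes inside MTA-supported gene-search windows,
#' and (iii) genes with a filter-passing rice ortholog inside any MQTL
#' physical interval. Each candidate is scored on the four evidence flags.
#'
#' @param data List with `catalog`, `study_maps`, `ref_map`, `mtas`,
#'   `annotation`, `ortholog_hits`, `fpkm` (the last four optional; the
#'   corresponding stages are skipped when absent).
#' @param criterion Model-selection criterion, default `"AIC"`.
#' @param K_max Maximum mixture components per chromosome (default
#'   `min(n, 10)`).
#' @param window_bp MTA co-localization flanking window (bp).
#' @param mta_threshold Strict MTA-count threshold for gene-search windows.
#' @param breeder_max_bp,breeder_max_cm,breeder_min_qtls Breeder's-MQTL
#'   thresholds.
#' @param expression_threshold FPKM threshold for the expressed flag.
#' @param expression_tissues Optional tissue subset for the expressed flag.
#' @param seed Integer root seed.
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there as TSV plus a run log of every exclusion.
#' @return List: `catalog` (imputed), `projected`, `projection_report`,
#'   `meta` (mqtls/assignments/diagnostics), `mqtls` (with validation and
#'   core flags), `mta_pairs`, `candidates`, `tier_report`, `summary`.
#' @export
run_pipeline <- function(data,
                         criterion = "AIC", K_max = NULL,
                         window_bp = 500000, mta_threshold = 3,
                         breeder_max_bp = 1e6, breeder_max_cm = 4,
                         breeder_min_qtls = 2,
                         expression_threshold = 2,
                         expression_tissues = NULL,
                         seed = 1L, out_dir = NULL) {
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  # stage 1: curation
  catalog <- suppressMessages(
    impute_qtl_catalog(data$catalog, study_maps = data$study_maps))
  usable <- catalog[catalog$usable, ]
  validate_qtl_records(usable)
  note("curate: ", nrow(catalog), " records, ", sum(!catalog$usable),
       " unusable (",
       paste(stats::na.omit(unique(catalog$reason)), collapse = "; "), ")")

  # stage 2: projection
  projected <- project_qtl_catalog(usable, data$study_maps, data$ref_map)
  prep <- projection_report(projected)
  note("project: ", prep$n_projected, "/", prep$n_usable, " projected (",
       prep$projected_pct, "%), ", prep$n_excluded_out_of_range,
       " out-of-range, ", prep$n_excluded_no_anchor, " no-anchor")

  # stage 3: meta-analysis
  meta <- run_meta_analysis(projected, K_max = K_max, criterion = criterion,
                            seed = seed)
  mqtls <- meta$mqtls
  note("meta: ", nrow(mqtls), " MQTLs on ",
       length(unique(mqtls$chromosome)), " chromosomes")

  # stage 4: physical reconciliation + GWAS validation
  mqtls <- mqtl_physical_intervals(mqtls, data$ref_map)
  mta_pairs <- NULL
  if (!is.null(data$mtas)) {
    cl <- colocalize_mtas(mqtls, data$mtas, window_bp = window_bp)
    mqtls <- cl$mqtls
    mta_pairs <- cl$pairs
    vr <- validation_rate(mqtls)
    note("validate: ", vr$n_validated, "/", vr$n_mqtls, " MQTLs (",
         vr$validated_pct, "%) co-localize with >=1 MTA")
  } else {
    mqtls$n_mtas <- 0L
    mqtls$is_mta_validated <- FALSE
  }
  mqtls <- breeder_filter(mqtls, max_bp = breeder_max_bp,
                          max_cm = breeder_max_cm,
                          min_qtls = breeder_min_qtls)
  mqtls <- mta_mqtl_windows(mqtls, threshold = mta_threshold,
                            flank_bp = window_bp)
  mqtls <- core_mqtl_set(mqtls)
  note("core: ", sum(mqtls$is_breeder), " breeder + ",
       sum(mqtls$has_mta_window), " MTA-supported -> ",
       sum(mqtls$is_core), " core MQTLs (non-redundant union)")

  # stage 5: candidate genes
  candidates <- NULL
  tiers <- NULL
  if (!is.null(data$annotation)) {
    ortho_best <- if (!is.null(data$ortholog_hits) &&
                      nrow(data$ortholog_hits) > 0) {
      filter_orthologs(data$ortholog_hits)$best
    } else NULL
    expr <- if (!is.null(data$fpkm)) {
      expression_screen(data$fpkm, threshold = expression_threshold,
                        tissues = expression_tissues)$flags
    } else NULL

    in_windows <- function(use, start_col, end_col) {
      found <- rep(FALSE, nrow(data$annotation))
      for (i in which(use)) {
        g <- genes_in_window(data$annotation, mqtls$chromosome[i],
                             mqtls[[start_col]][i], mqtls[[end_col]][i])
        found <- found | data$annotation$gene_id %in% g$gene_id
      }
      found
    }
    in_breeder <- in_windows(mqtls$is_breeder, "start_bp", "end_bp")
    in_gwas <- in_windows(mqtls$has_mta_window,
                          "window_start_bp", "window_end_bp")
    in_any_mqtl <- in_windows(!mqtls$no_physical, "start_bp", "end_bp")
    has_ortho <- data$annotation$gene_id %in% (ortho_best$query_gene_id %||% character(0))
    expressed <- if (is.null(expr)) rep(FALSE, nrow(data$annotation)) else
      expr$expressed[match(data$annotation$gene_id, expr$gene_id)]
    expressed[is.na(expressed)] <- FALSE

    keep <- in_breeder | in_gwas | (has_ortho & in_any_mqtl)
    candidates <- data$annotation[keep, ]
    candidates$in_breeder_mqtl <- in_breeder[keep]
    candidates$in_gwas_window <- in_gwas[keep]
    candidates$has_rice_ortholog <- has_ortho[keep]
    candidates$expressed <- expressed[keep]
    candidates <- score_candidate_genes(candidates)
    tiers <- tier_report(candidates)
    note("genes: ", nrow(candidates), " candidates; tiers high/medium/low = ",
         paste(tiers$n[1:3], collapse = "/"))
  }

  summary_tbl <- tibble::tibble(
    n_records = nrow(catalog),
    n_usable = nrow(usable),
    n_projected = prep$n_projected,
    projected_pct = prep$projected_pct,
    n_mqtls = nrow(mqtls),
    n_validated = sum(mqtls$is_mta_validated),
    validated_pct = pct_of(sum(mqtls$is_mta_validated), nrow(mqtls), 1),
    n_breeder = sum(mqtls$is_breeder),
    n_mta_mqtl = sum(mqtls$has_mta_window),
    n_core = sum(mqtls$is_core),
    n_candidates = if (is.null(candidates)) NA_integer_ else nrow(candidates)
  )

  out <- list(catalog = catalog, projected = projected,
              projection_report = prep, meta = meta, mqtls = mqtls,
              mta_pairs = mta_pairs, candidates = candidates,
              tier_report = tiers, summary = summary_tbl, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) if (!is.null(x))
      readr::write_tsv(x, file.path(out_dir, f), na = "", progress = FALSE)
    w(catalog, "catalog_imputed.tsv")
    w(projected, "projected_qtls.tsv")
    w(meta$diagnostics, "fit_diagnostics.tsv")
    w(mqtls, "mqtls.tsv")
    w(mta_pairs, "mqtl_mta_pairs.tsv")
    w(candidates, "candidate_genes.tsv")
    w(tiers, "gene_tiers.tsv")
    w(summary_tbl, "summary.tsv")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  out
}

#' Human-readable pipeline digest
#'
#' One text block mirroring the headline accounting of a meta-QTL study:
#' catalog size, projection rate, MQTL count, validated fraction as
#' "x% (a/b)", core set size and gene-tier shares.
#'
#' @param result Output of [run_pipeline()].
#' @return Character vector of lines (also printed).
#' @export
report_summary <- function(result) {
  s <- result$summary
  lines <- c(
    sprintf("QTL records: %d (%d usable after curation)",
            s$n_records, s$n_usable),
    sprintf("Projected onto reference map: %d/%d (%.1f%%)",
            s$n_projected, s$n_usable, s$projected_pct),
    sprintf("MQTLs: %d", s$n_mqtls),
    sprintf("GWAS-validated MQTLs: %.1f%% (%d/%d)",
            s$validated_pct, s$n_validated, s$n_mqtls),
    sprintf("Breeder / MTA-supported / core MQTLs: %d / %d / %d",
            s$n_breeder, s$n_mta_mqtl, s$n_core))
  if (!is.null(result$tier_report)) {
    tr <- result$tier_report
    lines <- c(lines,
               sprintf("Candidate genes: %d (high %.2f%%, medium %.2f%%, low %.2f%%)",
                       s$n_candidates, tr$pct[tr$tier == "high"],
                       tr$pct[tr$tier == "medium"], tr$pct[tr$tier == "low"]))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
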