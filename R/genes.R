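#' Read a gene annotation
#'
#' Accepts either a TSV with columns `gene_id`, `chromosome`, `start_bp`,
#' `end_bp` (1-based closed) and optional `description`, or a GFF3 file
#' (`.gff`/`.gff3`), of which only seqid, start, end and the ID attribute
#' are consumed (gene-type features only). GFF3 reading goes through
#' rtracklayer.
#'
#' @param path File path.
#' @return Annotation tibble sorted by chromosome and start.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    df <- tibble::tibble(
      gene_id = as.character(gr$ID),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start_bp = GenomicRanges::start(gr),
      end_bp = GenomicRanges::end(gr),
      description = NA_character_
    )
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(), chromosome = readr::col_character(),
      start_bp = readr::col_double(), end_bp = readr::col_double(),
      .default = readr::col_character()), progress = FALSE)
  }
  if (any(df$start_bp > df$end_bp)) stop("gene annotation has start_bp > end_bp")
  dplyr::arrange(df, .data$chromosome, .data$start_bp)
}

#' Genes overlapping a physical window
#'
#' Returns the genes whose body overlaps the closed window
#' `[start_bp, end_bp]` by at least 1 bp, in positional order.
#'
#' @param annotation Gene-annotation tibble.
#' @param chromosome Chromosome id.
#' @param start_bp,end_bp Window bounds (1-based closed).
#' @return Annotation rows overlapping the window.
#' @export
genes_in_window <- function(annotation, chromosome, start_bp, end_bp) {
  hits <- annotation[annotation$chromosome == chromosome &
                       annotation$end_bp >= start_bp &
                       annotation$start_bp <= end_bp, ]
  dplyr::arrange(hits, .data$start_bp)
}

#' Filter protein-alignment ortholog hits
#'
#' Keeps hits with `e_value < e_max` and `identity_pct > identity_min`,
#' both bounds strict. Input columns follow BLAST tabular conventions
#' (`qseqid`, `sseqid`, `pident`, `evalue`) or the equivalent names
#' `query_gene_id`, `subject_gene_id`, `identity_pct`, `e_value`.
#'
#' @param hits Hit tibble.
#' @param e_max E-value bound (strict `<`), default 1e-10.
#' @param identity_min Percent-identity bound (strict `>`), default 60.
#' @return List: `hits` (passing hits) and `best` (one row per query:
#'   lowest E, ties broken by highest identity).
#' @export
filter_orthologs <- function(hits, e_max = 1e-10, identity_min = 60) {
  nm <- names(hits)
  std <- c(qseqid = "query_gene_id", sseqid = "subject_gene_id",
           pident = "identity_pct", evalue = "e_value")
  for (b in names(std)) if (b %in% nm) names(hits)[nm == b] <- std[[b]]
  stopifnot(all(c("query_gene_id", "subject_gene_id", "identity_pct",
                  "e_value") %in% names(hits)))
  if (any(hits$e_value < 0)) stop("negative e_value in ortholog hits")
  if (any(hits$identity_pct < 0 | hits$identity_pct > 100)) {
    stop("identity_pct outside [0, 100]")
  }
  keep <- hits[hits$e_value < e_max & hits$identity_pct > identity_min, ]
  best <- dplyr::slice_head(
    dplyr::group_by(
      dplyr::arrange(keep, .data$e_value, dplyr::desc(.data$identity_pct)),
      .data$query_gene_id),
    n = 1)
  best <- dplyr::ungroup(best)
  list(hits = keep, best = best)
}

#' Expression screen of an FPKM matrix
#'
#' A gene counts as expressed when any considered tissue exceeds the FPKM
#' threshold (strict `>`). Also returns the `log2(FPKM + 1)` transform used
#' for heatmap display.
#'
#' @param fpkm Wide tibble: `gene_id` column plus one numeric column per
#'   tissue.
#' @param threshold FPKM threshold, default 2 (strict).
#' @param tissues Optional character vector restricting which tissue columns
#'   count toward the expressed flag (the transform always covers all).
#' @return List: `flags` (tibble `gene_id`, `expressed`, `max_fpkm`) and
#'   `transformed` (same shape as `fpkm`, values `log2(FPKM + 1)`).
#' @export
expression_screen <- function(fpkm, threshold = 2, tissues = NULL) {
  tissue_cols <- setdiff(names(fpkm), "gene_id")
  vals <- as.matrix(fpkm[, tissue_cols, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative FPKM for gene ", fpkm$gene_id[bad[1]], " in tissue ",
         tissue_cols[bad[2]])
  }
  screen_cols <- if (is.null(tissues)) tissue_cols else {
    miss <- setdiff(tissues, tissue_cols)
    if (length(miss) > 0) stop("unknown tissue(s): ", paste(miss, collapse = ", "))
    tissues
  }
  sv <- as.matrix(fpkm[, screen_cols, drop = FALSE])
  max_fpkm <- apply(sv, 1, max)
  flags <- tibble::tibble(gene_id = fpkm$gene_id,
                          expressed = max_fpkm > threshold,
                          max_fpkm = max_fpkm)
  transformed <- fpkm
  transformed[tissue_cols] <- log2(vals + 1)
  list(flags = flags, transformed = transformed)
}

#' Score candidate genes on four lines of evidence
#'
#' Each gene earns one point per evidence flag: located in a breeder's
#' MQTL, located in a GWAS-supported gene window, carrying a rice ortholog
#' passing the alignment filter, and expressed above the FPKM threshold.
#' Tiers: score >= 3 high, 2 medium, 1 low, 0 unsupported. (Four-point
#' genes fall in the high tier; they are visible via the `score` column.)
#'
#' @param genes Tibble with `gene_id` plus logical columns
#'   `in_breeder_mqtl`, `in_gwas_window`, `has_rice_ortholog`, `expressed`.
#' @return `genes` with integer `score` and ordered factor `tier`.
#' @export
score_candidate_genes <- function(genes) {
  flags <- c("in_breeder_mqtl", "in_gwas_window", "has_rice_ortholog",
             "expressed")
  stopifnot(all(flags %in% names(genes)))
  score <- Reduce(`+`, lapply(flags, function(f) as.integer(genes[[f]])))
  genes$score <- as.integer(score)
  genes$tier <- cut(genes$score, breaks = c(-0.5, 0.5, 1.5, 2.5, 4.5),
                    labels = c("unsupported", "low", "medium", "high"))
  genes
}

#' Confidence-tier report
#'
#' Counts per tier; percentages are over genes carrying at least one
#' evidence point (score >= 1), printed to 2 d.p. (half-up).
#'
#' @param candidates Output of [score_candidate_genes()].
#' @return Tibble `tier`, `n`, `pct`.
#' @export
tier_report <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(tier = character(), n = integer(), pct = numeric()))
  }
  lv <- c("high", "medium", "low", "unsupported")
  tab <- table(factor(as.character(candidates$tier), levels = lv))
  n_scored <- sum(candidates$score >= 1)
  tibble::tibble(
    tier = lv,
    n = as.integer(tab),
    pct = ifelse(lv == "unsupported", NA_real_,
                 pct_of(as.integer(tab), n_scored, 2))
  )
}
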