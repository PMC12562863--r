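# Seeded synthetic-data generator.
#
# Emulates the structure of a heterogeneous multi-study stalk-lodging QTL
# compilation: an expanded high-density reference map (IBM2-like geometry:
# several-fold more cM per chromosome than individual study maps), study
# maps that subsample its markers and distort interval lengths locally, QTL
# catalogs whose reported CI widths follow the population-size formulas,
# GWAS MTAs clustered near the true loci, and gene/expression/ortholog
# tables with known causal genes. Every output is deterministic given the
# seed, and the ground truth is exported for recovery tests.

#' Synthetic-data generator configuration
#'
#' Defaults describe a three-chromosome design with three well-separated
#' true loci per chromosome, twelve mapping studies, 8-20 QTLs per locus,
#' true positional scatter of 0.5-3 cM around each locus on the expanded
#' reference scale (a fraction of typical projected CI widths), and GWAS-supported loci (Poisson mean 8 MTAs per locus). Reported
#' CI widths follow the population formulas and are therefore NOT equal to
#' the true scatter (a realistic stressor); `well_specified = TRUE` makes
#' the reported widths match the true scatter instead.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_cm Reference-map length per chromosome (cM).
#' @param chrom_length_bp Chromosome physical length (bp).
#' @param n_ref_markers Reference markers per chromosome.
#' @param n_true_loci True loci per chromosome.
#' @param locus_spacing_min_cm Minimum spacing between true loci (cM,
#'   reference scale).
#' @param n_studies Number of mapping studies.
#' @param qtls_per_locus Integer range of QTLs per true locus.
#' @param population_mix Tibble `type`, `prob`, `n_min`, `n_max`.
#' @param r2_meanlog,r2_sdlog Log-normal parameters of the reported R2,
#'   clipped to `r2_clip`.
#' @param r2_clip Clipping range of R2 (the span of per-QTL phenotypic
#'   variance explained seen across published stalk-lodging studies).
#' @param sd_cm_range True scatter of QTL peaks around their locus (cM).
#' @param study_compression Range of the per-interval study-map cM
#'   compression factor relative to the reference map.
#' @param frac_blank_ci,frac_blank_r2,frac_blank_peak Fractions of records
#'   with the CI, the R2, or the peak+CI blanked to exercise imputation.
#' @param mta_per_locus Poisson mean of MTAs per true locus.
#' @param mta_bp_sd Physical scatter of locus MTAs (bp).
#' @param background_mta_per_chrom Poisson mean of background MTAs per
#'   chromosome.
#' @param n_genes_per_chrom Annotated genes per chromosome.
#' @param gene_length_bp Gene body length (bp).
#' @param n_tissues Tissues in the FPKM matrix.
#' @param causal_ortholog_prob,causal_expressed_prob Probability that a
#'   causal gene carries a filter-passing rice ortholog / is expressed
#'   above threshold.
#' @param background_expressed_prob Expression probability of background
#'   genes.
#' @param well_specified Make reported CI widths equal the true scatter.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_chromosomes = 3,
    chrom_length_cm = 800,
    chrom_length_bp = 150e6,
    n_ref_markers = 121,
    n_true_loci = 3,
    locus_spacing_min_cm = 100,
    n_studies = 12,
    qtls_per_locus = c(8L, 20L),
    population_mix = tibble::tibble(
      type = c("RIL", "DH", "F2", "F2:3", "BC", "IF2"),
      prob = c(0.35, 0.20, 0.15, 0.15, 0.05, 0.10),
      n_min = c(150L, 120L, 200L, 200L, 200L, 250L),
      n_max = c(300L, 250L, 300L, 300L, 300L, 450L)),
    r2_meanlog = log(0.09), r2_sdlog = 0.5, r2_clip = c(0.013, 0.43),
    sd_cm_range = c(0.5, 3),
    study_compression = c(0.18, 0.35),
    frac_blank_ci = 0.3, frac_blank_r2 = 0.2, frac_blank_peak = 0.1,
    mta_per_locus = 8, mta_bp_sd = 200000, background_mta_per_chrom = 5,
    n_genes_per_chrom = 300, gene_length_bp = 4000,
    n_tissues = 6,
    causal_ortholog_prob = 0.95, causal_expressed_prob = 0.95,
    background_expressed_prob = 0.3,
    well_specified = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes >= 1, cfg$n_true_loci >= 1,
            cfg$locus_spacing_min_cm >= 0, all(cfg$qtls_per_locus >= 1),
            abs(sum(cfg$population_mix$prob) - 1) < 1e-9)
  structure(cfg, class = "simulation_config")
}

.TRAIT_WEIGHTS <- c(PH = 0.21, RPR = 0.13, Lig = 0.12, EH = 0.12, IL = 0.08,
                    DF = 0.07, Cel = 0.06, Hem = 0.05, SSC = 0.05, SD = 0.05,
                    SBS = 0.03, Vb = 0.03)

#' Generate the synthetic reference map
#'
#' Markers at sorted uniform cM positions spanning each chromosome (the two
#' endpoints always included), with strictly increasing physical positions
#' produced by a monotone random cM-to-bp warp.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Genetic-map tibble with `map_name = "ref"`.
#' @export
generate_reference_map <- function(config, seed = 1L) {
  set.seed(seed)
  maps <- lapply(seq_len(config$n_chromosomes), function(chrom) {
    n <- config$n_ref_markers
    L <- config$chrom_length_cm
    cm <- if (n == 2) c(0, L) else c(0, sort(stats::runif(n - 2, 0, L)), L)
    # monotone warp: per-interval bp rate jitters log-normally around the
    # mean bp/cM, then the cumulative sum is rescaled to the chromosome size
    gaps <- diff(cm)
    rate <- exp(stats::rnorm(length(gaps), 0, 0.4))
    bp_raw <- cumsum(c(0, gaps * rate))
    bp <- 1 + (config$chrom_length_bp - 1) * bp_raw / bp_raw[length(bp_raw)]
    tibble::tibble(
      map_name = "ref", chromosome = as.character(chrom),
      marker = sprintf("c%dm%03d", chrom, seq_len(n)),
      position_cm = cm, position_bp = round(bp))
  })
  dplyr::bind_rows(maps)
}

#' Generate distorted study maps
#'
#' Each study samples a contiguous-span subset of the reference markers per
#' chromosome (at least two) and rebuilds cM positions with an independent
#' positive compression factor per interval, preserving marker order. This
#' reproduces the geometry of published study maps: much shorter than the
#' expanded reference map, with locally varying scale.
#'
#' @param ref_map Reference map from [generate_reference_map()].
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Map tibble with `map_name = "S01"..`.
#' @export
generate_study_maps <- function(ref_map, config, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (s in seq_len(config$n_studies)) {
    sid <- sprintf("S%02d", s)
    for (chrom in unique(ref_map$chromosome)) {
      rm <- ref_map[ref_map$chromosome == chrom, ]
      n <- nrow(rm)
      i1 <- sample(seq_len(max(1, round(0.08 * n))), 1)
      i2 <- n - sample(seq_len(max(1, round(0.08 * n))), 1) + 1
      inner <- setdiff(seq(i1, i2), c(i1, i2))
      keep <- sort(c(i1, i2, sample(inner, max(0, round(0.4 * length(inner))))))
      gaps_ref <- diff(rm$position_cm[keep])
      f <- stats::runif(length(gaps_ref), config$study_compression[1],
                        config$study_compression[2])
      cm <- cumsum(c(0, gaps_ref * f))
      out[[length(out) + 1]] <- tibble::tibble(
        map_name = sid, chromosome = chrom, marker = rm$marker[keep],
        position_cm = cm, position_bp = NA_real_)
    }
  }
  dplyr::bind_rows(out)
}

# Map a reference-scale cM position onto a study map (inverse of the
# projection direction), extrapolating linearly beyond the common-marker
# span. Extrapolated positions are exactly the records the projection stage
# later excludes as out-of-range.
.ref_to_study <- function(p, ref_cm, study_cm) {
  n <- length(ref_cm)
  if (p <= ref_cm[1]) {
    slope <- (study_cm[2] - study_cm[1]) / (ref_cm[2] - ref_cm[1])
    return(study_cm[1] + (p - ref_cm[1]) * slope)
  }
  if (p >= ref_cm[n]) {
    slope <- (study_cm[n] - study_cm[n - 1]) / (ref_cm[n] - ref_cm[n - 1])
    return(study_cm[n] + (p - ref_cm[n]) * slope)
  }
  stats::approx(ref_cm, study_cm, xout = p, ties = "ordered")$y
}

#' Place the true loci
#'
#' Sorted uniform positions within the central 15-85% of each chromosome,
#' re-drawn until all gaps respect the minimum spacing; physical positions
#' follow from the reference-map warp.
#'
#' @param ref_map Reference map.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Tibble `locus_id`, `chromosome`, `cm`, `bp`.
#' @export
generate_true_loci <- function(ref_map, config, seed = 1L) {
  set.seed(seed)
  L <- config$chrom_length_cm
  out <- list()
  for (chrom in unique(ref_map$chromosome)) {
    repeat {
      cm <- sort(stats::runif(config$n_true_loci, 0.15 * L, 0.85 * L))
      if (config$n_true_loci == 1 ||
          min(diff(cm)) >= config$locus_spacing_min_cm) break
    }
    out[[length(out) + 1]] <- tibble::tibble(
      locus_id = sprintf("L%s.%d", chrom, seq_along(cm)),
      chromosome = chrom, cm = cm,
      bp = round(genetic_to_physical(chrom, cm, ref_map)))
  }
  dplyr::bind_rows(out)
}

#' Generate the synthetic QTL catalog
#'
#' For each true locus, 8-20 QTL reports: the observed peak scatters
#' normally around the locus on the reference scale (sd drawn from
#' `sd_cm_range`); the record is then pulled back onto a randomly chosen
#' study map so projection is genuinely exercised. The reported CI width on
#' the study scale follows the population-size formula for the record's
#' population type, and the LOD is set by inverting the LOD-to-R2 formula,
#' so blanked fields re-impute to exactly consistent values. Configurable
#' fractions of records have the CI, the R2, or the peak+CI blanked.
#'
#' @param ref_map,study_maps,loci Outputs of the upstream generators.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List: `catalog` (QTL tibble) and `truth` (tibble `qtl_id`,
#'   `locus_id`, `true_peak_ref_cm`, `extrapolated`).
#' @export
generate_qtl_catalog <- function(ref_map, study_maps, loci, config, seed = 1L) {
  set.seed(seed)
  pm <- config$population_mix
  rows <- list()
  truth <- list()
  qn <- 0L
  for (li in seq_len(nrow(loci))) {
    locus <- loci[li, ]
    n_q <- sample(seq(config$qtls_per_locus[1], config$qtls_per_locus[2]), 1)
    for (q in seq_len(n_q)) {
      qn <- qn + 1L
      qid <- sprintf("Q%04d", qn)
      sid <- sprintf("S%02d", sample.int(config$n_studies, 1))
      sm <- study_maps[study_maps$map_name == sid &
                         study_maps$chromosome == locus$chromosome, ]
      anchors_ref <- ref_map$position_cm[match(sm$marker, ref_map$marker)]
      sd_true <- stats::runif(1, config$sd_cm_range[1], config$sd_cm_range[2])
      peak_ref <- stats::rnorm(1, locus$cm, sd_true)
      peak_study <- .ref_to_study(peak_ref, anchors_ref, sm$position_cm)
      extrapolated <- peak_ref < anchors_ref[1] ||
        peak_ref > anchors_ref[length(anchors_ref)]

      pt_i <- sample.int(nrow(pm), 1, prob = pm$prob)
      ptype <- pm$type[pt_i]
      N <- sample(seq(pm$n_min[pt_i], pm$n_max[pt_i]), 1)
      r2 <- min(max(stats::rlnorm(1, config$r2_meanlog, config$r2_sdlog),
                    config$r2_clip[1]), config$r2_clip[2])
      lod <- lod_from_r2(r2, N)
      if (config$well_specified) {
        # reported width reproduces the true scatter after projection: scale
        # 3.92 * sd_true by the local ref->study compression at the peak
        k <- max(1, min(findInterval(peak_ref, anchors_ref),
                        length(anchors_ref) - 1))
        f_local <- (sm$position_cm[k + 1] - sm$position_cm[k]) /
          (anchors_ref[k + 1] - anchors_ref[k])
        width_study <- 3.92 * sd_true * f_local
      } else {
        width_study <- estimate_ci_width(ptype, N, r2)
      }
      flank_k <- max(1, min(findInterval(peak_study, sm$position_cm),
                            nrow(sm) - 1))
      trait <- sample(names(.TRAIT_WEIGHTS), 1, prob = .TRAIT_WEIGHTS)

      u <- stats::runif(1)
      blank_peak <- u < config$frac_blank_peak
      blank_ci <- blank_peak || u < config$frac_blank_peak + config$frac_blank_ci
      blank_r2 <- stats::runif(1) < config$frac_blank_r2

      rows[[qn]] <- tibble::tibble(
        qtl_id = qid, study_id = sid, trait = trait,
        chromosome = locus$chromosome,
        peak_cm = if (blank_peak) NA_real_ else peak_study,
        ci_lower_cm = if (blank_ci) NA_real_ else peak_study - width_study / 2,
        ci_upper_cm = if (blank_ci) NA_real_ else peak_study + width_study / 2,
        lod = lod, r2 = if (blank_r2) NA_real_ else r2,
        population_type = ptype, population_size = as.integer(N),
        flank_lower = sm$marker[flank_k], flank_upper = sm$marker[flank_k + 1])
      truth[[qn]] <- tibble::tibble(qtl_id = qid, locus_id = locus$locus_id,
                                    true_peak_ref_cm = peak_ref,
                                    extrapolated = extrapolated)
    }
  }
  list(catalog = as_qtl_catalog(dplyr::bind_rows(rows)),
       truth = dplyr::bind_rows(truth))
}

#' Generate synthetic GWAS marker-trait associations
#'
#' Per true locus, `Poisson(mta_per_locus)` MTAs scattered normally (sd
#' `mta_bp_sd`) around the locus's physical position; plus
#' `Poisson(background_mta_per_chrom)` background MTAs uniform on each
#' chromosome.
#'
#' @param loci True-locus tibble.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List: `mtas` (MTA tibble) and `truth` (`mta_id`, `locus_id`,
#'   background rows have `locus_id = NA`).
#' @export
generate_mtas <- function(loci, config, seed = 1L) {
  set.seed(seed)
  rows <- list()
  truth <- list()
  mn <- 0L
  add <- function(chrom, bp, locus_id) {
    mn <<- mn + 1L
    id <- sprintf("MTA%04d", mn)
    rows[[mn]] <<- tibble::tibble(
      mta_id = id, study_id = sprintf("GWAS%d", sample.int(9, 1)),
      trait = sample(names(.TRAIT_WEIGHTS), 1, prob = .TRAIT_WEIGHTS),
      chromosome = chrom, position_bp = bp)
    truth[[mn]] <<- tibble::tibble(mta_id = id, locus_id = locus_id)
  }
  for (li in seq_len(nrow(loci))) {
    m <- stats::rpois(1, config$mta_per_locus)
    for (j in seq_len(m)) {
      bp <- round(stats::rnorm(1, loci$bp[li], config$mta_bp_sd))
      add(loci$chromosome[li],
          min(max(bp, 1), config$chrom_length_bp), loci$locus_id[li])
    }
  }
  for (chrom in unique(loci$chromosome)) {
    b <- stats::rpois(1, config$background_mta_per_chrom)
    for (j in seq_len(b)) {
      add(chrom, round(stats::runif(1, 1, config$chrom_length_bp)),
          NA_character_)
    }
  }
  list(mtas = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
}

#' Generate gene annotation, ortholog hits and an FPKM matrix
#'
#' One causal gene is placed within 50 kb of each true locus; background
#' genes tile the rest of each chromosome on a jittered grid. Causal genes
#' carry filter-passing rice-ortholog hits and above-threshold FPKM with
#' the configured (high) probabilities; background genes mostly carry
#' failing hits or none, and are expressed at the background rate.
#'
#' @param loci True-locus tibble.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List: `annotation`, `ortholog_hits`, `fpkm`, `truth`
#'   (`gene_id`, `causal`, `locus_id`).
#' @export
generate_genes_expression_orthologs <- function(loci, config, seed = 1L) {
  set.seed(seed)
  glen <- config$gene_length_bp
  ann <- list()
  for (chrom in unique(loci$chromosome)) {
    lchrom <- loci[loci$chromosome == chrom, ]
    causal_start <- round(lchrom$bp + stats::runif(nrow(lchrom), -5e4, 5e4))
    causal_start <- pmin(pmax(causal_start, 1), config$chrom_length_bp - glen)
    causal <- tibble::tibble(
      gene_id = sprintf("G%s_causal%d", chrom, seq_len(nrow(lchrom))),
      chromosome = chrom, start_bp = causal_start,
      end_bp = causal_start + glen - 1,
      causal = TRUE, locus_id = lchrom$locus_id)
    n_bg <- config$n_genes_per_chrom - nrow(causal)
    grid <- round(seq(1, config$chrom_length_bp - glen, length.out = n_bg) +
                    stats::runif(n_bg, 0, glen))
    bg <- tibble::tibble(
      gene_id = sprintf("G%s_%04d", chrom, seq_len(n_bg)),
      chromosome = chrom, start_bp = grid, end_bp = grid + glen - 1,
      causal = FALSE, locus_id = NA_character_)
    # drop background genes colliding with a causal gene
    hit <- vapply(seq_len(n_bg), function(i) {
      any(bg$start_bp[i] <= causal$end_bp & bg$end_bp[i] >= causal$start_bp)
    }, logical(1))
    ann[[length(ann) + 1]] <- dplyr::arrange(
      dplyr::bind_rows(causal, bg[!hit, ]), .data$start_bp)
  }
  ann <- dplyr::bind_rows(ann)

  hits <- list()
  for (i in seq_len(nrow(ann))) {
    if (ann$causal[i] &&
        stats::runif(1) < config$causal_ortholog_prob) {
      hits[[length(hits) + 1]] <- tibble::tibble(
        query_gene_id = ann$gene_id[i],
        subject_gene_id = sprintf("Os%05d", sample.int(99999, 1)),
        identity_pct = stats::runif(1, 65, 95),
        e_value = 10^stats::runif(1, -50, -15))
    } else if (stats::runif(1) < 0.1) {
      # failing hit: bad E-value or low identity
      bad_e <- stats::runif(1) < 0.5
      hits[[length(hits) + 1]] <- tibble::tibble(
        query_gene_id = ann$gene_id[i],
        subject_gene_id = sprintf("Os%05d", sample.int(99999, 1)),
        identity_pct = if (bad_e) stats::runif(1, 62, 90)
                       else stats::runif(1, 20, 55),
        e_value = if (bad_e) 10^stats::runif(1, -9, -1)
                  else 10^stats::runif(1, -40, -15))
    }
  }
  hits <- if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(query_gene_id = character(), subject_gene_id = character(),
                   identity_pct = numeric(), e_value = numeric())

  tissues <- c("internode_v9", "internode_v12", "stem_v1", "root_v7",
               "tassel_v13", "embryo_16d")[seq_len(config$n_tissues)]
  fpkm_mat <- matrix(stats::runif(nrow(ann) * length(tissues), 0, 1.5),
                     nrow(ann), length(tissues))
  for (i in seq_len(nrow(ann))) {
    p <- if (ann$causal[i]) config$causal_expressed_prob
         else config$background_expressed_prob
    if (stats::runif(1) < p) {
      k <- sample.int(length(tissues), sample(1:3, 1))
      fpkm_mat[i, k] <- stats::runif(length(k), 5, 60)
    }
  }
  fpkm <- tibble::as_tibble(stats::setNames(as.data.frame(fpkm_mat), tissues))
  fpkm <- dplyr::bind_cols(tibble::tibble(gene_id = ann$gene_id), fpkm)

  list(annotation = ann[, c("gene_id", "chromosome", "start_bp", "end_bp")],
       ortholog_hits = hits, fpkm = fpkm,
       truth = ann[, c("gene_id", "causal", "locus_id")])
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Runs all generators with seeds derived from the one root seed and
#' returns every input table the pipeline consumes plus the ground truth.
#'
#' @param config A [simulation_config()].
#' @param seed Integer root seed.
#' @return List: `ref_map`, `study_maps`, `catalog`, `mtas`, `annotation`,
#'   `ortholog_hits`, `fpkm`, `truth` (list with `loci`, `qtls`, `mtas`,
#'   `genes`), `config`, `seed`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1L) {
  ref_map <- generate_reference_map(config, derive_seed(seed, 1))
  study_maps <- generate_study_maps(ref_map, config, derive_seed(seed, 2))
  loci <- generate_true_loci(ref_map, config, derive_seed(seed, 3))
  qtl <- generate_qtl_catalog(ref_map, study_maps, loci, config,
                              derive_seed(seed, 4))
  mta <- generate_mtas(loci, config, derive_seed(seed, 5))
  genes <- generate_genes_expression_orthologs(loci, config,
                                               derive_seed(seed, 6))
  list(ref_map = ref_map, study_maps = study_maps, catalog = qtl$catalog,
       mtas = mta$mtas, annotation = genes$annotation,
       ortholog_hits = genes$ortholog_hits, fpkm = genes$fpkm,
       truth = list(loci = loci, qtls = qtl$truth, mtas = mta$truth,
                    genes = genes$truth),
       config = config, seed = seed)
}

#' Write a simulated dataset to a directory
#'
#' Emits every input table as TSV plus a ground-truth TSV per component.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f), na = "",
                                       progress = FALSE)
  w(sim$ref_map, "ref_map.tsv")
  w(sim$study_maps, "study_maps.tsv")
  w(sim$catalog, "qtl_catalog.tsv")
  w(sim$mtas, "mtas.tsv")
  w(sim$annotation, "gene_annotation.tsv")
  w(sim$ortholog_hits, "ortholog_hits.tsv")
  w(sim$fpkm, "fpkm.tsv")
  w(sim$truth$loci, "truth_loci.tsv")
  w(sim$truth$qtls, "truth_qtls.tsv")
  w(sim$truth$mtas, "truth_mtas.tsv")
  w(sim$truth$genes, "truth_genes.tsv")
  invisible(dir)
}

#' Simulate a single-chromosome mixture instance
#'
#' Direct simulation of the consensus-clustering observation model: `n_loci`
#' true positions at least `spacing_min_cm` apart, each generating 8-20
#' observed positions `x_i ~ N(mu, s_i^2)` with known per-observation sds
#' drawn from `s_range`. Used for parameter-recovery tests where the
#' reported precision equals the true precision.
#'
#' @param seed Integer seed.
#' @param n_loci Number of true loci.
#' @param spacing_min_cm Minimum spacing (cM).
#' @param range_cm Placement range of the loci.
#' @param qtls_per_locus Integer range of observations per locus.
#' @param s_range Range of the per-observation sd (cM).
#' @return List: `x`, `s`, `z_true` (generating locus index), `mu_true`.
#' @export
simulate_mixture_instance <- function(seed = 1L, n_loci = 3,
                                      spacing_min_cm = 20,
                                      range_cm = c(0, 150),
                                      qtls_per_locus = c(8L, 20L),
                                      s_range = c(1, 5)) {
  set.seed(seed)
  repeat {
    mu <- sort(stats::runif(n_loci, range_cm[1], range_cm[2]))
    if (n_loci == 1 || min(diff(mu)) >= spacing_min_cm) break
  }
  x <- numeric(0); s <- numeric(0); z <- integer(0)
  for (k in seq_len(n_loci)) {
    n_k <- sample(seq(qtls_per_locus[1], qtls_per_locus[2]), 1)
    s_k <- stats::runif(n_k, s_range[1], s_range[2])
    x <- c(x, stats::rnorm(n_k, mu[k], s_k))
    s <- c(s, s_k)
    z <- c(z, rep(k, n_k))
  }
  list(x = x, s = s, z_true = z, mu_true = mu)
}
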