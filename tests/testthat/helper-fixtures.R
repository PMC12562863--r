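# Small hand-built fixtures shared across test files.

# Two identical single-chromosome maps (identity projection).
identity_maps <- function(n = 6, L = 100) {
  m <- tibble::tibble(
    map_name = "ref", chromosome = "1",
    marker = sprintf("m%02d", seq_len(n)),
    position_cm = seq(0, L, length.out = n),
    position_bp = seq(1, 10e6, length.out = n))
  list(ref = m, study = dplyr::mutate(m, map_name = "S01"))
}

# A minimal usable QTL record.
make_record <- function(qtl_id = "Q0001", study_id = "S01", trait = "PH",
                        chromosome = "1", peak_cm = 10,
                        ci_lower_cm = 9.5, ci_upper_cm = 10.5,
                        lod = 3, r2 = 0.1, population_type = "RIL",
                        population_size = 200L,
                        flank_lower = NA_character_,
                        flank_upper = NA_character_) {
  as_qtl_catalog(tibble::tibble(
    qtl_id = qtl_id, study_id = study_id, trait = trait,
    chromosome = chromosome, peak_cm = peak_cm,
    ci_lower_cm = ci_lower_cm, ci_upper_cm = ci_upper_cm,
    lod = lod, r2 = r2, population_type = population_type,
    population_size = population_size,
    flank_lower = flank_lower, flank_upper = flank_upper))
}

# Random single-chromosome study/reference map pair for projection
# property tests: the study map subsamples the reference markers and
# rescales each interval by a positive factor.
random_map_pair <- function(seed, affine = FALSE) {
  set.seed(seed)
  n <- sample(6:15, 1)
  ref_cm <- c(0, sort(runif(n - 2, 0, 200)), 200)
  ref <- tibble::tibble(
    map_name = "ref", chromosome = "1",
    marker = sprintf("m%02d", seq_len(n)),
    position_cm = ref_cm,
    position_bp = round(seq(1, 50e6, length.out = n)))
  keep <- sort(c(1, n, sample(2:(n - 1), max(0, sample(0:(n - 2), 1)))))
  keep <- unique(keep)
  if (affine) {
    a <- runif(1, -10, 10); b <- runif(1, 0.2, 3)
    study_cm <- a + b * ref_cm[keep]
  } else {
    f <- runif(length(keep) - 1, 0.2, 2)
    study_cm <- cumsum(c(0, diff(ref_cm[keep]) * f))
  }
  study <- tibble::tibble(
    map_name = "S01", chromosome = "1",
    marker = ref$marker[keep], position_cm = study_cm,
    position_bp = NA_real_)
  list(ref = ref, study = study, a = if (affine) a else NA,
       b = if (affine) b else NA)
}
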