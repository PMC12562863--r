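test_that("CI-width formula reproduces hand-computed values and routing", {
  # inbred-line numerator cancels at N * r2 = 163
  expect_equal(estimate_ci_width("RIL", 163, 1.0), 1.0)
  # hand evaluation of 530 / (282 * 0.10)
  expect_equal(round(estimate_ci_width("F2", 282, 0.10), 3), 18.794)
  # F2-derived and inbred-line types route to their formulas
  expect_equal(estimate_ci_width("F2:3", 200, 0.1),
               estimate_ci_width("F2", 200, 0.1))
  expect_equal(estimate_ci_width("DH", 200, 0.1),
               estimate_ci_width("RIL", 200, 0.1))
  # the two formulas differ exactly by the 530/163 numerator ratio
  for (N in c(118L, 200L, 1948L)) {
    for (r2 in c(0.013, 0.1, 0.43)) {
      expect_equal(estimate_ci_width("F2", N, r2) / estimate_ci_width("RIL", N, r2),
                   530 / 163)
    }
  }
  expect_error(estimate_ci_width("F2", 200, 0), "r2")
  expect_error(estimate_ci_width("F2", 1, 0.1), "population_size")
  expect_error(estimate_ci_width("MAGIC", 200, 0.1), "MAGIC")
})

test_that("LOD-to-R2 conversion is exact, bounded and invertible", {
  expect_equal(estimate_r2_from_lod(0, 200), 0)
  expect_equal(round(estimate_r2_from_lod(3, 200), 4), 0.0667)
  expect_gt(estimate_r2_from_lod(6, 200), estimate_r2_from_lod(3, 200))
  # decreasing in N at fixed LOD
  expect_lt(estimate_r2_from_lod(3, 400), estimate_r2_from_lod(3, 200))
  # bounded in [0, 1) and round-trips through the inverse to 1e-9 relative
  set.seed(42)
  lod <- runif(50, 0, 40)
  N <- sample(100:2000, 50, replace = TRUE)
  r2 <- estimate_r2_from_lod(lod, N)
  expect_true(all(r2 >= 0 & r2 < 1))
  expect_equal(lod_from_r2(r2, N), lod, tolerance = 1e-9)
  expect_error(estimate_r2_from_lod(-1, 200), "lod")
})

test_that("imputation fills peak, r2 and CI without overwriting, idempotently", {
  maps <- identity_maps()
  # missing CI: width 163/(163*1) = 1 centred on the peak
  rec <- make_record(peak_cm = 10, ci_lower_cm = NA, ci_upper_cm = NA,
                     population_type = "RIL", population_size = 163L, r2 = 1.0)
  imp <- impute_qtl_catalog(rec, maps$study)
  expect_equal(imp$ci_lower_cm, 9.5)
  expect_equal(imp$ci_upper_cm, 10.5)
  expect_true(imp$usable)

  # missing peak: midpoint of the flanking markers (m01 at 0, m02 at 20)
  rec <- make_record(peak_cm = NA, ci_lower_cm = NA, ci_upper_cm = NA,
                     flank_lower = "m01", flank_upper = "m02")
  imp <- impute_qtl_catalog(rec, maps$study)
  expect_equal(imp$peak_cm, 10)

  # missing r2 and CI: chained Eq-style imputation, hand-checked
  rec <- make_record(peak_cm = 50, ci_lower_cm = NA, ci_upper_cm = NA,
                     r2 = NA, lod = 3, population_type = "F2",
                     population_size = 200L)
  imp <- impute_qtl_catalog(rec, maps$study)
  expect_equal(round(imp$r2, 4), 0.0667)
  expect_equal(round(imp$ci_upper_cm - imp$ci_lower_cm, 2), 39.70)

  # idempotence: a complete record is unchanged
  rec <- make_record()
  once <- impute_qtl_catalog(rec, maps$study)
  twice <- impute_qtl_catalog(once, maps$study)
  expect_equal(twice[names(rec)], rec)

  # unusable records are flagged with a reason, not dropped
  rec <- make_record(peak_cm = NA, ci_lower_cm = NA, ci_upper_cm = NA)
  imp <- suppressMessages(impute_qtl_catalog(rec, maps$study))
  expect_equal(nrow(imp), 1)
  expect_false(imp$usable)
  expect_match(imp$reason, "flanking")
})

test_that("catalog summary bins LOD, R2 and categories with printed rounding", {
  recs <- as_qtl_catalog(tibble::tibble(
    study_id = "S01", trait = c("PH", "RPR", "Lig"), chromosome = "1",
    peak_cm = 10, ci_lower_cm = 9, ci_upper_cm = 11,
    lod = c(2, 4, 5), r2 = c(0.04, 0.07, 0.12),
    population_type = "RIL", population_size = 200L))
  s <- summarize_catalog(recs)
  expect_equal(s$lod_bins$n, c(1L, 2L, 0L, 0L, 0L))
  expect_equal(s$lod_bins$pct[1:2], c(33.3, 66.7))
  expect_equal(s$r2_bins$n, c(1L, 1L, 1L, 0L, 0L))
  # bin counts always sum to the catalog size; percentages to 100 +/- slack
  expect_equal(sum(s$lod_bins$n), nrow(recs))
  expect_lt(abs(sum(s$lod_bins$pct) - 100), 0.15)
  expect_equal(s$categories$n[s$categories$category == "SM"], 1L)
  # empty catalog: empty tables, not an error
  empty <- summarize_catalog(recs[0, ])
  expect_equal(sum(empty$lod_bins$n), 0L)
})

test_that("QTL tables round-trip through TSV with missing values preserved", {
  recs <- dplyr::bind_rows(
    make_record(qtl_id = "Q1"),
    make_record(qtl_id = "Q2", lod = NA, r2 = 0.5),
    make_record(qtl_id = "Q3", peak_cm = 22.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qtl_table(recs, path)
  back <- read_qtl_table(path)
  core <- c("qtl_id", "study_id", "trait", "chromosome", "peak_cm",
            "ci_lower_cm", "ci_upper_cm", "lod", "r2",
            "population_type", "population_size")
  expect_equal(as.data.frame(back[core]), as.data.frame(recs[core]))
  expect_true(is.na(back$lod[2]))
  expect_equal(back$r2[2], 0.5)

  # header-only file reads as an empty catalog
  writeLines("qtl_id\tstudy_id\ttrait\tchromosome", path)
  expect_equal(nrow(read_qtl_table(path)), 0)

  # missing mandatory columns are a parse error
  writeLines(c("qtl_id\ttrait", "a\tPH"), path)
  expect_error(read_qtl_table(path), "study_id")
})

test_that("record validation enforces the invariants", {
  expect_silent(validate_qtl_records(make_record()))
  expect_error(validate_qtl_records(make_record(ci_lower_cm = 11)),
               "Q0001")
  expect_error(validate_qtl_records(make_record(r2 = 1.2)), "r2")
  expect_error(
    as_qtl_catalog(tibble::tibble(study_id = "s", trait = "XX",
                                  chromosome = "1")),
    "unknown trait")
  # the trait-category mapping is total over the twelve trait codes
  expect_equal(trait_category(c("PH", "RPR", "Cel", "Vb")),
               c("SM", "SS", "SC", "SA"))
})
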