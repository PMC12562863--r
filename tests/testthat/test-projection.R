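test_that("common markers are intersected by name and order-checked", {
  maps <- identity_maps()
  cm <- find_common_markers(maps$study, maps$ref, "1")
  expect_equal(cm$marker, maps$ref$marker)
  expect_true(all(cm$consistent))

  study <- tibble::tibble(map_name = "s", chromosome = "1",
                          marker = c("A", "B"), position_cm = c(0, 10),
                          position_bp = NA_real_)
  ref <- tibble::tibble(map_name = "ref", chromosome = "1",
                        marker = c("B", "C"), position_cm = c(5, 9),
                        position_bp = NA_real_)
  expect_equal(find_common_markers(study, ref, "1")$marker, "B")

  # order reversal flags both markers inconsistent
  ref2 <- tibble::tibble(map_name = "ref", chromosome = "1",
                         marker = c("B", "A"), position_cm = c(2, 8),
                         position_bp = NA_real_)
  cm2 <- find_common_markers(study, ref2, "1")
  expect_equal(cm2$marker, c("A", "B"))
  expect_false(any(cm2$consistent))
})

test_that("interval scaling interpolates, hits anchors exactly, never extrapolates", {
  anchors <- tibble::tibble(study_cm = c(0, 10), ref_cm = c(0, 20))
  # hand interpolation: 4 in [0,10] -> 8 in [0,20]
  expect_equal(project_position(4, anchors)$value, 8.0)
  # anchor positions map to themselves exactly
  expect_equal(project_position(c(0, 10), anchors)$value, c(0, 20))
  # outside the common-marker span: out-of-range, not extrapolated
  expect_equal(project_position(11, anchors)$status, "out_of_range")
  expect_equal(project_position(-0.5, anchors)$status, "out_of_range")
  # fewer than two anchors: no-anchor signal
  expect_equal(project_position(5, anchors[1, ])$status, "no_anchor")
  # zero-length study interval collapses to the midpoint of its ref images
  z <- tibble::tibble(study_cm = c(0, 5, 5, 10), ref_cm = c(0, 6, 8, 20))
  expect_equal(project_position(5, z)$value, 7)
  z2 <- tibble::tibble(study_cm = c(0, 5, 5, 10), ref_cm = c(0, 6, 6, 20))
  expect_equal(project_position(5, z2)$value, 6)
})

test_that("projection is the identity on equal maps and exact on affine maps", {
  maps <- identity_maps()
  rec <- make_record()
  proj <- project_qtl_catalog(impute_qtl_catalog(rec, maps$study),
                              maps$study, maps$ref)
  expect_equal(proj$status, "projected")
  expect_equal(proj$ref_peak_cm, 10)
  expect_equal(proj$ref_ci_lower_cm, 9.5)
  expect_equal(proj$ref_ci_upper_cm, 10.5)
  # sd from the projected 95% CI: width / 3.92
  expect_equal(round(proj$position_sd_cm, 4), 0.2551)

  # doubling map: CI width and sd scale linearly
  ref2 <- dplyr::mutate(maps$ref, position_cm = 2 * position_cm)
  proj2 <- project_qtl_catalog(impute_qtl_catalog(rec, maps$study),
                               maps$study, ref2)
  expect_equal(proj2$ref_peak_cm, 20)
  expect_equal(proj2$position_sd_cm, 2 * proj$position_sd_cm)

  # affine invariance over randomized map pairs (ref = a + b * study)
  for (seed in 1:40) {
    mp <- random_map_pair(seed, affine = TRUE)
    anchors <- find_common_markers(mp$study, mp$ref, "1")
    p <- runif(5, min(mp$study$position_cm), max(mp$study$position_cm))
    got <- project_position(p, anchors)
    expect_true(all(got$status == "projected"))
    # study = a + b*ref, so projecting back onto ref inverts the transform
    expect_equal(got$value, (p - mp$a) / mp$b, tolerance = 1e-9)
  }
})

test_that("projection preserves order and accounts for every record", {
  # order preservation + exclusion accounting over randomized map pairs
  n_pairs <- 200
  for (seed in seq_len(n_pairs)) {
    mp <- random_map_pair(seed)
    anchors <- find_common_markers(mp$study, mp$ref, "1")
    span <- range(mp$study$position_cm)
    p <- sort(runif(6, span[1] - 10, span[2] + 10))
    got <- project_position(p, anchors)
    inside <- got$status == "projected"
    expect_true(all(diff(got$value[inside]) >= -1e-12))
    expect_true(all(got$status %in% c("projected", "out_of_range")))
    # out-of-range exactly when outside the common-marker span
    expect_equal(got$status == "out_of_range",
                 p < span[1] | p > span[2])
  }

  # record-level exclusion accounting: projected + excluded = usable
  maps <- identity_maps()
  recs <- dplyr::bind_rows(
    make_record(qtl_id = "Qin", peak_cm = 50, ci_lower_cm = 49,
                ci_upper_cm = 51),
    make_record(qtl_id = "Qout", peak_cm = 150, ci_lower_cm = 149,
                ci_upper_cm = 151),
    make_record(qtl_id = "Qnochrom", chromosome = "9"))
  proj <- project_qtl_catalog(impute_qtl_catalog(recs, maps$study),
                              maps$study, maps$ref)
  expect_equal(proj$status,
               c("projected", "excluded_out_of_range", "excluded_no_anchor"))
  rep <- projection_report(proj)
  expect_equal(rep$n_projected + rep$n_excluded_out_of_range +
                 rep$n_excluded_no_anchor, nrow(recs))
  expect_equal(rep$projected_pct, 33.3)
})

test_that("CI bounds are clamped to the chromosome ends when out of span", {
  maps <- identity_maps(n = 6, L = 100)
  rec <- make_record(peak_cm = 2, ci_lower_cm = -5, ci_upper_cm = 9)
  proj <- project_qtl_catalog(impute_qtl_catalog(rec, maps$study),
                              maps$study, maps$ref)
  expect_equal(proj$status, "projected")
  expect_equal(proj$ref_ci_lower_cm, 0)   # clamped to chromosome start
  expect_equal(proj$ref_ci_upper_cm, 9)
})

test_that("SNP markers place onto the map through physical anchors", {
  ref <- tibble::tibble(
    map_name = "ref", chromosome = "1", marker = c("a", "b"),
    position_cm = c(10, 20), position_bp = c(1e6, 3e6))
  # hand interpolation between (1 Mb -> 10 cM) and (3 Mb -> 20 cM)
  expect_equal(project_snp_marker("1", 2e6, ref)$value, 15.0)
  # exact anchor hit
  expect_equal(project_snp_marker("1", 1e6, ref)$value, 10)
  # outside the anchored bp span
  expect_equal(project_snp_marker("1", 5e5, ref)$status, "out_of_range")
})
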