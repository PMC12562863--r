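#!/usr/bin/env Rscript
# Project the curated catalog onto the reference map by common-marker
# interval scaling and report the exclusion accounting.
suppressMessages(library(maizeMQTL))

imputed <- read_qtl_table("results/catalog_imputed.tsv")
imputed$usable <- as.logical(imputed$usable)
maps <- read_map_table("results/simulated/study_maps.tsv")
ref <- read_map_table("results/simulated/ref_map.tsv")

proj <- project_qtl_catalog(imputed[imputed$usable, ], maps, ref)
readr::write_tsv(proj, "results/projected_qtls.tsv")
rep <- projection_report(proj)
readr::write_tsv(rep, "results/projection_report.tsv")
cat(rep$n_projected, "of", rep$n_usable, "usable QTLs projected (",
    rep$projected_pct, "%);", rep$n_excluded_out_of_range, "out of range,",
    rep$n_excluded_no_anchor, "without anchors.\n")
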