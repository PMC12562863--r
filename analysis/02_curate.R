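#!/usr/bin/env Rscript
# Curate the simulated QTL catalog: impute missing peaks, R2 values and
# confidence intervals, and summarize the LOD/R2/trait distributions.
suppressMessages(library(maizeMQTL))

catalog <- read_qtl_table("results/simulated/qtl_catalog.tsv")
maps <- read_map_table("results/simulated/study_maps.tsv")
imputed <- impute_qtl_catalog(catalog, maps)
write_qtl_table(imputed, "results/catalog_imputed.tsv")

s <- summarize_catalog(imputed[imputed$usable, ])
readr::write_tsv(s$lod_bins, "results/summary_lod_bins.tsv")
readr::write_tsv(s$r2_bins, "results/summary_r2_bins.tsv")
readr::write_tsv(s$categories, "results/summary_categories.tsv")

cat(sum(!imputed$usable), "of", nrow(imputed),
    "records were unusable after imputation.\n")
cat("LOD-bin shares (%):",
    paste(s$lod_bins$bin, s$lod_bins$pct, sep = "=", collapse = "  "), "\n")
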