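#!/usr/bin/env Rscript
# Stage 5: source-level syntheses.
#
# Pools per-source contribution means within each habitat x source cell,
# builds 1000-draw bootstrap density summaries (truncated-normal draws per
# dataset, pooled, boundary-corrected kernel density), and demonstrates the
# two-source isotope mixing computation used for studies that reported
# signatures but no mixing model.

suppressPackageStartupMessages(library(bcmeta))

seed <- 2024L
records <- read_compilation("results/compilation.csv")
contrib <- utils::read.csv("results/contributions.csv",
                           stringsAsFactors = FALSE)

dens <- habitat_source_densities(contrib, records, n_boot = 1000L,
                                 seed = seed)
summ <- attr(dens, "summary")
utils::write.csv(summ, "results/source_summary.csv", row.names = FALSE)
utils::write.csv(do.call(rbind, lapply(names(dens), function(k) {
  d <- dens[[k]]
  data.frame(cell = k, grid_point = d$grid, density = d$density)
})), "results/densities.csv", row.names = FALSE)

cat("pooled source contributions (mean % of soil C_org, n datasets):\n")
summ <- summ[order(summ$habitat, -summ$mean), ]
for (i in seq_len(nrow(summ))) {
  cat(sprintf("  %-9s <- %-11s %5.1f%% +/- %4.1f (n = %d)\n",
              summ$habitat[i], summ$source_name[i], summ$mean[i],
              summ$sd[i], summ$n_datasets[i]))
}

## two-source mixing example: a seagrass soil mixture between mangrove and
## seagrass end-member signatures (per-mil d13C)
mix <- two_source_mixing(mix = iso_signature(-22.0, 1.5, 6),
                         source1 = iso_signature(-28.5, 1.2, 8),
                         source2 = iso_signature(-17.5, 1.0, 10))
cat(sprintf("\ntwo-source mixing demo: mangrove fraction %.2f (SE %.3f)\n",
            mix$f1, mix$se_f1))
cat("wrote results/source_summary.csv, results/densities.csv\n")
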