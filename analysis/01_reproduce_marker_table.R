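#!/usr/bin/env Rscript
# Stage 1: estimate the MSC fraction of the coculture transcriptome from the
# seven Y-chromosome marker genes of the packaged marker table.
#
# The two male MSC donors (A211, A283) were each cocultured with the same
# female chondrocyte donor, so chrY transcripts in a coculture can only come
# from the MSCs. The per-marker coculture/monoculture ratio estimates the
# surviving MSC signal; averaging over markers and donors gives the mixture
# weights used by the additivity screen.

suppressPackageStartupMessages(library(cocultex))
dir.create("results", showWarnings = FALSE)

fx <- table1_fixture()
est <- lapply(c("A211", "A283"), function(p)
  estimate_proportion(fx$matrix, fx$design, fx$markers, p))
for (e in est) print(e)

pooled <- pool_proportions(est, rounding = 2)
print(pooled)

att <- attrition_report(pooled$pi, seeded_fraction = 0.8)
message(sprintf(
  "MSC contribution dropped from %.0f%% (seeding) to %.0f%% of coculture RNA (%.0f point drop; relative retention %.4f)",
  100 * att$seeded_fraction, 100 * att$estimated_fraction,
  att$drop_percent_points, att$relative_retention))

write_results("results/marker_proportions.tsv", proportion_table(est),
              header_comments = c(pi = pooled$pi,
                                  seeded_fraction = att$seeded_fraction,
                                  drop_percent_points = att$drop_percent_points))
message("wrote results/marker_proportions.tsv")
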