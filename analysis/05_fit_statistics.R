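#!/usr/bin/env Rscript
# Stage 5 — analytic global-fit conversions for the published models.
#
# The published structural equation models report their goodness of fit as
# (Fisher's C, df, P) triples. Given C and df, the global P is fully
# determined by the chi-square upper tail; this stage recomputes all eight
# and writes them as a table.

suppressPackageStartupMessages(library(stabsem))

out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

published <- data.frame(
  model = c("grassland plants", "forest plants", "grassland arthropods",
            "grassland herbivores", "grassland carnivores",
            "multitrophic arthropods", "multitrophic herbivores",
            "multitrophic carnivores"),
  C = c(32.064, 39.647, 39.344, 40.074, 50.672, 54.344, 78.18, 141.569),
  df = c(26, 36, 34, 30, 38, 62, 68, 140))

published$P <- fisher_c_pvalue(published$C, published$df)
published$adequate_fit <- published$P > 0.05

write.csv(published, file.path(out, "published_fit_statistics.csv"),
          row.names = FALSE)
print(cbind(published[, c("model", "C", "df")], P = round(published$P, 3)))
cat("\nAll eight models show P > 0.05: the hypothesised causal structures\n")
cat("are consistent with their data under the d-separation test.\n")
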