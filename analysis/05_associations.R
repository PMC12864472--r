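#!/usr/bin/env Rscript
# Stage 5: brain-behavior association models.
#
# Tract-wise and cluster-wise associations of each metric with GDS
# language scores (within group plus the group x language interaction)
# and, within the ASD group, with ADOS total scores. Cluster-level
# responses are the segment means over the intervals detected in stage
# 4 — a selection-dependent analysis, flagged as such in the outputs.

suppressPackageStartupMessages(library(tractstats))

ds <- read_profiles("results/cohort/profiles.csv")
dem <- read_demographics("results/cohort/demographics.csv")
clusters <- read.csv("results/tables/pointwise_clusters.csv")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
cfg <- perm_config(n_perm = 5000, seed = 42)

lang_tract <- behavior_assoc(ds, dem, "gds_language", level = "tract",
                             cfg = cfg)
write.csv(lang_tract, "results/tables/assoc_language_tract.csv",
          row.names = FALSE)
hit <- lang_tract[lang_tract$p_corrected < 0.05, ]
cat(sprintf("tract-level language associations surviving correction: %d of %d\n",
            nrow(hit), nrow(lang_tract)))
if (nrow(hit) > 0)
  print(hit[, c("group_scope", "tractID", "metric", "beta", "t",
                "p_corrected", "partial_r2")], digits = 3,
        row.names = FALSE)

if (nrow(clusters) > 0) {
  lang_cl <- behavior_assoc(ds, dem, "gds_language", level = "cluster",
                            clusters = clusters, cfg = cfg)
  write.csv(lang_cl, "results/tables/assoc_language_cluster.csv",
            row.names = FALSE)
  cat(sprintf("\ncluster-level language associations (selection-dependent): %d tested, %d surviving\n",
              nrow(lang_cl), sum(lang_cl$p_corrected < 0.05)))
}

sev <- severity_assoc(ds, dem, clusters = clusters, cfg = cfg)
write.csv(sev, "results/tables/assoc_severity.csv", row.names = FALSE)
sev_hit <- sev[sev$p_corrected < 0.05, ]
cat(sprintf("\nADOS-severity associations surviving correction: %d of %d\n",
            nrow(sev_hit), nrow(sev)))
if (nrow(sev_hit) > 0)
  print(sev_hit[, c("level", "tractID", "metric", "beta", "t",
                    "p_corrected")], digits = 3, row.names = FALSE)
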