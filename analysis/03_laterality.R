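#!/usr/bin/env Rscript
# Stage 3: lateralization-index analyses.
#
# Per subject, tract pair and metric the LI = (R - L)/(R + L) of the
# tract-wise means; then (a) one-sample tests per group with sign-flip
# permutation correction over the pair family, (b) the between-group
# comparison LI ~ group + age + sex, and (c) the LI-language models
# within group and with the group x language interaction. 5000
# permutations throughout.

suppressPackageStartupMessages(library(tractstats))

ds <- read_profiles("results/cohort/profiles.csv")
dem <- read_demographics("results/cohort/demographics.csv")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
cfg <- perm_config(n_perm = 5000, seed = 42)

li <- li_table(ds)
write.csv(li, "results/tables/li_subject.csv", row.names = FALSE)

one <- li_one_sample(li, dem, cfg)
write.csv(one, "results/tables/li_one_sample.csv", row.names = FALSE)
lat <- one[one$direction != "none", ]
cat(sprintf("significant lateralization in %d of %d (group, pair, metric) cells:\n",
            nrow(lat), nrow(one)))
print(lat[, c("group", "tract_pair", "metric", "mean_li", "t",
              "p_corrected", "direction")], digits = 3, row.names = FALSE)

grp <- li_group_compare(li, dem, cfg)
write.csv(grp, "results/tables/li_group_compare.csv", row.names = FALSE)
cat(sprintf("\nbetween-group LI differences surviving correction: %d of %d\n",
            sum(grp$p_corrected < 0.05), nrow(grp)))

beh <- li_behavior(li, dem, "gds_language", cfg)
write.csv(beh, "results/tables/li_language.csv", row.names = FALSE)
hit <- beh[beh$p_corrected < 0.05, ]
cat(sprintf("LI-language associations surviving correction: %d of %d\n",
            nrow(hit), nrow(beh)))
if (nrow(hit) > 0)
  print(hit[, c("scope", "tract_pair", "metric", "beta", "t",
                "p_corrected", "partial_r2")], digits = 3,
        row.names = FALSE)
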