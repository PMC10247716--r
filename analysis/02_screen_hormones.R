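#!/usr/bin/env Rscript
# Stage 2: hormone panel screening — per-hormone unpaired two-tailed
# Student t-tests between hypoxia and control, mirroring how HPA/HPT-axis
# panels are compared group-wise.

suppressPackageStartupMessages(library(mediomics))

md <- read_metadata("results/tables/metadata.tsv")
hormones <- read_feature_table("results/tables/hormones.csv", "hormone_csv", md)

screen <- screen_hormones(hormones, alpha = 0.05)
print(screen, digits = 3)

dir.create("results/screens", showWarnings = FALSE, recursive = TRUE)
write.table(screen, "results/screens/hormone_screen.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("%d of %d hormones differ between groups (p < 0.05)\n",
            sum(screen$significant), nrow(screen)))
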