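#!/usr/bin/env Rscript
# Stage 3: gut microbiota analysis — rarefaction to the minimum sample
# depth, alpha diversity (Shannon/Chao1/Observed/Simpson with Mann-Whitney
# group tests), CSS normalization, Bray-Curtis PCoA, and the LEfSe-style
# LDA effect-size screen (KW p < 0.05, LDA score > 3) for differential
# genera.

suppressPackageStartupMessages(library(mediomics))

seed <- 20260923L
md <- read_metadata("results/tables/metadata.tsv")
genera <- read_feature_table("results/tables/genus_counts.tsv", "counts_tsv", md)

depth <- min(colSums(genera$values))
cat("rarefying to minimum sample depth:", depth, "\n")
rare <- rarefy(genera, depth, seed = seed)

adiv <- alpha_diversity(rare)
g <- rare$group
alpha_tests <- do.call(rbind, lapply(
  c("shannon", "chao1", "observed", "simpson"),
  function(metric) {
    res <- mann_whitney(adiv[[metric]][g == "hypoxia"],
                        adiv[[metric]][g == "control"])
    data.frame(metric = metric, statistic = res$statistic, p = res$p_value,
               method = res$method)
  }
))
cat("\nalpha diversity group tests (Mann-Whitney):\n")
print(alpha_tests, digits = 3)

css <- css_normalize(rare)
dmat <- bray_curtis(css)
ord <- pcoa(dmat)
cat(sprintf("\nPCoA: first two axes explain %.1f%% and %.1f%% of variation\n",
            100 * ord$proportion_explained[1], 100 * ord$proportion_explained[2]))

lda <- lda_effect_screen(rare, alpha = 0.05, lda_threshold = 3, seed = seed + 1L)
hits <- lda[lda$passed, ]
cat(sprintf("\nLDA screen: %d of %d genera differential (KW p < 0.05 & LDA > 3)\n",
            nrow(hits), nrow(lda)))
print(hits[order(-hits$lda_score), ], digits = 3, row.names = FALSE)

dir.create("results/screens", showWarnings = FALSE, recursive = TRUE)
write.table(adiv, "results/screens/alpha_diversity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(alpha_tests, "results/screens/alpha_diversity_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(dmat, "results/screens/bray_curtis.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(ord$coordinates, "results/screens/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, col.names = NA)
write.table(lda, "results/screens/lda_screen.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_feature_table(rare, "results/screens/genus_rarefied.tsv")
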