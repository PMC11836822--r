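#!/usr/bin/env Rscript
# Principal component overview of the 23 numerical features: how strongly
# the five production types cluster before any supervised learning.

suppressMessages(library(cattletype))
suppressMessages(library(data.table))

fx <- fread("scratch/features.csv")
pv <- pca_overview(fx)

vf <- data.table(component = seq_along(pv$variance_fraction),
                 variance_fraction = pv$variance_fraction,
                 cumulative = cumsum(pv$variance_fraction))
fwrite(vf, "results/pca_variance.csv")
fwrite(data.table(feature = rownames(pv$loadings),
                  round(pv$loadings[, 1:5], 4)),
       "results/pca_loadings.csv")
fwrite(data.table(production_type = pv$labels,
                  round(pv$scores[, 1:5], 4)),
       "results/pca_scores.csv")

cat(sprintf("First two components explain %.1f%% of the variance.\n",
            100 * sum(pv$variance_fraction[1:2])))
top <- function(j) {
  o <- order(-abs(pv$loadings[, j]))[1:3]
  paste(sprintf("%s (%.2f)", rownames(pv$loadings)[o], pv$loadings[o, j]),
        collapse = ", ")
}
cat("Top PC1 loadings:", top(1), "\n")
cat("Top PC2 loadings:", top(2), "\n")
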