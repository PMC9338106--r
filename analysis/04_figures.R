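#!/usr/bin/env Rscript
# Figures from the group tables written by 03_response_analysis.R:
# the response time courses per square size (mean +/- SEM across
# participants, frame vs tile), the magnitude-by-size lines per participant,
# and the tile-vs-frame magnitude scatter.

library(mfresponse)

group_curves <- read.csv("results/group/group_curves.csv")
magnitudes <- read.csv("results/group/magnitudes.csv")
pairing <- read.csv("results/group/pairing.csv")

dir.create("results/figures", showWarnings = FALSE)

g <- list(magnitudes = NULL, pairing = pairing, curves = group_curves,
          n_participants = length(unique(magnitudes$participant)))
class(g) <- "mfr_group_summary"

p_curves <- plot_response_curves(g)
ggplot2::ggsave("results/figures/response_curves.pdf", p_curves,
                width = 8, height = 3.2)

p_mag <- plot_magnitudes(magnitudes, pairing)
ggplot2::ggsave("results/figures/magnitude_by_size.pdf", p_mag$size,
                width = 4.5, height = 3.5)
ggplot2::ggsave("results/figures/tile_vs_frame.pdf", p_mag$scatter,
                width = 4.5, height = 3.8)
cat("wrote 3 figures under results/figures/\n")
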