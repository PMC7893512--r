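#!/usr/bin/env Rscript
# Evaluate the PAI recommendations: observed average follow-up BDI-II of
# participants randomized to their indicated vs non-indicated treatment,
# in the full sample, the top-60% |PAI| subset, and separately by
# indicated arm.

suppressMessages(library(paitrial))

outc <- read.csv("results/outcomes.csv")
pai <- read.csv("results/pai.csv")
pai$arm <- factor(pai$arm, levels = c("CT", "IPT"))
class(pai) <- c("pai_table", "data.frame")

ev <- evaluate_pai(pai, outc$avg_bdi[match(pai$id, outc$id)])
print(ev)

write.csv(ev$contrasts, "results/evaluation.csv", row.names = FALSE)
cat("wrote results/evaluation.csv\n")
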