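#!/usr/bin/env Rscript

# Extended active-site motif analysis on a simulated thioredoxin-fold family:
# -CXXC- detection, slot extraction, conservation tabulation at the design
# frequencies of the 494-sequence comparison (Q 380, R 72, K 42), and the
# electrostatic classification of representative layouts.

suppressPackageStartupMessages(library(trxpka))
dir.create("results", showWarnings = FALSE)

sim <- sim_motif_sequences(494, seed = 494)
write_fasta(sim$sequences, "results/simulated_family.fasta")

recs <- lapply(seq_along(sim$sequences), function(k) {
  extract_extended_site(sim$sequences[[k]], sim$truth$motif_start[k],
                        sequence_id = sim$truth$sequence_id[k])
})
tab <- tabulate_conservation(recs, "partner")
cat("Distal-partner conservation over", attr(tab, "total"), "sequences:\n")
print(tab, row.names = FALSE)
cat(sprintf("(design frequencies: Q %.1f%%, R %.1f%%, K %.1f%%)\n",
            100 * 380 / 494, 100 * 72 / 494, 100 * 42 / 494))
write_report(tab, "results/motif_conservation.csv")

cls <- table(vapply(recs, function(r) classify_active_site(r)$class,
                    character(1)))
cat("\nClassification of the simulated family:\n")
print(cls)
cat("\nQ/N partners give the stabilized-acid class (elevated attacking-Cys\n")
cat("pKa); K/R partners give the coupled-microscopic class; the family\n")
cat("splits accordingly. Outputs written under results/.\n")
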