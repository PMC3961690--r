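#!/usr/bin/env Rscript

# The coupled aspartate/cysteine ionization scheme: microstate populations,
# the exact equivalence of the site titration curve with the macroscopic
# two-pKa closed form, and end-to-end recovery of the shared microscopic
# pair from synthetic double-sigmoid titrations.

suppressPackageStartupMessages(library(trxpka))
dir.create("results", showWarnings = FALSE)
seed <- 20260925

model <- symmetric_coupled_model(7.6, 10.4)
print(model)

mac <- macroscopic_from_microscopic(model)
grid <- seq(2, 14, by = 0.1)
frac <- microstate_fractions(grid, model)
frac$site_b <- site_deprotonation_fraction(grid, model, "B")
write_report(frac, "results/coupled_microstates.csv")

share <- 10^(-model$pk_b_first) /
  (10^(-model$pk_a_first) + 10^(-model$pk_b_first))
oracle <- shift_two_pka(grid, two_pka_params(0, share, 1,
                                             mac[["pka1"]], mac[["pka2"]]))
cat(sprintf("\nfirst-step amplitude K_B/(K_A+K_B) = %.3f (two equal steps)\n",
            share))
cat(sprintf("max |site curve - macroscopic closed form| = %.2e\n",
            max(abs(oracle - frac$site_b))))

sim <- sim_coupled_titration(model, n_resonances = 5,
                             ph_grid = seq(4, 13, 0.25), amplitude_b = 2.7,
                             noise_sd = 0.05, seed = seed)
fits <- lapply(sim$series, fit_two_pka)
lo <- aggregate_pka(fits, "lower")
hi <- aggregate_pka(fits, "upper")
micro <- microscopic_from_macroscopic(lo$mean_pka, hi$mean_pka)
cat(sprintf("\nfitted macroscopic pair: %s / %s\n",
            format_pka_estimate(lo), format_pka_estimate(hi)))
cat(sprintf("converted microscopic pair: %.3f / %.3f (truth 7.6 / 10.4)\n",
            micro$pk_a_first, micro$pk_b_given_a))

write_report(fits, "results/coupled_fits.csv")
cat("\nMicrostate table and per-resonance fits written under results/.\n")
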