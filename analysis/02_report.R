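#!/usr/bin/env Rscript
# Run the full codon-usage report on the synthetic panel and narrate the
# analysis surface: composition, dinucleotide odds, RSCU, bias indices,
# parity, neutrality, ENc-GC3, PCA, protein indices and correlations.
# Requires analysis/01_simulate.R to have been run.

suppressPackageStartupMessages(library(cubtools))

fasta <- "results/synthetic/panel.fasta"
if (!file.exists(fasta)) stop("run analysis/01_simulate.R first")

res <- run_report(fasta, "results/report", seed = 20260925L %% 100000L)

summ <- res$summary
message(sprintf("panel: %d sequences, %d codons", summ$n_sequences,
                summ$total_codons))
message(sprintf("Nc classes: %.1f%% high bias (<35), %.1f%% moderate (35-50), %.1f%% low (>50)",
                summ$nc_class_pct$HIGH_BIAS, summ$nc_class_pct$MODERATE,
                summ$nc_class_pct$LOW))
message(sprintf("parity means: x = %.3f +/- %.3f, y = %.3f +/- %.3f",
                summ$parity_mean$x, summ$parity_sd$x,
                summ$parity_mean$y, summ$parity_sd$y))
if (!is.null(res$neutrality)) {
  message(sprintf("neutrality: GC12 = %.4f GC3 + %.2f (R2 = %.3f) -> mutation %.2f%%, selection %.2f%%",
                  res$neutrality$slope, res$neutrality$intercept,
                  res$neutrality$r2, res$neutrality$mutation_pct,
                  res$neutrality$selection_pct))
}
message(sprintf("CAI range %.3f-%.3f; mean ICDI %.3f",
                summ$cai_range$min, summ$cai_range$max, summ$icdi_mean))
message(sprintf("rare codons (<1%% pooled frequency): %s",
                paste(summ$rare_codons, collapse = " ")))
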