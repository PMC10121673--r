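#!/usr/bin/env Rscript
# Re-extract SBS-96 spectra from the emitted VCF + FASTA files and
# check them against the simulated spectrum: classification into the
# 96 trinucleotide channels must reproduce the planted counts exactly.

suppressMessages(library(sigbenefit))

X_sim <- read_spectrum("results/sim/spectrum_sbs96.tsv", "SBS-96")
vcfs <- list.files("results/sim/variants", pattern = "\\.vcf$",
                   full.names = TRUE)
samples <- sub("\\.vcf$", "", basename(vcfs))
variants <- do.call(rbind, Map(read_variants, vcfs, samples))
X_ext <- build_spectrum(variants, "results/sim/variants/reference.fa",
                        samples = samples)
write_matrix("results/sim/spectrum_extracted.tsv", X_ext)

stopifnot(all(X_ext[, colnames(X_sim)] == X_sim[samples, ]))
cat(sprintf("extracted spectra for %d patients (%d variants): identical to the simulated counts\n",
            length(samples), nrow(variants)))
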