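#!/usr/bin/env Rscript
# Step 1: simulate a truth landscape at the study's cohort scale and emit
# caller-native output files (CNVnator tables, DELLY-style VCF, PennCNV
# rawcnv, array QC) under results/sim/. The moderate noise preset gives
# each platform independent false positives, misses and breakpoint jitter.

suppressPackageStartupMessages(library(cnvrcons))

seed <- 2024
co <- cohort(547, 38, 36)
truth <- simulate_truth(n_loci = 60, freq_range = c(0.03, 0.5), seed = seed)
truth <- assign_carriers(truth, unique(c(co$genotyped, co$sequenced)),
                         seed = seed + 1)
files <- emit_caller_files(truth, co, noise_preset("moderate"),
                           out_dir = "results/sim", seed = seed + 2)

cat("Simulated", nrow(truth), "truth loci on", length(unique(truth$chrom)),
    "autosomes;", sum(lengths(truth$carriers)), "carrier-locus pairs.\n")
cat("Emitted calls:", paste(names(files$n_calls), files$n_calls,
                            collapse = ", "), "\n")
cat("Dual-platform animals see",
    sum(files$n_calls_dual[c("cnvnator", "delly")]), "WGS calls vs",
    files$n_calls_dual[["penncnv"]], "array calls.\n")
writeLines(c(co$genotyped, setdiff(co$sequenced, co$genotyped)),
           "results/sim/samples.txt")
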