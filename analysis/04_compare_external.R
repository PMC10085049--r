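#!/usr/bin/env Rscript
# Step 4: compare the unique high-confidence set against an external-style
# CNVR catalogue. The catalogue here is synthetic (the simulation uses a
# synthetic genome, so no real repository coordinates apply): three mock
# "studies" re-report a subset of the truth loci with jittered breakpoints
# plus study-specific extra regions, which is how published catalogues
# disagree in practice. Two regions are considered equal at >= 50%
# reciprocal overlap.

suppressPackageStartupMessages(library(cnvrcons))

set.seed(77)
truth <- read_truth_table("results/sim/truth.tsv")
studies <- lapply(1:3, function(k) {
  keep <- truth[runif(nrow(truth)) < 0.5, ]
  jit <- sample(-3000:3000, nrow(keep), replace = TRUE)
  extra_start <- sample.int(45e6, 12)
  data.frame(
    chrom = c(keep$chrom, as.character(sample(1:5, 12, replace = TRUE))),
    start = c(pmax(1, keep$start + jit), extra_start),
    end = c(keep$end + jit, extra_start + sample.int(2e5, 12) + 999),
    cnv_type = c(keep$cnv_type, rep("UNKNOWN", 12)),
    study_id = paste0("study", k)
  )
})
catalogue <- do.call(rbind, studies)
write_external_cnvr(catalogue, "results/tables/external_catalogue.tsv")

ext <- build_external_set(read_external_cnvr("results/tables/external_catalogue.tsv"))
uni <- read_cnvr_bed("results/pipeline/cnvr_unique.bed", kind = "UNIQUE")
res <- match_external(uni, ext)
write_external_report(res, "results/tables/external_overlap.tsv")

cat(sprintf("External catalogue: %d raw records -> %d merged regions.\n",
            nrow(catalogue), nrow(ext)))
cat(sprintf("%d/%d unique regions matched externally (unmatched fraction %.2f).\n",
            res$n_matched, res$n_query, res$unmatched_fraction))
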