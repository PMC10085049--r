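#!/usr/bin/env Rscript
# Step 5: overlap the unique high-confidence regions with gene and QTL
# intervals (>= 1 bp) and summarize the annotation the way CNVR surveys
# report it: annotated-region percentages, QTL by trait class, QTL by
# region type. Features here are synthetic intervals on the simulated
# genome; with real data this step consumes a BED6+ export of gene/QTL
# databases.

suppressPackageStartupMessages(library(cnvrcons))

set.seed(99)
genome <- default_genome()
n_genes <- 400
gstart <- sort(sample.int(49e6, n_genes))
genes <- genomic_features(
  chrom = sample(genome$chrom, n_genes, replace = TRUE), start = gstart,
  end = gstart + sample(2e3:2e5, n_genes, replace = TRUE),
  feature_id = sprintf("GENE%03d", seq_len(n_genes)),
  category = sample(c("GENE", "PSEUDOGENE"), n_genes, replace = TRUE,
                    prob = c(0.95, 0.05))
)
n_qtl <- 120
qstart <- sample.int(48e6, n_qtl)
qtl <- genomic_features(
  chrom = sample(genome$chrom, n_qtl, replace = TRUE), start = qstart,
  end = qstart + sample(5e4:1e6, n_qtl, replace = TRUE),
  feature_id = sprintf("QTL%03d", seq_len(n_qtl)), category = "QTL",
  subcategory = sample(c("production", "reproduction", "health", "milk",
                         "conformation"), n_qtl, replace = TRUE),
  p_value = runif(n_qtl)
)

uni <- read_cnvr_bed("results/pipeline/cnvr_unique.bed", kind = "UNIQUE")
ov <- overlap_features(uni, rbind(genes, qtl))
write_annotation(ov, "results/tables/annotation.tsv")
s <- summarize_annotation(ov, qtl_max_p = 0.05)

cat(sprintf("%d genes and %d pseudogenes annotated in %d regions (%.2f%%).\n",
            s$n_genes, s$n_pseudogenes, s$n_annotated_regions,
            s$pct_annotated_regions))
cat(sprintf("%d significant QTL in %d regions (%.2f%%).\n",
            s$n_qtl, s$n_qtl_regions, s$pct_qtl_regions))
print(s$qtl_by_class)
print(s$qtl_by_region_type)
write.table(s$qtl_by_class, "results/tables/qtl_by_class.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
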