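#!/usr/bin/env Rscript
# Core annotation: read the emitted gene models and candidate BED back
# through the parsers, classify every transcript (intergenic / intronic /
# overlapped, then the UTR-related refinement), assign neighbors and
# orientation, and summarize the positional distribution.

source("analysis/00_setup.R")

genome <- generate_genome(CFG)
nc <- generate_ncrnas(CFG, genome)  # regenerated for the sequence-bearing assembly

genes <- parse_gene_models(file.path(RESULTS, "data", "genes.gff3"), "gff3")
tx <- parse_intervals(file.path(RESULTS, "data", "ncrnas.bed"))

ann <- annotate_ncrnas(tx, genes, nc$assembly)
tsv(ann, "classification.tsv")

counts <- table(factor(ann$category, c("utr_related", "intergenic",
                                       "intronic", "overlapped")))
shares <- vapply(counts, percentage, numeric(1), denominator = sum(counts))
tsv(data.frame(category = names(counts), count = as.integer(counts),
               percent = shares), "category_counts.tsv")
cat("category counts:\n")
print(counts)
truth_class <- nc$truth$class[match(ann$transcript_id,
                                    nc$truth$transcript_id)]
cat(sprintf("agreement with planted classes: %.1f%%\n",
            100 * mean(ann$category == truth_class)))

hist_tab <- positional_histogram(ann, bin_edges = seq(0, 20000, by = 1000))
tsv(hist_tab, "positional_histogram.tsv")
prox <- select_gene_proximate(ann)
p3 <- prox$p3[prox$p3$orientation != "unknown", ]
cat(sprintf("gene-proximate (<=5 kb): %d at 5', %d at 3'\n",
            nrow(prox$p5), nrow(prox$p3)))
cat(sprintf("3'-proximate sense fraction: %.2f (planted skew %.2f)\n",
            mean(p3$orientation == "sense"), CFG$sense_skew_3p))
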