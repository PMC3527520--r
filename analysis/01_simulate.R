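#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a two-chromosome genome with spaced
# protein-coding gene models, 200 planted ncRNAs with known classes, and the
# ground-truth table. Emits the standard formats the pipeline reads.

source("analysis/00_setup.R")

genome <- generate_genome(CFG)
nc <- generate_ncrnas(CFG, genome)

dir.create(file.path(RESULTS, "data"), showWarnings = FALSE)
write_gff3(genome$genes, file.path(RESULTS, "data", "genes.gff3"))
write_intervals(genome$genes, file.path(RESULTS, "data", "genes.bed"))
write_intervals(nc$transcripts, file.path(RESULTS, "data", "ncrnas.bed"))
seqs <- Biostrings::DNAStringSet(nc$assembly$sequence)
Biostrings::writeXStringSet(seqs, file.path(RESULTS, "data", "genome.fa"))
utils::write.table(nc$truth, file.path(RESULTS, "data", "ground_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d chromosomes x %s bp, %d gene models\n",
            CFG$n_chroms, format(CFG$chrom_len, big.mark = ","),
            nrow(genome$genes)))
cat(sprintf("planted ncRNAs: %d (%s)\n", nrow(nc$transcripts),
            paste(sprintf("%s %d", names(table(nc$truth$class)),
                          table(nc$truth$class)), collapse = ", ")))
cat(sprintf("spliced: %d; declared strand unknown: %d\n",
            sum(nc$truth$spliced), sum(nc$transcripts$strand == "*")))
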