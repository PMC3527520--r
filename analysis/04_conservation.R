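#!/usr/bin/env Rscript
# Conservation layer: class-dependent per-base track, length-matched
# un-transcribed control regions, per-interval mean scores and the
# cumulative-frequency comparison across classes.

source("analysis/00_setup.R")

genome <- generate_genome(CFG)
nc <- generate_ncrnas(CFG, genome)
genes <- genome$genes
ann <- annotate_ncrnas(nc$transcripts, genes, nc$assembly)
track <- generate_score_track(CFG, nc$assembly, genes, nc$transcripts,
                              nc$truth)

transcribed <- transcript_set(
  c(paste0("gs_", genes$gene_id), nc$transcripts$transcript_id),
  c(genes$chrom, nc$transcripts$chrom), "*",
  c(lapply(seq_len(nrow(genes)), function(i)
      ivmat(genes$start[i], genes$end[i])),
    lapply(nc$transcripts$blocks, function(b)
      ivmat(b[1, 1], b[nrow(b), 2]))))
controls <- sample_untranscribed_controls(
  nc$assembly, transcribed,
  control_sampler_config(nrow(nc$transcripts), max_len = 2500,
                         seed = CFG$seed + 17L))
write_intervals(controls, file.path(RESULTS, "controls.bed"))

groups <- list(
  coding = transcript_set(paste0("cds_", genes$gene_id), genes$chrom,
                          genes$strand, genes$exons),
  utr_related = nc$transcripts[ann$category == "utr_related", ],
  intergenic = nc$transcripts[ann$category == "intergenic", ],
  intronic = nc$transcripts[ann$category == "intronic", ],
  control = controls)
scores <- lapply(groups, interval_mean_score, track = track)
tsv(do.call(rbind, lapply(names(scores), function(g)
  cbind(group = g, scores[[g]]))), "interval_scores.tsv")

cmp <- compare_conservation(scores)
tsv(cmp$pairs, "conservation_pairs.tsv")
tsv(do.call(rbind, lapply(names(cmp$ecdfs), function(g)
  cbind(group = g, cmp$ecdfs[[g]]))), "conservation_ecdf.tsv")

cat("group mean conservation, most conserved first:\n")
print(round(cmp$group_means, 3))
cat(sprintf("recovered ordering: %s\n", paste(cmp$ordering, collapse = " > ")))
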