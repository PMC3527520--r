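# The generator defines the study conditions; these tests pin its contracts:
# determinism, ground-truth coverage, valid gene models, and recoverable
# planted structure.

test_that("generators are deterministic under the seed", {
  cfg <- synth_config(seed = 17, n_ncrnas = 60L)
  g1 <- generate_genome(cfg); g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  n1 <- generate_ncrnas(cfg, g1); n2 <- generate_ncrnas(cfg, g2)
  expect_identical(n1, n2)
  t1 <- generate_score_track(cfg, n1$assembly, g1$genes, n1$transcripts,
                             n1$truth)
  t2 <- generate_score_track(cfg, n2$assembly, g2$genes, n2$transcripts,
                             n2$truth)
  expect_identical(t1, t2)
  expect_identical(generate_species_trio(cfg), generate_species_trio(cfg))
  expect_identical(generate_go_annotation(cfg), generate_go_annotation(cfg))
  # emitted files byte-identical
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_intervals(n1$transcripts, p1); write_intervals(n2$transcripts, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated gene models satisfy every invariant and fit the genome", {
  cfg <- synth_config(seed = 18)
  g <- generate_genome(cfg)
  genes <- g$genes
  expect_equal(nrow(genes), cfg$n_chroms * cfg$genes_per_chrom)
  expect_true(all(vapply(genes$exons, nrow, integer(1)) >= 2L))
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    expect_true(ex[1, 1] == genes$start[i] && ex[nrow(ex), 2] == genes$end[i])
    expect_true(all(diff(as.vector(t(ex))) > 0))  # sorted, disjoint
    expect_true(nrow(genes$utr5[[i]]) >= 1 && nrow(genes$utr3[[i]]) >= 1)
  }
  # genes do not overlap each other
  for (cn in unique(genes$chrom)) {
    gg <- genes[genes$chrom == cn, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  expect_equal(nchar(g$assembly$sequence[["chr1"]]), cfg$chrom_len)
})

test_that("planted classes are truthful under the per-base oracle", {
  cfg <- synth_config(seed = 19, n_ncrnas = 150L)
  g <- generate_genome(cfg)
  nc <- generate_ncrnas(cfg, g)
  lens <- g$assembly$chrom_lengths
  expect_equal(oracle_classify(nc$transcripts, g$genes, lens),
               ifelse(nc$truth$class == "utr_related", "intergenic",
                      nc$truth$class))
  expect_equal(nrow(nc$truth), nrow(nc$transcripts))  # truth covers all

  # pure intergenic config
  cfg1 <- synth_config(seed = 20, n_ncrnas = 50L,
                       class_props = c(intergenic = 1, intronic = 0,
                                       overlapped = 0, utr_related = 0))
  g1 <- generate_genome(cfg1)
  nc1 <- generate_ncrnas(cfg1, g1)
  expect_true(all(oracle_classify(nc1$transcripts, g1$genes,
                                  g1$assembly$chrom_lengths) == "intergenic"))
})

test_that("classification recovers at least 99% of planted labels", {
  cfg <- synth_config(seed = 22)
  g <- generate_genome(cfg)
  nc <- generate_ncrnas(cfg, g)
  ann <- annotate_ncrnas(nc$transcripts, g$genes, nc$assembly)
  expect_gte(mean(ann$category == nc$truth$class), 0.99)
  # neighbor and end recovery on rows where both sides name one
  has <- !is.na(ann$neighbor_gene_id) & !is.na(nc$truth$neighbor)
  expect_gte(mean(ann$neighbor_gene_id[has] == nc$truth$neighbor[has]), 0.99)
  expect_gte(mean(ann$gene_end[has] == nc$truth$gene_end[has]), 0.99)
})

test_that("splice motifs let strand inference recover planted strands", {
  cfg <- synth_config(seed = 23, n_ncrnas = 120L, spliced_fraction = 1,
                      unknown_strand_fraction = 1)
  g <- generate_genome(cfg)
  nc <- generate_ncrnas(cfg, g)
  spliced <- nc$truth$spliced
  inf <- infer_strand(nc$transcripts, nc$assembly)
  expect_true(all(inf$strand[spliced] == nc$truth$strand[spliced]))
  # unspliced records keep the declared (unknown) strand
  expect_true(all(inf$strand[!spliced] == "*"))
})

test_that("noncanonical introns leave the strand unknown", {
  cfg <- synth_config(seed = 24, n_ncrnas = 60L, spliced_fraction = 1,
                      noncanonical_fraction = 1, unknown_strand_fraction = 1)
  g <- generate_genome(cfg)
  nc <- generate_ncrnas(cfg, g)
  inf <- infer_strand(nc$transcripts, nc$assembly)
  # random dinucleotides essentially never form a unanimous canonical vote
  expect_gte(mean(inf$strand[nc$truth$spliced] == "*"), 0.9)
})

test_that("proximity bias is recovered within 3 binomial sd at n = 2000", {
  cfg <- synth_config(seed = 25, n_chroms = 5L, chrom_len = 500000L,
                      genes_per_chrom = 10L, n_ncrnas = 2000L,
                      class_props = c(intergenic = 1, intronic = 0,
                                      overlapped = 0, utr_related = 0),
                      ncrna_len = c(250L, 1500L), spliced_fraction = 0,
                      unknown_strand_fraction = 0)
  g <- generate_genome(cfg)
  nc <- generate_ncrnas(cfg, g)
  ann <- annotate_ncrnas(nc$transcripts, g$genes, nc$assembly)
  inter <- ann[ann$category == "intergenic", ]
  frac <- mean(inter$distance_bp <= 5000)
  tol <- 3 * sqrt(cfg$p_prox * (1 - cfg$p_prox) / nrow(inter))
  expect_lt(abs(frac - cfg$p_prox), tol)

  # 3' sense skew among proximate intergenic ncRNAs
  prox <- select_gene_proximate(relative_orientation(ann, nc$transcripts,
                                                     g$genes))
  p3 <- prox$p3[prox$p3$orientation != "unknown", ]
  skew <- mean(p3$orientation == "sense")
  tol3 <- 3 * sqrt(cfg$sense_skew_3p * (1 - cfg$sense_skew_3p) / nrow(p3))
  expect_lt(abs(skew - cfg$sense_skew_3p), tol3)
})

test_that("score track encodes class means and the uncovered fraction", {
  cfg <- synth_config(seed = 26, n_ncrnas = 80L, score_sd = 0,
                      uncovered_fraction = 0)
  g <- generate_genome(cfg)
  nc <- generate_ncrnas(cfg, g)
  tr <- generate_score_track(cfg, nc$assembly, g$genes, nc$transcripts,
                             nc$truth)
  # sd = 0: every exon base sits exactly at the coding mean
  ex1 <- g$genes$exons[[1]]
  v <- as.numeric(S4Vectors::window(tr$values[[g$genes$chrom[1]]],
                                    ex1[1, 1] + 1L, ex1[1, 2]))
  expect_true(all(v == cfg$class_means[["coding"]]))

  cfg2 <- synth_config(seed = 27, n_ncrnas = 40L, uncovered_fraction = 0.3)
  g2 <- generate_genome(cfg2)
  nc2 <- generate_ncrnas(cfg2, g2)
  tr2 <- generate_score_track(cfg2, nc2$assembly, g2$genes, nc2$transcripts,
                              nc2$truth)
  sc <- interval_mean_score(nc2$transcripts, tr2)
  expect_lt(abs(mean(sc$covered_fraction) - 0.7), 0.02)
})

test_that("species trio respects the homolog fraction at the extremes", {
  cfg1 <- synth_config(seed = 28, trio_n_genes = 12L, homolog_fraction = 1,
                       homolog_identity = 1, neighbor_seq_len = 200L)
  trio <- generate_species_trio(cfg1)
  sym <- symbol_intersection(lapply(trio$sets, function(s) s$symbol))
  expect_equal(length(sym$common), 12L)
  m <- sequence_conserved_neighbors(trio$sets$spA$gene_id,
                                    lapply(trio$sets[-1], `[[`, "gene_id"),
                                    trio$sequences)
  expect_true(all(m$conserved))

  cfg0 <- synth_config(seed = 29, trio_n_genes = 12L, homolog_fraction = 0,
                       neighbor_seq_len = 200L)
  trio0 <- generate_species_trio(cfg0)
  sym0 <- symbol_intersection(lapply(trio0$sets, function(s) s$symbol))
  expect_equal(length(sym0$common), 0L)
})

test_that("GO generator covers the universe and plants no signal at fold 1", {
  cfg <- synth_config(seed = 30)
  go <- generate_go_annotation(cfg)
  expect_true(all(go$annotation$gene %in% go$universe))
  expect_true(all(go$gene_list %in% go$universe))
  cfg1 <- synth_config(seed = 30, go_planted_fold = 1)
  go1 <- generate_go_annotation(cfg1)
  res <- enrich_terms(go1$gene_list, go1$annotation, background = go1$universe)
  planted <- res[res$term == go1$planted_term, ]
  expect_true(nrow(planted) == 0 || !planted$significant)
})

test_that("generated files are valid under the parsers", {
  cfg <- synth_config(seed = 32, n_ncrnas = 40L)
  g <- generate_genome(cfg)
  nc <- generate_ncrnas(cfg, g)
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gff3(g$genes, gff)
  write_intervals(nc$transcripts, bed)
  expect_equal(nrow(parse_gene_models(gff, "gff3")), nrow(g$genes))
  expect_equal(nrow(parse_intervals(bed)), nrow(nc$transcripts))
})
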