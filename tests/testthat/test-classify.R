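# Positional classification, neighbor assignment, UTR refinement, strand
# inference and positional summaries.

test_that("positional categories follow the exon/gene-body rules", {
  genes <- toy_genes()
  tx <- transcript_set(c("a", "b", "c"), "chr1", "+",
                       list(ivmat(1300L, 1500L),   # inside the intron
                            ivmat(1900L, 2100L),   # 100 bp exon overlap
                            ivmat(2500L, 2600L)))  # between genes
  ann <- classify_transcripts(tx, genes)
  expect_equal(ann$category, c("intronic", "overlapped", "intergenic"))
})

test_that("transcripts on chromosomes without genes are intergenic with a warning", {
  expect_warning(
    ann <- classify_transcripts(toy_tx("x", 0L, 100L, chrom = "chrZ"),
                                toy_genes()),
    "without gene")
  expect_equal(ann$category, "intergenic")
})

test_that("nearest gene takes the smallest gap with deterministic ties", {
  genes <- toy_genes()  # gA [1000,2000)+, gB [5000,6000)+
  near <- function(s, e) {
    tx <- toy_tx("t", s, e)
    assign_neighbors(classify_transcripts(tx, genes), tx, genes)
  }
  a <- near(2500L, 2600L)
  expect_equal(a$neighbor_gene_id, "gA")
  expect_equal(a$distance_bp, 500L)
  expect_equal(a$gene_end, "3prime")
  b <- near(4000L, 4100L)
  expect_equal(b$neighbor_gene_id, "gB")
  expect_equal(b$distance_bp, 900L)
  expect_equal(b$gene_end, "5prime")
  tie <- near(3400L, 3600L)  # gap 1400 to both
  expect_equal(tie$neighbor_gene_id, "gA")
})

test_that("nearest-gene distance is invariant under coordinate reflection", {
  set.seed(10)
  cfg <- synth_config(seed = 21, n_chroms = 1L, chrom_len = 400000L,
                      genes_per_chrom = 6L)
  genes <- generate_genome(cfg)$genes
  tx <- random_transcripts(60, c(chr1 = 400000L), max_len = 1500L)
  ann <- assign_neighbors(classify_transcripts(tx, genes), tx, genes)
  # reflect everything within the chromosome
  refl_genes <- gene_models(
    gene_id = genes$gene_id, symbol = genes$symbol, chrom = genes$chrom,
    strand = ifelse(genes$strand == "+", "-", "+"),
    start = 400000L - genes$end, end = 400000L - genes$start,
    exons = lapply(genes$exons, function(m) ivmat(400000L - m[, 2],
                                                  400000L - m[, 1])))
  refl_tx <- transcript_set(tx$transcript_id, tx$chrom, tx$strand,
                            lapply(tx$blocks, function(m)
                              ivmat(400000L - m[, 2], 400000L - m[, 1])))
  refl <- assign_neighbors(classify_transcripts(refl_tx, refl_genes),
                           refl_tx, refl_genes)
  keep <- !is.na(ann$neighbor_gene_id) & !is.na(refl$neighbor_gene_id)
  expect_equal(ann$distance_bp[keep], refl$distance_bp[keep])
  # gene_end is only defined for non-overlapping spans with a unique nearest
  # gene; restrict to rows where both runs agree on the neighbor and the
  # transcript is strictly clear of it
  strict <- keep & !is.na(ann$distance_bp) & ann$distance_bp > 0 &
    ann$neighbor_gene_id == refl$neighbor_gene_id
  strict[is.na(strict)] <- FALSE
  expect_equal(ann$gene_end[strict], refl$gene_end[strict])
})

test_that("UTR-related refinement uses the distance rule and the similarity branch", {
  genes <- toy_genes()
  near <- toy_tx("near", 2100L, 2600L)     # 100 bp from gA
  far <- toy_tx("far", 2600L, 3000L)       # 600 bp: utr_related by distance
  vfar <- toy_tx("vfar", 6500L, 7000L)     # > 1 kb from everything? gB ends 6000
  tx <- rbind(near, far, vfar)
  class(tx) <- c("transcript_set", "data.frame")
  ann <- assign_neighbors(classify_transcripts(tx, genes), tx, genes)
  out <- subclassify_utr_related(ann)
  expect_equal(out$category[out$transcript_id == "near"], "utr_related")
  expect_equal(out$category[out$transcript_id == "far"], "utr_related")
  expect_equal(out$category[out$transcript_id == "vfar"], "utr_related")

  # distance beyond 1 kb stays intergenic without sequence similarity
  distal <- toy_tx("d", 9000L, 9400L)
  ann2 <- assign_neighbors(classify_transcripts(distal, genes), distal, genes)
  expect_equal(subclassify_utr_related(ann2)$category, "intergenic")

  # similarity branch: transcript equal to an annotated UTR, planted 3 kb away
  utr_seq <- paste(rep("ACGT", 60), collapse = "")
  ann3 <- subclassify_utr_related(
    ann2, utr_seqs = c(u1 = utr_seq),
    tx_seqs = c(d = utr_seq))
  expect_equal(ann3$category, "utr_related")
})

test_that("splice-site dinucleotides vote on strand", {
  seq <- strsplit(paste(rep("A", 100), collapse = ""), "")[[1]]
  put <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    seq[at:(at + length(ch) - 1L)] <<- ch
  }
  # blocks [0,10),[30,40),[60,70): introns [10,30) and [40,60)
  put("GT", 11); put("AG", 29)
  put("GT", 41); put("AG", 59)
  asm <- genome_assembly(c(chr1 = 100L),
                         c(chr1 = paste(seq, collapse = "")))
  tx <- transcript_set("s", "chr1", "*",
                       list(ivmat(c(0L, 30L, 60L), c(10L, 40L, 70L))))
  expect_equal(infer_strand(tx, asm)$strand, "+")
  put("CT", 11); put("AC", 29); put("CT", 41); put("AC", 59)
  asm <- genome_assembly(c(chr1 = 100L), c(chr1 = paste(seq, collapse = "")))
  expect_equal(infer_strand(tx, asm)$strand, "-")
  put("GT", 11); put("AG", 29)  # now one + and one - intron
  asm <- genome_assembly(c(chr1 = 100L), c(chr1 = paste(seq, collapse = "")))
  expect_equal(infer_strand(tx, asm)$strand, "*")
})

test_that("orientation is relative to the neighbor gene strand", {
  genes <- toy_genes()
  tx <- transcript_set(c("s", "a", "u"), "chr1", c("+", "-", "*"),
                       list(ivmat(2500L, 2600L), ivmat(2600L, 2700L),
                            ivmat(2700L, 2800L)))
  ann <- relative_orientation(
    assign_neighbors(classify_transcripts(tx, genes), tx, genes), tx, genes)
  expect_equal(ann$orientation, c("sense", "antisense", "unknown"))
})

test_that("gene-proximate selection respects the 5-kb boundary and category", {
  ann <- data.frame(
    transcript_id = c("a", "b", "c", "d"),
    category = c("intergenic", "intergenic", "intergenic", "utr_related"),
    neighbor_gene_id = "g", distance_bp = c(4999L, 5001L, 5000L, 100L),
    gene_end = c("3prime", "3prime", "5prime", "3prime"),
    orientation = "sense", stringsAsFactors = FALSE)
  sel <- select_gene_proximate(ann)
  expect_equal(sort(c(sel$p5$transcript_id, sel$p3$transcript_id)),
               c("a", "c"))
})

test_that("positional histogram conserves counts and bins half-open", {
  ann <- data.frame(
    transcript_id = c("a", "b"), category = "intergenic",
    neighbor_gene_id = "g", distance_bp = c(500L, 1000L),
    gene_end = "3prime", orientation = c("sense", NA),
    stringsAsFactors = FALSE)
  h <- positional_histogram(ann, bin_edges = c(0, 1000, 5000))
  expect_equal(sum(h$count), 2L)
  expect_equal(h$count[h$bin_lo == 0 & h$gene_end == "3prime" &
                         h$orientation == "sense"], 1L)
  # 1000 lands in [1000,5000), and NA orientation counts as unknown
  expect_equal(h$count[h$bin_lo == 1000 & h$gene_end == "3prime" &
                         h$orientation == "unknown"], 1L)
})

test_that("classification matches the per-base oracle and is order-invariant", {
  set.seed(31)
  cfg <- synth_config(seed = 31, n_chroms = 1L, chrom_len = 95000L,
                      genes_per_chrom = 2L, ncrna_len = c(250L, 1200L),
                      n_exons = c(2L, 3L))
  genes <- generate_genome(cfg)$genes
  lens <- c(chr1 = 95000L)
  tx <- random_transcripts(300, lens, max_len = 2500L)
  ann <- classify_transcripts(tx, genes)
  expect_equal(ann$category, oracle_classify(tx, genes, lens))
  # order shuffle
  perm <- sample(nrow(tx))
  ann2 <- classify_transcripts(tx[perm, ], genes)
  expect_equal(ann2$category, ann$category[perm])
  # chromosome renaming
  tx3 <- tx; tx3$chrom <- "chrX"
  g3 <- genes; g3$chrom <- "chrX"
  expect_equal(classify_transcripts(tx3, g3)$category, ann$category)
  # partition: every transcript gets exactly one category
  expect_equal(nrow(ann), nrow(tx))
  expect_true(all(ann$category %in% c("intergenic", "intronic", "overlapped")))
})
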