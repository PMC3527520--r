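# Format boundaries: 1-based inclusive GFF3/wiggle and 0-based half-open BED/
# bedGraph both land on the internal 0-based half-open convention, and every
# writer round-trips through its parser.

test_that("GFF3 gene models convert 1-based inclusive to half-open", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=g1;Name=S1",
               "chr1\tx\texon\t101\t140\t.\t+\t.\tParent=g1",
               "chr1\tx\texon\t161\t200\t.\t+\t.\tParent=g1",
               "chr1\tx\tfive_prime_UTR\t101\t110\t.\t+\t.\tParent=g1"), path)
  g <- parse_gene_models(path, "gff3")
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  expect_equal(g$exons[[1]], ivmat(c(100L, 160L), c(140L, 200L)),
               ignore_attr = TRUE)
  expect_equal(g$utr5[[1]][1, ], c(start = 100L, end = 110L))
  expect_equal(g$end[1] - g$start[1], 100L)  # half-open length
})

test_that("BED12 gene models take thick as CDS and the rest as UTRs", {
  path <- withr::local_tempfile(fileext = ".bed")
  # blocks [999,1200) and [1800,2000); CDS [1050,1900)
  writeLines("chr1\t999\t2000\tg1|S1\t0\t+\t1050\t1900\t0\t2\t201,200\t0,801",
             path)
  g <- parse_gene_models(path, "bed12")
  expect_equal(g$start, 999L)
  expect_equal(g$end, 2000L)
  expect_equal(g$strand, "+")
  expect_equal(g$symbol, "S1")
  expect_equal(g$utr5[[1]][1, ], c(start = 999L, end = 1050L))
  expect_equal(g$utr3[[1]][1, ], c(start = 1900L, end = 2000L))
})

test_that("gene models without strand are rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tg1\t0\t.\t0\t100\t0\t1\t100,\t0,", path)
  expect_error(parse_gene_models(path, "bed12"), "strand")
})

test_that("BED6/BED12 interval parsing handles strand dots and blocks", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tx\t0\t.", path)
  tx <- parse_intervals(path)
  expect_equal(tx$strand, "*")
  expect_equal(tx$blocks[[1]], ivmat(100L, 200L), ignore_attr = TRUE)

  writeLines("chr1\t100\t300\ty\t0\t+\t100\t300\t0\t2\t50,50\t0,150", path)
  tx <- parse_intervals(path)
  expect_equal(tx$blocks[[1]], ivmat(c(100L, 250L), c(150L, 300L)),
               ignore_attr = TRUE)

  file.create(empty <- withr::local_tempfile(fileext = ".bed"))
  expect_equal(nrow(parse_intervals(empty)), 0L)
})

test_that("interval writer is deterministic and round-trips", {
  set.seed(7)
  asm_len <- c(chr1 = 50000L, chr2 = 40000L)
  tx <- random_transcripts(30, asm_len)
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_intervals(tx, p1)
  shuffled <- tx[sample(nrow(tx)), ]
  write_intervals(shuffled, p2)
  expect_identical(readLines(p1), readLines(p2))

  back <- parse_intervals(p1, source = "")
  ord <- order(tx$chrom, tx$start, tx$transcript_id, method = "radix")
  orig <- tx[ord, ]; rownames(orig) <- NULL; orig$source <- ""
  rownames(back) <- NULL
  expect_equal(back$transcript_id, orig$transcript_id)
  expect_equal(back$strand, orig$strand)
  expect_equal(unname(back$blocks), unname(orig$blocks), ignore_attr = TRUE)
})

test_that("unknown strand is written as a dot", {
  tx <- toy_tx("u1", 10L, 20L, strand = "*")
  path <- withr::local_tempfile(fileext = ".bed")
  write_intervals(tx, path)
  expect_equal(strsplit(readLines(path), "\t")[[1]][6], ".")
})

test_that("gene models round-trip through BED12 and GFF3", {
  cfg <- synth_config(seed = 11, n_chroms = 1L, genes_per_chrom = 5L)
  genes <- generate_genome(cfg)$genes
  for (fmt in c("bed12", "gff3")) {
    path <- withr::local_tempfile()
    if (fmt == "bed12") write_intervals(genes, path) else write_gff3(genes, path)
    back <- parse_gene_models(path, fmt)
    ord <- order(genes$chrom, genes$start, genes$gene_id, method = "radix")
    orig <- genes[ord, ]; rownames(orig) <- NULL; rownames(back) <- NULL
    expect_equal(back$gene_id, orig$gene_id)
    expect_equal(back$symbol, orig$symbol)
    expect_equal(back$strand, orig$strand)
    expect_equal(back$start, orig$start)
    expect_equal(back$end, orig$end)
    expect_equal(unname(back$exons), unname(orig$exons), ignore_attr = TRUE)
    expect_equal(unname(back$utr5), unname(orig$utr5), ignore_attr = TRUE)
    expect_equal(unname(back$utr3), unname(orig$utr3), ignore_attr = TRUE)
  }
})

test_that("bedGraph tracks cover listed bases and apply last-wins", {
  asm <- genome_assembly(c(chr1 = 10L))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t3\t1.5", path)
  tr <- parse_score_track(path, asm)
  v <- as.numeric(tr$values$chr1)
  expect_equal(v[1:3], rep(1.5, 3))
  expect_true(all(is.na(v[4:10])))

  writeLines(c("chr1\t0\t4\t1.0", "chr1\t2\t6\t9.0"), path)
  expect_warning(tr <- parse_score_track(path, asm), "last written")
  expect_equal(as.numeric(tr$values$chr1)[1:6], c(1, 1, 9, 9, 9, 9))

  writeLines("chr1\t5\t12\t1.0", path)
  expect_error(parse_score_track(path, asm), "beyond")
})

test_that("fixed-step wiggle is read as 1-based", {
  asm <- genome_assembly(c(chr1 = 10L))
  path <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "1", "2", "3"), path)
  tr <- parse_score_track(path, asm)
  v <- as.numeric(tr$values$chr1)
  expect_equal(v[1:3], c(1, 2, 3))
  expect_true(all(is.na(v[4:10])))
})

test_that("score tracks round-trip through bedGraph", {
  set.seed(5)
  asm <- genome_assembly(c(chr1 = 200L))
  vals <- rep(NA_real_, 200)
  vals[21:80] <- round(rnorm(60), 3)
  vals[151:170] <- 2.25
  tr <- score_track(list(chr1 = vals))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_score_track(tr, path)
  back <- parse_score_track(path, asm)
  expect_equal(as.numeric(back$values$chr1), vals)
})

test_that("assembly invariants are enforced", {
  expect_error(genome_assembly(c(chr1 = 0L)), "> 0")
  expect_error(genome_assembly(c(chr1 = 5L), c(chr1 = "ACGT")), "disagrees")
  expect_silent(genome_assembly(c(chr1 = 4L), c(chr1 = "ACGT")))
})

test_that("spliced sequences concatenate blocks and respect strand", {
  asm <- genome_assembly(c(chr1 = 12L), c(chr1 = "AAACCCGGGTTT"))
  tx <- transcript_set(c("p", "m"), "chr1", c("+", "-"),
                       list(ivmat(c(0L, 9L), c(3L, 12L)),
                            ivmat(c(0L, 9L), c(3L, 12L))))
  sq <- transcript_sequences(tx, asm)
  expect_equal(unname(sq["p"]), "AAATTT")
  expect_equal(unname(sq["m"]), "AAATTT")  # revcomp of AAATTT
})
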