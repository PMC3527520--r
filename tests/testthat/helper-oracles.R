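# Independent oracles, implemented with no shared code paths with the
# package: brute-force scans, quadratic pairings, explicit tail summations.

# affine-gap Smith-Waterman best score; a gap of length L costs go+(L-1)*ge
oracle_sw_score <- function(q, s, match = 1, mismatch = -1, go = 2, ge = 1) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- if (qv[i - 1] == sv[j - 1] && qv[i - 1] %in% c("A", "C", "G", "T"))
      match else mismatch
    X[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - ge)
    Y[i, j] <- max(M[i, j - 1] - go, Y[i, j - 1] - ge)
    M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc)
    best <- max(best, M[i, j], X[i, j], Y[i, j])
  }
  best
}

# enumerate every ATG in all six frames and walk to the next in-frame stop
oracle_longest_orf <- function(seq) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    for (off in 0:2) {
      i <- off + 1L
      while (i + 2L <= n) {
        if (paste(ch[i:(i + 2L)], collapse = "") == "ATG") {
          j <- i + 3L; aa <- 1L
          while (j + 2L <= n) {
            cod <- paste(ch[j:(j + 2L)], collapse = "")
            if (cod %in% c("TAA", "TAG", "TGA")) {
              if (aa > best) best <- aa
              break
            }
            aa <- aa + 1L; j <- j + 3L
          }
        }
        i <- i + 3L
      }
    }
  }
  best
}

# per-base membership classification: exon base => overlapped; otherwise all
# span bases inside one gene's span => intronic; otherwise intergenic
oracle_classify <- function(transcripts, genes, chrom_lengths) {
  exonic <- genebody <- lapply(chrom_lengths, function(l) logical(l))
  body_sets <- list()
  for (g in seq_len(nrow(genes))) {
    cn <- genes$chrom[g]
    ex <- genes$exons[[g]]
    for (j in seq_len(nrow(ex)))
      exonic[[cn]][(ex[j, 1] + 1L):ex[j, 2]] <- TRUE
    body_sets[[g]] <- list(chrom = cn, lo = genes$start[g], hi = genes$end[g])
  }
  vapply(seq_len(nrow(transcripts)), function(i) {
    cn <- transcripts$chrom[i]
    b <- transcripts$blocks[[i]]
    bases <- unlist(lapply(seq_len(nrow(b)), function(j)
      seq.int(b[j, 1] + 1L, b[j, 2])))
    if (cn %in% names(exonic) && any(exonic[[cn]][bases])) return("overlapped")
    s <- transcripts$start[i]; e <- transcripts$end[i]
    for (bs in body_sets)
      if (bs$chrom == cn && bs$lo <= s && e <= bs$hi) return("intronic")
    "intergenic"
  }, character(1))
}

# base-by-base accumulation over decoded per-chromosome vectors
oracle_interval_means <- function(intervals, track) {
  decoded <- lapply(track$values, as.numeric)
  vapply(seq_len(nrow(intervals)), function(i) {
    v <- decoded[[intervals$chrom[i]]]
    b <- intervals$blocks[[i]]
    tot <- 0; cnt <- 0L
    for (j in seq_len(nrow(b))) for (p in (b[j, 1] + 1L):b[j, 2]) {
      if (!is.na(v[p])) { tot <- tot + v[p]; cnt <- cnt + 1L }
    }
    if (cnt == 0L) NA_real_ else tot / cnt
  }, numeric(1))
}

# quadratic all-pairs span overlap
oracle_overlap_pairs <- function(ours, theirs) {
  out <- list()
  for (i in seq_len(nrow(ours))) for (j in seq_len(nrow(theirs))) {
    if (ours$chrom[i] == theirs$chrom[j] &&
        ours$start[i] < theirs$end[j] && theirs$start[j] < ours$end[i])
      out[[length(out) + 1L]] <- c(ours$transcript_id[i],
                                   theirs$transcript_id[j])
  }
  if (!length(out))
    return(data.frame(ours_id = character(0), theirs_id = character(0)))
  m <- do.call(rbind, out)
  data.frame(ours_id = m[, 1], theirs_id = m[, 2], stringsAsFactors = FALSE)
}

# explicit hypergeometric upper tail on the decremented table
oracle_ease <- function(k, n, K, N) {
  kp <- max(k - 1L, 0L)
  i <- kp:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# quick random transcript set on a fixed assembly
random_transcripts <- function(n, chrom_lengths, max_len = 3000L,
                               prefix = "rt") {
  chroms <- sample(names(chrom_lengths), n, replace = TRUE)
  len <- sample.int(max_len - 1L, n) + 1L
  start <- vapply(seq_len(n), function(i)
    sample.int(chrom_lengths[[chroms[i]]] - len[i], 1L) - 1L, integer(1))
  nblocks <- sample(1:3, n, replace = TRUE)
  blocks <- lapply(seq_len(n), function(i) {
    if (nblocks[i] == 1L || len[i] < 60L)
      return(cbind(start = start[i], end = start[i] + len[i]))
    cuts <- sort(sample.int(len[i] - 2L, 2L * (nblocks[i] - 1L)))
    bnd <- unique(c(0L, cuts, len[i]))
    if (length(bnd) %% 2 == 1) bnd <- bnd[-2]
    s <- bnd[seq(1, length(bnd) - 1, by = 2)]
    e <- bnd[seq(2, length(bnd), by = 2)]
    keep <- e > s
    cbind(start = start[i] + s[keep], end = start[i] + e[keep])
  })
  transcript_set(sprintf("%s%05d", prefix, seq_len(n)), chroms,
                 sample(c("+", "-", "*"), n, replace = TRUE), blocks)
}

# small deterministic gene set used across classification tests
toy_genes <- function() {
  gene_models(gene_id = c("gA", "gB"), symbol = c("A", "B"),
              chrom = c("chr1", "chr1"), strand = c("+", "+"),
              start = c(1000L, 5000L), end = c(2000L, 6000L),
              exons = list(ivmat(c(1000L, 1800L), c(1200L, 2000L)),
                           ivmat(5000L, 6000L)))
}

toy_tx <- function(id, start, end, chrom = "chr1", strand = "+") {
  transcript_set(id, chrom, strand, list(ivmat(start, end)))
}
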