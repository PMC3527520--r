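# Positional classification of candidate ncRNAs against protein-coding gene
# models, UTR-related refinement, neighbor-gene assignment, splice-motif
# strand inference and positional summaries.

#' Classification configuration
#'
#' @param utr_distance_bp intergenic transcripts at most this far from a gene
#'   span are re-labeled UTR-related (default 1000, the 1-kb rule).
#' @param proximate_distance_bp distance bound for "gene-proximate" selection
#'   (default 5000, the 5-kb flanking rule).
#' @param utr_identity_threshold,utr_coverage_threshold percent thresholds for
#'   the UTR sequence-similarity branch (defaults 90 and 50).
#' @return list of class `classify_config`.
#' @export
classify_config <- function(utr_distance_bp = 1000, proximate_distance_bp = 5000,
                            utr_identity_threshold = 90,
                            utr_coverage_threshold = 50) {
  stopifnot(utr_distance_bp >= 0, proximate_distance_bp >= 0,
            utr_identity_threshold >= 0, utr_coverage_threshold >= 0)
  structure(list(utr_distance_bp = utr_distance_bp,
                 proximate_distance_bp = proximate_distance_bp,
                 utr_identity_threshold = utr_identity_threshold,
                 utr_coverage_threshold = utr_coverage_threshold),
            class = "classify_config")
}

#' Classify transcripts as intergenic, intronic or overlapped
#'
#' Strand-agnostic positional rule: a transcript with any block overlapping
#' any exon base of any gene is `overlapped`; otherwise a transcript whose
#' span lies wholly inside some gene's span is `intronic`; everything else is
#' `intergenic` (pending UTR-related refinement). Transcripts on chromosomes
#' absent from the gene set are intergenic, with a warning.
#'
#' @param transcripts a `transcript_set`.
#' @param genes a `gene_models` table.
#' @return data.frame `ncrna_annotation`: transcript_id, category,
#'   neighbor_gene_id, distance_bp, gene_end, orientation (the last four `NA`
#'   at this stage).
#' @export
classify_transcripts <- function(transcripts, genes) {
  n <- nrow(transcripts)
  category <- rep("intergenic", n)
  if (n > 0L) {
    orphan <- !(transcripts$chrom %in% genes$chrom)
    if (any(orphan))
      warning(sum(orphan), " transcript(s) on chromosomes without gene models; ",
              "classified intergenic")
    bl <- blocks_granges(transcripts)
    ex <- exons_granges(genes)
    # seqlevel-mismatch warnings are expected here: orphan chromosomes were
    # already reported above
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(bl, ex, ignore.strand = TRUE))
    overlapped <- unique(bl$tx[S4Vectors::queryHits(hits)])
    category[overlapped] <- "overlapped"
    sp <- spans_granges(transcripts)
    gs <- spans_granges(genes)
    within <- suppressWarnings(
      GenomicRanges::findOverlaps(sp, gs, type = "within",
                                  ignore.strand = TRUE))
    intronic <- setdiff(unique(S4Vectors::queryHits(within)), overlapped)
    category[intronic] <- "intronic"
  }
  ann <- data.frame(transcript_id = transcripts$transcript_id,
                    category = category,
                    neighbor_gene_id = NA_character_,
                    distance_bp = NA_integer_,
                    gene_end = NA_character_,
                    orientation = NA_character_,
                    stringsAsFactors = FALSE)
  class(ann) <- c("ncrna_annotation", "data.frame")
  ann
}

#' Assign the nearest protein-coding gene to non-overlapping transcripts
#'
#' Distance is the gap between the transcript span and the gene span (0 when
#' abutting). `gene_end` records which end of the gene faces the transcript,
#' strand-aware: a transcript on the side of the gene's transcription start is
#' `5prime`, else `3prime`. Equidistant genes are broken by smaller start,
#' then lexicographic gene_id. Transcripts with no gene on their chromosome
#' keep an undefined neighbor.
#'
#' @param annotations output of [classify_transcripts()].
#' @param transcripts the matching `transcript_set`.
#' @param genes a `gene_models` table.
#' @return `annotations` with neighbor_gene_id, distance_bp, gene_end filled
#'   for intergenic (and later UTR-related) rows.
#' @export
assign_neighbors <- function(annotations, transcripts, genes) {
  stopifnot(identical(annotations$transcript_id, transcripts$transcript_id))
  todo <- which(annotations$category %in% c("intergenic", "utr_related"))
  for (i in todo) {
    cand <- which(genes$chrom == transcripts$chrom[i])
    if (!length(cand)) next
    s <- transcripts$start[i]; e <- transcripts$end[i]
    gap <- pmax(genes$start[cand] - e, s - genes$end[cand], 0L)
    ord <- order(gap, genes$start[cand], genes$gene_id[cand], method = "radix")
    j <- cand[ord[1L]]
    annotations$neighbor_gene_id[i] <- genes$gene_id[j]
    annotations$distance_bp[i] <- gap[ord[1L]]
    upstream <- e <= genes$start[j]  # transcript left of the gene
    annotations$gene_end[i] <-
      if ((upstream && genes$strand[j] == "+") ||
          (!upstream && genes$strand[j] == "-")) "5prime" else "3prime"
  }
  annotations
}

#' Refine intergenic transcripts into UTR-related RNAs
#'
#' An intergenic transcript becomes `utr_related` iff its distance to the
#' nearest gene is at most `cfg$utr_distance_bp`, or its best local alignment
#' against any supplied UTR sequence exceeds the configured identity and
#' coverage thresholds. Remaining intergenic transcripts are the stringent
#' ("bona fide") intergenic set.
#'
#' @param annotations neighbor-bearing annotations ([assign_neighbors()]).
#' @param utr_seqs optional named character vector of UTR sequences.
#' @param tx_seqs optional named character vector of transcript sequences
#'   (required when `utr_seqs` is given).
#' @param cfg a [classify_config()].
#' @return annotations with `utr_related` rows re-labeled.
#' @export
subclassify_utr_related <- function(annotations, utr_seqs = NULL,
                                    tx_seqs = NULL, cfg = classify_config()) {
  inter <- which(annotations$category == "intergenic")
  near <- inter[!is.na(annotations$distance_bp[inter]) &
                  annotations$distance_bp[inter] <= cfg$utr_distance_bp]
  annotations$category[near] <- "utr_related"
  if (!is.null(utr_seqs) && length(utr_seqs)) {
    rest <- setdiff(inter, near)
    if (length(rest) && is.null(tx_seqs))
      stop("transcript sequences required for the UTR similarity branch")
    missing_seq <- setdiff(annotations$transcript_id[rest], names(tx_seqs))
    if (length(missing_seq))
      stop("missing sequence for: ", paste(missing_seq, collapse = ", "))
    for (i in rest) {
      q <- tx_seqs[[annotations$transcript_id[i]]]
      for (u in utr_seqs) {
        st <- local_alignment_stats(q, u)
        if (st$identity > cfg$utr_identity_threshold &&
            st$coverage > cfg$utr_coverage_threshold) {
          annotations$category[i] <- "utr_related"
          break
        }
      }
    }
  }
  annotations
}

#' Infer transcript strand from splice-site dinucleotides
#'
#' For each intron of a spliced transcript the terminal dinucleotides vote:
#' `GT..AG` for `+`, `CT..AC` for `-` (the reverse complement). A unanimous
#' vote sets the strand; conflicting or absent canonical motifs leave it
#' unknown. Introns shorter than 4 bp abstain. Single-block transcripts keep
#' their declared strand.
#'
#' @param transcripts a `transcript_set`.
#' @param assembly a `genome_assembly` with sequence.
#' @return `transcripts` with updated `strand`.
#' @export
infer_strand <- function(transcripts, assembly) {
  if (is.null(assembly$sequence)) stop("assembly carries no sequence")
  for (i in seq_len(nrow(transcripts))) {
    b <- transcripts$blocks[[i]]
    if (nrow(b) < 2L) next
    chromseq <- assembly$sequence[[transcripts$chrom[i]]]
    votes <- character(0)
    for (j in seq_len(nrow(b) - 1L)) {
      is_ <- b[j, 2]; ie <- b[j + 1L, 1]  # intron [is_, ie)
      if (ie - is_ < 4L) next
      donor <- substring(chromseq, is_ + 1L, is_ + 2L)
      accept <- substring(chromseq, ie - 1L, ie)
      if (donor == "GT" && accept == "AG") votes <- c(votes, "+")
      else if (donor == "CT" && accept == "AC") votes <- c(votes, "-")
      else votes <- c(votes, "?")
    }
    votes <- votes[votes != "?"]
    transcripts$strand[i] <-
      if (length(votes) && length(unique(votes)) == 1L) votes[1L] else "*"
  }
  transcripts
}

#' Relative orientation of transcripts to their neighbor genes
#'
#' `sense` when transcript and neighbor strand agree, `antisense` when they
#' are opposite, `unknown` when the transcript strand is unknown.
#'
#' @param annotations neighbor-bearing annotations.
#' @param transcripts the matching `transcript_set` (strands resolved).
#' @param genes a `gene_models` table.
#' @return annotations with `orientation` filled.
#' @export
relative_orientation <- function(annotations, transcripts, genes) {
  stopifnot(identical(annotations$transcript_id, transcripts$transcript_id))
  gstrand <- stats::setNames(genes$strand, genes$gene_id)
  has <- !is.na(annotations$neighbor_gene_id)
  ts <- transcripts$strand[has]
  gs <- gstrand[annotations$neighbor_gene_id[has]]
  annotations$orientation[has] <-
    ifelse(ts == "*", "unknown", ifelse(ts == gs, "sense", "antisense"))
  annotations
}

#' Run the full annotation: category, neighbor, orientation
#'
#' Convenience wrapper chaining [classify_transcripts()],
#' [assign_neighbors()], [subclassify_utr_related()] (distance rule, plus the
#' similarity branch when UTR sequences are supplied), strand inference when
#' the assembly carries sequence, and [relative_orientation()].
#'
#' @inheritParams classify_transcripts
#' @param assembly optional `genome_assembly` with sequence (strand
#'   inference for unknown-strand spliced transcripts).
#' @param utr_seqs,tx_seqs optional sequences for the UTR similarity branch.
#' @param cfg a [classify_config()].
#' @return list with `annotations` and `transcripts` (strand-resolved).
#' @export
annotate_ncrnas <- function(transcripts, genes, assembly = NULL,
                            utr_seqs = NULL, tx_seqs = NULL,
                            cfg = classify_config()) {
  if (!is.null(assembly) && !is.null(assembly$sequence)) {
    unknown <- transcripts$strand == "*"
    inferred <- infer_strand(transcripts, assembly)
    transcripts$strand[unknown] <- inferred$strand[unknown]
  }
  ann <- classify_transcripts(transcripts, genes)
  ann <- assign_neighbors(ann, transcripts, genes)
  ann <- subclassify_utr_related(ann, utr_seqs, tx_seqs, cfg)
  ann <- relative_orientation(ann, transcripts, genes)
  ann
}

#' Select gene-proximate stringent intergenic ncRNAs
#'
#' Intergenic (not UTR-related) annotations with a neighbor at distance at
#' most `cfg$proximate_distance_bp`, partitioned by the gene end they face.
#'
#' @param annotations finalized annotations.
#' @param cfg a [classify_config()].
#' @return list with data.frames `p5` and `p3`.
#' @export
select_gene_proximate <- function(annotations, cfg = classify_config()) {
  sel <- annotations$category == "intergenic" &
    !is.na(annotations$distance_bp) &
    annotations$distance_bp <= cfg$proximate_distance_bp
  keep <- annotations[sel, , drop = FALSE]
  list(p5 = keep[keep$gene_end == "5prime", , drop = FALSE],
       p3 = keep[keep$gene_end == "3prime", , drop = FALSE])
}

#' Positional histogram of neighbor distances
#'
#' Counts per half-open distance bin, split by gene end and orientation.
#' Distances beyond the last edge fall in an overflow bin.
#'
#' @param annotations neighbor-bearing annotations (rows without a neighbor
#'   are dropped).
#' @param bin_edges increasing numeric distances in bp (default 1-kb bins,
#'   0 to 50 kb).
#' @return data.frame with bin_lo, bin_hi, gene_end, orientation, count;
#'   counts sum to the number of neighbor-bearing input rows.
#' @export
positional_histogram <- function(annotations,
                                 bin_edges = seq(0, 50000, by = 1000)) {
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges, strictly = TRUE))
  keep <- annotations[!is.na(annotations$neighbor_gene_id), , drop = FALSE]
  if (nrow(keep) && any(keep$distance_bp < bin_edges[1L]))
    stop("distances below the first bin edge")
  edges <- c(bin_edges, Inf)
  lo <- edges[-length(edges)]; hi <- edges[-1L]
  bin <- findInterval(keep$distance_bp, edges, rightmost.closed = FALSE)
  orient <- ifelse(is.na(keep$orientation), "unknown", keep$orientation)
  grid <- expand.grid(bin = seq_along(lo),
                      gene_end = c("5prime", "3prime"),
                      orientation = c("sense", "antisense", "unknown"),
                      stringsAsFactors = FALSE)
  key <- paste(bin, keep$gene_end, orient)
  tab <- table(key)
  grid$count <- as.integer(tab[paste(grid$bin, grid$gene_end, grid$orientation)])
  grid$count[is.na(grid$count)] <- 0L
  data.frame(bin_lo = lo[grid$bin], bin_hi = hi[grid$bin],
             gene_end = grid$gene_end, orientation = grid$orientation,
             count = grid$count, stringsAsFactors = FALSE)
}
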