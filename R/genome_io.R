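#' @importFrom methods is
#' @importFrom utils read.table
NULL

# ---- internal coordinate convention -----------------------------------------
# Every container in this package stores 0-based half-open intervals [start,end).
# Conversion to/from 1-based inclusive (GFF3, wiggle) happens only inside the
# parse_* / write_* functions in this file.

#' Construct a genome assembly
#'
#' Chromosome names, lengths and (optionally) nucleotide sequences. Sequences,
#' when supplied, must match the declared lengths exactly.
#'
#' @param chrom_lengths named integer vector, chromosome -> length in bp.
#' @param sequence optional named character vector of nucleotide strings.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(chrom_lengths, sequence = NULL) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must be uniquely named by chromosome")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  if (!is.null(sequence)) {
    if (!all(names(chrom_lengths) %in% names(sequence)))
      stop("sequence missing for some chromosomes")
    sequence <- sequence[names(chrom_lengths)]
    if (any(nchar(sequence) != chrom_lengths))
      stop("sequence length disagrees with declared chromosome length")
  }
  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = chrom_lengths,
                 sequence = sequence),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d chromosome(s), %s bp total, sequence: %s\n",
              length(x$chrom_names),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ","),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Build a sorted interval matrix
#'
#' Two-column integer matrix of 0-based half-open `[start,end)` rows, sorted
#' by start; the element type used for exon, UTR and block lists throughout
#' the package.
#'
#' @param start,end integer vectors of equal length.
#' @return integer matrix with columns `start`, `end`.
#' @export
ivmat <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, 1]), , drop = FALSE]
}

validate_ivmat <- function(m, what = "interval") {
  if (nrow(m) == 0L) return(invisible(m))
  if (any(m[, 2] <= m[, 1])) stop(what, " with non-positive width")
  if (nrow(m) > 1L && any(m[-1L, 1] < m[-nrow(m), 2]))
    stop(what, "s overlap or are unsorted")
  invisible(m)
}

#' Build a gene-model table
#'
#' @param gene_id,symbol,chrom,strand,start,end vectors, one entry per gene;
#'   coordinates 0-based half-open, strand "+" or "-".
#' @param exons,utr5,utr3 lists of two-column integer matrices
#'   (`start`,`end`), one per gene; UTR lists may hold empty matrices.
#' @return data.frame of class `gene_models`.
#' @export
gene_models <- function(gene_id, symbol, chrom, strand, start, end,
                        exons, utr5 = NULL, utr3 = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  if (!all(strand %in% c("+", "-")))
    stop("protein-coding gene models require a known strand")
  empty <- ivmat(integer(0), integer(0))
  if (is.null(utr5)) utr5 <- rep(list(empty), n)
  if (is.null(utr3)) utr3 <- rep(list(empty), n)
  df <- data.frame(gene_id = as.character(gene_id),
                   symbol = as.character(symbol),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  df$utr5 <- utr5
  df$utr3 <- utr3
  for (i in seq_len(n)) {
    ex <- validate_ivmat(df$exons[[i]], "exon")
    if (nrow(ex) == 0L) stop("gene ", df$gene_id[i], " has no exons")
    if (ex[1, 1] < df$start[i] || ex[nrow(ex), 2] > df$end[i])
      stop("exon outside gene span for ", df$gene_id[i])
    for (u in list(df$utr5[[i]], df$utr3[[i]])) {
      if (nrow(u) == 0L) next
      inside <- vapply(seq_len(nrow(u)), function(j)
        any(ex[, 1] <= u[j, 1] & u[j, 2] <= ex[, 2]), logical(1))
      if (!all(inside)) stop("UTR interval outside exons for ", df$gene_id[i])
    }
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Build a transcript set
#'
#' @param transcript_id,chrom,strand vectors; strand may be `"+"`, `"-"` or
#'   `"*"` (unknown).
#' @param blocks list of two-column integer matrices, 0-based half-open.
#' @param source free-text origin tag.
#' @return data.frame of class `transcript_set` with derived `start`/`end`.
#' @export
transcript_set <- function(transcript_id, chrom, strand, blocks, source = "") {
  if (anyDuplicated(transcript_id)) stop("duplicate transcript_id")
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be +, - or *")
  for (b in blocks) validate_ivmat(b, "block")
  df <- data.frame(transcript_id = as.character(transcript_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = vapply(blocks, function(b) b[1L, 1L], integer(1)),
                   end = vapply(blocks, function(b) b[nrow(b), 2L], integer(1)),
                   source = rep_len(as.character(source), length(transcript_id)),
                   stringsAsFactors = FALSE)
  df$blocks <- blocks
  class(df) <- c("transcript_set", "data.frame")
  df
}

empty_transcript_set <- function(source = "") {
  transcript_set(character(0), character(0), character(0), list(), source)
}

# span GRanges for a transcript_set or gene_models table
spans_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

blocks_granges <- function(tx) {
  n <- vapply(tx$blocks, nrow, integer(1))
  if (length(n) == 0L || sum(n) == 0L) return(GenomicRanges::GRanges())
  starts <- unlist(lapply(tx$blocks, function(b) b[, 1]), use.names = FALSE)
  ends <- unlist(lapply(tx$blocks, function(b) b[, 2]), use.names = FALSE)
  GenomicRanges::GRanges(rep(tx$chrom, n),
                         IRanges::IRanges(start = starts + 1L, end = ends),
                         tx = rep(seq_along(tx$blocks), n))
}

exons_granges <- function(genes) {
  n <- vapply(genes$exons, nrow, integer(1))
  starts <- unlist(lapply(genes$exons, function(b) b[, 1]), use.names = FALSE)
  ends <- unlist(lapply(genes$exons, function(b) b[, 2]), use.names = FALSE)
  GenomicRanges::GRanges(rep(genes$chrom, n),
                         IRanges::IRanges(start = starts + 1L, end = ends),
                         gene = rep(seq_len(nrow(genes)), n))
}

# ---- parsers ----------------------------------------------------------------

first_or_na <- function(cl) {
  v <- as.list(cl)
  vapply(v, function(x) if (length(x)) x[[1]] else NA_character_, character(1))
}

#' Parse protein-coding gene models
#'
#' Reads GFF3 (`gene`/`exon`/`five_prime_UTR`/`three_prime_UTR` features keyed
#' by `ID`/`Parent`) or BED12 (thick region = CDS; block parts outside the
#' thick region become UTRs, 5' vs 3' decided by strand). Coordinates are
#' converted to the internal 0-based half-open convention. Genes without a
#' declared strand are rejected.
#'
#' @param path file path.
#' @param dialect `"gff3"` or `"bed12"`.
#' @return A `gene_models` table.
#' @export
parse_gene_models <- function(path, dialect = c("gff3", "bed12")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") parse_gene_models_gff3(path) else parse_gene_models_bed12(path)
}

parse_gene_models_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  type <- as.character(gr$type)
  parent <- first_or_na(gr$Parent)
  gi <- which(type == "gene")
  if (!length(gi)) stop("no gene features in ", path)
  gene_id <- gr$ID[gi]
  if (anyNA(gene_id)) stop("gene feature without ID in ", path)
  strand <- as.character(GenomicRanges::strand(gr)[gi])
  if (any(strand == "*")) stop("gene with missing strand: ",
                               paste(gene_id[strand == "*"], collapse = ", "))
  sym <- gr$Name[gi]
  sym[is.na(sym)] <- gene_id[is.na(sym)]
  pick <- function(what, id) {
    j <- which(type == what & parent == id)
    ivmat(GenomicRanges::start(gr)[j] - 1L, GenomicRanges::end(gr)[j])
  }
  gene_models(gene_id = gene_id, symbol = sym,
              chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
              strand = strand,
              start = GenomicRanges::start(gr)[gi] - 1L,
              end = GenomicRanges::end(gr)[gi],
              exons = lapply(gene_id, function(id) pick("exon", id)),
              utr5 = lapply(gene_id, function(id) pick("five_prime_UTR", id)),
              utr3 = lapply(gene_id, function(id) pick("three_prime_UTR", id)))
}

parse_gene_models_bed12 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("BED parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(gr$blocks)) stop("BED12 (with blocks) required for gene models")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("gene with missing strand in ", path)
  name <- gr$name
  parts <- strsplit(name, "|", fixed = TRUE)
  gene_id <- vapply(parts, `[[`, character(1), 1L)
  symbol <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else p[[1]],
                   character(1))
  start0 <- GenomicRanges::start(gr) - 1L
  exons <- lapply(seq_along(gr), function(i) {
    b <- gr$blocks[[i]]  # 1-based, relative to span
    ivmat(start0[i] + IRanges::start(b) - 1L, start0[i] + IRanges::end(b))
  })
  thick_s <- GenomicRanges::start(gr$thick) - 1L
  thick_e <- GenomicRanges::end(gr$thick)
  utr_left <- utr_right <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    ex <- exons[[i]]
    clip <- function(lo, hi) {
      s <- pmax(ex[, 1], lo); e <- pmin(ex[, 2], hi)
      keep <- e > s
      ivmat(s[keep], e[keep])
    }
    utr_left[[i]] <- clip(start0[i], thick_s[i])
    utr_right[[i]] <- clip(thick_e[i], GenomicRanges::end(gr)[i])
  }
  plus <- strand == "+"
  utr5 <- utr3 <- vector("list", length(gr))
  utr5[plus] <- utr_left[plus];  utr5[!plus] <- utr_right[!plus]
  utr3[plus] <- utr_right[plus]; utr3[!plus] <- utr_left[!plus]
  gene_models(gene_id = gene_id, symbol = symbol,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              strand = strand,
              start = start0, end = GenomicRanges::end(gr),
              exons = exons, utr5 = utr5, utr3 = utr3)
}

#' Parse candidate transcript intervals from BED
#'
#' BED6 or BED12; a `"."` strand becomes unknown (`"*"`); BED12 blocks become
#' transcript blocks, BED6 records a single block spanning the record.
#'
#' @param path BED file.
#' @param source origin tag stored on every record (default: file name).
#' @return A `transcript_set`.
#' @export
parse_intervals <- function(path, source = basename(path)) {
  if (file.size(path) == 0) return(empty_transcript_set(source))
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("BED parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0L) return(empty_transcript_set(source))
  start0 <- GenomicRanges::start(gr) - 1L
  if (!is.null(gr$blocks)) {
    blocks <- lapply(seq_along(gr), function(i) {
      b <- gr$blocks[[i]]
      m <- ivmat(start0[i] + IRanges::start(b) - 1L, start0[i] + IRanges::end(b))
      if (m[1, 1] != start0[i] || m[nrow(m), 2] != GenomicRanges::end(gr)[i])
        stop("BED12 blocks inconsistent with span for record ", gr$name[i])
      m
    })
  } else {
    blocks <- lapply(seq_along(gr), function(i)
      ivmat(start0[i], GenomicRanges::end(gr)[i]))
  }
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) nm <- paste0("iv", seq_along(gr))
  transcript_set(transcript_id = nm,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 strand = as.character(GenomicRanges::strand(gr)),
                 blocks = blocks, source = source)
}

#' Parse a per-base conservation score track
#'
#' Accepts bedGraph or fixed/variable-step wiggle. Bases inside listed
#' intervals are covered at the stated score; every other base is uncovered.
#' When records overlap, the last written record wins and a warning is issued.
#'
#' @param path track file.
#' @param assembly a [genome_assembly()]; intervals beyond a chromosome bound
#'   are a validation error.
#' @return An object of class `score_track`: per chromosome a numeric
#'   run-length vector with `NA` at uncovered bases.
#' @export
parse_score_track <- function(path, assembly) {
  fmt <- detect_track_format(path)
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("track parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  score_track_from_granges(gr, assembly)
}

detect_track_format <- function(path) {
  for (ln in readLines(path, n = 50L)) {
    if (grepl("^(fixedStep|variableStep)", ln)) return("wig")
  }
  "bedGraph"
}

score_track_from_granges <- function(gr, assembly) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  bad <- !(chrom %in% assembly$chrom_names)
  if (any(bad)) stop("track interval on unknown chromosome: ",
                     paste(unique(chrom[bad]), collapse = ", "))
  if (any(GenomicRanges::end(gr) > assembly$chrom_lengths[chrom]) ||
      any(GenomicRanges::start(gr) < 1L))
    stop("track interval beyond chromosome length")
  values <- lapply(assembly$chrom_names, function(cn)
    S4Vectors::Rle(NA_real_, assembly$chrom_lengths[[cn]]))
  names(values) <- assembly$chrom_names
  overlapped <- FALSE
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    s <- GenomicRanges::start(gr)[idx]; e <- GenomicRanges::end(gr)[idx]
    cov <- IRanges::coverage(IRanges::IRanges(s, e),
                             width = assembly$chrom_lengths[[cn]])
    if (any(S4Vectors::runValue(cov) > 1L)) overlapped <- TRUE
    v <- values[[cn]]
    for (k in seq_along(idx))   # file order: last written value wins
      v[s[k]:e[k]] <- gr$score[idx[k]]
    values[[cn]] <- v
  }
  if (overlapped)
    warning("overlapping track records: last written value wins")
  structure(list(values = values, chrom_lengths = assembly$chrom_lengths),
            class = "score_track")
}

#' Build a score track directly from per-base vectors
#'
#' @param values named list, chromosome -> numeric vector (NA = uncovered).
#' @return A `score_track`.
#' @export
score_track <- function(values) {
  structure(list(values = lapply(values, S4Vectors::Rle),
                 chrom_lengths = stats::setNames(
                   vapply(values, length, integer(1)), names(values))),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cov <- vapply(x$values, function(v) sum(!is.na(v)), numeric(1))
  cat(sprintf("<score_track> %d chromosome(s); %.1f%% of %s bp covered\n",
              length(x$values),
              100 * sum(cov) / sum(as.numeric(x$chrom_lengths)),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ",")))
  invisible(x)
}

# ---- writers ----------------------------------------------------------------

bed12_line <- function(chrom, start, end, name, strand, thick_s, thick_e, blocks) {
  paste(chrom, start, end, name, 0L,
        if (strand == "*") "." else strand,
        thick_s, thick_e, "0", nrow(blocks),
        paste0(paste(blocks[, 2] - blocks[, 1], collapse = ","), ","),
        paste0(paste(blocks[, 1] - start, collapse = ","), ","),
        sep = "\t")
}

#' Write transcripts or gene models as BED12
#'
#' Output is deterministic: records are sorted by (chrom, start, id) and an
#' unknown strand is written as `"."`. Gene models carry `gene_id|symbol` in
#' the name field and their CDS (span minus UTRs) as the thick region, so a
#' write/parse round trip is the identity.
#'
#' @param records a `transcript_set` or `gene_models` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(records, path) {
  if (inherits(records, "gene_models")) {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      utr <- rbind(records$utr5[[i]], records$utr3[[i]])
      ex <- records$exons[[i]]
      if (nrow(utr)) {
        cds_bases <- setdiff(unlist(lapply(seq_len(nrow(ex)), function(j)
          seq.int(ex[j, 1], ex[j, 2] - 1L))),
          unlist(lapply(seq_len(nrow(utr)), function(j)
            seq.int(utr[j, 1], utr[j, 2] - 1L))))
        thick_s <- min(cds_bases); thick_e <- max(cds_bases) + 1L
      } else {
        thick_s <- records$start[i]; thick_e <- records$end[i]
      }
      bed12_line(records$chrom[i], records$start[i], records$end[i],
                 paste(records$gene_id[i], records$symbol[i], sep = "|"),
                 records$strand[i], thick_s, thick_e, ex)
    }, character(1))
    ids <- records$gene_id
  } else {
    lines <- vapply(seq_len(nrow(records)), function(i)
      bed12_line(records$chrom[i], records$start[i], records$end[i],
                 records$transcript_id[i], records$strand[i],
                 records$start[i], records$end[i], records$blocks[[i]]),
      character(1))
    ids <- records$transcript_id
  }
  ord <- order(records$chrom, records$start, ids, method = "radix")
  writeLines(lines[ord], path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `exon` and UTR features keyed by `ID`/`Parent`, 1-based
#' inclusive per the GFF3 definition, sorted by (chrom, start, gene_id).
#'
#' @param genes a `gene_models` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  ord <- order(genes$chrom, genes$start, genes$gene_id, method = "radix")
  out <- "##gff-version 3"
  feat <- function(chrom, type, s, e, strand, attrs)
    paste(chrom, "lncclass", type, s + 1L, e, ".", strand, ".", attrs, sep = "\t")
  for (i in ord) {
    out <- c(out, feat(genes$chrom[i], "gene", genes$start[i], genes$end[i],
                       genes$strand[i],
                       sprintf("ID=%s;Name=%s", genes$gene_id[i], genes$symbol[i])))
    emit <- function(m, type) vapply(seq_len(nrow(m)), function(j)
      feat(genes$chrom[i], type, m[j, 1], m[j, 2], genes$strand[i],
           sprintf("Parent=%s", genes$gene_id[i])), character(1))
    out <- c(out, emit(genes$exons[[i]], "exon"))
    if (nrow(genes$utr5[[i]])) out <- c(out, emit(genes$utr5[[i]], "five_prime_UTR"))
    if (nrow(genes$utr3[[i]])) out <- c(out, emit(genes$utr3[[i]], "three_prime_UTR"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a score track as bedGraph
#'
#' Covered runs only; 0-based half-open per the bedGraph definition.
#'
#' @param track a `score_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  out <- character(0)
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    rl <- S4Vectors::runLength(v); rv <- S4Vectors::runValue(v)
    ends <- cumsum(rl); starts <- ends - rl  # 0-based half-open
    keep <- !is.na(rv)
    if (any(keep))
      out <- c(out, sprintf("%s\t%d\t%d\t%s", cn, starts[keep], ends[keep],
                            formatC(rv[keep], format = "g", digits = 15)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Extract the spliced sequence of transcripts
#'
#' Concatenates block sequences and reverse-complements on the minus strand;
#' unknown-strand transcripts are returned in genome orientation.
#'
#' @param tx a `transcript_set`.
#' @param assembly a `genome_assembly` with sequence.
#' @return named character vector of nucleotide strings.
#' @export
transcript_sequences <- function(tx, assembly) {
  if (is.null(assembly$sequence)) stop("assembly carries no sequence")
  out <- vapply(seq_len(nrow(tx)), function(i) {
    chromseq <- assembly$sequence[[tx$chrom[i]]]
    b <- tx$blocks[[i]]
    s <- paste(substring(chromseq, b[, 1] + 1L, b[, 2]), collapse = "")
    if (tx$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  stats::setNames(out, tx$transcript_id)
}
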