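# Screens that remove putative protein-coding transcripts from a candidate
# set: a local-alignment similarity screen against known transcripts and a
# six-frame ORF screen.

#' Screen configuration
#'
#' @param identity_threshold,coverage_threshold percent; a candidate is
#'   similarity-removed when some reference alignment exceeds both (default 90,
#'   matching the coverage >90%% / identity >90%% screen of the source
#'   pipeline's reference comparison).
#' @param orf_aa_threshold amino acids; candidates whose longest six-frame ORF
#'   reaches this length are removed as putative coding (default 100 aa, the
#'   conventional long-ORF cutoff for lncRNA screens).
#' @param match,mismatch,gap_open,gap_extend local-alignment scoring. A gap of
#'   length L costs `gap_open + (L-1) * gap_extend` (the first gap base pays
#'   the opening cost).
#' @return list of class `screen_config`.
#' @export
screen_config <- function(identity_threshold = 90, coverage_threshold = 90,
                          orf_aa_threshold = 100,
                          match = 1, mismatch = -1, gap_open = 2, gap_extend = 1) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 100,
            coverage_threshold >= 0, coverage_threshold <= 100,
            orf_aa_threshold >= 0, gap_open > 0, gap_extend > 0)
  structure(list(identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold,
                 orf_aa_threshold = orf_aa_threshold,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "screen_config")
}

# substitution matrix over ACGTN in which N never scores as a match
screen_submat <- function(match, mismatch) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- mismatch; m[, "N"] <- mismatch
  m
}

#' Best local alignment statistics between two nucleotide sequences
#'
#' Exact Smith-Waterman (via [Biostrings::pairwiseAlignment()]) under the
#' scoring in `cfg`. Identity is the percent of aligned columns that match;
#' coverage is the percent of the query length inside the aligned region.
#' `N` bases never count as matches.
#'
#' @param query,subject nucleotide strings (alphabet ACGTN), non-empty.
#' @param cfg a [screen_config()].
#' @return list with `query_id`-free fields `identity`, `coverage`,
#'   `aligned_length` (alignment columns) and `score`.
#' @export
local_alignment_stats <- function(query, subject, cfg = screen_config()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = screen_submat(cfg$match, cfg$mismatch),
    gapOpening = cfg$gap_open - cfg$gap_extend, gapExtension = cfg$gap_extend)
  ncol <- Biostrings::nchar(al)  # alignment columns incl. gaps
  if (BiocGenerics::score(al) <= 0 || ncol == 0) {
    return(list(identity = 0, coverage = 0, aligned_length = 0L, score = 0))
  }
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  nmatch <- sum(pat == sub & pat %in% c("A", "C", "G", "T"))
  qlen_aligned <- Biostrings::width(Biostrings::pattern(al))
  list(identity = 100 * nmatch / ncol,
       coverage = 100 * qlen_aligned / nchar(query),
       aligned_length = as.integer(ncol),
       score = BiocGenerics::score(al))
}

#' Longest open reading frame over all six frames
#'
#' An ORF is `ATG ... {TAA,TAG,TGA}` in frame; the stop codon is not counted in
#' the amino-acid length (so the reported length includes the initial Met).
#' All three frames of both strands are searched; ties are broken by frame
#' order +1, +2, +3, -1, -2, -3.
#'
#' @param seq nucleotide string (ACGTN).
#' @return list with `longest_orf_aa` and `frame` (`NA` when no ORF exists).
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) return(list(longest_orf_aa = 0L, frame = NA_character_))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  best_aa <- 0L; best_frame <- NA_character_
  frames <- list(`+1` = c(seq, 1L), `+2` = c(seq, 2L), `+3` = c(seq, 3L),
                 `-1` = c(rc, 1L), `-2` = c(rc, 2L), `-3` = c(rc, 3L))
  for (fname in names(frames)) {
    s <- frames[[fname]][1]; off <- as.integer(frames[[fname]][2])
    n_cod <- (nchar(s) - off + 1L) %/% 3L
    if (n_cod < 2L) next
    cod <- substring(s, off + 3L * (seq_len(n_cod) - 1L),
                     off + 3L * seq_len(n_cod) - 1L)
    is_start <- cod == "ATG"
    is_stop <- cod %in% c("TAA", "TAG", "TGA")
    if (!any(is_start) || !any(is_stop)) next
    stop_pos <- which(is_stop)
    for (st in which(is_start)) {
      nxt <- stop_pos[stop_pos > st]
      if (!length(nxt)) next
      aa <- nxt[1] - st  # codons from ATG up to (not including) the stop
      if (aa > best_aa) { best_aa <- aa; best_frame <- fname }
    }
  }
  list(longest_orf_aa = as.integer(best_aa), frame = best_frame)
}

#' Remove putative protein-coding candidates
#'
#' A candidate is removed iff (a) its best local alignment against some
#' reference exceeds both the identity and coverage thresholds, or (b) its
#' longest six-frame ORF reaches the amino-acid threshold. Retained and
#' removed partition the input.
#'
#' @param candidates named character vector of candidate sequences.
#' @param references named character vector of known transcript sequences
#'   (may be empty, in which case only the ORF screen applies).
#' @param cfg a [screen_config()].
#' @return list with `retained` (ids) and `report` (one row per candidate:
#'   id, removed, reason, best_identity, best_coverage, longest_orf_aa).
#' @export
filter_noncoding <- function(candidates, references = character(0),
                             cfg = screen_config()) {
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be named by transcript id")
  miss <- names(candidates)[is.na(candidates) | !nzchar(candidates)]
  if (length(miss)) stop("candidate without sequence: ",
                         paste(miss, collapse = ", "))
  rows <- lapply(names(candidates), function(id) {
    best_id <- 0; best_cov <- 0
    similar <- FALSE
    for (ref in references) {
      st <- local_alignment_stats(candidates[[id]], ref, cfg)
      hit <- st$identity > cfg$identity_threshold &&
        st$coverage > cfg$coverage_threshold
      if (st$identity > best_id) best_id <- st$identity
      if (st$coverage > best_cov) best_cov <- st$coverage
      if (hit) { similar <- TRUE; best_id <- st$identity; best_cov <- st$coverage; break }
    }
    orf <- find_longest_orf(candidates[[id]])
    reason <- if (similar) "similarity"
      else if (orf$longest_orf_aa >= cfg$orf_aa_threshold) "long_orf"
      else NA_character_
    data.frame(transcript_id = id, removed = !is.na(reason), reason = reason,
               best_identity = best_id, best_coverage = best_cov,
               longest_orf_aa = orf$longest_orf_aa, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(retained = report$transcript_id[!report$removed], report = report)
}
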