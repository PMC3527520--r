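# Cross-dataset overlap accounting between annotated ncRNAs and external
# long-ncRNA catalogs: per-category counts, percentage reporting, and
# exclusive Venn-region counts.

#' Span overlap pairing between two transcript sets
#'
#' A pair is recorded iff the genomic spans share at least `min_overlap` bp,
#' strand-agnostic. Both directions are retrievable from the returned pairing.
#'
#' @param ours,theirs `transcript_set` tables on the same assembly.
#' @param min_overlap minimum shared bases (default 1).
#' @return data.frame `ours_id`, `theirs_id`, one row per overlapping pair.
#' @export
overlap_datasets <- function(ours, theirs, min_overlap = 1L) {
  if (!nrow(ours) || !nrow(theirs))
    return(data.frame(ours_id = character(0), theirs_id = character(0),
                      stringsAsFactors = FALSE))
  hits <- GenomicRanges::findOverlaps(spans_granges(ours),
                                      spans_granges(theirs),
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
  data.frame(ours_id = ours$transcript_id[S4Vectors::queryHits(hits)],
             theirs_id = theirs$transcript_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Per-category overlap report against one external dataset
#'
#' Each of our ncRNAs is counted once per dataset regardless of how many
#' external records it hits. The intergenic percentage is taken against the
#' total number of intergenic ncRNAs in the annotation (not just those that
#' overlap), rounded to 2 decimals.
#'
#' @param pairing output of [overlap_datasets()].
#' @param annotations finalized `ncrna_annotation` table.
#' @param total_intergenic denominator for the percentage (default: count of
#'   intergenic rows in `annotations`).
#' @param dataset_name label stored in the report.
#' @return one-row data.frame: dataset_name, intronic, overlapped,
#'   utr_related, intergenic, intergenic_percent, total, reciprocal_count.
#' @export
category_report <- function(pairing, annotations,
                            total_intergenic = sum(annotations$category ==
                                                     "intergenic"),
                            dataset_name = "dataset") {
  cat_of <- stats::setNames(annotations$category, annotations$transcript_id)
  hit_ids <- unique(pairing$ours_id)
  cats <- cat_of[hit_ids]
  cnt <- function(cl) sum(cats == cl, na.rm = TRUE)
  n_inter <- cnt("intergenic")
  pct <- if (total_intergenic > 0) percentage(n_inter, total_intergenic)
         else NA_real_
  if (is.na(pct) && total_intergenic == 0)
    warning("total_intergenic is 0; percentage undefined")
  data.frame(dataset_name = dataset_name,
             intronic = cnt("intronic"), overlapped = cnt("overlapped"),
             utr_related = cnt("utr_related"), intergenic = n_inter,
             intergenic_percent = pct,
             total = length(hit_ids),
             reciprocal_count = length(unique(pairing$theirs_id)),
             stringsAsFactors = FALSE)
}

#' Exclusive Venn-region counts of our ncRNAs across datasets
#'
#' For every non-empty subset of datasets, the number of our ncRNAs
#' overlapping exactly that subset. Counts partition the set of ncRNAs
#' overlapping at least one dataset.
#'
#' @param ours a `transcript_set`.
#' @param datasets named list of `transcript_set` tables (at most 5).
#' @param min_overlap minimum shared bases (default 1).
#' @return data.frame `subset` (dataset names joined by `&`), `count`.
#' @export
venn_counts <- function(ours, datasets, min_overlap = 1L) {
  stopifnot(length(datasets) >= 1L, length(datasets) <= 5L,
            !is.null(names(datasets)))
  member <- vapply(datasets, function(d)
    ours$transcript_id %in% overlap_datasets(ours, d, min_overlap)$ours_id,
    logical(nrow(ours)))
  member <- matrix(member, nrow = nrow(ours),
                   dimnames = list(NULL, names(datasets)))
  pattern <- apply(member, 1L, function(r)
    paste(names(datasets)[r], collapse = "&"))
  pattern <- pattern[nzchar(pattern)]
  labels <- unlist(lapply(seq_along(datasets), function(k)
    utils::combn(names(datasets), k, paste, collapse = "&", simplify = FALSE)))
  tab <- table(pattern)
  data.frame(subset = labels,
             count = as.integer(ifelse(labels %in% names(tab),
                                       tab[labels], 0L)),
             stringsAsFactors = FALSE)
}
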