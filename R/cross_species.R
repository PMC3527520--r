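# Cross-species conservation of neighbor genes of gene-proximate intergenic
# ncRNAs: symbol intersection across species, and sequence-similarity
# conservation at identity/coverage thresholds.

#' Symbol intersection across species
#'
#' Case-insensitive intersection of neighbor-gene symbols across all species,
#' plus every pairwise (and higher) region count for Venn reporting.
#'
#' @param sets named list (one entry per species) of character vectors of
#'   gene symbols.
#' @return list with `common` (symbols present in every species, upper-cased)
#'   and `regions` (data.frame subset/count of exclusive Venn regions over
#'   symbols present in >= 1 species).
#' @export
symbol_intersection <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(toupper(s)))
  common <- sort(Reduce(intersect, sets))
  all_sym <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_sym %in% s, logical(length(all_sym)))
  member <- matrix(member, nrow = length(all_sym),
                   dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  labels <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)))
  tab <- table(pattern)
  regions <- data.frame(subset = labels,
                        count = as.integer(ifelse(labels %in% names(tab),
                                                  tab[labels], 0L)),
                        stringsAsFactors = FALSE)
  list(common = common, regions = regions)
}

#' Sequence-conserved neighbor genes across species
#'
#' For each query gene the best local alignment against every other species'
#' neighbor set is computed; the gene is conserved iff identity and coverage
#' (measured on the query) exceed the thresholds in *every* other species.
#'
#' @param query_genes character vector of gene ids (species A).
#' @param target_sets named list (other species) of character vectors of gene
#'   ids.
#' @param sequences named character vector covering all gene ids; queries
#'   without a sequence are flagged and excluded.
#' @param min_identity,min_coverage percent thresholds (defaults 60 and 60).
#' @param cfg a [screen_config()] providing alignment scoring.
#' @return data.frame: query, one `identity_<sp>`/`coverage_<sp>`/
#'   `match_<sp>` triple per target species, `conserved`, `flagged`.
#' @export
sequence_conserved_neighbors <- function(query_genes, target_sets, sequences,
                                         min_identity = 60, min_coverage = 60,
                                         cfg = screen_config()) {
  stopifnot(length(target_sets) >= 1L, !is.null(names(target_sets)))
  rows <- lapply(query_genes, function(q) {
    row <- data.frame(query = q, stringsAsFactors = FALSE)
    if (!q %in% names(sequences)) {
      for (sp in names(target_sets)) {
        row[[paste0("identity_", sp)]] <- NA_real_
        row[[paste0("coverage_", sp)]] <- NA_real_
        row[[paste0("match_", sp)]] <- NA_character_
      }
      row$conserved <- FALSE; row$flagged <- TRUE
      return(row)
    }
    qseq <- sequences[[q]]
    ok <- TRUE
    for (sp in names(target_sets)) {
      best_pass <- FALSE; best_id <- 0; best_cov <- 0; best_g <- NA_character_
      for (g in target_sets[[sp]]) {
        if (!g %in% names(sequences)) next
        st <- local_alignment_stats(qseq, sequences[[g]], cfg)
        better <- st$identity + st$coverage > best_id + best_cov
        if (better) { best_id <- st$identity; best_cov <- st$coverage; best_g <- g }
        if (st$identity > min_identity && st$coverage > min_coverage) {
          best_pass <- TRUE
          best_id <- st$identity; best_cov <- st$coverage; best_g <- g
          break
        }
      }
      row[[paste0("identity_", sp)]] <- best_id
      row[[paste0("coverage_", sp)]] <- best_cov
      row[[paste0("match_", sp)]] <- best_g
      if (!best_pass) ok <- FALSE
    }
    row$conserved <- ok; row$flagged <- FALSE
    row
  })
  do.call(rbind, rows)
}

#' Per-end conserved neighbor-gene accounting
#'
#' Counts conserved genes among 5'-proximate and 3'-proximate neighbor sets
#' and their sum.
#'
#' @param matches_5prime,matches_3prime [sequence_conserved_neighbors()]
#'   outputs for the two gene ends.
#' @return list `n_5prime`, `n_3prime`, `total`.
#' @export
conserved_accounting <- function(matches_5prime, matches_3prime) {
  n5 <- sum(matches_5prime$conserved)
  n3 <- sum(matches_3prime$conserved)
  list(n_5prime = n5, n_3prime = n3, total = n5 + n3)
}
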