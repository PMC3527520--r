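# GO over-representation of neighbor-gene lists with the EASE score: the
# conservative variant of the one-sided Fisher exact test in which one gene
# is removed from the list-hit cell before taking the enrichment tail.

#' Enrichment configuration
#'
#' @param min_count minimum list hits for a term to be flagged significant
#'   (default 6, i.e. the "gene count > 5" rule).
#' @param p_threshold EASE p-value threshold for the significance flag
#'   (default 0.05). Raw, uncorrected p-values are thresholded; a
#'   Benjamini-Hochberg column is emitted alongside but not used for the flag.
#' @return list of class `enrich_config`.
#' @export
enrich_config <- function(min_count = 6L, p_threshold = 0.05) {
  stopifnot(min_count >= 1L, p_threshold > 0, p_threshold <= 1)
  structure(list(min_count = as.integer(min_count), p_threshold = p_threshold),
            class = "enrich_config")
}

#' EASE score p-value
#'
#' One-sided (enrichment) Fisher exact tail probability of the 2x2 table in
#' which the list-hit count is decremented by one: `p = P(X >= k - 1)` for
#' `X ~ Hypergeometric(N, K, n)`; `k = 0` gives `p = 1`. Decrementing makes
#' the statistic conservative relative to the classical Fisher test.
#'
#' @param k list hits for the term.
#' @param n list size.
#' @param K background hits for the term.
#' @param N background size.
#' @return p-value in (0, 1].
#' @export
ease_pvalue <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || k > K || K > N)
    stop("inconsistent 2x2 margins")
  kprime <- max(k - 1L, 0L)
  # P(X >= kprime), X ~ hypergeom(N, K, n)
  stats::phyper(kprime - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Read a gene -> GO term annotation table
#'
#' Two-column TSV (gene, term), no header.
#'
#' @param path file path.
#' @return data.frame `gene`, `term`.
#' @export
read_go_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene", "term"),
                          colClasses = "character")
  df
}

#' GO term over-representation of a gene list (EASE score)
#'
#' One result per term with at least one list hit. A term is flagged
#' significant iff its list hits reach `cfg$min_count` and its EASE p-value is
#' below `cfg$p_threshold`. Results are sorted by ascending EASE p.
#'
#' @param gene_list character vector of genes (must be a subset of the
#'   background).
#' @param annotation data.frame `gene`, `term` (see [read_go_annotation()]).
#' @param background gene universe (default: all genes in the annotation).
#' @param cfg an [enrich_config()].
#' @return data.frame: term, k, n, K, N, ease_p, bh_p, significant.
#' @export
enrich_terms <- function(gene_list, annotation,
                         background = unique(annotation$gene),
                         cfg = enrich_config()) {
  if (!length(background)) stop("empty background universe")
  background <- unique(background)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% background))
    stop("gene_list contains genes outside the background universe")
  annotation <- annotation[annotation$gene %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(gene_list)
  in_list <- annotation$gene %in% gene_list
  K_tab <- table(annotation$term)
  k_tab <- table(annotation$term[in_list])
  terms <- names(k_tab)[k_tab > 0]
  if (!length(terms))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), ease_p = numeric(0),
                      bh_p = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p <- vapply(seq_along(terms), function(i) ease_pvalue(k[i], n, K[i], N),
              numeric(1))
  res <- data.frame(term = terms, k = k, n = n, K = K, N = N, ease_p = p,
                    bh_p = stats::p.adjust(p, method = "BH"),
                    significant = k >= cfg$min_count & p < cfg$p_threshold,
                    stringsAsFactors = FALSE)
  res[order(res$ease_p, res$term), , drop = FALSE]
}

#' Terms significantly over-represented in every species
#'
#' Intersects the significant term sets of two or more species-level
#' enrichment results and reports per-species p-values, ordered by the first
#' species' p-value.
#'
#' @param results named list of [enrich_terms()] outputs (>= 2 entries).
#' @return data.frame `term` plus one `p_<species>` column per input.
#' @export
common_terms <- function(results) {
  stopifnot(length(results) >= 2L, !is.null(names(results)))
  sig <- lapply(results, function(r) r$term[r$significant])
  common <- Reduce(intersect, sig)
  out <- data.frame(term = common, stringsAsFactors = FALSE)
  for (sp in names(results)) {
    p <- stats::setNames(results[[sp]]$ease_p, results[[sp]]$term)
    out[[paste0("p_", sp)]] <- as.numeric(p[common])
  }
  out[order(out[[paste0("p_", names(results)[1L])]], out$term), ,
      drop = FALSE]
}
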