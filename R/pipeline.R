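# End-to-end orchestration over synthetic or caller-supplied inputs, plus the
# small reporting helpers shared by every output table.

#' Percentage rounded to two decimals
#'
#' Round-half-to-even (the R default) of `100 * numerator / denominator`.
#'
#' @param numerator,denominator counts; a zero denominator yields `NA` with a
#'   warning.
#' @return numeric percent, 2 decimals.
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator == 0)) {
    warning("denominator is 0; percentage undefined")
    return(ifelse(denominator == 0, NA_real_,
                  round(100 * numerator / denominator, 2)))
  }
  round(100 * numerator / denominator, 2)
}

# 31-bit polynomial rolling hash over a string; used only to stamp a config
# fingerprint into output headers (no cryptographic intent)
string_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(cfg) {
  string_hash(paste(deparse(cfg[order(names(cfg))]), collapse = ""))
}

output_header <- function(seed, hash) {
  c(sprintf("# lncclass %s", as.character(utils::packageVersion("lncclass"))),
    sprintf("# seed=%d config=%s", seed, hash))
}

write_tsv_report <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-data analysis end to end
#'
#' Generates every input from `cfg`, then runs screening, classification,
#' positional histograms, conservation scoring with un-transcribed controls,
#' GO enrichment on proximate neighbor genes, and the cross-species trio
#' comparison. All tables are written under `out_dir` with a version/seed/
#' config-hash header, plus a machine-readable `summary.json`. Byte-identical
#' across runs with the same configuration.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @param n_screen candidates per class for the coding screen demonstration.
#' @return the summary list, invisibly.
#' @export
run_all <- function(cfg, out_dir, n_screen = 15L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(cfg))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  genome <- stage("simulate", generate_genome(cfg))
  nc <- stage("simulate", generate_ncrnas(cfg, genome))
  assembly <- nc$assembly
  genes <- genome$genes

  mix <- stage("screen", generate_screen_candidates(
    n_screen, n_screen, seed = stage_seed(cfg$seed, 6L)))
  screen <- stage("screen", filter_noncoding(mix$sequences))
  write_tsv_report(screen$report, file.path(out_dir, "screen_report.tsv"),
                   cfg$seed, hash)

  ann <- stage("classify", annotate_ncrnas(nc$transcripts, genes, assembly))
  write_tsv_report(ann, file.path(out_dir, "classification.tsv"),
                   cfg$seed, hash)
  cat_counts <- table(factor(ann$category,
                             c("utr_related", "intergenic", "intronic",
                               "overlapped")))
  hist_tab <- stage("classify", positional_histogram(ann))
  write_tsv_report(hist_tab, file.path(out_dir, "positional_histogram.tsv"),
                   cfg$seed, hash)
  prox <- select_gene_proximate(ann)

  track <- stage("conserve", generate_score_track(cfg, assembly, genes,
                                                  nc$transcripts, nc$truth))
  transcribed <- transcript_set(
    c(paste0("genespan_", genes$gene_id), nc$transcripts$transcript_id),
    c(genes$chrom, nc$transcripts$chrom),
    rep("*", nrow(genes) + nrow(nc$transcripts)),
    c(lapply(seq_len(nrow(genes)), function(i)
        ivmat(genes$start[i], genes$end[i])),
      lapply(nc$transcripts$blocks, function(b)
        ivmat(b[1, 1], b[nrow(b), 2]))))
  ctrl_cfg <- control_sampler_config(
    n_controls = nrow(nc$transcripts),
    min_len = 500, max_len = min(15000L, max(500L, cfg$ncrna_len[2])),
    seed = stage_seed(cfg$seed, 7L))
  controls <- stage("conserve",
                    sample_untranscribed_controls(assembly, transcribed,
                                                  ctrl_cfg))
  write_intervals(controls, file.path(out_dir, "controls.bed"))
  coding_tx <- transcript_set(paste0("cds_", genes$gene_id), genes$chrom,
                              genes$strand, genes$exons)
  groups_tx <- list(
    coding = coding_tx,
    utr_related = nc$transcripts[ann$category == "utr_related", ],
    intergenic = nc$transcripts[ann$category == "intergenic", ],
    intronic = nc$transcripts[ann$category == "intronic", ],
    control = controls)
  groups_tx <- Filter(nrow, groups_tx)
  scores <- lapply(groups_tx, interval_mean_score, track = track)
  comp <- stage("conserve", compare_conservation(scores))
  ecdf_tab <- do.call(rbind, lapply(names(comp$ecdfs), function(g)
    cbind(group = g, comp$ecdfs[[g]])))
  write_tsv_report(ecdf_tab, file.path(out_dir, "conservation_ecdf.tsv"),
                   cfg$seed, hash)
  write_tsv_report(comp$pairs, file.path(out_dir, "conservation_pairs.tsv"),
                   cfg$seed, hash)

  go <- stage("enrich", generate_go_annotation(cfg))
  enr <- stage("enrich", enrich_terms(go$gene_list, go$annotation,
                                      background = go$universe))
  write_tsv_report(enr, file.path(out_dir, "enrichment.tsv"), cfg$seed, hash)

  trio <- stage("conserve-neighbors", generate_species_trio(cfg))
  sym <- symbol_intersection(lapply(trio$sets, function(s) s$symbol))
  ends_of <- stats::setNames(trio$sets[[1]]$end, trio$sets[[1]]$gene_id)
  per_end <- lapply(c(p5 = "5prime", p3 = "3prime"), function(endv) {
    q <- trio$sets[[1]]$gene_id[trio$sets[[1]]$end == endv]
    tg <- lapply(trio$sets[-1], function(s) s$gene_id[s$end == endv])
    sequence_conserved_neighbors(q, tg, trio$sequences)
  })
  acct <- conserved_accounting(per_end$p5, per_end$p3)
  write_tsv_report(do.call(rbind, per_end),
                   file.path(out_dir, "cross_species_matches.tsv"),
                   cfg$seed, hash)

  summary <- list(
    version = as.character(utils::packageVersion("lncclass")),
    seed = cfg$seed, config = hash,
    n_transcripts = nrow(nc$transcripts),
    categories = as.list(cat_counts),
    category_total = sum(cat_counts),
    screen = list(input = nrow(screen$report),
                  retained = length(screen$retained),
                  removed = sum(screen$report$removed)),
    proximate = list(p5 = nrow(prox$p5), p3 = nrow(prox$p3)),
    conservation_ordering = comp$ordering,
    n_controls = nrow(controls),
    enrichment = list(n_terms = nrow(enr),
                      n_significant = sum(enr$significant)),
    cross_species = list(common_symbols = length(sym$common),
                         conserved_5prime = acct$n_5prime,
                         conserved_3prime = acct$n_3prime,
                         conserved_total = acct$total))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
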