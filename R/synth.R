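# Seeded synthetic-data generator: genomes with spaced gene models, planted
# ncRNAs of every positional class with configurable proximity bias and
# sense skew, class-dependent conservation tracks, GO annotations with a
# planted over-represented term, and cross-species neighbor-gene trios.

# derived per-stage seeds keep every generator deterministic on its own
stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) %% 1000003L) * 2011L + stage * 7919L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Synthetic-data configuration
#'
#' Defaults define the study conditions the generator emulates: a mostly
#' intronic/intergenic class mix, a 5-kb proximity bias of 0.6 for intergenic
#' ncRNAs, a 3'-end sense skew of 0.7 (sense enrichment near 3' ends, mild
#' antisense lean at 5' ends), and per-base conservation means ordered
#' coding > UTR-related > intergenic > intronic > background.
#'
#' @param seed integer master seed; each generator stage derives its own.
#' @param n_chroms,chrom_len genome shape.
#' @param genes_per_chrom protein-coding gene models per chromosome.
#' @param exon_len,intron_len,n_exons per-gene sampling ranges (bp / counts).
#' @param utr5_len,utr3_len UTR lengths carved from the terminal exons.
#' @param n_ncrnas planted ncRNA count.
#' @param class_props named proportions over intergenic/intronic/overlapped/
#'   utr_related (must sum to 1).
#' @param ncrna_len transcript length range in bp.
#' @param p_prox probability an intergenic ncRNA is planted within 5 kb of a
#'   gene end.
#' @param sense_skew_3p,sense_skew_5p probability a proximate intergenic
#'   ncRNA is sense-strand at the 3' / 5' end of its neighbor.
#' @param spliced_fraction fraction of (non-overlapped) ncRNAs given introns
#'   with canonical splice motifs written into the genome.
#' @param noncanonical_fraction fraction of spliced ncRNAs whose motifs are
#'   left random (exercises the unknown-strand path).
#' @param unknown_strand_fraction fraction of emitted ncRNAs whose declared
#'   strand is unknown (truth keeps the planted strand).
#' @param class_means,score_sd,uncovered_fraction conservation-track model:
#'   per-base Normal means per feature class, common sd, and the fraction of
#'   bases masked uncovered.
#' @param trio_n_genes,homolog_fraction,homolog_identity,neighbor_seq_len
#'   cross-species trio: neighbor genes per species, fraction in shared
#'   homolog groups, per-copy sequence identity, sequence length.
#' @param go_n_genes,go_list_size,go_n_terms,go_term_prob,go_planted_fold
#'   GO generator: universe size, designated list size, term count, baseline
#'   annotation probability, fold over-representation of the planted term.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_chroms = 2L, chrom_len = 400000L,
                         genes_per_chrom = 8L,
                         exon_len = c(200L, 600L), intron_len = c(500L, 1500L),
                         n_exons = c(2L, 4L),
                         utr5_len = 80L, utr3_len = 120L,
                         n_ncrnas = 200L,
                         class_props = c(intergenic = 0.4, intronic = 0.3,
                                         overlapped = 0.15, utr_related = 0.15),
                         ncrna_len = c(250L, 2500L),
                         p_prox = 0.6, sense_skew_3p = 0.7, sense_skew_5p = 0.45,
                         spliced_fraction = 0.5, noncanonical_fraction = 0,
                         unknown_strand_fraction = 0.3,
                         class_means = c(coding = 3, overlapped = 2,
                                         utr_related = 1.5,
                                         intergenic = 1, intronic = 0.5,
                                         background = 0),
                         score_sd = 0.5, uncovered_fraction = 0.1,
                         trio_n_genes = 40L, homolog_fraction = 0.3,
                         homolog_identity = 0.85, neighbor_seq_len = 400L,
                         go_n_genes = 400L, go_list_size = 60L,
                         go_n_terms = 40L, go_term_prob = 0.05,
                         go_planted_fold = 5) {
  stopifnot(abs(sum(class_props) - 1) < 1e-8,
            all(class_props >= 0), p_prox >= 0, p_prox <= 1,
            sense_skew_3p >= 0, sense_skew_3p <= 1,
            homolog_fraction >= 0, homolog_fraction <= 1,
            homolog_identity > 0, homolog_identity <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))

random_dna <- function(len) {
  paste(c("A", "C", "G", "T")[runif_int(len, 1L, 4L)], collapse = "")
}

#' Generate a synthetic genome with spaced gene models
#'
#' Non-overlapping genes, each with at least two exons and UTRs carved from
#' the terminal exons; inter-gene gaps are sized to leave room for distal
#' intergenic placements (at least twice the maximum ncRNA length plus the
#' 5-kb flank on both sides). Deterministic under `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `assembly` (sequence-bearing `genome_assembly`) and
#'   `genes` (`gene_models`).
#' @export
generate_genome <- function(cfg) with_seed(stage_seed(cfg$seed, 1L), {
  min_gap <- 2L * (10000L + cfg$ncrna_len[2]) + 2000L
  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
  seqs <- character(cfg$n_chroms); names(seqs) <- chrom_names
  rows <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    seqs[ci] <- random_dna(cfg$chrom_len)
    ng <- cfg$genes_per_chrom
    exn <- runif_int(ng, cfg$n_exons[1], cfg$n_exons[2])
    gene_lens <- integer(ng)
    exon_sets <- vector("list", ng)
    for (g in seq_len(ng)) {
      el <- runif_int(exn[g], cfg$exon_len[1], cfg$exon_len[2])
      il <- runif_int(exn[g] - 1L, cfg$intron_len[1], cfg$intron_len[2])
      gene_lens[g] <- sum(el) + sum(il)
      off <- cumsum(c(0L, as.vector(rbind(el, c(il, 0L)))[seq_len(2L * exn[g] - 1L)]))
      exon_sets[[g]] <- cbind(off[seq(1L, by = 2L, length.out = exn[g])],
                              off[seq(1L, by = 2L, length.out = exn[g])] + el)
    }
    slack <- cfg$chrom_len - sum(gene_lens) - (ng + 1L) * min_gap
    if (slack < 0)
      stop("genes cannot fit: increase chrom_len or reduce genes_per_chrom")
    wt <- stats::runif(ng + 1L)
    gaps <- min_gap + as.integer(floor(slack * wt / sum(wt)))
    pos <- 0L
    for (g in seq_len(ng)) {
      pos <- pos + gaps[g]
      ex <- ivmat(pos + exon_sets[[g]][, 1], pos + exon_sets[[g]][, 2])
      strand <- sample(c("+", "-"), 1L)
      left_u <- ivmat(ex[1, 1], ex[1, 1] +
                        if (strand == "+") cfg$utr5_len else cfg$utr3_len)
      right_u <- ivmat(ex[nrow(ex), 2] -
                         if (strand == "+") cfg$utr3_len else cfg$utr5_len,
                       ex[nrow(ex), 2])
      rows[[length(rows) + 1L]] <- list(
        gene_id = sprintf("g%s_%02d", ci, g),
        symbol = sprintf("SYM%s_%02d", ci, g),
        chrom = chrom_names[ci], strand = strand,
        start = pos, end = pos + gene_lens[g],
        exons = ex,
        utr5 = if (strand == "+") left_u else right_u,
        utr3 = if (strand == "+") right_u else left_u)
      pos <- pos + gene_lens[g]
    }
  }
  genes <- gene_models(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    symbol = vapply(rows, `[[`, character(1), "symbol"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    exons = lapply(rows, `[[`, "exons"),
    utr5 = lapply(rows, `[[`, "utr5"),
    utr3 = lapply(rows, `[[`, "utr3"))
  list(assembly = genome_assembly(
         stats::setNames(rep(cfg$chrom_len, cfg$n_chroms), chrom_names),
         seqs),
       genes = genes)
})

# distance from span [s,e) to every gene on the same chromosome; the nearest
# gene under the (distance, start, gene_id) tie rule, or NA
true_neighbor <- function(s, e, chrom, genes) {
  cand <- which(genes$chrom == chrom)
  if (!length(cand)) return(NULL)
  gap <- pmax(genes$start[cand] - e, s - genes$end[cand], 0L)
  ovl <- genes$start[cand] < e & s < genes$end[cand]
  ord <- order(gap, genes$start[cand], genes$gene_id[cand], method = "radix")
  j <- cand[ord[1L]]
  list(idx = j, distance = gap[ord[1L]], any_overlap = any(ovl),
       min_gap = min(gap))
}

#' Plant synthetic ncRNAs with known classes and biases
#'
#' Plants ncRNAs per `cfg$class_props`: intronic transcripts wholly inside an
#' intron, overlapped transcripts crossing an exon boundary by at least 1 bp,
#' UTR-related transcripts 1-950 bp from a gene end, and intergenic
#' transcripts either 1050-4950 bp from a gene end (probability `p_prox`) or
#' more than 5100 bp from every gene. Proximate intergenic strands follow the
#' configured sense skews; spliced transcripts receive canonical GT..AG
#' (CT..AC on minus) motifs written into the genome sequence. A configurable
#' fraction of emitted records has its declared strand blanked to unknown.
#'
#' @param cfg a [synth_config()].
#' @param genome output of [generate_genome()] (assembly + genes).
#' @return list with `transcripts` (`transcript_set`), `truth` (data.frame:
#'   transcript_id, class, strand, neighbor, gene_end, distance, spliced) and
#'   `assembly` (sequence updated with splice motifs).
#' @export
generate_ncrnas <- function(cfg, genome) with_seed(stage_seed(cfg$seed, 2L), {
  genes <- genome$genes
  assembly <- genome$assembly
  classes <- sample(names(cfg$class_props), cfg$n_ncrnas, replace = TRUE,
                    prob = cfg$class_props)
  n <- cfg$n_ncrnas
  ids <- sprintf("nc%05d", seq_len(n))
  out_chrom <- character(n); out_strand <- character(n)
  out_blocks <- vector("list", n)
  tr_neighbor <- rep(NA_character_, n); tr_end <- rep(NA_character_, n)
  tr_dist <- rep(NA_integer_, n); tr_spliced <- logical(n)
  # occupancy of already-planted ncRNAs, to keep intergenic placements from
  # stacking onto each other's neighborhoods is not required; only gene
  # distances define the class, so collisions between ncRNAs are allowed.
  for (i in seq_len(n)) {
    len <- runif_int(1L, cfg$ncrna_len[1], cfg$ncrna_len[2])
    cls <- classes[i]
    # decide proximate vs distal once, outside the retry loop: retrying a
    # failed placement must not re-draw the bias coin or the planted
    # proximate fraction drifts toward the easier-to-place mode
    proximate_mode <- cls == "intergenic" && stats::runif(1) < cfg$p_prox
    placed <- FALSE
    for (att in 1:200) {
      if (cls == "intronic") {
        g <- sample.int(nrow(genes), 1L)
        ex <- genes$exons[[g]]
        if (nrow(ex) < 2L) next
        ii <- sample.int(nrow(ex) - 1L, 1L)
        is_ <- ex[ii, 2]; ie <- ex[ii + 1L, 1]
        if (ie - is_ < 220L) next
        l <- min(len, ie - is_)
        s <- is_ + sample.int(ie - is_ - l + 1L, 1L) - 1L
        chrom <- genes$chrom[g]; e <- s + l
        strand <- sample(c("+", "-"), 1L)
      } else if (cls == "overlapped") {
        g <- sample.int(nrow(genes), 1L)
        ex <- genes$exons[[g]]
        j <- sample.int(nrow(ex), 1L)
        k <- sample.int(min(len - 1L, ex[j, 2] - ex[j, 1]), 1L)  # exon overlap
        s <- ex[j, 2] - k; e <- s + len
        chrom <- genes$chrom[g]
        if (e > assembly$chrom_lengths[[chrom]]) next
        strand <- sample(c("+", "-"), 1L)
      } else {
        g <- sample.int(nrow(genes), 1L)
        side <- sample(c("left", "right"), 1L)
        if (cls == "utr_related") {
          gap <- runif_int(1L, 1L, 950L)
        } else if (proximate_mode) {
          gap <- runif_int(1L, 1050L, 4950L)
        } else {
          gap <- NA_integer_  # distal: uniform placement, distance > 5100
        }
        chrom <- genes$chrom[g]
        if (is.na(gap)) {
          s <- sample.int(assembly$chrom_lengths[[chrom]] - len, 1L) - 1L
          e <- s + len
        } else if (side == "left") {
          e <- genes$start[g] - gap; s <- e - len
        } else {
          s <- genes$end[g] + gap; e <- s + len
        }
        if (s < 0L || e > assembly$chrom_lengths[[chrom]]) next
        nb <- true_neighbor(s, e, chrom, genes)
        if (nb$any_overlap) next
        if (cls == "utr_related") {
          if (nb$distance > 950L) next
        } else if (is.na(gap)) {
          if (nb$distance <= 5100L) next
        } else {
          if (nb$distance <= 1000L || nb$distance > 5000L) next
        }
        gidx <- nb$idx
        upstream <- e <= genes$start[gidx]
        gend <- if ((upstream && genes$strand[gidx] == "+") ||
                    (!upstream && genes$strand[gidx] == "-")) "5prime" else "3prime"
        skew <- if (gend == "3prime") cfg$sense_skew_3p else cfg$sense_skew_5p
        proximate <- !is.na(gap) || cls == "utr_related"
        strand <- if (proximate) {
          if (stats::runif(1) < skew) genes$strand[gidx]
          else setdiff(c("+", "-"), genes$strand[gidx])
        } else sample(c("+", "-"), 1L)
        tr_neighbor[i] <- genes$gene_id[gidx]
        tr_end[i] <- gend
        tr_dist[i] <- nb$distance
      }
      placed <- TRUE
      break
    }
    if (!placed) stop("ncRNA placement failed for class ", cls)
    # splicing: two or three blocks for non-overlapped classes
    blocks <- ivmat(s, e)
    if (cls != "overlapped" && e - s >= 700L &&
        stats::runif(1) < cfg$spliced_fraction) {
      nint <- sample(1:2, 1L)
      width <- e - s
      # cut interior introns of 80-150 bp at spaced offsets
      offs <- sort(sample(seq.int(120L, width - 260L, by = 10L), nint))
      bs <- s; bl <- list()
      ok <- TRUE
      for (o in offs) {
        il <- runif_int(1L, 80L, 110L)
        if (s + o <= bs + 50L || s + o + il >= e - 50L) { ok <- FALSE; break }
        bl[[length(bl) + 1L]] <- c(bs, s + o)
        bs <- s + o + il
      }
      if (ok) {
        bl[[length(bl) + 1L]] <- c(bs, e)
        blocks <- ivmat(vapply(bl, `[[`, numeric(1), 1),
                        vapply(bl, `[[`, numeric(1), 2))
        tr_spliced[i] <- TRUE
        if (stats::runif(1) >= cfg$noncanonical_fraction) {
          chromseq <- assembly$sequence[[chrom]]
          for (j in seq_len(nrow(blocks) - 1L)) {
            is_ <- blocks[j, 2]; ie <- blocks[j + 1L, 1]
            if (strand == "-") {
              substr(chromseq, is_ + 1L, is_ + 2L) <- "CT"
              substr(chromseq, ie - 1L, ie) <- "AC"
            } else {
              substr(chromseq, is_ + 1L, is_ + 2L) <- "GT"
              substr(chromseq, ie - 1L, ie) <- "AG"
            }
          }
          assembly$sequence[[chrom]] <- chromseq
        }
      }
    }
    out_chrom[i] <- chrom; out_strand[i] <- strand; out_blocks[[i]] <- blocks
  }
  declared <- out_strand
  blank <- stats::runif(n) < cfg$unknown_strand_fraction
  declared[blank] <- "*"
  tx <- transcript_set(ids, out_chrom, declared, out_blocks,
                       source = "synthetic")
  truth <- data.frame(transcript_id = ids, class = classes,
                      strand = out_strand, neighbor = tr_neighbor,
                      gene_end = tr_end, distance = tr_dist,
                      spliced = tr_spliced, stringsAsFactors = FALSE)
  list(transcripts = tx, truth = truth, assembly = assembly)
})

#' Generate a class-dependent conservation track
#'
#' Per-base scores are Normal with a mean set by feature class (coding exons
#' over ncRNA blocks by planted class over background; coding wins where
#' features overlap) and common sd; a configurable fraction of bases is
#' masked uncovered. The class-mean defaults are generator conventions chosen
#' to produce the qualitative ordering coding > UTR-related > intergenic >
#' intronic > background.
#'
#' @param cfg a [synth_config()].
#' @param assembly a `genome_assembly`.
#' @param genes `gene_models`.
#' @param transcripts planted `transcript_set`.
#' @param truth ground-truth table from [generate_ncrnas()].
#' @return a `score_track`.
#' @export
generate_score_track <- function(cfg, assembly, genes, transcripts, truth)
  with_seed(stage_seed(cfg$seed, 3L), {
  mu <- cfg$class_means
  values <- lapply(assembly$chrom_names, function(cn) {
    len <- assembly$chrom_lengths[[cn]]
    v <- stats::rnorm(len, mu[["background"]], cfg$score_sd)
    cls_of <- stats::setNames(truth$class, truth$transcript_id)
    idx <- which(transcripts$chrom == cn)
    for (i in idx) {
      m <- mu[[cls_of[[transcripts$transcript_id[i]]]]]
      b <- transcripts$blocks[[i]]
      for (j in seq_len(nrow(b)))
        v[(b[j, 1] + 1L):b[j, 2]] <- stats::rnorm(b[j, 2] - b[j, 1], m,
                                                  cfg$score_sd)
    }
    gidx <- which(genes$chrom == cn)
    for (g in gidx) {
      ex <- genes$exons[[g]]
      for (j in seq_len(nrow(ex)))
        v[(ex[j, 1] + 1L):ex[j, 2]] <- stats::rnorm(ex[j, 2] - ex[j, 1],
                                                    mu[["coding"]], cfg$score_sd)
    }
    if (cfg$uncovered_fraction > 0)
      v[stats::runif(len) < cfg$uncovered_fraction] <- NA_real_
    v
  })
  names(values) <- assembly$chrom_names
  score_track(values)
})

mutate_sequence <- function(seq, identity) {
  n <- nchar(seq)
  n_mut <- round((1 - identity) * n)
  if (n_mut == 0L) return(seq)
  pos <- sample.int(n, n_mut)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Generate a three-species neighbor-gene trio
#'
#' A fraction `homolog_fraction` of neighbor genes is copied across all three
#' species with point mutations to the configured identity, retaining a
#' shared symbol; the rest are species-unique in symbol and sequence. Each
#' homolog group keeps one gene end across species.
#'
#' @param cfg a [synth_config()].
#' @param species species labels (default `spA`, `spB`, `spC`).
#' @return list with `sets` (per species: data.frame gene_id, symbol, end),
#'   `sequences` (named vector over all gene ids) and `truth` (data.frame
#'   symbol, homolog, end).
#' @export
generate_species_trio <- function(cfg, species = c("spA", "spB", "spC"))
  with_seed(stage_seed(cfg$seed, 4L), {
  n <- cfg$trio_n_genes
  n_hom <- round(cfg$homolog_fraction * n)
  ends <- sample(c("5prime", "3prime"), n, replace = TRUE)
  base_seqs <- vapply(seq_len(n_hom), function(i)
    random_dna(cfg$neighbor_seq_len), character(1))
  sets <- list(); sequences <- character(0)
  for (sp in species) {
    gene_id <- sprintf("%s_g%03d", sp, seq_len(n))
    symbol <- character(n)
    for (i in seq_len(n)) {
      if (i <= n_hom) {
        symbol[i] <- sprintf("HOMG%03d", i)
        sequences[[gene_id[i]]] <- mutate_sequence(base_seqs[i],
                                                   cfg$homolog_identity)
      } else {
        symbol[i] <- sprintf("%s_U%03d", toupper(sp), i)
        sequences[[gene_id[i]]] <- random_dna(cfg$neighbor_seq_len)
      }
    }
    sets[[sp]] <- data.frame(gene_id = gene_id, symbol = symbol, end = ends,
                             stringsAsFactors = FALSE)
  }
  truth <- data.frame(symbol = sets[[1]]$symbol,
                      homolog = seq_len(n) <= n_hom, end = ends,
                      stringsAsFactors = FALSE)
  list(sets = sets, sequences = sequences, truth = truth)
})

#' Generate a GO annotation with a planted over-represented term
#'
#' Background term frequencies are uniform Bernoulli(`go_term_prob`); the
#' planted term is assigned to designated list genes at `go_planted_fold`
#' times that probability (capped at 1). A fold of 1 plants no signal.
#'
#' @param cfg a [synth_config()].
#' @param universe optional character vector of gene ids (default: synthetic
#'   ids of size `cfg$go_n_genes`).
#' @return list with `annotation` (data.frame gene, term), `universe`,
#'   `gene_list` (the designated list) and `planted_term`.
#' @export
generate_go_annotation <- function(cfg, universe = NULL)
  with_seed(stage_seed(cfg$seed, 5L), {
  if (is.null(universe)) universe <- sprintf("gene%04d", seq_len(cfg$go_n_genes))
  terms <- sprintf("GO:%07d", seq_len(cfg$go_n_terms))
  planted <- terms[1L]
  gene_list <- sample(universe, cfg$go_list_size)
  rows <- list()
  p_planted <- min(1, cfg$go_planted_fold * cfg$go_term_prob)
  for (tm in terms) {
    p <- rep(cfg$go_term_prob, length(universe))
    if (tm == planted) p[universe %in% gene_list] <- p_planted
    hit <- stats::runif(length(universe)) < p
    if (any(hit))
      rows[[length(rows) + 1L]] <- data.frame(gene = universe[hit], term = tm,
                                              stringsAsFactors = FALSE)
  }
  list(annotation = do.call(rbind, rows), universe = universe,
       gene_list = gene_list, planted_term = planted)
})

#' Generate coding-like and noncoding-like screen candidates
#'
#' Coding-like sequences carry an embedded ORF of `orf_aa` codons; noncoding
#' sequences are rejection-sampled until their longest six-frame ORF is under
#' `max_noncoding_aa`.
#'
#' @param n_coding,n_noncoding counts.
#' @param len sequence length in bp.
#' @param orf_aa planted ORF length (amino acids, default 150).
#' @param max_noncoding_aa upper bound for noncoding ORFs (default 80).
#' @param seed integer seed.
#' @return list with `sequences` (named vector) and `truth` (data.frame id,
#'   coding).
#' @export
generate_screen_candidates <- function(n_coding, n_noncoding, len = 600L,
                                       orf_aa = 150L, max_noncoding_aa = 80L,
                                       seed = 1L) with_seed(seed, {
  stopifnot(len >= 3L * (orf_aa + 1L) + 6L)
  non_stop <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                        c("A","C","G","T")), 1L, paste,
                            collapse = ""),
                      c("TAA", "TAG", "TGA"))
  seqs <- character(0); coding <- logical(0)
  for (i in seq_len(n_coding)) {
    orf <- paste0("ATG",
                  paste(sample(non_stop, orf_aa - 1L, replace = TRUE),
                        collapse = ""), "TAA")
    pad <- len - nchar(orf)
    lead <- sample.int(pad, 1L) - 1L
    seqs[[sprintf("coding%03d", i)]] <-
      paste0(random_dna(lead), orf, random_dna(pad - lead))
    coding <- c(coding, TRUE)
  }
  for (i in seq_len(n_noncoding)) {
    repeat {
      s <- random_dna(len)
      if (find_longest_orf(s)$longest_orf_aa < max_noncoding_aa) break
    }
    seqs[[sprintf("noncoding%03d", i)]] <- s
    coding <- c(coding, FALSE)
  }
  list(sequences = seqs,
       truth = data.frame(transcript_id = names(seqs), coding = coding,
                          stringsAsFactors = FALSE))
})
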