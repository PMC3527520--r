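# Length-normalized conservation scoring of interval sets, sampling of
# length-matched un-transcribed control regions, and cumulative-frequency
# comparison between groups.

#' Control sampler configuration
#'
#' @param n_controls number of control intervals to draw.
#' @param min_len,max_len control length bounds in bp (defaults 500 and
#'   15000, the size range used for un-transcribed control fragments).
#' @param seed integer seed; a fixed seed reproduces the interval list.
#' @param max_n_fraction when assembly sequence is available, candidate
#'   intervals with a larger fraction of `N` bases are rejected.
#' @param max_attempts placement attempts per interval before giving up.
#' @return list of class `control_sampler_config`.
#' @export
control_sampler_config <- function(n_controls, min_len = 500, max_len = 15000,
                                   seed = 1L, max_n_fraction = 0.5,
                                   max_attempts = 100L) {
  stopifnot(n_controls >= 0, min_len > 0, min_len <= max_len)
  structure(list(n_controls = as.integer(n_controls),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 seed = as.integer(seed), max_n_fraction = max_n_fraction,
                 max_attempts = as.integer(max_attempts)),
            class = "control_sampler_config")
}

#' Mean conservation score per interval
#'
#' For each transcript the mean is the sum of covered per-base scores over its
#' blocks (exonic bases only for spliced intervals) divided by the number of
#' covered bases; uncovered bases are excluded from numerator and denominator.
#' Intervals with no covered base are flagged (`mean_score = NA`).
#'
#' @param intervals a `transcript_set`.
#' @param track a `score_track`.
#' @return data.frame `interval_id`, `mean_score`, `covered_fraction`.
#' @export
interval_mean_score <- function(intervals, track) {
  n <- nrow(intervals)
  mean_score <- rep(NA_real_, n); covered_fraction <- numeric(n)
  for (i in seq_len(n)) {
    v <- track$values[[intervals$chrom[i]]]
    if (is.null(v)) stop("no track for chromosome ", intervals$chrom[i])
    b <- intervals$blocks[[i]]
    if (b[nrow(b), 2] > length(v)) stop("interval beyond chromosome bounds")
    x <- unlist(lapply(seq_len(nrow(b)), function(j)
      as.numeric(S4Vectors::window(v, b[j, 1] + 1L, b[j, 2]))),
      use.names = FALSE)
    cov <- !is.na(x)
    covered_fraction[i] <- mean(cov)
    if (any(cov)) mean_score[i] <- sum(x[cov]) / sum(cov)
  }
  data.frame(interval_id = intervals$transcript_id, mean_score = mean_score,
             covered_fraction = covered_fraction, stringsAsFactors = FALSE)
}

#' Sample length-matched un-transcribed control intervals
#'
#' Draws `cfg$n_controls` intervals, each wholly inside a gap of the excluded
#' (transcribed) set, with length uniform on `[min_len, max_len]` truncated to
#' the enclosing gap. Gaps are chosen with probability proportional to their
#' width among gaps at least `min_len` long. When assembly sequence is
#' present, intervals with more than `max_n_fraction` `N` bases are rejected
#' and redrawn. Fully deterministic for a fixed `cfg$seed`.
#'
#' @param assembly a `genome_assembly`.
#' @param excluded a `transcript_set` (or any object with chrom/start/end)
#'   marking every transcribed region; pass the union of gene spans and all
#'   candidate ncRNAs.
#' @param cfg a [control_sampler_config()].
#' @return a `transcript_set` of single-block control intervals.
#' @export
sample_untranscribed_controls <- function(assembly, excluded, cfg) {
  gaps <- do.call(rbind, lapply(assembly$chrom_names, function(cn) {
    len <- assembly$chrom_lengths[[cn]]
    idx <- which(excluded$chrom == cn)
    if (length(idx)) {
      ir <- IRanges::reduce(IRanges::IRanges(excluded$start[idx] + 1L,
                                             excluded$end[idx]))
      gp <- IRanges::gaps(ir, start = 1L, end = len)
    } else gp <- IRanges::IRanges(1L, len)
    if (!length(gp)) return(NULL)
    data.frame(chrom = cn, start = IRanges::start(gp) - 1L,
               end = IRanges::end(gp), stringsAsFactors = FALSE)
  }))
  if (is.null(gaps) || !nrow(gaps))
    stop("no un-transcribed gap of at least min_len; achieved 0 of ",
         cfg$n_controls)
  gaps <- gaps[(gaps$end - gaps$start) >= cfg$min_len, , drop = FALSE]
  if (!nrow(gaps))
    stop("no un-transcribed gap of at least min_len; achieved 0 of ",
         cfg$n_controls)
  w <- gaps$end - gaps$start
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  out_chrom <- character(cfg$n_controls)
  out_start <- out_end <- integer(cfg$n_controls)
  for (k in seq_len(cfg$n_controls)) {
    placed <- FALSE
    for (att in seq_len(cfg$max_attempts)) {
      g <- sample.int(nrow(gaps), 1L, prob = w)
      maxlen <- min(cfg$max_len, w[g])
      lens <- seq.int(cfg$min_len, maxlen)
      len <- lens[sample.int(length(lens), 1L)]
      s <- gaps$start[g] + sample.int(w[g] - len + 1L, 1L) - 1L
      if (!is.null(assembly$sequence)) {
        frag <- substring(assembly$sequence[[gaps$chrom[g]]], s + 1L, s + len)
        nfrac <- lengths(regmatches(frag, gregexpr("N", frag))) / len
        if (nfrac > cfg$max_n_fraction) next
      }
      out_chrom[k] <- gaps$chrom[g]; out_start[k] <- s; out_end[k] <- s + len
      placed <- TRUE
      break
    }
    if (!placed)
      stop("control placement failed; achieved ", k - 1L, " of ",
           cfg$n_controls)
  }
  transcript_set(sprintf("control_%05d", seq_len(cfg$n_controls)),
                 out_chrom, rep("*", cfg$n_controls),
                 lapply(seq_len(cfg$n_controls),
                        function(k) ivmat(out_start[k], out_end[k])),
                 source = "control")
}

#' Empirical cumulative distribution of scores
#'
#' Standard right-continuous ECDF: sorted unique values with the cumulative
#' fraction of observations at or below each.
#'
#' @param values numeric vector with at least one finite value; `NA`s dropped.
#' @return data.frame `value`, `cum_fraction` (nondecreasing, ending at 1).
#' @export
score_ecdf <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  v <- sort(unique(values))
  data.frame(value = v,
             cum_fraction = cumsum(tabulate(match(sort(values), v),
                                            length(v))) / length(values))
}

#' Compare conservation between interval groups
#'
#' Groups are ranked by mean interval score; every ordered pair gets the
#' difference of group means and a one-sided Mann-Whitney (Wilcoxon rank-sum)
#' p-value for the first group scoring higher. Intervals with
#' `covered_fraction` below `min_covered_fraction`, or with no covered base,
#' are dropped (with a message reporting how many).
#'
#' @param groups named list of [interval_mean_score()] outputs.
#' @param min_covered_fraction minimum covered fraction (default 0.2).
#' @return list with `group_means` (sorted decreasing), `ordering` (labels,
#'   most conserved first), `pairs` (label_a, label_b, mean_diff, p_greater)
#'   and `ecdfs` (named list of [score_ecdf()] tables).
#' @export
compare_conservation <- function(groups, min_covered_fraction = 0.2) {
  stopifnot(length(groups) >= 2L, !is.null(names(groups)))
  vals <- lapply(groups, function(g) {
    keep <- !is.na(g$mean_score) & g$covered_fraction >= min_covered_fraction
    if (any(!keep))
      message(sum(!keep), " interval(s) dropped for insufficient coverage")
    g$mean_score[keep]
  })
  if (any(!lengths(vals))) stop("a group lost all intervals to filtering")
  means <- vapply(vals, mean, numeric(1))
  labs <- names(groups)
  pairs <- do.call(rbind, lapply(seq_along(labs), function(a)
    do.call(rbind, lapply(seq_along(labs)[-a], function(b)
      data.frame(label_a = labs[a], label_b = labs[b],
                 mean_diff = means[a] - means[b],
                 p_greater = stats::wilcox.test(
                   vals[[a]], vals[[b]], alternative = "greater",
                   exact = FALSE)$p.value,
                 stringsAsFactors = FALSE)))))
  list(group_means = sort(means, decreasing = TRUE),
       ordering = names(sort(means, decreasing = TRUE)),
       pairs = pairs,
       ecdfs = lapply(vals, score_ecdf))
}
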