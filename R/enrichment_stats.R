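# Region-size-aware overlap significance between TF peak sets and gene
# sets or DHS patterns, H3K27ac bootstrap Z-scores at TF binding sites,
# and the integration matrix combining both per (expression pattern, TF).

#' Build per-gene regulatory domains
#'
#' Assigns each gene the genomic territory used for peak-to-gene
#' attribution: on each chromosome, domain boundaries sit at the
#' midpoints between consecutive TSS, with the first and last domains
#' extending to the chromosome ends. Domains tile each chromosome without
#' overlap, so every peak midpoint is attributed to exactly one gene;
#' their unequal lengths are what the resampling null of
#' [overlap_significance()] accounts for.
#'
#' @param genes Gene models from [gene_models()].
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @return \code{GRanges} of domains with \code{gene_id} metadata, in
#'   gene order along each chromosome.
#' @export
build_regulatory_domains <- function(genes, chrom_sizes) {
  chroms <- unique(as.character(GenomicRanges::seqnames(genes)))
  if (!all(chroms %in% names(chrom_sizes))) {
    stop("chrom_sizes missing: ",
         paste(setdiff(chroms, names(chrom_sizes)), collapse = ", "))
  }
  out <- list()
  for (ch in sort(chroms)) {
    gi <- which(as.character(GenomicRanges::seqnames(genes)) == ch)
    tss <- S4Vectors::mcols(genes)$tss[gi]
    gid <- S4Vectors::mcols(genes)$gene_id[gi]
    o <- order(tss, gid)
    tss <- tss[o]; gid <- gid[o]
    size <- chrom_sizes[[ch]]
    if (any(tss > size)) stop("gene TSS beyond chromosome length on ", ch)
    # 0-based half-open boundaries at floor midpoints, then back to 1-based
    bounds <- c(0, floor((tss[-1] + tss[-length(tss)]) / 2), size)
    out[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(bounds[-length(bounds)] + 1, bounds[-1]),
      gene_id = gid)
  }
  suppressWarnings(do.call(c, unname(out)))
}

#' Genes targeted by a peak set
#'
#' A gene is a target when at least one peak midpoint falls inside its
#' regulatory domain.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param domains Domains from [build_regulatory_domains()].
#' @return Character vector of target gene ids (sorted, unique).
#' @export
peak_targets <- function(peaks, domains) {
  if (length(peaks) == 0L) return(character(0))
  mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                 IRanges::IRanges(interval_midpoint(peaks),
                                                  width = 1L))
  hits <- GenomicRanges::findOverlaps(mids, domains, ignore.strand = TRUE)
  sort(unique(S4Vectors::mcols(domains)$gene_id[S4Vectors::subjectHits(hits)]))
}

# Shared Monte-Carlo machinery: empirical upper-tail p for an observed
# overlap count against resampled same-size sets. Uses the add-one
# (Phipson-Smyth-style) estimator so p is never 0 and strict thresholds
# such as p < 1e-4 remain meaningful.
resample_overlap_p <- function(observed, n_universe, size, indicator,
                               weights, n_resamples, seed) {
  null_counts <- with_local_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      s <- sample.int(n_universe, size, replace = FALSE, prob = weights)
      sum(indicator[s])
    }, 0L)
  })
  list(p = (1 + sum(null_counts >= observed)) / (n_resamples + 1),
       null_mean = mean(null_counts), null_sd = stats::sd(null_counts))
}

#' Significance of a gene set / peak-target overlap
#'
#' Tests whether the genes of a set are peak targets more often than
#' expected, with a null that accounts for the differing sizes of
#' per-gene regulatory regions: resampled gene sets of equal size are
#' drawn without replacement with probability proportional to domain
#' length, so genes with large intergenic territories (which catch peaks
#' by chance) are drawn more often under the null. The empirical p-value
#' uses the add-one estimator
#' \eqn{p = (1 + \#\{null \ge observed\}) / (n_{resamples} + 1)}.
#' When all domains have equal length the null reduces to simple random
#' sampling and the p-value matches the hypergeometric upper tail.
#'
#' @param gene_set Character vector of gene ids (subset of the domain
#'   universe).
#' @param peaks \code{GRanges} of TF peaks.
#' @param domains Domains from [build_regulatory_domains()].
#' @param n_resamples Number of resampled null sets (>= 1000; default
#'   1e5 so that p-values below the 1e-4 significance threshold are
#'   resolvable).
#' @param seed Integer seed.
#' @return An object of class \code{overlap_result}: list with
#'   \code{observed}, \code{size}, \code{null_mean}, \code{null_sd},
#'   \code{p}, \code{n_resamples}.
#' @export
overlap_significance <- function(gene_set, peaks, domains,
                                 n_resamples = 1e5L, seed = 1L) {
  universe <- S4Vectors::mcols(domains)$gene_id
  if (length(gene_set) < 1L) stop("gene_set is empty")
  if (n_resamples < 1000L) stop("n_resamples must be >= 1000")
  if (!all(gene_set %in% universe)) {
    stop("gene_set contains ids outside the domain universe: ",
         paste(utils::head(setdiff(gene_set, universe), 3L), collapse = ", "))
  }
  targets <- peak_targets(peaks, domains)
  indicator <- as.integer(universe %in% targets)
  observed <- sum(gene_set %in% targets)
  res <- resample_overlap_p(observed, length(universe), length(gene_set),
                            indicator, BiocGenerics::width(domains),
                            n_resamples, substream_seed(seed, "gsca"))
  structure(list(observed = observed, size = length(gene_set),
                 null_mean = res$null_mean, null_sd = res$null_sd,
                 p = res$p, n_resamples = n_resamples),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: %d/%d observed (null %.2f +/- %.2f), p = %.3g [%d resamples]\n",
              x$observed, x$size, x$null_mean, x$null_sd, x$p, x$n_resamples))
  invisible(x)
}

#' Overlap significance between DHS patterns and a TF peak set
#'
#' For each eligible pattern (population > 100, strict), counts the
#' pattern's union-DHS rows overlapped by at least one TF peak and
#' compares against equal-size row samples drawn uniformly from the whole
#' union-DHS universe. Uniform (rather than length-weighted) row sampling
#' is used because union DHS are near-constant in width; the choice is a
#' declared strategy of this implementation. Ineligible patterns are
#' skipped with a message.
#'
#' @param table Pattern table from [encode_patterns()] (optionally
#'   classified).
#' @param tf_peaks \code{GRanges} of TF peaks.
#' @param n_resamples,seed As in [overlap_significance()].
#' @param min_population Population-size eligibility cutoff (strict >),
#'   default 100.
#' @return data.frame, one row per eligible code: \code{code},
#'   \code{population}, \code{observed}, \code{null_mean},
#'   \code{null_sd}, \code{p}.
#' @export
dhs_pattern_tf_overlap <- function(table, tf_peaks, n_resamples = 1e5L,
                                   seed = 1L, min_population = 100L) {
  census <- pattern_census(table)
  census$eligible <- census$count > min_population
  skipped <- census$code[!census$eligible]
  if (length(skipped)) {
    message("skipping ", length(skipped),
            " pattern(s) with population <= ", min_population, ": ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  }
  codes <- census$code[census$eligible]
  hit <- as.integer(suppressWarnings(IRanges::overlapsAny(
    table, tf_peaks, ignore.strand = TRUE)))
  all_codes <- S4Vectors::mcols(table)$code
  out <- lapply(codes, function(cd) {
    rows <- which(all_codes == cd)
    observed <- sum(hit[rows])
    res <- resample_overlap_p(observed, length(table), length(rows), hit,
                              NULL, n_resamples,
                              substream_seed(seed, paste0("dhs-", cd)))
    data.frame(code = cd, population = length(rows), observed = observed,
               null_mean = res$null_mean, null_sd = res$null_sd, p = res$p)
  })
  if (length(out) == 0L) {
    return(data.frame(code = character(0), population = integer(0),
                      observed = integer(0), null_mean = numeric(0),
                      null_sd = numeric(0), p = numeric(0)))
  }
  do.call(rbind, out)
}

# Mean binned-track signal over a set of intervals.
track_region_means <- function(track, gr) {
  bs <- track$bin_size
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- BiocGenerics::start(gr)
  end <- BiocGenerics::end(gr)
  vapply(seq_along(gr), function(i) {
    v <- track$counts[[chrom[i]]]
    if (is.null(v)) return(NA_real_)
    b0 <- (start[i] - 1L) %/% bs + 1L
    b1 <- min((end[i] - 1L) %/% bs + 1L, length(v))
    if (b0 > length(v)) return(NA_real_)
    mean(v[b0:b1])
  }, 0)
}

#' Bootstrap Z-score of H3K27ac signal at a subset of TF binding sites
#'
#' Measures whether the TF binding sites attributed to a gene set carry
#' more H3K27 acetylation than TF binding sites at large: the observed
#' mean signal over the site subset is compared with bootstrap means of
#' equal-size site samples (drawn with replacement) from all sites, and
#' reported as \eqn{Z = (obs - mean_{null}) / sd_{null}}. The statistic
#' is invariant to affine rescaling of the signal track.
#'
#' @param sites \code{GRanges} of the TF sites attributed to the gene
#'   set (non-empty).
#' @param all_sites \code{GRanges} of all sites of the same TF data set.
#' @param ac_track [binned_track()] of H3K27ac counts.
#' @param n_boot Bootstrap samples, default 10000.
#' @param seed Integer seed.
#' @return List with \code{z}, \code{observed}, \code{null_mean},
#'   \code{null_sd}, \code{degenerate} (TRUE when the null sd is 0, in
#'   which case \code{z} is reported as 0).
#' @export
h3k27ac_zscore <- function(sites, all_sites, ac_track, n_boot = 10000L,
                           seed = 1L) {
  if (length(sites) == 0L) stop("empty site subset")
  sig_all <- track_region_means(ac_track, all_sites)
  sig_sub <- track_region_means(ac_track, sites)
  observed <- mean(sig_sub, na.rm = TRUE)
  boot <- with_local_seed(substream_seed(seed, "ac-z"), {
    vapply(seq_len(n_boot), function(i) {
      mean(sig_all[sample.int(length(sig_all), length(sites),
                              replace = TRUE)], na.rm = TRUE)
    }, 0)
  })
  mu <- mean(boot)
  sdv <- stats::sd(boot)
  degenerate <- !is.finite(sdv) || sdv == 0
  list(z = if (degenerate) 0 else (observed - mu) / sdv,
       observed = observed, null_mean = mu, null_sd = sdv,
       degenerate = degenerate)
}

#' Integration matrix of expression patterns x TF binding
#'
#' For every (expression pattern, TF-at-stage) cell, combines the
#' region-size-aware overlap p-value ([overlap_significance()]) with the
#' H3K27ac bootstrap Z-score at the TF's binding sites attributed to the
#' pattern's genes ([h3k27ac_zscore()]). Cells are flagged significant at
#' \code{p_threshold} (strict inequality; default 1e-4, the threshold
#' used for this analysis). Stages without TF data simply contribute no
#' columns.
#'
#' @param clusters Named list of gene-id vectors (one per expression
#'   pattern).
#' @param tf_stage_peaks Named list of \code{GRanges}; names of the form
#'   \code{"TF@STAGE"} (e.g. \code{"Tal1@HB"}).
#' @param domains Domains from [build_regulatory_domains()].
#' @param ac_tracks Named list of H3K27ac [binned_track()]s per stage
#'   (may omit stages; Z is \code{NA} for those columns).
#' @param n_resamples Resamples for the overlap p, default 1e5.
#' @param n_boot Bootstrap samples for the Z-score, default 1000.
#' @param seed Integer seed.
#' @param p_threshold Significance flag threshold (strict <), default
#'   1e-4.
#' @return data.frame with one row per (cluster, TF@stage):
#'   \code{cluster}, \code{tf}, \code{stage}, \code{observed}, \code{p},
#'   \code{z}, \code{significant}.
#' @export
integration_matrix <- function(clusters, tf_stage_peaks, domains,
                               ac_tracks = list(), n_resamples = 1e5L,
                               n_boot = 1000L, seed = 1L,
                               p_threshold = 1e-4) {
  stopifnot(length(clusters) > 0L, length(tf_stage_peaks) > 0L)
  keys <- names(tf_stage_peaks)
  parts <- strsplit(keys, "@", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("peak-set names must be 'TF@STAGE'")
  rows <- list()
  for (i in seq_along(keys)) {
    tf <- parts[[i]][1L]
    stage <- parts[[i]][2L]
    peaks <- tf_stage_peaks[[i]]
    targets <- peak_targets(peaks, domains)
    mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                   IRanges::IRanges(interval_midpoint(peaks),
                                                    width = 1L))
    hit_gene <- rep(NA_character_, length(peaks))
    ov <- GenomicRanges::findOverlaps(mids, domains, ignore.strand = TRUE)
    hit_gene[S4Vectors::queryHits(ov)] <-
      S4Vectors::mcols(domains)$gene_id[S4Vectors::subjectHits(ov)]
    for (cl in names(clusters)) {
      genes <- clusters[[cl]]
      ores <- overlap_significance(genes, peaks, domains,
                                   n_resamples = n_resamples,
                                   seed = substream_seed(seed, paste0(keys[i], cl)))
      z <- NA_real_
      if (stage %in% names(ac_tracks)) {
        subset <- peaks[!is.na(hit_gene) & hit_gene %in% genes]
        z <- if (length(subset) == 0L) NA_real_ else {
          h3k27ac_zscore(subset, peaks, ac_tracks[[stage]], n_boot = n_boot,
                         seed = substream_seed(seed, paste0("z", keys[i], cl)))$z
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, tf = tf, stage = stage, observed = ores$observed,
        p = ores$p, z = z, significant = ores$p < p_threshold)
    }
  }
  do.call(rbind, rows)
}
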