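# PWM motif scanning and relative enrichment (RE) statistics: log-odds
# scanning of both strands, bootstrap significance of hit-fraction
# ratios between region sets, the pairwise-unique-DHS RE matrix with
# hierarchical clustering, and motif co-localization within TF peaks.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix (PWM)
#'
#' @param motif_id Motif identifier.
#' @param mat Numeric matrix, positions x 4 (columns A, C, G, T), each
#'   row a probability distribution; motif length >= 4.
#' @param background Background base distribution (4-simplex), default
#'   uniform.
#' @param threshold Hit threshold as a fraction of the maximum attainable
#'   log-odds score, default 0.8.
#' @param tf Optional name of the cognate TF gene (used by [re_matrix()]
#'   to restrict libraries to expressed factors).
#' @return Object of class \code{pwm}.
#' @export
pwm <- function(motif_id, mat, background = rep(0.25, 4), threshold = 0.8,
                tf = NA_character_) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PWM must have 4 base columns")
  if (nrow(mat) < 4L) stop("PWM length must be >= 4")
  if (any(abs(rowSums(mat) - 1) > 1e-6)) {
    stop("each PWM row must sum to 1")
  }
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6) {
    stop("background must be a 4-simplex")
  }
  colnames(mat) <- DNA_BASES
  structure(list(motif_id = motif_id, mat = mat,
                 background = stats::setNames(background, DNA_BASES),
                 threshold = threshold, tf = tf),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", x$motif_id, "|", nrow(x$mat), "bp | consensus",
      pwm_consensus(x), "| threshold", x$threshold, "x max score\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x A [pwm()].
#' @return Character string of most probable bases.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$mat, 1L, which.max)], collapse = "")
}

# Log-odds score matrix with a 5th column for N: an N contributes
# log2(0.25 / mean(background)) at any position (0 for uniform
# background). Small floor keeps log2 finite for zero-probability cells.
pwm_score_matrix <- function(x) {
  p <- pmax(x$mat, 1e-4)
  s <- log2(sweep(p, 2L, x$background, `/`))
  cbind(s, N = log2(0.25 / mean(x$background)))
}

pwm_max_score <- function(x) {
  sum(apply(pwm_score_matrix(x)[, 1:4, drop = FALSE], 1L, max))
}

# Map a DNA string to integer codes A=1 C=2 G=3 T=4 N=5.
encode_dna <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1L]],
             c(DNA_BASES, "N"))
  if (anyNA(v)) stop("sequence contains non-ACGTN characters")
  v
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Score every window of `code` under score matrix S (L x 5).
scan_code <- function(code, S) {
  L <- nrow(S)
  nw <- length(code) - L + 1L
  if (nw < 1L) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    sc <- sc + S[j, code[j:(j + nw - 1L)]]
  }
  sc
}

#' Scan sequences with a PWM on both strands
#'
#' Log-odds scanning: each window of motif length is scored as
#' \eqn{\sum_j \log_2(p_{j,base} / bg_{base})}; windows scoring at least
#' \code{threshold} (a fraction of the maximum attainable score) on
#' either strand are reported. A minus-strand hit at offset \eqn{o}
#' means the reverse complement of the window starting at \eqn{o}
#' (0-based, forward coordinates) matches the motif. \code{N} bases
#' score \eqn{\log_2(0.25 / \overline{bg})}. Sequences shorter than the
#' motif yield no hits.
#'
#' @param seqs Named character vector (or \code{DNAStringSet}) of
#'   sequences over ACGTN.
#' @param x A [pwm()].
#' @param threshold Optional override of the PWM's fractional threshold.
#' @return data.frame with columns \code{seq_id}, \code{offset}
#'   (0-based), \code{strand}, \code{score}.
#' @export
scan_pwm <- function(seqs, x, threshold = NULL) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  thr <- (threshold %||% x$threshold) * pwm_max_score(x)
  S_fwd <- pwm_score_matrix(x)
  # scanning the forward sequence with the reverse-complemented matrix is
  # equivalent to scanning the reverse complement, and keeps offsets in
  # forward coordinates
  S_rev <- S_fwd[rev(seq_len(nrow(S_fwd))), c(4L, 3L, 2L, 1L, 5L), drop = FALSE]
  out <- list()
  for (id in names(seqs)) {
    code <- encode_dna(seqs[[id]])
    for (str in c("+", "-")) {
      sc <- scan_code(code, if (str == "+") S_fwd else S_rev)
      hit <- which(sc >= thr)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = id, offset = hit - 1L, strand = str, score = sc[hit])
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(match(res$seq_id, names(seqs)), res$offset, res$strand), ,
      drop = FALSE]
}

# Per-region hit indicator (>= 1 hit on either strand).
region_has_hit <- function(seqs, x, threshold = NULL) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  hits <- scan_pwm(seqs, x, threshold = threshold)
  names(seqs) %in% hits$seq_id
}

#' Relative motif enrichment between two region sets
#'
#' Compares per-region motif presence between two sequence sets:
#' \eqn{RE = (f_A + \epsilon) / (f_B + \epsilon)} where \eqn{f} is the
#' fraction of regions containing at least one hit and
#' \eqn{\epsilon = 1 / (2 \min(n_A, n_B))} is a pseudocount keeping the
#' ratio finite. Hit counting is presence/absence per region (robust to
#' region length); callers should supply length-matched regions (see
#' [re_matrix()], which centers regions at midpoints with fixed width).
#' Significance of enrichment comes from bootstrapping regions with
#' replacement within each set: the reported p is the (add-one smoothed)
#' fraction of bootstrap replicates with \eqn{RE \le 1}.
#'
#' @param set_a_seqs,set_b_seqs Named character vectors (or
#'   \code{DNAStringSet}) of region sequences; both non-empty.
#' @param x A [pwm()].
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Integer seed.
#' @return Object of class \code{motif_enrichment}: list with
#'   \code{motif_id}, \code{f_a}, \code{f_b}, \code{re}, \code{log2_re},
#'   \code{p}, \code{ci} (bootstrap 2.5/97.5 percentiles of RE),
#'   \code{n_a}, \code{n_b}, \code{n_boot}, \code{no_signal} (TRUE when
#'   neither set contains a hit, in which case RE = 1 by pseudocount).
#' @export
relative_enrichment <- function(set_a_seqs, set_b_seqs, x, n_boot = 1000L,
                                seed = 1L) {
  ha <- region_has_hit(set_a_seqs, x)
  hb <- region_has_hit(set_b_seqs, x)
  n_a <- length(ha); n_b <- length(hb)
  if (n_a == 0L || n_b == 0L) stop("both region sets must be non-empty")
  eps <- 1 / (2 * min(n_a, n_b))
  re_of <- function(fa, fb) (fa + eps) / (fb + eps)
  re <- re_of(mean(ha), mean(hb))
  boot <- with_local_seed(substream_seed(seed, paste0("re-", x$motif_id)), {
    vapply(seq_len(n_boot), function(i) {
      re_of(mean(ha[sample.int(n_a, n_a, replace = TRUE)]),
            mean(hb[sample.int(n_b, n_b, replace = TRUE)]))
    }, 0)
  })
  structure(list(motif_id = x$motif_id, f_a = mean(ha), f_b = mean(hb),
                 re = re, log2_re = log2(re),
                 p = (1 + sum(boot <= 1)) / (n_boot + 1),
                 ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
                 n_a = n_a, n_b = n_b, n_boot = n_boot,
                 no_signal = !any(ha) && !any(hb)),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf(
    "motif_enrichment: %s | f_A = %.3f (n=%d), f_B = %.3f (n=%d) | RE = %.2f [%.2f, %.2f], p = %.3g%s\n",
    x$motif_id, x$f_a, x$n_a, x$f_b, x$n_b, x$re, x$ci[1L], x$ci[2L], x$p,
    if (x$no_signal) " (no signal)" else ""))
  invisible(x)
}

#' Fetch fixed-width, midpoint-centered region sequences
#'
#' Extracts the genomic sequence of each interval after re-centering at
#' the interval midpoint with a fixed width, so that region sets compared
#' by [relative_enrichment()] are length-matched. Regions are clipped at
#' chromosome ends.
#'
#' @param genome Named character vector (or \code{DNAStringSet}) of
#'   chromosome sequences.
#' @param gr \code{GRanges} of regions.
#' @param width Fixed region width in bp, default 400.
#' @return Named character vector of sequences (names = region index).
#' @export
region_sequences <- function(genome, gr, width = 400L) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  mids <- interval_midpoint(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  half <- width %/% 2L
  out <- vapply(seq_along(gr), function(i) {
    s <- genome[[chrom[i]]]
    lo <- max(mids[i] - half + 1L, 1L)
    hi <- min(mids[i] + (width - half), nchar(s))
    substr(s, lo, hi)
  }, "")
  stats::setNames(out, as.character(seq_along(gr)))
}

#' Relative-enrichment matrix over pairwise stage-unique distal DHS
#'
#' For each of the 30 ordered stage pairs (a, b), takes the distal DHS
#' unique to stage a versus b ([unique_stage_dhs()]) as the foreground
#' and the mirror set (unique to b versus a) as the background, and
#' computes \eqn{\log_2 RE} for every motif in the library, optionally
#' restricted to motifs whose cognate TF is expressed at the focal stage
#' (expression >= \code{floor}). Motif rows of the resulting matrix are
#' clustered with average-linkage hierarchical clustering on Euclidean
#' distance; the leaf order of the returned dendrogram is deterministic.
#' Pairs with an empty unique set yield a column of \code{NA} (with a
#' message) and are ignored by the clustering distance.
#'
#' @param table Classified pattern table
#'   ([classify_proximal_distal()]).
#' @param genome Chromosome sequences as in [region_sequences()].
#' @param pwms List of [pwm()] objects.
#' @param expression Optional expression matrix (genes x stages) for the
#'   expressed-TF filter; motifs without a \code{tf} or TFs absent from
#'   the matrix are always kept.
#' @param floor Expression floor (FPKM) for the expressed-TF filter,
#'   default 1.
#' @param width Region width for sequence extraction, default 400.
#' @return List with \code{log2_re} (motifs x 30 pair columns named
#'   \code{"A|B"}), \code{hclust} (or NULL for < 2 usable motif rows)
#'   and \code{leaf_order}.
#' @export
re_matrix <- function(table, genome, pwms, expression = NULL, floor = 1,
                      width = 400L) {
  stages <- hemo_stages()
  pairs <- expand.grid(b = stages, a = stages, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, c("a", "b")]
  motif_ids <- vapply(pwms, `[[`, "", "motif_id")
  mat <- matrix(NA_real_, length(pwms), nrow(pairs),
                dimnames = list(motif_ids,
                                paste(pairs$a, pairs$b, sep = "|")))
  seq_cache <- list()
  get_seqs <- function(a, b) {
    key <- paste(a, b, sep = "|")
    if (is.null(seq_cache[[key]])) {
      u <- unique_stage_dhs(table, a, b)
      seq_cache[[key]] <<- if (length(u) == 0L) character(0) else {
        region_sequences(genome, u, width = width)
      }
    }
    seq_cache[[key]]
  }
  for (j in seq_len(nrow(pairs))) {
    a <- pairs$a[j]; b <- pairs$b[j]
    sa <- get_seqs(a, b)
    sb <- get_seqs(b, a)
    if (length(sa) == 0L || length(sb) == 0L) {
      message("empty unique DHS set for pair ", a, "|", b, "; column is NA")
      next
    }
    eps <- 1 / (2 * min(length(sa), length(sb)))
    for (i in seq_along(pwms)) {
      p <- pwms[[i]]
      if (!is.null(expression) && !is.na(p$tf) &&
          p$tf %in% rownames(expression) &&
          expression[p$tf, a] < floor) {
        next
      }
      fa <- mean(region_has_hit(sa, p))
      fb <- mean(region_has_hit(sb, p))
      mat[i, j] <- log2((fa + eps) / (fb + eps))
    }
  }
  usable <- rowSums(is.finite(mat)) > 0L
  hc <- NULL
  leaf_order <- motif_ids
  if (sum(usable) >= 2L) {
    m <- mat[usable, , drop = FALSE]
    m[!is.finite(m)] <- 0
    hc <- stats::hclust(stats::dist(m), method = "average")
    leaf_order <- c(rownames(m)[hc$order], motif_ids[!usable])
  }
  list(log2_re = mat, hclust = hc, leaf_order = leaf_order)
}

#' Motif co-localization within TF ChIP peaks
#'
#' Tests whether a motif occurs in a TF's peaks more often than in
#' length-matched background regions, via [relative_enrichment()] of
#' peak-centered sequences against background-centered sequences.
#' Co-localization is called significant when the bootstrap p-value is
#' below \code{alpha} (default 0.01). When fewer background regions than
#' peaks are supplied, backgrounds are resampled with replacement to
#' match (with a message).
#'
#' @param tf_peaks Non-empty \code{GRanges} of TF peaks.
#' @param x A [pwm()].
#' @param genome Chromosome sequences as in [region_sequences()].
#' @param background_regions Non-empty \code{GRanges} of background
#'   regions.
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Integer seed.
#' @param width Region width, default 400.
#' @param alpha Significance level on the bootstrap p, default 0.01.
#' @return The [relative_enrichment()] result, with an added
#'   \code{significant} element.
#' @export
motif_colocalization <- function(tf_peaks, x, genome, background_regions,
                                 n_boot = 1000L, seed = 1L, width = 400L,
                                 alpha = 0.01) {
  if (length(tf_peaks) == 0L) stop("empty peak set")
  if (length(background_regions) == 0L) stop("empty background set")
  if (length(background_regions) < length(tf_peaks)) {
    message("background smaller than peak set; sampling with replacement")
    idx <- with_local_seed(substream_seed(seed, "coloc-bg"), {
      sample.int(length(background_regions), length(tf_peaks),
                 replace = TRUE)
    })
    background_regions <- background_regions[idx]
  }
  res <- relative_enrichment(
    region_sequences(genome, tf_peaks, width = width),
    region_sequences(genome, background_regions, width = width),
    x, n_boot = n_boot, seed = seed)
  res$significant <- res$p < alpha
  res
}

#' Read / write PWMs in MEME minimal format
#'
#' Supports the minimal MEME text format: a \code{MOTIF} line followed by
#' a \code{letter-probability matrix} header and one row of A/C/G/T
#' probabilities per position. Background frequencies are taken from a
#' \code{Background letter frequencies} block when present, else uniform.
#'
#' @param path File path.
#' @return \code{read_meme} returns a list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    f <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
    bg <- as.numeric(f[c(2L, 4L, 6L, 8L)])
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    h <- s + 1L
    while (h <= length(lines) && !grepl("letter-probability matrix", lines[h])) {
      h <- h + 1L
    }
    if (h > length(lines)) stop("no letter-probability matrix for motif ", id)
    rows <- list()
    i <- h + 1L
    while (i <= length(lines) &&
           grepl("^\\s*[0-9.eE+-]+\\s", paste0(lines[i], " "))) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
      if (length(v) != 4L || anyNA(v)) break
      rows[[length(rows) + 1L]] <- v
      i <- i + 1L
    }
    out[[id]] <- pwm(id, do.call(rbind, rows), background = bg)
  }
  out
}

#' @rdname read_meme
#' @param pwms List of [pwm()] objects.
#' @export
write_meme <- function(pwms, path) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", DNA_BASES, pwms[[1L]]$background),
                   collapse = " "), "")
  for (p in pwms) {
    lines <- c(lines,
               paste("MOTIF", p$motif_id),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(p$mat)),
               apply(p$mat, 1L, function(r) paste(sprintf("%.6f", r),
                                                  collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
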