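# Chromatin-state segmentation: binarized mark tracks, a multivariate
# hidden Markov model with product-Bernoulli emissions (ChromHMM-style,
# extended with a DNaseI accessibility track), coarse graining to the
# four-state promoter model, and per-gene promoter-state timelines.

CHROMATIN_MARKS <- c("DHS", "H3K4me3", "H3K9ac", "H3K27ac", "H3K27me3")
COARSE_STATES <- c("ACTIVE", "REPRESSED", "POISED", "UNMARKED")
COARSE_LETTERS <- c(ACTIVE = "A", REPRESSED = "R", POISED = "P", UNMARKED = "U")

#' Binned signal track
#'
#' Container for a genome-wide binned count track for one chromatin mark
#' (DHS or a histone modification): one integer vector of per-bin counts
#' per chromosome, with a uniform bin size.
#'
#' @param counts Named list of non-negative integer vectors, one per
#'   chromosome, or a single vector (named "chr1" implicitly is not
#'   assumed; a name is required via \code{names(counts)}).
#' @param bin_size Bin width in bp.
#' @param mark Mark name, one of \code{"DHS"}, \code{"H3K4me3"},
#'   \code{"H3K9ac"}, \code{"H3K27ac"}, \code{"H3K27me3"}.
#' @return An object of class \code{binned_track}.
#' @export
binned_track <- function(counts, bin_size, mark) {
  if (!is.list(counts)) stop("counts must be a named list of per-chrom vectors")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts list must be named by chromosome")
  }
  if (!mark %in% CHROMATIN_MARKS) {
    stop("mark must be one of ", paste(CHROMATIN_MARKS, collapse = ", "))
  }
  if (any(vapply(counts, function(x) any(x < 0), TRUE))) {
    stop("counts must be non-negative")
  }
  structure(list(counts = lapply(counts, as.numeric),
                 bin_size = as.integer(bin_size), mark = mark),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", x$mark, "| bin", x$bin_size, "bp |",
      sum(lengths(x$counts)), "bins on", length(x$counts), "chromosome(s)\n")
  invisible(x)
}

#' Write / read a binned track as TSV (chrom, bin_start, count)
#'
#' \code{bin_start} is the 0-based bp offset of the bin.
#' @param track A [binned_track()].
#' @param path File path.
#' @return \code{write_track} returns \code{path} invisibly;
#'   \code{read_track} returns a \code{binned_track}.
#' @export
write_track <- function(track, path) {
  df <- do.call(rbind, lapply(names(track$counts), function(ch) {
    n <- length(track$counts[[ch]])
    data.frame(chrom = ch, bin_start = (seq_len(n) - 1L) * track$bin_size,
               count = track$counts[[ch]])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @param mark Mark name for the track being read.
#' @export
read_track <- function(path, mark) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  bs <- unique(diff(df$bin_start[df$chrom == df$chrom[1L]]))
  if (length(bs) != 1L) stop("non-uniform bin size in ", path)
  counts <- split(df$count, df$chrom)
  binned_track(counts[unique(df$chrom)], bs, mark)
}

#' Binarize a count track against a global Poisson background
#'
#' A bin is called present (1) when the upper-tail Poisson p-value of its
#' count under the genome-wide mean rate falls below
#' \code{p_threshold}: \eqn{P(X \ge c \mid \lambda = \bar c) < p}. This is
#' the preprocessing step feeding the chromatin-state model; the global
#' (not locally estimated) background keeps the rule transparent and
#' reproducible.
#'
#' @param track A [binned_track()].
#' @param p_threshold Upper-tail significance threshold in (0, 1);
#'   default \code{1e-4}.
#' @return A \code{binned_track} of 0/1 calls (same shape as the input).
#' @export
binarize_track <- function(track, p_threshold = 1e-4) {
  if (!inherits(track, "binned_track")) stop("track must be a binned_track")
  if (sum(lengths(track$counts)) == 0L) stop("empty track")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop("p_threshold must be in (0, 1)")
  }
  lambda <- mean(unlist(track$counts, use.names = FALSE))
  out <- lapply(track$counts, function(x) {
    p <- stats::ppois(x - 1, lambda, lower.tail = FALSE)
    as.numeric(p < p_threshold)
  })
  structure(list(counts = out, bin_size = track$bin_size, mark = track$mark),
            class = "binned_track")
}

# Flatten one binary track per mark into a bins x marks matrix
# (chromosomes concatenated in lexicographic order).
#' Stack binarized mark tracks into an observation matrix
#'
#' @param tracks Named list of binarized [binned_track()] objects, one per
#'   mark; all tracks must share chromosomes, bin size and bin counts.
#' @return Numeric 0/1 matrix (bins x marks) with mark column names; the
#'   chromosome and bin index of each row are kept in attributes
#'   \code{"chrom"} and \code{"bin"} (0-based).
#' @export
tracks_to_matrix <- function(tracks) {
  marks <- names(tracks)
  chroms <- sort(names(tracks[[1L]]$counts))
  for (tr in tracks) {
    if (!identical(sort(names(tr$counts)), chroms)) {
      stop("tracks disagree on chromosomes")
    }
  }
  cols <- lapply(tracks, function(tr) unlist(tr$counts[chroms], use.names = FALSE))
  if (length(unique(lengths(cols))) != 1L) stop("tracks disagree on bin counts")
  x <- do.call(cbind, cols)
  colnames(x) <- marks
  attr(x, "chrom") <- rep(chroms, lengths(tracks[[1L]]$counts[chroms]))
  attr(x, "bin") <- unlist(lapply(tracks[[1L]]$counts[chroms],
                                  function(v) seq_along(v) - 1L), use.names = FALSE)
  x
}

# Log emission densities: obs (T x M) under emissions E (K x M) of
# independent Bernoulli marks. Returns T x K.
bernoulli_loglik <- function(x, emission) {
  x %*% t(log(emission)) + (1 - x) %*% t(log1p(-emission))
}

# Scaled forward pass. Returns list(alpha, scale, logmax, loglik).
hmm_forward <- function(logb, transition, initial) {
  n <- nrow(logb); K <- ncol(logb)
  m <- apply(logb, 1L, max)
  b <- exp(logb - m)
  alpha <- matrix(0, n, K)
  scale <- numeric(n)
  a <- initial * b[1L, ]
  scale[1L] <- sum(a)
  alpha[1L, ] <- a / scale[1L]
  for (t in 2L:n) {
    a <- as.vector(alpha[t - 1L, ] %*% transition) * b[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  list(alpha = alpha, scale = scale, b = b,
       loglik = sum(log(scale)) + sum(m))
}

# Scaled backward pass reusing the forward scaling constants.
hmm_backward <- function(b, transition, scale) {
  n <- nrow(b); K <- ncol(b)
  beta <- matrix(0, n, K)
  beta[n, ] <- 1 / scale[n]
  for (t in (n - 1L):1L) {
    beta[t, ] <- as.vector(transition %*% (b[t + 1L, ] * beta[t + 1L, ])) / scale[t]
  }
  beta
}

# Independent total-likelihood computation from the backward recursion,
# used to cross-check the forward value.
hmm_loglik_backward <- function(logb, transition, initial) {
  m <- apply(logb, 1L, max)
  b <- exp(logb - m)
  n <- nrow(b)
  beta <- rep(1, ncol(b))
  logc <- 0
  if (n >= 2L) {
    for (t in (n - 1L):1L) {
      beta <- as.vector(transition %*% (b[t + 1L, ] * beta))
      s <- sum(beta)
      beta <- beta / s
      logc <- logc + log(s)
    }
  }
  log(sum(initial * b[1L, ] * beta)) + logc + sum(m)
}

# Reorder states into a canonical order (decreasing total emission
# propensity, ties broken mark by mark) so that fitted models are stable
# under label permutation.
canonicalize_model <- function(model) {
  E <- model$emission
  keys <- c(list(-rowSums(E)), lapply(seq_len(ncol(E)), function(m) -E[, m]))
  o <- do.call(order, keys)
  model$emission <- E[o, , drop = FALSE]
  model$transition <- model$transition[o, o, drop = FALSE]
  model$initial <- model$initial[o]
  model
}

#' Fit a multivariate chromatin-state hidden Markov model
#'
#' Baum-Welch expectation maximization for a K-state HMM whose emissions
#' are independent Bernoulli variables, one per binarized mark (DNaseI
#' accessibility plus histone modifications). This is the segmentation
#' model underlying the chromatin-state analysis; the number of states is
#' a free parameter that is subsequently collapsed by [coarse_grain()] to
#' the four-state promoter model, which makes results comparable across
#' choices of \code{K}.
#'
#' Emissions are initialized at the empirical mark frequencies with
#' seed-controlled jitter; transitions start uniform. The per-iteration
#' log-likelihood is non-decreasing (recorded in the returned
#' \code{loglik} trace) and fitting stops when its relative increase
#' drops below \code{tol} or after \code{max_iter} iterations. States of
#' the returned model are relabeled into a canonical emission-sorted
#' order so a given seed always yields the same model.
#'
#' @param x Binary observation matrix (bins x marks), e.g. from
#'   [tracks_to_matrix()].
#' @param K Number of hidden states (>= 1).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param seed Integer seed controlling initialization.
#' @return An object of class \code{chromatin_state_model}: list with
#'   \code{K}, \code{emission} (K x M), \code{transition} (K x K,
#'   row-stochastic), \code{initial}, \code{loglik} (trace),
#'   \code{converged}, \code{marks}.
#' @export
fit_hmm <- function(x, K, max_iter = 100L, tol = 1e-6, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "numeric"
  if (K < 1L) stop("K must be >= 1")
  if (!all(x %in% c(0, 1))) stop("observations must be binary")
  n <- nrow(x); M <- ncol(x)
  n_distinct <- nrow(unique(x))
  if (K > n_distinct) {
    warning("K = ", K, " exceeds the ", n_distinct,
            " distinct observation vectors; expect degenerate states")
  }
  freq <- colMeans(x)
  E <- with_local_seed(substream_seed(seed, "hmm-init"), {
    jitter <- matrix(stats::runif(K * M, -0.25, 0.25), K, M)
    pmin(pmax(matrix(freq, K, M, byrow = TRUE) + jitter, 0.02), 0.98)
  })
  A <- matrix(1 / K, K, K)
  init <- rep(1 / K, K)
  eps <- 1e-6
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logb <- bernoulli_loglik(x, E)
    fw <- hmm_forward(logb, A, init)
    beta <- hmm_backward(fw$b, A, fw$scale)
    gamma <- fw$alpha * beta
    gamma <- gamma / rowSums(gamma)
    ll_trace <- c(ll_trace, fw$loglik)
    if (iter > 1L) {
      delta <- fw$loglik - ll_trace[iter - 1L]
      if (delta < tol * abs(ll_trace[iter - 1L])) {
        converged <- TRUE
        break
      }
    }
    # transition expected counts
    if (K > 1L && n > 1L) {
      xi_num <- matrix(0, K, K)
      bb <- fw$b * beta
      for (t in seq_len(n - 1L)) {
        xi_num <- xi_num + (fw$alpha[t, ] %o% bb[t + 1L, ])
      }
      A_new <- A * xi_num
      A <- A_new / rowSums(A_new)
    }
    denom <- colSums(gamma)
    E <- t(gamma) %*% x / denom
    E <- pmin(pmax(E, eps), 1 - eps)
    init <- gamma[1L, ]
    init <- pmin(pmax(init, eps), 1)
    init <- init / sum(init)
  }
  model <- structure(
    list(K = as.integer(K), emission = E, transition = A, initial = init,
         loglik = ll_trace, converged = converged,
         marks = colnames(x) %||% paste0("mark", seq_len(M))),
    class = "chromatin_state_model")
  rownames(model$emission) <- NULL
  colnames(model$emission) <- model$marks
  canonicalize_model(model)
}

#' @export
print.chromatin_state_model <- function(x, ...) {
  cat("chromatin_state_model:", x$K, "states x", length(x$marks), "marks;",
      length(x$loglik), "EM iterations;",
      if (x$converged) "converged" else "not converged", "\n")
  cat("final log-likelihood:", format(utils::tail(x$loglik, 1L)), "\n")
  print(round(x$emission, 3))
  invisible(x)
}

#' Decode the most probable state path
#'
#' Viterbi decoding of a fitted [fit_hmm()] model over a binary
#' observation matrix with the same marks.
#'
#' @param model A \code{chromatin_state_model}.
#' @param x Binary observation matrix (bins x marks); column names must
#'   match \code{model$marks}.
#' @return Integer vector of state labels (1..K) per bin, in the
#'   model's canonical state order.
#' @export
decode_states <- function(model, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "numeric"
  if (!is.null(colnames(x)) && !identical(colnames(x), model$marks)) {
    stop("observation marks do not match the model: got ",
         paste(colnames(x), collapse = ","))
  }
  if (ncol(x) != length(model$marks)) stop("wrong number of mark columns")
  logb <- bernoulli_loglik(x, model$emission)
  n <- nrow(logb); K <- ncol(logb)
  logA <- log(model$transition)
  delta <- log(model$initial) + logb[1L, ]
  psi <- matrix(0L, n, K)
  for (t in seq_len(n - 1L) + 1L) {
    cand <- delta + logA  # K x K: previous state rows, next state cols
    psi[t, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(psi[t, ], seq_len(K))] + logb[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1L) {
    for (t in n:2L) path[t - 1L] <- psi[t, path[t]]
  }
  path
}

# The four-state coarse-graining rule, vectorized over logical mark calls.
coarse_rule <- function(dhs, k4, k9ac, k27ac, k27me3) {
  ac <- k9ac | k27ac
  out <- rep("UNMARKED", length(dhs))
  out[k27me3] <- "REPRESSED"
  out[dhs & k4 & ac & !(dhs & k27me3 & (k4 | ac))] <- "ACTIVE"
  out[dhs & k27me3 & (k4 | ac)] <- "POISED"
  factor(out, levels = COARSE_STATES)
}

#' Coarse-grain chromatin marks to the four-state model
#'
#' Collapses mark combinations to the four-state promoter model: a region
#' is \emph{poised} when accessible (DHS) and carrying H3K27me3 together
#' with H3K4me3 and/or acetylated H3; otherwise \emph{active} when
#' accessible with H3K4me3 and acetylated H3 (H3K9ac or H3K27ac);
#' otherwise \emph{repressed} when carrying H3K27me3; otherwise
#' \emph{unmarked}. The four rules partition every mark combination, so
#' the function is total.
#'
#' Two inputs are supported: a fitted [fit_hmm()] model, whose per-state
#' emission probabilities are thresholded at \code{threshold} to yield one
#' coarse label per hidden state; or a matrix / data.frame of per-region
#' mark calls (0/1 or logical) with columns named \code{DHS},
#' \code{H3K4me3}, \code{H3K9ac}, \code{H3K27ac}, \code{H3K27me3}.
#'
#' @param x Model or mark-call matrix (see Details).
#' @param ... Passed to methods.
#' @return Factor of labels \code{ACTIVE}, \code{REPRESSED},
#'   \code{POISED}, \code{UNMARKED}; one per state (model input) or per
#'   row (matrix input).
#' @export
coarse_grain <- function(x, ...) UseMethod("coarse_grain")

#' @rdname coarse_grain
#' @param threshold Emission probability above which a mark counts as
#'   present for a state (default 0.5).
#' @export
coarse_grain.chromatin_state_model <- function(x, threshold = 0.5, ...) {
  pres <- x$emission >= threshold
  colnames(pres) <- x$marks
  coarse_grain(pres)
}

#' @rdname coarse_grain
#' @export
coarse_grain.default <- function(x, ...) {
  x <- as.matrix(x)
  need <- CHROMATIN_MARKS
  if (!all(need %in% colnames(x))) {
    stop("mark matrix must have columns ", paste(need, collapse = ", "))
  }
  mode(x) <- "logical"
  coarse_rule(x[, "DHS"], x[, "H3K4me3"], x[, "H3K9ac"],
              x[, "H3K27ac"], x[, "H3K27me3"])
}

#' Per-gene promoter chromatin-state timelines
#'
#' Labels each gene's promoter (TSS +/- \code{halfwidth}) with a coarse
#' chromatin state at every stage and concatenates the labels into a
#' six-letter string (A = active, R = repressed, P = poised,
#' U = unmarked), e.g. \code{"UUPAAA"} for a promoter that is poised at
#' the hemangioblast stage and active thereafter. The promoter label is
#' the majority coarse state over the window's bins; ties are broken by
#' the precedence POISED > ACTIVE > REPRESSED > UNMARKED, which preserves
#' the rarer, more informative states. A promoter window overlapping no
#' bins is labeled with the sentinel \code{"N"} and a warning is issued.
#'
#' @param genes Gene models from [gene_models()].
#' @param binarized Nested list: \code{binarized[[stage]][[mark]]} is a
#'   binarized [binned_track()]; stages must cover [hemo_stages()] and
#'   marks must cover the five chromatin marks.
#' @param halfwidth Promoter half-window in bp (default 1000, i.e. 1 kb
#'   up- or downstream of the TSS).
#' @return Named character vector of 6-letter state strings per gene.
#' @export
promoter_state_timeline <- function(genes, binarized, halfwidth = 1000L) {
  stages <- hemo_stages()
  if (!all(stages %in% names(binarized))) {
    stop("binarized tracks must be supplied for all six stages")
  }
  gid <- S4Vectors::mcols(genes)$gene_id
  tss <- S4Vectors::mcols(genes)$tss
  chrom <- as.character(GenomicRanges::seqnames(genes))
  out <- matrix("N", nrow = length(genes), ncol = length(stages))
  missing_any <- FALSE
  for (s in seq_along(stages)) {
    tracks <- binarized[[stages[s]]]
    if (!all(CHROMATIN_MARKS %in% names(tracks))) {
      stop("stage ", stages[s], " must provide marks ",
           paste(CHROMATIN_MARKS, collapse = ", "))
    }
    bs <- tracks[[1L]]$bin_size
    for (g in seq_along(genes)) {
      lo <- max(tss[g] - halfwidth, 1L)
      hi <- tss[g] + halfwidth
      b0 <- (lo - 1L) %/% bs
      b1 <- (hi - 1L) %/% bs
      nb <- length(tracks[[1L]]$counts[[chrom[g]]]) %||% 0L
      if (is.null(tracks[[1L]]$counts[[chrom[g]]]) || b0 >= nb) {
        missing_any <- TRUE
        next
      }
      idx <- (b0:min(b1, nb - 1L)) + 1L
      calls <- vapply(CHROMATIN_MARKS,
                      function(m) tracks[[m]]$counts[[chrom[g]]][idx],
                      numeric(length(idx)))
      if (length(idx) == 1L) calls <- matrix(calls, nrow = 1L,
                                             dimnames = list(NULL, CHROMATIN_MARKS))
      lab <- coarse_grain(calls)
      counts <- table(lab)
      best <- names(counts)[counts == max(counts)]
      pick <- c("POISED", "ACTIVE", "REPRESSED", "UNMARKED")
      winner <- pick[pick %in% best][1L]
      out[g, s] <- COARSE_LETTERS[[winner]]
    }
  }
  if (missing_any) {
    warning("some promoter windows overlapped no bins; labeled 'N'")
  }
  stats::setNames(apply(out, 1L, paste, collapse = ""), gid)
}
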