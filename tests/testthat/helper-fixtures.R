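# Shared, memoised fixtures. Everything is generated in code at test time;
# the noise-free variants are the planted-truth baselines, the noisy ones
# exercise robustness.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(name, build) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# compact genome (2 x 2.5 Mb, 560 planted DHS) used by unit tests
small_zero_config <- function(seed = 2L, ...) {
  fixture_config(
    seed = seed, n_chroms = 2L, chrom_length = 2.5e6,
    jitter_bp = 0L, replicate_dropout_rate = 0, count_mode = "none",
    expression_noise_sd = 0,
    # the compact genome carries a higher enriched-bin fraction, which
    # lifts the global Poisson mean; a slightly stronger planted signal
    # keeps deterministic binarization exact
    enriched_rate = 10,
    distal_pattern_counts = c(
      "100000" = 60L, "010000" = 40L, "001000" = 40L, "000100" = 40L,
      "000010" = 20L, "000001" = 80L, "110000" = 20L, "000110" = 30L,
      "000011" = 20L, "001110" = 20L, "111111" = 30L),
    ...)
}

small_fx <- function() {
  cache_get("small_fx", function() generate_fixture(small_zero_config()))
}

# reproducible DHS sets, classified pattern table, promoter timelines
small_pipeline <- function() {
  cache_get("small_pipeline", function() {
    fx <- small_fx()
    rep_sets <- lapply(fx$dhs_peaks, filter_reproducible)
    tab <- classify_proximal_distal(encode_patterns(rep_sets), fx$genes)
    binz <- lapply(fx$tracks, function(stg) lapply(stg, binarize_track))
    tl <- promoter_state_timeline(fx$genes, binz)
    list(fx = fx, stage_sets = rep_sets, tab = tab, timelines = tl)
  })
}

small_grns <- function() {
  cache_get("small_grns", function() {
    pipe <- small_pipeline()
    fx <- pipe$fx
    panel <- rownames(fx$config$tf_panel$expression)
    lapply(hemo_stages(), function(st) {
      tfp <- list()
      for (tf in panel) {
        if (st %in% names(fx$tf_peaks[[tf]])) {
          tfp[[tf]] <- filter_reproducible(fx$tf_peaks[[tf]][[st]])
        }
      }
      build_stage_grn(st, tfp, panel, fx$genes, pipe$timelines, pipe$tab,
                      fx$expression, fx$chrom_sizes)
    })
  })
}

# full-size noise-free fixture (2 x 5 Mb, 2,000 distal DHS, genome with
# embedded motifs) shared by the acceptance tests
acc_fx <- function() {
  cache_get("acc_fx", function() {
    generate_fixture(fixture_config(
      seed = 11L, jitter_bp = 0L, replicate_dropout_rate = 0,
      count_mode = "none", expression_noise_sd = 0))
  })
}

acc_pipeline <- function() {
  cache_get("acc_pipeline", function() {
    fx <- acc_fx()
    rep_sets <- lapply(fx$dhs_peaks, filter_reproducible)
    tab <- classify_proximal_distal(encode_patterns(rep_sets), fx$genes)
    list(fx = fx, stage_sets = rep_sets, tab = tab)
  })
}

# all permutations of 1..n (for optimal HMM state matching, small n)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# best state-label permutation by total absolute emission difference
match_states <- function(emission, truth_emission) {
  perms <- all_perms(seq_len(nrow(emission)))
  errs <- vapply(perms, function(p) {
    sum(abs(emission[p, , drop = FALSE] - truth_emission))
  }, 0)
  perms[[which.min(errs)]]
}

# random interval set on one chromosome
random_granges <- function(n, chrom = "chr1", max_pos = 1e5, width = 50) {
  s <- sort(sample.int(max_pos - width, n))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, width = width))
}

# independent per-window PWM scan oracle: explicit loops and explicit
# reverse-complement handling (forward-coordinate offsets)
oracle_scan <- function(seq, mat, background, thr_frac) {
  bases <- c("A", "C", "G", "T")
  sc_one <- function(window, m) {
    tot <- 0
    for (j in seq_len(nrow(m))) {
      b <- substr(window, j, j)
      tot <- tot + if (b == "N") {
        log2(0.25 / mean(background))
      } else {
        log2(max(m[j, b], 1e-4) / background[match(b, bases)])
      }
    }
    tot
  }
  m <- mat
  colnames(m) <- bases
  maxsc <- sum(apply(log2(pmax(m, 1e-4) / rep(background, each = nrow(m))),
                     1, max))
  thr <- thr_frac * maxsc
  L <- nrow(m)
  n <- nchar(seq)
  hits <- list()
  if (n >= L) {
    for (o in 0:(n - L)) {
      w <- substr(seq, o + 1, o + L)
      s_f <- sc_one(w, m)
      if (s_f >= thr) hits[[length(hits) + 1L]] <- c(o, 1L, s_f)
      w_rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(w)))
      s_r <- sc_one(w_rc, m)
      if (s_r >= thr) hits[[length(hits) + 1L]] <- c(o, 2L, s_r)
    }
  }
  if (!length(hits)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  h <- do.call(rbind, hits)
  data.frame(offset = as.integer(h[, 1]), strand = c("+", "-")[h[, 2]],
             score = h[, 3])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant a motif instance into a random sequence at a random offset
seq_with_motif <- function(len, motif) {
  s <- random_dna(len)
  o <- sample.int(len - nchar(motif), 1L)
  paste0(substr(s, 1, o), motif, substr(s, o + nchar(motif) + 1, len))
}
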