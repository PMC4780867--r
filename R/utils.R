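# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package code never perturbs the
# session stream.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a named substream seed from a global seed. Adding a new substream
# never shifts the draws of existing ones because each stream is seeded
# independently from (seed, name). Result is kept inside 32-bit range.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 1048573
  as.integer((as.numeric(seed) %% 65521) * 32749 + h * 17 + 1)
}

# Midpoint of 1-based closed intervals, matching floor((bed_start + bed_end)/2)
# on the equivalent 0-based half-open interval.
interval_midpoint <- function(gr) {
  as.integer(floor((BiocGenerics::start(gr) - 1 + BiocGenerics::end(gr)) / 2))
}

# Sort a GRanges by plain lexicographic (chrom, start, end) tuple order,
# independent of seqlevel factor order.
sort_lex <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             BiocGenerics::start(gr), BiocGenerics::end(gr))
  gr[o]
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    stop(name, " must be a single number >= ", lower)
  }
  invisible(x)
}
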