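# DHS dynamics: replicate reproducibility filtering, cross-stage union,
# six-digit binary pattern codes, proximal/distal classification, pattern
# census with the population filter, and cell-type-unique distal sets.

#' Keep regions supported by at least two replicates
#'
#' Implements the reproducibility rule used throughout the analysis:
#' only genomic regions found in at least two independent biological
#' experiments are retained. Support is counted per base pair: each
#' replicate's peaks are first collapsed, the per-bp replicate support is
#' accumulated, and the merged stretches where support reaches
#' \code{min_support} (>= 1 bp of mutual overlap between replicates) are
#' returned.
#'
#' @param replicates List (length >= 2) of \code{GRanges} peak sets, one
#'   per biological replicate.
#' @param min_support Minimum number of supporting replicates, default 2.
#' @return Sorted, merged \code{GRanges} of reproducible regions.
#' @export
filter_reproducible <- function(replicates, min_support = 2L) {
  if (!is.list(replicates) || length(replicates) < 2L) {
    stop("need at least 2 replicate peak sets")
  }
  covs <- lapply(replicates, function(gr) {
    GenomicRanges::coverage(GenomicRanges::reduce(gr, ignore.strand = TRUE))
  })
  chroms <- sort(unique(unlist(lapply(covs, names))))
  out <- list()
  for (ch in chroms) {
    per <- lapply(covs, function(cv) {
      if (ch %in% names(cv)) cv[[ch]] else S4Vectors::Rle(0L, 0L)
    })
    len <- max(vapply(per, length, 0L))
    if (len == 0L) next
    total <- Reduce(`+`, lapply(per, function(r) {
      if (length(r) < len) c(r, S4Vectors::Rle(0L, len - length(r))) else r
    }))
    hits <- IRanges::slice(total, lower = min_support, rangesOnly = TRUE)
    if (length(hits)) {
      out[[length(out) + 1L]] <- GenomicRanges::GRanges(ch, hits)
    }
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  sort_lex(GenomicRanges::reduce(suppressWarnings(do.call(c, unname(out))),
                                 ignore.strand = TRUE))
}

#' Encode DHS presence across the six stages as binary codes
#'
#' Builds the union of reproducible DHS across all six stages (merged
#' with gap 0, so each union row is the atomic element of all downstream
#' pattern analyses) and assigns each union row a six-character code over
#' \{0,1\}: digit \eqn{s} is 1 when the row overlaps a stage-\eqn{s} peak
#' (>= 1 bp), in the fixed order ESC, MES, HB, HE, HP, MAC. For example
#' \code{"111111"} is constitutively open chromatin and \code{"000110"}
#' is open only in hemogenic endothelium and hematopoietic progenitors.
#' The encoding is invariant to the order in which the stage sets are
#' supplied (they are matched by name).
#'
#' @param stage_sets Named list of six \code{GRanges} (names =
#'   [hemo_stages()]), typically outputs of [filter_reproducible()].
#' @return \code{GRanges} of union DHS with a \code{code} metadata
#'   column (the pattern table; extend with
#'   [classify_proximal_distal()]).
#' @export
encode_patterns <- function(stage_sets) {
  stages <- hemo_stages()
  if (!all(stages %in% names(stage_sets))) {
    stop("stage_sets must be named with all of ",
         paste(stages, collapse = ", "))
  }
  stage_sets <- stage_sets[stages]
  union <- sort_lex(GenomicRanges::reduce(
    suppressWarnings(do.call(c, unname(lapply(stage_sets, function(g)
      GenomicRanges::granges(g))))),
    ignore.strand = TRUE))
  bits <- vapply(stage_sets, function(g) {
    as.integer(IRanges::overlapsAny(union, g, ignore.strand = TRUE))
  }, integer(length(union)))
  if (length(union) == 1L) bits <- matrix(bits, nrow = 1L)
  S4Vectors::mcols(union)$code <- apply(bits, 1L, paste, collapse = "")
  union
}

#' Classify union DHS as promoter-proximal or distal
#'
#' A union DHS is \emph{proximal} when its midpoint lies within
#' \code{cutoff} bp of the nearest TSS (boundary inclusive; the default
#' 1 kb matches the promoter window used for promoter-state calling, so
#' "proximal" and "promoter" mean the same thing throughout), and
#' \emph{distal} otherwise. The nearest gene and the signed midpoint-TSS
#' distance are recorded.
#'
#' @param table Pattern table from [encode_patterns()].
#' @param genes Gene models from [gene_models()].
#' @param cutoff Proximal distance cutoff in bp, default 1000.
#' @return The input \code{GRanges} with added metadata columns
#'   \code{class}, \code{nearest_gene}, \code{distance}.
#' @export
classify_proximal_distal <- function(table, genes, cutoff = 1000L) {
  if (length(table) == 0L) {
    S4Vectors::mcols(table)$class <- character(0)
    S4Vectors::mcols(table)$nearest_gene <- character(0)
    S4Vectors::mcols(table)$distance <- integer(0)
    return(table)
  }
  res <- nearest_tss_many(interval_midpoint(table),
                          as.character(GenomicRanges::seqnames(table)), genes)
  S4Vectors::mcols(table)$class <- ifelse(abs(res$distance) <= cutoff,
                                          "proximal", "distal")
  S4Vectors::mcols(table)$nearest_gene <- res$gene_id
  S4Vectors::mcols(table)$distance <- res$distance
  table
}

#' Census of DHS pattern populations
#'
#' Counts union DHS per six-digit code and flags the codes whose
#' population exceeds 100 elements; only those patterns are eligible for
#' the pattern-level overlap significance analysis (strict inequality:
#' a population of exactly 100 is not eligible).
#'
#' @param table Pattern table from [encode_patterns()].
#' @return data.frame with columns \code{code}, \code{count},
#'   \code{eligible}, sorted by decreasing count.
#' @export
pattern_census <- function(table) {
  if (length(table) == 0L) {
    return(data.frame(code = character(0), count = integer(0),
                      eligible = logical(0)))
  }
  tab <- table(S4Vectors::mcols(table)$code)
  df <- data.frame(code = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$code), , drop = FALSE]
  df$eligible <- df$count > 100L
  rownames(df) <- NULL
  df
}

#' Distal DHS unique to one stage relative to another
#'
#' Selects the distal union DHS open in stage \code{a} but closed in
#' stage \code{b} -- the pairwise "unique to a given cell type" sets that
#' feed the relative motif-enrichment matrix. All 30 ordered stage pairs
#' are meaningful; callers wanting DHS unique to \code{a} versus every
#' other stage can intersect the five pairwise results.
#'
#' @param table Classified pattern table
#'   (from [classify_proximal_distal()]).
#' @param stage_a,stage_b Distinct stage names.
#' @return Subset of \code{table} with bit(a) = 1, bit(b) = 0 and
#'   class \code{"distal"}.
#' @export
unique_stage_dhs <- function(table, stage_a, stage_b) {
  ia <- stage_index(stage_a)
  ib <- stage_index(stage_b)
  if (ia == ib) stop("stage_a and stage_b must differ")
  code <- S4Vectors::mcols(table)$code
  keep <- substr(code, ia, ia) == "1" & substr(code, ib, ib) == "0" &
    S4Vectors::mcols(table)$class == "distal"
  table[keep]
}
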