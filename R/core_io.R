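#' Read a BED file of genomic intervals
#'
#' Reads a BED3/BED6 file (tab-separated, 0-based half-open) into a
#' \link[GenomicRanges]{GRanges} (1-based closed, the package-wide internal
#' convention). Optional columns 4--6 are kept as \code{name}, \code{score}
#' and strand. Lines starting with \code{track}, \code{browser} or \code{#}
#' are skipped. Chromosome names are compared verbatim throughout the
#' package (no "chr" stripping), so mixed naming dialects surface as
#' zero-overlap results rather than being silently papered over.
#'
#' @param path Path to an existing BED file.
#' @return A \code{GRanges}, sorted by lexicographic (chrom, start, end).
#' @seealso [write_bed()], [sort_merge()]
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t10\t20", "chr1\t5\t8"), p)
#' read_bed(p)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 3L)
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]],
         ": non-numeric coordinates or empty chrom")
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop("invalid interval at BED line ", idx[bad[1L]],
         ": need end > start >= 0 (got [", start[bad[1L]], ",",
         end[bad[1L]], "))")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (any(n >= 4L)) {
    S4Vectors::mcols(gr)$name <- vapply(fields, function(f) {
      if (length(f) >= 4L) f[[4L]] else NA_character_
    }, "")
  }
  if (any(n >= 5L)) {
    S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")
    ))
  }
  if (any(n >= 6L)) {
    st <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", "")
    bad <- which(!st %in% c("+", "-", "."))
    if (length(bad)) {
      stop("malformed BED line ", idx[bad[1L]], ": bad strand '", st[bad[1L]], "'")
    }
    BiocGenerics::strand(gr) <- sub("^\\.$", "*", st)
  }
  sort_lex(gr)
}

#' Write genomic intervals to a BED file
#'
#' Inverse of [read_bed()]: converts internal 1-based closed coordinates
#' back to BED's 0-based half-open convention. \code{name}, \code{score}
#' and strand columns are written when present (missing entries padded so
#' that the field count is constant per file).
#'
#' @param gr A \code{GRanges}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(gr, path) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- BiocGenerics::start(gr) - 1L
  end <- BiocGenerics::end(gr)
  mc <- S4Vectors::mcols(gr)
  strand_chr <- sub("^\\*$", ".", as.character(BiocGenerics::strand(gr)))
  has_strand <- any(strand_chr != ".")
  cols <- list(chrom, start, end)
  if ("name" %in% names(mc) || "score" %in% names(mc) || has_strand) {
    cols <- c(cols, list(if ("name" %in% names(mc)) ifelse(is.na(mc$name), ".", mc$name)
                         else rep(".", length(gr))))
  }
  if ("score" %in% names(mc) || has_strand) {
    cols <- c(cols, list(if ("score" %in% names(mc)) ifelse(is.na(mc$score), 0, mc$score)
                         else rep(0, length(gr))))
  }
  if (has_strand) cols <- c(cols, list(strand_chr))
  tab <- do.call(paste, c(cols, sep = "\t"))
  writeLines(tab, path)
  invisible(path)
}

#' Sort and merge intervals within a gap tolerance
#'
#' Standard interval-union primitive used throughout the pipeline (union
#' DHS construction, reproducibility filtering). Two intervals are merged
#' when they overlap, abut, or are separated by at most \code{gap} bp.
#' The operation is idempotent and metadata columns are dropped.
#'
#' @param gr A \code{GRanges}.
#' @param gap Non-negative merge distance in bp (default 0: merge
#'   overlapping or bookended intervals only).
#' @return A sorted, non-overlapping \code{GRanges}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 26), c(20, 30)))
#' sort_merge(gr, gap = 5)
#' @export
sort_merge <- function(gr, gap = 0) {
  stopifnot_scalar_number(gap, "gap", lower = 0)
  out <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1, ignore.strand = TRUE)
  sort_lex(out)
}

#' Construct a table of gene models
#'
#' Builds the package's gene-model container: a \code{GRanges} of gene
#' spans with \code{gene_id} and \code{tss} metadata. The TSS is the
#' promoter anchor used for promoter windows (TSS +/- 1 kb), proximal /
#' distal classification and nearest-gene assignment.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome names.
#' @param start,end 1-based closed span coordinates.
#' @param strand "+" or "-" per gene.
#' @param tss Optional TSS positions; defaults to \code{start} on "+" and
#'   \code{end} on "-". Must lie inside (or on the boundary of) the span.
#' @return \code{GRanges} with \code{gene_id} and \code{tss} metadata.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, tss = NULL) {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (is.null(tss)) tss <- ifelse(strand == "+", start, end)
  if (any(tss < start | tss > end)) {
    stop("tss must lie within the gene span")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  S4Vectors::mcols(gr)$tss <- as.integer(tss)
  sort_lex(gr)
}

#' Read gene models from a GTF file
#'
#' Uses \code{rtracklayer} to parse GTF (1-based inclusive) and extracts
#' one model per gene from \code{gene} features (falling back to
#' \code{transcript} features when no \code{gene} rows exist). The TSS is
#' the strand-aware 5' end of the feature.
#'
#' @param path Path to a GTF file.
#' @return \code{GRanges} as produced by [gene_models()].
#' @export
read_gtf_genes <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  type <- as.character(S4Vectors::mcols(g)$type)
  g <- g[type %in% if ("gene" %in% type) "gene" else "transcript"]
  if (length(g) == 0L) stop("no gene or transcript features in ", path)
  strand_chr <- as.character(BiocGenerics::strand(g))
  if (any(strand_chr == "*")) stop("gene features must be stranded")
  gene_models(
    gene_id = as.character(S4Vectors::mcols(g)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = BiocGenerics::start(g),
    end = BiocGenerics::end(g),
    strand = strand_chr
  )
}

#' Write gene models as GTF
#'
#' @param genes \code{GRanges} from [gene_models()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return Invisibly, \code{path}.
#' @export
write_gtf_genes <- function(genes, path, source = "hemodyn") {
  lines <- sprintf(
    "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    as.character(GenomicRanges::seqnames(genes)), source,
    BiocGenerics::start(genes), BiocGenerics::end(genes),
    as.character(BiocGenerics::strand(genes)),
    S4Vectors::mcols(genes)$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}

# Vectorized nearest-TSS lookup. mids/chroms describe query midpoints;
# ties on |mid - tss| are broken by the lexicographically smaller gene_id
# so results are reproducible. Returns a data.frame (gene_id, distance)
# where distance is signed by the gene's strand (positive = downstream).
nearest_tss_many <- function(mids, chroms, genes) {
  gid <- S4Vectors::mcols(genes)$gene_id
  tss <- S4Vectors::mcols(genes)$tss
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  gstrand <- as.character(BiocGenerics::strand(genes))
  out_gene <- character(length(mids))
  out_dist <- integer(length(mids))
  for (ch in unique(chroms)) {
    qi <- which(chroms == ch)
    gi <- which(gchrom == ch)
    if (length(gi) == 0L) {
      stop("no gene models on chromosome ", ch)
    }
    # order candidate genes by (tss, gene_id) so that among equidistant
    # TSS the smaller gene_id wins deterministically
    gi <- gi[order(tss[gi], gid[gi])]
    t_ch <- tss[gi]
    for (q in qi) {
      d <- abs(mids[q] - t_ch)
      best <- which(d == min(d))
      if (length(best) > 1L) {
        best <- best[order(gid[gi[best]])[1L]]
      }
      j <- gi[best]
      out_gene[q] <- gid[j]
      raw <- mids[q] - tss[j]
      out_dist[q] <- if (gstrand[j] == "-") -raw else raw
    }
  }
  data.frame(gene_id = out_gene, distance = out_dist,
             stringsAsFactors = FALSE)
}

#' Nearest TSS to a genomic interval
#'
#' Finds the gene whose TSS is closest to the query's midpoint (the
#' package-wide peak anchor). Distance is signed by the gene's strand:
#' positive values are downstream of the TSS in the gene's orientation.
#' Ties on absolute distance are broken by the lexicographically smaller
#' \code{gene_id}.
#'
#' @param query A length-1 \code{GRanges}.
#' @param genes Gene models from [gene_models()].
#' @return A list with elements \code{gene_id}, \code{tss},
#'   \code{distance} (signed bp).
#' @export
nearest_tss <- function(query, genes) {
  if (length(genes) == 0L) stop("gene list is empty")
  if (length(query) != 1L) stop("query must be a single interval")
  res <- nearest_tss_many(interval_midpoint(query),
                          as.character(GenomicRanges::seqnames(query)), genes)
  j <- match(res$gene_id, S4Vectors::mcols(genes)$gene_id)
  list(gene_id = res$gene_id, tss = S4Vectors::mcols(genes)$tss[j],
       distance = res$distance)
}
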