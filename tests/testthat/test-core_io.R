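test_that("read_bed maps fields, validates intervals and sorts", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", p)
  gr <- read_bed(p)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), "chr1")
  expect_equal(BiocGenerics::start(gr), 11)  # 0-based half-open in, 1-based closed out
  expect_equal(BiocGenerics::end(gr), 20)

  writeLines("chr1\t20\t10", p)
  expect_error(read_bed(p), "end > start")

  writeLines(c("chr2\t5\t9", "chr1\t30\t40", "chr1\t10\t20"), p)
  gr <- read_bed(p)
  expect_length(gr, 3)
  # tuple-sort oracle computed independently from the raw fields
  raw <- data.frame(chrom = c("chr2", "chr1", "chr1"), start = c(5, 30, 10))
  o <- order(raw$chrom, raw$start)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), raw$chrom[o])
  expect_equal(BiocGenerics::start(gr), raw$start[o] + 1)

  writeLines("chr1\t10", p)
  expect_error(read_bed(p), "line 1")
})

test_that("write_bed / read_bed round-trips validated interval lists", {
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(11, 51, 21), c(20, 80, 40)),
    strand = c("+", "-", "*"))
  S4Vectors::mcols(gr)$name <- c("a", "b", "c")
  S4Vectors::mcols(gr)$score <- c(1, 2.5, 0)
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, p)
  back <- read_bed(p)
  expect_equal(as.character(GenomicRanges::seqnames(back)),
               as.character(GenomicRanges::seqnames(gr)))
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(gr))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(gr))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(gr)$name)
  expect_equal(S4Vectors::mcols(back)$score, S4Vectors::mcols(gr)$score)
  expect_equal(as.character(BiocGenerics::strand(back)),
               as.character(BiocGenerics::strand(gr)))
})

test_that("sort_merge merges within gap and is idempotent", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 16), c(20, 25)))
  m <- sort_merge(gr, gap = 0)
  expect_length(m, 1)
  expect_equal(c(BiocGenerics::start(m), BiocGenerics::end(m)), c(11, 25))

  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 31), c(20, 40)))
  expect_length(sort_merge(gr, gap = 0), 2)

  # 0-based [10,20) and [25,30) are 5 bp apart: merged at gap 5
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 26), c(20, 30)))
  expect_length(sort_merge(gr, gap = 4), 2)
  m <- sort_merge(gr, gap = 5)
  expect_length(m, 1)
  expect_equal(c(BiocGenerics::start(m), BiocGenerics::end(m)), c(11, 30))
  expect_error(sort_merge(gr, gap = -1), "gap")
})

test_that("sort_merge agrees with a brute-force pairwise-distance oracle", {
  set.seed(7)
  for (rep in 1:20) {
    gr <- random_granges(25, max_pos = 2000, width = 30)
    gap <- sample(0:40, 1)
    m <- sort_merge(gr, gap = gap)
    # oracle: per-bp painting with gap closure
    paint <- logical(3000)
    for (i in seq_along(gr)) {
      paint[BiocGenerics::start(gr)[i]:BiocGenerics::end(gr)[i]] <- TRUE
    }
    # close gaps <= gap between painted runs
    r <- rle(paint)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] && k > 1 && k < length(r$values) &&
          r$lengths[k] <= gap) {
        paint[starts[k]:ends[k]] <- TRUE
      }
    }
    r2 <- rle(paint)
    e2 <- cumsum(r2$lengths)
    s2 <- e2 - r2$lengths + 1
    keep <- which(r2$values)
    expect_equal(BiocGenerics::start(m), s2[keep])
    expect_equal(BiocGenerics::end(m), e2[keep])
    # idempotence
    expect_equal(sort_merge(m, gap = gap), m)
  }
})

test_that("nearest_tss anchors at the midpoint, signs by strand and breaks ties", {
  genes <- gene_models(c("gB", "gA"), "chr1", c(1000, 3000), c(2000, 4000),
                       c("+", "-"), tss = c(1000, 4000))
  q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(996, 1005))  # mid 1000
  res <- nearest_tss(q, genes)
  expect_equal(res$gene_id, "gB")
  expect_equal(res$distance, 0)

  # midpoint 2500 equidistant from tss 1000 and 4000: smaller gene_id wins
  q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2496, 2505))
  res <- nearest_tss(q, genes)
  expect_equal(res$gene_id, "gA")
  # gA is on "-": midpoint upstream of tss 4000 by 1500 => +1500 downstream-signed
  expect_equal(res$distance, 1500)

  expect_error(nearest_tss(q, genes[0]), "empty")
})

test_that("nearest_tss matches an exhaustive all-TSS scan on random fixtures", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    tss <- sample.int(5e4, n)
    genes <- gene_models(sprintf("g%02d", sample(n)), "chr1",
                         pmax(tss - 100, 1), tss + 100,
                         sample(c("+", "-"), n, replace = TRUE), tss = tss)
    q <- random_granges(1, max_pos = 5e4, width = sample(10:500, 1))
    got <- nearest_tss(q, genes)
    # oracle: full scan with the tie rule applied literally
    mid <- floor((BiocGenerics::start(q) - 1 + BiocGenerics::end(q)) / 2)
    d <- abs(mid - S4Vectors::mcols(genes)$tss)
    cand <- which(d == min(d))
    ids <- S4Vectors::mcols(genes)$gene_id[cand]
    expect_equal(got$gene_id, sort(ids)[1])
    expect_equal(abs(got$distance), min(d))
  }
})

test_that("GTF gene models round-trip through write/read", {
  genes <- gene_models(c("a", "b"), c("chr1", "chr2"), c(100, 200),
                       c(500, 900), c("+", "-"))
  p <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_genes(genes, p)
  back <- read_gtf_genes(p)
  expect_equal(S4Vectors::mcols(back)$gene_id, c("a", "b"))
  expect_equal(S4Vectors::mcols(back)$tss, c(100, 900))
  expect_equal(BiocGenerics::start(back), c(100, 200))
})

test_that("GraphML round-trip preserves graphs and annotations", {
  empty <- stage_grn("ESC",
                     data.frame(name = character(0), expression = numeric(0),
                                dhs_promoter = logical(0),
                                promoter_state = character(0),
                                has_chip_data = logical(0)),
                     data.frame(source = character(0), target = character(0),
                                n_peaks = integer(0)))
  p <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(empty, p)
  expect_equal(nrow(read_graphml(p)$nodes), 0)

  g <- stage_grn("HB",
                 data.frame(name = c("A", "B"), expression = c(1.5, 0),
                            dhs_promoter = c(TRUE, FALSE),
                            promoter_state = c("A", "U"),
                            has_chip_data = c(TRUE, FALSE)),
                 data.frame(source = "A", target = "B", n_peaks = 2L))
  write_graphml(g, p)
  expect_identical(read_graphml(p), g)

  # 16-node stage graph from the fixture: attribute-by-attribute equality
  g16 <- small_grns()[[stage_index("HE")]]
  write_graphml(g16, p)
  back <- read_graphml(p)
  expect_equal(back$stage, g16$stage)
  expect_identical(back$edges, g16$edges)
  expect_identical(back$nodes[setdiff(names(back$nodes), "expression")],
                   g16$nodes[setdiff(names(g16$nodes), "expression")])
  # numeric attributes survive up to text serialization precision
  expect_equal(back$nodes$expression, g16$nodes$expression, tolerance = 1e-6)
})
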