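equal_domain_setup <- function(n = 100, spacing = 1000) {
  tss <- seq(spacing / 2, by = spacing, length.out = n)
  genes <- gene_models(sprintf("g%03d", 1:n), "chr1", tss, tss + 400,
                       rep("+", n), tss = tss)
  list(genes = genes,
       domains = build_regulatory_domains(genes, c(chr1 = n * spacing)))
}

test_that("regulatory domains tile chromosomes at TSS midpoints", {
  genes <- gene_models(c("a", "b"), "chr1", c(100, 300), c(150, 350),
                       c("+", "+"), tss = c(100, 300))
  dom <- build_regulatory_domains(genes, c(chr1 = 1000))
  expect_equal(BiocGenerics::start(dom), c(1, 201))
  expect_equal(BiocGenerics::end(dom), c(200, 1000))
  expect_equal(S4Vectors::mcols(dom)$gene_id, c("a", "b"))

  one <- build_regulatory_domains(gene_models("a", "chr1", 500, 600, "+"),
                                  c(chr1 = 1000))
  expect_equal(c(BiocGenerics::start(one), BiocGenerics::end(one)), c(1, 1000))

  set.seed(3)
  tss <- sort(sample.int(9000, 10))
  genes <- gene_models(sprintf("g%02d", 1:10), "chr1", tss, tss + 50,
                       rep("+", 10), tss = tss)
  dom <- build_regulatory_domains(genes, c(chr1 = 10000))
  expect_equal(sum(BiocGenerics::width(dom)), 10000)  # summation oracle
  expect_true(all(BiocGenerics::start(dom)[-1] ==
                    BiocGenerics::end(dom)[-10] + 1))

  expect_error(build_regulatory_domains(
    gene_models("a", "chr1", 2000, 2100, "+"), c(chr1 = 1500)),
    "beyond chromosome")
})

test_that("peak targets are genes whose domain contains a peak midpoint", {
  su <- equal_domain_setup()
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(450, 455), width = 100))
  expect_equal(peak_targets(peaks, su$domains), "g001")
  expect_equal(peak_targets(GenomicRanges::GRanges(), su$domains), character(0))

  set.seed(5)
  peaks <- random_granges(20, max_pos = 99000, width = 80)
  got <- peak_targets(peaks, su$domains)
  # exhaustive point-in-interval oracle
  mids <- floor((BiocGenerics::start(peaks) - 1 + BiocGenerics::end(peaks)) / 2)
  want <- character(0)
  for (m in mids) {
    j <- which(BiocGenerics::start(su$domains) <= m &
                 BiocGenerics::end(su$domains) >= m)
    want <- c(want, S4Vectors::mcols(su$domains)$gene_id[j])
  }
  expect_equal(got, sort(unique(want)))
})

test_that("overlap significance attains its floor for a fully planted set", {
  su <- equal_domain_setup()
  tss <- S4Vectors::mcols(su$genes)$tss
  # targets: genes 1..30; gene set drawn from the planted targets
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(tss[1:30], width = 20))
  gs <- sprintf("g%03d", 1:20)
  res <- overlap_significance(gs, peaks, su$domains, n_resamples = 2000,
                              seed = 1)
  expect_equal(res$observed, 20)
  expect_equal(res$p, 1 / 2001)
  expect_error(overlap_significance(c(gs, "nope"), peaks, su$domains,
                                    n_resamples = 1000), "universe")
  expect_error(overlap_significance(gs, peaks, su$domains, n_resamples = 10),
               "1000")
})

test_that("null-drawn gene sets give uniform-ish p (mean about 0.5)", {
  su <- equal_domain_setup()
  tss <- S4Vectors::mcols(su$genes)$tss
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(tss[seq(1, 100, 2)],
                                                   width = 20))
  set.seed(23)
  ps <- vapply(1:60, function(i) {
    gs <- sprintf("g%03d", sample.int(100, 20))
    overlap_significance(gs, peaks, su$domains, n_resamples = 1000,
                         seed = i)$p
  }, 0)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("with equal domains the test matches the hypergeometric tail", {
  su <- equal_domain_setup()
  tss <- S4Vectors::mcols(su$genes)$tss
  set.seed(9)
  for (rep in 1:5) {
    k <- sample(20:60, 1)
    peaks <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(tss[sample.int(100, k)],
                                                     width = 20))
    gs <- sprintf("g%03d", sample.int(100, 15))
    res <- overlap_significance(gs, peaks, su$domains, n_resamples = 4000,
                                seed = rep)
    phg <- phyper(res$observed - 1, k, 100 - k, 15, lower.tail = FALSE)
    mc_sd <- sqrt(phg * (1 - phg) / 4000)
    expect_lt(abs(res$p - phg), 3 * mc_sd + 1 / 4001)
  }
})

test_that("pattern x TF overlap respects the population filter and nulls", {
  pipe <- small_pipeline()
  tab <- pipe$tab
  tal1_hb <- pipe$fx$tf_peaks$Tal1$HB$rep1
  expect_message(
    res <- dhs_pattern_tf_overlap(tab, tal1_hb, n_resamples = 20000,
                                  seed = 2, min_population = 35),
    "skipping")
  # Tal1 binds half of the 001000 population: that pattern is enriched
  expect_true("001000" %in% res$code)
  expect_lt(res$p[res$code == "001000"], 1e-3)
  # a TF with zero peaks: observed 0, p = 1 everywhere
  res0 <- suppressMessages(dhs_pattern_tf_overlap(
    tab, GenomicRanges::GRanges(), n_resamples = 1000, seed = 1,
    min_population = 50))
  expect_true(all(res0$observed == 0))
  expect_true(all(res0$p == 1))
  # populations at exactly the cutoff are skipped
  res100 <- suppressMessages(dhs_pattern_tf_overlap(
    tab, tal1_hb, n_resamples = 1000, seed = 1, min_population = 80))
  expect_true(all(res100$population > 80))
})

test_that("H3K27ac bootstrap Z-scores behave and rescale invariantly", {
  # constant signal: Z = 0 with the degenerate flag
  flat <- binned_track(list(chr1 = rep(4, 500)), 200, "H3K27ac")
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1001, 5001), width = 200))
  all_sites <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(seq(1, 90000, 1000),
                                                       width = 200))
  z <- h3k27ac_zscore(sites, all_sites, flat, n_boot = 200, seed = 1)
  expect_true(z$degenerate)
  expect_equal(z$z, 0)

  # planted shift: first 10 site positions carry elevated signal
  counts <- rep(2, 500)
  counts[1:50] <- 30
  tr <- binned_track(list(chr1 = counts), 200, "H3K27ac")
  hot <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(1, 9000, 1000),
                                                         width = 200))
  z <- h3k27ac_zscore(hot, all_sites, tr, n_boot = 2000, seed = 2)
  expect_gt(z$z, 3)
  # affine rescaling leaves Z unchanged
  tr2 <- binned_track(list(chr1 = counts * 5 + 7), 200, "H3K27ac")
  z2 <- h3k27ac_zscore(hot, all_sites, tr2, n_boot = 2000, seed = 2)
  expect_equal(z$z, z2$z, tolerance = 1e-9)

  # subset = all sites: Z near 0
  zs <- h3k27ac_zscore(all_sites, all_sites, tr, n_boot = 2000, seed = 3)
  expect_lt(abs(zs$z), 1)
  expect_error(h3k27ac_zscore(all_sites[0], all_sites, tr), "empty")
})

test_that("the integration matrix flags only truly enriched cells", {
  pipe <- small_pipeline()
  fx <- pipe$fx
  mg <- fx$manifest$genes
  clusters <- split(mg$gene_id[!is.na(mg$cluster)],
                    mg$cluster[!is.na(mg$cluster)])[c("C2", "C3", "C4")]
  dom <- build_regulatory_domains(fx$genes, fx$chrom_sizes)
  tfsets <- list("Fli1@HE" = filter_reproducible(fx$tf_peaks$Fli1$HE),
                 "Spi1@MAC" = filter_reproducible(fx$tf_peaks$Spi1$MAC))
  im <- suppressWarnings(integration_matrix(
    clusters, tfsets, dom, ac_tracks = lapply(fx$tracks, `[[`, "H3K27ac"),
    n_resamples = 20000, n_boot = 200, seed = 5))
  expect_equal(nrow(im), 6)
  expect_identical(im$significant, im$p < 1e-4)
  planted <- im$cluster == "C3" & im$tf == "Fli1"
  expect_true(all(im$significant[planted]))
  expect_false(any(im$significant[!planted]))
  # stages without TF data simply contribute no columns
  expect_false("HB" %in% im$stage)
})
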