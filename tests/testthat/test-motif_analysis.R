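test_pwm <- function(p = 0.85) {
  hemodyn:::pwm_from_consensus("TEST", "AAACGGTC", p = p)
}

test_that("PWM construction validates its matrix", {
  m <- matrix(0.25, 8, 4)
  expect_s3_class(pwm("ok", m), "pwm")
  expect_error(pwm("bad", m[, 1:3]), "4 base columns")
  expect_error(pwm("bad", m[1:3, ]), "length")
  expect_error(pwm("bad", m * 2), "sum to 1")
  expect_equal(pwm_consensus(test_pwm()), "AAACGGTC")
})

test_that("scanning finds planted consensus sites on both strands", {
  pw <- test_pwm()
  s <- paste0(strrep("C", 20), "AAACGGTC", strrep("G", 20))
  hits <- scan_pwm(c(seq1 = s), pw, threshold = 0.9)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 20)
  expect_equal(hits$strand, "+")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  hits_rc <- scan_pwm(c(seq1 = rc), pw, threshold = 0.9)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$offset, 20)  # symmetric position from the right end
  expect_equal(hits_rc$score, hits$score)

  expect_equal(nrow(scan_pwm(character(0), pw)), 0)
  expect_equal(nrow(scan_pwm(c(short = "ACG"), pw)), 0)  # shorter than motif
})

test_that("scanning agrees with the exhaustive per-window oracle", {
  set.seed(41)
  for (rep in 1:15) {
    len <- sample(6:10, 1)
    cons <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    pw <- hemodyn:::pwm_from_consensus(sprintf("m%02d", rep), cons,
                                       p = runif(1, 0.6, 0.95))
    s <- seq_with_motif(80, cons)
    if (rep %% 3 == 0) substr(s, 5, 6) <- "NN"  # exercise N handling
    thr <- runif(1, 0.6, 0.9)
    got <- scan_pwm(c(x = s), pw, threshold = thr)
    want <- oracle_scan(s, pw$mat, unname(pw$background), thr)
    got <- got[order(got$offset, got$strand), ]
    want <- want[order(want$offset, want$strand), ]
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("relative enrichment has its algebraic fixed points", {
  pw <- test_pwm()
  set.seed(51)
  seqs <- vapply(1:40, function(i) random_dna(120), "")
  names(seqs) <- paste0("r", 1:40)
  same <- relative_enrichment(seqs, seqs, pw, n_boot = 100, seed = 1)
  expect_equal(same$re, 1)
  expect_equal(same$log2_re, 0)

  # motif absent from both sets: RE = 1 by pseudocount, flagged
  none <- relative_enrichment(seqs, seqs, pw, n_boot = 50, seed = 1)
  expect_true(none$no_signal)

  # reciprocal identity at equal set sizes
  withm <- vapply(1:40, function(i) seq_with_motif(120, "AAACGGTC"), "")
  names(withm) <- paste0("m", 1:40)
  ab <- relative_enrichment(withm, seqs, pw, n_boot = 50, seed = 2)
  ba <- relative_enrichment(seqs, withm, pw, n_boot = 50, seed = 2)
  expect_equal(ab$re * ba$re, 1, tolerance = 1e-12)
  expect_error(relative_enrichment(character(0), seqs, pw), "non-empty")
})

test_that("planted enrichment is detected and p is monotone in strength", {
  pw <- test_pwm()
  set.seed(61)
  mk_set <- function(n, frac) {
    out <- vapply(seq_len(n), function(i) {
      if (i <= round(frac * n)) seq_with_motif(200, "AAACGGTC")
      else random_dna(200)
    }, "")
    names(out) <- sprintf("s%03d", seq_len(n))
    out
  }
  b <- mk_set(200, 0.05)
  a <- mk_set(200, 0.5)
  res <- relative_enrichment(a, b, pw, n_boot = 500, seed = 3)
  eps <- 1 / 400
  planted <- (0.5 + eps) / (0.05 + eps)
  expect_gt(res$re, 3)
  expect_lt(res$p, 0.01)
  expect_true(res$ci[1] <= planted && planted <= res$ci[2])

  ps <- vapply(c(0.05, 0.1, 0.2, 0.4), function(f) {
    relative_enrichment(mk_set(200, f), b, pw, n_boot = 300, seed = 4)$p
  }, 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("the RE matrix highlights stage-specific planted motifs", {
  pipe <- small_pipeline()
  fx <- pipe$fx
  lib <- fx$config$motif_library[c("TEAD", "RUNX")]
  rem <- suppressMessages(re_matrix(pipe$tab, fx$genome, lib,
                                    expression = fx$expression, floor = 0.001))
  # TEAD planted in HB-unique distal DHS: maximal in every HB|other column
  hb_cols <- grep("^HB\\|", colnames(rem$log2_re))
  expect_true(all(rem$log2_re["TEAD", hb_cols] > 1))
  # in the mirror columns TEAD is depleted
  rev_cols <- grep("\\|HB$", colnames(rem$log2_re))
  expect_true(all(rem$log2_re["TEAD", rev_cols] < 0))
  # RUNX occurs nowhere: its row stays near zero
  expect_lt(mean(abs(rem$log2_re["RUNX", ]), na.rm = TRUE), 1)

  # identical motifs cluster at distance zero, adjacent leaves
  lib2 <- list(T1 = fx$config$motif_library$TEAD,
               T2 = fx$config$motif_library$TEAD,
               E1 = fx$config$motif_library$EBOX)
  lib2$T2$motif_id <- "T2"; lib2$T1$motif_id <- "T1"
  rem2 <- suppressMessages(re_matrix(pipe$tab, fx$genome, lib2))
  i1 <- match("T1", rem2$leaf_order); i2 <- match("T2", rem2$leaf_order)
  expect_equal(abs(i1 - i2), 1)
})

test_that("motif co-localization separates planted from background peaks", {
  pipe <- small_pipeline()
  fx <- pipe$fx
  tead <- fx$config$motif_library$TEAD
  tal1_hb <- filter_reproducible(fx$tf_peaks$Tal1$HB)
  # background: distal DHS never bound by Tal1 and without planted TEAD
  bg <- pipe$tab[S4Vectors::mcols(pipe$tab)$code == "000001" &
                   S4Vectors::mcols(pipe$tab)$class == "distal"]
  res <- motif_colocalization(tal1_hb, tead, fx$genome, bg,
                              n_boot = 500, seed = 6)
  expect_true(res$significant)  # TEAD planted in the Tal1-bound pattern

  ebox <- fx$config$motif_library$EBOX
  res2 <- motif_colocalization(bg[1:40], ebox, fx$genome, bg[41:80],
                               n_boot = 500, seed = 7)
  expect_false(res2$significant)  # background vs background
  expect_error(motif_colocalization(tal1_hb[0], tead, fx$genome, bg),
               "empty")
})

test_that("MEME minimal format round-trips the library", {
  lib <- default_motif_library()
  p <- withr::local_tempfile(fileext = ".meme")
  write_meme(lib, p)
  back <- read_meme(p)
  expect_equal(names(back), names(lib))
  for (nm in names(lib)) {
    expect_equal(unname(back[[nm]]$mat), unname(lib[[nm]]$mat),
                 tolerance = 1e-6)
  }
})
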