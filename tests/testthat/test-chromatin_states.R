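test_that("binarization follows the exact Poisson upper tail", {
  tr <- binned_track(list(chr1 = rep(3, 100)), 200, "DHS")
  b <- binarize_track(tr, 1e-4)
  expect_true(all(b$counts$chr1 == 0))  # no bin beats its own mean

  counts <- c(rep(1, 999), 20)
  tr <- binned_track(list(chr1 = counts), 200, "H3K4me3")
  b <- binarize_track(tr, 1e-4)
  lambda <- mean(counts)
  # oracle: exact Poisson tail per count
  expected <- as.numeric(ppois(counts - 1, lambda, lower.tail = FALSE) < 1e-4)
  expect_equal(b$counts$chr1, expected)
  expect_equal(b$counts$chr1[1000], 1)
  expect_equal(b$counts$chr1[1], 0)

  tr0 <- binned_track(list(chr1 = c(0, 0, 5)), 200, "DHS")
  expect_equal(binarize_track(tr0, 0.5)$counts$chr1[1:2], c(0, 0))
  expect_error(binarize_track(binned_track(list(chr1 = numeric(0)), 200, "DHS")),
               "empty")
  expect_error(binarize_track(tr, 2), "p_threshold")
})

test_that("EM fitting recovers a planted 2-state model", {
  hf <- generate_hmm_fixture(n_bins = 6000, seed = 5)
  m <- fit_hmm(hf$obs, K = 2, seed = 2)
  expect_true(all(diff(m$loglik) >= -1e-8))  # monotone EM
  expect_equal(rowSums(m$transition), c(1, 1), tolerance = 1e-9)
  p <- match_states(m$emission, hf$emission)
  expect_lt(max(abs(m$emission[p, ] - hf$emission)), 0.05)
  # decoding accuracy after optimal label matching
  dec <- decode_states(m, hf$obs)
  acc <- mean(match(dec, p) == hf$states)
  expect_gte(acc, 0.95)
  # determinism
  m2 <- fit_hmm(hf$obs, K = 2, seed = 2)
  expect_identical(m$emission, m2$emission)
  expect_identical(m$loglik, m2$loglik)
})

test_that("K = 1 EM fixed point equals the empirical mark frequencies", {
  set.seed(8)
  x <- matrix(rbinom(500, 1, c(0.2, 0.7)), ncol = 2, byrow = TRUE)
  colnames(x) <- c("DHS", "H3K27me3")
  m <- fit_hmm(x, K = 1, seed = 1)
  expect_equal(as.vector(m$emission), colMeans(x), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("forward and backward recursions agree on the total likelihood", {
  hf <- generate_hmm_fixture(n_bins = 800, seed = 9)
  m <- fit_hmm(hf$obs, K = 2, max_iter = 5, seed = 4)
  logb <- hemodyn:::bernoulli_loglik(hf$obs, m$emission)
  ll_f <- hemodyn:::hmm_forward(logb, m$transition, m$initial)$loglik
  ll_b <- hemodyn:::hmm_loglik_backward(logb, m$transition, m$initial)
  expect_lt(abs(ll_f - ll_b) / abs(ll_f), 1e-8)
})

test_that("fitting warns when K exceeds the distinct observation vectors", {
  x <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), ncol = 2)
  colnames(x) <- c("DHS", "H3K4me3")
  expect_warning(fit_hmm(x, K = 3, max_iter = 3, seed = 1), "distinct")
})

test_that("Viterbi decoding handles degenerate inputs", {
  # near-silent state should absorb an all-zero observation sequence
  m <- structure(list(
    K = 2L,
    emission = matrix(c(0.01, 0.01, 0.9, 0.9), 2, 2, byrow = TRUE,
                      dimnames = list(NULL, c("DHS", "H3K4me3"))),
    transition = matrix(0.5, 2, 2), initial = c(0.5, 0.5),
    loglik = numeric(0), converged = TRUE,
    marks = c("DHS", "H3K4me3")), class = "chromatin_state_model")
  x <- matrix(0, 50, 2, dimnames = list(NULL, c("DHS", "H3K4me3")))
  expect_true(all(decode_states(m, x) == 1))
  # single bin: argmax of initial x emission
  x1 <- matrix(c(1, 1), 1, 2, dimnames = list(NULL, c("DHS", "H3K4me3")))
  expect_equal(decode_states(m, x1), 2)
  colnames(x1) <- c("DHS", "H3K9ac")
  expect_error(decode_states(m, x1), "marks")
})

test_that("four-state coarse graining reproduces the definitions", {
  marks <- function(dhs, k4, k9, k27ac, k27me3) {
    m <- matrix(c(dhs, k4, k9, k27ac, k27me3), 1, 5,
                dimnames = list(NULL, c("DHS", "H3K4me3", "H3K9ac",
                                        "H3K27ac", "H3K27me3")))
    as.character(coarse_grain(m))
  }
  # accessible promoter with H3K4me3 + acetylation: active
  expect_equal(marks(1, 1, 1, 0, 0), "ACTIVE")
  # H3K27me3 without accessibility: repressed
  expect_equal(marks(0, 0, 0, 0, 1), "REPRESSED")
  # accessible + H3K27me3 + H3K4me3: poised
  expect_equal(marks(1, 1, 0, 0, 1), "POISED")
  expect_equal(marks(0, 0, 0, 0, 0), "UNMARKED")
})

test_that("coarse graining is total over all 32 mark combinations", {
  combos <- expand.grid(DHS = 0:1, H3K4me3 = 0:1, H3K9ac = 0:1,
                        H3K27ac = 0:1, H3K27me3 = 0:1)
  lab <- coarse_grain(as.matrix(combos))
  expect_length(lab, 32)
  expect_false(anyNA(lab))
  # independent truth-table oracle, written from the state definitions
  for (i in seq_len(32)) {
    r <- combos[i, ]
    ac <- r$H3K9ac == 1 || r$H3K27ac == 1
    expected <- if (r$DHS == 1 && r$H3K27me3 == 1 && (r$H3K4me3 == 1 || ac)) {
      "POISED"
    } else if (r$DHS == 1 && r$H3K4me3 == 1 && ac) {
      "ACTIVE"
    } else if (r$H3K27me3 == 1) {
      "REPRESSED"
    } else {
      "UNMARKED"
    }
    expect_equal(as.character(lab[i]), expected)
  }
})

test_that("coarse graining a fitted model thresholds its emissions", {
  m <- structure(list(
    K = 2L,
    emission = matrix(c(0.9, 0.8, 0.7, 0.6, 0.1,
                        0.1, 0.2, 0.1, 0.2, 0.9), 2, 5, byrow = TRUE,
                      dimnames = list(NULL, c("DHS", "H3K4me3", "H3K9ac",
                                              "H3K27ac", "H3K27me3"))),
    transition = matrix(0.5, 2, 2), initial = c(0.5, 0.5),
    loglik = numeric(0), converged = TRUE,
    marks = c("DHS", "H3K4me3", "H3K9ac", "H3K27ac", "H3K27me3")),
    class = "chromatin_state_model")
  expect_equal(as.character(coarse_grain(m)), c("ACTIVE", "REPRESSED"))
})

test_that("promoter timelines match planted states on noise-free marks", {
  pipe <- small_pipeline()
  truth <- setNames(pipe$fx$manifest$genes$states,
                    pipe$fx$manifest$genes$gene_id)
  got <- pipe$timelines[names(truth)]
  expect_equal(unname(got), unname(truth))
})

test_that("promoter windows outside the tracks get a sentinel label", {
  genes <- gene_models("far", "chrX", 5e6, 5e6 + 100, "+")
  tr <- binned_track(list(chr1 = rep(0, 10)), 200, "DHS")
  binz <- lapply(setNames(hemo_stages(), hemo_stages()), function(s) {
    list(DHS = tr, H3K4me3 = tr, H3K9ac = tr, H3K27ac = tr, H3K27me3 = tr)
  })
  expect_warning(tl <- promoter_state_timeline(genes, binz), "no bins")
  expect_equal(unname(tl["far"]), "NNNNNN")
})
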