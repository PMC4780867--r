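# Synthetic six-stage fixture generator. Emulates the data structure of a
# staged hematopoietic differentiation study -- genome, gene models,
# replicated DHS and TF ChIP peak sets, binned histone/DHS count tracks,
# motif-embedded sequence, an expression matrix and a planted TF->TF
# network -- together with a machine-readable truth manifest sufficient
# to recompute every planted summary by counting.
#
# The layout (gene grid, DHS slots, plan assignments) is deterministic
# given the configuration; the seed drives only the noise channels
# (genome sequence, motif mutations and strands, Poisson counts, jitter,
# replicate dropout, expression noise). Planted-truth comparisons are
# therefore stable across seeds, and determinism is byte-exact for a
# fixed (config, seed).

# ---- default plans ---------------------------------------------------

#' Default 16-factor TF panel for the fixture
#'
#' Expression profiles (log10 FPKM per stage), promoter-state timelines,
#' and per-stage ChIP availability for a panel of 16 hematopoietic
#' regulators. The panel deliberately contains no factor expressed above
#' the 1-FPKM floor before the hemangioblast stage: the reprogramming
#' ranking keys on earliest activation, and the fixture plants its
#' early/high-connectivity pair (the Tal1/Lmo2 analogues) at HB.
#'
#' @return List with \code{expression} (16 x 6, log10 FPKM),
#'   \code{states} (named timeline strings) and \code{chip} (named list
#'   of stage vectors).
#' @export
default_tf_panel <- function() {
  prof <- rbind(
    Tal1  = c(-1.0, -0.7,  1.2,  1.3,  1.4,  0.2),
    Lmo2  = c(-1.0, -0.8,  1.1,  1.3,  1.5,  0.3),
    Fli1  = c(-1.0, -0.5,  1.0,  1.4,  1.3,  0.8),
    Gata2 = c(-1.0, -1.0,  1.0,  1.2,  0.8, -0.5),
    Etv2  = c(-1.0, -0.5,  1.0,  0.5, -0.5, -1.0),
    Ldb1  = c(-1.0, -1.0,  0.5,  0.5,  0.5,  0.0),
    Runx1 = c(-1.0, -1.0, -0.5,  1.0,  1.5,  1.0),
    Meis1 = c(-1.0, -1.0, -0.5,  1.0,  1.2,  0.5),
    Erg   = c(-1.0, -1.0, -0.3,  1.0,  0.8,  0.0),
    Gata1 = c(-1.0, -1.0, -1.0, -0.3,  1.2, -0.5),
    Gfi1  = c(-1.0, -1.0, -1.0, -0.5,  1.0,  0.8),
    Gfi1b = c(-1.0, -1.0, -1.0, -0.5,  1.0,  0.5),
    Spi1  = c(-1.0, -1.0, -1.0, -0.5,  1.2,  2.0),
    Cebpb = c(-1.0, -1.0, -0.5, -0.5,  1.0,  2.2),
    Elk4  = c(-1.0, -1.0, -1.0, -0.5,  1.0,  0.5),
    Cbfb  = c(-0.5, -0.5, -0.5, -0.5, -0.5, -0.5))
  colnames(prof) <- hemo_stages()
  states <- c(
    Tal1 = "UUPAAA", Lmo2 = "UPPAAA", Fli1 = "UUAAAA", Gata2 = "UUAAAR",
    Etv2 = "UUAAUU", Ldb1 = "UUAAAU", Runx1 = "RRPAAA", Meis1 = "UUPAAA",
    Erg = "UUUAAA", Gata1 = "RRRPAU", Gfi1 = "UUUPAA", Gfi1b = "UUUPAA",
    Spi1 = "RRRPAA", Cebpb = "UUPPAA", Elk4 = "UUUUAA", Cbfb = "UUUUUU")
  chip <- list(
    Tal1 = c("HB", "HE", "HP"), Lmo2 = c("HB", "HE", "HP"),
    Fli1 = c("HE", "HP", "MAC"), Gata2 = c("HB", "HE", "HP"),
    Etv2 = "HB", Ldb1 = c("HB", "HE"), Runx1 = c("HE", "HP"),
    Meis1 = c("HE", "HP"), Erg = "HE", Gata1 = "HP", Gfi1 = "HP",
    Gfi1b = "HP", Spi1 = c("HP", "MAC"), Cebpb = c("HP", "MAC"),
    Elk4 = "HP", Cbfb = character(0))
  list(expression = prof, states = states, chip = chip)
}

#' Default planted TF -> TF binding network
#'
#' One row per planted binding event (source TF bound at the target TF's
#' locus at a stage). The Tal1/Lmo2 analogues bind 13 distinct panel
#' loci at or before the HE stage, far exceeding any other factor,
#' mirroring the connectivity asymmetry that predicts reprogramming
#' competence.
#'
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{stage}.
#' @export
default_grn_truth <- function() {
  e <- function(src, stage, targets) {
    data.frame(source = src, target = targets, stage = stage)
  }
  hb13 <- c("Tal1", "Lmo2", "Fli1", "Gata2", "Runx1", "Meis1")
  he13 <- c("Gata1", "Gfi1", "Gfi1b", "Spi1", "Erg", "Cebpb", "Elk4")
  rbind(
    e("Tal1", "HB", hb13), e("Tal1", "HE", he13),
    e("Lmo2", "HB", hb13), e("Lmo2", "HE", he13),
    e("Fli1", "HE", c("Fli1", "Erg", "Gata2", "Runx1", "Meis1")),
    e("Gata2", "HB", c("Gata2", "Tal1", "Lmo2", "Runx1")),
    e("Etv2", "HB", c("Fli1", "Gata2")),
    e("Ldb1", "HB", "Tal1"), e("Ldb1", "HE", "Lmo2"),
    e("Runx1", "HE", c("Spi1", "Gfi1")),
    e("Meis1", "HE", "Gata2"),
    e("Erg", "HE", "Fli1"),
    e("Tal1", "HP", c("Runx1", "Gata1")),
    e("Lmo2", "HP", c("Runx1", "Gata1")),
    e("Fli1", "HP", c("Runx1", "Gfi1b")),
    e("Gata1", "HP", "Gata2"),
    e("Gfi1", "HP", c("Gata2", "Gfi1b")),
    e("Gfi1b", "HP", "Runx1"),
    e("Spi1", "HP", c("Spi1", "Cebpb")),
    e("Cebpb", "HP", c("Spi1", "Cebpb")),
    e("Elk4", "HP", "Spi1"),
    e("Meis1", "HP", "Runx1"),
    e("Runx1", "HP", "Spi1"),
    e("Gata2", "HP", "Gata2"),
    e("Spi1", "MAC", c("Cebpb", "Spi1", "Tal1")),
    e("Cebpb", "MAC", c("Spi1", "Cebpb", "Lmo2")),
    e("Fli1", "MAC", c("Cebpb", "Elk4")))
}

pwm_from_consensus <- function(motif_id, consensus, p = 0.85, tf = NA_character_) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  mat <- matrix((1 - p) / 3, length(bases), 4L,
                dimnames = list(NULL, DNA_BASES))
  mat[cbind(seq_along(bases), match(bases, DNA_BASES))] <- p
  pwm(motif_id, mat, tf = tf)
}

#' Default PWM library for the fixture
#'
#' Five motifs standing in for the canonical hematopoietic binding-site
#' families (E-box, GATA, ETS, TEAD and RUNX sites), built as
#' near-consensus PWMs.
#'
#' @return Named list of [pwm()] objects.
#' @export
default_motif_library <- function() {
  list(
    EBOX = pwm_from_consensus("EBOX", "ACAGCTGT", tf = "Tal1"),
    GATA = pwm_from_consensus("GATA", "AGATAAGA", tf = "Gata1"),
    ETS  = pwm_from_consensus("ETS",  "ACAGGAAG", tf = "Fli1"),
    TEAD = pwm_from_consensus("TEAD", "ACATTCCA", tf = "Tead4"),
    RUNX = pwm_from_consensus("RUNX", "TGTGGTTG", tf = "Runx1"))
}

# ---- configuration ---------------------------------------------------

#' Configure the synthetic six-stage fixture
#'
#' All planted structure of the fixture is declared here: genome
#' geometry, the gene grid, per-code distal DHS populations, promoter
#' chromatin-state timelines, expression pattern means, the TF panel
#' with its ChIP availability, TF binding plans (DHS-pattern binding,
#' gene-targeting, and the planted TF->TF network), and the noise
#' channels (replicate jitter and dropout, count noise, expression
#' noise). Defaults are a 2 x 5 Mb genome, 200 genes, 2,000 distal DHS,
#' 6 stages x 2 replicates, 200 bp bins, Poisson count tracks with
#' background mean 1 and enriched mean 8 per bin.
#'
#' @param seed Integer master seed; all randomness derives from it via
#'   named substreams.
#' @param n_chroms,chrom_length Genome geometry.
#' @param n_genes Total genes (including the 16 panel TF genes).
#' @param bin_size Track bin width (bp).
#' @param n_replicates Replicates per assay and stage (>= 2).
#' @param gene_span Gene body length (bp).
#' @param dhs_width,promoter_dhs_halfwidth,tf_peak_width Element widths.
#' @param distal_pattern_counts Named integer vector: distal DHS count
#'   per six-digit code.
#' @param promoter_state_profiles Named integer vector: number of
#'   non-panel genes per promoter timeline string (letters A/R/P/U).
#' @param expression_profiles Named list of per-stage mean log10-FPKM
#'   vectors defining the planted expression patterns.
#' @param expression_noise_sd SD of stage-independent Gaussian noise
#'   added to log10 expression.
#' @param jitter_bp Max absolute replicate peak jitter (bp).
#' @param replicate_dropout_rate Probability that a planted peak is
#'   missing from a given replicate (i.i.d. per peak, stage and
#'   replicate).
#' @param count_mode \code{"poisson"} for Poisson count tracks or
#'   \code{"none"} for deterministic rounded-rate tracks (noise-free).
#' @param background_rate,enriched_rate Per-bin track rates.
#' @param tf_panel Panel description, see [default_tf_panel()].
#' @param grn_truth Planted network, see [default_grn_truth()].
#' @param tf_dhs_plan data.frame(tf, stage, pattern, fraction, motif):
#'   each TF binds the first \code{fraction} of the pattern's distal
#'   rows at that stage, with the motif embedded in the peak.
#' @param tf_target_plan data.frame(tf, stage, cluster, fraction,
#'   background_fraction): the TF targets \code{fraction} of the
#'   cluster's genes plus an evenly spread \code{background_fraction} of
#'   the remaining non-panel genes.
#' @param motif_library Named list of [pwm()]s, see
#'   [default_motif_library()].
#' @param dhs_motif_plan data.frame(motif, pattern, fraction,
#'   background_fraction): motif embedded in the first \code{fraction}
#'   of the pattern's distal DHS and in an evenly spread
#'   \code{background_fraction} of all other distal DHS.
#' @param motif_mutation_prob Per-position mutation probability of
#'   embedded motif instances.
#' @param include_genome Generate sequence and embed motifs (disable for
#'   speed when only intervals/tracks/expression are needed).
#' @param expression_floor Activation floor in FPKM used by consumers.
#' @return Object of class \code{fixture_config}.
#' @export
fixture_config <- function(
    seed = 1L,
    n_chroms = 2L,
    chrom_length = 5e6,
    n_genes = 200L,
    bin_size = 200L,
    n_replicates = 2L,
    gene_span = 2000L,
    dhs_width = 200L,
    promoter_dhs_halfwidth = 300L,
    tf_peak_width = 100L,
    distal_pattern_counts = c(
      "100000" = 300L, "010000" = 200L, "001000" = 150L, "000100" = 200L,
      "000010" = 100L, "000001" = 500L, "110000" = 100L,
      "000110" = 150L, "000011" = 100L, "001110" = 100L, "111111" = 100L),
    promoter_state_profiles = c(
      "AAAAAA" = 40L, "UUPAAA" = 24L, "PPPAAA" = 20L, "UUUAAA" = 24L,
      "RRRRRR" = 20L, "UUUUUU" = 20L, "AAARRR" = 20L, "RRPAAA" = 16L),
    expression_profiles = list(
      C1 = c(1.5, 1.2, -1.0, -1.0, -1.0, -1.0),
      C2 = c(-1.0, 1.2, 1.5, -1.0, -1.0, -1.0),
      C3 = c(-1.0, -1.0, 0.5, 1.5, -0.5, -1.0),
      C4 = c(-1.0, -1.0, -1.0, 0.3, 1.2, 1.5),
      C5 = c(-1.0, -1.0, -1.0, -1.0, 0.3, 1.8),
      C6 = c(1.2, 1.2, 1.2, 1.2, 1.2, 1.2)),
    expression_noise_sd = 0.1,
    jitter_bp = 10L,
    replicate_dropout_rate = 0,
    count_mode = c("poisson", "none"),
    background_rate = 1,
    enriched_rate = 8,
    tf_panel = default_tf_panel(),
    grn_truth = default_grn_truth(),
    tf_dhs_plan = data.frame(
      tf = c("Tal1", "Lmo2", "Tal1", "Fli1", "Spi1", "Spi1"),
      stage = c("HB", "HB", "HB", "HE", "MAC", "HP"),
      pattern = c("001000", "001000", "000110", "000100", "000001", "000001"),
      fraction = c(0.5, 0.4, 0.3, 0.4, 0.4, 0.2),
      motif = c("EBOX", "EBOX", "EBOX", "ETS", "ETS", "ETS")),
    tf_target_plan = data.frame(
      tf = "Fli1", stage = "HE", cluster = "C3",
      fraction = 0.9, background_fraction = 0.05),
    motif_library = default_motif_library(),
    dhs_motif_plan = data.frame(
      motif = c("TEAD", "GATA"),
      pattern = c("001000", "000110"),
      fraction = c(0.5, 0.3),
      background_fraction = c(0.05, 0.02)),
    motif_mutation_prob = 0.05,
    include_genome = TRUE,
    expression_floor = 1) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    bin_size = as.integer(bin_size), n_replicates = as.integer(n_replicates),
    gene_span = as.integer(gene_span), dhs_width = as.integer(dhs_width),
    promoter_dhs_halfwidth = as.integer(promoter_dhs_halfwidth),
    tf_peak_width = as.integer(tf_peak_width),
    distal_pattern_counts = distal_pattern_counts,
    promoter_state_profiles = promoter_state_profiles,
    expression_profiles = expression_profiles,
    expression_noise_sd = expression_noise_sd,
    jitter_bp = as.integer(jitter_bp),
    replicate_dropout_rate = replicate_dropout_rate,
    count_mode = match.arg(count_mode),
    background_rate = background_rate, enriched_rate = enriched_rate,
    tf_panel = tf_panel, grn_truth = grn_truth,
    tf_dhs_plan = tf_dhs_plan, tf_target_plan = tf_target_plan,
    motif_library = motif_library, dhs_motif_plan = dhs_motif_plan,
    motif_mutation_prob = motif_mutation_prob,
    include_genome = isTRUE(include_genome),
    expression_floor = expression_floor)
  class(cfg) <- "fixture_config"
  validate_fixture_config(cfg)
  cfg
}

validate_fixture_config <- function(cfg) {
  codes <- names(cfg$distal_pattern_counts)
  if (any(nchar(codes) != 6L) || any(!grepl("^[01]{6}$", codes))) {
    stop("pattern codes must be 6-character strings over {0,1}")
  }
  if (any(cfg$distal_pattern_counts < 0)) stop("pattern counts must be >= 0")
  if (cfg$n_replicates < 2L) stop("need >= 2 replicates per assay")
  probs <- c(cfg$replicate_dropout_rate, cfg$motif_mutation_prob,
             cfg$tf_dhs_plan$fraction, cfg$tf_target_plan$fraction,
             cfg$tf_target_plan$background_fraction,
             cfg$dhs_motif_plan$fraction,
             cfg$dhs_motif_plan$background_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  panel <- rownames(cfg$tf_panel$expression)
  if (cfg$n_genes < length(panel) * 12L + 8L) {
    stop("n_genes too small for the TF panel layout")
  }
  bad <- setdiff(cfg$tf_dhs_plan$pattern, codes)
  if (length(bad)) {
    stop("tf_dhs_plan references nonexistent DHS pattern(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(cfg$dhs_motif_plan$pattern, codes)
  if (length(bad)) {
    stop("dhs_motif_plan references nonexistent DHS pattern(s): ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(c(cfg$tf_dhs_plan$tf, cfg$tf_target_plan$tf,
                   cfg$grn_truth$source), panel)
  if (length(bad)) stop("unknown TF(s) in plans: ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$grn_truth$target, panel)
  if (length(bad)) {
    stop("grn_truth target(s) outside the panel: ", paste(bad, collapse = ", "))
  }
  chip_of <- cfg$tf_panel$chip
  for (df in list(cfg$tf_dhs_plan, cfg$tf_target_plan,
                  cfg$grn_truth[, c("source", "stage")])) {
    tfs <- if ("tf" %in% names(df)) df$tf else df$source
    ok <- mapply(function(tf, st) st %in% chip_of[[tf]], tfs, df$stage)
    if (!all(ok)) {
      stop("plan assigns binding to a (TF, stage) without ChIP data: ",
           paste(unique(paste0(tfs[!ok], "@", df$stage[!ok])), collapse = ", "))
    }
  }
  bad <- setdiff(c(cfg$tf_dhs_plan$motif, cfg$dhs_motif_plan$motif),
                 names(cfg$motif_library))
  if (length(bad)) stop("unknown motif(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$tf_target_plan$cluster, names(cfg$expression_profiles))
  if (length(bad)) stop("unknown expression cluster(s): ",
                        paste(bad, collapse = ", "))
  if (!all(grepl("^[ARPU]{6}$", names(cfg$promoter_state_profiles)))) {
    stop("promoter timelines must be 6 letters over A/R/P/U")
  }
  n_non_panel <- cfg$n_genes - length(panel)
  if (sum(cfg$promoter_state_profiles) != n_non_panel) {
    stop("promoter_state_profiles counts must sum to ", n_non_panel,
         " (non-panel genes)")
  }
  invisible(cfg)
}

# Spread category counts evenly over n slots: returns a character vector
# of length n with category labels (NA for unassigned slots), interleaved
# so every category is close to uniformly distributed along the slot
# order. Deterministic: planted elements land at reproducible positions.
interleave_assign <- function(counts, n_slots) {
  total <- sum(counts)
  if (total > n_slots) stop("more planted elements than available slots")
  counts <- counts[counts > 0]
  labs <- rep(names(counts), counts)
  frac <- unlist(lapply(counts, function(k) (seq_len(k) - 0.5) / k),
                 use.names = FALSE)
  o <- order(frac, labs)
  # place the `total` labels at evenly spaced slot positions
  pos <- round(seq(1, n_slots, length.out = total))
  out <- rep(NA_character_, n_slots)
  out[pos] <- labs[o]
  out
}

state_marks <- function(letter) {
  switch(letter,
         A = c("DHS", "H3K4me3", "H3K9ac", "H3K27ac"),
         P = c("DHS", "H3K4me3", "H3K9ac", "H3K27me3"),
         R = "H3K27me3",
         U = character(0))
}

# ---- generator -------------------------------------------------------

#' Generate the synthetic six-stage fixture
#'
#' Materializes the configuration into an in-memory fixture and its
#' truth manifest; use [write_fixture()] to emit the on-disk form
#' (FASTA/GTF/BED/TSV/JSON/YAML). With the noise channels disabled
#' (\code{jitter_bp = 0}, \code{replicate_dropout_rate = 0},
#' \code{count_mode = "none"}, \code{expression_noise_sd = 0}) every
#' downstream module recovers the planted truth exactly.
#'
#' @param config A [fixture_config()].
#' @return Object of class \code{hemo_fixture}: list with
#'   \code{config}, \code{chrom_sizes}, \code{genes} (gene models),
#'   \code{expression} (FPKM matrix), \code{dhs_peaks}
#'   (\code{[[stage]][[replicate]]} \code{GRanges}), \code{tf_peaks}
#'   (\code{[[tf]][[stage]][[replicate]]}), \code{tracks}
#'   (\code{[[stage]][[mark]]} [binned_track()]), \code{genome} (named
#'   character vector or NULL) and \code{manifest}
#'   (class \code{truth_manifest}).
#' @export
generate_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  validate_fixture_config(config)
  cfg <- config
  stages <- hemo_stages()
  panel <- rownames(cfg$tf_panel$expression)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  # -- gene grid
  per_chrom <- cfg$n_genes %/% cfg$n_chroms
  extra <- cfg$n_genes %% cfg$n_chroms
  gene_chrom <- rep(chroms, per_chrom + c(rep(1L, extra),
                                          rep(0L, cfg$n_chroms - extra)))
  idx_in_chrom <- unlist(lapply(table(factor(gene_chrom, chroms)), seq_len),
                         use.names = FALSE)
  spacing <- as.integer(cfg$chrom_length %/% max(table(factor(gene_chrom, chroms))))
  locus_start <- (idx_in_chrom - 1L) * spacing  # 0-based
  tss <- locus_start + spacing %/% 2L           # 1-based (offset lands mid-locus)
  strand <- ifelse(seq_len(cfg$n_genes) %% 2L == 1L, "+", "-")
  span_start <- ifelse(strand == "+", tss, tss - cfg$gene_span)
  span_end <- ifelse(strand == "+", tss + cfg$gene_span, tss)

  panel_idx <- seq(5L, by = 12L, length.out = length(panel))
  gene_id <- sprintf("g%03d", seq_len(cfg$n_genes))
  gene_id[panel_idx] <- panel
  genes <- gene_models(gene_id, gene_chrom, span_start, span_end, strand,
                       tss = tss)

  non_panel <- setdiff(seq_len(cfg$n_genes), panel_idx)

  # -- promoter state timelines
  states <- stats::setNames(rep(NA_character_, cfg$n_genes), gene_id)
  states[panel_idx] <- unname(cfg$tf_panel$states[gene_id[panel_idx]])
  states[non_panel] <- rep(names(cfg$promoter_state_profiles),
                           cfg$promoter_state_profiles)

  # -- expression
  clusters <- stats::setNames(rep(NA_character_, cfg$n_genes), gene_id)
  clusters[non_panel] <- rep_len(names(cfg$expression_profiles),
                                 length(non_panel))
  log_mu <- matrix(NA_real_, cfg$n_genes, 6L,
                   dimnames = list(gene_id, stages))
  for (cl in names(cfg$expression_profiles)) {
    sel <- which(clusters == cl)
    log_mu[sel, ] <- matrix(cfg$expression_profiles[[cl]], length(sel), 6L,
                            byrow = TRUE)
  }
  log_mu[panel_idx, ] <- cfg$tf_panel$expression[gene_id[panel_idx], ]
  noise <- with_local_seed(substream_seed(cfg$seed, "expression"), {
    matrix(stats::rnorm(length(log_mu), 0, cfg$expression_noise_sd),
           nrow(log_mu), ncol(log_mu))
  })
  expression <- 10^(log_mu + noise)

  # -- DHS truth table: promoter rows (state A/P => open) + distal slots
  state_mat <- do.call(rbind, strsplit(states, "", fixed = TRUE))
  prom_code <- apply(state_mat, 1L, function(r) {
    paste(as.integer(r %in% c("A", "P")), collapse = "")
  })
  prom_keep <- which(prom_code != "000000")
  prom_dhs <- data.frame(
    chrom = gene_chrom[prom_keep],
    start = tss[prom_keep] - cfg$promoter_dhs_halfwidth,
    end = tss[prom_keep] + cfg$promoter_dhs_halfwidth - 1L,
    code = prom_code[prom_keep], class = "proximal",
    gene = gene_id[prom_keep], stringsAsFactors = FALSE)

  # distal slots: a 3-kb grid inside each non-reserved gene locus, keeping
  # a 3-kb guard zone around the TSS (so slots stay distal) and a guard at
  # the locus edges (so slots never merge across loci)
  reserved <- gene_id %in% panel
  free <- which(!reserved)
  center <- spacing %/% 2L
  offs <- seq(3500L, spacing - 3500L - cfg$dhs_width, by = 3000L)
  # align slots to bin boundaries so each DHS occupies few whole bins and
  # the global Poisson background stays close to the background rate
  offs <- as.integer((offs %/% cfg$bin_size) * cfg$bin_size)
  offs <- offs[abs(offs + cfg$dhs_width %/% 2L - center) > 3000L]
  if (length(offs) * length(free) < sum(cfg$distal_pattern_counts)) {
    stop("genome too small for the requested distal DHS populations")
  }
  slot_chrom <- rep(gene_chrom[free], each = length(offs))
  slot_start <- rep(locus_start[free], each = length(offs)) +
    rep(offs, length(free))
  slot_gene <- rep(gene_id[free], each = length(offs))
  o <- order(slot_chrom, slot_start)
  slot_chrom <- slot_chrom[o]; slot_start <- slot_start[o]
  slot_gene <- slot_gene[o]
  codes <- interleave_assign(cfg$distal_pattern_counts, length(slot_start))
  keep <- !is.na(codes)
  distal_dhs <- data.frame(
    chrom = slot_chrom[keep], start = slot_start[keep] + 1L,
    end = slot_start[keep] + cfg$dhs_width,
    code = codes[keep], class = "distal", gene = slot_gene[keep],
    stringsAsFactors = FALSE)

  dhs <- rbind(prom_dhs, distal_dhs)
  dhs <- dhs[order(dhs$chrom, dhs$start, dhs$end), , drop = FALSE]
  dhs$dhs_id <- sprintf("dhs%05d", seq_len(nrow(dhs)))
  rownames(dhs) <- NULL
  dhs_bits <- do.call(rbind, strsplit(dhs$code, "", fixed = TRUE)) == "1"

  # -- replicate peak files: each replicate is the planted set, jittered
  # by up to jitter_bp and thinned i.i.d. at replicate_dropout_rate
  replicate_peaks <- function(df, stream) {
    lapply(stats::setNames(seq_len(cfg$n_replicates),
                           paste0("rep", seq_len(cfg$n_replicates))),
           function(r) {
      n <- nrow(df)
      noise <- with_local_seed(substream_seed(cfg$seed,
                                              paste(stream, r, sep = ":")), {
        list(shift = if (cfg$jitter_bp > 0L && n > 0L)
          sample.int(2L * cfg$jitter_bp + 1L, n, replace = TRUE) -
            cfg$jitter_bp - 1L else integer(n),
          keep = if (n > 0L)
            stats::runif(n) >= cfg$replicate_dropout_rate else logical(0))
      })
      kept <- df[noise$keep, , drop = FALSE]
      shift <- noise$shift[noise$keep]
      if (nrow(kept) == 0L) return(GenomicRanges::GRanges())
      sort_lex(GenomicRanges::GRanges(
        kept$chrom,
        IRanges::IRanges(pmax(kept$start + shift, 1L), kept$end + shift)))
    })
  }
  dhs_peaks <- lapply(stats::setNames(stages, stages), function(st) {
    s <- stage_index(st)
    replicate_peaks(dhs[dhs_bits[, s], , drop = FALSE], paste("dhs", st))
  })

  # -- TF peaks: pattern binding, gene targeting, planted network edges
  tf_peak_rows <- list()
  add_peaks <- function(tf, stage, chrom, start, end, kind, target, dhs_ids) {
    tf_peak_rows[[length(tf_peak_rows) + 1L]] <<- data.frame(
      tf = tf, stage = stage, chrom = chrom, start = start, end = end,
      kind = kind, target = target, dhs_id = dhs_ids,
      stringsAsFactors = FALSE)
  }
  half_pk <- cfg$tf_peak_width %/% 2L
  for (i in seq_len(nrow(cfg$tf_dhs_plan))) {
    pl <- cfg$tf_dhs_plan[i, ]
    rows <- which(dhs$code == pl$pattern & dhs$class == "distal")
    take <- rows[seq_len(round(pl$fraction * length(rows)))]
    if (length(take) == 0L) next
    mid <- (dhs$start[take] + dhs$end[take]) %/% 2L
    add_peaks(pl$tf, pl$stage, dhs$chrom[take], mid - half_pk,
              mid - half_pk + cfg$tf_peak_width - 1L,
              "dhs", NA_character_, dhs$dhs_id[take])
  }
  for (i in seq_len(nrow(cfg$tf_target_plan))) {
    pl <- cfg$tf_target_plan[i, ]
    cl_genes <- which(clusters == pl$cluster)
    take <- cl_genes[seq_len(round(pl$fraction * length(cl_genes)))]
    others <- setdiff(non_panel, cl_genes)
    if (pl$background_fraction > 0) {
      step <- max(1L, round(1 / pl$background_fraction))
      take <- c(take, others[seq(1L, length(others), by = step)])
    }
    if (length(take) == 0L) next
    pos <- tss[take] + 3000L
    add_peaks(pl$tf, pl$stage, gene_chrom[take], pos - half_pk,
              pos - half_pk + cfg$tf_peak_width - 1L,
              "target", gene_id[take], NA_character_)
  }
  for (i in seq_len(nrow(cfg$grn_truth))) {
    ed <- cfg$grn_truth[i, ]
    gi <- which(gene_id == ed$target)
    pos <- tss[gi] + 750L
    add_peaks(ed$source, ed$stage, gene_chrom[gi], pos - half_pk,
              pos - half_pk + cfg$tf_peak_width - 1L,
              "edge", ed$target, NA_character_)
  }
  tf_peak_df <- if (length(tf_peak_rows)) do.call(rbind, tf_peak_rows) else {
    data.frame(tf = character(0), stage = character(0), chrom = character(0),
               start = integer(0), end = integer(0), kind = character(0),
               target = character(0), dhs_id = character(0))
  }

  tf_peaks <- lapply(stats::setNames(panel, panel), function(tf) {
    avail <- cfg$tf_panel$chip[[tf]]
    lapply(stats::setNames(avail, avail), function(st) {
      sub_df <- tf_peak_df[tf_peak_df$tf == tf & tf_peak_df$stage == st, ,
                           drop = FALSE]
      sub_df <- sub_df[order(sub_df$chrom, sub_df$start), , drop = FALSE]
      replicate_peaks(sub_df, paste("tf", tf, st))
    })
  })

  # -- binned count tracks
  n_bins <- as.integer(ceiling(cfg$chrom_length / cfg$bin_size))
  bins_of <- function(lo, hi) {
    b0 <- max((lo - 1L) %/% cfg$bin_size, 0L)
    b1 <- min((hi - 1L) %/% cfg$bin_size, n_bins - 1L)
    if (b0 > b1) integer(0) else (b0:b1) + 1L
  }
  tracks <- lapply(stats::setNames(stages, stages), function(st) {
    s <- stage_index(st)
    lapply(stats::setNames(CHROMATIN_MARKS, CHROMATIN_MARKS), function(mk) {
      rate <- lapply(stats::setNames(chroms, chroms),
                     function(ch) rep(cfg$background_rate, n_bins))
      for (g in seq_len(cfg$n_genes)) {
        letter <- substr(states[g], s, s)
        if (mk %in% state_marks(letter)) {
          # enrich the bins inside the promoter window but short of its
          # edges: the window majority stays with the planted state while
          # the genome-wide enriched fraction (which lifts the Poisson
          # background mean used for binarization) stays small
          b <- bins_of(tss[g] - 1000L + cfg$bin_size,
                       tss[g] + 1000L - cfg$bin_size)
          rate[[gene_chrom[g]]][b] <- cfg$enriched_rate
        }
      }
      if (mk %in% c("DHS", "H3K27ac")) {
        open_rows <- which(dhs_bits[, s] & dhs$class == "distal")
        for (rix in open_rows) {
          b <- bins_of(dhs$start[rix], dhs$end[rix])
          rate[[dhs$chrom[rix]]][b] <- cfg$enriched_rate
        }
        if (mk == "DHS") {
          prom_rows <- which(dhs_bits[, s] & dhs$class == "proximal")
          for (rix in prom_rows) {
            b <- bins_of(dhs$start[rix], dhs$end[rix])
            rate[[dhs$chrom[rix]]][b] <- cfg$enriched_rate
          }
        }
      }
      counts <- if (cfg$count_mode == "poisson") {
        with_local_seed(substream_seed(cfg$seed, paste("track", st, mk,
                                                       sep = ":")), {
          lapply(rate, function(v) stats::rpois(length(v), v))
        })
      } else {
        lapply(rate, function(v) round(v))
      }
      binned_track(counts, cfg$bin_size, mk)
    })
  })

  # -- genome sequence + motif embedding
  genome <- NULL
  motif_sites <- data.frame(motif = character(0), chrom = character(0),
                            start = integer(0), strand = character(0),
                            context = character(0))
  if (cfg$include_genome) {
    letters_by_chrom <- with_local_seed(substream_seed(cfg$seed, "genome"), {
      lapply(stats::setNames(chroms, chroms), function(ch) {
        DNA_BASES[sample.int(4L, cfg$chrom_length, replace = TRUE)]
      })
    })
    site_rows <- list()
    plant <- function(motif_id, chrom, start, context) {
      site_rows[[length(site_rows) + 1L]] <<- data.frame(
        motif = motif_id, chrom = chrom, start = start,
        strand = NA_character_, context = context, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(cfg$dhs_motif_plan))) {
      pl <- cfg$dhs_motif_plan[i, ]
      rows <- which(dhs$code == pl$pattern & dhs$class == "distal")
      take <- rows[seq_len(round(pl$fraction * length(rows)))]
      offset <- 10L + 14L * (i - 1L)
      for (rix in take) {
        plant(pl$motif, dhs$chrom[rix], dhs$start[rix] + offset,
              dhs$dhs_id[rix])
      }
      if (pl$background_fraction > 0) {
        others <- which(dhs$class == "distal" & dhs$code != pl$pattern)
        step <- max(1L, round(1 / pl$background_fraction))
        for (rix in others[seq(1L, length(others), by = step)]) {
          plant(pl$motif, dhs$chrom[rix], dhs$start[rix] + offset,
                dhs$dhs_id[rix])
        }
      }
    }
    pk_dhs <- tf_peak_df[tf_peak_df$kind == "dhs", , drop = FALSE]
    pk_dhs <- pk_dhs[!duplicated(pk_dhs[, c("chrom", "start", "tf")]), ,
                     drop = FALSE]
    for (j in seq_len(nrow(pk_dhs))) {
      pl_tf <- cfg$tf_dhs_plan[cfg$tf_dhs_plan$tf == pk_dhs$tf[j], ,
                               drop = FALSE][1L, ]
      mid <- (pk_dhs$start[j] + pk_dhs$end[j]) %/% 2L
      plant(pl_tf$motif, pk_dhs$chrom[j], mid - 4L,
            paste0("peak:", pk_dhs$tf[j], "@", pk_dhs$stage[j]))
    }
    sites <- if (length(site_rows)) do.call(rbind, site_rows) else motif_sites
    if (nrow(sites)) {
      emb <- with_local_seed(substream_seed(cfg$seed, "motif-embed"), {
        list(rev = stats::runif(nrow(sites)) < 0.5,
             mut = lapply(seq_len(nrow(sites)), function(k) {
               len <- nrow(cfg$motif_library[[sites$motif[k]]]$mat)
               which(stats::runif(len) < cfg$motif_mutation_prob)
             }),
             repl = lapply(seq_len(nrow(sites)), function(k) {
               len <- nrow(cfg$motif_library[[sites$motif[k]]]$mat)
               sample.int(3L, len, replace = TRUE)
             }))
      })
      for (k in seq_len(nrow(sites))) {
        pw <- cfg$motif_library[[sites$motif[k]]]
        inst <- strsplit(pwm_consensus(pw), "", fixed = TRUE)[[1L]]
        for (m in emb$mut[[k]]) {
          inst[m] <- setdiff(DNA_BASES, inst[m])[emb$repl[[k]][m]]
        }
        if (emb$rev[k]) {
          inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
        }
        pos <- sites$start[k]
        letters_by_chrom[[sites$chrom[k]]][pos:(pos + length(inst) - 1L)] <- inst
      }
      sites$strand <- ifelse(emb$rev, "-", "+")
    }
    motif_sites <- sites
    genome <- vapply(letters_by_chrom, paste, "", collapse = "")
  }

  manifest <- structure(list(
    dhs = dhs[, c("dhs_id", "chrom", "start", "end", "code", "class",
                  "gene")],
    genes = data.frame(gene_id = gene_id, chrom = gene_chrom,
                       strand = strand, tss = tss,
                       span_start = span_start, span_end = span_end,
                       cluster = unname(clusters), states = unname(states),
                       panel = gene_id %in% panel,
                       stringsAsFactors = FALSE),
    tf_peaks = tf_peak_df,
    edges = cfg$grn_truth,
    motif_sites = motif_sites,
    expression_means = log_mu),
    class = "truth_manifest")

  structure(list(config = cfg, chrom_sizes = chrom_sizes, genes = genes,
                 expression = expression, dhs_peaks = dhs_peaks,
                 tf_peaks = tf_peaks, tracks = tracks, genome = genome,
                 manifest = manifest),
            class = "hemo_fixture")
}

#' @export
print.hemo_fixture <- function(x, ...) {
  cat("hemo_fixture:", length(x$chrom_sizes), "chromosome(s) x",
      format(x$chrom_sizes[[1L]], big.mark = ","), "bp;",
      length(x$genes), "genes;", nrow(x$manifest$dhs), "planted DHS;",
      x$config$n_replicates, "replicates/assay; seed", x$config$seed, "\n")
  invisible(x)
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat("truth_manifest:", nrow(x$dhs), "DHS,", nrow(x$genes), "genes,",
      nrow(x$tf_peaks), "TF peaks,", nrow(x$edges), "network edges,",
      nrow(x$motif_sites), "motif instances\n")
  invisible(x)
}

#' Oracle summary tables from a truth manifest
#'
#' Recomputes, by plain counting over the manifest, the summaries that
#' every downstream module is expected to recover: DHS population per
#' six-digit code, genes per expression cluster, genes per
#' promoter-state timeline, and the planted edge table.
#'
#' @param manifest A \code{truth_manifest}.
#' @return List with data.frames \code{pattern_counts} (code, count),
#'   \code{cluster_counts}, \code{state_counts}, and \code{edges}.
#' @export
manifest_census <- function(manifest) {
  stopifnot(inherits(manifest, "truth_manifest"))
  count_df <- function(x, nm) {
    if (length(x) == 0L || all(is.na(x))) {
      out <- data.frame(a = character(0), count = integer(0))
    } else {
      tab <- table(x[!is.na(x)])
      out <- data.frame(a = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
    }
    names(out)[1L] <- nm
    out[order(out[[nm]]), , drop = FALSE]
  }
  list(pattern_counts = count_df(manifest$dhs$code, "code"),
       cluster_counts = count_df(manifest$genes$cluster, "cluster"),
       state_counts = count_df(manifest$genes$states, "states"),
       edges = manifest$edges)
}

#' Truth DHS table as GRanges
#'
#' @param manifest A \code{truth_manifest}.
#' @return \code{GRanges} with \code{dhs_id}, \code{code}, \code{class},
#'   \code{gene} metadata.
#' @export
manifest_dhs_granges <- function(manifest) {
  gr <- GenomicRanges::GRanges(manifest$dhs$chrom,
                               IRanges::IRanges(manifest$dhs$start,
                                                manifest$dhs$end))
  S4Vectors::mcols(gr)$dhs_id <- manifest$dhs$dhs_id
  S4Vectors::mcols(gr)$code <- manifest$dhs$code
  S4Vectors::mcols(gr)$class <- manifest$dhs$class
  S4Vectors::mcols(gr)$gene <- manifest$dhs$gene
  gr
}

#' Write a fixture to disk in standard formats
#'
#' Emits genome FASTA (+ .fai index), gene models as GTF, per-assay /
#' stage / replicate peak BED files, binned count tracks as TSV,
#' the expression table as TSV, the truth manifest as JSON and a
#' simplified YAML copy of the scalar configuration. Re-running with the
#' same configuration produces byte-identical output.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "hemo_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  if (!is.null(fixture$genome)) {
    fa <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(fixture$genome), fa)
    Rsamtools::indexFa(fa)
  }
  write_gtf_genes(fixture$genes, file.path(dir, "genes.gtf"))
  for (st in names(fixture$dhs_peaks)) {
    for (r in names(fixture$dhs_peaks[[st]])) {
      write_bed(fixture$dhs_peaks[[st]][[r]],
                file.path(dir, "peaks", paste0("dhs_", st, "_", r, ".bed")))
    }
  }
  for (tf in names(fixture$tf_peaks)) {
    for (st in names(fixture$tf_peaks[[tf]])) {
      for (r in names(fixture$tf_peaks[[tf]][[st]])) {
        write_bed(fixture$tf_peaks[[tf]][[st]][[r]],
                  file.path(dir, "peaks",
                            paste0("tf_", tf, "_", st, "_", r, ".bed")))
      }
    }
  }
  for (st in names(fixture$tracks)) {
    for (mk in names(fixture$tracks[[st]])) {
      write_track(fixture$tracks[[st]][[mk]],
                  file.path(dir, "tracks", paste0(st, "_", mk, ".tsv")))
    }
  }
  write_expression(fixture$expression, file.path(dir, "expression.tsv"))
  m <- fixture$manifest
  jsonlite::write_json(
    list(dhs = m$dhs, genes = m$genes, tf_peaks = m$tf_peaks,
         edges = m$edges, motif_sites = m$motif_sites),
    file.path(dir, "manifest.json"), dataframe = "columns", digits = NA)
  cfg <- fixture$config
  scalars <- cfg[vapply(cfg, function(x)
    is.atomic(x) && length(x) <= 12L && is.null(dim(x)), TRUE)]
  yaml::write_yaml(scalars, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate binarized observations from a planted chromatin-state HMM
#'
#' Generates a Markov state sequence and conditionally independent
#' Bernoulli mark emissions -- the controlled fixture for validating
#' [fit_hmm()] / [decode_states()] recovery. The default is a 2-state
#' model with mirrored emission probabilities 0.9 / 0.1 over the five
#' chromatin marks and sticky transitions (0.95 self-transition).
#'
#' @param n_bins Number of bins to simulate.
#' @param emission K x M emission probability matrix.
#' @param transition K x K row-stochastic transition matrix.
#' @param initial Initial state distribution.
#' @param seed Integer seed.
#' @return List with \code{obs} (n_bins x M binary matrix, mark column
#'   names when M = 5), \code{states} (planted labels), and the
#'   generating \code{emission} / \code{transition} / \code{initial}.
#' @export
generate_hmm_fixture <- function(n_bins = 10000L,
                                 emission = rbind(c(0.9, 0.9, 0.9, 0.1, 0.1),
                                                  c(0.1, 0.1, 0.1, 0.9, 0.9)),
                                 transition = matrix(c(0.95, 0.05,
                                                       0.05, 0.95), 2L, 2L,
                                                     byrow = TRUE),
                                 initial = NULL,
                                 seed = 1L) {
  K <- nrow(emission)
  M <- ncol(emission)
  if (is.null(initial)) initial <- rep(1 / K, K)
  stopifnot(nrow(transition) == K, ncol(transition) == K,
            all(abs(rowSums(transition) - 1) < 1e-9))
  out <- with_local_seed(substream_seed(seed, "hmm-fixture"), {
    states <- integer(n_bins)
    states[1L] <- sample.int(K, 1L, prob = initial)
    for (t in seq_len(n_bins - 1L) + 1L) {
      states[t] <- sample.int(K, 1L, prob = transition[states[t - 1L], ])
    }
    obs <- matrix(stats::runif(n_bins * M), n_bins, M) <
      emission[states, , drop = FALSE]
    storage.mode(obs) <- "numeric"
    list(states = states, obs = obs)
  })
  if (M == 5L) colnames(out$obs) <- CHROMATIN_MARKS
  list(obs = out$obs, states = out$states, emission = emission,
       transition = transition, initial = initial)
}
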