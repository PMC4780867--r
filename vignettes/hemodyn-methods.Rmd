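---
title: "Methods: integrative analysis of staged hematopoietic chromatin and expression data"
author: "hemodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative analysis of staged hematopoietic chromatin and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`hemodyn` analyses multi-omics data from an ordered six-stage
differentiation series — embryonic stem cells (ESC), mesoderm (MES),
hemangioblast (HB), hemogenic endothelium (HE), hematopoietic progenitors
(HP) and macrophages (MAC) — with, per stage, replicated DNaseI
hypersensitive site (DHS) peak sets, replicated ChIP peak sets for
histone marks (H3K4me3, H3K9ac, H3K27ac, H3K27me3) and transcription
factors (TFs), binned signal tracks, and a genes × stages expression
matrix (FPKM-like units). Six analysis layers are built on this input:

1. **Chromatin states.** A K-state hidden Markov model over binarized
   marks, coarse-grained to a four-state promoter model.
2. **DHS dynamics.** Six-digit binary presence codes for the union of
   reproducible DHS across stages.
3. **Overlap statistics.** Region-size-aware significance of overlaps
   between TF binding and gene sets or DHS patterns, with bootstrap
   H3K27ac Z-scores.
4. **Motif analysis.** PWM scanning and bootstrap relative-enrichment
   (RE) statistics on stage-unique distal DHS and TF peaks.
5. **Gene regulatory networks (GRNs).** Stage-resolved TF→TF-locus
   binding graphs with chromatin/expression annotations, and a
   reprogramming-candidate ranking.
6. **Expression dynamics.** Differential calling across the five stage
   transitions, z-standardization and k-means pattern discovery.

Every layer is exercised end-to-end against a synthetic data generator
with a machine-readable truth manifest, so the whole pipeline is testable
without any external download.

# Coordinate and container conventions

Internally every interval is a `GenomicRanges::GRanges` (1-based,
closed), the canonical Bioconductor container; BED input/output
(0-based, half-open) and GTF input (1-based) are converted exactly once,
at the I/O boundary. A peak's *position* for distance computations and
peak-to-gene attribution is its interval midpoint
(`floor((start0 + end0) / 2)` in 0-based terms). Chromosome names are
compared verbatim — no `"chr"` stripping — so mixed naming dialects
surface as empty overlaps instead of being silently reconciled.
Nearest-TSS ties (a midpoint equidistant from two TSS) are broken by the
lexicographically smaller `gene_id`, which makes peak-to-gene assignment
deterministic and therefore testable.

# Chromatin-state layer

**Binarization.** A bin is called "marked" when the upper-tail Poisson
p-value of its count under the *genome-wide mean rate* is below
`p_threshold` (default `1e-4`). The global (rather than locally
estimated) background keeps the rule a one-parameter, order-preserving
function of the counts. One consequence worth knowing: the genome-wide
mean includes the enriched bins, so very broad enrichment lifts the
background estimate and weakens calls; the synthetic generator therefore
keeps its enriched-bin fraction below ~5% (bin-aligned elements, promoter
enrichment just inside the window edges), which is also the regime of
real chromatin data.

**The HMM.** `fit_hmm()` is Baum–Welch EM for a K-state chain whose
emissions are independent Bernoulli variables, one per mark
(a "ChromHMM-style" multivariate model extended with the DNaseI
accessibility track, which separates inactive-closed from
repressed/poised-open chromatin). Numerical choices: emissions are
initialized at the empirical mark frequencies plus seed-controlled
uniform jitter (±0.25, clipped to [0.02, 0.98]) — enough asymmetry to
break the label symmetry deterministically; transitions start uniform;
emission estimates are clipped to [1e-6, 1 − 1e-6] to keep logs finite;
the forward–backward pass uses per-bin scaling; fitting stops when the
relative log-likelihood gain falls below `tol` (default 1e-6) or at
`max_iter` (default 100). The per-iteration log-likelihood trace is
stored so monotonicity is asserted, not assumed. Fitted states are
re-ordered into a canonical emission-sorted order, making a fitted model
a pure function of `(data, K, seed)`.

K is deliberately a free parameter. Genome-scale chromatin studies use
large K (twenty-plus states); the value is data-scale-dependent, and the
four-state coarse-graining is what makes analyses at different K
comparable. The recovery tests plant K = 2 with mirrored emissions
0.9/0.1 and sticky transitions (0.95), the cleanest setting in which
estimation error is attributable to the fitter rather than to model
ambiguity; at 10,000 bins the fitted emissions land within ±0.05 of
truth and Viterbi decoding exceeds 90% label accuracy.

**Coarse graining.** The four-state rule is applied either to a model's
emission probabilities thresholded at 0.5 or directly to per-region mark
calls: *poised* = DHS ∧ H3K27me3 ∧ (H3K4me3 ∨ acetyl);
else *active* = DHS ∧ H3K4me3 ∧ acetyl; else *repressed* = H3K27me3;
else *unmarked* (acetyl = H3K9ac ∨ H3K27ac). The rule order matters —
poised must be tested before active and repressed — and the four branches
partition all 32 mark combinations, which the tests verify exhaustively.

**Promoter timelines.** A promoter is the TSS ± 1 kb window. Its label
per stage is the majority coarse state over the window's bins, with ties
broken by the precedence POISED > ACTIVE > REPRESSED > UNMARKED so that
the rarer, more informative states survive ties. A window overlapping no
bins gets the sentinel `"N"` plus a warning rather than an error: a
missing annotation for one gene should not abort a genome-wide run.

# DHS dynamics layer

Reproducibility filtering implements "present in at least two
independent experiments" at base-pair resolution: each replicate's peaks
are collapsed, per-bp replicate support is summed, and merged stretches
with support ≥ 2 are kept. The per-bp formulation agrees with an
independent counting oracle by construction, whereas an
interval-level rule ("union interval backed by two replicate lists") can
chain together peaks that never mutually overlap.

The union of reproducible DHS across all six stages (merged with gap 0)
is the *atomic unit* of everything downstream: each union row receives a
six-character code over {0,1} (bit *s* = 1 iff the row overlaps a
stage-*s* peak, in fixed ESC→MAC order), one proximal/distal class, and
one nearest gene. Using the union row — not per-stage peaks — guarantees
a single consistent code per element. *Proximal* means the midpoint is
within 1 kb of the nearest TSS, boundary inclusive; the cutoff equals
the promoter window half-width on purpose, so "proximal" and "promoter"
never disagree. Pattern-level statistics only consider codes with
population strictly greater than 100, below which overlap p-values are
too granular to be informative.

# Overlap-significance layer

Attributing peaks to genes is size-biased: genes with large intergenic
territories catch more peaks by chance. The package therefore assigns
each gene a *regulatory domain* — on each chromosome, boundaries at the
midpoints between consecutive TSS, end domains running to the chromosome
ends — and a gene is a *target* of a peak set when at least one peak
midpoint falls in its domain. Significance of an observed overlap
between a gene set and the target set is computed against resampled gene
sets of equal size drawn *without replacement with probability
proportional to domain length*. This length-weighted null is a declared
reconstruction of "accounting for differing region sizes": it is exposed
as the default strategy, reduces provably to simple random sampling
(hence the hypergeometric tail) when domains are equal, and its type-I
error is verified by simulation (500 null draws at α = 0.05 against the
exact binomial confidence band).

Empirical p-values use the add-one estimator
`p = (1 + #{null ≥ obs}) / (n_resamples + 1)`, which can never return 0;
with the default `n_resamples = 1e5`, p-values below the strict `1e-4`
reporting threshold are resolvable (minimum attainable p ≈ 1e-5). For
DHS-pattern × TF overlaps the null resamples *rows uniformly* from the
union-DHS universe rather than length-weighted: union DHS widths are
near-constant, and the uniform null keeps the pattern statistic
independent of the gene annotation. This is a strategy switch, not a
hard-wired assumption.

H3K27ac Z-scores at TF sites use a bootstrap null: the observed mean
acetylation over the TF sites attributed to a gene set is compared with
means of equal-size site samples drawn with replacement from all the
TF's sites; `Z = (obs − mean)/sd`. A degenerate null (sd = 0, e.g. a
constant track) reports Z = 0 with a flag instead of dividing by zero.
The statistic is invariant to affine rescaling of the track, so
normalization conventions do not leak into it.

# Motif layer

Scanning is plain log-odds scoring, `sum(log2(p/bg))` over the window,
on both strands (a minus-strand hit at offset *o* means the reverse
complement of the window at *o* matches; offsets always refer to forward
coordinates). `N` scores `log2(0.25/mean(bg))` — neutral under a uniform
background. The default hit threshold is 80% of each PWM's maximum
attainable score, the common practice for near-consensus libraries, and
is exposed per motif.

Relative enrichment between region sets A and B is a ratio of per-region
hit *fractions* (presence/absence, robust to region length), with
pseudocount ε = 1/(2·min(nA, nB)):
`RE = (fA + ε)/(fB + ε)`. Regions are re-centered at their midpoints at
fixed width (default 400 bp) before sequence extraction so both sets are
length-matched. Significance comes from bootstrapping regions with
replacement within each set; the reported p is the (add-one) fraction of
bootstrap replicates with RE ≤ 1. Two useful identities follow directly
and are tested: RE(A,A) = 1 exactly, and RE(A,B)·RE(B,A) = 1 when
nA = nB. An important practical property: imperfect motif instances
(the generator mutates embedded sites at 5% per position) reduce *both*
sets' detection rates nearly proportionally, so RE remains close to the
planted embedding ratio even when absolute detection is well below 1.

The RE matrix takes, for each ordered stage pair (a, b), the distal DHS
open in a but not b as foreground and the mirror set (open in b, not a)
as background — a symmetric definition under which every one of the 30
columns has a well-defined contrast. The motif library can be restricted
to motifs whose cognate TF is expressed at the focal stage (floor
1 FPKM by default). Motif rows are clustered with average-linkage
hierarchical clustering on Euclidean distance; leaf order is the
deterministic `hclust` order, so heatmaps reproduce exactly.

# GRN layer

An edge source→target exists at a stage when the source TF has at least
one reproducible peak whose midpoint lies in the target gene's *locus
window*: the gene span ± 50 kb, clipped at the target's
regulatory-domain boundaries so a peak can support at most one target.
The 50 kb flank is the single most consequential free parameter of the
network and is deliberately a visible argument rather than a constant.
Nodes carry the stage's expression level, promoter DHS presence (any
open union DHS overlapping TSS ± 1 kb), the promoter coarse-state
letter, and a ChIP-availability flag; a TF without ChIP data has no
out-edges by construction (absence of evidence, not evidence of
absence), and the constructor enforces this invariant. Self-edges encode
autoregulation. Graphs round-trip through GraphML with all annotations
(numeric attributes up to text-serialization precision).

Reprogramming candidates are ranked by (1) earliest stage at which the
TF's expression reaches the floor (1 FPKM), then (2) the number of
target loci bound at or before the HE stage, then lexicographically.
The logic mirrors the observation that factors that both turn on early
and wire into many blood-regulator loci are the ones that can impose the
program on a foreign cell. Because the primary key is activation stage,
a panel containing constitutively ESC-expressed factors would rank them
first regardless of connectivity; the generator's default panel is
therefore 16 hematopoietic factors whose activation occurs during
specification (the earliest at HB), which is the regime the ranking is
designed for.

# Expression layer

Differential calling is a transparent fold-change rule: up at transition
k when `expr(k+1) ≥ floor` and `expr(k+1)/max(expr(k), floor) ≥ min_fc`
(defaults `min_fc = 2`, `floor = 1` FPKM), down symmetric. Flooring the
denominator keeps switch-on ratios finite and makes the call invariant
to jointly rescaling matrix and floor. Profiles of dynamic genes are
standardized as `z = (log10(x + 0.01) − mean)/sd` per gene; sd-zero
genes are excluded and recorded. Pattern discovery is k-means with
greedy farthest-point seeding per restart (deterministic given the seed)
and Lloyd iterations, keeping the best of 20 restarts by total
within-cluster sum of squares. k is a free parameter — genome-scale
studies of this kind use k in the tens; the generator plants 5 dynamic
patterns (plus one flat housekeeping profile) because recovery can then
be scored exactly (adjusted Rand index 1 at separation ≥ 2 noise sd).
External profiles are scored by Pearson correlation with each stage
column on the log scale, and correlations are compared with the
two-sample Fisher z-transform test; a correlation compared with itself
gives p = 1 by convention.

# The synthetic-data generator

The generator emulates the *structure* of a staged multi-omics study:

* genome: 2 chromosomes × 5 Mb of i.i.d. uniform ACGT sequence;
* genes: 200 on a uniform grid (50 kb loci, TSS mid-locus, alternating
  strand), 16 of them the TF panel, placed at regular spread-out
  indices;
* DHS: 2,000 distal elements (200 bp, bin-aligned) distributed over
  per-code populations plus promoter DHS implied by each gene's planted
  promoter-state timeline (a state of A or P at a stage implies an open
  promoter, so promoter codes follow the state string);
* tracks: Poisson counts, background mean 1/bin, enriched mean 8/bin at
  200 bp bins — chosen so Poisson binarization separates cleanly but not
  trivially; a `count_mode = "none"` switch makes counts deterministic
  (`round(rate)`) for exactness tests;
* TF peaks: nested in DHS of planned patterns (with the plan's motif
  embedded at the peak), targeting planned fractions of expression
  clusters (background targets spread evenly), and planted at panel-TF
  loci according to the truth network;
* motifs: near-consensus PWMs; embedded instances are consensus strings
  mutated at 5% per position, on a random strand;
* expression: per-cluster stage means (log10 scale) plus
  stage-independent Gaussian noise (sd 0.1);
* replicates: each replicate is the planted peak set jittered by up to
  `jitter_bp` and thinned i.i.d. at `replicate_dropout_rate`.

Two properties are deliberate. First, the *layout is deterministic given
the configuration*: the seed drives only noise channels (sequence,
mutations, strands, counts, jitter, dropout, expression noise). Planted
elements and background assignments are spread evenly along the genome,
so "unplanted" cells of the enrichment matrix sit at their null
expectation instead of fluctuating with the seed, and with all noise
channels off every module recovers planted truth *exactly* — the
strongest possible oracle. Second, the truth manifest is sufficient to
recompute every planted summary by counting (`manifest_census()`), so
tests never compare implementation against implementation.

**Replication design for the dropout analysis.** With two replicates, a
filter requiring support in two experiments turns a 10% per-replicate
miss rate into a ~19% loss of stage presences (1 − 0.9²), so six-digit
codes cannot be recovered at high rates — a property of the filter, not
of the encoder. The dropout robustness analysis therefore runs at four
replicates, the smallest replicate count at which two misses of the same
peak are rare (P ≈ 0.4%), where ≥ 99% of codes are recovered; the
zero-noise baseline stays at two replicates.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: mappability and GC structure, read-level
noise and fragment-length effects, peak-width and signal-strength
heterogeneity, correlated replicate artifacts, overlapping or nested
genes, non-uniform TSS density, enhancer–promoter looping, and any
biological coupling between promoter state and expression beyond the
planted plans. Results on real data will degrade in proportion to how
far these assumptions are violated; the tests certify algorithmic
correctness and statistical calibration, not biological performance.

# Problem sizes and numerical tolerances used in validation

The validation suite runs at sizes chosen to make every statistic stable
yet quick to recompute: the default fixture (2 × 5 Mb, 200 genes,
~2,200 union DHS, 6 stages × 2 replicates); HMM recovery at 10,000 bins;
overlap-test calibration with 500 null simulations × 9,999 resamples
(the binomial 95% band at α = 0.05 is then decisive); planted-enrichment
detection at 100,000 resamples (resolving the strict 1e-4 threshold);
motif RE with 1,000 bootstrap replicates; clustering recovery across 10
seeds. Exactness assertions use tolerance 1e-9 (z-profiles, transition
row sums), the forward/backward likelihood cross-check uses 1e-8
relative, and EM monotonicity allows −1e-8 numerical slack per step.

# Known limitations

* The HMM is fitted in plain R; it is comfortable at 10⁴–10⁵ bins and
  small K but not tuned for whole-genome segmentation at large K.
* The length-weighted overlap null resamples genes, not positions; it
  corrects for domain size but not for chromosome-scale covariates
  (GC, gene density).
* `filter_reproducible()` returns intersection-like regions; with very
  large jitter the retained region can be much narrower than the
  underlying peak.
* The RE statistic conditions on the supplied region sets; it does not
  model motif clustering within a region (a region with five sites
  counts once).
* The reprogramming ranking is a transparent two-key sort, not a causal
  model; it is only as good as the activation floor and the binding
  windows feeding it.
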