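# Expression dynamics: differential calling across stage transitions,
# z-standardization of log profiles, k-means pattern discovery, and
# stage-correlation scoring of external profiles.

#' Read / write a genes x stages expression matrix
#'
#' TSV format: a \code{gene_id} column followed by one column per stage,
#' with stage names in the header. Columns are reordered into the
#' canonical ESC..MAC order on read.
#'
#' @param path File path.
#' @return \code{read_expression} returns a numeric matrix (genes x 6,
#'   FPKM-like non-negative values) with gene row names.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(hemo_stages() %in% colnames(df))) {
    stop("expression table must have columns ",
         paste(hemo_stages(), collapse = ", "))
  }
  m <- as.matrix(df[, hemo_stages()])
  rownames(m) <- df$gene_id
  if (any(m < 0)) stop("expression values must be non-negative")
  m
}

#' @rdname read_expression
#' @param m Expression matrix (genes x stages).
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call differentially expressed genes per stage transition
#'
#' A transparent fold-change rule: gene \eqn{g} is up at transition
#' \eqn{T_k} (stage \eqn{k} to \eqn{k+1}) when its expression at the later
#' stage reaches \code{floor} and exceeds \code{min_fc} times its
#' (floored) expression at the earlier stage; down-regulation is the
#' symmetric rule. A gene is \emph{dynamic} when it appears in any
#' transition set. Flooring the denominator keeps ratios finite for genes
#' switching on from zero, and makes the call invariant to rescaling the
#' whole matrix together with \code{floor}.
#'
#' @param m Expression matrix (genes x 6 stages, FPKM-like).
#' @param min_fc Minimum fold change (> 1), default 2.
#' @param floor Expression floor in the same units as \code{m}, default 1.
#' @return List with \code{up} and \code{down} (lists of gene-id vectors
#'   per transition T1..T5) and \code{dynamic} (all genes in any set).
#' @export
call_differential_genes <- function(m, min_fc = 2, floor = 1) {
  if (ncol(m) < 2L) stop("need at least two stages")
  if (min_fc <= 1) stop("min_fc must be > 1")
  if (floor < 0) stop("floor must be >= 0")
  genes <- rownames(m)
  up <- down <- stats::setNames(vector("list", ncol(m) - 1L),
                                paste0("T", seq_len(ncol(m) - 1L)))
  for (k in seq_len(ncol(m) - 1L)) {
    a <- m[, k]
    b <- m[, k + 1L]
    up[[k]] <- genes[b >= floor & b / pmax(a, floor) >= min_fc]
    down[[k]] <- genes[a >= floor & a / pmax(b, floor) >= min_fc]
  }
  dynamic <- unique(c(unlist(up, use.names = FALSE),
                      unlist(down, use.names = FALSE)))
  list(up = up, down = down, dynamic = dynamic)
}

#' Standardize expression profiles to z-scores over stages
#'
#' Computes per-gene standardized profiles
#' \eqn{z_{ij} = (\log_{10}(x_{ij} + c) - \mu_i) / \sigma_i} over the six
#' stages; the clustering of these shapes is what defines the expression
#' patterns. Genes whose log profile is constant (zero standard
#' deviation) cannot be standardized and are excluded, with their ids
#' recorded in the \code{"excluded"} attribute.
#'
#' @param m Expression matrix (genes x stages).
#' @param genes Optional subset of gene ids to standardize (typically the
#'   dynamic genes from [call_differential_genes()]); default all.
#' @param pseudocount Added before taking logs, default 0.01.
#' @return Matrix of z-profiles (genes x stages), each row with mean 0
#'   and sd 1; excluded gene ids in \code{attr(, "excluded")}.
#' @export
standardize_profiles <- function(m, genes = NULL, pseudocount = 0.01) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) stop("genes not in matrix: ", missing[1L], " ...")
    m <- m[genes, , drop = FALSE]
  }
  lx <- log10(m + pseudocount)
  mu <- rowMeans(lx)
  sd <- apply(lx, 1L, stats::sd)
  keep <- sd > 0
  z <- (lx[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  attr(z, "excluded") <- rownames(m)[!keep]
  z
}

# Greedy farthest-point seeding: pick a random first center, then
# repeatedly the profile farthest from all chosen centers.
farthest_point_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2L:k) {
      centers[j] <- which.max(d)
      d <- pmin(d, rowSums((x - matrix(x[centers[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' Cluster standardized expression profiles into patterns
#'
#' k-means over z-profiles with multiple restarts; each restart is seeded
#' by greedy farthest-point selection (deterministic given \code{seed}),
#' run with Lloyd iterations, and the solution with the lowest total
#' within-cluster sum of squares is kept. With well-separated planted
#' patterns this recovers the partition exactly; \code{k} is a free
#' parameter of the analysis (the staged differentiation study that
#' motivates this package used k = 31).
#'
#' @param z Matrix of standardized profiles from [standardize_profiles()].
#' @param k Number of patterns (1 <= k <= rows of z).
#' @param restarts Number of seeded restarts, default 20.
#' @param seed Integer seed; all restarts derive from it.
#' @return List with \code{labels} (named integer vector), \code{centers}
#'   (k x stages), \code{inertia} (best total within-cluster SS) and
#'   \code{restart} (index of the winning restart).
#' @export
cluster_patterns <- function(z, k, restarts = 20L, seed = 1L) {
  z <- as.matrix(z)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(z)) stop("k exceeds the number of profiles")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_local_seed(substream_seed(seed, paste0("kmeans-", r)), {
      centers <- farthest_point_centers(z, k)
      tryCatch(
        suppressWarnings(stats::kmeans(z, centers = centers,
                                       iter.max = 100L, algorithm = "Lloyd")),
        error = function(e) NULL)
    })
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
      best <- fit
      best$restart <- r
    }
  }
  if (is.null(best)) stop("k-means failed in every restart")
  list(labels = stats::setNames(best$cluster, rownames(z)),
       centers = best$centers, inertia = best$tot.withinss,
       restart = best$restart)
}

#' Correlate an expression profile with each developmental stage
#'
#' Pearson correlation (on \eqn{\log_{10}} scale) between an external
#' per-gene expression profile (e.g. from a reprogramming experiment) and
#' each stage column of a reference matrix, over the shared gene
#' universe. Differences between per-stage correlations are tested with
#' the two-sample Fisher z-transform test
#' \eqn{(\mathrm{atanh}(r_a) - \mathrm{atanh}(r_b)) /
#' \sqrt{2/(n-3)}}, two-sided; a correlation compared with itself gives
#' p = 1.
#'
#' @param profile Named numeric vector of expression values per gene
#'   (same units as \code{m}).
#' @param m Reference expression matrix (genes x stages).
#' @param pseudocount Added before logs, default 0.01.
#' @return List with \code{r} (named per-stage correlations), \code{n}
#'   (shared gene count) and \code{p} (stages x stages matrix of Fisher-z
#'   p-values).
#' @export
stage_correlation <- function(profile, m, pseudocount = 0.01) {
  shared <- intersect(names(profile), rownames(m))
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  lp <- log10(profile[shared] + pseudocount)
  lm <- log10(m[shared, , drop = FALSE] + pseudocount)
  r <- apply(lm, 2L, function(col) stats::cor(lp, col))
  n <- length(shared)
  z <- atanh(pmin(pmax(r, -1), 1))
  se <- sqrt(2 / (n - 3))
  S <- length(r)
  p <- matrix(1, S, S, dimnames = list(names(r), names(r)))
  for (a in seq_len(S)) {
    for (b in seq_len(S)) {
      if (a == b || identical(r[a], r[b])) next
      stat <- (z[a] - z[b]) / se
      p[a, b] <- 2 * stats::pnorm(-abs(stat))
    }
  }
  list(r = r, n = n, p = p)
}
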