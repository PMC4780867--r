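# Stage-resolved core gene regulatory networks: TF -> TF-locus binding
# graphs annotated with expression and promoter chromatin state, their
# rewiring across transitions, and reprogramming-candidate ranking.

#' Construct a stage GRN object
#'
#' Low-level constructor and validator for a one-stage TF network.
#' Nodes are the configured TF panel with expression and promoter
#' chromatin annotations; directed edges record binding of a source TF
#' at the locus of a target TF. Edges are only allowed from sources with
#' ChIP data (a node without ChIP data simply has no out-edges, not
#' zero-confidence ones), and self-edges represent autoregulation.
#'
#' @param stage Stage name.
#' @param nodes data.frame with columns \code{name}, \code{expression},
#'   \code{dhs_promoter} (logical), \code{promoter_state} (single letter
#'   A/R/P/U/N), \code{has_chip_data} (logical).
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{n_peaks}.
#' @return Object of class \code{stage_grn}.
#' @export
stage_grn <- function(stage, nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("name", "expression", "dhs_promoter", "promoter_state",
              "has_chip_data")
  if (!all(need_n %in% names(nodes))) {
    stop("nodes must have columns ", paste(need_n, collapse = ", "))
  }
  need_e <- c("source", "target", "n_peaks")
  if (!all(need_e %in% names(edges))) {
    stop("edges must have columns ", paste(need_e, collapse = ", "))
  }
  if (!all(edges$source %in% nodes$name) ||
      !all(edges$target %in% nodes$name)) {
    stop("edge endpoints must be panel nodes")
  }
  bad <- setdiff(edges$source, nodes$name[nodes$has_chip_data])
  if (length(bad)) {
    stop("edge source(s) without ChIP data: ", paste(bad, collapse = ", "))
  }
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(stage = stage, nodes = nodes, edges = edges),
            class = "stage_grn")
}

#' @export
print.stage_grn <- function(x, ...) {
  cat("stage_grn:", x$stage, "|", nrow(x$nodes), "TF nodes,",
      nrow(x$edges), "binding edges (",
      sum(x$edges$source == x$edges$target), "autoregulatory )\n")
  invisible(x)
}

edge_keys <- function(grn) {
  if (nrow(grn$edges) == 0L) return(character(0))
  paste(grn$edges$source, grn$edges$target, sep = "->")
}

#' Build the TF network for one stage from binding data
#'
#' An edge source -> target is drawn when the source TF has at least one
#' (reproducible) peak whose midpoint lies within the target gene's
#' locus window: the gene span extended by \code{flank} bp on both
#' sides, clipped at the target's regulatory-domain boundaries so that a
#' peak supports at most one target. Node annotations: expression level
#' at the stage, promoter DHS presence (any union DHS open at this stage
#' overlapping TSS +/- 1 kb), and the promoter coarse state letter from
#' the gene's timeline. TFs without ChIP data at this stage get
#' \code{has_chip_data = FALSE} and no out-edges. The flank default
#' (50 kb) is the single most consequential free parameter of the
#' network and is deliberately exposed.
#'
#' @param stage Stage name.
#' @param tf_peaks Named list of \code{GRanges}, one per TF \emph{with
#'   ChIP data at this stage} (reproducibility-filtered).
#' @param panel Character vector: all TFs of the configured panel. Every
#'   panel TF must be present in \code{genes} as a gene model.
#' @param genes Gene models from [gene_models()] (must include the panel
#'   TF genes by \code{gene_id}).
#' @param promoter_states Named vector of six-letter promoter timelines
#'   (from [promoter_state_timeline()]).
#' @param dhs_table Classified pattern table, for promoter DHS presence.
#' @param expression Expression matrix (genes x stages).
#' @param chrom_sizes Named chromosome lengths.
#' @param flank Locus window flank in bp, default 50000.
#' @return A [stage_grn()].
#' @export
build_stage_grn <- function(stage, tf_peaks, panel, genes, promoter_states,
                            dhs_table, expression, chrom_sizes,
                            flank = 50000L) {
  stage_i <- stage_index(stage)
  gid <- S4Vectors::mcols(genes)$gene_id
  missing <- setdiff(panel, gid)
  if (length(missing)) {
    stop("panel TF(s) missing from gene models: ",
         paste(missing, collapse = ", "))
  }
  if (!all(names(tf_peaks) %in% panel)) {
    stop("tf_peaks contains non-panel TFs")
  }
  domains <- build_regulatory_domains(genes, chrom_sizes)
  dom_gid <- S4Vectors::mcols(domains)$gene_id
  # locus windows: span +/- flank, clipped at domain bounds
  windows <- lapply(panel, function(tf) {
    g <- genes[gid == tf]
    d <- domains[dom_gid == tf]
    lo <- max(BiocGenerics::start(g) - flank, BiocGenerics::start(d))
    hi <- min(BiocGenerics::end(g) + flank, BiocGenerics::end(d))
    GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                           IRanges::IRanges(lo, hi))
  })
  names(windows) <- panel

  open_here <- dhs_table[substr(S4Vectors::mcols(dhs_table)$code,
                                stage_i, stage_i) == "1"]
  nodes <- do.call(rbind, lapply(panel, function(tf) {
    g <- genes[gid == tf]
    tss <- S4Vectors::mcols(g)$tss
    prom <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                   IRanges::IRanges(max(tss - 1000L, 1L),
                                                    tss + 1000L))
    tl <- promoter_states[[tf]] %||% paste(rep("N", 6L), collapse = "")
    data.frame(
      name = tf,
      expression = if (tf %in% rownames(expression))
        unname(expression[tf, stage_i]) else NA_real_,
      dhs_promoter = length(open_here) > 0L &&
        any(suppressWarnings(IRanges::overlapsAny(prom, open_here,
                                                  ignore.strand = TRUE))),
      promoter_state = substr(tl, stage_i, stage_i),
      has_chip_data = tf %in% names(tf_peaks))
  }))
  edges <- list()
  for (src in names(tf_peaks)) {
    pk <- tf_peaks[[src]]
    if (length(pk) == 0L) next
    mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(pk),
                                   IRanges::IRanges(interval_midpoint(pk),
                                                    width = 1L))
    for (tgt in panel) {
      n <- sum(suppressWarnings(IRanges::overlapsAny(mids, windows[[tgt]],
                                                     ignore.strand = TRUE)))
      if (n > 0L) {
        edges[[length(edges) + 1L]] <- data.frame(
          source = src, target = tgt, n_peaks = n)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(source = character(0), target = character(0),
               n_peaks = integer(0))
  }
  stage_grn(stage, nodes, edges)
}

#' Edge rewiring of the network across the five transitions
#'
#' @param grns List of six [stage_grn()]s in stage order (same TF
#'   panel).
#' @return List with \code{transitions} (per transition: \code{gained},
#'   \code{lost}, \code{retained} edge-key vectors \code{"src->tgt"})
#'   and \code{degree} (data.frame of per-stage in/out degrees per TF).
#' @export
grn_dynamics <- function(grns) {
  stages <- hemo_stages()
  if (length(grns) != 6L) stop("need six stage graphs")
  panel <- grns[[1L]]$nodes$name
  for (g in grns) {
    if (!identical(sort(g$nodes$name), sort(panel))) {
      stop("stage graphs have mismatched TF panels")
    }
  }
  keys <- lapply(grns, edge_keys)
  transitions <- lapply(1:5, function(k) {
    list(gained = setdiff(keys[[k + 1L]], keys[[k]]),
         lost = setdiff(keys[[k]], keys[[k + 1L]]),
         retained = intersect(keys[[k]], keys[[k + 1L]]))
  })
  names(transitions) <- hemo_transitions()
  degree <- do.call(rbind, lapply(seq_along(grns), function(s) {
    e <- grns[[s]]$edges
    data.frame(stage = stages[s], tf = panel,
               out_degree = as.integer(table(factor(e$source, panel))),
               in_degree = as.integer(table(factor(e$target, panel))))
  }))
  list(transitions = transitions, degree = degree)
}

#' Rank TFs as reprogramming candidates
#'
#' Orders the panel TFs by the two criteria that predicted successful
#' reprogramming factors in staged blood specification: (1) earlier
#' activation (first stage whose expression reaches \code{floor}), and
#' (2) among ties, a larger number of target loci from
#' \code{target_gene_set} bound at or before the hemogenic-endothelium
#' stage; remaining ties break lexicographically by TF name. TFs never
#' reaching the floor are excluded (with a message when the ranking
#' comes out empty).
#'
#' @param grns List of six [stage_grn()]s in stage order.
#' @param expression Expression matrix (genes x stages).
#' @param target_gene_set Character vector of target loci (subset of the
#'   panel).
#' @param floor Activation expression floor (FPKM), default 1.
#' @return data.frame ranked best-first: \code{tf},
#'   \code{activation_stage}, \code{n_targets_bound}.
#' @export
rank_reprogramming_candidates <- function(grns, expression, target_gene_set,
                                          floor = 1) {
  if (length(target_gene_set) == 0L) stop("target_gene_set is empty")
  stages <- hemo_stages()
  panel <- grns[[1L]]$nodes$name
  he <- stage_index("HE")
  rows <- lapply(panel, function(tf) {
    if (!tf %in% rownames(expression)) return(NULL)
    act <- which(expression[tf, ] >= floor)
    if (length(act) == 0L) return(NULL)
    bound <- unique(unlist(lapply(grns[seq_len(he)], function(g) {
      g$edges$target[g$edges$source == tf]
    })))
    data.frame(tf = tf, activation_stage = stages[min(act)],
               n_targets_bound = length(intersect(bound, target_gene_set)))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    message("no TF is ever expressed above the floor; empty ranking")
    return(data.frame(tf = character(0), activation_stage = character(0),
                      n_targets_bound = integer(0)))
  }
  o <- order(stage_index(rows$activation_stage), -rows$n_targets_bound,
             rows$tf)
  rows <- rows[o, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

grn_to_igraph <- function(grn) {
  nodes <- grn$nodes
  g <- igraph::graph_from_data_frame(
    grn$edges[, c("source", "target", "n_peaks"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(
      name = nodes$name,
      expression = as.numeric(nodes$expression),
      dhs_promoter = as.integer(nodes$dhs_promoter),
      promoter_state = as.character(nodes$promoter_state),
      has_chip_data = as.integer(nodes$has_chip_data)))
  igraph::graph_attr(g, "stage") <- grn$stage
  g
}

igraph_to_grn <- function(g) {
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(
    name = v$name,
    expression = as.numeric(v$expression),
    dhs_promoter = as.logical(as.integer(v$dhs_promoter)),
    promoter_state = as.character(v$promoter_state),
    has_chip_data = as.logical(as.integer(v$has_chip_data)))
  edges <- if (nrow(e)) {
    data.frame(source = e$from, target = e$to,
               n_peaks = as.integer(e$n_peaks))
  } else {
    data.frame(source = character(0), target = character(0),
               n_peaks = integer(0))
  }
  stage_grn(igraph::graph_attr(g, "stage"), nodes, edges)
}

#' Write / read a stage GRN as GraphML
#'
#' Round-trip safe: reading a written file reconstructs an identical
#' [stage_grn()] (nodes, edges and all annotations). Empty graphs are
#' valid.
#'
#' @param grn A [stage_grn()].
#' @param path File path.
#' @return \code{write_graphml} returns \code{path} invisibly;
#'   \code{read_graphml} returns a \code{stage_grn}.
#' @export
write_graphml <- function(grn, path) {
  igraph::write_graph(grn_to_igraph(grn), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph_to_grn(igraph::read_graph(path, format = "graphml"))
}

#' Export a stage GRN in DOT format
#'
#' @param grn A [stage_grn()].
#' @param path File path.
#' @return Invisibly, \code{path}.
#' @export
write_dot <- function(grn, path) {
  igraph::write_graph(grn_to_igraph(grn), path, format = "dot")
  invisible(path)
}
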