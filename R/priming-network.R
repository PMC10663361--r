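#' Build the priming gene-regulatory network for one transition
#'
#' Nodes are TF-family labels and primed target genes; a directed edge
#' family -> gene exists iff some motif of that family hits some primed
#' element linked to the gene AND at least one member gene of the family
#' is expressed (mean CPM >= `expr_threshold`) at the expression stage.
#' By default expression is evaluated at S1 — the network of factors that
#' are already present while their targets are still silent; rebuilding
#' with `expr_stage = s2` gives the post-activation network for
#' [network_delta()].
#'
#' @param primed primed records for the transition
#'   ([classify_primed()]).
#' @param motif_matrix binary element x motif matrix
#'   ([annotate_elements()]); rows must cover every primed element.
#' @param tf_catalog data.frame mapping motifs to families and member
#'   genes: columns `motif_id`, `tf_family`, `members` (comma-separated
#'   gene ids).
#' @param cpm_table CPM matrix.
#' @param s1,s2 transition stages (node expression attributes carry
#'   both).
#' @param expr_stage stage at which the family-expressed gate is
#'   evaluated (default `s1`).
#' @param expr_threshold CPM cutoff for an "expressed" TF (default 9,
#'   harmonized with the gene gate).
#' @return a `priming_network`: list with `edges` (`tf_family`,
#'   `gene_id`, `carried_by`, `transition`), `nodes` (`node`, `kind`,
#'   `expr_s1`, `expr_s2`, `primed`) and `transition`.
#' @export
build_network <- function(primed, motif_matrix, tf_catalog, cpm_table,
                          s1, s2, expr_stage = s1, expr_threshold = 9) {
  if (nrow(primed)) {
    miss <- setdiff(primed$element_id, rownames(motif_matrix))
    if (length(miss))
      stop("motif annotation missing for primed element(s): ",
           paste(miss, collapse = ", "))
    bad <- setdiff(colnames(motif_matrix), tf_catalog$motif_id)
    if (length(bad))
      stop("motif(s) absent from the TF catalog: ",
           paste(bad, collapse = ", "))
  }
  stage_cpm <- .stage_mean_cpm(cpm_table)
  members_of <- function(fam) {
    m <- tf_catalog$members[tf_catalog$tf_family == fam]
    unique(unlist(strsplit(m, ",", fixed = TRUE)))
  }
  fam_expressed <- vapply(unique(tf_catalog$tf_family), function(fam) {
    mem <- intersect(members_of(fam), rownames(stage_cpm))
    length(mem) > 0 && any(stage_cpm[mem, expr_stage] >= expr_threshold)
  }, logical(1))

  edges <- list()
  if (nrow(primed)) {
    fam_by_motif <- stats::setNames(tf_catalog$tf_family, tf_catalog$motif_id)
    for (i in seq_len(nrow(primed))) {
      el <- primed$element_id[i]
      hit_motifs <- colnames(motif_matrix)[motif_matrix[el, ] == 1L]
      fams <- unique(fam_by_motif[hit_motifs])
      fams <- fams[fam_expressed[fams]]
      for (f in fams)
        edges[[length(edges) + 1L]] <- data.frame(
          tf_family = f, gene_id = primed$gene_id[i], carried = el,
          stringsAsFactors = FALSE)
    }
  }
  transition <- paste0(s1, ">", s2)
  if (length(edges)) {
    ed <- do.call(rbind, edges)
    agg <- stats::aggregate(carried ~ tf_family + gene_id, data = ed,
                            FUN = function(x) paste(sort(unique(x)),
                                                    collapse = ","))
    edges <- data.frame(tf_family = agg$tf_family, gene_id = agg$gene_id,
                        carried_by = agg$carried, transition = transition,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$tf_family, edges$gene_id), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(tf_family = character(0), gene_id = character(0),
                        carried_by = character(0), transition = character(0),
                        stringsAsFactors = FALSE)
  }

  fam_nodes <- sort(unique(edges$tf_family))
  gene_nodes <- sort(unique(edges$gene_id))
  fam_expr <- function(fam, stage) {
    mem <- intersect(members_of(fam), rownames(stage_cpm))
    if (!length(mem)) return(NA_real_)
    max(stage_cpm[mem, stage])
  }
  gene_expr <- function(g, stage) {
    if (!g %in% rownames(stage_cpm)) return(NA_real_)
    stage_cpm[g, stage]
  }
  nodes <- rbind(
    if (length(fam_nodes)) data.frame(
      node = fam_nodes, kind = "tf_family",
      expr_s1 = vapply(fam_nodes, fam_expr, numeric(1), stage = s1),
      expr_s2 = vapply(fam_nodes, fam_expr, numeric(1), stage = s2),
      primed = FALSE, stringsAsFactors = FALSE),
    if (length(gene_nodes)) data.frame(
      node = gene_nodes, kind = "gene",
      expr_s1 = vapply(gene_nodes, gene_expr, numeric(1), stage = s1),
      expr_s2 = vapply(gene_nodes, gene_expr, numeric(1), stage = s2),
      primed = TRUE, stringsAsFactors = FALSE))
  if (is.null(nodes))
    nodes <- data.frame(node = character(0), kind = character(0),
                        expr_s1 = numeric(0), expr_s2 = numeric(0),
                        primed = logical(0), stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes, transition = transition,
                 elements = sort(unique(primed$element_id))),
            class = "priming_network")
}

#' @export
print.priming_network <- function(x, ...) {
  cat("priming network (", x$transition, "): ",
      nrow(x$edges), " edges, ", nrow(x$nodes), " nodes\n", sep = "")
  invisible(x)
}

#' Number of distinct primed target genes encoding TFs
#'
#' @param primed primed records for one transition.
#' @param genes `gene_annotation` table with `is_tf` flags.
#' @return integer count.
#' @export
count_primed_tf_genes <- function(primed, genes) {
  tf_genes <- genes$gene_id[genes$is_tf]
  length(unique(intersect(primed$gene_id, tf_genes)))
}

#' Edge gains and losses between the primed and post-activation networks
#'
#' Compares the network built with S1 expression against the rebuild of
#' the same primed elements with S2 expression: which family -> gene
#' links exist only before activation, only after, or at both stages.
#'
#' @param net_s1,net_s2 `priming_network` objects over the same
#'   transition's elements.
#' @return list with data.frames `only_s1`, `only_s2`, `shared`
#'   (columns `tf_family`, `gene_id`).
#' @export
network_delta <- function(net_s1, net_s2) {
  if (!identical(net_s1$elements, net_s2$elements))
    stop("networks cover different element universes")
  key <- function(n) paste(n$edges$tf_family, n$edges$gene_id, sep = "\r")
  k1 <- key(net_s1); k2 <- key(net_s2)
  pick <- function(n, keep) {
    out <- n$edges[keep, c("tf_family", "gene_id"), drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(only_s1 = pick(net_s1, !k1 %in% k2),
       only_s2 = pick(net_s2, !k2 %in% k1),
       shared = pick(net_s1, k1 %in% k2))
}
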