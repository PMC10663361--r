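#' Partition elements into intergenic and intragenic
#'
#' Intragenic means overlapping at least one gene body; everything else
#' (including elements on chromosomes without genes) is intergenic.
#'
#' @param elements interval table with `element_id`.
#' @param genes `gene_annotation` table (gene bodies).
#' @return data.frame `element_id`, `location` in
#'   `{"intergenic", "intragenic"}`.
#' @export
classify_intergenic <- function(elements, genes) {
  bodies <- data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, stringsAsFactors = FALSE)
  intra <- .overlaps_any(elements, bodies)
  data.frame(element_id = elements$element_id,
             location = ifelse(intra, "intragenic", "intergenic"),
             stringsAsFactors = FALSE)
}

#' Per-stage median eRNA Z-score at intergenic primed elements
#'
#' Element-level RNA fragment counts per stage are CPM-normalized
#' against each stage's library size, log2(+0.5) transformed, and
#' standardized per element across stages (constant elements contribute
#' zeros); the per-stage median across the element set tracks when eRNA
#' transcription appears.
#'
#' @param counts numeric matrix, elements x stages, of RNA fragment
#'   counts over the elements.
#' @param stage_order column order to use; all must be present.
#' @param library_sizes per-stage RNA library sizes used for CPM; default
#'   the column sums of `counts`.
#' @param element_ids optional subset of rownames (e.g. the intergenic
#'   primed elements).
#' @return named numeric vector of per-stage medians.
#' @export
erna_zscores <- function(counts, stage_order = colnames(counts),
                         library_sizes = NULL, element_ids = NULL) {
  miss <- setdiff(stage_order, colnames(counts))
  if (length(miss)) stop("missing stage(s): ", paste(miss, collapse = ", "))
  m <- counts[, stage_order, drop = FALSE]
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  if (any(library_sizes <= 0)) stop("non-positive library size")
  m <- sweep(m, 2, library_sizes, "/") * 1e6
  if (!is.null(element_ids)) {
    miss <- setdiff(element_ids, rownames(m))
    if (length(miss)) stop("missing element(s): ",
                           paste(miss, collapse = ", "))
    m <- m[element_ids, , drop = FALSE]
  }
  z <- .zscore_rows(log2(m + 0.5))
  apply(z, 2, stats::median)
}

#' Classify VEGF-responsive primed elements
#'
#' An element is VEGF-responsive (in the direction that primes the
#' hematopoietic fate) iff at the queried stage it overlaps a peak in
#' the minus-VEGF condition set and no peak in the all-cytokines set:
#' withdrawal of VEGF opens the element.  Elements open only with VEGF
#' are reported separately as `opposite`.
#'
#' @param elements primed element interval table (with `element_id`).
#' @param minus_vegf peak set called without VEGF at the stage.
#' @param all_cytokines peak set called with the full cytokine mix
#'   (including VEGF) at the stage.
#' @return data.frame `element_id`, `in_minus_vegf`, `in_all_cytokines`,
#'   `responsive`, `opposite`.
#' @export
classify_vegf_responsive <- function(elements, minus_vegf, all_cytokines) {
  if (is.null(minus_vegf) || is.null(all_cytokines))
    stop("both condition peak sets are required")
  in_mv <- .overlaps_any(elements, minus_vegf)
  in_ac <- .overlaps_any(elements, all_cytokines)
  data.frame(element_id = elements$element_id,
             in_minus_vegf = in_mv, in_all_cytokines = in_ac,
             responsive = in_mv & !in_ac,
             opposite = in_ac & !in_mv,
             stringsAsFactors = FALSE)
}

#' Expression report for genes linked to VEGF-responsive elements
#'
#' Per linked gene: fold change of mean expression (minus-VEGF over
#' plus-VEGF) and a Bonferroni-corrected p-value, either taken from a
#' supplied external test or computed with a Welch t-test over the
#' per-condition replicate values.
#'
#' @param gene_ids genes linked to responsive elements.
#' @param expr_minus,expr_plus numeric matrices (genes x replicates) of
#'   expression in the two conditions.
#' @param m Bonferroni family size (default: number of genes tested).
#' @param external_p optional named vector of raw p-values replacing the
#'   internal test.
#' @return data.frame `gene_id`, `mean_minus`, `mean_plus`,
#'   `fold_change`, `pvalue`, `p_bonferroni`; genes absent from the
#'   expression matrices are skipped with a message.
#' @export
vegf_gene_report <- function(gene_ids, expr_minus, expr_plus,
                             m = NULL, external_p = NULL) {
  gene_ids <- unique(gene_ids)
  present <- gene_ids %in% rownames(expr_minus) &
    gene_ids %in% rownames(expr_plus)
  if (any(!present))
    message("skipping gene(s) missing from expression: ",
            paste(gene_ids[!present], collapse = ", "))
  gene_ids <- gene_ids[present]
  if (is.null(m)) m <- max(length(gene_ids), 1L)
  rows <- lapply(gene_ids, function(g) {
    x <- as.numeric(expr_minus[g, ])
    y <- as.numeric(expr_plus[g, ])
    fc <- if (mean(y) == 0) {
      if (mean(x) == 0) 1 else Inf
    } else mean(x) / mean(y)
    p <- if (!is.null(external_p)) {
      unname(external_p[g])
    } else if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(x, y)$p.value
    }
    data.frame(gene_id = g, mean_minus = mean(x), mean_plus = mean(y),
               fold_change = fc, pvalue = p, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), mean_minus = numeric(0),
               mean_plus = numeric(0), fold_change = numeric(0),
               pvalue = numeric(0))
  out$p_bonferroni <- if (nrow(out)) bonferroni_adjust(out$pvalue, m) else numeric(0)
  rownames(out) <- NULL
  out
}
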