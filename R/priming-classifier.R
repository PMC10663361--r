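#' Merge stage-specific peak sets into reference elements
#'
#' Peaks called independently per stage rarely have identical
#' coordinates, so "the same element occurring at two stages" needs a
#' reference: all stage peak sets are pooled and merged by single-linkage
#' at >= 1 bp overlap.  Each merged span is one reference element,
#' identified by its coordinates and sorted by (chrom, start) for
#' determinism.
#'
#' @param peak_sets named list (stage -> interval table) of per-stage
#'   ATAC peaks.
#' @return a `genomic_intervals` data.frame of elements with an
#'   `element_id` column (`el_<i>` in coordinate order).
#' @export
merge_elements <- function(peak_sets) {
  pooled <- do.call(rbind, lapply(peak_sets, function(p)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               stringsAsFactors = FALSE)))
  gr <- GenomicRanges::reduce(.as_granges(pooled), ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  out <- gi(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1L,
            GenomicRanges::end(gr))
  out$element_id <- paste0("el_", seq_len(nrow(out)))
  out
}

#' Lift per-peak screen calls onto reference elements
#'
#' For each reference element and stage, the stage's peaks overlapping
#' the element are aggregated: the element is positive if any overlapping
#' peak is positive; fragment counts and normalized rates are summed and
#' the High/Low state re-derived from the summed normalized rates (ties
#' to Low, as in [assign_activity_state()]).
#'
#' @param elements output of [merge_elements()].
#' @param stage_peaks named list (stage -> peak table) as given to the
#'   screen.
#' @param stage_calls named list (stage -> call data.frame from
#'   [assign_activity_state()]), rows parallel to `stage_peaks`.
#' @return data.frame: `element_id`, `stage`, `positive`, `n_high`,
#'   `n_low`, `norm_high`, `norm_low`, `state`.
#' @export
element_calls <- function(elements, stage_peaks, stage_calls) {
  stopifnot(identical(sort(names(stage_peaks)), sort(names(stage_calls))))
  res <- lapply(names(stage_peaks), function(s) {
    peaks <- stage_peaks[[s]]
    calls <- stage_calls[[s]]
    if (nrow(peaks) != nrow(calls))
      stop("stage ", s, ": peak table and call table differ in length")
    ov <- find_overlaps(elements, peaks)
    n <- nrow(elements)
    agg <- function(v, f) {
      out <- rep(0, n)
      if (nrow(ov)) {
        t <- tapply(v[ov$subject], ov$query, f)
        out[as.integer(names(t))] <- as.numeric(t)
      }
      out
    }
    positive <- agg(calls$positive, any) > 0
    n_high <- agg(calls$n_high, sum)
    n_low <- agg(calls$n_low, sum)
    norm_high <- agg(calls$norm_high, sum)
    norm_low <- agg(calls$norm_low, sum)
    state <- ifelse(!positive, "NotPositive",
                    ifelse(norm_high > norm_low, "High", "Low"))
    data.frame(element_id = elements$element_id, stage = s,
               positive = positive, n_high = n_high, n_low = n_low,
               norm_high = norm_high, norm_low = norm_low, state = state,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Link a distal element to its target gene
#'
#' Promoter-capture Hi-C first: if any interaction other-end overlaps the
#' element, the bait gene of the highest-scoring such interaction is the
#' target (score ties broken by lexicographically smallest gene id);
#' otherwise the nearest gene by TSS distance.
#'
#' @param peak single-row interval table (element).
#' @param interactions link table from [read_links()] (may be empty).
#' @param genes `gene_annotation` table.
#' @return list with `gene_id` and `link_method` (`"chic"` or
#'   `"nearest"`).
#' @export
link_peak_to_gene <- function(peak, interactions, genes) {
  if (nrow(interactions)) {
    hit <- .overlaps_any(interactions, peak)
    if (any(hit)) {
      cand <- interactions[hit, , drop = FALSE]
      sc <- ifelse(is.na(cand$score), -Inf, cand$score)
      best <- cand$bait_gene[sc == max(sc)]
      return(list(gene_id = min(best), link_method = "chic"))
    }
  }
  list(gene_id = nearest_gene(peak, genes), link_method = "nearest")
}

# internal: vectorized linking over an element table; NA gene for
# unassignable elements (dropped by callers with a warning)
.link_elements <- function(elements, interactions, genes) {
  n <- nrow(elements)
  gene <- character(n)
  method <- character(n)
  chic_hit <- if (nrow(interactions))
    find_overlaps(elements, interactions)
  else data.frame(query = integer(0), subject = integer(0))
  nt <- .nearest_tss_table(elements, genes)
  for (i in seq_len(n)) {
    sub <- chic_hit$subject[chic_hit$query == i]
    if (length(sub)) {
      cand <- interactions[sub, , drop = FALSE]
      sc <- ifelse(is.na(cand$score), -Inf, cand$score)
      gene[i] <- min(cand$bait_gene[sc == max(sc)])
      method[i] <- "chic"
    } else {
      gene[i] <- nt$gene_id[i]
      method[i] <- "nearest"
    }
  }
  data.frame(element_id = elements$element_id, gene_id = gene,
             link_method = method, distance_tss = nt$distance,
             stringsAsFactors = FALSE)
}

#' Dynamics class of an element across a transition
#'
#' The 2x2 label from the High/Low activity states at the two stages,
#' e.g. `"Low>High"` for an element increasing in activity.
#'
#' @param state_s1,state_s2 activity states, each `"High"` or `"Low"`.
#' @return character vector of labels.
#' @export
dynamics_class <- function(state_s1, state_s2) {
  ok <- c("High", "Low")
  if (any(!state_s1 %in% ok) || any(!state_s2 %in% ok))
    stop("dynamics is defined only for High/Low states")
  paste0(state_s1, ">", state_s2)
}

#' Classify primed enhancer elements for one stage transition
#'
#' An element x gene pair is primed for the transition S1 -> S2 iff all
#' four gates hold:
#' \enumerate{
#'   \item distal: element nearest-TSS distance strictly greater than
#'     `distal_min_bp` (default 1500);
#'   \item enhancer-positive at S1 and at S2 (on merged reference
#'     elements);
#'   \item the linked gene is not expressed at S1 (mean CPM below
#'     `expr_threshold`, default 9);
#'   \item the gene is significantly up-regulated S1 -> S2:
#'     `log2fc >= lfc_min` (default 1, i.e. twofold) and
#'     `padj < padj_max` (default 0.05).
#' }
#'
#' @param s1,s2 stage labels of the transition (S2 immediately follows
#'   S1 in the stage order).
#' @param el_calls element-level calls from [element_calls()].
#' @param elements reference element table from [merge_elements()].
#' @param genes `gene_annotation` table.
#' @param interactions CHi-C link table (may be empty; all elements then
#'   fall back to nearest gene).
#' @param cpm_table CPM matrix from [cpm()].
#' @param de DE result table (external or [simple_de()]) containing rows
#'   for the pair (`stage1 == s1`, `stage2 == s2`).
#' @param distal_min_bp,expr_threshold,lfc_min,padj_max gate parameters.
#' @return data.frame of primed records: `element_id`, `stage1`,
#'   `stage2`, `gene_id`, `link_method`, `distance_tss`, `state_s1`,
#'   `state_s2`, `dynamics`.
#' @export
classify_primed <- function(s1, s2, el_calls, elements, genes, interactions,
                            cpm_table, de, distal_min_bp = 1500,
                            expr_threshold = 9, lfc_min = 1,
                            padj_max = 0.05) {
  de_pair <- de[de$stage1 == s1 & de$stage2 == s2, , drop = FALSE]
  if (!nrow(de_pair))
    stop("no DE results for transition ", s1, " -> ", s2)
  c1 <- el_calls[el_calls$stage == s1, , drop = FALSE]
  c2 <- el_calls[el_calls$stage == s2, , drop = FALSE]
  if (!nrow(c1) || !nrow(c2))
    stop("missing screen calls for stage ", if (!nrow(c1)) s1 else s2)
  rownames(c1) <- c1$element_id
  rownames(c2) <- c2$element_id

  links <- .link_elements(elements, interactions, genes)
  drop <- is.na(links$gene_id)
  if (any(drop)) {
    warning(sum(drop), " element(s) unassignable to a gene; dropped")
    links <- links[!drop, , drop = FALSE]
  }

  keep <- links$distance_tss > distal_min_bp
  links <- links[keep, , drop = FALSE]
  pos <- c1[links$element_id, "positive"] & c2[links$element_id, "positive"]
  links <- links[pos, , drop = FALSE]
  if (!nrow(links)) return(.empty_primed(s1, s2))

  in_expr <- links$gene_id %in% rownames(cpm_table)
  links <- links[in_expr, , drop = FALSE]
  if (!nrow(links)) return(.empty_primed(s1, s2))
  silent <- !is_expressed(links$gene_id, s1, cpm_table,
                          threshold = expr_threshold)
  links <- links[silent, , drop = FALSE]
  if (!nrow(links)) return(.empty_primed(s1, s2))

  de_idx <- match(links$gene_id, de_pair$gene_id)
  up <- !is.na(de_idx) &
    de_pair$log2fc[de_idx] >= lfc_min &
    de_pair$padj[de_idx] < padj_max
  links <- links[up, , drop = FALSE]
  if (!nrow(links)) return(.empty_primed(s1, s2))

  out <- data.frame(element_id = links$element_id, stage1 = s1, stage2 = s2,
                    gene_id = links$gene_id, link_method = links$link_method,
                    distance_tss = links$distance_tss,
                    state_s1 = c1[links$element_id, "state"],
                    state_s2 = c2[links$element_id, "state"],
                    stringsAsFactors = FALSE)
  out$dynamics <- dynamics_class(out$state_s1, out$state_s2)
  rownames(out) <- NULL
  out
}

.empty_primed <- function(s1, s2) {
  data.frame(element_id = character(0), stage1 = character(0),
             stage2 = character(0), gene_id = character(0),
             link_method = character(0), distance_tss = numeric(0),
             state_s1 = character(0), state_s2 = character(0),
             dynamics = character(0), stringsAsFactors = FALSE)
}

#' Persistence of primed-element activity at later stages
#'
#' For elements primed at S1, the percentage still enhancer-positive at
#' each later stage of the differentiation.
#'
#' @param primed primed records from [classify_primed()] (one
#'   transition).
#' @param el_calls element-level calls across all stages.
#' @param stage_order character vector of stages in developmental order.
#' @return named numeric vector (percent positive), one entry per stage
#'   after S1; empty for an empty primed set.
#' @export
persistence <- function(primed, el_calls, stage_order) {
  if (!nrow(primed)) return(stats::setNames(numeric(0), character(0)))
  s1 <- primed$stage1[1]
  later <- stage_order[seq_along(stage_order) > match(s1, stage_order)]
  els <- unique(primed$element_id)
  vapply(stats::setNames(later, later), function(s) {
    cs <- el_calls[el_calls$stage == s, , drop = FALSE]
    100 * sum(cs$positive[match(els, cs$element_id)], na.rm = TRUE) / length(els)
  }, numeric(1))
}

# internal: row-wise z-scores; constant rows map to all zeros
.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  z
}

#' Median expression Z-score of primed genes per stage
#'
#' Per gene, the stage profile of mean log2(CPM + 0.5) is standardized
#' across stages (mean 0, sd 1; genes constant across stages contribute
#' all-zero profiles); the per-stage median over the gene set summarizes
#' when the set switches on.
#'
#' @param gene_ids genes linked to primed elements of one transition.
#' @param cpm_table CPM matrix.
#' @param stage_order stages in developmental order.
#' @return named numeric vector of per-stage medians.
#' @export
median_expression_zscore <- function(gene_ids, cpm_table, stage_order) {
  if (length(stage_order) < 2) stop("need >= 2 stages")
  gene_ids <- unique(gene_ids)
  logc <- log2(cpm_table + 0.5)
  sm <- .stage_mean_cpm(logc)[gene_ids, stage_order, drop = FALSE]
  z <- .zscore_rows(sm)
  apply(z, 2, stats::median)
}

#' Primed-element count per linked gene
#'
#' @param primed primed records.
#' @return data.frame `gene_id`, `n_elements`, `multi` (TRUE when a gene
#'   has two or more primed elements), sorted by decreasing count.
#' @export
multiplicity_per_gene <- function(primed) {
  if (!nrow(primed))
    return(data.frame(gene_id = character(0), n_elements = integer(0),
                      multi = logical(0)))
  t <- table(primed$gene_id)
  out <- data.frame(gene_id = names(t), n_elements = as.integer(t),
                    stringsAsFactors = FALSE)
  out$multi <- out$n_elements >= 2
  out <- out[order(-out$n_elements, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
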