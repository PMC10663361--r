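#' Counts-per-million normalization
#'
#' `cpm = 1e6 * count / library size` (column sum).  Every column of the
#' result sums to exactly one million.
#'
#' @param counts numeric matrix, genes x samples, non-negative.
#' @return CPM matrix of the same shape (sample design attribute
#'   preserved).
#' @export
cpm <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stop("zero library size in sample(s): ",
                              paste(colnames(counts)[libsize <= 0], collapse = ", "))
  out <- sweep(counts, 2, libsize, "/") * 1e6
  attr(out, "samples") <- attr(counts, "samples")
  out
}

# internal: mean CPM per gene per stage (genes x stages matrix)
.stage_mean_cpm <- function(cpm_table, samples = attr(cpm_table, "samples")) {
  if (is.null(samples)) samples <- parse_sample_names(colnames(cpm_table))
  stages <- unique(samples$stage)
  out <- vapply(stages, function(s) {
    rowMeans(cpm_table[, samples$stage == s, drop = FALSE])
  }, numeric(nrow(cpm_table)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(cpm_table), stages))
  out
}

#' Is a gene expressed at a stage?
#'
#' Expressed means mean CPM across the stage's replicates at or above
#' `threshold` (default 9, the not-expressed cutoff used by the priming
#' gate: genes with CPM below 9 count as silent).
#'
#' @param gene_id gene identifier (vectorized).
#' @param stage stage label.
#' @param cpm_table CPM matrix from [cpm()], with `STAGE_repN` columns.
#' @param threshold CPM cutoff.
#' @param aggregate `"mean"` (default): compare the replicate mean to the
#'   threshold; `"all_below"`: expressed unless every replicate is below.
#' @return logical vector.
#' @export
is_expressed <- function(gene_id, stage, cpm_table, threshold = 9,
                         aggregate = c("mean", "all_below")) {
  aggregate <- match.arg(aggregate)
  samples <- attr(cpm_table, "samples")
  if (is.null(samples)) samples <- parse_sample_names(colnames(cpm_table))
  if (!stage %in% samples$stage) stop("unknown stage: ", stage)
  miss <- setdiff(gene_id, rownames(cpm_table))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  sub <- cpm_table[gene_id, samples$stage == stage, drop = FALSE]
  if (aggregate == "mean") rowMeans(sub) >= threshold
  else apply(sub >= threshold, 1, any)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper over `p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni correction with an explicit family size
#'
#' `min(1, p * m)`.  `m` may exceed the length of `p` (tests reported
#' elsewhere still count toward the family).
#'
#' @param p numeric vector of p-values.
#' @param m family size; must be >= 1 and >= length(p).
#' @return corrected p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (m < length(p)) stop("m smaller than the number of tests")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' Simple internal differential-expression test between two stages
#'
#' A deliberately plain stand-in used when no external DE table is
#' supplied: per gene, log2 fold change of stage-mean CPM (with 0.5
#' pseudo-CPM) and a Welch two-sample t-test on log2(CPM + 0.5) across
#' replicates, BH-adjusted over all genes.  Zero-variance degenerate
#' cases: equal means give p = 1, unequal means with zero pooled variance
#' give p = 0.  Externally computed DE tables (e.g. from limma-voom)
#' take precedence in the pipeline when provided.
#'
#' @param counts raw count matrix with `STAGE_repN` columns.
#' @param s1,s2 the two stage labels; log2fc is s2 vs s1.
#' @return data.frame: `gene_id`, `stage1`, `stage2`, `log2fc`,
#'   `pvalue`, `padj`, `method`.
#' @export
simple_de <- function(counts, s1, s2) {
  samples <- attr(counts, "samples")
  if (is.null(samples)) samples <- parse_sample_names(colnames(counts))
  i1 <- which(samples$stage == s1)
  i2 <- which(samples$stage == s2)
  if (length(i1) < 2 || length(i2) < 2)
    stop("need >= 2 replicates per stage for the internal test; ",
         "supply an external DE table instead")
  cp <- cpm(counts)
  l1 <- log2(cp[, i1, drop = FALSE] + 0.5)
  l2 <- log2(cp[, i2, drop = FALSE] + 0.5)
  log2fc <- log2(rowMeans(cp[, i2, drop = FALSE]) + 0.5) -
    log2(rowMeans(cp[, i1, drop = FALSE]) + 0.5)
  pvalue <- vapply(seq_len(nrow(counts)), function(i) {
    x <- l1[i, ]; y <- l2[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(y, x)$p.value
    }
  }, numeric(1))
  data.frame(gene_id = rownames(counts), stage1 = s1, stage2 = s2,
             log2fc = log2fc, pvalue = pvalue, padj = bh_adjust(pvalue),
             method = "internal_ttest", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read an externally computed DE table
#'
#' TSV with columns `gene_id`, `stage1`, `stage2`, `log2fc`, `pvalue`,
#' `padj`; rows for several stage pairs may share one file.
#'
#' @param path file path.
#' @return data.frame with a `method = "external"` column appended.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "stage1", "stage2", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DE table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$pvalue < 0 | df$pvalue > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  df$method <- "external"
  df
}
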