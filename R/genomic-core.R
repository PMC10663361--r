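#' Construct a table of genomic intervals
#'
#' Intervals are the universal location unit of the pipeline: ATAC peaks,
#' screen fragments, CHi-C other-ends, ChIP features and merged reference
#' elements are all interval tables.  Coordinates follow the BED convention
#' throughout: 0-based starts, exclusive ends (`[start, end)`).
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start offsets.
#' @param end integer vector, exclusive end offsets (`end > start`).
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"` (unstranded).
#' @param ... further equal-length vectors kept as extra columns
#'   (e.g. `name`, `library`, `stage`).
#' @return a `data.frame` of class `genomic_intervals`.
#' @examples
#' gi("chr1", c(100L, 300L), c(200L, 400L))
#' @export
gi <- function(chrom, start, end, strand = "*", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep(as.character(strand),
                                length.out = length(chrom)),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Validate an interval table
#'
#' Enforces the coordinate invariants: non-empty chromosome names,
#' `start >= 0`, `end > start`, strand in `{+, -, *}`.
#'
#' @param x a data.frame with columns `chrom`, `start`, `end` (and
#'   optionally `strand`).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
      stop("empty chromosome name")
    if (any(is.na(x$start)) || any(is.na(x$end)))
      stop("NA coordinates")
    if (any(x$start < 0))
      stop("negative start coordinate")
    bad <- which(x$end <= x$start)
    if (length(bad))
      stop("end <= start at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    if ("strand" %in% names(x) && any(!x$strand %in% c("+", "-", "*")))
      stop("strand must be one of '+', '-', '*'")
  }
  invisible(x)
}

# internal: 0-based half-open table -> GRanges (1-based closed)
.as_granges <- function(x) {
  validate_intervals(x)
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Do two intervals share at least one base?
#'
#' Half-open semantics: abutting intervals (`end == start`) do not overlap.
#'
#' @param a,b single-row interval tables (or lists with `chrom`, `start`,
#'   `end` fields).
#' @return logical scalar.
#' @examples
#' overlaps(gi("chr1", 100, 200), gi("chr1", 150, 250))  # TRUE
#' overlaps(gi("chr1", 100, 200), gi("chr1", 200, 300))  # FALSE
#' @export
overlaps <- function(a, b) {
  identical(as.character(a$chrom[1]), as.character(b$chrom[1])) &&
    max(a$start[1], b$start[1]) < min(a$end[1], b$end[1])
}

#' All overlapping query/subject pairs
#'
#' Wraps the interval-tree search of \pkg{GenomicRanges} and returns the
#' pair set sorted by query then subject index, so the result is
#' deterministic and independent of input order.
#'
#' @param queries,subjects interval tables.
#' @return a `data.frame` with integer columns `query` and `subject`
#'   (1-based row indices), one row per overlapping pair.
#' @export
find_overlaps <- function(queries, subjects) {
  if (!nrow(queries) || !nrow(subjects))
    return(data.frame(query = integer(0), subject = integer(0)))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.as_granges(queries), .as_granges(subjects),
                                ignore.strand = TRUE))
  out <- data.frame(query = S4Vectors::queryHits(hits),
                    subject = S4Vectors::subjectHits(hits))
  out[order(out$query, out$subject), , drop = FALSE]
}

# internal: logical vector, TRUE where queries[i] overlaps >=1 subject
.overlaps_any <- function(queries, subjects) {
  if (!nrow(queries)) return(logical(0))
  if (!nrow(subjects)) return(rep(FALSE, nrow(queries)))
  # seqlevel-mismatch warnings are expected when the sets share no
  # chromosome; disjoint chromosomes simply cannot overlap
  suppressWarnings(
    IRanges::overlapsAny(.as_granges(queries), .as_granges(subjects),
                         ignore.strand = TRUE))
}

#' Construct a gene annotation table
#'
#' @param gene_id unique gene identifiers.
#' @param chrom,start,end gene-body coordinates (0-based half-open).
#' @param tss transcription start site offset; must lie within
#'   `[start, end]`.
#' @param strand gene strand.
#' @param symbol display names (defaults to `gene_id`).
#' @param is_tf logical: is the gene in the transcription-factor catalog?
#' @return a `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, tss,
                            strand = "+", symbol = gene_id, is_tf = FALSE) {
  df <- data.frame(gene_id = as.character(gene_id),
                   symbol = as.character(symbol),
                   chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   tss = as.integer(tss),
                   strand = as.character(strand),
                   is_tf = as.logical(is_tf),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation")
  if (any(df$tss < df$start | df$tss > df$end))
    stop("tss outside gene body")
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Distance from a peak to the nearest TSS
#'
#' Distance is measured from the nearest peak edge: 0 if any TSS falls
#' inside `[start, end)`, otherwise the minimum over TSS of
#' `min(|tss - start|, |tss - (end - 1)|)`.  Used for the distal-element
#' gate (elements more than 1.5 kb from any TSS).
#'
#' @param peak a single-row interval table.
#' @param genes a `gene_annotation` table.
#' @return a list with `distance` (bp) and `gene_id` (the minimizing gene;
#'   ties broken by lexicographically smallest `gene_id`).
#' @export
distance_to_nearest_tss <- function(peak, genes) {
  d <- .tss_distances(peak$chrom[1], peak$start[1], peak$end[1], genes)
  if (all(is.na(d)))
    stop("unassignable: no gene on chromosome ", peak$chrom[1])
  dmin <- min(d, na.rm = TRUE)
  cand <- genes$gene_id[which(d == dmin)]
  list(distance = dmin, gene_id = min(cand))
}

# internal: vector of edge distances from one peak to every TSS (NA off-chrom)
.tss_distances <- function(chrom, start, end, genes) {
  d <- rep(NA_real_, nrow(genes))
  on <- genes$chrom == chrom
  tss <- genes$tss[on]
  inside <- tss >= start & tss < end
  d[on] <- ifelse(inside, 0, pmin(abs(tss - start), abs(tss - (end - 1L))))
  d
}

# internal, vectorized: per-peak nearest-TSS distance and gene over a table
.nearest_tss_table <- function(peaks, genes) {
  n <- nrow(peaks)
  dist <- numeric(n)
  gene <- character(n)
  split_idx <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(n)) {
    gi_idx <- split_idx[[peaks$chrom[i]]]
    if (is.null(gi_idx)) {
      dist[i] <- NA_real_; gene[i] <- NA_character_; next
    }
    tss <- genes$tss[gi_idx]
    inside <- tss >= peaks$start[i] & tss < peaks$end[i]
    d <- ifelse(inside, 0,
                pmin(abs(tss - peaks$start[i]), abs(tss - (peaks$end[i] - 1L))))
    dmin <- min(d)
    cand <- genes$gene_id[gi_idx][d == dmin]
    dist[i] <- dmin
    gene[i] <- min(cand)
  }
  data.frame(distance = dist, gene_id = gene, stringsAsFactors = FALSE)
}

#' Nearest gene to a peak
#'
#' The gene whose TSS minimizes [distance_to_nearest_tss()]; ties are
#' broken by the lexicographically smallest `gene_id` so results are
#' reproducible across runs.
#'
#' @inheritParams distance_to_nearest_tss
#' @return the `gene_id` (character scalar).
#' @export
nearest_gene <- function(peak, genes) {
  distance_to_nearest_tss(peak, genes)$gene_id
}
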