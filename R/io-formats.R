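#' Read a BED/BEDPE file into an interval table
#'
#' Accepts BED3+ (chrom, start, end, ...) and 6-column BEDPE
#' (chrom1, start1, end1, chrom2, start2, end2): BEDPE rows on a single
#' chromosome are collapsed to the fragment span
#' `min(start1, start2) .. max(end1, end2)`, mirroring how paired-end
#' reporter fragments are reduced to one coordinate span.  Coordinates are
#' kept 0-based half-open.  Malformed lines are hard errors (with line
#' numbers), never silently skipped.
#'
#' @param path file path.
#' @param library optional library label attached to every record, one of
#'   `"plasmid"`, `"negative_control"`, `"sorted_high"`, `"sorted_low"`.
#' @param stage optional stage label attached to every record.
#' @param dedup remove duplicate fragments (identical chrom/start/end)?
#'   Defaults to `TRUE` for fragment libraries, matching the uniq-style
#'   duplicate removal of the screen pipeline.
#' @return a `genomic_intervals` data.frame, in file order (first
#'   occurrence kept when deduplicating), with `library`/`stage` columns
#'   when the labels are given.
#' @export
read_bed <- function(path, library = NULL, stage = NULL, dedup = !is.null(library)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- gi(character(0), integer(0), integer(0))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3))
      stop("malformed BED line ", lineno[which(nf < 3)[1]], " in ", path,
           ": fewer than 3 columns")
    is_bedpe <- all(nf >= 6) && !any(is.na(suppressWarnings(
      as.integer(vapply(fields, `[`, "", 5)))))
    # BEDPE detection: column 5 numeric (a start), column 4 a chromosome name
    is_bedpe <- is_bedpe && all(vapply(fields, function(f)
      is.na(suppressWarnings(as.numeric(f[4]))), logical(1)))
    col <- function(i) vapply(fields, `[`, "", i)
    to_int <- function(v, what) {
      out <- suppressWarnings(as.integer(v))
      if (any(is.na(out)))
        stop("malformed BED line ", lineno[which(is.na(out))[1]], " in ",
             path, ": non-integer ", what)
      out
    }
    if (is_bedpe) {
      c1 <- col(1); c2 <- col(4)
      if (any(c1 != c2))
        stop("BEDPE line ", lineno[which(c1 != c2)[1]],
             ": mates on different chromosomes cannot be collapsed")
      s1 <- to_int(col(2), "start"); s2 <- to_int(col(5), "start")
      e1 <- to_int(col(3), "end"); e2 <- to_int(col(6), "end")
      chrom <- c1; start <- pmin(s1, s2); end <- pmax(e1, e2)
    } else {
      chrom <- col(1)
      start <- to_int(col(2), "start")
      end <- to_int(col(3), "end")
    }
    bad <- which(end <= start)
    if (length(bad))
      stop("invalid interval (end <= start) at line ", lineno[bad[1]],
           " in ", path)
    out <- gi(chrom, start, end)
  }
  if (!is.null(library)) {
    stopifnot(library %in% c("plasmid", "negative_control",
                             "sorted_high", "sorted_low"))
    out$library <- if (nrow(out)) library else character(0)
  }
  if (!is.null(stage)) out$stage <- if (nrow(out)) stage else character(0)
  if (dedup && nrow(out)) {
    out <- out[!duplicated(out[c("chrom", "start", "end")]), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Write an interval table as BED3 (plus a name column when present)
#'
#' @param x interval table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- cbind(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                format(x$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(x)) cols <- cbind(cols, x$name)
  writeLines(apply(cols, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a replicate count matrix
#'
#' Expects a TSV with a `gene_id` first column and sample columns named
#' `STAGE_repN` (e.g. `ES_rep1`).  Returns a numeric matrix with gene
#' rownames; the parsed (stage, replicate) design is attached as the
#' `"samples"` attribute.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples, with attribute `samples`
#'   (data.frame: `sample`, `stage`, `replicate`).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  if (any(is.na(m))) stop("missing counts in ", path)
  rownames(m) <- df$gene_id
  attr(m, "samples") <- parse_sample_names(colnames(m))
  m
}

#' Parse `STAGE_repN` sample labels into a design table
#' @param x character vector of sample names.
#' @return data.frame with columns `sample`, `stage`, `replicate`.
#' @export
parse_sample_names <- function(x) {
  ok <- grepl("^.+_rep[0-9]+$", x)
  if (any(!ok))
    stop("sample name(s) not of the form STAGE_repN: ",
         paste(x[!ok], collapse = ", "))
  data.frame(sample = x,
             stage = sub("_rep[0-9]+$", "", x),
             replicate = as.integer(sub("^.+_rep", "", x)),
             stringsAsFactors = FALSE)
}

#' Write a count/CPM matrix as TSV
#' @param m numeric matrix with gene rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JASPAR-style PWM file
#'
#' Blocks start with `>motif_id tf_family`, followed by four rows (A, C,
#' G, T) of equal length holding counts or probabilities.  Counts are
#' converted to probabilities with a pseudocount added to every cell;
#' rows that already sum to ~1 per column are taken as probabilities and
#' left untouched.  Motifs without an explicit threshold are assigned the
#' default fraction-of-maximum log-odds threshold when scanned (see
#' [log_odds_matrix()]).
#'
#' @param path file path.
#' @param pseudocount added to each count cell before normalization
#'   (default 1).
#' @return a list of `pwm` objects: each a list with `motif_id`,
#'   `tf_family`, `matrix` (4 x L probability matrix, rows A/C/G/T) and
#'   `threshold` (NA until set).
#' @export
read_pwms <- function(path, pseudocount = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no PWM blocks in ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    motif_id <- toks[1]
    tf_family <- if (length(toks) >= 2) toks[2] else motif_id
    body <- lines[(heads[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4)
      stop("motif ", motif_id, ": expected 4 base rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*[\\[|]?", "", l)
      l <- gsub("[]\\[]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1)
      stop("motif ", motif_id, ": base rows have unequal lengths")
    if (L < 4) stop("motif ", motif_id, ": length ", L, " < 4")
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    csums <- colSums(m)
    if (all(abs(csums - 1) < 1e-6)) {
      # already probabilities
    } else {
      m <- sweep(m + pseudocount, 2, csums + 4 * pseudocount, "/")
    }
    out[[k]] <- structure(list(motif_id = motif_id, tf_family = tf_family,
                               matrix = m, threshold = NA_real_),
                          class = "pwm")
  }
  names(out) <- vapply(out, `[[`, "", "motif_id")
  out
}

#' Write PWMs in the JASPAR-style block format read by [read_pwms()]
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$tf_family), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste(signif(p$matrix[b, ], 6), collapse = " "), con)
  }
  invisible(path)
}

#' Read promoter-capture Hi-C links
#'
#' TSV with columns `bait_gene`, `chrom`, `start`, `end` and optionally
#' `score`; each row links a promoter bait gene to a distal other-end
#' interval.
#'
#' @param path file path.
#' @return data.frame with those columns (`score` filled with `NA` when
#'   absent).
#' @export
read_links <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("bait_gene", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("link table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"score" %in% names(df)) df$score <- NA_real_
  validate_intervals(df)
  df
}

#' Read a gene annotation TSV
#'
#' Columns: `gene_id`, `symbol`, `chrom`, `start`, `end`, `tss`,
#' `strand`, `is_tf`.
#'
#' @param path file path.
#' @return a `gene_annotation` data.frame.
#' @export
read_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_annotation(df$gene_id, df$chrom, df$start, df$end, df$tss,
                  strand = df$strand, symbol = df$symbol, is_tf = df$is_tf)
}

#' Write a gene annotation TSV
#' @param genes `gene_annotation` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a priming network for Cytoscape-style tools
#'
#' Writes three files sharing `path_prefix`: a SIF edge list
#' (`<prefix>.sif`, relation `motif`), a node-attribute TSV
#' (`<prefix>_nodes.tsv`: node, kind, expression at the two transition
#' stages, primed flag) and a GraphML file (`<prefix>.graphml`) carrying
#' the same content.  Output is byte-stable: edges and nodes are sorted
#' and numbers formatted at 6 significant digits.  An empty network
#' yields empty-but-valid files.
#'
#' @param network a `priming_network` (see [build_network()]).
#' @param path_prefix path prefix for the three output files.
#' @return character vector of the paths written, invisibly.
#' @export
write_network <- function(network, path_prefix) {
  stopifnot(inherits(network, "priming_network"))
  edges <- network$edges
  nodes <- network$nodes
  sif_path <- paste0(path_prefix, ".sif")
  node_path <- paste0(path_prefix, "_nodes.tsv")
  gml_path <- paste0(path_prefix, ".graphml")
  if (nrow(edges)) {
    edges <- edges[order(edges$tf_family, edges$gene_id), , drop = FALSE]
    writeLines(paste(edges$tf_family, "motif", edges$gene_id, sep = "\t"),
               sif_path)
  } else writeLines(character(0), sif_path)
  nd <- nodes[order(nodes$node), , drop = FALSE]
  nd$expr_s1 <- signif(nd$expr_s1, 6)
  nd$expr_s2 <- signif(nd$expr_s2, 6)
  utils::write.table(nd, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- .network_igraph(network)
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(sif_path, node_path, gml_path))
}

# internal: priming_network -> igraph with node/edge attributes
.network_igraph <- function(network) {
  nd <- network$nodes[order(network$nodes$node), , drop = FALSE]
  ed <- network$edges
  if (nrow(ed))
    ed <- ed[order(ed$tf_family, ed$gene_id), c("tf_family", "gene_id",
                                                "carried_by"), drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = if (nrow(ed)) ed else data.frame(from = character(0), to = character(0)),
    directed = TRUE,
    vertices = data.frame(name = nd$node, kind = nd$kind,
                          expr_s1 = nd$expr_s1, expr_s2 = nd$expr_s2,
                          primed = nd$primed))
  g
}

#' Re-read the edge set of an exported GraphML network
#' @param path a `.graphml` file written by [write_network()].
#' @return data.frame with columns `tf_family`, `gene_id`.
#' @export
read_network_edges <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g)
  data.frame(tf_family = el[, 1], gene_id = el[, 2],
             stringsAsFactors = FALSE)
}

#' Read element sequences from FASTA
#' @param path FASTA file; record names must be element (peak) ids.
#' @return named character vector of upper-case DNA sequences.
#' @export
read_element_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write element sequences as FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_element_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
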