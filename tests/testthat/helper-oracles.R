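# Brute-force reference implementations used as independent oracles.
# They deliberately share no code with the package internals: overlap is
# decided by per-base set intersection, searches are exhaustive loops.

bf_overlaps <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1L), seq(b$start, b$end - 1L))) > 0
}

bf_find_overlaps <- function(queries, subjects) {
  out <- list()
  for (i in seq_len(nrow(queries)))
    for (j in seq_len(nrow(subjects)))
      if (bf_overlaps(queries[i, ], subjects[j, ]))
        out[[length(out) + 1L]] <- c(i, j)
  if (!length(out)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(query = m[, 1], subject = m[, 2])
  df[order(df$query, df$subject), , drop = FALSE]
}

bf_nearest_tss <- function(peak, genes) {
  best_d <- Inf; best_g <- NULL
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != peak$chrom) next
    tss <- genes$tss[i]
    d <- if (tss >= peak$start && tss < peak$end) 0
         else min(abs(tss - peak$start), abs(tss - (peak$end - 1L)))
    if (d < best_d || (d == best_d && genes$gene_id[i] < best_g)) {
      best_d <- d; best_g <- genes$gene_id[i]
    }
  }
  list(distance = best_d, gene_id = best_g)
}

bf_filter_fragments <- function(screen, negatives, plasmid, peaks) {
  key <- function(d) paste(d$chrom, d$start, d$end)
  s <- screen[!key(screen) %in% key(negatives), , drop = FALSE]
  s <- s[key(s) %in% key(plasmid), , drop = FALSE]
  keep <- vapply(seq_len(nrow(s)), function(i)
    any(vapply(seq_len(nrow(peaks)), function(j)
      bf_overlaps(s[i, ], peaks[j, ]), logical(1))), logical(1))
  if (!nrow(s)) s else s[keep, , drop = FALSE]
}

bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

bf_scan_window <- function(seq, pwm_mat, background, pos, strand) {
  # score one window starting at 0-based pos; N contributes 0
  rownames(pwm_mat) <- c("A", "C", "G", "T")
  w <- ncol(pwm_mat)
  s <- substr(seq, pos + 1, pos + w)
  if (strand == "-") {
    s <- chartr("ACGTN", "TGCAN", s)
    s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }
  chars <- strsplit(s, "")[[1]]
  total <- 0
  for (j in seq_len(w)) {
    if (chars[j] == "N") next
    p <- max(pwm_mat[chars[j], j], 1e-3)
    total <- total + log2(p / background[match(chars[j], c("A", "C", "G", "T"))])
  }
  total
}

bf_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  se <- sqrt(ss_res / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot,
       p_slope = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
}

# random interval generator used across oracle tests
rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                           max_len = 50) {
  start <- sample.int(max_pos, n, replace = TRUE)
  gi(sample(chroms, n, replace = TRUE), start,
     start + sample.int(max_len, n, replace = TRUE))
}

# small, fast simulation configuration shared by pipeline-level tests
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chromosomes = 2L, chrom_length = 2000000L,
             n_elements = 60L, primed_per_transition = 6L,
             primed_genes_per_transition = 5L, n_active = 20L,
             n_proximal = 6L, ...)
}
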