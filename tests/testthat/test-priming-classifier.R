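# A tiny fully hand-constructed study: two elements, two genes, two
# stages.  Element el at [10000,10400) is distal to gene GP (tss 2000)
# and positive at both stages; GP is silent at ES and strongly up at HB.
tiny_study <- function(positive_s2 = TRUE, gene_cpm_s1 = 2) {
  genes <- gene_annotation(c("GP", "GQ"), "chr1", c(2000, 52000),
                           c(7000, 57000), c(2000, 52000))
  peaks <- list(
    ES = gi("chr1", c(10000, 60000), c(10400, 60400)),
    HB = gi("chr1", c(10050, 60050), c(10450, 60450)))
  mkcall <- function(stage, pos) data.frame(
    peak_id = c("p1", "p2"), stage = stage, positive = pos,
    n_high = ifelse(pos, 8L, 0L), n_low = ifelse(pos, 2L, 0L),
    norm_high = ifelse(pos, 8, 0), norm_low = ifelse(pos, 2, 0),
    state = ifelse(pos, "High", "NotPositive"), stringsAsFactors = FALSE)
  calls <- list(ES = mkcall("ES", c(TRUE, FALSE)),
                HB = mkcall("HB", c(positive_s2, FALSE)))
  elements <- merge_elements(peaks)
  ec <- element_calls(elements, peaks, calls)
  lib <- 1e6 - gene_cpm_s1 - 1   # filler keeps CPM on the nominal scale
  counts <- matrix(c(gene_cpm_s1, gene_cpm_s1, 40, 40,
                     1, 1, 1, 1,
                     lib, lib, 1e6 - 42, 1e6 - 42), 3, byrow = TRUE,
                   dimnames = list(c("GP", "GQ", "FILL"),
                                   c("ES_rep1", "ES_rep2",
                                     "HB_rep1", "HB_rep2")))
  de <- data.frame(gene_id = c("GP", "GQ"), stage1 = "ES", stage2 = "HB",
                   log2fc = c(4.2, 0), pvalue = c(1e-5, 0.9),
                   padj = c(1e-4, 0.9), method = "external",
                   stringsAsFactors = FALSE)
  links <- data.frame(bait_gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0))
  list(genes = genes, peaks = peaks, calls = calls, elements = elements,
       ec = ec, cpm = cpm(counts), de = de, links = links)
}

test_that("stage peak sets merge into single-linkage reference elements", {
  peaks <- list(A = gi("chr1", c(100, 500), c(200, 600)),
                B = gi("chr1", c(150, 900), c(260, 950)))
  els <- merge_elements(peaks)
  expect_equal(nrow(els), 3)
  expect_equal(els$start, c(100L, 500L, 900L))
  expect_equal(els$end, c(260L, 600L, 950L))
  expect_equal(els$element_id, paste0("el_", 1:3))
})

test_that("element-level calls aggregate overlapping stage peaks", {
  st <- tiny_study()
  es <- st$ec[st$ec$stage == "ES", ]
  expect_equal(es$positive, c(TRUE, FALSE))
  expect_equal(es$state, c("High", "NotPositive"))
  expect_equal(es$n_high[1], 8)
})

test_that("CHi-C link takes precedence over nearest gene", {
  genes <- gene_annotation(c("GA", "GB"), "chr1", c(1000, 90000),
                           c(2000, 95000), c(1000, 90000))
  peak <- gi("chr1", 10000, 10400)
  no_links <- data.frame(bait_gene = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         score = numeric(0))
  expect_equal(link_peak_to_gene(peak, no_links, genes),
               list(gene_id = "GA", link_method = "nearest"))
  links <- data.frame(bait_gene = c("GB", "GA"), chrom = "chr1",
                      start = c(10000, 10000), end = c(10400, 10400),
                      score = c(5, 2))
  expect_equal(link_peak_to_gene(peak, links, genes),
               list(gene_id = "GB", link_method = "chic"))
  # score tie -> lexicographic bait
  links$score <- c(5, 5)
  expect_equal(link_peak_to_gene(peak, links, genes)$gene_id, "GA")

  # random layouts match the two-pass brute-force oracle
  set.seed(31)
  genes <- gene_annotation(sprintf("G%02d", 1:30), "chr1",
                           s <- sort(sample.int(2e5, 30)), s + 1000L, s)
  for (i in 1:50) {
    p <- rand_intervals(1, chroms = "chr1", max_pos = 2e5, max_len = 400)
    lk <- data.frame(bait_gene = sample(genes$gene_id, 5), chrom = "chr1",
                     start = ls <- sample.int(2e5, 5), end = ls + 300L,
                     score = runif(5))
    got <- link_peak_to_gene(p, lk, genes)
    ov <- vapply(seq_len(5), function(j) bf_overlaps(p, lk[j, ]), logical(1))
    if (any(ov)) {
      cand <- lk[ov, ]
      expect_equal(got$link_method, "chic")
      expect_equal(got$gene_id,
                   min(cand$bait_gene[cand$score == max(cand$score)]))
    } else {
      expect_equal(got$link_method, "nearest")
      expect_equal(got$gene_id, bf_nearest_tss(p, genes)$gene_id)
    }
  }
})

test_that("all four priming gates are enforced", {
  st <- tiny_study()
  pr <- classify_primed("ES", "HB", st$ec, st$elements, st$genes, st$links,
                        st$cpm, st$de)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$gene_id, "GP")
  expect_equal(pr$link_method, "nearest")
  expect_equal(pr$dynamics, "High>High")

  # positive at S1 only -> not primed
  st2 <- tiny_study(positive_s2 = FALSE)
  expect_equal(nrow(classify_primed("ES", "HB", st2$ec, st2$elements,
                                    st2$genes, st2$links, st2$cpm, st2$de)), 0)

  # gene already expressed at S1 (CPM 20) -> not primed
  st3 <- tiny_study(gene_cpm_s1 = 20)
  expect_equal(nrow(classify_primed("ES", "HB", st3$ec, st3$elements,
                                    st3$genes, st3$links, st3$cpm, st3$de)), 0)

  # DE gate boundaries: log2fc below 1, or padj at 0.05, fail
  st4 <- tiny_study()
  st4$de$log2fc[1] <- 0.99
  expect_equal(nrow(classify_primed("ES", "HB", st4$ec, st4$elements,
                                    st4$genes, st4$links, st4$cpm, st4$de)), 0)
  st4$de$log2fc[1] <- 1            # inclusive at exactly twofold
  st4$de$padj[1] <- 0.049
  expect_equal(nrow(classify_primed("ES", "HB", st4$ec, st4$elements,
                                    st4$genes, st4$links, st4$cpm, st4$de)), 1)
  st4$de$padj[1] <- 0.05           # strict at 0.05
  expect_equal(nrow(classify_primed("ES", "HB", st4$ec, st4$elements,
                                    st4$genes, st4$links, st4$cpm, st4$de)), 0)

  expect_error(classify_primed("HB", "HE", st$ec, st$elements, st$genes,
                               st$links, st$cpm, st$de), "no DE results")
})

test_that("raising the distal cutoff never enlarges the primed set", {
  st <- tiny_study()
  n_at <- function(d) nrow(classify_primed("ES", "HB", st$ec, st$elements,
                                           st$genes, st$links, st$cpm,
                                           st$de, distal_min_bp = d))
  sizes <- vapply(c(0, 1500, 7999, 8001, 1e6), n_at, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], 1)
  expect_equal(sizes[5], 0)
})

test_that("dynamics labels enumerate the 2x2 state combinations", {
  expect_equal(dynamics_class("High", "High"), "High>High")
  expect_equal(dynamics_class("Low", "High"), "Low>High")
  combos <- expand.grid(s1 = c("High", "Low"), s2 = c("High", "Low"),
                        stringsAsFactors = FALSE)
  expect_equal(length(unique(dynamics_class(combos$s1, combos$s2))), 4)
  expect_error(dynamics_class("NotPositive", "High"), "High/Low")
})

test_that("persistence counts positive primed elements at later stages", {
  primed <- data.frame(element_id = c("el_1", "el_2"), stage1 = "ES",
                       stage2 = "HB", gene_id = c("g1", "g2"),
                       stringsAsFactors = FALSE)
  ec <- expand.grid(element_id = c("el_1", "el_2"),
                    stage = c("ES", "HB", "HE", "HP"),
                    stringsAsFactors = FALSE)
  ec$positive <- TRUE
  p <- persistence(primed, ec, c("ES", "HB", "HE", "HP"))
  expect_equal(unname(p), c(100, 100, 100))
  ec$positive[ec$stage == "HP" & ec$element_id == "el_2"] <- FALSE
  p <- persistence(primed, ec, c("ES", "HB", "HE", "HP"))
  expect_equal(p[["HP"]], 50)
  expect_length(persistence(primed[0, ], ec, c("ES", "HB")), 0)
})

test_that("stage Z-scores are standardized per gene; medians track activation", {
  set.seed(12)
  stages <- c("ES", "HB", "HE", "HP")
  counts <- matrix(rpois(50 * 8, 100), 50, 8,
                   dimnames = list(paste0("g", 1:50),
                                   paste0(rep(stages, each = 2), "_rep", 1:2)))
  cpm_t <- cpm(counts)
  logc <- log2(cpm_t + 0.5)
  sm <- primescan:::.stage_mean_cpm(logc)[, stages]
  z <- primescan:::.zscore_rows(sm)
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-9))

  # monotonically rising gene -> strictly increasing median trace
  rise <- matrix(rep(c(10, 100, 1000, 10000), each = 2), 1, byrow = TRUE,
                 dimnames = list("gr", paste0(rep(stages, each = 2),
                                              "_rep", 1:2)))
  mz <- median_expression_zscore("gr", cpm(rbind(rise, counts[1, , drop = FALSE] * 0 + 50)),
                                 stages)
  expect_true(all(diff(mz) > 0))

  # constant gene contributes zeros
  const <- median_expression_zscore("g_const",
    cpm(matrix(c(rep(30, 8), rep(70, 8)), 2, byrow = TRUE,
               dimnames = list(c("g_const", "g_fill"),
                               colnames(counts)))), stages)
  expect_equal(unname(const), rep(0, 4))
})

test_that("per-gene multiplicity conserves the record count", {
  primed <- data.frame(element_id = paste0("el_", 1:5),
                       gene_id = c("gA", "gA", "gA", "gB", "gC"),
                       stringsAsFactors = FALSE)
  m <- multiplicity_per_gene(primed)
  expect_equal(m$n_elements[m$gene_id == "gA"], 3)
  expect_equal(sum(m$n_elements), nrow(primed))
  expect_true(m$multi[m$gene_id == "gA"])
  expect_false(m$multi[m$gene_id == "gB"])
  expect_equal(nrow(multiplicity_per_gene(primed[0, ])), 0)
})
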