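test_that("intergenic/intragenic is a partition by gene-body overlap", {
  genes <- gene_annotation(c("G1", "G2"), c("chr1", "chr1"),
                           c(1000, 50000), c(6000, 56000), c(1000, 50000))
  els <- gi(c("chr1", "chr1", "chr9"), c(2000, 20000, 100),
            c(2400, 20400, 500), element_id = paste0("el_", 1:3))
  loc <- classify_intergenic(els, genes)
  expect_equal(loc$location, c("intragenic", "intergenic", "intergenic"))
  expect_equal(nrow(loc), nrow(els))
})

test_that("eRNA Z-scores are standardized and track activation", {
  set.seed(9)
  stages <- c("ES", "HB", "HE", "HP")
  m <- matrix(rpois(40 * 4, 20), 40, 4,
              dimnames = list(paste0("el_", 1:40), stages))
  z <- erna_zscores(m)
  expect_length(z, 4)

  # internal per-element z-scores have mean 0 and sd 1
  cpm_m <- sweep(m, 2, colSums(m), "/") * 1e6
  zz <- primescan:::.zscore_rows(log2(cpm_m + 0.5))
  expect_true(all(abs(rowMeans(zz)) < 1e-9))
  expect_true(all(abs(apply(zz, 1, sd) - 1) < 1e-9))

  # element transcribed only at HP peaks there; all-zero rows contribute 0
  m2 <- matrix(c(0, 0, 0, 200,
                 0, 0, 0, 0,
                 100, 100, 100, 100), 3, byrow = TRUE,
               dimnames = list(c("up", "zero", "flat"), stages))
  z2 <- erna_zscores(m2, library_sizes = rep(1000, 4),
                     element_ids = "up")
  expect_equal(which.max(z2), c(HP = 4L))
  single <- erna_zscores(m2, library_sizes = rep(1000, 4),
                         element_ids = "zero")
  expect_equal(unname(single), rep(0, 4))

  # invariant to uniform scaling of a stage library
  m3 <- m
  m3[, 2] <- m3[, 2] * 10
  z3 <- erna_zscores(m3, library_sizes = c(colSums(m)[1],
                                           colSums(m)[2] * 10,
                                           colSums(m)[3:4]))
  expect_equal(z3, erna_zscores(m, library_sizes = colSums(m)))
  expect_error(erna_zscores(m, stage_order = c(stages, "XX")), "missing stage")
})

test_that("VEGF-responsive means open only when VEGF is withdrawn", {
  els <- gi("chr1", c(100, 500, 900), c(200, 600, 1000),
            element_id = paste0("el_", 1:3))
  minus_vegf <- gi("chr1", c(100, 500), c(200, 600))   # el_1, el_2 open
  all_cyt <- gi("chr1", c(500, 900), c(600, 1000))     # el_2, el_3 open
  r <- classify_vegf_responsive(els, minus_vegf, all_cyt)
  expect_equal(r$responsive, c(TRUE, FALSE, FALSE))
  expect_equal(r$opposite, c(FALSE, FALSE, TRUE))
  expect_error(classify_vegf_responsive(els, NULL, all_cyt), "required")

  # anti-monotone in the all-cytokines set: adding +VEGF peaks never adds
  # responsive calls
  set.seed(44)
  for (rep in 1:20) {
    e <- rand_intervals(20, chroms = "chr1", max_pos = 2000, max_len = 50)
    e$element_id <- paste0("el_", 1:20)
    mv <- rand_intervals(10, chroms = "chr1", max_pos = 2000, max_len = 50)
    ac <- rand_intervals(6, chroms = "chr1", max_pos = 2000, max_len = 50)
    base <- classify_vegf_responsive(e, mv, ac)
    grown <- classify_vegf_responsive(e, mv, rbind(ac,
      rand_intervals(6, chroms = "chr1", max_pos = 2000, max_len = 50)))
    expect_true(all(grown$responsive <= base$responsive))
    # agreement with the two-overlap-test oracle
    for (i in 1:20) {
      in_mv <- any(vapply(seq_len(nrow(mv)), function(j)
        bf_overlaps(e[i, ], mv[j, ]), logical(1)))
      in_ac <- any(vapply(seq_len(nrow(ac)), function(j)
        bf_overlaps(e[i, ], ac[j, ]), logical(1)))
      expect_equal(base$responsive[i], in_mv && !in_ac)
    }
  }
})

test_that("VEGF gene report computes fold change and Bonferroni p", {
  em <- matrix(c(10, 10, 10, 20, 22, 18), 2, 3, byrow = TRUE,
               dimnames = list(c("flat", "up"), paste0("r", 1:3)))
  ep <- matrix(c(10, 10, 10, 10, 11, 9), 2, 3, byrow = TRUE,
               dimnames = list(c("flat", "up"), paste0("r", 1:3)))
  rep_ <- vegf_gene_report(c("flat", "up"), em, ep)
  expect_equal(rep_$fold_change[rep_$gene_id == "flat"], 1)
  expect_equal(rep_$pvalue[rep_$gene_id == "flat"], 1)
  expect_equal(rep_$p_bonferroni[rep_$gene_id == "flat"], 1)
  expect_equal(rep_$fold_change[rep_$gene_id == "up"], 2)
  expect_equal(rep_$p_bonferroni, pmin(1, rep_$pvalue * 2))

  # missing genes are skipped, never invented
  expect_message(out <- vegf_gene_report(c("flat", "ghost"), em, ep),
                 "ghost")
  expect_equal(out$gene_id, "flat")
  # external p-values take precedence over the internal test
  ext <- vegf_gene_report("up", em, ep, m = 5,
                          external_p = c(up = 0.01))
  expect_equal(ext$p_bonferroni, 0.05)
})
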