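network_fixture <- function(smad_cpm_es = 50) {
  primed <- data.frame(element_id = c("el_1", "el_2"), stage1 = "ES",
                       stage2 = "HB", gene_id = c("Runx1", "Tal1"),
                       link_method = "nearest", distance_tss = 5000,
                       state_s1 = "High", state_s2 = "High",
                       dynamics = "High>High", stringsAsFactors = FALSE)
  mm <- matrix(c(1L, 0L,
                 0L, 1L), 2, byrow = TRUE,
               dimnames = list(c("el_1", "el_2"), c("SMAD_01", "TEAD_01")))
  catalog <- data.frame(motif_id = c("SMAD_01", "TEAD_01"),
                        tf_family = c("SMAD", "TEAD"),
                        members = c("Smad1,Smad5", "Tead4"),
                        stringsAsFactors = FALSE)
  counts <- matrix(c(smad_cpm_es, smad_cpm_es, smad_cpm_es, 200, 200, 220,
                     2, 2, 2, 30, 40, 40,
                     rep(1e6, 6)), 3, byrow = TRUE,
                   dimnames = list(c("Smad1", "Tead4", "FILL"),
                                   paste0(rep(c("ES", "HB"), each = 3),
                                          "_rep", 1:3)))
  list(primed = primed, mm = mm, catalog = catalog, cpm = cpm(counts))
}

test_that("edges require a motif hit and an expressed family member", {
  fx <- network_fixture()
  # library is dominated by FILL, so nominal CPM ~ value for the others
  net <- build_network(fx$primed, fx$mm, fx$catalog, fx$cpm, "ES", "HB")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$tf_family, "SMAD")
  expect_equal(net$edges$gene_id, "Runx1")
  expect_equal(net$edges$carried_by, "el_1")
  # TEAD motif hits el_2 but no TEAD member reaches CPM 9 at ES
  expect_false("TEAD" %in% net$edges$tf_family)

  # silencing SMAD at ES removes its edge
  fx2 <- network_fixture(smad_cpm_es = 1)
  net2 <- build_network(fx2$primed, fx2$mm, fx2$catalog, fx2$cpm, "ES", "HB")
  expect_equal(nrow(net2$edges), 0)

  # target-gene nodes are flagged primed; family nodes are not
  expect_true(all(net$nodes$primed[net$nodes$kind == "gene"]))
  expect_false(any(net$nodes$primed[net$nodes$kind == "tf_family"]))

  bad_mm <- fx$mm
  colnames(bad_mm)[2] <- "UNKNOWN_01"
  expect_error(build_network(fx$primed, bad_mm, fx$catalog, fx$cpm,
                             "ES", "HB"), "absent from the TF catalog")
})

test_that("edge set equals the exhaustive family x motif x element loop", {
  set.seed(66)
  for (rep in 1:20) {
    n_el <- 8; n_motif <- 5
    els <- paste0("el_", 1:n_el)
    motifs <- paste0("m", 1:n_motif)
    fams <- paste0("F", sample(1:3, n_motif, replace = TRUE))
    members <- paste0("TF_", seq_len(n_motif))
    catalog <- data.frame(motif_id = motifs, tf_family = fams,
                          members = members, stringsAsFactors = FALSE)
    mm <- matrix(rbinom(n_el * n_motif, 1, 0.4), n_el,
                 dimnames = list(els, motifs))
    primed <- data.frame(element_id = els, stage1 = "ES", stage2 = "HB",
                         gene_id = paste0("g", sample(1:4, n_el, replace = TRUE)),
                         stringsAsFactors = FALSE)
    expr_tf <- runif(n_motif) < 0.6
    counts <- matrix(1, n_motif + 1, 4,
                     dimnames = list(c(members, "FILL"),
                                     paste0(rep(c("ES", "HB"), each = 2),
                                            "_rep", 1:2)))
    counts[seq_len(n_motif), 1:2] <- ifelse(expr_tf, 100000, 1)
    counts["FILL", ] <- 1e6
    net <- build_network(primed, mm, catalog, cpm(counts), "ES", "HB")

    want <- character(0)
    for (f in unique(fams)) {
      fam_ok <- any(expr_tf[fams == f])
      if (!fam_ok) next
      for (k in which(fams == f))
        for (i in seq_len(n_el))
          if (mm[i, k] == 1)
            want <- c(want, paste(f, primed$gene_id[i]))
    }
    expect_setequal(paste(net$edges$tf_family, net$edges$gene_id),
                    unique(want))
    # collapsing motifs into families never inflates the edge count
    expect_lte(nrow(net$edges), sum(mm))
  }
})

test_that("primed TF-gene count is over distinct genes", {
  genes <- gene_annotation(c("Runx1", "Tal1", "Gata2", "Other"), "chr1",
                           c(0, 1e4, 2e4, 3e4) + 0L,
                           c(5e3, 1.5e4, 2.5e4, 3.5e4) + 0L,
                           c(0, 1e4, 2e4, 3e4) + 0L,
                           is_tf = c(TRUE, TRUE, TRUE, FALSE))
  primed <- data.frame(element_id = paste0("el_", 1:4),
                       gene_id = c("Runx1", "Runx1", "Tal1", "Other"),
                       stringsAsFactors = FALSE)
  expect_equal(count_primed_tf_genes(primed, genes), 2)
  expect_equal(count_primed_tf_genes(primed[0, ], genes), 0)
})

test_that("network delta reports gains and losses against the rebuild", {
  fx <- network_fixture()
  n1 <- build_network(fx$primed, fx$mm, fx$catalog, fx$cpm, "ES", "HB",
                      expr_stage = "ES")
  expect_equal(network_delta(n1, n1),
               list(only_s1 = n1$edges[0, c("tf_family", "gene_id")],
                    only_s2 = n1$edges[0, c("tf_family", "gene_id")],
                    shared = structure(n1$edges[, c("tf_family", "gene_id")],
                                       row.names = 1L)),
               ignore_attr = TRUE)
  # TEAD switches on at HB: its edge exists only in the S2 rebuild
  n2 <- build_network(fx$primed, fx$mm, fx$catalog, fx$cpm, "ES", "HB",
                      expr_stage = "HB")
  d <- network_delta(n1, n2)
  expect_equal(d$only_s2$tf_family, "TEAD")
  expect_equal(nrow(d$only_s1), 0)
  expect_equal(nrow(d$shared), 1)

  n_other <- n2
  n_other$elements <- "el_99"
  expect_error(network_delta(n1, n_other), "element universes")
})
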