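#' Run the full priming-analysis pipeline
#'
#' Config-driven end-to-end orchestration: (optionally) simulate the
#' input bundle, run the screen filtering and activity calling per
#' stage, merge reference elements, compute differential expression,
#' classify primed elements for every consecutive stage transition,
#' scan motifs and build/export the priming networks, profile features
#' against active enhancers, summarize eRNA at intergenic primed
#' elements, classify VEGF-responsive elements, and — when ground-truth
#' tables are present in the data directory — evaluate every call
#' against the planted truth.  A machine-readable summary (JSON + TSV)
#' and a manifest of input hashes and parameters are written to
#' `out_dir`.  The run is a pure function of the config and input
#' files: identical inputs give a byte-identical summary.
#'
#' @param config a list or path to a YAML file.  Recognized fields:
#'   `data_dir` (bundle directory), `out_dir`, `stages` (default ES,
#'   HB, HE, HP), `simulate` (TRUE or a list of [sim_config()]
#'   overrides; generates the bundle into `data_dir`), `seed` (used by
#'   `simulate`), `de_table` (optional external DE TSV; otherwise the
#'   internal test is used), and the gate parameters `distal_min_bp`,
#'   `expr_threshold`, `lfc_min`, `padj_max`, `activity_ratio`.
#' @return the run summary, invisibly (a named list, also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(stages = c("ES", "HB", "HE", "HP"), seed = 7L,
                   distal_min_bp = 1500, expr_threshold = 9,
                   lfc_min = 1, padj_max = 0.05, activity_ratio = 1.0,
                   simulate = FALSE, de_table = NULL)
  for (f in names(defaults))
    if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  if (is.null(cfg$data_dir)) stop("config lacks data_dir")
  if (is.null(cfg$out_dir)) stop("config lacks out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dd <- cfg$data_dir
  stages <- cfg$stages
  log <- function(...) message("[primescan] ", ...)
  stage_wrap <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log(name, " done (", round(as.numeric(Sys.time() - t0, units = "secs"),
                               2), " s)")
    out
  }

  if (!isFALSE(cfg$simulate)) stage_wrap("simulate", {
    over <- if (is.list(cfg$simulate)) cfg$simulate else list()
    over$seed <- as.integer(cfg$seed)
    simulate_bundle(do.call(sim_config, over), dd)
  })

  inputs <- stage_wrap("read", {
    genes <- read_genes(file.path(dd, "genes.tsv"))
    peaks <- lapply(stats::setNames(stages, stages), function(s)
      read_bed(file.path(dd, sprintf("peaks_%s.bed", s))))
    counts <- read_expression(file.path(dd, "counts.tsv"))
    links_path <- file.path(dd, "chic_links.tsv")
    links <- if (file.exists(links_path)) read_links(links_path)
      else data.frame(bait_gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0))
    list(genes = genes, peaks = peaks, counts = counts, links = links)
  })

  calls <- stage_wrap("screen", {
    negatives <- read_bed(file.path(dd, "frags_negative.bed"),
                          library = "negative_control")
    plasmid <- read_bed(file.path(dd, "frags_plasmid.bed"),
                        library = "plasmid")
    lapply(stats::setNames(stages, stages), function(s) {
      high <- read_bed(file.path(dd, sprintf("frags_high_%s.bed", s)),
                       library = "sorted_high", stage = s)
      low <- read_bed(file.path(dd, sprintf("frags_low_%s.bed", s)),
                      library = "sorted_low", stage = s)
      screen_stage(inputs$peaks[[s]], high, low, negatives, plasmid,
                   stage = s, activity_ratio = cfg$activity_ratio)
    })
  })

  elements <- stage_wrap("merge", merge_elements(inputs$peaks))
  el_calls <- stage_wrap("element_calls",
                         element_calls(elements, inputs$peaks, calls))
  cpm_table <- cpm(inputs$counts)

  de <- stage_wrap("de", {
    if (!is.null(cfg$de_table)) read_de_table(cfg$de_table)
    else do.call(rbind, lapply(seq_len(length(stages) - 1L), function(t)
      simple_de(inputs$counts, stages[t], stages[t + 1L])))
  })

  transitions <- paste0(stages[-length(stages)], ">", stages[-1])
  primed <- stage_wrap("prime", {
    out <- lapply(seq_along(transitions), function(t)
      classify_primed(stages[t], stages[t + 1L], el_calls, elements,
                      inputs$genes, inputs$links, cpm_table, de,
                      distal_min_bp = cfg$distal_min_bp,
                      expr_threshold = cfg$expr_threshold,
                      lfc_min = cfg$lfc_min, padj_max = cfg$padj_max))
    names(out) <- transitions
    for (t in transitions)
      utils::write.table(out[[t]],
        file.path(cfg$out_dir, sprintf("primed_%s.tsv", gsub(">", "_", t))),
        sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  motif_ann <- stage_wrap("motifs", {
    fasta <- file.path(dd, "elements.fasta")
    pwm_path <- file.path(dd, "pwms.txt")
    if (!file.exists(fasta) || !file.exists(pwm_path)) return(NULL)
    seqs <- read_element_fasta(fasta)
    pwms <- read_pwms(pwm_path)
    el_seqs <- .sequences_for_elements(elements, seqs)
    list(matrix = annotate_elements(el_seqs, pwms), pwms = pwms)
  })

  networks <- stage_wrap("grn", {
    cat_path <- file.path(dd, "tf_catalog.tsv")
    if (is.null(motif_ann) || !file.exists(cat_path)) return(NULL)
    tf_catalog <- utils::read.delim(cat_path, stringsAsFactors = FALSE)
    out <- lapply(seq_along(transitions), function(t) {
      pr <- primed[[t]]
      pr <- pr[pr$element_id %in% rownames(motif_ann$matrix), , drop = FALSE]
      n1 <- build_network(pr, motif_ann$matrix, tf_catalog, cpm_table,
                          stages[t], stages[t + 1L],
                          expr_stage = stages[t],
                          expr_threshold = cfg$expr_threshold)
      n2 <- build_network(pr, motif_ann$matrix, tf_catalog, cpm_table,
                          stages[t], stages[t + 1L],
                          expr_stage = stages[t + 1L],
                          expr_threshold = cfg$expr_threshold)
      write_network(n1, file.path(cfg$out_dir,
        sprintf("network_%s", gsub(">", "_", transitions[t]))))
      list(primed_net = n1, active_net = n2, delta = network_delta(n1, n2))
    })
    names(out) <- transitions
    out
  })

  features <- stage_wrap("features", {
    fdir <- file.path(dd, "features")
    if (!dir.exists(fdir)) return(NULL)
    beds <- list.files(fdir, pattern = "\\.bed$", full.names = TRUE)
    sets <- lapply(beds, read_bed)
    names(sets) <- sub("\\.bed$", "", basename(beds))
    lapply(stats::setNames(seq_along(transitions), transitions), function(t) {
      s1 <- stages[t]
      pr_ids <- unique(primed[[t]]$element_id)
      active_ids <- .active_enhancer_ids(el_calls, elements, inputs$genes,
                                         inputs$links, cpm_table, s1,
                                         cfg$distal_min_bp,
                                         cfg$expr_threshold)
      active_ids <- setdiff(active_ids, pr_ids)
      ids <- c(pr_ids, active_ids)
      if (length(pr_ids) < 1 || length(active_ids) < 1) return(NULL)
      els <- elements[match(ids, elements$element_id), , drop = FALSE]
      cls <- c(rep("primed", length(pr_ids)),
               rep("active_enhancer", length(active_ids)))
      fm <- build_feature_matrix(els, sets,
                                 motif_matrix = motif_ann$matrix,
                                 class = cls)
      px <- feature_proportions(fm, "active_enhancer")
      py <- feature_proportions(fm, "primed")
      reg <- proportion_regression(px, py)
      list(proportions = data.frame(feature = names(px), active = px,
                                    primed = py, row.names = NULL),
           regression = reg)
    })
  })

  erna <- stage_wrap("erna", {
    ep <- file.path(dd, "erna_counts.tsv")
    if (!file.exists(ep)) return(NULL)
    df <- utils::read.delim(ep, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    # eRNA counts are keyed by planted element span; map pipeline
    # elements onto them by overlap
    key <- map_elements_to_truth(elements,
      data.frame(element = rownames(m), .parse_region(rownames(m))))
    loc <- classify_intergenic(elements, inputs$genes)
    lapply(stats::setNames(seq_along(transitions), transitions), function(t) {
      ids <- unique(primed[[t]]$element_id)
      inter <- ids[loc$location[match(ids, loc$element_id)] == "intergenic"]
      keys <- stats::na.omit(key[inter])
      if (length(keys) < 2) return(NULL)
      list(n_intergenic = length(inter),
           n_intragenic = length(ids) - length(inter),
           median_z = erna_zscores(m, stage_order = stages,
                                   element_ids = unique(keys)))
    })
  })

  vegf <- stage_wrap("vegf", {
    mv_path <- file.path(dd, "vegf_HE_minus_vegf.bed")
    ac_path <- file.path(dd, "vegf_HE_all_cytokines.bed")
    if (!file.exists(mv_path) || !file.exists(ac_path)) return(NULL)
    last_t <- transitions[length(transitions)]
    pr <- primed[[last_t]]
    els <- elements[match(unique(pr$element_id), elements$element_id), ,
                    drop = FALSE]
    resp <- classify_vegf_responsive(els, read_bed(mv_path),
                                     read_bed(ac_path))
    report <- NULL
    cm <- file.path(dd, "counts_minus_vegf.tsv")
    cp <- file.path(dd, "counts_plus_vegf.tsv")
    if (file.exists(cm) && file.exists(cp)) {
      resp_genes <- unique(pr$gene_id[pr$element_id %in%
                                        resp$element_id[resp$responsive]])
      report <- vegf_gene_report(resp_genes, read_expression(cm),
                                 read_expression(cp))
      utils::write.table(report, file.path(cfg$out_dir, "vegf_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(resp, file.path(cfg$out_dir, "vegf_elements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(responsive = resp, report = report)
  })

  evaluation <- stage_wrap("evaluate", {
    tp_path <- file.path(dd, "truth_primed.tsv")
    if (!file.exists(tp_path)) return(NULL)
    truth_primed <- utils::read.delim(tp_path, stringsAsFactors = FALSE)
    key <- map_elements_to_truth(elements, truth_primed)
    per_tr <- lapply(stats::setNames(seq_along(transitions), transitions),
                     function(t) {
      pr <- primed[[t]]
      pred <- paste(key[pr$element_id], pr$gene_id)
      tr <- truth_primed[truth_primed$transition == transitions[t], ]
      evaluate_calls(pred, paste(tr$element, tr$gene_id))
    })
    out <- list(primed = per_tr)
    ts_path <- file.path(dd, "truth_states.tsv")
    if (file.exists(ts_path)) {
      ts <- utils::read.delim(ts_path, stringsAsFactors = FALSE)
      skey <- map_elements_to_truth(elements, ts)
      ts_pos <- ts[ts$reporter_positive, ]
      pred_state <- el_calls$state[match(
        paste(names(skey)[match(ts_pos$element, skey)], ts_pos$stage),
        paste(el_calls$element_id, el_calls$stage))]
      out$state_accuracy <- mean(pred_state == ts_pos$state, na.rm = TRUE)
    }
    tv_path <- file.path(dd, "truth_vegf.tsv")
    if (file.exists(tv_path) && !is.null(vegf)) {
      tv <- utils::read.delim(tv_path, stringsAsFactors = FALSE)
      vkey <- map_elements_to_truth(elements, tv)
      pred <- stats::na.omit(vkey[vegf$responsive$element_id[
        vegf$responsive$responsive]])
      out$vegf <- evaluate_calls(pred, tv$element[tv$responsive])
    }
    out
  })

  summary <- stage_wrap("summary", {
    per_tr <- lapply(stats::setNames(seq_along(transitions), transitions),
                     function(t) {
      pr <- primed[[t]]
      dyn <- if (nrow(pr)) {
        tab <- table(factor(pr$dynamics, levels = c("High>High", "Low>Low",
                                                    "Low>High", "High>Low")))
        as.list(signif(as.numeric(tab) / nrow(pr), 6)) |>
          stats::setNames(names(tab))
      } else NULL
      s <- list(
        n_primed_elements = length(unique(pr$element_id)),
        n_primed_records = nrow(pr),
        n_primed_genes = length(unique(pr$gene_id)),
        n_primed_tf_genes = count_primed_tf_genes(pr, inputs$genes),
        dynamics_fractions = dyn,
        persistence_pct = as.list(signif(
          persistence(pr, el_calls, stages), 6)))
      if (nrow(pr))
        s$median_expression_z <- as.list(signif(
          median_expression_zscore(pr$gene_id, cpm_table, stages), 6))
      if (!is.null(features) && !is.null(features[[transitions[t]]]))
        s$feature_r_squared <-
          signif(features[[transitions[t]]]$regression$r_squared, 6)
      s
    })
    out <- list(transitions = per_tr)
    if (!is.null(vegf)) {
      out$vegf <- list(
        n_responsive_elements = sum(vegf$responsive$responsive),
        n_responsive_genes = if (!is.null(vegf$report)) nrow(vegf$report)
          else 0L)
    }
    if (!is.null(evaluation)) {
      out$evaluation <- list(
        primed = lapply(evaluation$primed, function(e)
          list(precision = signif(e$precision, 6),
               recall = signif(e$recall, 6))),
        state_accuracy = if (!is.null(evaluation$state_accuracy))
          signif(evaluation$state_accuracy, 6),
        vegf = if (!is.null(evaluation$vegf))
          list(precision = signif(evaluation$vegf$precision, 6),
               recall = signif(evaluation$vegf$recall, 6)))
    }
    out
  })

  stage_wrap("write", {
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    tsv <- do.call(rbind, lapply(names(summary$transitions), function(t) {
      s <- summary$transitions[[t]]
      data.frame(transition = t, primed_elements = s$n_primed_elements,
                 primed_records = s$n_primed_records,
                 primed_genes = s$n_primed_genes,
                 primed_tf_genes = s$n_primed_tf_genes)
    }))
    utils::write.table(tsv, file.path(cfg$out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("primescan")),
      parameters = cfg[c("stages", "distal_min_bp", "expr_threshold",
                         "lfc_min", "padj_max", "activity_ratio")],
      input_md5 = as.list(tools::md5sum(sort(list.files(dd,
        full.names = TRUE, recursive = TRUE)))))
    names(manifest$input_md5) <- basename(names(manifest$input_md5))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(NULL)
  })

  invisible(summary)
}

# internal: parse "chrom:start-end" keys into an interval data.frame
.parse_region <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4
  if (any(bad)) stop("unparseable region key(s): ",
                     paste(x[bad], collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

# internal: name FASTA sequences (keyed "chrom:start-end") by the
# pipeline element id they overlap
.sequences_for_elements <- function(elements, seqs) {
  reg <- .parse_region(names(seqs))
  ov <- find_overlaps(elements, reg)
  ov <- ov[!duplicated(ov$query), , drop = FALSE]
  out <- unname(seqs[ov$subject])
  names(out) <- elements$element_id[ov$query]
  out
}

# internal: active-enhancer class for feature comparison — distal
# elements positive at the stage whose linked gene IS expressed there
.active_enhancer_ids <- function(el_calls, elements, genes, links,
                                 cpm_table, stage, distal_min_bp,
                                 expr_threshold) {
  cs <- el_calls[el_calls$stage == stage & el_calls$positive, , drop = FALSE]
  els <- elements[match(cs$element_id, elements$element_id), , drop = FALSE]
  ln <- .link_elements(els, links, genes)
  keep <- !is.na(ln$gene_id) & ln$distance_tss > distal_min_bp &
    ln$gene_id %in% rownames(cpm_table)
  ln <- ln[keep, , drop = FALSE]
  if (!nrow(ln)) return(character(0))
  expr <- is_expressed(ln$gene_id, stage, cpm_table,
                       threshold = expr_threshold)
  ln$element_id[expr]
}
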