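#' Default simulation configuration
#'
#' Returns the configuration of the synthetic study emulated by
#' [simulate_bundle()]: four ordered differentiation stages (ES, HB, HE,
#' HP), 400 candidate cis-elements laid out in isolated 40-kb gene slots
#' over four 4-Mb chromosomes, 40 planted primed element-gene pairs per
#' stage transition, sorted reporter libraries sampling fragments from
#' true-High elements at a 4:1 high:low ratio (1:4 for true-Low), a 5%
#' screen-artefact rate and 5% negative-library contamination,
#' negative-binomial expression counts in which planted primed genes sit
#' below CPM 9 before their transition and rise at least twofold after,
#' CHi-C links covering half of the elements, planted TF-binding motif
#' consensi, and VEGF-dependent condition peak sets for 30% of the
#' HE-to-HP primed elements.
#'
#' @param ... named overrides of any default field.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 7L,
    stages = c("ES", "HB", "HE", "HP"),
    n_chromosomes = 4L,
    chrom_length = 4400000L,
    slot_width = 40000L,
    n_elements = 400L,
    element_length = 400L,
    primed_per_transition = 40L,
    primed_genes_per_transition = 32L,
    n_active = 120L,
    n_proximal = 20L,
    replicates = 4L,
    frags_per_element = 20L,
    pool_size = 30L,
    high_ratio = 0.8,
    artefact_rate = 0.05,
    negative_contamination_rate = 0.05,
    chic_fraction = 0.5,
    vegf_responsive_fraction = 0.3,
    persistence_prob = 0.85,
    lib_size = 4000000,
    dispersion = 0.02,
    cpm_silent = 2,
    cpm_active = 80,
    cpm_background = 30,
    expr_threshold = 9,
    motif_per_element = 2L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  for (f in c("artefact_rate", "negative_contamination_rate",
              "chic_fraction", "vegf_responsive_fraction",
              "persistence_prob", "high_ratio"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$primed_per_transition < 1)
    stop("infeasible config: fewer than one primed pair per transition")
  if ((length(cfg$stages) - 1) * cfg$primed_per_transition +
      cfg$n_active + cfg$n_proximal > cfg$n_elements)
    stop("infeasible config: element roles exceed n_elements")
  class(cfg) <- "sim_config"
  cfg
}

# built-in PWM set: strong-consensus count matrices for six TF families
.builtin_pwms <- function() {
  consensi <- c(RUNX_01 = "TGTGGTTT", GATA_01 = "AGATAAGA",
                ETS_01 = "ACAGGAAGT", SOX_01 = "AACAATGG",
                SMAD_01 = "GTCTAGAC", TEAD_01 = "ACATTCCAC")
  families <- c(RUNX_01 = "RUNX", GATA_01 = "GATA", ETS_01 = "ETS",
                SOX_01 = "SOX", SMAD_01 = "SMAD", TEAD_01 = "TEAD")
  lapply(names(consensi), function(id) {
    cons <- strsplit(consensi[[id]], "")[[1]]
    m <- matrix(5, nrow = 4, ncol = length(cons),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(match(cons, rownames(m)), seq_along(cons))] <- 85
    p <- sweep(m + 1, 2, colSums(m) + 4, "/")
    structure(list(motif_id = id, tf_family = families[[id]],
                   matrix = p, threshold = NA_real_), class = "pwm")
  })
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate the complete synthetic data bundle with ground truth
#'
#' Deterministically (seeded) writes every input the pipeline consumes:
#' gene annotation, per-stage ATAC peak BEDs, plasmid / negative-control
#' / sorted-high / sorted-low fragment BEDs per stage, a replicate count
#' matrix, CHi-C links, element sequences with planted motif consensi,
#' the PWM set and TF catalog, per-condition (+/- VEGF) peak sets and
#' expression tables for HE and HP, element-level eRNA counts, synthetic
#' ChIP-style feature peak sets, and ground-truth tables for every
#' planted signal.
#'
#' @param config a `sim_config` (see [sim_config()]).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the `truth` tables, the element layout
#'   and the file `paths` written.
#' @export
simulate_bundle <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
  set.seed(config$seed)
  stages <- config$stages
  n_stage <- length(stages)
  n_trans <- n_stage - 1L

  ## ---- genome layout: one gene per 40-kb slot -------------------------
  slots_per_chrom <- config$chrom_length %/% config$slot_width
  n_slots <- config$n_chromosomes * slots_per_chrom
  n_filler <- 20L
  if (n_slots < config$n_elements + 12L + n_filler)
    stop("infeasible config: genome too small for the element count")
  slot_chrom <- paste0("chr", rep(seq_len(config$n_chromosomes),
                                  each = slots_per_chrom))
  slot_start <- rep((seq_len(slots_per_chrom) - 1L) * config$slot_width,
                    config$n_chromosomes)
  gene_start <- slot_start + 2000L
  gene_end <- gene_start + 5000L
  gene_tss <- gene_start
  gene_id <- sprintf("G%04d", seq_len(n_slots))

  ## ---- element roles --------------------------------------------------
  n_el <- config$n_elements
  el_slot <- seq_len(n_el)           # element i sits in slot i
  roles <- rep("background", n_el)
  k <- 0L
  primed_idx <- vector("list", n_trans)
  for (t in seq_len(n_trans)) {
    idx <- k + seq_len(config$primed_per_transition)
    primed_idx[[t]] <- idx
    roles[idx] <- paste0("primed_t", t)
    k <- k + config$primed_per_transition
  }
  active_idx <- k + seq_len(config$n_active)
  roles[active_idx] <- "active"
  k <- k + config$n_active
  proximal_idx <- k + seq_len(config$n_proximal)
  roles[proximal_idx] <- "proximal"

  # element coordinates: distal elements ~8 kb downstream of their slot's
  # TSS; proximal elements within 1 kb of the TSS (caught by the distal
  # filter)
  el_offset <- ifelse(seq_len(n_el) %in% proximal_idx,
                      2000L + sample(200:800, n_el, replace = TRUE),
                      10000L + sample(0:2000, n_el, replace = TRUE))
  el_start <- slot_start[el_slot] + el_offset
  el_end <- el_start + config$element_length
  el_chrom <- slot_chrom[el_slot]
  el_key <- sprintf("%s:%d-%d", el_chrom, el_start, el_end)

  ## ---- element -> gene designation and CHi-C links --------------------
  # primed elements map onto a reduced gene set so some genes carry
  # several primed elements (multiplicity); chic-linked elements may be
  # assigned a non-nearest bait gene, which only CHi-C can recover
  target_gene <- gene_id[el_slot]
  for (t in seq_len(n_trans)) {
    idx <- primed_idx[[t]]
    ng <- min(config$primed_genes_per_transition, length(idx))
    gene_pool <- gene_id[el_slot[idx][seq_len(ng)]]
    target_gene[idx] <- gene_pool[((seq_along(idx) - 1L) %% ng) + 1L]
  }
  has_chic <- stats::runif(n_el) < config$chic_fraction
  # for a third of chic elements the bait is the next slot's gene
  # (non-nearest), exercising the CHi-C-over-nearest precedence
  reassign <- which(has_chic & stats::runif(n_el) < 1 / 3 &
                      !seq_len(n_el) %in% unlist(primed_idx))
  nxt <- el_slot[reassign] + 1L
  ok <- nxt <= n_slots & slot_chrom[pmin(nxt, n_slots)] == el_chrom[reassign]
  target_gene[reassign[ok]] <- gene_id[nxt[ok]]
  # any element whose designated gene is not its nearest gene must carry
  # a CHi-C link, or the designation would be unrecoverable
  has_chic <- has_chic | target_gene != gene_id[el_slot]
  chic <- data.frame(bait_gene = target_gene[has_chic],
                     chrom = el_chrom[has_chic],
                     start = el_start[has_chic] - 50L,
                     end = el_end[has_chic] + 50L,
                     score = round(stats::runif(sum(has_chic), 1, 10), 3))

  ## ---- openness and activity states per stage -------------------------
  open <- matrix(FALSE, n_el, n_stage, dimnames = list(el_key, stages))
  state <- matrix(NA_character_, n_el, n_stage, dimnames = list(el_key, stages))
  for (t in seq_len(n_trans)) {
    for (i in primed_idx[[t]]) {
      open[i, t:(t + 1L)] <- TRUE
      if (t + 2L <= n_stage)
        for (s in (t + 2L):n_stage)
          open[i, s] <- open[i, s - 1L] &&
            stats::runif(1) < config$persistence_prob
    }
  }
  for (i in active_idx) {
    s0 <- sample(seq_len(n_stage), 1)
    open[i, s0:n_stage] <- TRUE
  }
  for (i in proximal_idx) open[i, ] <- stats::runif(n_stage) < 0.7
  # a subset of background elements is open but reporter-negative
  bg <- which(roles == "background")
  for (i in bg[seq_len(length(bg) %/% 2)])
    open[i, sample(seq_len(n_stage), sample(1:2, 1))] <- TRUE
  reporter_pos <- roles != "background"
  for (i in which(reporter_pos)) {
    st <- sample(c("High", "Low"), n_stage, replace = TRUE)
    state[i, open[i, ]] <- st[open[i, ]]
  }

  ## ---- per-stage ATAC peaks (jittered per stage) ----------------------
  peak_paths <- character(0)
  for (s in seq_len(n_stage)) {
    sel <- which(open[, s])
    jit <- sample(-50:50, length(sel), replace = TRUE)
    peaks <- gi(el_chrom[sel], el_start[sel] + jit,
                el_end[sel] + sample(-50:50, length(sel), replace = TRUE))
    p <- file.path(out_dir, sprintf("peaks_%s.bed", stages[s]))
    write_bed(peaks, p)
    peak_paths <- c(peak_paths, p)
  }

  ## ---- fragment libraries ---------------------------------------------
  # plasmid pool: pool_size distinct fragments per element (all elements)
  pool <- vector("list", n_el)
  for (i in seq_len(n_el)) {
    fs <- el_start[i] - 100L + sample(0:300, config$pool_size * 2, replace = TRUE)
    fl <- sample(150:350, config$pool_size * 2, replace = TRUE)
    df <- unique(data.frame(chrom = el_chrom[i], start = fs, end = fs + fl,
                            stringsAsFactors = FALSE))
    pool[[i]] <- df[seq_len(min(config$pool_size, nrow(df))), , drop = FALSE]
  }
  plasmid <- do.call(rbind, pool)
  plasmid <- plasmid[!duplicated(plasmid), , drop = FALSE]
  # artefact fragments are length 97, so never coordinate-identical to a
  # pool fragment (pool lengths are 150-350)
  rand_frag <- function(n) {
    if (n == 0)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    ch <- sample(config$n_chromosomes, n, replace = TRUE)
    st <- sample(config$chrom_length - 200L, n, replace = TRUE)
    data.frame(chrom = paste0("chr", ch), start = st, end = st + 97L,
               stringsAsFactors = FALSE)
  }
  neg <- rand_frag(50)
  n_contam <- round(config$negative_contamination_rate * nrow(plasmid))
  if (n_contam > 0)
    neg <- rbind(neg, plasmid[sample(nrow(plasmid), n_contam), ])
  frag_paths <- c(plasmid = file.path(out_dir, "frags_plasmid.bed"),
                  negative = file.path(out_dir, "frags_negative.bed"))
  write_bed(gi(plasmid$chrom, plasmid$start, plasmid$end), frag_paths["plasmid"])
  write_bed(gi(neg$chrom, neg$start, neg$end), frag_paths["negative"])
  for (s in seq_len(n_stage)) {
    hi <- list(); lo <- list()
    for (i in which(reporter_pos & open[, s])) {
      draw <- pool[[i]][sample(nrow(pool[[i]]),
                               min(config$frags_per_element,
                                   nrow(pool[[i]]))), , drop = FALSE]
      p_hi <- if (state[i, s] == "High") config$high_ratio else 1 - config$high_ratio
      to_hi <- stats::runif(nrow(draw)) < p_hi
      hi[[length(hi) + 1L]] <- draw[to_hi, , drop = FALSE]
      lo[[length(lo) + 1L]] <- draw[!to_hi, , drop = FALSE]
    }
    hi <- do.call(rbind, c(hi, list(rand_frag(0))))
    lo <- do.call(rbind, c(lo, list(rand_frag(0))))
    n_art <- round(config$artefact_rate * (nrow(hi) + nrow(lo)) / 2)
    if (n_art > 0) {
      hi <- rbind(hi, rand_frag(n_art))
      lo <- rbind(lo, rand_frag(n_art))
    }
    ph <- file.path(out_dir, sprintf("frags_high_%s.bed", stages[s]))
    pl <- file.path(out_dir, sprintf("frags_low_%s.bed", stages[s]))
    write_bed(gi(hi$chrom, hi$start, hi$end), ph)
    write_bed(gi(lo$chrom, lo$start, lo$end), pl)
    frag_paths <- c(frag_paths, stats::setNames(c(ph, pl),
      paste0(c("high_", "low_"), stages[s])))
  }

  ## ---- TF catalog and annotation flags --------------------------------
  fams <- c("RUNX", "GATA", "ETS", "SOX", "SMAD", "TEAD")
  tf_slots <- (n_el + 1L):(n_el + 2L * length(fams))
  tf_gene <- gene_id[tf_slots]
  tf_family_of <- rep(fams, each = 2)
  # family expression profiles (CPM) over stages: most constitutive,
  # RUNX switches on at HE, TEAD switches off after HB
  fam_profile <- list(RUNX = c(1, 1, 50, 50), GATA = c(50, 50, 50, 50),
                      ETS = c(50, 50, 50, 50), SOX = c(50, 50, 50, 50),
                      SMAD = c(50, 50, 50, 50), TEAD = c(50, 50, 1, 1))
  pwms <- .builtin_pwms()
  tf_catalog <- data.frame(
    motif_id = vapply(pwms, `[[`, "", "motif_id"),
    tf_family = vapply(pwms, `[[`, "", "tf_family"),
    members = vapply(vapply(pwms, `[[`, "", "tf_family"), function(f)
      paste(tf_gene[tf_family_of == f], collapse = ","), ""),
    stringsAsFactors = FALSE)

  is_tf <- gene_id %in% tf_gene
  # flag a quarter of each transition's primed target genes as
  # TF-encoding so the primed-TF-gene count is exercised
  for (t in seq_len(n_trans)) {
    tg <- unique(target_gene[primed_idx[[t]]])
    is_tf[match(tg[seq_len(max(1L, length(tg) %/% 4))], gene_id)] <- TRUE
  }
  genes <- gene_annotation(gene_id, slot_chrom, gene_start, gene_end,
                           gene_tss, strand = "+",
                           symbol = gene_id, is_tf = is_tf)
  write_genes(genes, file.path(out_dir, "genes.tsv"))

  ## ---- expression counts ----------------------------------------------
  cpm_profile <- matrix(0.5, n_slots, n_stage,
                        dimnames = list(gene_id, stages))
  bg_expressed <- setdiff(which(stats::runif(n_slots) < 0.5),
                          c(unlist(lapply(primed_idx, function(i)
                            match(target_gene[i], gene_id))), tf_slots))
  cpm_profile[bg_expressed, ] <- config$cpm_background
  for (t in seq_len(n_trans)) {
    gidx <- match(unique(target_gene[primed_idx[[t]]]), gene_id)
    cpm_profile[gidx, seq_len(t)] <- config$cpm_silent
    cpm_profile[gidx, (t + 1L):n_stage] <- config$cpm_active
  }
  cpm_profile[match(target_gene[active_idx], gene_id), ] <- config$cpm_background
  for (j in seq_along(tf_slots))
    cpm_profile[tf_slots[j], ] <- fam_profile[[tf_family_of[j]]]
  # filler housekeeping genes absorb the rest of the library so that the
  # realized CPM of every other gene matches its nominal profile
  filler_slots <- (max(tf_slots) + 1L):(max(tf_slots) + n_filler)
  for (s in seq_len(n_stage)) {
    rest <- 1e6 - sum(cpm_profile[-filler_slots, s])
    if (rest <= 0) stop("infeasible config: CPM profiles exceed 1e6")
    cpm_profile[filler_slots, s] <- rest / n_filler
  }

  mu <- cpm_profile * config$lib_size / 1e6
  counts <- matrix(0L, n_slots, n_stage * config$replicates,
                   dimnames = list(gene_id, paste0(
                     rep(stages, each = config$replicates), "_rep",
                     rep(seq_len(config$replicates), n_stage))))
  for (s in seq_len(n_stage))
    for (r in seq_len(config$replicates))
      counts[, (s - 1L) * config$replicates + r] <-
        stats::rnbinom(n_slots, mu = mu[, s], size = 1 / config$dispersion)
  write_expression(counts, file.path(out_dir, "counts.tsv"))

  ## ---- CHi-C links -----------------------------------------------------
  utils::write.table(chic, file.path(out_dir, "chic_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- element sequences with planted motifs ---------------------------
  consensus_of <- function(p) {
    paste(rownames(p$matrix)[apply(p$matrix, 2, which.max)], collapse = "")
  }
  cons <- vapply(pwms, consensus_of, "")
  names(cons) <- vapply(pwms, `[[`, "", "motif_id")
  fam_of_motif <- stats::setNames(vapply(pwms, `[[`, "", "tf_family"),
                                  names(cons))
  seqs <- character(n_el)
  truth_motifs <- list()
  for (i in seq_len(n_el)) {
    s <- .rand_dna(config$element_length)
    if (reporter_pos[i]) {
      planted <- sample(names(cons), config$motif_per_element)
      pos0 <- 20L
      for (mid in planted) {
        ins <- cons[[mid]]
        if (stats::runif(1) < 0.5) ins <- .revcomp(ins)
        substr(s, pos0, pos0 + nchar(ins) - 1L) <- ins
        pos0 <- pos0 + nchar(ins) + 15L
        truth_motifs[[length(truth_motifs) + 1L]] <- data.frame(
          element = el_key[i], motif_id = mid, stringsAsFactors = FALSE)
      }
    }
    seqs[i] <- s
  }
  names(seqs) <- el_key
  write_element_fasta(seqs, file.path(out_dir, "elements.fasta"))
  write_pwms(pwms, file.path(out_dir, "pwms.txt"))
  utils::write.table(tf_catalog, file.path(out_dir, "tf_catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- VEGF condition peak sets and per-condition expression ----------
  he_t <- n_trans                   # the HE -> HP transition index
  he_primed <- primed_idx[[he_t]]
  n_resp <- round(config$vegf_responsive_fraction * length(he_primed))
  resp <- he_primed[seq_len(n_resp)]
  vegf_paths <- character(0)
  for (s in c("HE", "HP")) {
    si <- match(s, stages)
    open_now <- which(open[, si])
    mv <- open_now                          # all open elements, -VEGF
    ac <- setdiff(open_now, resp)           # responsive ones need VEGF gone
    for (cond in c("minus_vegf", "all_cytokines")) {
      sel <- if (cond == "minus_vegf") mv else ac
      p <- file.path(out_dir, sprintf("vegf_%s_%s.bed", s, cond))
      write_bed(gi(el_chrom[sel], el_start[sel], el_end[sel]), p)
      vegf_paths <- c(vegf_paths, p)
    }
  }
  resp_genes <- unique(target_gene[resp])
  other <- setdiff(rownames(counts), resp_genes)
  vegf_expr <- function(up) {
    m <- matrix(stats::rnbinom(n_slots * config$replicates,
                               mu = rep(mu[, match("HP", stages)],
                                        config$replicates),
                               size = 1 / config$dispersion),
                n_slots, config$replicates,
                dimnames = list(gene_id, paste0("HP_rep",
                                                seq_len(config$replicates))))
    if (!up) m[resp_genes, ] <-
        stats::rnbinom(length(resp_genes) * config$replicates,
                       mu = config$cpm_silent * config$lib_size / 1e6,
                       size = 1 / config$dispersion)
    m
  }
  write_expression(vegf_expr(TRUE), file.path(out_dir, "counts_minus_vegf.tsv"))
  write_expression(vegf_expr(FALSE), file.path(out_dir, "counts_plus_vegf.tsv"))

  ## ---- eRNA counts: transcription follows gene activation --------------
  erna_mu <- matrix(1, n_el, n_stage, dimnames = list(el_key, stages))
  for (t in seq_len(n_trans))
    for (i in primed_idx[[t]])
      erna_mu[i, (t + 1L):n_stage] <- 40
  erna_mu[active_idx, ] <- 30
  erna <- matrix(stats::rpois(n_el * n_stage, erna_mu), n_el, n_stage,
                 dimnames = list(el_key, stages))
  df <- data.frame(element = rownames(erna), erna, check.names = FALSE)
  utils::write.table(df, file.path(out_dir, "erna_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- ChIP-style feature peak sets (no class difference planted) ------
  feat_prev <- c(H3K27ac = 0.7, H3K27me3 = 0.3, PolII = 0.5)
  for (f in names(feat_prev)) {
    sel <- which(stats::runif(n_el) < feat_prev[[f]])
    write_bed(gi(el_chrom[sel], pmax(el_start[sel] - 200L, 0L),
                 el_end[sel] + 200L),
              file.path(out_dir, "features", paste0(f, ".bed")))
  }

  ## ---- truth tables -----------------------------------------------------
  truth_primed <- do.call(rbind, lapply(seq_len(n_trans), function(t) {
    idx <- primed_idx[[t]]
    data.frame(transition = paste0(stages[t], ">", stages[t + 1L]),
               element = el_key[idx], chrom = el_chrom[idx],
               start = el_start[idx], end = el_end[idx],
               gene_id = target_gene[idx], stringsAsFactors = FALSE)
  }))
  truth_states <- do.call(rbind, lapply(seq_len(n_stage), function(s) {
    data.frame(element = el_key, chrom = el_chrom, start = el_start,
               end = el_end, stage = stages[s], open = open[, s],
               reporter_positive = reporter_pos & open[, s],
               state = state[, s], stringsAsFactors = FALSE)
  }))
  truth_vegf <- data.frame(element = el_key[he_primed],
                           chrom = el_chrom[he_primed],
                           start = el_start[he_primed],
                           end = el_end[he_primed],
                           responsive = he_primed %in% resp,
                           stringsAsFactors = FALSE)
  truth_motifs <- if (length(truth_motifs)) do.call(rbind, truth_motifs)
    else data.frame(element = character(0), motif_id = character(0))
  truth_tf <- do.call(rbind, lapply(seq_len(n_stage), function(s)
    data.frame(stage = stages[s], tf_family = fams,
               expressed = vapply(fams, function(f)
                 fam_profile[[f]][s] >= config$expr_threshold, logical(1)),
               stringsAsFactors = FALSE)))
  tw <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tw(truth_primed, "truth_primed.tsv")
  tw(truth_states, "truth_states.tsv")
  tw(truth_vegf, "truth_vegf.tsv")
  tw(truth_motifs, "truth_motifs.tsv")
  tw(truth_tf, "truth_tf_expressed.tsv")
  cfg_out <- unclass(config)
  yaml::write_yaml(cfg_out, file.path(out_dir, "sim_config.yaml"))

  invisible(list(
    truth = list(primed = truth_primed, states = truth_states,
                 vegf = truth_vegf, motifs = truth_motifs,
                 tf_expressed = truth_tf),
    elements = gi(el_chrom, el_start, el_end, element_id = el_key,
                  role = roles, target_gene = target_gene),
    paths = list(dir = out_dir, peaks = peak_paths, frags = frag_paths,
                 vegf = vegf_paths)))
}

#' Confusion metrics of predicted vs ground-truth key sets
#'
#' @param predicted character vector of predicted item keys.
#' @param truth character vector of true item keys.
#' @return list: `tp`, `fp`, `fn`, `precision` (NA when nothing was
#'   predicted), `recall`.
#' @export
evaluate_calls <- function(predicted, truth) {
  predicted <- unique(predicted)
  truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

#' Map pipeline element ids onto planted truth elements by overlap
#'
#' Merged reference elements carry ids assigned in coordinate order;
#' ground-truth tables identify planted elements by their coordinate
#' span.  This maps each pipeline element to the planted element it
#' overlaps (NA when none).
#'
#' @param elements element table from [merge_elements()].
#' @param truth_elements data.frame with `element`, `chrom`, `start`,
#'   `end` columns (any truth table).
#' @return named character vector: pipeline `element_id` -> truth
#'   element key.
#' @export
map_elements_to_truth <- function(elements, truth_elements) {
  te <- unique(truth_elements[, c("element", "chrom", "start", "end")])
  ov <- find_overlaps(elements, gi(te$chrom, te$start, te$end))
  out <- stats::setNames(rep(NA_character_, nrow(elements)),
                         elements$element_id)
  out[ov$query] <- te$element[ov$subject]
  out
}
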