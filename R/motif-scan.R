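#' Log-odds score matrix of a PWM
#'
#' `score[b, i] = log2(p[b, i] / background[b])`, in bits, with
#' probabilities floored at 1e-3 before the log so zero-probability cells
#' cannot produce -Inf.
#'
#' @param pwm a `pwm` object (see [read_pwms()]).
#' @param background base frequencies over A, C, G, T; strictly positive
#'   and summing to 1 (default uniform).
#' @return 4 x L numeric matrix (rows A/C/G/T), with attribute
#'   `"max_score"` = sum over positions of the per-position maximum.
#' @export
log_odds_matrix <- function(pwm, background = rep(0.25, 4)) {
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 positive frequencies summing to 1")
  p <- pmax(pwm$matrix, 1e-3)
  s <- log2(p / background)
  attr(s, "max_score") <- sum(apply(s, 2, max))
  s
}

# internal: default threshold = fraction of the maximum achievable score
.pwm_threshold <- function(pwm, background, frac = 0.8) {
  if (!is.na(pwm$threshold)) return(pwm$threshold)
  frac * attr(log_odds_matrix(pwm, background), "max_score")
}

# internal: score every window of seq (index vector, N = 0 contribution)
.scan_one_strand <- function(idx, lom) {
  w <- ncol(lom)
  L <- length(idx)
  if (L < w) return(numeric(0))
  nwin <- L - w + 1L
  scores <- numeric(nwin)
  # row 0 in idx means N: contributes 0 (scores as background)
  for (j in seq_len(w)) {
    b <- idx[j:(j + nwin - 1L)]
    sc <- ifelse(b == 0L, 0, lom[cbind(pmax(b, 1L), j)])
    scores <- scores + sc
  }
  scores
}

.BASE_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)
.COMP_IDX <- c(A = 4L, C = 3L, G = 2L, T = 1L, N = 0L)

#' Scan a DNA sequence with a PWM on both strands
#'
#' Every window on the forward strand and on the reverse complement is
#' scored by summed log-odds; `N` bases contribute 0 (i.e. score as
#' background).  Hits are windows scoring at or above the motif
#' threshold (default: 0.8 x the maximum achievable score, see
#' [log_odds_matrix()]).  Reverse-strand hits are reported at the
#' forward-strand coordinate of the window start.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param pwm a `pwm` object.
#' @param background base frequencies (default uniform).
#' @param threshold overrides the motif's threshold when given.
#' @return data.frame of hits: `position` (0-based window start on the
#'   forward strand), `strand`, `score`; empty when the sequence is
#'   shorter than the motif.
#' @export
scan_sequence <- function(seq, pwm, background = rep(0.25, 4),
                          threshold = NULL) {
  lom <- log_odds_matrix(pwm, background)
  if (is.null(threshold)) threshold <- .pwm_threshold(pwm, background)
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- !chars %in% names(.BASE_IDX)
  if (any(bad)) stop("sequence contains non-ACGTN character(s): ",
                     paste(unique(chars[bad]), collapse = ""))
  idx <- unname(.BASE_IDX[chars])
  w <- ncol(lom)
  L <- length(idx)
  if (L < w)
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  fwd <- .scan_one_strand(idx, lom)
  # reverse strand: score the reverse complement, then map window starts
  # back to forward coordinates
  ridx <- rev(unname(.COMP_IDX[chars]))
  rev_sc <- .scan_one_strand(ridx, lom)
  nwin <- L - w + 1L
  hits_f <- which(fwd >= threshold)
  hits_r <- which(rev_sc >= threshold)
  out <- data.frame(
    position = c(hits_f - 1L, (nwin - hits_r + 1L) - 1L),
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    score = c(fwd[hits_f], rev_sc[hits_r]))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of element sequences with a set of PWMs
#'
#' @param seqs named character vector of element sequences (names are
#'   element/peak ids).
#' @param pwms list of `pwm` objects.
#' @param background base frequencies.
#' @return data.frame of hits: `peak_id`, `motif_id`, `position`,
#'   `strand`, `score`.
#' @export
scan_elements <- function(seqs, pwms, background = rep(0.25, 4)) {
  res <- list()
  for (p in pwms) {
    for (id in names(seqs)) {
      h <- scan_sequence(seqs[[id]], p, background)
      if (nrow(h))
        res[[length(res) + 1L]] <- data.frame(
          peak_id = id, motif_id = p$motif_id, h,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(peak_id = character(0), motif_id = character(0),
                      position = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Binary element x motif annotation matrix
#'
#' Entry 1 iff the element has at least one hit of the motif at the
#' motif's threshold.
#'
#' @param seqs named character vector of element sequences; every
#'   element id in `element_ids` must be present.
#' @param pwms list of `pwm` objects.
#' @param element_ids which elements to annotate (default: all in
#'   `seqs`).
#' @param background base frequencies.
#' @return binary integer matrix, elements x motifs.
#' @export
annotate_elements <- function(seqs, pwms, element_ids = names(seqs),
                              background = rep(0.25, 4)) {
  miss <- setdiff(element_ids, names(seqs))
  if (length(miss))
    stop("missing sequence for element(s): ", paste(miss, collapse = ", "))
  m <- matrix(0L, nrow = length(element_ids), ncol = length(pwms),
              dimnames = list(element_ids,
                              vapply(pwms, `[[`, "", "motif_id")))
  hits <- scan_elements(seqs[element_ids], pwms, background)
  if (nrow(hits))
    m[cbind(hits$peak_id, hits$motif_id)] <- 1L
  m
}
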