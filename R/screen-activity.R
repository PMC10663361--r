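#' Filter enhancer-screen fragments
#'
#' The three-step artefact filter applied to sorted screen libraries
#' before any activity calling, in this order:
#' \enumerate{
#'   \item drop fragments coordinate-identical to any negative-control
#'     fragment (PCR artefacts from cells without a reporter cassette);
#'   \item keep only fragments coordinate-identical to some plasmid
#'     library fragment (the fragment must have existed in the
#'     transfected library);
#'   \item keep only fragments overlapping at least one ATAC peak.
#' }
#' "Identical" means exact chrom/start/end equality up to `slop` bp on
#' each coordinate (default 0, exact uniq-style matching).
#'
#' @param screen fragment table (sorted high/low screen library).
#' @param negatives negative-control fragment table.
#' @param plasmid plasmid-library fragment table; must be non-empty
#'   (an empty plasmid library would silently erase everything).
#' @param atac_peaks interval table of open-chromatin peaks.
#' @param slop coordinate tolerance in bp for "identical fragment".
#' @return the retained fragment table, with attribute `"removed"`
#'   (named integer vector of removals per step).
#' @export
filter_fragments <- function(screen, negatives, plasmid, atac_peaks,
                             slop = 0L) {
  if (!nrow(plasmid))
    stop("empty plasmid library: the plasmid-identity filter would remove every fragment")
  n0 <- nrow(screen)
  in_neg <- .frag_match(screen, negatives, slop)
  screen <- screen[!in_neg, , drop = FALSE]
  n1 <- nrow(screen)
  in_plasmid <- .frag_match(screen, plasmid, slop)
  screen <- screen[in_plasmid, , drop = FALSE]
  n2 <- nrow(screen)
  in_peak <- .overlaps_any(screen, atac_peaks)
  screen <- screen[in_peak, , drop = FALSE]
  rownames(screen) <- NULL
  class(screen) <- c("genomic_intervals", "data.frame")
  attr(screen, "removed") <- c(negative_control = n0 - n1,
                               not_in_plasmid = n1 - n2,
                               no_atac_peak = n2 - nrow(screen))
  screen
}

# internal: which rows of x have an (near-)identical fragment in ref
.frag_match <- function(x, ref, slop = 0L) {
  if (!nrow(x)) return(logical(0))
  if (!nrow(ref)) return(rep(FALSE, nrow(x)))
  if (slop == 0) {
    key <- function(d) paste(d$chrom, d$start, d$end)
    key(x) %in% key(ref)
  } else {
    vapply(seq_len(nrow(x)), function(i) {
      any(ref$chrom == x$chrom[i] &
            abs(ref$start - x$start[i]) <= slop &
            abs(ref$end - x$end[i]) <= slop)
    }, logical(1))
  }
}

#' Call per-peak enhancer positivity
#'
#' A peak is enhancer-positive if at least one retained (filtered) screen
#' fragment overlaps it.
#'
#' @param atac_peaks interval table of peaks; a `peak_id` column is used
#'   when present, otherwise ids `peak_1..n` are assigned.
#' @param retained_fragments output of [filter_fragments()] (high and low
#'   libraries combined).
#' @return logical vector, one element per peak, named by peak id.
#' @export
call_enhancer_positive <- function(atac_peaks, retained_fragments) {
  ids <- if ("peak_id" %in% names(atac_peaks)) atac_peaks$peak_id
         else paste0("peak_", seq_len(nrow(atac_peaks)))
  pos <- .overlaps_any(atac_peaks, retained_fragments)
  names(pos) <- ids
  pos
}

#' Assign High/Low activity states to enhancer-positive peaks
#'
#' Per positive peak, fragments from the high- and low-fluorescence
#' sorted libraries are counted, normalized to fragments-per-million of
#' the respective library, and the state set by the normalized ratio:
#' `High` if `norm_high / norm_low > activity_ratio` (default 1), `Low`
#' otherwise.  An exact tie at the boundary is called `Low`, biasing
#' against over-calling strong enhancers.  Peaks with no overlapping
#' fragment are `NotPositive`.
#'
#' @param atac_peaks interval table of peaks (optionally with `peak_id`).
#' @param high_frags,low_frags retained fragments of the sorted-high and
#'   sorted-low libraries.
#' @param total_high_library,total_low_library total fragment counts of
#'   the two libraries (before peak filtering), used as normalization
#'   denominators; must be positive.
#' @param stage stage label recorded in the output.
#' @param activity_ratio decision boundary on `norm_high / norm_low`.
#' @return a data.frame of enhancer calls: `peak_id`, `stage`,
#'   `positive`, `n_high`, `n_low`, `norm_high`, `norm_low`, `state`.
#' @export
assign_activity_state <- function(atac_peaks, high_frags, low_frags,
                                  total_high_library, total_low_library,
                                  stage = NA_character_,
                                  activity_ratio = 1.0) {
  if (total_high_library <= 0 || total_low_library <= 0)
    stop("library totals must be positive")
  ids <- if ("peak_id" %in% names(atac_peaks)) atac_peaks$peak_id
         else paste0("peak_", seq_len(nrow(atac_peaks)))
  n_high <- .count_overlaps(atac_peaks, high_frags)
  n_low <- .count_overlaps(atac_peaks, low_frags)
  norm_high <- 1e6 * n_high / total_high_library
  norm_low <- 1e6 * n_low / total_low_library
  positive <- (n_high + n_low) >= 1
  state <- ifelse(!positive, "NotPositive",
                  ifelse(norm_high > activity_ratio * norm_low, "High", "Low"))
  data.frame(peak_id = ids, stage = stage, positive = positive,
             n_high = n_high, n_low = n_low,
             norm_high = norm_high, norm_low = norm_low,
             state = state, stringsAsFactors = FALSE)
}

# internal: per-query overlap counts
.count_overlaps <- function(queries, subjects) {
  if (!nrow(queries)) return(integer(0))
  if (!nrow(subjects)) return(rep(0L, nrow(queries)))
  suppressWarnings(
    GenomicRanges::countOverlaps(.as_granges(queries), .as_granges(subjects),
                                 ignore.strand = TRUE))
}

#' Run the full per-stage screen: filter, call, assign states
#'
#' Convenience wrapper chaining [filter_fragments()] (separately for the
#' high and low sorted libraries), [call_enhancer_positive()] and
#' [assign_activity_state()] for one stage.
#'
#' @param atac_peaks stage peak table.
#' @param high,low sorted high-/low-library fragment tables (raw).
#' @param negatives,plasmid control libraries.
#' @param stage stage label.
#' @param activity_ratio see [assign_activity_state()].
#' @return enhancer-call data.frame as from [assign_activity_state()].
#' @export
screen_stage <- function(atac_peaks, high, low, negatives, plasmid,
                         stage = NA_character_, activity_ratio = 1.0) {
  high_f <- filter_fragments(high, negatives, plasmid, atac_peaks)
  low_f <- filter_fragments(low, negatives, plasmid, atac_peaks)
  assign_activity_state(atac_peaks, high_f, low_f,
                        total_high_library = max(nrow(high), 1L),
                        total_low_library = max(nrow(low), 1L),
                        stage = stage, activity_ratio = activity_ratio)
}
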