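#' Binary feature matrix over elements
#'
#' One row per element, one column per feature: ChIP/histone features
#' score 1 when the element overlaps at least one interval of that peak
#' set; motif columns are appended unchanged from the motif annotation
#' matrix.
#'
#' @param elements interval table with `element_id`.
#' @param feature_peak_sets named list (feature name -> interval table)
#'   of ChIP/histone peak sets.
#' @param motif_matrix optional binary element x motif matrix; its rows
#'   are matched to `elements$element_id` (elements without a row get
#'   zero motif columns).
#' @param class optional per-element class labels (`"primed"` /
#'   `"active_enhancer"`), attached as the `"class"` attribute.
#' @return binary integer matrix, elements x features, with attribute
#'   `"class"` when given.
#' @export
build_feature_matrix <- function(elements, feature_peak_sets,
                                 motif_matrix = NULL, class = NULL) {
  if (!nrow(elements)) stop("empty element set")
  if (any(names(feature_peak_sets) %in% colnames(motif_matrix)))
    stop("feature names collide with motif ids")
  if (length(feature_peak_sets)) {
    chip <- vapply(feature_peak_sets, function(p)
      as.integer(.overlaps_any(elements, p)), integer(nrow(elements)))
    if (is.null(dim(chip)))
      chip <- matrix(chip, nrow = nrow(elements),
                     dimnames = list(NULL, names(feature_peak_sets)))
  } else {
    chip <- matrix(integer(0), nrow = nrow(elements), ncol = 0)
  }
  rownames(chip) <- elements$element_id
  out <- chip
  if (!is.null(motif_matrix)) {
    mm <- matrix(0L, nrow = nrow(elements), ncol = ncol(motif_matrix),
                 dimnames = list(elements$element_id, colnames(motif_matrix)))
    common <- intersect(elements$element_id, rownames(motif_matrix))
    mm[common, ] <- motif_matrix[common, , drop = FALSE]
    out <- cbind(out, mm)
  }
  storage.mode(out) <- "integer"
  if (!is.null(class)) {
    stopifnot(length(class) == nrow(elements))
    attr(out, "class_label") <- stats::setNames(class, elements$element_id)
  }
  out
}

#' Per-feature percentage within an element class
#'
#' 100 x the column mean of the binary matrix over the elements of one
#' class.
#'
#' @param matrix feature matrix from [build_feature_matrix()] (with a
#'   class attribute) or any binary matrix.
#' @param class which class to profile; ignored when the matrix has no
#'   class attribute (all rows used).
#' @return named numeric vector of percentages.
#' @export
feature_proportions <- function(matrix, class = NULL) {
  rows <- seq_len(nrow(matrix))
  if (!is.null(class)) {
    lab <- attr(matrix, "class_label")
    if (is.null(lab)) stop("matrix carries no class labels")
    if (!class %in% lab) stop("unknown or empty class: ", class)
    rows <- which(lab == class)
  }
  100 * colMeans(matrix[rows, , drop = FALSE])
}

#' Regression of primed-class on active-class feature percentages
#'
#' Ordinary least squares of y on x over the feature points, as used to
#' ask whether any molecular feature separates primed from active
#' enhancers (a slope near 1 with high R-squared means none does).
#'
#' @param x active-enhancer feature percentages.
#' @param y primed-element feature percentages (same features, same
#'   order).
#' @return list with `slope`, `intercept`, `r_squared` and `p_slope`
#'   (two-sided, t distribution with n - 2 df).
#' @export
proportion_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need >= 3 feature points")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exactly collinear input; the fit itself is valid
  co <- suppressWarnings(summary(fit))$coefficients
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(co["x", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       r_squared = r2,
       p_slope = unname(co["x", "Pr(>|t|)"]))
}
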