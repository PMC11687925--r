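#' Gray-level histogram of an image
#'
#' Tabulates all `L = 2^n` gray levels (including empty bins) and normalizes
#' to probabilities `p_i = counts_i / sum(counts)`.
#'
#' @param image a `gray_image`.
#' @return An object of class `gray_histogram` with fields `counts`, `probs`
#'   (both length `L`) and `levels` (`= L`).
#' @export
compute_histogram <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  L <- gray_levels(image)
  counts <- tabulate(as.vector(image$pixels) + 1L, nbins = L)
  gray_histogram(counts)
}

#' Construct a gray-level histogram from counts or probabilities
#'
#' @param counts non-negative integer vector of per-level counts, or `NULL`
#'   if `probs` is given directly.
#' @param probs optional probability vector; must sum to 1.
#' @return A `gray_histogram`.
#' @export
gray_histogram <- function(counts = NULL, probs = NULL) {
  if (is.null(probs)) {
    stopifnot(is.numeric(counts), all(counts >= 0), sum(counts) > 0)
    probs <- counts / sum(counts)
  } else {
    stopifnot(is.numeric(probs), all(probs >= 0))
    if (abs(sum(probs) - 1) > 1e-12)
      stop("probabilities must sum to 1", call. = FALSE)
    if (is.null(counts)) counts <- rep(NA_integer_, length(probs))
  }
  structure(list(counts = counts, probs = probs,
                 levels = length(probs)),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- sum(x$probs > 0)
  cat(sprintf("<gray_histogram> L = %d levels, %d occupied\n", x$levels, nz))
  invisible(x)
}

#' Export a histogram as a data frame (level, count, prob)
#' @param hist a `gray_histogram`.
#' @return A data.frame with columns `level` (0-based), `count`, `prob`.
#' @export
histogram_table <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  data.frame(level = seq_len(hist$levels) - 1L,
             count = hist$counts, prob = hist$probs)
}

#' Aggregate a histogram to fewer levels
#'
#' Adjacent bins are summed in groups of `L / target_levels`; total
#' probability is conserved. A threshold `t` found on the reduced histogram
#' maps back to the original scale as `t * (L / target_levels)` (left edge),
#' which is how the exhaustive oracle is made tractable at 12-bit depth.
#'
#' @param hist a `gray_histogram`.
#' @param target_levels divisor of `hist$levels`.
#' @return A `gray_histogram` with `target_levels` bins.
#' @export
rebin_histogram <- function(hist, target_levels) {
  stopifnot(inherits(hist, "gray_histogram"))
  target_levels <- as.integer(target_levels)
  L <- hist$levels
  if (target_levels < 1L || L %% target_levels != 0L)
    stop("target_levels must divide the histogram length", call. = FALSE)
  f <- L %/% target_levels
  grp <- rep(seq_len(target_levels), each = f)
  probs <- as.vector(tapply(hist$probs, grp, sum))
  counts <- if (anyNA(hist$counts)) rep(NA_integer_, target_levels)
            else as.vector(tapply(hist$counts, grp, sum))
  out <- gray_histogram(probs = probs / sum(probs))
  out$counts <- counts
  out
}

#' Construct a validated threshold set
#'
#' Thresholds `th_1 < ... < th_n` are strictly increasing integers in
#' `[1, L - 1]`; they partition `[0, L - 1]` into `n + 1` classes with
#' intervals `[th_k, th_{k+1} - 1]` (class 0 starts at 0, the top class is
#' closed at `L - 1`).
#'
#' @param values integer thresholds.
#' @param levels number of gray levels `L`.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(values, levels) {
  values <- as.integer(values)
  levels <- as.integer(levels)
  if (length(values) < 1L) stop("need at least one threshold", call. = FALSE)
  if (any(values < 1L) || any(values > levels - 1L))
    stop("thresholds must lie in [1, L-1]", call. = FALSE)
  if (any(diff(values) <= 0L))
    stop("thresholds must be strictly increasing", call. = FALSE)
  structure(list(values = values, levels = levels), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> {%s} over L = %d\n",
              paste(x$values, collapse = ", "), x$levels))
  invisible(x)
}

# Cumulative sums used by the entropy objective: P[k] = sum p_1..p_k and
# Q[k] = sum p_i*log(p_i) over the same range, with 0*log(0) := 0.
.kapur_cumsums <- function(probs) {
  plogp <- ifelse(probs > 0, probs * log(probs), 0)
  list(P = c(0, cumsum(probs)), Q = c(0, cumsum(plogp)))
}

# Entropy for class boundaries expressed as 0-based [start, end] levels,
# given precomputed cumsums. For class probability w and within-class
# sum S = sum p*log(p):  H = -sum (p/w) log(p/w) = log(w) - S/w.
.kapur_from_cumsums <- function(cs, starts, ends) {
  w <- cs$P[ends + 2L] - cs$P[starts + 1L]
  S <- cs$Q[ends + 2L] - cs$Q[starts + 1L]
  sum(ifelse(w > 0, log(w) - S / w, 0))
}

#' Kapur maximum-entropy objective for a threshold set
#'
#' The Kapur criterion scores a threshold set by the sum over classes of the
#' Shannon entropy (natural log) of the within-class normalized gray-level
#' distribution: for class `k` with probability `w_k = sum of p_i` over its
#' levels, `H_k = -sum (p_i/w_k) ln(p_i/w_k)`. Empty bins contribute 0 and an
#' empty class contributes `H_k = 0`, so the objective stays finite for any
#' threshold placement. Maximizing it spreads information across classes.
#'
#' @param hist a `gray_histogram`.
#' @param thresholds a `threshold_set` (or integer vector, validated against
#'   `hist$levels`).
#' @return Total entropy (non-negative, finite).
#' @export
kapur_entropy <- function(hist, thresholds) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (!inherits(thresholds, "threshold_set"))
    thresholds <- threshold_set(thresholds, hist$levels)
  if (thresholds$levels != hist$levels)
    stop("threshold set and histogram disagree on L", call. = FALSE)
  cs <- .kapur_cumsums(hist$probs)
  th <- thresholds$values
  starts <- c(0L, th)
  ends <- c(th - 1L, hist$levels - 1L)
  .kapur_from_cumsums(cs, starts, ends)
}

#' Fast Kapur-entropy evaluator bound to one histogram
#'
#' Precomputes the cumulative sums once so repeated evaluations inside an
#' optimizer cost O(nTh) each.
#'
#' @param hist a `gray_histogram`.
#' @return `function(th)` taking a sorted integer threshold vector.
#' @export
kapur_objective <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  cs <- .kapur_cumsums(hist$probs)
  L <- hist$levels
  function(th) {
    starts <- c(0L, th)
    ends <- c(th - 1L, L - 1L)
    .kapur_from_cumsums(cs, starts, ends)
  }
}

#' Label pixels by threshold class
#'
#' Pixel value `v` receives class `k` when `th_k <= v <= th_{k+1} - 1`
#' (`th_0 = 0`; the top class is closed at `L - 1`), i.e. classes are the
#' lower-closed intervals between consecutive thresholds.
#'
#' @param image a `gray_image`.
#' @param thresholds a `threshold_set` for the image's `L`.
#' @return Integer matrix of class indices `0..n`, same shape as the image.
#' @export
segment_image <- function(image, thresholds) {
  stopifnot(inherits(image, "gray_image"))
  if (!inherits(thresholds, "threshold_set"))
    thresholds <- threshold_set(thresholds, gray_levels(image))
  if (thresholds$levels != gray_levels(image))
    stop("threshold set and image disagree on L", call. = FALSE)
  labels <- matrix(findInterval(image$pixels, thresholds$values),
                   nrow(image$pixels), ncol(image$pixels))
  storage.mode(labels) <- "integer"
  labels
}

# round-half-up, the rounding convention used for rendering and decoding
.round_half_up <- function(x) floor(x + 0.5)

#' Render a segmented image with one gray value per class
#'
#' Replaces each pixel by a representative value of its class: the rounded
#' (half-up) mean of member pixel values (`class_mean`, default) or the
#' rounded midpoint of the class interval (`class_midpoint`). An empty class
#' under `class_mean` falls back to its midpoint. This rendering is what the
#' full-reference quality metrics compare against the original.
#'
#' @param image a `gray_image`.
#' @param thresholds a `threshold_set`.
#' @param mode `"class_mean"` or `"class_midpoint"`.
#' @return A `gray_image` with the same bit depth.
#' @export
render_segmented <- function(image, thresholds,
                             mode = c("class_mean", "class_midpoint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "gray_image"))
  if (!inherits(thresholds, "threshold_set"))
    thresholds <- threshold_set(thresholds, gray_levels(image))
  L <- gray_levels(image)
  th <- thresholds$values
  lo <- c(0L, th)
  hi <- c(th - 1L, L - 1L)
  midpoints <- .round_half_up((lo + hi) / 2)
  labels <- segment_image(image, thresholds)
  if (mode == "class_mean") {
    reps <- midpoints
    means <- tapply(as.vector(image$pixels), as.vector(labels), mean)
    idx <- as.integer(names(means)) + 1L
    reps[idx] <- .round_half_up(means)
  } else {
    reps <- midpoints
  }
  gray_image(matrix(reps[labels + 1L], nrow(labels), ncol(labels)),
             image$bit_depth)
}
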