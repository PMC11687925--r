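#' Specification of a Gaussian-mixture synthetic image
#'
#' Synthetic stand-ins for high-bit-depth scans with multimodal histograms:
#' each pixel is an independent draw from a Gaussian mixture, rounded and
#' clipped to the gray range. Mode means/sds are in gray levels; weights
#' must sum to 1. The seed makes generation bit-reproducible.
#'
#' @param means,sds,weights per-mode mean, standard deviation and mixing
#'   weight (equal-length vectors).
#' @param bit_depth image bit depth `n`.
#' @param shape `c(height, width)`.
#' @param seed integer seed.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(means, sds, weights = NULL, bit_depth = 12L,
                         shape = c(256L, 256L), seed = 1L) {
  k <- length(means)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(length(sds) == k, length(weights) == k,
            all(weights > 0), abs(sum(weights) - 1) < 1e-9,
            all(means >= 0), all(means <= 2^bit_depth - 1),
            all(sds >= 0), length(shape) == 2L)
  structure(list(means = means, sds = sds, weights = weights,
                 bit_depth = as.integer(bit_depth),
                 shape = as.integer(shape), seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Generate a synthetic grayscale image from a mixture spec
#'
#' @param spec a `mixture_spec`.
#' @return A `gray_image`; the same spec (same seed) always yields a
#'   bit-identical image.
#' @export
generate_synthetic_image <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  npix <- prod(spec$shape)
  comp <- sample.int(length(spec$weights), npix, replace = TRUE,
                     prob = spec$weights)
  vals <- stats::rnorm(npix, spec$means[comp], spec$sds[comp])
  vals <- pmin(pmax(.round_half_up(vals), 0), 2^spec$bit_depth - 1)
  gray_image(matrix(vals, spec$shape[1], spec$shape[2]), spec$bit_depth)
}

#' Analytic CDF of a mixture spec at gray value x
#' @param spec a `mixture_spec`.
#' @param x numeric vector of gray values.
#' @return Mixture CDF values (before rounding/clipping).
#' @export
mixture_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "mixture_spec"))
  out <- numeric(length(x))
  for (j in seq_along(spec$weights))
    out <- out + spec$weights[j] * stats::pnorm(x, spec$means[j], spec$sds[j])
  out
}

#' Exhaustive search for the optimal Kapur thresholds
#'
#' Enumerates every strictly increasing threshold tuple in `[1, L - 1]` and
#' returns the one maximizing Kapur entropy — the certified global optimum
#' that stochastic optimizers are validated against. Refuses when the
#' number of tuples `choose(L - 1, nTh)` exceeds `budget_cap`; reduce `L`
#' by [rebin_histogram()] or lower `nTh` in that case. Ties are broken by
#' the lexicographically smallest tuple (enumeration order).
#'
#' @param hist a `gray_histogram`.
#' @param nTh number of thresholds.
#' @param budget_cap maximum number of tuples to enumerate.
#' @return A list with `thresholds` (a `threshold_set`) and `entropy`.
#' @export
exhaustive_optimal_thresholds <- function(hist, nTh, budget_cap = 1e7) {
  stopifnot(inherits(hist, "gray_histogram"))
  L <- hist$levels
  nTh <- as.integer(nTh)
  if (nTh < 1L || nTh > L - 1L)
    stop("nTh must be in [1, L-1]", call. = FALSE)
  n_tuples <- choose(L - 1L, nTh)
  if (n_tuples > budget_cap)
    stop(sprintf(paste0("combinatorial budget exceeded: choose(%d, %d) = %g",
                        " tuples > cap %g; rebin the histogram or lower nTh"),
                 L - 1L, nTh, n_tuples, budget_cap), call. = FALSE)
  obj <- kapur_objective(hist)
  if (nTh == 1L) {
    vals <- vapply(1:(L - 1L), function(t) obj(t), numeric(1))
    best <- which.max(vals)  # first max = lexicographically smallest
    return(list(thresholds = threshold_set(best, L),
                entropy = vals[best]))
  }
  if (nTh == 2L) return(.exhaustive_pairs(hist))
  combos <- utils::combn(L - 1L, nTh)
  vals <- apply(combos, 2L, obj)
  best <- which.max(vals)
  list(thresholds = threshold_set(combos[, best], L), entropy = vals[best])
}

# Exact pair enumeration, vectorized over the second threshold so the
# full 12-bit search (choose(4095, 2) ~ 8.4M tuples) stays fast. The outer
# loop ascends t1 and strict improvement is required, so ties resolve to
# the lexicographically smallest tuple exactly as in the generic path.
.exhaustive_pairs <- function(hist) {
  L <- hist$levels
  cs <- .kapur_cumsums(hist$probs)
  P <- cs$P; Q <- cs$Q
  class_H <- function(w, S) ifelse(w > 0, log(w) - S / w, 0)
  t_all <- 1:(L - 1L)
  # first class [0, t-1] and last class [t, L-1] depend on one threshold
  H_first <- class_H(P[t_all + 1L], Q[t_all + 1L])
  H_last <- class_H(P[L + 1L] - P[t_all + 1L], Q[L + 1L] - Q[t_all + 1L])
  best_val <- -Inf
  best_pair <- c(1L, 2L)
  for (t1 in 1:(L - 2L)) {
    t2 <- (t1 + 1L):(L - 1L)
    w_mid <- P[t2 + 1L] - P[t1 + 1L]
    S_mid <- Q[t2 + 1L] - Q[t1 + 1L]
    total <- H_first[t1] + class_H(w_mid, S_mid) + H_last[t2]
    j <- which.max(total)
    if (total[j] > best_val) {
      best_val <- total[j]
      best_pair <- c(t1, t2[j])
    }
  }
  list(thresholds = threshold_set(best_pair, L), entropy = best_val)
}

#' Map thresholds found on a rebinned histogram back to the original scale
#'
#' Uses the left-edge convention: a reduced-scale threshold `t` becomes
#' `t * (L / target_levels)` on the original scale.
#'
#' @param thresholds a `threshold_set` on the reduced histogram.
#' @param L original number of levels.
#' @return A `threshold_set` on the original scale.
#' @export
upscale_thresholds <- function(thresholds, L) {
  stopifnot(inherits(thresholds, "threshold_set"))
  f <- L %/% thresholds$levels
  threshold_set(thresholds$values * f, L)
}
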