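#' Peak signal-to-noise ratio between an image and its segmented rendering
#'
#' `PSNR = 20 * log10(MAX / sqrt(MSE))` in dB, where `MSE` is the mean
#' squared pixel difference. The default peak follows the thresholding
#' literature's convention `MAX = 2^n` for an `n`-bit image;
#' `peak = "pow2m1"` selects the conventional `2^n - 1`. Identical images
#' (`MSE = 0`) return `Inf`.
#'
#' @param original,segmented `gray_image`s of equal shape and bit depth.
#' @param peak `"pow2"` (default) or `"pow2m1"`.
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
psnr <- function(original, segmented, peak = c("pow2", "pow2m1")) {
  peak <- match.arg(peak)
  .check_pair(original, segmented)
  mse <- mean((as.numeric(original$pixels) - as.numeric(segmented$pixels))^2)
  if (mse == 0) return(Inf)
  mx <- if (peak == "pow2") 2^original$bit_depth else 2^original$bit_depth - 1
  20 * log10(mx / sqrt(mse))
}

.check_pair <- function(x, y) {
  stopifnot(inherits(x, "gray_image"), inherits(y, "gray_image"))
  if (!identical(dim(x$pixels), dim(y$pixels)))
    stop("images differ in shape", call. = FALSE)
  if (x$bit_depth != y$bit_depth)
    stop("images differ in bit depth", call. = FALSE)
  invisible(TRUE)
}

# Separable valid-mode correlation with a 1-D kernel, as banded matrices:
# rows of A select windows along image rows, columns of B along columns.
.sep_filter <- function(X, k) {
  w <- length(k)
  m <- nrow(X); n <- ncol(X)
  if (m < w || n < w) stop("image smaller than the filter window",
                           call. = FALSE)
  A <- matrix(0, m - w + 1L, m)
  for (i in seq_len(m - w + 1L)) A[i, i:(i + w - 1L)] <- k
  B <- matrix(0, n, n - w + 1L)
  for (j in seq_len(n - w + 1L)) B[j:(j + w - 1L), j] <- k
  A %*% X %*% B
}

.gaussian_kernel <- function(width = 11L, sigma = 1.5) {
  half <- (width - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Structural similarity index (SSIM)
#'
#' Mean-pooled product of luminance, contrast and structure comparisons
#' (`l * c * s` with unit exponents), using the universal constants
#' `C1 = (0.01 * Dr)^2`, `C2 = (0.03 * Dr)^2`, `C3 = C2 / 2` with dynamic
#' range `Dr = 2^n - 1`. Local statistics use an 11x11 Gaussian window
#' (sigma 1.5, valid-mode); `window = "global"` instead treats the whole
#' image as one window with unweighted population moments, which makes the
#' value reproducible by scalar arithmetic.
#'
#' @param original,segmented `gray_image`s of equal shape and bit depth.
#' @param window `"gaussian"` (default) or `"global"`.
#' @return SSIM in `[-1, 1]`; 1 iff the inputs are identical.
#' @export
ssim <- function(original, segmented, window = c("gaussian", "global")) {
  window <- match.arg(window)
  .check_pair(original, segmented)
  X <- original$pixels * 1.0
  Y <- segmented$pixels * 1.0
  Dr <- 2^original$bit_depth - 1
  C1 <- (0.01 * Dr)^2
  C2 <- (0.03 * Dr)^2
  C3 <- C2 / 2
  if (window == "global") {
    mu_x <- mean(X); mu_y <- mean(Y)
    var_x <- mean(X^2) - mu_x^2
    var_y <- mean(Y^2) - mu_y^2
    cov_xy <- mean(X * Y) - mu_x * mu_y
  } else {
    k <- .gaussian_kernel()
    mu_x <- .sep_filter(X, k); mu_y <- .sep_filter(Y, k)
    var_x <- .sep_filter(X^2, k) - mu_x^2
    var_y <- .sep_filter(Y^2, k) - mu_y^2
    cov_xy <- .sep_filter(X * Y, k) - mu_x * mu_y
  }
  var_x <- pmax(var_x, 0); var_y <- pmax(var_y, 0)
  sd_x <- sqrt(var_x); sd_y <- sqrt(var_y)
  l <- (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1)
  cc <- (2 * sd_x * sd_y + C2) / (var_x + var_y + C2)
  s <- (cov_xy + C3) / (sd_x * sd_y + C3)
  mean(l * cc * s)
}

#' Feature similarity index (FSIM)
#'
#' Combines a log-Gabor phase-congruency map `PC` (local structure) and a
#' Scharr gradient-magnitude map `GM` (local contrast change):
#' `S_PC = (2*PC1*PC2 + T1) / (PC1^2 + PC2^2 + T1)`, `S_GM` analogously with
#' `T2`, `S_L = S_PC * S_GM`, and
#' `FSIM = sum(S_L * PCm) / sum(PCm)` with `PCm = pmax(PC1, PC2)`.
#' Images are linearly rescaled to the 8-bit reference range before the
#' transform so the stabilizers keep their standard values `T1 = 0.85`,
#' `T2 = 160`. Two identical constant images (no structure anywhere) return
#' the defined fallback 1.
#'
#' @param original,segmented `gray_image`s of equal shape and bit depth.
#' @param T1,T2 stabilizing constants for the PC and GM similarity terms.
#' @return FSIM in `[0, 1]`; 1 iff the inputs are identical.
#' @export
fsim <- function(original, segmented, T1 = 0.85, T2 = 160) {
  .check_pair(original, segmented)
  scale <- 255 / (2^original$bit_depth - 1)
  X <- original$pixels * scale
  Y <- segmented$pixels * scale
  if (identical(original$pixels, segmented$pixels) &&
      stats::sd(X) == 0) return(1)
  pc1 <- phase_congruency(X)
  pc2 <- phase_congruency(Y)
  gm1 <- .scharr_magnitude(X)
  gm2 <- .scharr_magnitude(Y)
  s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  s_gm <- (2 * gm1 * gm2 + T2) / (gm1^2 + gm2^2 + T2)
  pcm <- pmax(pc1, pc2)
  denom <- sum(pcm)
  if (denom < 1e-12) return(1)
  sum(s_pc * s_gm * pcm) / denom
}

# Scharr gradient magnitude, zero-padded 'same' correlation.
.scharr_magnitude <- function(X) {
  dx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  gx <- .conv2_same(X, dx)
  gy <- .conv2_same(X, t(dx))
  sqrt(gx^2 + gy^2)
}

# 3x3 zero-padded same-size correlation
.conv2_same <- function(X, K) {
  m <- nrow(X); n <- ncol(X)
  Xp <- matrix(0, m + 2L, n + 2L)
  Xp[2:(m + 1), 2:(n + 1)] <- X
  out <- matrix(0, m, n)
  for (a in 1:3) for (b in 1:3) {
    if (K[a, b] == 0) next
    out <- out + K[a, b] * Xp[a:(a + m - 1L), b:(b + n - 1L)]
  }
  out
}

#' Full-reference quality report for an original/segmented pair
#'
#' @param original,segmented `gray_image`s of equal shape and bit depth.
#' @param ... passed to [psnr()].
#' @return A list with `mse`, `psnr_db`, `ssim`, `fsim`.
#' @export
metrics_report <- function(original, segmented, ...) {
  .check_pair(original, segmented)
  mse <- mean((as.numeric(original$pixels) -
                 as.numeric(segmented$pixels))^2)
  list(mse = mse,
       psnr_db = psnr(original, segmented, ...),
       ssim = ssim(original, segmented),
       fsim = fsim(original, segmented))
}
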