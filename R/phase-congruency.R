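#' Log-Gabor phase congruency map
#'
#' Measures, at each pixel, how much the local Fourier components agree in
#' phase — a contrast-invariant detector of structure (edges, lines) that
#' underpins the feature-similarity index. The image is decomposed with a
#' bank of log-Gabor filters (geometric scale spacing, Gaussian angular
#' spread), per-orientation phase deviation is energy-weighted, an estimated
#' noise floor is subtracted, and a sigmoid weighting penalizes narrow
#' frequency spread. The returned map is normalized to `[0, 1)` by the total
#' filter-response amplitude.
#'
#' @param X numeric matrix (gray values; any linear scale).
#' @param nscale number of filter scales.
#' @param norient number of filter orientations.
#' @param min_wavelength wavelength of the smallest-scale filter (pixels).
#' @param mult scaling factor between successive scales.
#' @param sigma_onf ratio of the log-Gabor's radial std dev to its centre
#'   frequency (bandwidth parameter).
#' @param d_theta_sigma ratio of angular spacing to angular std dev.
#' @param k noise threshold in standard deviations above the mean noise
#'   energy.
#' @param cut_off,g cut-off and gain of the frequency-spread sigmoid weight.
#' @param epsilon guard against division by zero.
#' @return Matrix of phase-congruency values, same shape as `X`.
#' @export
phase_congruency <- function(X, nscale = 4L, norient = 4L,
                             min_wavelength = 6, mult = 2,
                             sigma_onf = 0.55, d_theta_sigma = 1.2,
                             k = 2.0, cut_off = 0.45, g = 10,
                             epsilon = 1e-4) {
  m <- nrow(X); n <- ncol(X)
  # frequency grids in natural FFT order (DC at [1,1])
  fy <- .fft_freqs(m)
  fx <- .fft_freqs(n)
  x <- matrix(fx, m, n, byrow = TRUE)
  y <- matrix(fy, m, n)
  radius <- sqrt(x^2 + y^2)
  radius[1, 1] <- 1  # avoid log(0) at DC; filter is zeroed there anyway
  theta <- atan2(-y, x)
  sintheta <- sin(theta); costheta <- cos(theta)

  # Butterworth low-pass keeps the largest-scale filter bounded at Nyquist
  lowpass <- 1 / (1 + (radius / 0.45)^(2 * 15))
  log_gabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    fo <- 1 / (min_wavelength * mult^(s - 1))
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigma_onf)^2)) * lowpass
    lg[1, 1] <- 0
    log_gabor[[s]] <- lg
  }

  imagefft <- stats::fft(X)
  theta_sigma <- pi / norient / d_theta_sigma
  energy_all <- matrix(0, m, n)
  an_all <- matrix(0, m, n)

  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))

    e_list <- vector("list", nscale)
    o_list <- vector("list", nscale)
    sum_e <- matrix(0, m, n); sum_o <- matrix(0, m, n)
    sum_a <- matrix(0, m, n); max_a <- matrix(0, m, n)
    tau <- 0
    for (s in seq_len(nscale)) {
      filt <- log_gabor[[s]] * spread
      eo <- stats::fft(imagefft * filt, inverse = TRUE) / (m * n)
      e_s <- Re(eo); o_s <- Im(eo)
      a_s <- sqrt(e_s^2 + o_s^2)
      e_list[[s]] <- e_s; o_list[[s]] <- o_s
      sum_e <- sum_e + e_s; sum_o <- sum_o + o_s
      sum_a <- sum_a + a_s
      if (s == 1L) tau <- stats::median(a_s) / sqrt(log(4))
      max_a <- pmax(max_a, a_s)
    }

    x_energy <- sqrt(sum_e^2 + sum_o^2) + epsilon
    mean_e <- sum_e / x_energy
    mean_o <- sum_o / x_energy
    energy <- matrix(0, m, n)
    for (s in seq_len(nscale)) {
      energy <- energy + e_list[[s]] * mean_e + o_list[[s]] * mean_o -
        abs(e_list[[s]] * mean_o - o_list[[s]] * mean_e)
    }

    # Rayleigh-model noise floor estimated from the smallest scale
    total_tau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sigma <- total_tau * sqrt((4 - pi) / 2)
    T_noise <- (noise_mean + k * noise_sigma) / 1.7
    energy <- pmax(energy - T_noise, 0)

    width <- sum_a / (max_a + epsilon) / nscale
    weight <- 1 / (1 + exp((cut_off - width) * g))
    energy_all <- energy_all + weight * energy
    an_all <- an_all + sum_a
  }
  energy_all / (an_all + epsilon)
}

# FFT sample frequencies in cycles/pixel, natural (unshifted) order
.fft_freqs <- function(n) {
  half <- floor((n - 1) / 2)
  c(0:half, -(n - half - 1):-1) / n
}
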