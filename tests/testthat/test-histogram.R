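test_that("compute_histogram counts every level of the declared range", {
  img <- gray_image(matrix(c(0, 0, 1, 3), 2, 2, byrow = TRUE), 2)
  h <- compute_histogram(img)
  expect_equal(h$counts, c(2L, 1L, 0L, 1L))
  expect_equal(h$probs, c(0.5, 0.25, 0, 0.25))
  expect_equal(h$levels, 4L)

  const <- gray_image(matrix(5L, 3, 3), 4)
  hc <- compute_histogram(const)
  expect_equal(sum(hc$probs), 1)
  expect_equal(hc$probs[6], 1)
})

test_that("images reject values beyond the declared bit depth", {
  expect_error(gray_image(matrix(4L, 1, 1), 2), "bit-depth mismatch")
  expect_error(gray_image(matrix(-1L, 1, 1), 8), "non-negative")
})

test_that("empirical histogram mass tracks the analytic mixture density", {
  spec <- bimodal_spec(seed = 424, shape = c(128L, 128L))
  img <- generate_synthetic_image(spec)
  h <- compute_histogram(img)
  n <- prod(spec$shape)
  # binomial band around the mixture probability of each of 16 coarse bins
  # (coarse so each expected count is comfortably large); 4 sigma per bin
  # keeps the joint false-alarm rate across the 16 simultaneous bins small
  coarse <- rebin_histogram(h, 16)
  edges <- seq(0, 4096, length.out = 17)
  p_expect <- diff(mixture_cdf(spec, edges - 0.5))
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_true(all(abs(coarse$probs - p_expect) <= 4 * se + 1e-12))
})

test_that("bit-depth remapping left-shifts gray values", {
  img <- gray_image(matrix(c(0L, 255L), 1, 2), 8)
  up <- remap_bit_depth(img, 12)
  expect_equal(up$pixels[1, ], c(0L, 4080L))
  expect_equal(up$bit_depth, 12L)
  expect_identical(remap_bit_depth(img, 8), img)
  expect_error(remap_bit_depth(up, 8), "downscale")
})

test_that("Kapur entropy matches closed forms on uniform histograms", {
  h <- gray_histogram(rep(1, 64))
  expect_equal(kapur_entropy(h, 32), 2 * log(32), tolerance = 1e-12)
  # equal classes of m bins contribute ln(m) each
  expect_equal(kapur_entropy(h, c(16, 32, 48)), 4 * log(16),
               tolerance = 1e-12)
})

test_that("degenerate histograms give zero entropy for any thresholds", {
  h <- gray_histogram(c(0, 0, 7, 0, 0, 0, 0, 0))
  for (th in list(1, 4, c(2, 5), c(1, 3, 6)))
    expect_equal(kapur_entropy(h, th), 0)
})

test_that("cumsum-based entropy agrees with a direct double loop", {
  direct_kapur <- function(probs, th) {
    L <- length(probs)
    bounds <- c(0L, th, L)
    total <- 0
    for (k in seq_len(length(th) + 1L)) {
      idx <- (bounds[k] + 1L):bounds[k + 1L]
      w <- sum(probs[idx])
      if (w == 0) next
      H <- 0
      for (i in idx) if (probs[i] > 0)
        H <- H - (probs[i] / w) * log(probs[i] / w)
      total <- total + H
    }
    total
  }
  set.seed(99)
  for (case in 1:100) {
    L <- sample(8:32, 1)
    nTh <- sample(1:3, 1)
    p <- stats::runif(L)
    p[sample(L, sample(0:3, 1))] <- 0  # exercise empty bins
    h <- gray_histogram(probs = p / sum(p))
    th <- sort(sample(1:(L - 1), nTh))
    expect_equal(kapur_entropy(h, th), direct_kapur(h$probs, th),
                 tolerance = 1e-10)
  }
})

test_that("segmentation follows the lower-closed interval convention", {
  img <- gray_image(matrix(c(0, 3, 5, 7), 2, 2, byrow = TRUE), 3)
  labels <- segment_image(img, threshold_set(4, 8))
  expect_equal(labels, matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE))

  zero <- gray_image(matrix(0L, 2, 2), 3)
  expect_true(all(segment_image(zero, threshold_set(1, 8)) == 0L))

  img16 <- gray_image(matrix(c(3, 4, 8, 9, 15, 0), 2, 3), 4)
  lab <- segment_image(img16, threshold_set(c(4, 9), 16))
  expect_equal(lab[match(c(3, 4, 8, 9, 15), img16$pixels)],
               c(0L, 1L, 1L, 2L, 2L))
})

test_that("rendering assigns one representative gray value per class", {
  img <- gray_image(matrix(c(0, 3, 5, 7), 2, 2, byrow = TRUE), 3)
  th <- threshold_set(4, 8)
  mean_r <- render_segmented(img, th, "class_mean")
  expect_equal(mean_r$pixels, matrix(c(2L, 2L, 6L, 6L), 2, 2, byrow = TRUE))

  img16 <- gray_image(matrix(c(0, 5, 9, 15), 2, 2), 4)
  mid_r <- render_segmented(img16, threshold_set(8, 16), "class_midpoint")
  expect_equal(sort(unique(as.vector(mid_r$pixels))), c(4L, 12L))

  const <- gray_image(matrix(3L, 2, 2), 3)
  expect_identical(render_segmented(const, th, "class_mean")$pixels,
                   const$pixels)
})

test_that("re-segmenting a rendered image reproduces the label map", {
  img <- generate_synthetic_image(bimodal_spec(seed = 31))
  th <- threshold_set(c(800, 2000, 3200), 4096)
  labels <- segment_image(img, th)
  for (mode in c("class_mean", "class_midpoint")) {
    rendered <- render_segmented(img, th, mode)
    expect_equal(segment_image(rendered, th), labels)
  }
})

test_that("rebinning conserves probability and uniformity", {
  h <- random_histogram(4096, seed = 5)
  r <- rebin_histogram(h, 256)
  expect_equal(sum(r$probs), 1, tolerance = 1e-12)
  expect_equal(r$levels, 256L)
  expect_error(rebin_histogram(h, 100), "divide")

  u <- gray_histogram(rep(1, 64))
  expect_equal(rebin_histogram(u, 16)$probs, rep(1 / 16, 16))
})

test_that("histograms round-trip through the CSV export table", {
  img <- gray_image(matrix(c(0, 0, 1, 3), 2, 2), 2)
  tab <- histogram_table(compute_histogram(img))
  expect_equal(tab$level, 0:3)
  expect_equal(tab$count, c(2L, 1L, 0L, 1L))
  expect_equal(sum(tab$prob), 1)
})
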