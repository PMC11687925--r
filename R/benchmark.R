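#' Read a score table (cases x algorithms) from CSV
#'
#' A score table holds one row per (image_id, nTh) case and one numeric
#' column per algorithm, as printed in thresholding benchmark papers. The
#' transcribed comparison tables shipped with the package live under
#' `system.file("extdata", package = "ciwpso")`.
#'
#' @param path CSV with columns `image_id`, `nTh`, then algorithm columns.
#' @return A data.frame of class `score_table`.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(image_id = "character"))
  stopifnot(all(c("image_id", "nTh") %in% names(tab)), ncol(tab) > 2L)
  if (anyNA(tab)) stop("score table has missing cells", call. = FALSE)
  key <- paste(tab$image_id, tab$nTh)
  if (anyDuplicated(key)) stop("duplicate case rows", call. = FALSE)
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' Count the cases an algorithm wins in a score table
#'
#' A win is a row where the algorithm's score equals the row optimum
#' (maximum for higher-is-better scores); ties count as a win for every
#' tied algorithm. Scores transcribed at fixed decimal precision compare
#' exactly, so no tolerance is applied.
#'
#' @param table a `score_table` (or data.frame with `image_id`, `nTh` and
#'   algorithm columns).
#' @param algorithm column name to count wins for.
#' @param higher_is_better direction of the row optimum.
#' @return Integer number of winning rows.
#' @export
count_wins <- function(table, algorithm, higher_is_better = TRUE) {
  cols <- setdiff(names(table), c("image_id", "nTh"))
  if (!algorithm %in% cols)
    stop("algorithm not in table: ", algorithm, call. = FALSE)
  scores <- as.matrix(table[, cols, drop = FALSE])
  opt <- if (higher_is_better) apply(scores, 1L, max)
         else apply(scores, 1L, min)
  sum(scores[, algorithm] == opt)
}

# stable 31-bit hash of a string, for per-case seed derivation
.string_seed <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

#' Derive the seed for one benchmark run
#'
#' Deterministic in (image id, nTh, algorithm, repeat) and the base seed,
#' so adding an algorithm or image to a benchmark does not perturb the
#' random streams of existing cases.
#'
#' @param base_seed integer base seed.
#' @param image_id character image identifier.
#' @param nTh threshold count.
#' @param algorithm algorithm name.
#' @param rep repeat index (1-based).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(base_seed, image_id, nTh, algorithm, rep) {
  key <- paste(image_id, nTh, algorithm, rep, sep = "/")
  as.integer((as.numeric(base_seed) + .string_seed(key)) %% 2147483647)
}

# lower-middle order statistic: the reported "median" of an even number of
# repeats is an actual run's value, so its segmentation can be rendered
.median_low <- function(x) sort(x)[floor((length(x) + 1) / 2)]

#' Run a benchmark over images, threshold counts and algorithms
#'
#' Replicates the standard protocol: for every (image, nTh, algorithm)
#' case, `repeats` independent runs are executed with per-case derived
#' seeds and the median best fitness is recorded (for an even repeat count,
#' the lower-middle order statistic, so the reported value belongs to an
#' actual run). Optionally the median run's thresholds are rendered and
#' scored with PSNR/SSIM/FSIM.
#'
#' @param images named list of `gray_image`s or `mixture_spec`s (specs are
#'   generated on the fly).
#' @param nTh_list integer vector of threshold counts.
#' @param algorithms character vector of registered algorithm names
#'   (`"pso"`, `"ciwp-pso"`).
#' @param repeats independent runs per case.
#' @param base_seed base seed for [derive_seed()].
#' @param N,T_max swarm size and iteration budget.
#' @param metrics also compute image-quality metrics of the median run.
#' @param ... further arguments to [swarm_config()].
#' @return A `score_table` with one fitness column per algorithm;
#'   attributes `convergence` (named list of median-run curves) and, if
#'   requested, `metrics` (long data.frame of PSNR/SSIM/FSIM rows).
#' @export
run_benchmark <- function(images, nTh_list, algorithms = c("pso", "ciwp-pso"),
                          repeats = 10L, base_seed = 1L,
                          N = 30L, T_max = 100L, metrics = FALSE, ...) {
  stopifnot(repeats >= 1L, length(images) >= 1L)
  if (is.null(names(images)))
    names(images) <- paste0("img", seq_along(images))
  rows <- expand.grid(image_id = names(images), nTh = nTh_list,
                      stringsAsFactors = FALSE)
  scores <- matrix(NA_real_, nrow(rows), length(algorithms),
                   dimnames = list(NULL, algorithms))
  curves <- list()
  metric_rows <- list()
  for (r in seq_len(nrow(rows))) {
    img <- images[[rows$image_id[r]]]
    if (inherits(img, "mixture_spec")) img <- generate_synthetic_image(img)
    hist <- compute_histogram(img)
    nTh <- rows$nTh[r]
    for (alg in algorithms) {
      runs <- vector("list", repeats)
      for (rep in seq_len(repeats)) {
        cfg <- swarm_config(N = N, T_max = T_max, D = nTh,
                            LB = 1, UB = hist$levels - 1,
                            seed = derive_seed(base_seed, rows$image_id[r],
                                               nTh, alg, rep), ...)
        runs[[rep]] <- run_optimizer(alg, hist, nTh, cfg)
      }
      fits <- vapply(runs, function(x) x$best_fitness, numeric(1))
      med <- .median_low(fits)
      med_run <- runs[[which(fits == med)[1]]]
      scores[r, alg] <- med
      case_id <- paste(rows$image_id[r], nTh, alg, sep = "/")
      curves[[case_id]] <- med_run$convergence
      if (metrics) {
        seg <- render_segmented(img, med_run$best_thresholds)
        mr <- metrics_report(img, seg)
        metric_rows[[case_id]] <- data.frame(
          image_id = rows$image_id[r], nTh = nTh, algorithm = alg,
          psnr = mr$psnr_db, ssim = mr$ssim, fsim = mr$fsim)
      }
    }
  }
  out <- cbind(rows, as.data.frame(scores, check.names = FALSE))
  class(out) <- c("score_table", "data.frame")
  attr(out, "convergence") <- curves
  if (metrics) attr(out, "metrics") <- do.call(rbind, metric_rows)
  out
}

#' Export a convergence curve as CSV
#'
#' Writes `(iteration, best_so_far)` rows; floating-point values are
#' formatted with 17 significant digits so the file round-trips to the
#' exact doubles and re-export is byte-identical.
#'
#' @param result a `run_result` (or bare numeric convergence vector).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_convergence <- function(result, path) {
  curve <- if (inherits(result, "run_result")) result$convergence
           else as.numeric(result)
  lines <- c("iteration,best_so_far",
             sprintf("%d,%.17g", seq_along(curve), curve))
  writeLines(lines, path)
  invisible(path)
}
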