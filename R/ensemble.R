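#' Summarize an ensemble of per-conformer cross-sections
#'
#' Aggregates cross-sections computed over a set of protein conformers
#' (e.g. structures sampled along an MD trajectory) into a distribution
#' summary: mean, unbiased standard deviation, a histogram, and a mode
#' estimate taken as the midpoint of the highest-count bin (ties resolved
#' to the lowest such bin — a deliberately histogram-level estimate, since
#' conformer ensembles are typically far too small for density
#' estimation). Optionally places a reference structure's cross-section
#' (e.g. from an annealed geometry) within the distribution as a
#' percentile.
#'
#' Default binning follows the Freedman-Diaconis rule with a floor of five
#' bins; an explicit `bin_width` overrides it.
#'
#' @param samples numeric vector of cross-sections in GM, all >= 0.
#' @param bin_width optional explicit histogram bin width in GM.
#' @param reference optional cross-section of a designated structure, GM.
#' @return An object of class `ensemble_summary`: `samples`, `n`, `mean`,
#'   `std`, `mode_estimate`, `breaks`, `counts`, and (if given)
#'   `reference_value` with `reference_percentile`.
#' @examples
#' s <- random_ensemble(21, mean = 15, sd = 4, seed = 7)
#' summarize_ensemble(s, reference = 15)
#' @export
summarize_ensemble <- function(samples, bin_width = NULL, reference = NULL) {
  if (length(samples) < 1) stop("empty sample list", call. = FALSE)
  .assert_finite(samples, "samples")
  if (any(samples < 0)) stop("cross-sections must be non-negative", call. = FALSE)
  n <- length(samples)
  rng <- range(samples)
  span <- diff(rng)
  if (span == 0) {
    breaks <- rng[1L] + c(-0.5, 0.5)
    counts <- n
  } else {
    if (is.null(bin_width)) {
      bin_width <- 2 * stats::IQR(samples) / n^(1 / 3)  # Freedman-Diaconis
    }
    n_bins <- if (bin_width > 0) ceiling(span / bin_width) else 0L
    if (n_bins < 5L) n_bins <- 5L                        # floor of 5 bins
    breaks <- seq(rng[1L], by = span / n_bins, length.out = n_bins + 1L)
    bin <- findInterval(samples, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(bin, nbins = n_bins)
  }
  mids <- (utils::head(breaks, -1L) + utils::tail(breaks, -1L)) / 2
  mode_bin <- which.max(counts)                          # ties -> lowest bin
  out <- list(samples = samples, n = n,
              mean = mean(samples),
              std = if (n > 1) stats::sd(samples) else 0,
              mode_estimate = mids[mode_bin],
              breaks = breaks, counts = counts)
  if (!is.null(reference)) {
    out$reference_value <- reference
    out$reference_percentile <- percentile_of(reference, samples)
  }
  structure(out, class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: n = %d cross-sections (GM)\n", x$n))
  cat(sprintf("  mean %.3g, sd %.3g, mode (bin midpoint) %.3g\n",
              x$mean, x$std, x$mode_estimate))
  cat(sprintf("  histogram: %d bins, counts %s\n",
              length(x$counts), paste(x$counts, collapse = " ")))
  if (!is.null(x$reference_value))
    cat(sprintf("  reference %.3g GM at percentile %.1f\n",
                x$reference_value, x$reference_percentile))
  invisible(x)
}

#' Percentile placement of a value within a sample
#'
#' Fraction of samples at or below `value`, times 100, with the midpoint
#' convention for ties (each sample equal to `value` counts one half), so
#' the median of an odd-length sample sits at exactly 50.
#'
#' @param value the cross-section to place, GM.
#' @param samples numeric vector, non-empty.
#' @return Percentile in [0, 100].
#' @export
percentile_of <- function(value, samples) {
  if (length(samples) < 1) stop("empty sample list", call. = FALSE)
  .assert_finite(value, "value"); .assert_finite(samples, "samples")
  100 * (sum(samples < value) + 0.5 * sum(samples == value)) / length(samples)
}

#' Synthetic conformer ensemble of cross-sections
#'
#' Draws cross-sections from a normal distribution truncated at zero, the
#' simplest model of the unimodal, broadly dispersed distributions that
#' conformational sampling of a chromophore environment produces. The
#' defaults mimic a 21-conformer protocol centered at 15 GM with a 4 GM
#' spread.
#'
#' @param n number of conformers.
#' @param mean,sd center and spread of the generating normal, GM.
#' @param seed integer seed.
#' @return Numeric vector of `n` non-negative cross-sections.
#' @export
random_ensemble <- function(n = 21, mean = 15, sd = 4, seed) {
  stopifnot(n >= 1, sd >= 0)
  .with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(n, mean, sd)
      out <- c(out, draw[draw >= 0])
    }
    out[seq_len(n)]
  })
}

#' Read and write ensemble data
#'
#' `read_ensemble_csv()` reads plain CSV with one cross-section (GM) per
#' line in the first column (an optional second column carries labels; a
#' header row is detected and skipped). `read_ensemble_dir()` collects
#' `sigma_gm` from a directory of serialized [compute_tpa()] JSON results.
#' `write_ensemble_summary()` writes a JSON summary and a CSV histogram
#' (`bin_low,bin_high,count`).
#'
#' @param path CSV file, directory, or output path prefix.
#' @param x an `ensemble_summary`.
#' @return A numeric vector of cross-sections, or (for the writer) the
#'   paths written, invisibly.
#' @export
read_ensemble_csv <- function(path) {
  if (!file.exists(path)) stop("ensemble file not found: ", path, call. = FALSE)
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- is.na(suppressWarnings(as.numeric(first[[1L]])))
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  vals <- suppressWarnings(as.numeric(df[[1L]]))
  if (any(is.na(vals)))
    stop("non-numeric cross-section values in ", path, call. = FALSE)
  vals
}

#' @rdname read_ensemble_csv
#' @export
read_ensemble_dir <- function(path) {
  files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no .json result files in ", path, call. = FALSE)
  vapply(sort(files), function(f) {
    doc <- jsonlite::fromJSON(f)
    if (is.null(doc$sigma_gm)) stop("no sigma_gm field in ", f, call. = FALSE)
    as.numeric(doc$sigma_gm)
  }, 0, USE.NAMES = FALSE)
}

#' @rdname read_ensemble_csv
#' @export
write_ensemble_summary <- function(x, path) {
  stopifnot(inherits(x, "ensemble_summary"))
  json_path <- paste0(path, ".json")
  csv_path <- paste0(path, "_histogram.csv")
  doc <- list(n = x$n, mean = x$mean, std = x$std,
              mode_estimate = x$mode_estimate, samples = x$samples)
  if (!is.null(x$reference_value)) {
    doc$reference_value <- x$reference_value
    doc$reference_percentile <- x$reference_percentile
  }
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  hist_df <- data.frame(bin_low = utils::head(x$breaks, -1L),
                        bin_high = utils::tail(x$breaks, -1L),
                        count = x$counts)
  utils::write.csv(hist_df, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
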