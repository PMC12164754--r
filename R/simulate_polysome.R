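#' Simulate a polysome absorbance trace
#'
#' Sum of Gaussian peaks (parameterized by center, width = Gaussian sd, and
#' total area) over a flat baseline, plus optional white noise — the shape of
#' an A254 sucrose-gradient profile with 40S, 60S, monosome and polysome
#' peaks. True areas are recorded for downstream P/M checks.
#'
#' @param peaks data.frame with columns `center`, `width`, `area`; centers
#'   must be strictly increasing. Zero rows give a flat baseline trace.
#' @param baseline constant baseline absorbance.
#' @param noise_sd sd of additive Gaussian noise (0 = noise free).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @param positions gradient-depth grid; defaults to 2001 points spanning the
#'   peaks with a 4-width margin.
#' @return list of class `polysome_trace` with `position`, `a254`, and
#'   `truth` (the peak table and baseline).
#' @export
simulate_polysome_trace <- function(peaks, baseline = 0.05, noise_sd = 0,
                                    seed = 1L, positions = NULL) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks)) {
    stopifnot(all(c("center", "width", "area") %in% names(peaks)))
    if (is.unsorted(peaks$center, strictly = TRUE)) {
      stop("peak centers must be strictly increasing")
    }
    if (any(peaks$width <= 0) || any(peaks$area < 0)) {
      stop("peak widths must be > 0 and areas >= 0")
    }
    gaps <- diff(peaks$center)
    minw <- pmax(head(peaks$width, -1L), tail(peaks$width, -1L))
    if (nrow(peaks) > 1L && any(gaps < minw)) {
      warning("peaks closer than one width: segmentation may be ambiguous")
    }
  }
  if (is.null(positions)) {
    if (nrow(peaks)) {
      lo <- min(peaks$center - 4 * peaks$width)
      hi <- max(peaks$center + 4 * peaks$width)
    } else {
      lo <- 0; hi <- 10
    }
    positions <- seq(lo, hi, length.out = 2001L)
  }
  y <- rep(baseline, length(positions))
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$area[i] *
      stats::dnorm(positions, peaks$center[i], peaks$width[i])
  }
  if (noise_sd > 0) {
    y <- with_seed(seed, y + rnorm(length(y), 0, noise_sd))
  }
  structure(list(position = positions, a254 = y,
                 truth = list(peaks = peaks, baseline = baseline)),
            class = "polysome_trace")
}

#' Write / read a two-column polysome trace TSV (`position`, `a254`)
#' @param trace a `polysome_trace` (or list with `position`, `a254`).
#' @param path file path.
#' @return `path` invisibly; `read_polysome_trace` returns a
#'   `polysome_trace` (without truth).
#' @export
write_polysome_trace <- function(trace, path) {
  write.table(data.frame(position = trace$position, a254 = trace$a254),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polysome_trace
#' @export
read_polysome_trace <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("position", "a254") %in% names(df)))
  if (is.unsorted(df$position, strictly = TRUE)) {
    stop("trace positions must be strictly increasing")
  }
  structure(list(position = df$position, a254 = df$a254, truth = NULL),
            class = "polysome_trace")
}
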