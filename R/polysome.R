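#' Segment a polysome trace into peak regions
#'
#' Peaks are local maxima rising above the baseline (the 5th percentile of
#' the signal) by at least `min_prominence` of the trace's dynamic range;
#' when more candidates than expected are found, the `n_expected_peaks`
#' tallest are kept (in position order). Region boundaries sit at the
#' minima between consecutive peaks. With the canonical four peaks
#' (40S, 60S, monosome, polysome), the monosome region spans the valleys
#' around the third peak and the polysome region runs from the
#' monosome/polysome valley to the trace end.
#'
#' @param trace a `polysome_trace` (or list with `position`, `a254`).
#' @param n_expected_peaks number of peaks required (default 4).
#' @param baseline_quantile quantile of the signal used as baseline.
#' @param min_prominence minimum height above baseline, as a fraction of
#'   the dynamic range, for a local maximum to count as a peak.
#' @param smooth_frac width of the running-mean smoother applied before
#'   maxima detection, as a fraction of the number of grid points (the
#'   smoothed signal is used only to locate peaks and valleys; areas are
#'   integrated on the raw trace).
#' @param min_sep_frac minimum separation between retained peaks, as a
#'   fraction of the position span; of two closer maxima the taller wins.
#' @return list of class `trace_segmentation`: `peaks` (positions),
#'   `peak_heights`, `valleys` (positions between peaks), `baseline`,
#'   `monosome` and `polysome` (position ranges), `regions` (per-peak
#'   position ranges).
#' @export
segment_trace <- function(trace, n_expected_peaks = 4,
                          baseline_quantile = 0.05,
                          min_prominence = 0.05,
                          smooth_frac = 0.01, min_sep_frac = 0.02) {
  x <- trace$position; y <- trace$a254
  if (length(x) < 50L) stop("trace must have >= 50 points")
  n <- length(y)
  # centered running mean; locates extrema without moving symmetric peaks
  w <- max(1L, round(n * smooth_frac))
  ys <- as.numeric(stats::filter(y, rep(1 / (2L * w + 1L), 2L * w + 1L),
                                 sides = 2L))
  edge <- c(seq_len(w), n + 1L - seq_len(w))
  ys[edge] <- y[edge]
  baseline <- as.numeric(quantile(y, baseline_quantile))
  rng <- max(y) - min(y)
  thr <- baseline + min_prominence * rng
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] &
                ys[2:(n - 1)] >= ys[3:n], FALSE) & ys > thr
  if (rng == 0) is_max[] <- FALSE   # flat trace has no peaks
  cand <- which(is_max)
  # merge maxima closer than the minimum separation; the taller survives
  if (length(cand) > 1L) {
    min_sep <- min_sep_frac * (x[n] - x[1])
    keep <- integer(0)
    for (i in cand[order(ys[cand], decreasing = TRUE)]) {
      if (!length(keep) || all(abs(x[i] - x[keep]) >= min_sep)) {
        keep <- c(keep, i)
      }
    }
    cand <- sort(keep)
  }
  if (length(cand) < n_expected_peaks) {
    stop("expected ", n_expected_peaks, " peaks but found ", length(cand),
         if (length(cand)) paste0(" (at ",
                                  paste(signif(x[cand], 4), collapse = ", "),
                                  ")") else "")
  }
  if (length(cand) > n_expected_peaks) {
    cand <- sort(cand[order(ys[cand], decreasing = TRUE)][
      seq_len(n_expected_peaks)])
  }
  valleys_idx <- vapply(seq_len(length(cand) - 1L), function(i) {
    seg <- cand[i]:cand[i + 1L]
    seg[which.min(ys[seg])]
  }, integer(1))
  bounds_idx <- c(1L, valleys_idx, n)
  regions <- lapply(seq_along(cand), function(i) {
    c(x[bounds_idx[i]], x[bounds_idx[i + 1L]])
  })
  k <- length(cand)
  structure(list(
    peaks = x[cand], peak_heights = y[cand],
    valleys = x[valleys_idx], baseline = baseline,
    monosome = regions[[min(3L, k)]],
    polysome = c(regions[[min(4L, k)]][1], x[n]),
    regions = regions
  ), class = "trace_segmentation")
}

#' Polysome-to-monosome (P/M) ratio
#'
#' Trapezoidal, baseline-subtracted area of the polysome region divided by
#' that of the monosome region. Signal below baseline contributes zero.
#' The ratio is invariant under rescaling the whole trace's dynamic range.
#'
#' @param trace a `polysome_trace`.
#' @param boundaries a [segment_trace()] result, or a list with `monosome`
#'   and `polysome` position ranges (and optional `baseline`).
#' @return the dimensionless P/M ratio.
#' @export
pm_ratio <- function(trace, boundaries = segment_trace(trace)) {
  baseline <- boundaries$baseline %||%
    as.numeric(quantile(trace$a254, 0.05))
  area <- function(range) {
    sel <- trace$position >= range[1] & trace$position <= range[2]
    if (sum(sel) < 2L) return(0)
    trapz(trace$position[sel], pmax(trace$a254[sel] - baseline, 0))
  }
  m <- area(boundaries$monosome)
  if (m <= 0) stop("monosome area is not positive after baseline subtraction")
  area(boundaries$polysome) / m
}

#' Per-fraction transcript distribution as percent of input
#'
#' Each fraction's quantification value is expressed as a percentage of the
#' input sample's value; monosome and polysome group sums are reported.
#'
#' @param values_per_fraction numeric vector of per-fraction values (>= 0).
#' @param input_value the input-sample value (> 0).
#' @param monosome_fractions,polysome_fractions indices of the fractions in
#'   each group.
#' @return list of class `fraction_distribution`: `percent` (per fraction),
#'   `monosome_pct`, `polysome_pct`.
#' @export
fraction_distribution <- function(values_per_fraction, input_value,
                                  monosome_fractions = integer(0),
                                  polysome_fractions = integer(0)) {
  if (input_value <= 0) stop("input_value must be > 0")
  if (any(values_per_fraction < 0)) {
    stop("negative quantification value")
  }
  pct <- 100 * values_per_fraction / input_value
  structure(list(percent = pct,
                 monosome_pct = sum(pct[monosome_fractions]),
                 polysome_pct = sum(pct[polysome_fractions])),
            class = "fraction_distribution")
}
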