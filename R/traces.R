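## Single-cell trace analysis: normalisation, peak detection, first-peak
## alignment and the 20-minute peak-interval histogram.

#' Normalise a single-cell intensity trace
#'
#' Optional centred moving-average smoothing followed by min-max scaling to
#' `[0, 1]`. Affine transforms of the input give identical output.
#'
#' @param y raw intensity series (>= 2 points).
#' @param smooth_window smoothing window in frames (odd; 1 = no smoothing).
#'   The default of 3 frames corresponds to 6 min at 2-min live-imaging
#'   acquisition intervals.
#' @return numeric series in `[0, 1]`.
#' @export
normalize_trace <- function(y, smooth_window = 3L) {
  if (!is.numeric(y) || length(y) < 2L || any(!is.finite(y)))
    stop("'y' must be a finite numeric series with at least 2 points")
  y <- moving_average(y, smooth_window)
  rng <- range(y)
  if (diff(rng) == 0)
    stop("constant series cannot be normalized")
  (y - rng[1]) / diff(rng)
}

#' Detect peaks in a normalised trace
#'
#' Local maxima (plateaus count once, at their first point) filtered by
#' topographic prominence and a minimum separation. When two candidate
#' peaks are closer than `min_separation_min`, the higher one is kept; at
#' equal height the earlier one wins. Maxima at the series endpoints are
#' not counted.
#'
#' @param y normalised series.
#' @param t_min time grid (default: frame index).
#' @param min_prominence minimum prominence as a fraction of the series
#'   range.
#' @param min_separation_min minimum distance between kept peaks, in the
#'   units of `t_min`.
#' @return object of class `peak_set`: list with `peak_times_min`,
#'   `peak_heights` and `intervals_min`.
#' @export
detect_peaks <- function(y, t_min = seq_along(y) - 1, min_prominence = 0.2,
                         min_separation_min = 20) {
  stopifnot(length(y) == length(t_min))
  n <- length(y)
  rng <- diff(range(y))
  cand <- integer(0)
  if (n >= 3L && rng > 0) {
    i <- 2L
    while (i < n) {
      if (y[i] > y[i - 1L]) {
        j <- i
        while (j < n && y[j + 1L] == y[j]) j <- j + 1L  # plateau
        if (j < n && y[j + 1L] < y[j]) cand <- c(cand, i)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (length(cand)) {
    prom <- vapply(cand, function(i) {
      left <- if (any(y[seq_len(i - 1L)] > y[i])) {
        k <- max(which(y[seq_len(i - 1L)] > y[i]))
        min(y[k:i])
      } else min(y[seq_len(i)])
      right <- if (any(y[(i + 1L):n] > y[i])) {
        k <- i + min(which(y[(i + 1L):n] > y[i]))
        min(y[i:k])
      } else min(y[i:n])
      y[i] - max(left, right)
    }, numeric(1))
    cand <- cand[prom >= min_prominence * rng]
  }
  if (length(cand) > 1L) {
    # greedy by height (ties: earlier first), enforcing separation
    ord <- cand[order(-y[cand], t_min[cand])]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) ||
          all(abs(t_min[i] - t_min[kept]) >= min_separation_min))
        kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  structure(list(peak_times_min = t_min[cand], peak_heights = y[cand],
                 intervals_min = diff(t_min[cand])),
            class = "peak_set")
}

#' Align traces on their first peak
#'
#' Shifts each trace in time so that its first detected peak sits at
#' `t = 0`, and computes the mean trace over the overlapping support.
#' Traces without a detected peak are excluded with a warning.
#'
#' @param traces list of normalised series, all sampled on `t_min`.
#' @param t_min shared time grid.
#' @param ... passed to [detect_peaks()].
#' @return list with `aligned` (list of data frames `t_min`, `value`),
#'   `mean` (data frame over the common support), and `excluded` (indices
#'   of traces without peaks).
#' @export
align_first_peak <- function(traces, t_min, ...) {
  stopifnot(is.list(traces), length(traces) > 0)
  first_pk <- vapply(traces, function(y) {
    pk <- detect_peaks(y, t_min = t_min, ...)
    if (length(pk$peak_times_min)) pk$peak_times_min[1] else NA_real_
  }, numeric(1))
  excluded <- which(is.na(first_pk))
  if (length(excluded))
    warning(length(excluded), " trace(s) without a detected peak excluded")
  keep <- setdiff(seq_along(traces), excluded)
  if (!length(keep)) stop("no trace has a detectable peak")
  aligned <- lapply(keep, function(i)
    data.frame(t_min = t_min - first_pk[i], value = traces[[i]]))
  lo <- max(vapply(aligned, function(d) min(d$t_min), numeric(1)))
  hi <- min(vapply(aligned, function(d) max(d$t_min), numeric(1)))
  dt <- t_min[2] - t_min[1]
  common <- seq(lo, hi, by = dt)
  mean_val <- rowMeans(vapply(aligned, function(d)
    approx(d$t_min, d$value, xout = common)$y, numeric(length(common))))
  list(aligned = aligned,
       mean = data.frame(t_min = common, value = mean_val),
       excluded = excluded)
}

#' Peak-to-peak interval histogram
#'
#' Fixed half-open 20-minute bins anchored at 40 min. The top regular bin
#' is closed (`[120, 140]`) and guard bins below 40 and above 140 min catch
#' out-of-range intervals instead of dropping them. The modal bin is the
#' regular bin with the largest count, ties going to the lower bin.
#'
#' @param intervals_min pooled peak-to-peak intervals (min).
#' @param bin_start,bin_end,bin_width histogram anatomy in minutes.
#' @return object of class `interval_histogram`: list with `bin_edges_min`,
#'   `counts` (named, including `under` and `over` guards), and `modal_bin`
#'   (`c(lower, upper)`).
#' @export
interval_histogram <- function(intervals_min, bin_start = 40, bin_end = 140,
                               bin_width = 20) {
  if (!length(intervals_min) || any(!is.finite(intervals_min)) ||
      any(intervals_min <= 0))
    stop("'intervals_min' must be positive and non-empty")
  edges <- seq(bin_start, bin_end, by = bin_width)
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (b in seq_len(nb)) {
    hi_ok <- if (b == nb) intervals_min <= edges[b + 1L]
             else intervals_min < edges[b + 1L]
    counts[b] <- sum(intervals_min >= edges[b] & hi_ok)
  }
  under <- sum(intervals_min < bin_start)
  over <- sum(intervals_min > bin_end)
  names(counts) <- paste0("[", edges[-length(edges)], ",",
                          edges[-1L], ifelse(seq_len(nb) == nb, "]", ")"))
  modal <- which.max(counts) # which.max takes the first (lower) tie
  structure(list(bin_edges_min = edges,
                 counts = c(under = under, counts, over = over),
                 modal_bin = c(lower = edges[modal],
                               upper = edges[modal + 1L])),
            class = "interval_histogram")
}
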