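#' Raw-moment autocorrelation of a sampled signal
#'
#' Computes the un-normalised autocorrelation sum
#' `c_k = sum_{i=1}^{T-k} f(t_{i+k}) f(t_i)` over lag indices `n = 0..N`
#' (lag `k = n dt`), normalised to `r_k = c_k / c_0`. No mean removal and no
#' per-lag renormalisation are applied: the trunk signals oscillate around
#' zero and the raw sum is what the detection rules are built on. An
#' optional demeaning flag exists for exploration.
#'
#' @param f Numeric vector, uniformly sampled.
#' @param dt Sampling interval, seconds.
#' @param max_lag Largest lag, seconds; must be shorter than the record.
#' @param demean If `TRUE`, subtract the signal mean first (default `FALSE`).
#' @return An object of class `autocorr_series`: data frame with columns
#'   `lag` (seconds) and `r` (dimensionless), attribute `dt`.
#' @examples
#' x <- sin(2 * pi * seq(0, 10, 0.01))
#' ac <- autocorrelation(x, 0.01, max_lag = 3)
#' head(dominant_periods(ac))
#' @export
autocorrelation <- function(f, dt, max_lag, demean = FALSE) {
  n <- length(f)
  if (n == 0L) stop("empty signal", call. = FALSE)
  N <- floor(max_lag / dt + 1e-9)
  if (N >= n)
    stop("`max_lag` must be shorter than the record", call. = FALSE)
  if (N < 0L) stop("`max_lag` must be non-negative", call. = FALSE)
  if (demean) f <- f - mean(f)
  c0 <- sum(f * f)
  if (c0 == 0)
    stop("degenerate signal: autocorrelation of an identically zero series",
         call. = FALSE)
  r <- vapply(0:N, function(k) {
    sum(f[(1L + k):n] * f[1:(n - k)])
  }, numeric(1)) / c0
  out <- data.frame(lag = (0:N) * dt, r = r)
  attr(out, "dt") <- dt
  class(out) <- c("autocorr_series", "data.frame")
  out
}

#' Dominant periods of an autocorrelation series
#'
#' Finds the local maxima of `r_k` over positive lags with the
#' zero-crossing segmentation of [local_extrema] (lag 0, whose segment
#' carries `r_0 = 1`, is excluded) and returns them sorted by descending
#' coefficient. The lag of the leading peak is the dominant period of the
#' signal.
#'
#' @param ac An `autocorr_series` from [autocorrelation].
#' @return Data frame with columns `lag` and `r`, sorted by descending `r`;
#'   zero rows when no interior maximum exists.
#' @export
dominant_periods <- function(ac) {
  if (!inherits(ac, "autocorr_series"))
    stop("`ac` must come from autocorrelation()", call. = FALSE)
  ex <- local_extrema(ac$r, ac$lag)
  peaks <- ex$maxima[ex$maxima$time > 0, c("time", "value"), drop = FALSE]
  names(peaks) <- c("lag", "r")
  peaks <- peaks[order(-peaks$r, peaks$lag), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Zero-crossing local extrema identifier
#'
#' Partitions the timeline into maximal segments of constant sign (values
#' `>= 0` count as positive) and takes, per segment, the element of largest
#' absolute value; ties are broken by the earliest time. Non-negative
#' segments contribute maxima, negative segments minima. This is the extrema
#' notion used throughout the framework: an extremum is the peak of one
#' excursion between two zero crossings, not a generic turning point.
#'
#' @param f Numeric vector of signal values.
#' @param t Numeric vector of sample times (defaults to `0, 1, 2, ...`).
#' @return A list with data frames `maxima` and `minima`, each with columns
#'   `value`, `time` and `segment` (1-based segment index).
#' @examples
#' local_extrema(c(2, 5, 5, 1, -3, -1))
#' @export
local_extrema <- function(f, t = seq_along(f) - 1) {
  n <- length(f)
  if (n == 0L) stop("empty signal", call. = FALSE)
  if (length(t) != n) stop("`f` and `t` must have equal length", call. = FALSE)
  sgn <- ifelse(f >= 0, 1L, -1L)
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg_of <- rep.int(seq_along(runs$lengths), runs$lengths)
  absf <- abs(f)
  # index of first occurrence of the per-segment max |value|
  ord <- order(seg_of, -absf, t)
  first <- ord[!duplicated(seg_of[ord])]
  picks <- data.frame(value = f[first], time = t[first],
                      segment = seg_of[first])
  is_max <- runs$values[picks$segment] == 1L
  list(maxima = picks[is_max, , drop = FALSE][, c("value", "time", "segment")],
       minima = picks[!is_max, , drop = FALSE][, c("value", "time", "segment")])
}

#' Summary statistics of an extrema set
#'
#' Arithmetic means of the local maxima and minima plus the global extrema
#' (largest maximum, smallest minimum). These four numbers, computed on
#' baseline walking, are the personalised thresholds of the framework.
#'
#' @param extrema A list with `maxima` and `minima` data frames as returned
#'   by [local_extrema] (possibly filtered).
#' @return A list with `avg_local_max`, `avg_local_min`, `global_max`,
#'   `global_min`. Fields whose extrema set is empty are `NA` with a
#'   warning-free marker; use `require_complete = TRUE` to error instead.
#' @param require_complete If `TRUE`, an empty maxima or minima set is an
#'   error.
#' @export
extrema_summary <- function(extrema, require_complete = FALSE) {
  mx <- extrema$maxima
  mn <- extrema$minima
  if (require_complete && (nrow(mx) == 0L || nrow(mn) == 0L))
    stop("missing extrema: cannot summarise an empty maxima or minima set",
         call. = FALSE)
  list(avg_local_max = if (nrow(mx) > 0L) mean(mx$value) else NA_real_,
       avg_local_min = if (nrow(mn) > 0L) mean(mn$value) else NA_real_,
       global_max = if (nrow(mx) > 0L) max(mx$value) else NA_real_,
       global_min = if (nrow(mn) > 0L) min(mn$value) else NA_real_)
}

#' Quartile (Tukey fence) outlier identification
#'
#' Flags values lying more than `c` interquartile ranges above the upper or
#' below the lower quartile. Quartiles are computed by linear interpolation
#' of the order statistics at position `(n - 1) p + 1` (the classic
#' interpolated-quantile definition), so e.g. for `{1, 2, 3, 4, 100}` the
#' quartiles are 2 and 4 and only 100 is flagged at the default `c = 1.5`.
#'
#' @param values Numeric vector, at least 4 values.
#' @param c Fence factor (default 1.5).
#' @return Logical vector marking outliers.
#' @export
outlier_quartile <- function(values, c = 1.5) {
  if (length(values) < 4L)
    stop("quartile outlier identification needs at least 4 values", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  values > q[2L] + c * iqr | values < q[1L] - c * iqr
}

#' Max-versus-mean outlier identification
#'
#' Tests whether the absolutely largest element of a set of (value, time)
#' pairs dominates the mean absolute value of the remaining elements by the
#' factor `c`: with `y*` the absolute maximum and `ybar` the mean |value|
#' over the set without it, `y*` is an outlier iff `y* >= c * ybar`. The
#' values are assumed all non-negative or all negative (apply separately to
#' maxima and minima sets). The test is scale invariant.
#'
#' @param values Numeric vector (all `>= 0` or all `< 0`), at least 2 values.
#' @param times Numeric vector of the corresponding sample times.
#' @param c Dominance factor (default 1.5).
#' @return A list: `is_outlier` (logical), `value`, `time` of the absolute
#'   maximum, and `mean_rest` (the reference mean).
#' @export
outlier_max_vs_mean <- function(values, times = seq_along(values), c = 1.5) {
  if (length(values) < 2L)
    stop("max-vs-mean outlier identification needs at least 2 values",
         call. = FALSE)
  if (length(times) != length(values))
    stop("`values` and `times` must have equal length", call. = FALSE)
  if (any(values < 0) && any(values >= 0))
    stop("values must be all non-negative or all negative", call. = FALSE)
  av <- abs(values)
  star <- which.max(av) # first index on ties = earliest time for sorted input
  ybar <- mean(av[-star])
  list(is_outlier = av[star] >= c * ybar,
       value = values[star], time = times[star], mean_rest = ybar)
}

#' Local extrema distribution monitor
#'
#' Detects low-magnitude clutter (sensor noise, irrelevant trunk motion) in
#' an extrema set by histogramming the extrema magnitudes in equidistant
#' bins of width `h` anchored at 0 and testing the counts of the five
#' lowest-magnitude bins against each other with [outlier_quartile]. If at
#' least one bin count is an outlier, the irrelevance bound is the highest
#' upper bin edge among outlier bins (maxima) or the lowest lower edge
#' (minima), then clamped so its magnitude is at least `clamp`. Extrema
#' whose magnitude falls at or below the bound are considered irrelevant.
#'
#' @param extrema Data frame with a `value` column: the maxima *or* the
#'   minima set from [local_extrema] (values all `>= 0` or all `< 0`).
#' @param kind `"maxima"` or `"minima"`.
#' @param h Bin width, signal units (e.g. 1 rad/s^2 for angular
#'   acceleration, 0.05 rad/s for angular velocity).
#' @param limit Half-range of magnitudes covered by the histogram (e.g.
#'   5 rad/s^2 or 0.25 rad/s); must span at least five bins.
#' @param clamp Magnitude floor/ceiling applied to a returned bound (e.g.
#'   2 rad/s^2: that magnitude range is attributable to noise-induced
#'   extrema or irrelevant trunk motion).
#' @param c Fence factor forwarded to [outlier_quartile].
#' @return The irrelevance bound (signed: positive for maxima, negative for
#'   minima), or `NULL` when no bin count is an outlier.
#' @export
distribution_monitor <- function(extrema, kind = c("maxima", "minima"),
                                 h, limit, clamp, c = 1.5) {
  kind <- match.arg(kind)
  if (h <= 0 || limit <= 0) stop("`h` and `limit` must be positive", call. = FALSE)
  nbins <- floor(limit / h + 1e-9)
  if (nbins < 5L)
    stop("distribution monitor needs at least five bins within the limit",
         call. = FALSE)
  if (nrow(extrema) == 0L)
    stop("empty extrema set", call. = FALSE)
  mag <- abs(extrema$value)
  counts <- vapply(1:5, function(b)
    sum(mag >= (b - 1) * h & mag < b * h), numeric(1))
  flagged <- outlier_quartile(counts, c = c)
  if (!any(flagged)) return(NULL)
  top <- max(which(flagged)) # highest upper edge (maxima) / lowest lower edge (minima)
  bound <- top * h
  bound <- max(bound, clamp)
  if (kind == "maxima") bound else -bound
}
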