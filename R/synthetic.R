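#' Spike-sequence container
#'
#' A long-format data frame holding multi-neuronal spike sequences: one row
#' per spike with columns `trial` (integer id), `channel` (integer),
#' `time` (ms) and `label` (optional class tag, `NA` if unlabelled). One
#' spike per channel per trial.
#'
#' @param times Numeric matrix, trials x channels (NA = missing spike).
#' @param labels Optional vector of per-trial class labels.
#' @return A data frame of class `"spike_sequences"`.
#' @export
spike_sequences <- function(times, labels = NULL) {
  times <- as.matrix(times)
  n <- nrow(times); k <- ncol(times)
  if (is.null(labels)) labels <- rep(NA, n)
  if (length(labels) != n)
    mnsd_stop("'labels' must have one entry per trial")
  out <- data.frame(
    trial = rep(seq_len(n), each = k),
    channel = rep(seq_len(k), times = n),
    time = as.vector(t(times)),
    label = rep(labels, each = k))
  class(out) <- c("spike_sequences", "data.frame")
  out
}

#' Convert spike sequences to a trials-by-channels matrix
#'
#' @param x A `spike_sequences` data frame, a long data frame with columns
#'   `trial`, `channel`, `time`, or a numeric matrix (returned as is).
#' @return Numeric matrix with one row per trial; attribute `"labels"`
#'   carries per-trial labels when present.
#' @export
as_spike_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    need <- c("trial", "channel", "time")
    if (!all(need %in% names(x)))
      mnsd_stop("long-format sequences need columns trial, channel, time")
    trials <- sort(unique(x$trial))
    channels <- sort(unique(x$channel))
    m <- matrix(NA_real_, length(trials), length(channels))
    ti <- match(x$trial, trials); ci <- match(x$channel, channels)
    m[cbind(ti, ci)] <- x$time
    if (!is.null(x$label)) {
      lab <- x$label[!duplicated(x$trial)]
      lab <- lab[order(unique(x$trial))]
      attr(m, "labels") <- lab
    }
    rownames(m) <- trials
    return(m)
  }
  if (is.numeric(x)) return(matrix(x, nrow = 1L))
  mnsd_stop("cannot interpret 'x' as spike sequences")
}

#' Labelled per-trial class tags of a sequence set
#'
#' @param x `spike_sequences` or a matrix with a `"labels"` attribute.
#' @return Vector of one label per trial (possibly `NA`).
#' @export
sequence_labels <- function(x) {
  m <- as_spike_matrix(x)
  lab <- attr(m, "labels")
  if (is.null(lab)) rep(NA, nrow(m)) else lab
}

#' Generate two Gaussian classes of 3-channel spike-time patterns
#'
#' Class 1 is drawn from an isotropic Gaussian around `anchor`; class 2 from
#' an isotropic Gaussian around a centroid displaced from the class-1 axis —
#' the line through `anchor` with direction `(1,1,1)/sqrt(3)` — by a
#' perpendicular distance `D_c`, along a seeded random direction orthogonal
#' to the axis. `D_c` must be positive: at zero the two point sets would
#' represent the same pattern, since detection is invariant to a common time
#' shift. Sample rows with any coordinate outside `[0, t_max]` are resampled
#' (not clipped, preserving the Gaussian shape) up to `max_resample` times.
#'
#' @param D_c Perpendicular distance (ms) of the class-2 centroid from the
#'   class-1 axis (> 0).
#' @param n_class1,n_class2 Pattern counts. Defaults 120 and 20.
#' @param sigma Per-channel standard deviation (ms). Default 1.
#' @param anchor Class-1 mean spike times (ms). Default `(12.5, 12.5, 12.5)`,
#'   the centre of the latency range.
#' @param t_max Upper bound of admissible spike times (ms). Default 25.
#' @param seed Optional RNG seed for reproducibility.
#' @param max_resample Cap on resampling attempts per class.
#' @return A `spike_sequences` data frame with labels 1 and 2; attribute
#'   `"class2_anchor"` records the displaced centroid.
#' @examples
#' x <- generate_spike_classes(D_c = 5, seed = 1)
#' table(sequence_labels(x))
#' @export
generate_spike_classes <- function(D_c, n_class1 = 120, n_class2 = 20,
                                   sigma = 1, anchor = c(12.5, 12.5, 12.5),
                                   t_max = 25, seed = NULL,
                                   max_resample = 1000) {
  if (D_c <= 0) mnsd_stop("'D_c' must be positive")
  if (sigma < 0) mnsd_stop("'sigma' must be non-negative")
  k <- length(anchor)
  if (!is.null(seed)) set.seed(seed)
  u <- rep(1, k) / sqrt(k)
  # seeded random unit vector orthogonal to the axis direction
  repeat {
    v <- stats::rnorm(k)
    v <- v - sum(v * u) * u
    if (sqrt(sum(v^2)) > 1e-8) break
  }
  v <- v / sqrt(sum(v^2))
  anchor2 <- anchor + D_c * v
  if (any(anchor2 < 0 | anchor2 > t_max))
    mnsd_stop("class-2 centroid falls outside [0, t_max]; shrink D_c or move the anchor")

  draw <- function(n, mu) {
    out <- matrix(NA_real_, n, k)
    need <- seq_len(n)
    tries <- 0L
    while (length(need)) {
      if (tries > max_resample)
        mnsd_stop("resampling cap exceeded; patterns escape [0, t_max]")
      cand <- matrix(stats::rnorm(length(need) * k, mean = rep(mu, each = length(need)),
                                  sd = sigma),
                     length(need), k)
      ok <- rowSums(cand < 0 | cand > t_max) == 0L
      out[need[ok], ] <- cand[ok, , drop = FALSE]
      need <- need[!ok]
      tries <- tries + 1L
    }
    out
  }
  x1 <- draw(n_class1, anchor)
  x2 <- draw(n_class2, anchor2)
  out <- spike_sequences(rbind(x1, x2),
                         labels = rep(c(1L, 2L), c(n_class1, n_class2)))
  attr(out, "class2_anchor") <- anchor2
  out
}

#' Add Gaussian timing jitter to spike sequences
#'
#' @param x Sequences (matrix or `spike_sequences`).
#' @param sd Jitter standard deviation (ms, >= 0); 0 is the identity.
#' @param seed Optional RNG seed.
#' @return Sequences of the same form as the input.
#' @export
jitter_sequences <- function(x, sd, seed = NULL) {
  if (sd < 0) mnsd_stop("'sd' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  m <- as_spike_matrix(x)
  if (sd > 0) {
    jit <- matrix(stats::rnorm(length(m), 0, sd), nrow(m), ncol(m))
    jit[is.na(m)] <- 0
    m2 <- m + jit
  } else m2 <- m
  if (is.matrix(x)) return(m2)
  spike_sequences(m2, labels = sequence_labels(x))
}

#' Encode sampled time series as a spike sequence by peak extraction
#'
#' For each channel, finds the time of the maximum sample inside the analysis
#' window (ties broken to the earliest maximum), subtracts the window start
#' and divides by `time_scale`, mapping the window onto model milliseconds.
#' With the defaults a 0.25 s window becomes 25 model ms.
#'
#' @param signals Numeric matrix (samples x channels) or list of equal-length
#'   numeric vectors.
#' @param times Sampling times in seconds (one per sample); alternatively
#'   give `rate` in Hz and times start at 0.
#' @param rate Sampling rate in Hz (used when `times` is `NULL`).
#' @param window Analysis window `(start, end)` in seconds relative to the
#'   recording. Default `c(0.1, 0.35)`.
#' @param time_scale Divisor mapping window milliseconds to model time units.
#'   Default 10.
#' @return Numeric vector of one spike time (model ms) per channel.
#' @examples
#' tt <- seq(0, 0.5, by = 1e-3)
#' sig <- outer(tt, c(0.225, 0.15, 0.30),
#'              function(t, p) exp(-((t - p) / 0.02)^2))
#' encode_peak_times(sig, times = tt)
#' @export
encode_peak_times <- function(signals, times = NULL, rate = NULL,
                              window = c(0.1, 0.35), time_scale = 10) {
  if (is.list(signals) && !is.data.frame(signals))
    signals <- do.call(cbind, signals)
  signals <- as.matrix(signals)
  if (is.null(times)) {
    if (is.null(rate)) mnsd_stop("give either 'times' or 'rate'")
    times <- (seq_len(nrow(signals)) - 1L) / rate
  }
  if (length(times) != nrow(signals))
    mnsd_stop("'times' must have one entry per sample")
  if (window[1] >= window[2]) mnsd_stop("'window' start must precede its end")
  if (time_scale <= 0) mnsd_stop("'time_scale' must be positive")
  keep <- which(times >= window[1] & times <= window[2])
  if (!length(keep)) mnsd_stop("the analysis window contains no samples")
  vapply(seq_len(ncol(signals)), function(j) {
    seg <- signals[keep, j]
    peak <- keep[which.max(seg)]  # which.max takes the earliest tie
    (times[peak] - window[1]) * 1000 / time_scale
  }, numeric(1))
}
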