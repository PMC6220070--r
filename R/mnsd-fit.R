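#' Fit (train) a multi-neuronal spike-sequence detector
#'
#' Builds an MNSD structure — `n` LIFL delay branches converging on one
#' coincidence-detecting target neuron — and trains its branch input weights
#' without supervision by presenting the rows of `x` in order. Each trial
#' resets every neuron to rest, injects one external spike per channel,
#' simulates the network event-driven, and applies the trial-batched
#' heterosynaptic STDP updates derived from the branch output times, clipping
#' weights to `[w_min, w_max]`.
#'
#' Because a branch's transmission delay is its spike latency
#' `1/(A w_n - 1)`, weight learning is delay learning: training moves the
#' synchronising input offsets of the structure (see
#' [simultaneity_offsets()]) toward the inter-spike offsets of the presented
#' pattern, so that its pulses arrive at the target together and fire it.
#'
#' @param x Training sequences: a numeric matrix with one row per trial and
#'   one column per channel (spike times in ms, all within `[0, 1/d]` after
#'   removing the common offset), a `spike_sequences` data frame, or `NULL`
#'   for an untrained structure (then `n_branches` is required). Training
#'   rows must be complete (no `NA`); partial sequences are only allowed at
#'   prediction time.
#' @param n_branches Number of delay branches (>= 2); defaults to the number
#'   of channels in `x`.
#' @param params Shared neuron constants, a [lifl_params()].
#' @param branch_weights Initial branch input weights `w(D_n, ES_n)`,
#'   recycled to `n_branches`. Default 1.08: unit-amplitude inputs then land
#'   every branch at the centre of the latency range (12.5 ms for d = 0.04).
#' @param target_weight Common weight `w(T, D_n)` of the branch-to-target
#'   synapses. Default: midpoint of [target_weight_bounds()], which
#'   guarantees that all `n` branches are needed to fire the target.
#' @param stdp [stdp_params()] for the heterosynaptic window.
#' @param lateral_amplitude Amplitude of the lateral pulses between adjacent
#'   branches. Default 0: lateral activity is purely modulatory (it drives
#'   the weight updates but does not perturb the neighbouring state).
#' @param w_min,w_max Clipping bounds for the branch weights. Defaults:
#'   `1 + d + 1e-3` (just above the branch activation bound, so branches keep
#'   firing and learning never halts) and 2 (latency never below 1 ms).
#' @param convention STDP timing convention, see [heterosynaptic_updates()].
#' @param learn If `FALSE`, sequences are presented without plasticity (the
#'   trajectory is then flat).
#' @return An object of class `"mnsd"` with components `weights` (trained
#'   branch weights), `target_weight`, `params`, `stdp`, `trajectory`
#'   (`(n_trials + 1) x n_branches` weight path), `desync` (per-trial spread
#'   of the branch output times, ms), and the configuration. Methods:
#'   [predict.mnsd()], `print`, `summary`, `coef`, `plot`, `residuals`,
#'   `simulate`.
#' @examples
#' pat <- matrix(rep(c(9, 12.5, 15), 40), ncol = 3, byrow = TRUE)
#' fit <- mnsd(pat)
#' coef(fit)
#' predict(fit, pat[1:2, ])
#' @export
mnsd <- function(x = NULL, n_branches = NULL, params = lifl_params(),
                 branch_weights = 1.08, target_weight = NULL,
                 stdp = stdp_params(), lateral_amplitude = 0,
                 w_min = NULL, w_max = 2,
                 convention = c("self_minus_neighbor", "neighbor_minus_self"),
                 learn = TRUE) {
  convention <- match.arg(convention)
  if (!is.null(x)) {
    x <- as_spike_matrix(x)
    if (is.null(n_branches)) n_branches <- ncol(x)
    if (ncol(x) != n_branches)
      mnsd_stop("sequence channel count does not match 'n_branches'")
    if (anyNA(x))
      mnsd_stop("training sequences must have one spike per channel (no NA)")
  }
  if (is.null(n_branches))
    mnsd_stop("'n_branches' is required when no training data is given")
  if (n_branches < 2) mnsd_stop("'n_branches' must be >= 2")

  d <- params$d
  if (is.null(w_min)) w_min <- 1 + d + 1e-3
  if (is.null(target_weight))
    target_weight <- mean(target_weight_bounds(d, n_branches))
  w <- rep_len(branch_weights, n_branches)
  if (any(w < 1 + d))
    mnsd_stop("initial branch weights must satisfy w >= 1 + d")
  if (w_min < 1 + d || w_max <= w_min)
    mnsd_stop("need 1 + d <= w_min < w_max")

  object <- structure(list(
    n_branches = as.integer(n_branches),
    weights = w,
    target_weight = target_weight,
    params = params,
    stdp = stdp,
    lateral_amplitude = lateral_amplitude,
    w_min = w_min, w_max = w_max,
    convention = convention,
    trajectory = matrix(w, nrow = 1L,
                        dimnames = list(NULL, paste0("D", seq_len(n_branches)))),
    desync = numeric(0),
    n_trials = 0L,
    call = match.call()
  ), class = "mnsd")

  if (!is.null(x) && nrow(x) > 0L) {
    traj <- matrix(NA_real_, nrow(x) + 1L, n_branches,
                   dimnames = list(NULL, paste0("D", seq_len(n_branches))))
    traj[1L, ] <- object$weights
    desync <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      pres <- mnsd_detect(object, x[i, ], learn = learn)
      object <- pres$model
      traj[i + 1L, ] <- object$weights
      desync[i] <- if (anyNA(pres$out_times)) NA_real_ else
        diff(range(pres$out_times))
    }
    object$trajectory <- traj
    object$desync <- desync
    object$n_trials <- nrow(x)
  }
  object
}

# Assemble the lifl_network for one presentation.
.mnsd_network <- function(object) {
  n <- object$n_branches
  syn <- data.frame(
    pre = c(paste0("ES", seq_len(n)), paste0("N", seq_len(n))),
    post = c(seq_len(n), rep(n + 1L, n)),
    weight = c(object$weights, rep(object$target_weight, n)))
  if (object$lateral_amplitude > 0) {
    lat <- data.frame(
      pre = paste0("N", rep(seq_len(n), each = 2L)),
      post = as.integer(rep(seq_len(n), each = 2L) + c(-1L, 1L)),
      weight = object$lateral_amplitude)
    lat <- lat[lat$post >= 1L & lat$post <= n, ]
    syn <- rbind(syn, lat)
  }
  lifl_network(n + 1L, syn, object$params)
}

#' Present a single sequence to an MNSD
#'
#' Resets all neurons to rest, injects the external spikes, runs the
#' event-driven simulation and reports whether the target neuron fired.
#' With `learn = TRUE` the trial-batched heterosynaptic updates are applied
#' to the branch weights (clipped to the model's `[w_min, w_max]`).
#'
#' @param object An `"mnsd"` object.
#' @param times Numeric vector of one spike time per channel (ms); `NA`
#'   denotes a missing spike (partial sequence), allowed only when
#'   `learn = FALSE`.
#' @param learn Apply plasticity after the trial?
#' @return A list: `detected` (did the target fire?), `chronicle` (data frame
#'   of all spikes), `out_times` (branch output times, `NA` if silent), `dw`
#'   (weight changes applied, zero vector if `learn = FALSE`), and `model`
#'   (the possibly updated object).
#' @export
mnsd_detect <- function(object, times, learn = FALSE) {
  if (!inherits(object, "mnsd")) mnsd_stop("not an mnsd object")
  n <- object$n_branches
  if (length(times) != n)
    mnsd_stop("sequence channel count does not match the structure")
  if (anyNA(times) && learn)
    mnsd_stop("partial sequences are not allowed during learning")
  live <- which(!is.na(times))
  if (length(live) == 0L) {
    return(list(detected = FALSE,
                chronicle = data.frame(time = numeric(), neuron = integer()),
                out_times = rep(NA_real_, n), dw = numeric(n),
                model = object))
  }
  events <- data.frame(time = times[live],
                       source = paste0("ES", live),
                       amplitude = 1)
  t_end <- max(times[live]) + 2 * max_latency(object$params$d) + 1
  chron <- run_lifl(.mnsd_network(object), events, t_end)
  out <- vapply(seq_len(n), function(i) {
    hit <- chron$time[chron$neuron == i]
    if (length(hit)) hit[1L] else NA_real_
  }, numeric(1))
  detected <- any(chron$neuron == n + 1L)
  dw <- numeric(n)
  if (learn) {
    dw <- heterosynaptic_updates(out, object$stdp, object$convention)
    object$weights <- pmin(pmax(object$weights + dw, object$w_min),
                           object$w_max)
  }
  list(detected = detected, chronicle = chron, out_times = out, dw = dw,
       model = object)
}

#' Predict detections for new sequences
#'
#' Presents each trial to the trained structure with plasticity disabled and
#' reports whether the target neuron fired. Partial sequences (`NA` spike
#' times) are allowed and, with target weights inside
#' [target_weight_bounds()], never detected.
#'
#' @param object An `"mnsd"` object.
#' @param newdata Matrix (trials x channels) or `spike_sequences`.
#' @param type `"detection"` for a logical vector (default) or `"chronicle"`
#'   for the list of per-trial spike chronicles.
#' @param ... Unused.
#' @return Logical vector of detections, or a list of chronicles.
#' @export
predict.mnsd <- function(object, newdata, type = c("detection", "chronicle"),
                         ...) {
  type <- match.arg(type)
  x <- as_spike_matrix(newdata)
  if (ncol(x) != object$n_branches)
    mnsd_stop("sequence channel count does not match the structure")
  res <- lapply(seq_len(nrow(x)),
                function(i) mnsd_detect(object, x[i, ], learn = FALSE))
  if (type == "detection")
    vapply(res, `[[`, logical(1), "detected")
  else
    lapply(res, `[[`, "chronicle")
}

#' @export
print.mnsd <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Multi-neuronal spike-sequence detector (LIFL + heterosynaptic STDP)\n")
  cat(sprintf("  %d delay branches; d = %g, L_d = %g, t_arp = %g\n",
              x$n_branches, x$params$d, x$params$L_d, x$params$t_arp))
  cat("  branch weights:", paste(signif(x$weights, digits), collapse = ", "),
      "\n")
  cat(sprintf("  target weight : %s  (bounds [%s, %s))\n",
              signif(x$target_weight, digits),
              signif(target_weight_bounds(x$params$d, x$n_branches)[1], digits),
              signif(target_weight_bounds(x$params$d, x$n_branches)[2], digits)))
  cat(sprintf("  trained on %d trial(s)\n", x$n_trials))
  invisible(x)
}

#' @export
coef.mnsd <- function(object, ...) {
  c(stats::setNames(object$weights,
                    paste0("w(D", seq_len(object$n_branches), ",ES",
                           seq_len(object$n_branches), ")")),
    "w(T,Dn)" = object$target_weight)
}

#' @export
summary.mnsd <- function(object, ...) {
  lat <- 1 / (object$weights - 1)
  out <- list(
    object = object,
    latencies = lat,
    offsets = simultaneity_offsets(object$weights),
    excursion = diff(range(object$trajectory)),
    final_desync = if (length(object$desync))
      utils::tail(stats::na.omit(object$desync), 1L) else NA_real_)
  class(out) <- "summary.mnsd"
  out
}

#' @export
print.summary.mnsd <- function(x, digits = 4L, ...) {
  print(x$object)
  cat("  branch latencies (ms):",
      paste(signif(x$latencies, digits), collapse = ", "), "\n")
  cat("  synchronising input offsets vs channel 1 (ms):",
      paste(signif(x$offsets, digits), collapse = ", "), "\n")
  if (x$object$n_trials > 0L) {
    cat(sprintf("  weight excursion over training: %s\n",
                signif(x$excursion, digits)))
    cat(sprintf("  final output desynchronisation: %s ms\n",
                signif(x$final_desync, digits)))
  }
  invisible(x)
}

#' @export
residuals.mnsd <- function(object, ...) {
  # per-trial output desynchronisation (spread of branch output times)
  object$desync
}

#' Plot the weight trajectory of a trained detector
#'
#' @param x An `"mnsd"` object.
#' @param which 1 = branch-weight path over trials, 2 = per-trial output
#'   desynchronisation.
#' @param ... Passed to [graphics::matplot()] / [graphics::plot()].
#' @export
plot.mnsd <- function(x, which = 1L, ...) {
  if (which == 1L) {
    graphics::matplot(seq_len(nrow(x$trajectory)) - 1L, x$trajectory,
                      type = "l", lty = 1,
                      xlab = "trial", ylab = "branch weight", ...)
    graphics::legend("topleft", legend = colnames(x$trajectory),
                     col = seq_len(ncol(x$trajectory)), lty = 1, bty = "n")
  } else {
    graphics::plot(seq_along(x$desync), x$desync, type = "l",
                   xlab = "trial", ylab = "output desynchronisation (ms)",
                   ...)
  }
  invisible(x)
}

#' Simulate spike sequences the detector is tuned to
#'
#' Draws patterns around the structure's synchronising offsets (the inputs
#' whose branch outputs coincide at the target), centred in the latency
#' range, with independent Gaussian jitter per channel.
#'
#' @param object An `"mnsd"` object.
#' @param nsim Number of sequences.
#' @param seed Optional RNG seed.
#' @param sd Per-channel jitter standard deviation (ms). Default 1.
#' @param centre Mean arrival time of the pattern (ms). Default half the
#'   maximum latency.
#' @param ... Unused.
#' @return A `spike_sequences` data frame.
#' @export
simulate.mnsd <- function(object, nsim = 1, seed = NULL, sd = 1,
                          centre = max_latency(object$params$d) / 2, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- c(0, simultaneity_offsets(object$weights))
  base <- base - mean(base) + centre
  times <- matrix(stats::rnorm(nsim * length(base), mean = base, sd = sd),
                  nrow = nsim, byrow = TRUE)
  spike_sequences(times)
}
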