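#' Confusion counts from labels and detections
#'
#' @param truth Logical vector (or coercible): is the trial a positive-class
#'   trial?
#' @param detected Logical vector of detector outputs.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(truth, detected) {
  truth <- as.logical(truth); detected <- as.logical(detected)
  if (length(truth) != length(detected))
    mnsd_stop("'truth' and 'detected' lengths differ")
  c(TP = sum(truth & detected), TN = sum(!truth & !detected),
    FP = sum(!truth & detected), FN = sum(truth & !detected))
}

#' Accuracy, precision and recall from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`. A metric whose
#' denominator is zero is undefined and reported as `NA` (never silently 0);
#' the names of the undefined metrics are attached as attribute
#' `"undefined"`.
#'
#' @param TP,TN,FP,FN Non-negative counts; alternatively pass a single named
#'   vector as produced by [confusion_counts()] in `TP`.
#' @return Named numeric `c(accuracy, precision, recall)`.
#' @examples
#' classification_metrics(15, 15, 7, 7)  # all 0.6818...
#' @export
classification_metrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (length(TP) == 4L && is.null(TN)) {
    cc <- TP
    TP <- cc[["TP"]]; TN <- cc[["TN"]]; FP <- cc[["FP"]]; FN <- cc[["FN"]]
  }
  if (any(c(TP, TN, FP, FN) < 0)) mnsd_stop("counts must be non-negative")
  tot <- TP + TN + FP + FN
  und <- character(0)
  acc <- if (tot > 0) (TP + TN) / tot else {und <- c(und, "accuracy"); NA_real_}
  prec <- if (TP + FP > 0) TP / (TP + FP) else {und <- c(und, "precision"); NA_real_}
  rec <- if (TP + FN > 0) TP / (TP + FN) else {und <- c(und, "recall"); NA_real_}
  out <- c(accuracy = acc, precision = prec, recall = rec)
  if (length(und)) attr(out, "undefined") <- und
  out
}

#' Run the two-class synthetic classification experiment
#'
#' Generates the two Gaussian pattern classes with [generate_spike_classes()],
#' trains an MNSD without supervision on the first `n_train` class-1 patterns,
#' freezes the weights, and predicts on a mixed test set — the remaining
#' class-1 patterns and all class-2 patterns. Class 1 is the positive class;
#' detection (a target spike) is a positive prediction.
#'
#' @param D_c Class separation: perpendicular distance of the class-2
#'   centroid from the class-1 axis (ms).
#' @param L_d Decay parameter (1/ms). Default 0.37.
#' @param seed RNG seed for the generator (the rest of the pipeline is
#'   deterministic).
#' @param n_class1,n_class2 Generated pattern counts (defaults 120, 20).
#' @param n_train Class-1 patterns used for training (default 100); the
#'   remaining `n_class1 - n_train` are the positive test set.
#' @param sigma Within-class standard deviation (ms). Default 1.
#' @param A_pm Magnitude of the STDP amplitudes (`A_plus = -A_minus = A_pm`).
#'   Default 0.002.
#' @param ... Further arguments passed to [mnsd()] (e.g. `target_weight`,
#'   `branch_weights`).
#' @return An object of class `"mnsd_experiment"`: list with `fit` (the
#'   trained `"mnsd"`), `counts` (TP/TN/FP/FN), `metrics`, `detections`,
#'   `truth`, and the configuration.
#' @examples
#' ex <- run_mnsd_experiment(D_c = 5, seed = 1,
#'                           n_class1 = 30, n_class2 = 10, n_train = 20)
#' ex$metrics
#' @export
run_mnsd_experiment <- function(D_c, L_d = 0.37, seed = 1,
                                n_class1 = 120, n_class2 = 20,
                                n_train = 100, sigma = 1, A_pm = 0.002,
                                ...) {
  if (n_train >= n_class1)
    mnsd_stop("'n_train' must leave class-1 patterns for the test set")
  seqs <- generate_spike_classes(D_c = D_c, n_class1 = n_class1,
                                 n_class2 = n_class2, sigma = sigma,
                                 seed = seed)
  m <- as_spike_matrix(seqs)
  lab <- sequence_labels(seqs)
  train <- m[lab == 1L, , drop = FALSE][seq_len(n_train), , drop = FALSE]
  test <- rbind(m[lab == 1L, , drop = FALSE][-seq_len(n_train), , drop = FALSE],
                m[lab == 2L, , drop = FALSE])
  truth <- rep(c(TRUE, FALSE), c(n_class1 - n_train, n_class2))

  fit <- mnsd(train, params = lifl_params(L_d = L_d),
              stdp = stdp_params(A_plus = A_pm, A_minus = -A_pm), ...)
  det <- predict(fit, test)
  counts <- confusion_counts(truth, det)
  structure(list(fit = fit, counts = counts,
                 metrics = classification_metrics(counts),
                 detections = det, truth = truth,
                 config = list(D_c = D_c, L_d = L_d, seed = seed,
                               n_class1 = n_class1, n_class2 = n_class2,
                               n_train = n_train, sigma = sigma,
                               A_pm = A_pm)),
            class = "mnsd_experiment")
}

#' @export
print.mnsd_experiment <- function(x, ...) {
  cat(sprintf("MNSD two-class experiment: D_c = %g, L_d = %g, seed = %g\n",
              x$config$D_c, x$config$L_d, x$config$seed))
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$counts[["TP"]], x$counts[["TN"]],
              x$counts[["FP"]], x$counts[["FN"]]))
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f\n",
              x$metrics[["accuracy"]], x$metrics[["precision"]],
              x$metrics[["recall"]]))
  invisible(x)
}

#' Sweep the experiment over class separations and decay parameters
#'
#' Runs [run_mnsd_experiment()] for every combination of `D_c`, `L_d` and
#' seed, reusing the same seeds in every cell (common random numbers, so
#' cell-to-cell contrasts are not confounded by generator noise).
#'
#' @param D_c Numeric vector of class separations. Default `c(2, 3.5, 5)`.
#' @param L_d Numeric vector of decay parameters. Default
#'   `c(0.25, 0.37, 0.55)`.
#' @param seeds Integer vector of generator seeds (>= 5 replicates
#'   recommended). Default `1:5`.
#' @param ... Passed to [run_mnsd_experiment()].
#' @return A data frame with one row per (D_c, L_d, seed): the metrics and
#'   confusion counts.
#' @export
mnsd_sweep <- function(D_c = c(2, 3.5, 5), L_d = c(0.25, 0.37, 0.55),
                       seeds = 1:5, ...) {
  if (!length(D_c) || !length(L_d) || !length(seeds))
    mnsd_stop("'D_c', 'L_d' and 'seeds' must be non-empty")
  grid <- expand.grid(seed = seeds, L_d = L_d, D_c = D_c,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ex <- run_mnsd_experiment(D_c = grid$D_c[i], L_d = grid$L_d[i],
                              seed = grid$seed[i], ...)
    data.frame(D_c = grid$D_c[i], L_d = grid$L_d[i], seed = grid$seed[i],
               accuracy = ex$metrics[["accuracy"]],
               precision = ex$metrics[["precision"]],
               recall = ex$metrics[["recall"]],
               TP = ex$counts[["TP"]], TN = ex$counts[["TN"]],
               FP = ex$counts[["FP"]], FN = ex$counts[["FN"]])
  })
  do.call(rbind, rows)
}
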