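#' Read and write spike-sequence files
#'
#' Sequences travel as UTF-8 tab-delimited text with a header row and columns
#' `trial`, `channel`, `time`, `label` (one row per spike). Times are written
#' with 17 significant digits so a write/read cycle reproduces them
#' bit-exactly.
#'
#' @param x Sequences (`spike_sequences` or matrix) to write.
#' @param path File path.
#' @return `read_spike_sequences()` returns a `spike_sequences` data frame;
#'   `write_spike_sequences()` returns `path` invisibly.
#' @export
write_spike_sequences <- function(x, path) {
  if (is.matrix(x)) x <- spike_sequences(x, labels = attr(x, "labels"))
  df <- as.data.frame(x)
  df$time <- fmt_num(df$time)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spike_sequences
#' @export
read_spike_sequences <- function(path) {
  if (!file.exists(path)) mnsd_stop("no such sequence file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("trial", "channel", "time")
  if (!all(need %in% names(df)))
    mnsd_stop("sequence file needs columns trial, channel, time")
  if (is.null(df$label)) df$label <- NA
  df$time <- as.numeric(df$time)
  class(df) <- c("spike_sequences", "data.frame")
  df
}

#' Serialise an MNSD model to flat key-value text
#'
#' Writes every quantity needed to reconstruct the detector — weights, neuron
#' constants, STDP parameters, clipping bounds, convention — as `key value`
#' lines. Numerics use 17 significant digits, so a write/read round trip is
#' bit-exact. The weight trajectory is not stored here; see
#' [write_weight_trajectory()].
#'
#' @param object An `"mnsd"` object.
#' @param path File path.
#' @return `read_mnsd()` returns an `"mnsd"` object; `write_mnsd()` returns
#'   `path` invisibly.
#' @export
write_mnsd <- function(object, path) {
  if (!inherits(object, "mnsd")) mnsd_stop("not an mnsd object")
  num <- function(x) paste(fmt_num(x), collapse = ",")
  lines <- c(
    "format mnsd-model-1",
    paste("n_branches", object$n_branches),
    paste("branch_weights", num(object$weights)),
    paste("target_weight", num(object$target_weight)),
    paste("d", num(object$params$d)),
    paste("L_d", num(object$params$L_d)),
    paste("t_arp", num(object$params$t_arp)),
    paste("A_plus", num(object$stdp$A_plus)),
    paste("A_minus", num(object$stdp$A_minus)),
    paste("tau_plus", num(object$stdp$tau_plus)),
    paste("tau_minus", num(object$stdp$tau_minus)),
    paste("lateral_amplitude", num(object$lateral_amplitude)),
    paste("w_min", num(object$w_min)),
    paste("w_max", num(object$w_max)),
    paste("convention", object$convention),
    paste("n_trials", object$n_trials))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_mnsd
#' @export
read_mnsd <- function(path) {
  if (!file.exists(path)) mnsd_stop("no such model file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  kv <- regmatches(lines, regexpr(" ", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) mnsd_stop("model file is missing field '", k, "'")
    vals[i]
  }
  if (get("format") != "mnsd-model-1") mnsd_stop("unrecognised model format")
  nums <- function(k) as.numeric(strsplit(get(k), ",", fixed = TRUE)[[1]])
  obj <- mnsd(NULL,
              n_branches = as.integer(get("n_branches")),
              params = lifl_params(d = nums("d"), L_d = nums("L_d"),
                                   t_arp = nums("t_arp")),
              branch_weights = nums("branch_weights"),
              target_weight = nums("target_weight"),
              stdp = stdp_params(A_plus = nums("A_plus"),
                                 A_minus = nums("A_minus"),
                                 tau_plus = nums("tau_plus"),
                                 tau_minus = nums("tau_minus")),
              lateral_amplitude = nums("lateral_amplitude"),
              w_min = nums("w_min"), w_max = nums("w_max"),
              convention = get("convention"))
  obj$n_trials <- as.integer(get("n_trials"))
  obj
}

#' Export a trained model's weight trajectory as tabular text
#'
#' One row per (trial, branch) with the branch weight after that trial; trial
#' 0 carries the initial weights.
#'
#' @param object An `"mnsd"` object.
#' @param path File path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_weight_trajectory <- function(object, path) {
  if (!inherits(object, "mnsd")) mnsd_stop("not an mnsd object")
  tr <- object$trajectory
  df <- data.frame(
    trial = rep(seq_len(nrow(tr)) - 1L, each = ncol(tr)),
    branch = rep(seq_len(ncol(tr)), times = nrow(tr)),
    weight = fmt_num(as.vector(t(tr))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
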