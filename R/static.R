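#' Branch activation condition
#'
#' A delay branch fires for every external spike iff the incoming pulse
#' reaches the threshold from rest: `A * w >= 1 + d`.
#'
#' @param amplitude External spike amplitude `A`.
#' @param weight Branch input weight `w(D_n, ES_n)`.
#' @param d Threshold constant.
#' @return Logical. Vectorised over its arguments.
#' @examples
#' check_branch_activation(1, 1.08, 0.04)  # TRUE
#' check_branch_activation(1, 1.00, 0.04)  # FALSE
#' @export
check_branch_activation <- function(amplitude, weight, d) {
  amplitude * weight >= 1 + d
}

#' Admissible target-weight interval
#'
#' With `k` unit-amplitude branch pulses required to drive the target over
#' threshold, the common target weight must satisfy
#' `(1 + d)/k <= w(T, D_n) < (1 + d)/(k - 1)`: large enough that all `k`
#' synchronous pulses fire the target, small enough that any `k - 1` (a
#' partial sequence) cannot.
#'
#' @param d Threshold constant.
#' @param k Number of branches required (>= 2). Default 3.
#' @return Named numeric `c(lower, upper)`; the interval is half-open,
#'   `[lower, upper)`.
#' @examples
#' target_weight_bounds(0.04, 3)  # 0.3466667 0.52
#' @export
target_weight_bounds <- function(d, k = 3) {
  if (k < 2) mnsd_stop("'k' must be >= 2")
  c(lower = (1 + d) / k, upper = (1 + d) / (k - 1))
}

#' Input offsets that synchronise the branch outputs
#'
#' For branch input weights `w_n > 1`, the input timing differences
#' `dt_in(D1, Dn) = 1/(w_1 - 1) - 1/(w_n - 1)` (n >= 2) make all branch
#' output pulses reach the target at the same instant, since branch `n`
#' delays its input by the latency `1/(w_n - 1)`.
#'
#' @param branch_weights Numeric vector of branch input weights (> 1).
#' @return Numeric vector of length `length(branch_weights) - 1`, named
#'   `"D1D2"`, `"D1D3"`, ...: the offsets `t_in(Dn) - t_in(D1)`.
#' @examples
#' simultaneity_offsets(c(1.08, 1.1, 1.08))  # 2.5, 0
#' @export
simultaneity_offsets <- function(branch_weights) {
  if (any(branch_weights <= 1))
    mnsd_stop("branch weights must exceed 1")
  n <- length(branch_weights)
  if (n < 2) mnsd_stop("need at least two branches")
  lat <- 1 / (branch_weights - 1)
  off <- lat[1] - lat[-1]
  names(off) <- paste0("D1D", seq(2, n))
  off
}

#' Jitter-tolerance condition for target firing
#'
#' Evaluates whether input offsets `dt_in(D1, D2)` and `dt_in(D1, D3)` keep a
#' three-branch structure within its detection tolerance. The residual
#' desynchronisation of branch `n` is
#' `r_n = dt_in(D1, Dn) - 1/(w_1 - 1) + 1/(w_n - 1)` — the branch-output
#' timing error left after the latencies. When the two input offsets have
#' concordant sign the condition is `max(|r_2|, |r_3|) < bound`; with
#' discordant signs it is `|r_2 - r_3| < bound`. A zero offset counts as
#' concordant with anything.
#'
#' The default bound is `(2 - d) / L_d` (ms). Note this equals the
#' event-driven threshold condition at the target, `(3 w_T - 1 - d) / L_d`,
#' only for unit target weights; pass `bound` explicitly to match a specific
#' target weight (see the vignette).
#'
#' @param delta_in_12,delta_in_13 Input timing offsets `t_in(D2) - t_in(D1)`
#'   and `t_in(D3) - t_in(D1)` (ms).
#' @param branch_weights Numeric vector of the three branch weights (> 1).
#' @param d Threshold constant.
#' @param L_d Decay parameter (> 0).
#' @param bound Tolerance bound in ms; default `(2 - d) / L_d`.
#' @return Logical: `TRUE` if the offsets are within tolerance.
#' @export
tolerance_condition <- function(delta_in_12, delta_in_13, branch_weights,
                                d, L_d, bound = NULL) {
  if (length(branch_weights) != 3L)
    mnsd_stop("'branch_weights' must have length 3")
  if (any(branch_weights <= 1)) mnsd_stop("branch weights must exceed 1")
  if (L_d <= 0) mnsd_stop("'L_d' must be positive for the tolerance bound")
  if (is.null(bound)) bound <- (2 - d) / L_d
  lat <- 1 / (branch_weights - 1)
  r2 <- delta_in_12 - lat[1] + lat[2]
  r3 <- delta_in_13 - lat[1] + lat[3]
  if (delta_in_12 * delta_in_13 >= 0) {
    max(abs(r2), abs(r3)) < bound
  } else {
    abs(r2 - r3) < bound
  }
}

#' Class-hypervolume axis of a trained structure
#'
#' The set of patterns a trained structure detects forms a cylinder in
#' spike-time space whose axis has direction `(1, ..., 1)/sqrt(n)` — detection
#' depends only on the inter-spike intervals, not on the arrival time of the
#' first spike. The printed anchor follows the published closed form,
#' `t_offset + 1/(w_n - 1)` per branch.
#'
#' Note: the anchor of the *synchronising* input patterns (those whose branch
#' outputs coincide at the target) has the negated offsets,
#' `t_offset - 1/(w_n - 1)` up to a constant; use [simultaneity_offsets()]
#' for the patterns the structure actually detects. See the vignette for the
#' discrepancy.
#'
#' @param branch_weights Numeric vector of branch input weights (> 1).
#' @param t_offset Arrival time of the first pulse (ms). Default 0.
#' @return An object of class `"mnsd_axis"`: list with `anchor` (per-branch
#'   ms coordinates) and `direction` (unit vector).
#' @examples
#' hypervolume_axis(c(1.1, 1.08, 1.05))$anchor  # 10, 12.5, 20
#' @export
hypervolume_axis <- function(branch_weights, t_offset = 0) {
  if (any(branch_weights <= 1)) mnsd_stop("branch weights must exceed 1")
  n <- length(branch_weights)
  structure(list(anchor = t_offset + 1 / (branch_weights - 1),
                 direction = rep(1, n) / sqrt(n)),
            class = "mnsd_axis")
}

#' @export
print.mnsd_axis <- function(x, ...) {
  cat("Class-hypervolume axis (45 degrees to every coordinate axis)\n")
  cat("  anchor   :", paste(signif(x$anchor, 6), collapse = ", "), "ms\n")
  cat("  direction:", paste(signif(x$direction, 6), collapse = ", "), "\n")
  invisible(x)
}

# Perpendicular distance of points (rows of x) to the line through `anchor`
# with direction `u` (unit). Used by the generator and its tests.
.axis_distance <- function(x, anchor, u) {
  x <- sweep(as.matrix(x), 2L, anchor)
  proj <- x %*% u
  sqrt(pmax(0, rowSums(x^2) - as.vector(proj)^2))
}
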