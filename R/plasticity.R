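#' STDP parameters
#'
#' Amplitudes and time constants of the exponential spike-timing-dependent
#' plasticity window. `A_plus` (> 0) and `A_minus` (< 0) are the maximum
#' potentiation and depression amplitudes, chosen as absolute weight changes;
#' `tau_plus` and `tau_minus` (ms) set how fast the window decays with the
#' post-minus-pre timing difference.
#'
#' @param A_plus Maximum potentiation (> 0). Default 0.002.
#' @param A_minus Maximum depression (< 0). Default -0.002.
#' @param tau_plus,tau_minus Time constants (ms, > 0). Default 9.6, chosen so
#'   spikes of one sequence interact while adjacent sequences do not.
#' @return An object of class `"stdp_params"`.
#' @export
stdp_params <- function(A_plus = 0.002, A_minus = -0.002,
                        tau_plus = 9.6, tau_minus = 9.6) {
  if (A_plus < 0) mnsd_stop("'A_plus' must be >= 0")
  if (A_minus > 0) mnsd_stop("'A_minus' must be <= 0")
  if (tau_plus <= 0 || tau_minus <= 0)
    mnsd_stop("'tau_plus' and 'tau_minus' must be positive")
  structure(list(A_plus = A_plus, A_minus = A_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus),
            class = "stdp_params")
}

#' @export
print.stdp_params <- function(x, ...) {
  cat(sprintf("STDP window: A+ = %g, A- = %g, tau+ = %g ms, tau- = %g ms\n",
              x$A_plus, x$A_minus, x$tau_plus, x$tau_minus))
  invisible(x)
}

#' STDP weight change for a timing difference
#'
#' The exponential learning window: potentiation `A_plus * exp(-dT/tau_plus)`
#' for `dT > 0` (pre before post), exactly 0 at `dT = 0`, and depression
#' `A_minus * exp(dT/tau_minus)` for `dT < 0`.
#'
#' @param params [stdp_params()].
#' @param delta_T Post-minus-pre timing difference(s) in ms. Vectorised.
#' @return Signed weight change(s), bounded by `max(A_plus, |A_minus|)` in
#'   magnitude.
#' @examples
#' stdp_delta(stdp_params(), 9.6)  # 0.002 * exp(-1)
#' stdp_delta(stdp_params(), 0)    # 0
#' @export
stdp_delta <- function(params, delta_T) {
  out <- numeric(length(delta_T))
  up <- !is.na(delta_T) & delta_T > 0
  dn <- !is.na(delta_T) & delta_T < 0
  out[up] <- params$A_plus * exp(-delta_T[up] / params$tau_plus)
  out[dn] <- params$A_minus * exp(delta_T[dn] / params$tau_minus)
  out[is.na(delta_T)] <- NA_real_
  out
}

#' Heterosynaptic nearest-neighbour weight updates
#'
#' For each delay branch `n`, sums the STDP contributions driven by its
#' lateral neighbours `n - 1` and `n + 1` (boundary branches have a single
#' neighbour). The timing difference fed to the window for the influence of
#' neighbour `m` on branch `n` is `t_out(n) - t_out(m)` — the branch's own
#' output minus the neighbour's, i.e. post-minus-pre with the instantaneous
#' lateral pulse as "pre". A branch fires later than its neighbour, is
#' potentiated, and so fires earlier on the next presentation; this is the
#' convention under which repeated presentation synchronises the branch
#' outputs (see the package vignette). `convention = "neighbor_minus_self"`
#' flips the sign for comparison.
#'
#' Branches that did not fire receive no update, and a silent neighbour
#' contributes nothing.
#'
#' @param out_times Numeric vector of branch output spike times (ms), `NA`
#'   for a branch that did not fire. At most one output per branch per trial.
#' @param params [stdp_params()].
#' @param convention `"self_minus_neighbor"` (default, synchronising) or
#'   `"neighbor_minus_self"`.
#' @return Numeric vector of weight changes, one per branch.
#' @examples
#' heterosynaptic_updates(c(10, 10, 10), stdp_params())  # all zero
#' @export
heterosynaptic_updates <- function(out_times, params,
                                   convention = c("self_minus_neighbor",
                                                  "neighbor_minus_self")) {
  convention <- match.arg(convention)
  sgn <- if (convention == "self_minus_neighbor") 1 else -1
  n <- length(out_times)
  dw <- numeric(n)
  for (b in seq_len(n)) {
    if (is.na(out_times[b])) next
    for (m in intersect(c(b - 1L, b + 1L), seq_len(n))) {
      if (is.na(out_times[m])) next
      dw[b] <- dw[b] + stdp_delta(params, sgn * (out_times[b] - out_times[m]))
    }
  }
  dw
}
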