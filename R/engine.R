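#' Define a small feed-forward LIFL network
#'
#' Neurons are numbered `1..n_neurons`. Synapses connect a source — either an
#' external channel (any character label, e.g. `"ES1"`) or a neuron (its
#' integer index, or the label `"N<i>"`) — to a postsynaptic neuron with a
#' dimensionless weight. Delivery is instantaneous; the only delays in the
#' network are the spike latencies.
#'
#' @param n_neurons Number of neurons (>= 1).
#' @param synapses Data frame with columns `pre` (character source label),
#'   `post` (neuron index) and `weight`.
#' @param params A single [lifl_params()] shared by all neurons, or a list of
#'   one per neuron.
#' @return An object of class `"lifl_network"`.
#' @examples
#' net <- lifl_network(1, data.frame(pre = "ES1", post = 1, weight = 1.08))
#' run_lifl(net, data.frame(time = 0, source = "ES1", amplitude = 1), 30)
#' @export
lifl_network <- function(n_neurons, synapses, params = lifl_params()) {
  if (n_neurons < 1L) mnsd_stop("'n_neurons' must be >= 1")
  synapses <- as.data.frame(synapses)
  need <- c("pre", "post", "weight")
  if (!all(need %in% names(synapses)))
    mnsd_stop("'synapses' needs columns pre, post, weight")
  synapses$pre <- as.character(synapses$pre)
  if (any(synapses$post < 1L | synapses$post > n_neurons))
    mnsd_stop("synapse 'post' out of range")
  if (inherits(params, "lifl_params")) params <- rep(list(params), n_neurons)
  if (length(params) != n_neurons)
    mnsd_stop("'params' must be one lifl_params or one per neuron")
  structure(list(n = as.integer(n_neurons), synapses = synapses,
                 params = params),
            class = "lifl_network")
}

# Deterministic integer rank for event sources: external channels first
# (sorted with a fixed locale), then neurons in index order.
.source_ranks <- function(network, external_sources) {
  ext <- sort(unique(external_sources), method = "radix")
  c(stats::setNames(seq_along(ext), ext),
    stats::setNames(length(ext) + seq_len(network$n),
                    paste0("N", seq_len(network$n))))
}

#' Run an event-driven LIFL network simulation
#'
#' Processes external pulses and internally scheduled fires in global time
#' order and returns the chronicle of every emitted spike. The schedule is
#' deterministic: simultaneous pulse deliveries are processed in ascending
#' (time, source) order, and a pulse arriving at the same instant as a
#' scheduled fire is delivered first, so it can still alter the latency.
#' Pulses reaching a refractory neuron are discarded.
#'
#' @param network [lifl_network()].
#' @param events Data frame of external pulses with columns `time` (ms),
#'   `source` (channel label) and optionally `amplitude` (default 1).
#' @param t_end End of the simulated window (ms); fires scheduled later are
#'   not emitted.
#' @return A data frame with columns `time` and `neuron`, ordered by time.
#' @export
run_lifl <- function(network, events, t_end) {
  if (!inherits(network, "lifl_network")) mnsd_stop("not a lifl_network")
  if (is.null(events) || nrow(events) == 0L)
    events <- data.frame(time = numeric(), source = character(),
                         amplitude = numeric())
  events <- as.data.frame(events)
  if (is.null(events$amplitude)) events$amplitude <- rep(1, nrow(events))
  events$source <- as.character(events$source)
  if (any(events$time < 0)) mnsd_stop("event times must be >= 0")
  if (!is.finite(t_end)) mnsd_stop("'t_end' must be finite")

  rank <- .source_ranks(network, events$source)
  if (any(!events$source %in% names(rank)))
    mnsd_stop("unknown event source label")

  syn <- network$synapses
  syn <- syn[order(syn$post), , drop = FALSE]  # delivery order within a pulse

  states <- replicate(network$n, lifl_rest_state(), simplify = FALSE)

  # pending pulse emissions (external + spikes as they occur)
  q_time <- events$time
  q_rank <- unname(rank[events$source])
  q_src  <- events$source
  q_amp  <- events$amplitude

  spikes_t <- numeric()
  spikes_i <- integer()

  pop_min <- function() {
    # index of earliest pending emission, ties by source rank
    o <- order(q_time, q_rank)[1L]
    o
  }

  repeat {
    t_emln <- if (length(q_time)) min(q_time) else Inf
    t_fires <- vapply(states, function(s)
      if (s$mode == "active") s$t_fire else Inf, numeric(1))
    t_fire <- min(t_fires)
    t_next <- min(t_emln, t_fire)
    if (t_next > t_end + .time_tol) break

    if (t_emln <= t_fire + .time_tol) {
      # deliver the earliest pending pulse (input before fire at a tie)
      k <- pop_min()
      src <- q_src[k]; tt <- q_time[k]; amp <- q_amp[k]
      q_time <- q_time[-k]; q_rank <- q_rank[-k]
      q_src <- q_src[-k]; q_amp <- q_amp[-k]
      hit <- which(syn$pre == src)
      for (j in hit) {
        post <- syn$post[j]
        states[[post]] <- lifl_apply_input(states[[post]],
                                           network$params[[post]],
                                           tt, amp, syn$weight[j])
      }
    } else {
      i <- which.min(t_fires)
      fired <- lifl_fire(states[[i]], network$params[[i]], t_fires[i])
      states[[i]] <- fired$state
      spikes_t <- c(spikes_t, fired$spike$time)
      spikes_i <- c(spikes_i, i)
      lab <- paste0("N", i)
      q_time <- c(q_time, fired$spike$time)
      q_rank <- c(q_rank, unname(rank[lab]))
      q_src <- c(q_src, lab)
      q_amp <- c(q_amp, fired$spike$amplitude)
    }
  }
  data.frame(time = spikes_t, neuron = spikes_i)
}
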