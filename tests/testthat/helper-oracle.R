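# Independent clock-driven LIFL simulator used as the reference for the
# event-driven engine. It advances a fixed wall-clock grid (dt, default
# 1e-4 ms), applying the passive decay and active rise increments over each
# sub-interval, splitting a step whenever a pulse delivery or a fire falls
# inside it. Fires are detected from the remaining latency 1/(S-1) crossing
# the current sub-interval; no fire scheduling, rescheduling or event queue
# is shared with the engine.
clock_lifl <- function(network, events, t_end, dt = 1e-4) {
  n <- network$n
  syn <- network$synapses
  d <- vapply(network$params, `[[`, numeric(1), "d")
  Ld <- vapply(network$params, `[[`, numeric(1), "L_d")
  tarp <- vapply(network$params, `[[`, numeric(1), "t_arp")
  Sth <- 1 + d

  S <- numeric(n)
  active <- logical(n)
  refr_end <- rep(-Inf, n)

  events <- events[order(events$time), , drop = FALSE]
  if (is.null(events$amplitude)) events$amplitude <- rep(1, nrow(events))
  del_t <- events$time
  del_src <- as.character(events$source)
  del_amp <- events$amplitude

  spikes_t <- numeric(); spikes_i <- integer()
  t <- 0

  deliver <- function(src, amp, tt) {
    hit <- which(syn$pre == src)
    for (j in hit) {
      i <- syn$post[j]
      if (tt < refr_end[i]) next               # refractory: discard
      if (refr_end[i] > -Inf && tt >= refr_end[i]) {
        S[i] <<- 0; active[i] <<- FALSE; refr_end[i] <<- -Inf
      }
      S[i] <<- S[i] + amp * syn$weight[j]
      if (!active[i] && S[i] >= Sth[i]) active[i] <<- TRUE
    }
  }

  advance <- function(delta) {
    # evolve every neuron over an interval containing no delivery or fire
    idx <- which(!active & S > 0 & refr_end == -Inf)
    S[idx] <<- pmax(0, S[idx] - Ld[idx] * delta)
    idx <- which(active)
    S[idx] <<- S[idx] + (S[idx] - 1)^2 * delta / (1 - (S[idx] - 1) * delta)
    done <- which(refr_end > -Inf & refr_end <= t + delta)
    if (length(done)) { S[done] <<- 0; refr_end[done] <<- -Inf }
  }

  repeat {
    t_del <- if (length(del_t)) del_t[1] else Inf
    if (!any(active) && all(S == 0) && all(refr_end == -Inf)) {
      # fully at rest: nothing evolves until the next delivery
      if (t_del > t_end + 1e-12) break
      t <- t_del
      while (length(del_t) && del_t[1] <= t + 1e-12) {
        deliver(del_src[1], del_amp[1], t)
        del_t <- del_t[-1]; del_src <- del_src[-1]; del_amp <- del_amp[-1]
      }
      next
    }
    t_grid <- (floor(t / dt + 1e-9) + 1) * dt
    ttf <- rep(Inf, n)
    ttf[active] <- 1 / (S[active] - 1)
    t_fire <- t + min(ttf)
    t_stop <- min(t_grid, t_del, t_fire, t_end)
    if (t_stop > t_end + 1e-12) break

    if (t_fire <= t_stop + 1e-12 && t_fire <= t_end + 1e-12) {
      i <- which.min(ttf)
      advance(t_fire - t)
      t <- t_fire
      spikes_t <- c(spikes_t, t); spikes_i <- c(spikes_i, i)
      S[i] <- 0; active[i] <- FALSE
      refr_end[i] <- if (tarp[i] > 0) t + tarp[i] else -Inf
      deliver(paste0("N", i), 1, t)
      next
    }
    advance(t_stop - t)
    t <- t_stop
    while (length(del_t) && del_t[1] <= t + 1e-12) {
      deliver(del_src[1], del_amp[1], t)
      del_t <- del_t[-1]; del_src <- del_src[-1]; del_amp <- del_amp[-1]
    }
  }
  data.frame(time = spikes_t, neuron = spikes_i)
}

# Random small feed-forward network plus a random event list, continuous
# times (no exact coincidences), for engine-vs-oracle comparisons.
random_lifl_case <- function() {
  n <- sample(2:5, 1)
  n_ext <- sample(1:3, 1)
  params <- lapply(seq_len(n), function(i)
    lifl_params(d = runif(1, 0.04, 0.3), L_d = runif(1, 0.05, 0.6),
                t_arp = sample(c(0, runif(1, 0.5, 2)), 1)))
  pre_pool <- c(paste0("ES", seq_len(n_ext)),
                if (n > 1) paste0("N", seq_len(n - 1)))
  syn <- do.call(rbind, lapply(seq_len(n), function(post) {
    pres <- unique(sample(pre_pool[seq_len(min(length(pre_pool), n_ext + post - 1))],
                          sample(1:2, 1), replace = TRUE))
    # neuron sources must precede the target to keep the graph feed-forward
    is_n <- grepl("^N", pres)
    keep <- !is_n
    keep[is_n] <- as.integer(sub("N", "", pres[is_n])) < post
    pres <- pres[keep]
    if (!length(pres)) pres <- paste0("ES", sample(n_ext, 1))
    data.frame(pre = pres, post = post, weight = runif(length(pres), 0.3, 1.5))
  }))
  net <- lifl_network(n, syn, params)
  k <- sample(3:10, 1)
  ev <- data.frame(time = round(runif(k, 0, 8), 4),
                   source = sample(paste0("ES", seq_len(n_ext)), k,
                                   replace = TRUE),
                   amplitude = runif(k, 0.5, 1.6))
  list(network = net, events = ev, t_end = 30)
}

# Spike-chronicle comparison: same neurons firing, times within tol.
expect_chronicle_equal <- function(a, b, tol = 1e-3) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a) == nrow(b) && nrow(a) > 0) {
    expect_equal(a$neuron, b$neuron)
    expect_lt(max(abs(a$time - b$time)), tol)
  }
}
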