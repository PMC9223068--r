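# Independent whole-trace reference for the fall state machine.
#
# Instead of stepping a state machine, this enumerates threshold crossings
# and quiescence windows directly over the complete trace:
#   * a candidate starts at a supra-threshold sample (the peak, time p);
#   * capture ends at the first sample strictly later than p + window;
#   * any supra-threshold sample after capture end restarts the candidate;
#   * otherwise the event fires at the first sample strictly later than
#     capture end + quiet, unless that sample is itself supra-threshold
#     (the re-trigger test precedes the deadline test).
oracle_fall_times <- function(t, svm, threshold = 2.5, window_ms = 1000,
                              quiet_ms = 1500) {
  n <- length(t)
  peaks <- which(svm > threshold)
  events <- integer(0)
  i <- 1
  while (i <= length(peaks)) {
    p_idx <- peaks[i]
    repeat {
      cap_candidates <- which(t > t[p_idx] + window_ms)
      cap_candidates <- cap_candidates[cap_candidates > p_idx]
      if (length(cap_candidates) == 0) return(events) # trace ends mid-capture
      cap_end <- cap_candidates[1]
      emit_candidates <- which(t > t[cap_end] + quiet_ms)
      emit_candidates <- emit_candidates[emit_candidates > cap_end]
      emit <- if (length(emit_candidates) == 0) NA_integer_ else emit_candidates[1]
      upper <- if (is.na(emit)) n else emit
      cancels <- peaks[peaks > cap_end & peaks <= upper]
      if (length(cancels) > 0) {
        p_idx <- cancels[1]
        next
      }
      if (is.na(emit)) return(events) # trace ends during quiescence
      events <- c(events, t[emit])
      i <- which(peaks > emit)[1]
      if (is.na(i)) return(events)
      break
    }
    if (is.na(i)) break
  }
  events
}

# Random svm-like trace: quiescent baseline around 1 g with occasional
# supra-threshold spikes, on a uniform 20 ms grid.
random_fall_trace <- function(n = 200, spike_prob = 0.04) {
  t <- seq(0L, by = 20L, length.out = n)
  ax <- 1 + rnorm(n, 0, 0.1)
  spikes <- runif(n) < spike_prob
  ax[spikes] <- runif(sum(spikes), 2.0, 4.0) # some spikes stay sub-threshold
  imu_stream(t_ms = t, ax = ax)
}
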