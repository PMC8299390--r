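# Independent oracles used across the suite.

# O(N^2) brute-force time-averaged MSD: direct double loop over all
# overlapping displacement pairs, independent of compute_msd's vectorized
# path.
brute_force_msd <- function(x, kmax) {
  vapply(seq_len(kmax), function(k) {
    s <- 0
    n <- 0L
    for (i in seq_len(length(x) - k)) {
      s <- s + (x[i + k] - x[i])^2
      n <- n + 1L
    }
    s / n
  }, numeric(1))
}

# random trajectory generator for oracle comparisons
random_trajectory <- function(n, dt = 0.025) {
  x <- cumsum(rnorm(n, 0, 0.1))
  df <- data.frame(time_s = (seq_len(n) - 1) * dt, position_um = x,
                   intensity = rep(10, n))
  df
}

# single-particle view of a trajectory_set
one_particle <- function(ts, i) {
  ts$pos <- ts$pos[i, , drop = FALSE]
  ts$state <- ts$state[i, , drop = FALSE]
  ts$birth_time <- ts$birth_time[i]
  ts
}
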