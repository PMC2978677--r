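# Independent oracles used across tests.

# Gillespie simulation of one vesicle's sensor chain at fixed calcium,
# driven directly by the generator matrix (independent of the C++ path).
# Returns the first-fusion time (Inf if none before t_max).
gillespie_first_fusion <- function(Q, t_max = 50) {
  n <- nrow(Q) - 3
  state <- 1 # (ns = 0, na = 0)
  t <- 0
  repeat {
    rates <- Q[state, ]
    rates[state] <- 0
    total <- sum(rates)
    if (total <= 0) return(Inf)
    t <- t + stats::rexp(1, total)
    if (t > t_max) return(Inf)
    state <- sample.int(length(rates), 1, prob = rates)
    if (state > n) return(t)
  }
}

# stationary distribution of a CTMC generator (rows sum to zero)
stationary_dist <- function(G) {
  n <- nrow(G)
  A <- t(G)
  A[n, ] <- 1
  solve(A, c(rep(0, n - 1), 1))
}

# master-equation occupancy of the sensor chain at fixed calcium after
# elapsed time t, starting from the unbound state (uses matrix exponential
# via repeated squaring of a fine-step Euler propagator)
sensor_occupancy_me <- function(Q, t_ms, n_steps = 2^14) {
  n <- nrow(Q)
  P <- diag(n) + Q * (t_ms / n_steps)
  for (i in seq_len(round(log2(n_steps)))) P <- P %*% P
  p0 <- c(1, rep(0, n - 1))
  as.vector(p0 %*% P)
}
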