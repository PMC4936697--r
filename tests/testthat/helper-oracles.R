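# Independent oracles, deliberately written in the most naive way possible
# so they share no code path with the package implementation.

# Linear-scan retrieval oracle: walks all 1728 chunks in index order,
# recomputing each activation from scratch, tracking the best strictly
# better activation (ties keep the earlier index).
oracle_retrieve <- function(memory, request, params, noise_vector, j) {
  best_i <- NA_integer_
  best_a <- -Inf
  for (i in seq_len(1728L)) {
    if (memory$populated[i]) {
      L <- j - memory$t[i] + params$T
      B <- log(memory$n[i] / (1 - params$d)) - params$d * log(L)
      s1 <- -abs(request[1] - memory$c2[i]) / max(request[1], memory$c2[i])
      s2 <- -abs(request[2] - memory$c3[i]) / max(request[2], memory$c3[i])
      a <- B + params$P * (s1 + s2) + noise_vector[i]
    } else {
      a <- -params$M
    }
    if (a > best_a) {
      best_a <- a
      best_i <- i
    }
  }
  if (best_a >= params$tau) list(retrieved = TRUE, index = best_i)
  else list(retrieved = FALSE, index = NA_integer_)
}

# A randomized populated memory state plus random retrieval context.
random_memory_state <- function() {
  mem <- new_memory()
  k <- sample(0:30, 1)
  if (k > 0) {
    idx <- sample(1728L, k)
    mem$populated[idx] <- TRUE
    mem$n[idx] <- sample(1:5, k, replace = TRUE)
    mem$t[idx] <- sample(1:20, k, replace = TRUE)
  }
  list(memory = mem,
       request = c(sample(1:12, 1), 9),
       params = act_params(tau = runif(1, -8.5, 1), P = runif(1, 0.5, 35)),
       j = 21L)
}

# Pure exploration oracle: the agent when retrieval is impossible. An
# independent transcription of the task dynamics driven only by the walk
# streams (anchored walk, on-target band rule: the package defaults).
oracle_pure_walk <- function(streams, N_r = 40L, p1 = 6L) {
  p <- p1
  u_w <- streams$w_init
  hits <- integer(N_r)
  for (j in seq_len(N_r)) {
    x <- u_w
    p_new <- 2 * x - p + streams$u_r[j]
    if (p_new > 12) p_new <- 12
    if (p_new < 1) p_new <- 1
    inc <- if (p_new >= 8 && p_new <= 10) streams$u_on[j] else streams$u_off[j]
    u_w <- x + inc
    if (u_w > 12) u_w <- 12
    if (u_w < 1) u_w <- 1
    hits[j] <- as.integer(p_new >= 8 && p_new <= 10)
    p <- p_new
  }
  sum(hits)
}
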