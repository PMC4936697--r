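#' Declarative memory for the Sugar Factory instance model
#'
#' The model's declarative memory preallocates one chunk for every possible
#' instance triple (workforce `c1`, current production `c2`, resulting
#' production `c3`), each slot ranging over 1..12, giving a fixed store of
#' 12^3 = 1728 chunks. A chunk that has never been presented is flagged
#' unpopulated and always reports the sentinel activation `-M`, so it can
#' never win a retrieval competition under any realistic threshold.
#'
#' Chunks are enumerated lexicographically over `(c1, c2, c3)`, 1-based:
#' index = (c1-1)*144 + (c2-1)*12 + c3. The enumeration is arbitrary but
#' fixed; ties in retrieval are broken toward the lowest index.
#'
#' @return An object of class `ibl_memory`: a list with integer vectors
#'   `c1`, `c2`, `c3` (the slot values of all 1728 chunks), `n`
#'   (presentation counts, 0 for unpopulated chunks), `t` (creation round,
#'   `NA` for unpopulated chunks), and logical `populated`.
#' @examples
#' mem <- new_memory()
#' sum(mem$populated)  # 0: a fresh memory holds no instances yet
#' @export
new_memory <- function() {
  idx <- seq_len(N_CHUNKS)
  structure(
    list(
      c1 = as.integer((idx - 1L) %/% 144L + 1L),
      c2 = as.integer(((idx - 1L) %/% 12L) %% 12L + 1L),
      c3 = as.integer((idx - 1L) %% 12L + 1L),
      n = integer(N_CHUNKS),
      t = rep(NA_integer_, N_CHUNKS),
      populated = logical(N_CHUNKS)
    ),
    class = "ibl_memory"
  )
}

#' Chunk index of a slot triple
#'
#' Maps a `(c1, c2, c3)` triple to its position in the fixed lexicographic
#' enumeration of the 1728-chunk store. Vectorized; the inverse is
#' [chunk_triple()].
#'
#' @param c1,c2,c3 Integer slot values in 1..12 (workforce, current
#'   production, new production).
#' @return Integer index in 1..1728.
#' @export
chunk_index <- function(c1, c2, c3) {
  stopifnot(all(c1 >= 1L & c1 <= SLOT_MAX),
            all(c2 >= 1L & c2 <= SLOT_MAX),
            all(c3 >= 1L & c3 <= SLOT_MAX))
  as.integer((c1 - 1L) * 144L + (c2 - 1L) * 12L + c3)
}

#' Slot triple of a chunk index
#'
#' @param idx Integer chunk index in 1..1728.
#' @return A list with integer vectors `c1`, `c2`, `c3`.
#' @export
chunk_triple <- function(idx) {
  stopifnot(all(idx >= 1L & idx <= N_CHUNKS))
  i0 <- as.integer(idx) - 1L
  list(c1 = i0 %/% 144L + 1L,
       c2 = (i0 %/% 12L) %% 12L + 1L,
       c3 = i0 %% 12L + 1L)
}

#' Activation parameters
#'
#' Bundles the subsymbolic parameters of the declarative memory: the
#' retrieval threshold `tau`, the base-level decay `d`, the partial-matching
#' similarity weight `P`, the transient activation noise scale `s`
#' (logistic distribution), the lifetime offset `T` (in rounds), and the
#' sentinel magnitude `M` assigned to never-presented chunks.
#'
#' `M` must dominate the reachable activation range so that an unpopulated
#' chunk can never be retrieved; with `|B|` of order a few units and the
#' partial-matching penalty bounded by `2 P`, the default `M = 1000` is far
#' beyond any threshold of interest.
#'
#' @param tau Retrieval threshold (activation units).
#' @param P Similarity weighting (dimensionless, >= 0).
#' @param d Base-level decay rate, in (0, 1). Default 0.5.
#' @param s Logistic noise scale, >= 0. Default 0.2.
#' @param T Lifetime offset added to the age of a chunk, > 0 rounds.
#'   Default 0.05.
#' @param M Sentinel activation magnitude for unpopulated chunks, > 0.
#'   Default 1000.
#' @return An object of class `ibl_act_params`.
#' @export
act_params <- function(tau, P, d = 0.5, s = 0.2, T = 0.05, M = 1000) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(P), length(P) == 1L, P >= 0,
            d > 0, d < 1, s >= 0, T > 0, M > 0)
  if (M <= abs(tau)) {
    stop("sentinel magnitude M must exceed |tau|")
  }
  structure(list(tau = tau, P = P, d = d, s = s, T = T, M = M),
            class = "ibl_act_params")
}

#' Lifetime of a chunk
#'
#' Age of a chunk in rounds, offset by the constant `T` so that a chunk
#' presented in the current round already has a strictly positive lifetime
#' (and hence a finite base-level activation).
#'
#' @param t_creation Round in which the chunk was first presented (>= 1).
#' @param j Current round (>= `t_creation`).
#' @param T Lifetime offset in rounds, > 0. Default 0.05.
#' @return `j - t_creation + T`, strictly positive. Vectorized.
#' @export
lifetime <- function(t_creation, j, T = 0.05) {
  stopifnot(T > 0)
  if (any(j < t_creation)) {
    stop("current round precedes chunk creation: inconsistent trajectory")
  }
  j - t_creation + T
}

#' Base-level activation
#'
#' Base-level learning: activation grows logarithmically with the number of
#' presentations `n` and decays with the power `d` of the chunk lifetime,
#' `B = ln(n / (1 - d)) - d ln(L)`.
#'
#' @param n Presentation count, >= 1.
#' @param L Lifetime in rounds, > 0.
#' @param d Decay rate in (0, 1).
#' @return Base-level activation (activation units). Vectorized.
#' @export
base_level <- function(n, L, d = 0.5) {
  if (any(n < 1) || any(L <= 0)) {
    stop("corrupt memory state: need n >= 1 and L > 0")
  }
  stopifnot(d > 0, d < 1)
  log(n / (1 - d)) - d * log(L)
}

#' Slot similarity
#'
#' Ratio similarity between two positive slot values:
#' `-|a - b| / max(a, b)`, which is 0 for identical values and bounded
#' below by -1 (maximal dissimilarity).
#'
#' @param a,b Positive slot values.
#' @return Similarity in `[-1, 0]`. Vectorized.
#' @export
similarity <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    stop("similarity is defined for positive slot values only")
  }
  -abs(a - b) / pmax(a, b)
}

# 12 x 12 lookup of similarity(a, b) for integer slot values, built once.
SIM_TAB <- local({
  g <- expand.grid(a = 1:12, b = 1:12)
  matrix(-abs(g$a - g$b) / pmax(g$a, g$b), nrow = 12L)
})

#' Partial-matching context component
#'
#' The context (mismatch) component of a chunk's activation for a retrieval
#' request `(p_j, p_star)`: the request's current production is matched
#' against the chunk's `c2` slot and the production target `p_star`
#' (9 in this task) against the chunk's `c3` slot, each via [similarity()],
#' and the sum is weighted by `P`. A perfectly matching chunk contributes 0;
#' mismatches contribute a penalty down to `-2 P`.
#'
#' @param chunk A list with slots `c2` and `c3` (e.g. one row of a memory),
#'   or vectors thereof.
#' @param request Numeric vector `c(p_j, p_star)`.
#' @param P Similarity weighting, >= 0.
#' @return Context component (activation units).
#' @export
context_component <- function(chunk, request, P) {
  stopifnot(length(request) == 2L, P >= 0)
  P * (similarity(request[[1L]], chunk$c2) + similarity(request[[2L]], chunk$c3))
}

#' Activation of a single chunk
#'
#' Total activation `A = B + C + noise` of one chunk for a retrieval
#' request at round `j`: base-level plus partial-matching context plus
#' transient noise. An unpopulated chunk reports exactly `-M`.
#'
#' @param chunk A list with fields `c2`, `c3`, `n`, `t`, `populated`
#'   describing one chunk.
#' @param request Numeric vector `c(p_j, p_star)`.
#' @param params An [act_params()] object.
#' @param noise Transient activation noise for this chunk (activation
#'   units). Default 0.
#' @param j Current round.
#' @return Activation in activation units.
#' @export
chunk_activation <- function(chunk, request, params, noise = 0, j) {
  stopifnot(inherits(params, "ibl_act_params"))
  if (!isTRUE(chunk$populated)) {
    return(-params$M)
  }
  B <- base_level(chunk$n, lifetime(chunk$t, j, params$T), params$d)
  B + context_component(chunk, request, params$P) + noise
}

#' Activations of the whole memory
#'
#' Computes the activation of all 1728 chunks for one retrieval request in
#' a single vectorized pass. Unpopulated chunks report the sentinel `-M`.
#'
#' @param memory An [new_memory()] object.
#' @param request Numeric vector `c(p_j, p_star)`.
#' @param params An [act_params()] object.
#' @param noise Numeric vector of per-chunk transient noise, length 1728
#'   (or a single 0 for the noise-free case).
#' @param j Current round.
#' @return Numeric vector of 1728 activations.
#' @export
chunk_activations <- function(memory, request, params, noise = 0, j) {
  stopifnot(inherits(memory, "ibl_memory"), inherits(params, "ibl_act_params"))
  if (length(noise) == 1L) noise <- rep(noise, N_CHUNKS)
  if (length(noise) != N_CHUNKS) {
    stop("noise vector must have one entry per chunk (", N_CHUNKS, ")")
  }
  A <- rep(-params$M, N_CHUNKS)
  pop <- memory$populated
  if (any(pop)) {
    B <- base_level(memory$n[pop], lifetime(memory$t[pop], j, params$T), params$d)
    C <- params$P * (SIM_TAB[request[[1L]], memory$c2[pop]] +
                       SIM_TAB[request[[2L]], memory$c3[pop]])
    A[pop] <- B + C + noise[pop]
  }
  A
}

#' Retrieve the best-matching chunk
#'
#' Computes all chunk activations for the request and returns the index of
#' the maximally active chunk provided its activation reaches the retrieval
#' threshold `tau`; otherwise reports a retrieval failure. Ties are broken
#' toward the lowest chunk index so that retrieval is deterministic.
#'
#' @inheritParams chunk_activations
#' @param noise_vector Per-chunk transient noise, length 1728.
#' @return A list with `retrieved` (logical), `index` (chunk index or `NA`),
#'   and `activation` (the maximal activation encountered).
#' @export
retrieve <- function(memory, request, params, noise_vector = rep(0, N_CHUNKS), j) {
  if (length(noise_vector) != N_CHUNKS) {
    stop("noise vector must have one entry per chunk (", N_CHUNKS, ")")
  }
  A <- chunk_activations(memory, request, params, noise_vector, j)
  a_max <- max(A)
  if (a_max >= params$tau) {
    list(retrieved = TRUE, index = which.max(A), activation = a_max)
  } else {
    list(retrieved = FALSE, index = NA_integer_, activation = a_max)
  }
}

#' Present an instance to memory
#'
#' Stores the experience triple `(x_j, p_j, p_{j+1})` at round `j`: if the
#' corresponding chunk is already populated its presentation count is
#' incremented (merging; the creation round is kept, so lifetime keeps
#' running from first creation), otherwise the chunk becomes populated with
#' `n = 1` and creation round `j`.
#'
#' @param memory An `ibl_memory` object.
#' @param triple Integer vector `c(x, p, p_new)`, each in 1..12.
#' @param j Current round (>= 1).
#' @return The updated `ibl_memory`.
#' @export
present <- function(memory, triple, j) {
  stopifnot(inherits(memory, "ibl_memory"), length(triple) == 3L, j >= 1L)
  k <- chunk_index(triple[[1L]], triple[[2L]], triple[[3L]])
  if (memory$populated[k]) {
    memory$n[k] <- memory$n[k] + 1L
  } else {
    memory$populated[k] <- TRUE
    memory$n[k] <- 1L
    memory$t[k] <- as.integer(j)
  }
  memory
}

#' Transient activation noise
#'
#' Draws transient activation noise from a logistic distribution with
#' location 0 and scale `s`. A scale of exactly 0 disables the noise and
#' returns exact zeros (no degenerate sampling).
#'
#' @param s Noise scale, >= 0.
#' @param n Number of draws. Default 1.
#' @return Numeric vector of `n` draws (activation units).
#' @export
logistic_noise <- function(s, n = 1L) {
  if (s < 0) stop("noise scale s must be non-negative")
  if (s == 0) return(numeric(n))
  rlogis(n, location = 0, scale = s)
}
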