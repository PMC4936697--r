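# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Pseudo-random input streams for one replicate
#'
#' The model's stochastic "inputs" are generated a priori and frozen: the
#' walk increments `u_on` (on-target exploration, uniform on `{-1..1}`) and
#' `u_off` (off-target exploration, uniform on `{-2..2}`), the environment
#' noise `u_r` (uniform on `{-1, 0, 1}`), the initial exploration workforce
#' `w_init` (uniform on `{7, 8, 9}`, the values human participants start
#' with), and, when enabled, a rounds-by-chunks matrix `u_n` of transient
#' activation noise (logistic with scale `s`). Freezing the streams makes
#' every simulated episode a deterministic function of the parameters, a
#' prerequisite for well-behaved derivative-free optimization (common
#' random numbers).
#'
#' @param seed Non-negative integer seed.
#' @param N_r Number of rounds. Default 40.
#' @param N_c Number of chunks (columns of `u_n`). Default 1728.
#' @param s Logistic noise scale for `u_n`. Default 0.2.
#' @param noise_enabled If `FALSE` (default) `u_n` is all-zero, stored
#'   compactly as `NULL`.
#' @return An object of class `ibl_streams`: a list with `u_on`, `u_off`,
#'   `u_r` (integer vectors of length `N_r`), `w_init`, `u_n` (an
#'   `N_r x N_c` matrix, or `NULL` when noise is disabled), and the
#'   generating `seed`, `N_r`, `N_c`.
#' @export
make_streams <- function(seed, N_r = 40L, N_c = N_CHUNKS, s = 0.2,
                         noise_enabled = FALSE) {
  stopifnot(seed >= 0, N_r >= 1L, N_c >= 1L, s >= 0)
  with_seed(seed, {
    u_on <- sample(-1:1, N_r, replace = TRUE)
    u_off <- sample(-2:2, N_r, replace = TRUE)
    u_r <- sample(-1:1, N_r, replace = TRUE)
    w_init <- sample(7:9, 1L)
    u_n <- if (noise_enabled && s > 0) {
      matrix(rlogis(N_r * N_c, 0, s), nrow = N_r, ncol = N_c)
    } else NULL
    structure(
      list(u_on = u_on, u_off = u_off, u_r = u_r, w_init = w_init,
           u_n = u_n, seed = as.integer(seed), N_r = as.integer(N_r),
           N_c = as.integer(N_c)),
      class = "ibl_streams"
    )
  })
}

# Deterministic sub-seed for replicate i under a master seed. Independent
# of the batch size, so replicate i is the same whatever n is. The map
# i -> (C + i * 7919) mod (2^31 - 1) is injective in i (prime modulus),
# hence sub-seeds within a batch are pairwise distinct.
derive_subseed <- function(master_seed, i) {
  m <- 2147483647
  (((master_seed %% m) * 2053 + i * 7919) %% m)
}

#' Batch of replicate input streams
#'
#' Derives `n` deterministic sub-seeds from one master seed and builds one
#' [make_streams()] replicate per sub-seed. Replicate `i` depends only on
#' `(master_seed, i)`, not on `n`.
#'
#' @param master_seed Non-negative integer master seed.
#' @param n Number of replicates, >= 1.
#' @param ... Passed to [make_streams()] (`N_r`, `N_c`, `s`,
#'   `noise_enabled`).
#' @return A list of `n` `ibl_streams` objects.
#' @export
make_batch <- function(master_seed, n, ...) {
  stopifnot(master_seed >= 0, n >= 1L)
  lapply(seq_len(n), function(i) make_streams(derive_subseed(master_seed, i), ...))
}

#' Write input streams to JSON
#'
#' Serializes one replicate's streams to a JSON fixture, for
#' cross-implementation comparison. The noise matrix is stored row-major.
#'
#' @param streams An `ibl_streams` object.
#' @param path Output file path.
#' @export
streams_to_json <- function(streams, path) {
  stopifnot(inherits(streams, "ibl_streams"))
  x <- unclass(streams)
  if (!is.null(x$u_n)) x$u_n <- as.vector(t(x$u_n))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read input streams from JSON
#'
#' @param path JSON file written by [streams_to_json()].
#' @return An `ibl_streams` object.
#' @export
streams_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$u_n) && length(x$u_n)) {
    x$u_n <- matrix(x$u_n, nrow = x$N_r, ncol = x$N_c, byrow = TRUE)
  } else {
    x$u_n <- NULL
  }
  x$u_on <- as.integer(x$u_on); x$u_off <- as.integer(x$u_off)
  x$u_r <- as.integer(x$u_r); x$w_init <- as.integer(x$w_init)
  structure(x[c("u_on", "u_off", "u_r", "w_init", "u_n", "seed", "N_r", "N_c")],
            class = "ibl_streams")
}
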