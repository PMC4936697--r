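#' Simulation configuration
#'
#' Bundles the run settings of an episode: number of rounds, initial
#' production, activation parameters, and the behavioral switches whose
#' defaults follow the formal round-loop specification of the model
#' (see the methods vignette for the two places where the informal task
#' description could be read differently).
#'
#' @param params An [act_params()] object.
#' @param N_r Number of rounds. Default 40.
#' @param p1 Initial production, integer in 1..12. Default 6 (the value
#'   used in experiments; 1 and 9 probe the sensitivity to starting
#'   conditions).
#' @param noise_enabled Use transient activation noise from the streams'
#'   `u_n` matrix. Default `FALSE`.
#' @param count_retrieval_as_presentation If `TRUE`, a successful retrieval
#'   also increments the retrieved chunk's presentation count. Default
#'   `FALSE`: only the end-of-round instance storage counts as a
#'   presentation.
#' @param on_target_rule_for_walk Which condition selects the on-target
#'   exploration increment `u_on` over `u_off` in the workforce walk:
#'   `"band_8_10"` (default; the band human participants react to,
#'   `8 <= p <= 10`) or `"exact_nine"` (`p == 9` exactly).
#' @param walk_anchor Where the next exploration workforce starts from:
#'   `"previous_choice"` (default; `x_j + u`, the previous actual
#'   workforce, as in the human choice rules `x_j = x_{j-1} + u`) or
#'   `"decoupled"` (a free-running walk state `u_w` that evolves
#'   independently of retrieved choices). The anchored walk lets
#'   exploration continue from retrieved good choices and is what
#'   reproduces the model's published performance surface; see the
#'   methods vignette.
#' @return An object of class `ibl_config`.
#' @export
sim_config <- function(params, N_r = 40L, p1 = 6L, noise_enabled = FALSE,
                       count_retrieval_as_presentation = FALSE,
                       on_target_rule_for_walk = c("band_8_10", "exact_nine"),
                       walk_anchor = c("previous_choice", "decoupled")) {
  stopifnot(inherits(params, "ibl_act_params"), N_r >= 1L,
            p1 >= 1L, p1 <= 12L)
  structure(
    list(params = params, N_r = as.integer(N_r), p1 = as.integer(p1),
         noise_enabled = isTRUE(noise_enabled),
         count_retrieval_as_presentation = isTRUE(count_retrieval_as_presentation),
         on_target_rule_for_walk = match.arg(on_target_rule_for_walk),
         walk_anchor = match.arg(walk_anchor)),
    class = "ibl_config"
  )
}

#' Run one episode of the instance-based learner
#'
#' Executes the full round loop on one replicate's frozen input streams.
#' Each round: (1) activations of all chunks for the request
#' `(p_j, p* = 9)`; (2) the maximally active chunk; (3) if its activation
#' reaches `tau` the agent applies that chunk's stored workforce, otherwise
#' the exploration workforce; (4) the factory updates production and the
#' next exploration workforce is formed by adding `u_on` (production on
#' target) or `u_off` (otherwise) to the walk anchor; (5-6) it is clipped
#' to 1..12; (7) the round is scored on target iff the new production is
#' in `{8, 9, 10}`; (8) the experience triple `(x_j, p_j, p_{j+1})` is
#' stored (or merged) in memory. The walk is updated every round,
#' including rounds decided by retrieval. Deterministic given
#' `(config, streams)`.
#'
#' Only populated chunks can win the retrieval competition (unpopulated
#' chunks sit at the sentinel `-M`, far below any activation a populated
#' chunk can reach), so the implementation scans the populated subset; the
#' result is identical to the full 1728-chunk scan exposed by
#' [retrieve()], including lowest-index tie-breaking.
#'
#' @param config An [sim_config()] object.
#' @param streams An [make_streams()] replicate with matching `N_r`.
#' @return An object of class `ibl_run`: a list with `rounds` (a data frame
#'   with columns `j`, `x`, `p_before`, `p_after`, `retrieved`,
#'   `retrieved_index`, `on_target`), `score`, `learned_score` (on-target
#'   rounds decided by a retrieved instance), and `final_memory`.
#' @export
run_episode <- function(config, streams) {
  stopifnot(inherits(config, "ibl_config"), inherits(streams, "ibl_streams"))
  if (streams$N_r < config$N_r) {
    stop("streams provide ", streams$N_r, " rounds but config needs ", config$N_r)
  }
  if (config$noise_enabled && is.null(streams$u_n)) {
    stop("noise enabled but streams carry no activation-noise matrix")
  }
  par <- config$params
  N_r <- config$N_r
  band_rule <- config$on_target_rule_for_walk == "band_8_10"
  anchor <- config$walk_anchor == "previous_choice"

  # compact store of populated chunks, in insertion order
  p_idx <- integer(0)   # chunk indices (1..1728)
  p_c1 <- integer(0); p_c2 <- integer(0); p_c3 <- integer(0)
  p_n <- integer(0); p_t <- integer(0)

  sim9 <- SIM_TAB[9L, ]  # similarity of target 9 to each possible c3

  p <- config$p1
  u_w <- streams$w_init
  x_seq <- integer(N_r); pb_seq <- integer(N_r); pa_seq <- integer(N_r)
  ret_seq <- logical(N_r); ridx_seq <- rep(NA_integer_, N_r)
  hit_seq <- integer(N_r)

  for (j in seq_len(N_r)) {
    retrieved <- FALSE
    r_at <- NA_integer_
    if (length(p_idx)) {
      B <- log(p_n * (1 / (1 - par$d))) - par$d * log(j - p_t + par$T)
      A <- B + par$P * (SIM_TAB[p, p_c2] + sim9[p_c3])
      if (config$noise_enabled) A <- A + streams$u_n[j, p_idx]
      a_max <- max(A)
      if (a_max >= par$tau) {
        retrieved <- TRUE
        hits <- which(A == a_max)
        k <- if (length(hits) > 1L) hits[which.min(p_idx[hits])] else hits
        r_at <- k
      }
    }
    if (retrieved) {
      x <- p_c1[r_at]
      if (config$count_retrieval_as_presentation) p_n[r_at] <- p_n[r_at] + 1L
    } else {
      x <- u_w
    }

    p_new <- min(max(2L * x - p + streams$u_r[j], 1L), 12L)
    walk_on <- if (band_rule) abs(p_new - 9L) <= 1L else p_new == 9L
    base <- if (anchor) x else u_w
    u_w <- base + if (walk_on) streams$u_on[j] else streams$u_off[j]
    u_w <- min(max(u_w, 1L), 12L)
    hit <- abs(p_new - 9L) <= 1L

    # store / merge the experience triple
    ci <- (x - 1L) * 144L + (p - 1L) * 12L + p_new
    pos <- match(ci, p_idx)
    if (is.na(pos)) {
      p_idx <- c(p_idx, ci)
      p_c1 <- c(p_c1, x); p_c2 <- c(p_c2, p); p_c3 <- c(p_c3, p_new)
      p_n <- c(p_n, 1L); p_t <- c(p_t, j)
    } else {
      p_n[pos] <- p_n[pos] + 1L
    }

    x_seq[j] <- x; pb_seq[j] <- p; pa_seq[j] <- p_new
    ret_seq[j] <- retrieved
    ridx_seq[j] <- if (retrieved) p_idx[r_at] else NA_integer_
    hit_seq[j] <- as.integer(hit)
    p <- p_new
  }

  mem <- new_memory()
  mem$populated[p_idx] <- TRUE
  mem$n[p_idx] <- p_n
  mem$t[p_idx] <- p_t

  structure(
    list(
      rounds = data.frame(j = seq_len(N_r), x = x_seq, p_before = pb_seq,
                          p_after = pa_seq, retrieved = ret_seq,
                          retrieved_index = ridx_seq, on_target = hit_seq),
      score = as.integer(sum(hit_seq)),
      learned_score = as.integer(sum(hit_seq[ret_seq])),
      final_memory = mem
    ),
    class = "ibl_run"
  )
}

#' Run a batch of replicate episodes
#'
#' Runs [run_episode()] on each replicate of a frozen batch and summarizes
#' the per-replicate scores.
#'
#' @param config An [sim_config()] object.
#' @param streams_list A list of `ibl_streams` replicates
#'   (see [make_batch()]).
#' @return An object of class `ibl_batch`: a list with `scores` and
#'   `learned_scores` (integer vectors, one entry per replicate), `mean`,
#'   `sd` (sample standard deviation, n-1 denominator; 0 with a warning
#'   when n = 1), and `learned_mean`.
#' @export
run_batch <- function(config, streams_list) {
  stopifnot(is.list(streams_list), length(streams_list) >= 1L)
  scores <- integer(length(streams_list))
  learned <- integer(length(streams_list))
  for (i in seq_along(streams_list)) {
    r <- run_episode(config, streams_list[[i]])
    scores[i] <- r$score
    learned[i] <- r$learned_score
  }
  s <- if (length(scores) > 1L) sd(scores) else {
    warning("single replicate: standard deviation undefined, reporting 0")
    0
  }
  structure(
    list(scores = scores, learned_scores = learned,
         mean = mean(scores), sd = s, learned_mean = mean(learned)),
    class = "ibl_batch"
  )
}
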