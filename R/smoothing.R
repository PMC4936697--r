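#' Smoothing parameters
#'
#' Sharpness constants of the continuously differentiable reformulation.
#' Every discrete branch of the model is rewritten with a smooth Heaviside
#' approximation `H(x) = arctan(h x) / pi + 1/2`; the equality test in the
#' exploration walk uses a Gaussian Delta approximation
#' `delta(x) = exp(-x^2 / a^2)`. Sharpness is tunable separately for the
#' similarity terms (`h_sim`), for chunk selection (`h_argmax`), and for
#' the environment (production/workforce clipping and scoring, `h_env`).
#' The defaults put selection in the sharp, discrete-matching regime
#' (`h_argmax = 1e7`) while keeping the rest mildly smoothed (`h = 10`),
#' the combination under which the smoothed model reproduces the discrete
#' one.
#'
#' @param h_sim Sharpness for similarity `|.|/max` terms. Default 10.
#' @param h_argmax Sharpness for the argmax selection and the threshold
#'   comparison. Default 1e7.
#' @param h_env Sharpness for clipping and on-target scoring. Default 10.
#' @param a_delta Width of the Delta approximation used by the walk's
#'   `p = 9` test. Default 0.01.
#' @return An object of class `ibl_smoothing`.
#' @export
smoothing_params <- function(h_sim = 10, h_argmax = 1e7, h_env = 10,
                             a_delta = 0.01) {
  stopifnot(h_sim > 0, h_argmax > 0, h_env > 0, a_delta > 0)
  structure(list(h_sim = h_sim, h_argmax = h_argmax, h_env = h_env,
                 a_delta = a_delta),
            class = "ibl_smoothing")
}

#' Smooth Heaviside step
#'
#' `H(x) = arctan(h x) / pi + 1/2`: strictly increasing, equal to 1/2 at
#' 0, approaching the unit step as `h` grows.
#'
#' @param x Real input. Vectorized.
#' @param h Sharpness, > 0.
#' @return Value in (0, 1).
#' @export
smooth_heaviside <- function(x, h) {
  stopifnot(h > 0)
  atan(h * x) / pi + 0.5
}

#' Smooth Delta (equality) kernel
#'
#' `delta(x) = exp(-x^2 / a^2)`: 1 at 0, symmetric, decaying on the scale
#' `a`.
#'
#' @param x Real input. Vectorized.
#' @param a_delta Width, > 0.
#' @return Value in (0, 1].
#' @export
smooth_delta <- function(x, a_delta) {
  stopifnot(a_delta > 0)
  exp(-x^2 / a_delta^2)
}

#' Smooth if-then selection
#'
#' `H(s) then + (1 - H(s)) else`: a convex blend of the two branches that
#' reduces to the discrete `if (s >= 0)` as `h` grows.
#'
#' @param condition_value The branch condition `s`.
#' @param then_val,else_val Branch values.
#' @param h Sharpness.
#' @return Blended value. Vectorized.
#' @export
smooth_if_then <- function(condition_value, then_val, else_val, h) {
  H <- smooth_heaviside(condition_value, h)
  H * then_val + (1 - H) * else_val
}

#' Smooth binary maximum
#'
#' `max(x, y)` rewritten as `H(x - y) x + (1 - H(x - y)) y`.
#'
#' @param x,y Real inputs. Vectorized.
#' @param h Sharpness.
#' @export
smooth_max <- function(x, y, h) {
  H <- smooth_heaviside(x - y, h)
  H * x + (1 - H) * y
}

#' Smooth `|x - y| / max(x, y)`
#'
#' The ratio dissimilarity rewritten branch-free:
#' `H(x - y) (x - y)/x + (1 - H(x - y)) (y - x)/y`. Both arguments must be
#' bounded away from 0 (slot values are >= 1 in this task).
#'
#' @param x,y Positive inputs. Vectorized.
#' @param h Sharpness.
#' @export
smooth_absratio <- function(x, y, h) {
  if (any(abs(x) < 1e-12) || any(abs(y) < 1e-12)) {
    stop("smooth_absratio: slot values must be bounded away from 0")
  }
  H <- smooth_heaviside(x - y, h)
  H * (x - y) / x + (1 - H) * (y - x) / y
}

#' Smooth clipping to an interval
#'
#' Branch-free `clip(x, lo, hi)`:
#' `H(x - hi) hi + (1 - H(x - hi)) (H(lo - x) lo + (1 - H(lo - x)) x)`.
#'
#' @param x Real input. Vectorized.
#' @param lo,hi Interval bounds.
#' @param h Sharpness.
#' @export
smooth_clip <- function(x, lo, hi, h) {
  Hu <- smooth_heaviside(x - hi, h)
  Hl <- smooth_heaviside(lo - x, h)
  Hu * hi + (1 - Hu) * (Hl * lo + (1 - Hl) * x)
}

#' Smooth n-ary maximum by pairwise folding
#'
#' Folds [smooth_max()] over the vector in ascending index order (the fold
#' order is fixed so results are reproducible). Converges to `max(v)` as
#' `h` grows; at finite `h` the result sits slightly below the true
#' maximum, each fold step against a dominated element contributing a
#' deficit of order `1/(pi h)`.
#'
#' @param v Numeric vector.
#' @param h Sharpness.
#' @return Smoothed maximum (scalar).
#' @export
smooth_max_fold <- function(v, h) {
  stopifnot(length(v) >= 1L)
  acc <- v[1L]
  for (i in seq_along(v)[-1L]) {
    H <- atan(h * (acc - v[i])) / pi + 0.5
    acc <- H * acc + (1 - H) * v[i]
  }
  acc
}

#' Smoothed retrieve-or-explore selection
#'
#' The branch-free form of "retrieve the maximally active chunk if its
#' activation reaches `tau`, otherwise explore": with
#' `A* = smooth_max_fold(activations)` and selection weights
#' `w_i = H(A_i - A*)`,
#' `sum_i w_i (H(A* - tau) b1_i + (1 - H(A* - tau)) b2) / sum_i w_i`,
#' where `b1_i` is chunk `i`'s stored workforce and `b2` the exploration
#' workforce. The weights are normalized so the selection is a convex
#' combination of the candidate choices: at sharp `h` exactly one weight
#' dominates and the result reproduces the discrete choice; when all
#' activations are equal (a fresh memory at the sentinel) every weight is
#' 1/2 and the normalized blend collapses cleanly to the fallback; at
#' small `h` many chunks leak weight and the output is a blend strictly
#' between the discrete candidates.
#'
#' @param activations Numeric vector of chunk activations.
#' @param tau Retrieval threshold.
#' @param b1 Per-chunk choice values (same length as `activations`).
#' @param b2 Fallback (exploration) choice, scalar.
#' @param h_argmax Sharpness.
#' @return Real-valued workforce choice.
#' @export
smooth_argmax_select <- function(activations, tau, b1, b2, h_argmax) {
  stopifnot(length(b1) == length(activations), length(b2) == 1L)
  A_star <- smooth_max_fold(activations, h_argmax)
  w <- smooth_heaviside(activations - A_star, h_argmax)
  ret <- smooth_heaviside(A_star - tau, h_argmax)
  sum(w * (ret * b1 + (1 - ret) * b2)) / sum(w)
}

#' Run one episode of the smoothed model
#'
#' The same round loop as [run_episode()], with every discrete operation
#' replaced by its smooth counterpart: similarity `|.|/max` terms use
#' `h_sim`; the argmax selection and the threshold comparison use
#' `h_argmax`; production and workforce clipping and the on-target score
#' use `h_env`; the walk's `p = 9` equality test uses the Delta kernel of
#' width `a_delta`. Productions, workforces and per-round scores are
#' real-valued; the episode score is a sum of smoothed indicators in
#' `[0, N_r]`.
#'
#' The chunk store itself stays discrete (1728 preallocated integer
#' triples): when the real-valued experience triple is stored at the end
#' of a round it is mapped to the nearest slot triple. Similarities, in
#' contrast, are evaluated on the raw real values. The on-target score
#' uses the band `[7.5, 10.5]` (the midpoints separating productions
#' 7|8 and 10|11), smoothed on both sides:
#' `H(p - 7.5) H(10.5 - p)`.
#'
#' @param config An [sim_config()] object.
#' @param streams An `ibl_streams` replicate.
#' @param smoothing An [smoothing_params()] object.
#' @param select_normalize Normalize the per-round selection weights to
#'   sum to one (a proper convex combination; the default). `FALSE` uses
#'   the raw weight sum, under which the choice is scaled by the total
#'   selection weight; at sharp `h_argmax` the two are numerically
#'   indistinguishable, at low sharpness the raw form degrades faster
#'   (see the vignette).
#' @return An object of class `ibl_run_smoothed`: `rounds` (data frame
#'   with real-valued `x`, `p_before`, `p_after`, the selection's
#'   retrieval weight `ret_weight`, and the per-round smoothed score
#'   `on_target`), `score` (real, in `[0, N_r]`), and `learned_score`
#'   (score weighted by the retrieval weight).
#' @export
run_episode_smoothed <- function(config, streams, smoothing = smoothing_params(),
                                 select_normalize = TRUE) {
  stopifnot(inherits(config, "ibl_config"), inherits(streams, "ibl_streams"),
            inherits(smoothing, "ibl_smoothing"))
  if (streams$N_r < config$N_r) {
    stop("streams provide ", streams$N_r, " rounds but config needs ", config$N_r)
  }
  par <- config$params
  N_r <- config$N_r
  hs <- smoothing$h_sim; ha <- smoothing$h_argmax; he <- smoothing$h_env
  ad <- smoothing$a_delta
  band_rule <- config$on_target_rule_for_walk == "band_8_10"
  anchor <- config$walk_anchor == "previous_choice"

  mem_c1 <- as.numeric((seq_len(N_CHUNKS) - 1L) %/% 144L + 1L)
  mem_c2 <- as.numeric(((seq_len(N_CHUNKS) - 1L) %/% 12L) %% 12L + 1L)
  mem_c3 <- as.numeric((seq_len(N_CHUNKS) - 1L) %% 12L + 1L)
  n_cnt <- numeric(N_CHUNKS)
  t_cre <- numeric(N_CHUNKS)

  # target-side similarity: -|9 - c3|/max(9, c3), smoothed, per slot value
  m2_slot <- -smooth_absratio(rep(9, SLOT_MAX), as.numeric(1:12), hs)

  p <- as.numeric(config$p1)
  u_w <- as.numeric(streams$w_init)
  x_seq <- numeric(N_r); pb_seq <- numeric(N_r); pa_seq <- numeric(N_r)
  ret_seq <- numeric(N_r); hit_seq <- numeric(N_r)

  for (j in seq_len(N_r)) {
    A <- rep(-par$M, N_CHUNKS)
    pop <- which(n_cnt > 0)
    if (length(pop)) {
      B <- log(n_cnt[pop] / (1 - par$d)) - par$d * log(j - t_cre[pop] + par$T)
      m1 <- -smooth_absratio(rep(p, SLOT_MAX), as.numeric(1:12), hs)
      A[pop] <- B + par$P * (m1[mem_c2[pop]] + m2_slot[mem_c3[pop]])
      if (config$noise_enabled && !is.null(streams$u_n)) {
        A[pop] <- A[pop] + streams$u_n[j, pop]
      }
    }
    if (length(pop)) {
      A_star <- smooth_max_fold(A, ha)
      w <- smooth_heaviside(A - A_star, ha)
      ret <- smooth_heaviside(A_star - par$tau, ha)
      x <- sum(w * (ret * mem_c1 + (1 - ret) * u_w))
      if (select_normalize) x <- x / sum(w)
    } else {
      # degenerate fresh memory: every activation sits at the sentinel,
      # the candidate set is empty and the choice is the exploration
      # workforce (the selection formula is indeterminate for an
      # all-equal activation vector)
      ret <- 0
      x <- u_w
    }

    p_tilde <- 2 * x - p + streams$u_r[j]
    p_new <- smooth_clip(p_tilde, 1, 12, he)
    pnr_ <- min(max(round(p_new), 1), 12)
    # the walk-branch test selects between two discrete input streams and
    # is evaluated on the nearest-grid production (see the vignette); the
    # exact-nine rule applies the Delta kernel, the band rule an indicator
    dl <- if (band_rule) {
      as.numeric(abs(pnr_ - 9) <= 1)
    } else {
      smooth_delta(pnr_ - 9, ad)
    }
    base <- if (anchor) x else u_w
    u_w <- smooth_clip(base + dl * streams$u_on[j] + (1 - dl) * streams$u_off[j],
                       1, 12, he)
    hit <- smooth_heaviside(p_new - 7.5, he) * smooth_heaviside(10.5 - p_new, he)

    # nearest preallocated slot triple receives the experience
    xr <- min(max(round(x), 1), 12)
    pr <- min(max(round(p), 1), 12)
    pnr <- pnr_
    ci <- (xr - 1) * 144 + (pr - 1) * 12 + pnr
    if (n_cnt[ci] == 0) {
      n_cnt[ci] <- 1
      t_cre[ci] <- j
    } else {
      n_cnt[ci] <- n_cnt[ci] + 1
    }

    x_seq[j] <- x; pb_seq[j] <- p; pa_seq[j] <- p_new
    ret_seq[j] <- ret; hit_seq[j] <- hit
    p <- p_new
  }

  structure(
    list(
      rounds = data.frame(j = seq_len(N_r), x = x_seq, p_before = pb_seq,
                          p_after = pa_seq, ret_weight = ret_seq,
                          on_target = hit_seq),
      score = sum(hit_seq),
      learned_score = sum(hit_seq * ret_seq)
    ),
    class = "ibl_run_smoothed"
  )
}

#' Mean smoothed score over a replicate batch
#'
#' Convenience wrapper: runs [run_episode_smoothed()] on each replicate
#' and returns the per-replicate smoothed scores with their mean.
#'
#' @param config An [sim_config()] object.
#' @param streams_list List of `ibl_streams` replicates.
#' @param smoothing An [smoothing_params()] object.
#' @return A list with `scores` (numeric vector) and `mean`.
#' @export
run_batch_smoothed <- function(config, streams_list,
                               smoothing = smoothing_params()) {
  scores <- vapply(streams_list,
                   function(s) run_episode_smoothed(config, s, smoothing)$score,
                   numeric(1))
  list(scores = scores, mean = mean(scores))
}
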