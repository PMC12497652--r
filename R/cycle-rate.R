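#' Sliding-window state-visit count feature
#'
#' Counts, for every sample, the number of state-visit onsets inside a
#' centered window of `w` samples (truncated at the sequence edges). An
#' onset is any sample whose label differs from its predecessor; sample 0
#' is always an onset. The window defaults to the grand-mean state lifetime
#' rounded to the nearest odd number of samples.
#'
#' @param stc A [state_tc()].
#' @param w Window length in samples (rounded up to odd if even).
#' @return Object of class `visit_count_feature`: integer vector `counts`
#'   (length T), plus `w`, `fs`.
#' @export
visit_count_feature <- function(stc, w = NULL) {
  stopifnot(inherits(stc, "state_tc"))
  T <- length(stc$labels)
  if (is.null(w)) {
    w <- round(mean_lifetimes(stc)$grand_mean_samples)
    if (w %% 2L == 0L) w <- w + 1L
  }
  w <- as.integer(w)
  if (w < 1L || w > T) stop("w must be in 1..T")
  if (w %% 2L == 0L) w <- w + 1L
  onset <- c(TRUE, stc$labels[-1L] != stc$labels[-T])
  cum <- c(0L, cumsum(onset))
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(T) - h, 1L)
  hi <- pmin(seq_len(T) + h, T)
  counts <- cum[hi + 1L] - cum[lo]
  structure(list(counts = as.integer(counts), w = w, fs = stc$fs),
            class = "visit_count_feature")
}

#' Assign states to four metastate quadrants of the cycle
#'
#' Partitions the circle into four contiguous arcs of consecutive positions
#' starting at phase 0 and computes each arc's centroid as the circular
#' mean of its member phases. With `K` not divisible by 4 the split is as
#' equal as possible (arc sizes differ by at most one), flagged with a
#' message.
#'
#' @param layout A [circle_layout()] with `K >= 4`.
#' @return List with `membership` (per-state metastate 1..4, indexed by
#'   state) and `centroids` (4 angles in radians).
#' @export
quadrant_assignment <- function(layout) {
  stopifnot(inherits(layout, "circle_layout"))
  K <- layout$K
  if (K < 4L) stop("quadrant assignment requires K >= 4")
  base <- K %/% 4L
  extra <- K %% 4L
  sizes <- rep(base, 4L) + (seq_len(4L) <= extra)
  if (extra != 0L)
    message("K = ", K, " not divisible by 4; arc sizes ",
            paste(sizes, collapse = "/"))
  meta_of_pos <- rep(seq_len(4L), times = sizes)
  membership <- integer(K)
  membership[layout$ordering] <- meta_of_pos
  pos_phase <- 2 * pi * (seq_len(K) - 1L) / K
  centroids <- vapply(seq_len(4L), function(k) {
    ph <- pos_phase[meta_of_pos == k]
    atan2(mean(sin(ph)), mean(cos(ph)))
  }, numeric(1L))
  centroids <- centroids %% (2 * pi)
  list(membership = membership, centroids = centroids)
}

#' Initialize metastate probabilities from circle-space distance
#'
#' For every sample, the probability of each of the four metastates is a
#' softmax of the negative circular distance between the active state's
#' phase and the metastate centroid: `p_k proportional to exp(-d_k / tau)`.
#' As `tau -> 0` this approaches a one-hot encoding of the nearest
#' centroid; rows always sum to 1.
#'
#' @param stc A [state_tc()].
#' @param layout A [circle_layout()].
#' @param tau Softmax temperature in radians (default 1).
#' @param quadrants Optional precomputed [quadrant_assignment()].
#' @return T x 4 probability matrix.
#' @export
initialize_state_probs <- function(stc, layout, tau = 1,
                                   quadrants = quadrant_assignment(layout)) {
  stopifnot(inherits(stc, "state_tc"), tau > 0)
  ph <- layout$phases[stc$labels]
  d <- vapply(quadrants$centroids, function(ct) circ_dist(ph - ct),
              numeric(length(ph)))
  w <- exp(-d / tau)
  w / rowSums(w)
}

#' Decode the sequential four-metastate path
#'
#' Fits the second-level model of cycle progression: a four-state hidden
#' Markov chain with Poisson observations on the visit-count feature and
#' sequential dynamics (each metastate can only persist or advance to the
#' next, 1 -> 2 -> 3 -> 4 -> 1). Poisson rates are initialized as the
#' init-probability-weighted mean counts per metastate; at most `n_em`
#' expectation-maximization sweeps refine them (default 0: the model is
#' deliberately not trained to convergence, so the decoded path keeps the
#' cycle definition imposed by the initialization). The most probable path
#' is found by max-product dynamic programming with the per-sample
#' initialization probabilities acting as a prior.
#'
#' @param feature A [visit_count_feature()].
#' @param init_probs T x 4 prior probabilities (from
#'   [initialize_state_probs()]).
#' @param p_stay Self-transition probability in (0, 1), default 0.95.
#' @param n_em Number of EM rate-update sweeps (0 or 1).
#' @return Object of class `metastate_model`: `path` (length-T metastate
#'   sequence), `lambda` (4 Poisson rates), `transition` (4 x 4), `p_stay`,
#'   `w`, `fs`.
#' @export
decode_metastates <- function(feature, init_probs, p_stay = 0.95,
                              n_em = 0L) {
  stopifnot(inherits(feature, "visit_count_feature"),
            p_stay > 0, p_stay < 1)
  c_t <- feature$counts
  T <- length(c_t)
  stopifnot(T >= 2L, nrow(init_probs) == T, ncol(init_probs) == 4L)
  lambda <- as.numeric(crossprod(init_probs, c_t) / colSums(init_probs))
  if (any(lambda <= 0)) {
    warning("zero Poisson rate floored at 1e-3")
    lambda <- pmax(lambda, 1e-3)
  }
  trans <- matrix(0, 4L, 4L)
  diag(trans) <- p_stay
  trans[cbind(1:4, c(2:4, 1L))] <- 1 - p_stay
  log_prior <- log(pmax(init_probs, 1e-300))

  emis <- function(lambda) {
    sapply(lambda, function(l) stats::dpois(c_t, l, log = TRUE))
  }

  for (sweep in seq_len(n_em)) {
    # forward-backward in log space, then rate update
    le <- emis(lambda) + log_prior
    lt <- log(trans)
    la <- matrix(-Inf, T, 4L)
    la[1L, ] <- log(0.25) + le[1L, ]
    for (t in 2:T) {
      for (k in 1:4) {
        prev <- c(k, if (k == 1L) 4L else k - 1L)  # stay or advance from k-1
        la[t, k] <- log(sum(exp(la[t - 1L, prev] + lt[prev, k] -
                                  max(la[t - 1L, prev])))) +
          max(la[t - 1L, prev]) + le[t, k]
      }
    }
    lb <- matrix(0, T, 4L)
    for (t in (T - 1L):1L) {
      for (k in 1:4) {
        nxt <- c(k, if (k == 4L) 1L else k + 1L)
        v <- lt[k, nxt] + le[t + 1L, nxt] + lb[t + 1L, nxt]
        m <- max(v)
        lb[t, k] <- m + log(sum(exp(v - m)))
      }
    }
    lg <- la + lb
    lg <- lg - apply(lg, 1L, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    lambda <- pmax(as.numeric(crossprod(g, c_t) / colSums(g)), 1e-3)
  }

  # Viterbi under the sequential transition structure
  le <- emis(lambda) + log_prior
  lt <- log(trans)
  delta <- matrix(-Inf, T, 4L)
  back <- matrix(0L, T, 4L)
  delta[1L, ] <- log(0.25) + le[1L, ]
  for (t in 2:T) {
    for (k in 1:4) {
      prev <- c(k, if (k == 1L) 4L else k - 1L)
      v <- delta[t - 1L, prev] + lt[prev, k]
      j <- which.max(v)
      delta[t, k] <- v[j] + le[t, k]
      back[t, k] <- prev[j]
    }
  }
  path <- integer(T)
  path[T] <- which.max(delta[T, ])
  for (t in (T - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]

  structure(list(path = path, lambda = lambda, transition = trans,
                 p_stay = p_stay, w = feature$w, fs = feature$fs,
                 n_em = n_em),
            class = "metastate_model")
}

#' Cycle durations and cycle rate from a decoded metastate path
#'
#' A completed cycle is the span between successive entries into metastate
#' 1 that traverses metastates 2, 3 and 4 in order. The subject-level cycle
#' duration is the mean over completed cycles; the cycle rate is its
#' inverse (more normally distributed across subjects than the duration).
#' Partial head and tail cycles are discarded.
#'
#' @param model A `metastate_model`, or an integer path vector.
#' @param fs Sampling rate in Hz (taken from the model if present).
#' @return List with `durations_ms`, `mean_duration_ms`, `cycle_rate_hz`,
#'   `n_completed_cycles`. With no completed cycle the duration and rate
#'   are `NA` with a warning.
#' @export
cycle_durations <- function(model, fs = NULL) {
  if (inherits(model, "metastate_model")) {
    path <- model$path
    if (is.null(fs)) fs <- model$fs
  } else {
    path <- as.integer(model)
    if (is.null(fs)) stop("fs required when passing a raw path")
  }
  r <- rle(path)
  onsets1 <- cumsum(c(0L, r$lengths))[which(r$values == 1L)]
  durations <- numeric(0)
  if (length(onsets1) >= 2L) {
    runs_start <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
    for (i in seq_len(length(onsets1) - 1L)) {
      a <- onsets1[i]
      b <- onsets1[i + 1L]
      between <- r$values[runs_start > a & runs_start < b]
      between <- between[between != 1L]
      if (identical(as.integer(between), c(2L, 3L, 4L)))
        durations <- c(durations, b - a)
    }
  }
  if (length(durations) == 0L) {
    warning("no completed 1>2>3>4 cycle in decoded path")
    return(list(durations_ms = numeric(0), mean_duration_ms = NA_real_,
                cycle_rate_hz = NA_real_, n_completed_cycles = 0L))
  }
  dur_ms <- durations / fs * 1000
  list(durations_ms = dur_ms, mean_duration_ms = mean(dur_ms),
       cycle_rate_hz = 1000 / mean(dur_ms),
       n_completed_cycles = length(durations))
}

#' Cycle rate for a whole cohort
#'
#' Runs the full second-level pipeline per subject: visit-count feature,
#' circle-distance initialization, constrained sequential decode, and
#' cycle-duration extraction.
#'
#' @param cohort A [state_cohort()].
#' @param layout A [circle_layout()] (normally the optimized full-data
#'   layout).
#' @param w Window length in samples; default per subject from the mean
#'   lifetime.
#' @param tau Softmax temperature (radians).
#' @param p_stay Self-transition probability.
#' @param n_em EM sweeps (0 or 1).
#' @return Data frame with one row per subject: `subject_id`, `w_samples`,
#'   `mean_cycle_duration_ms`, `cycle_rate_hz`, `n_completed_cycles`.
#' @export
cohort_cycle_rate <- function(cohort, layout, w = NULL, tau = 1,
                              p_stay = 0.95, n_em = 0L) {
  stopifnot(inherits(cohort, "state_cohort"))
  quad <- quadrant_assignment(layout)
  rows <- lapply(cohort, function(s) {
    f <- visit_count_feature(s, w = w)
    ip <- initialize_state_probs(s, layout, tau = tau, quadrants = quad)
    mm <- decode_metastates(f, ip, p_stay = p_stay, n_em = n_em)
    cd <- suppressWarnings(cycle_durations(mm))
    data.frame(subject_id = s$subject_id, w_samples = f$w,
               mean_cycle_duration_ms = cd$mean_duration_ms,
               cycle_rate_hz = cd$cycle_rate_hz,
               n_completed_cycles = cd$n_completed_cycles)
  })
  do.call(rbind, rows)
}
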