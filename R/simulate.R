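#' Simulation configuration for synthetic state-sequence cohorts
#'
#' Defines the generative conditions for a multi-subject cohort of
#' mutually exclusive state sequences with controllable cyclical structure.
#' Defaults emulate a resting-state electrophysiology cohort: K = 12
#' network states at 250 Hz with geometric dwell times of mean 16 samples
#' (64 ms, the typical mean state lifetime).
#'
#' @param K Number of states.
#' @param n_subjects Cohort size.
#' @param T Samples per subject.
#' @param fs Sampling rate in Hz.
#' @param cycle_order Permutation of `1:K`: the generative cyclical order.
#' @param rho Rotational bias (>= 0; 0 = unbiased transitions).
#' @param dwell Dwell-time model (in samples): one of
#'   `list(model = "geometric", p = ...)` (mean `1/p`),
#'   `list(model = "lognormal", meanlog = ..., sdlog = ...)`, or
#'   `list(model = "gamma", shape = ..., scale = ...)`. Draws are rounded
#'   up to at least 1 sample. Heavy-tailed choices produce the highly
#'   dispersive, long-tailed interval distributions seen in real state
#'   courses.
#' @param dwell_gate Optional threshold in samples: when set, the
#'   rotational bias applies only to transitions following a dwell longer
#'   than the gate (transitions after shorter dwells are uniform). This
#'   confines the cyclical structure to long timescales.
#' @param seed Master seed (mandatory); per-subject substreams are derived
#'   from it so cohorts are reproducible subject by subject.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(K = 12L, n_subjects = 12L, T = 12000L,
                              fs = 250, cycle_order = seq_len(K), rho = 0,
                              dwell = list(model = "geometric", p = 1 / 16),
                              dwell_gate = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (rho < 0) stop("rho must be >= 0")
  stopifnot(setequal(cycle_order, seq_len(K)))
  dwell$model <- match.arg(dwell$model, c("geometric", "lognormal", "gamma"))
  structure(list(K = as.integer(K), n_subjects = as.integer(n_subjects),
                 T = as.integer(T), fs = fs,
                 cycle_order = as.integer(cycle_order), rho = rho,
                 dwell = dwell, dwell_gate = dwell_gate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Rotationally biased transition matrix
#'
#' Row-stochastic K x K matrix with zero diagonal in which the probability
#' of jumping from the state at cycle position `i` to the state at position
#' `j` decays exponentially with the clockwise step distance:
#' `P[i, j] proportional to exp(-rho * d_cw(i, j))` with
#' `d_cw in 1..K-1`. `rho = 0` gives uniform off-diagonal transitions; its
#' stationary distribution is uniform for every `rho` (circulant symmetry).
#'
#' @param K Number of states.
#' @param cycle_order Permutation giving the cyclical order of states.
#' @param rho Rotational bias (>= 0).
#' @return K x K row-stochastic matrix (states in label order).
#' @export
rotational_transition_matrix <- function(K, cycle_order = seq_len(K),
                                         rho = 0) {
  K <- as.integer(K)
  stopifnot(rho >= 0, setequal(cycle_order, seq_len(K)))
  pos <- match(seq_len(K), cycle_order)  # position of each state
  P <- matrix(0, K, K)
  for (i in seq_len(K)) {
    d <- (pos - pos[i]) %% K  # clockwise steps, 0 for self
    w <- exp(-rho * d)
    w[d == 0L] <- 0
    P[i, ] <- w / sum(w)
  }
  P
}

draw_dwells <- function(n, dwell) {
  x <- switch(dwell$model,
              geometric = stats::rgeom(n, dwell$p) + 1,
              lognormal = stats::rlnorm(n, dwell$meanlog, dwell$sdlog),
              gamma = stats::rgamma(n, shape = dwell$shape,
                                    scale = dwell$scale))
  pmax(ceiling(x), 1L)
}

#' Simulate a first-order Markov state sequence
#'
#' @param P Row-stochastic K x K transition matrix (a nonzero diagonal
#'   produces geometric dwell times).
#' @param T Number of samples.
#' @param fs Sampling rate in Hz.
#' @param seed Seed (mandatory for reproducibility).
#' @param subject_id Identifier.
#' @return A [state_tc()].
#' @export
simulate_markov <- function(P, T, fs = 250, seed = NULL,
                            subject_id = "sim_markov") {
  stopifnot(is.matrix(P), nrow(P) == ncol(P),
            all(abs(rowSums(P) - 1) < 1e-8), all(P >= 0))
  K <- nrow(P)
  if (!is.null(seed)) set.seed(seed)
  labels <- integer(T)
  labels[1L] <- sample.int(K, 1L)
  for (t in 2:T)
    labels[t] <- sample.int(K, 1L, prob = P[labels[t - 1L], ])
  state_tc(labels, fs = fs, K = K, subject_id = subject_id)
}

# one subject's semi-Markov sequence under a sim_config (RNG state assumed set)
simulate_semi_markov_one <- function(config, subject_id) {
  K <- config$K
  P <- rotational_transition_matrix(K, config$cycle_order, config$rho)
  P0 <- rotational_transition_matrix(K, config$cycle_order, 0)
  labels <- integer(config$T)
  t <- 0L
  s <- sample.int(K, 1L)
  last_dwell <- Inf
  while (t < config$T) {
    d <- draw_dwells(1L, config$dwell)
    d <- min(d, config$T - t)
    labels[(t + 1L):(t + d)] <- s
    t <- t + d
    use_bias <- is.null(config$dwell_gate) || d > config$dwell_gate
    row <- if (use_bias) P[s, ] else P0[s, ]
    s <- sample.int(K, 1L, prob = row)
  }
  state_tc(labels, fs = config$fs, K = K, subject_id = subject_id)
}

#' Simulate a semi-Markov cohort
#'
#' Alternates dwell-length draws from the configured dwell model with
#' next-state draws from the rotationally biased transition matrix. Each
#' subject gets an independent RNG substream derived deterministically from
#' the master seed, so any subject can be regenerated alone.
#'
#' @param config A [simulation_config()].
#' @return A [state_cohort()].
#' @export
simulate_semi_markov <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  subs <- lapply(seq_len(config$n_subjects), function(i) {
    set.seed(sub_seeds[i])
    simulate_semi_markov_one(config, sprintf("sim%02d", i))
  })
  state_cohort(subs)
}

#' Fit a first-order Markov chain to a state sequence
#'
#' Maximum-likelihood sample-level transition matrix (row-normalized
#' transition counts). States never left (no outgoing observation) get an
#' `NA` row and are flagged. The fitted object supports [simulate()] for
#' the fit-then-resimulate comparison: sequences simulated from the
#' first-order fit lose cyclical structure that is carried by long-dwell,
#' variable-interval dependencies.
#'
#' @param stc A [state_tc()] with `T >= 2`.
#' @return Object of class `tinda_markov`: `P` (K x K), `counts`, `K`,
#'   `fs`.
#' @export
fit_markov <- function(stc) {
  stopifnot(inherits(stc, "state_tc"), length(stc$labels) >= 2L)
  K <- stc$K
  from <- stc$labels[-length(stc$labels)]
  to <- stc$labels[-1L]
  tab <- table(factor(from, levels = seq_len(K)),
               factor(to, levels = seq_len(K)))
  counts <- matrix(as.numeric(tab), K, K)
  rs <- rowSums(counts)
  P <- counts / rs
  if (any(rs == 0)) {
    warning("state(s) with no outgoing transitions: ",
            paste(which(rs == 0), collapse = ", "))
    P[rs == 0, ] <- NA_real_
  }
  structure(list(P = P, counts = counts, K = K, fs = stc$fs),
            class = "tinda_markov")
}

#' @export
print.tinda_markov <- function(x, digits = 3, ...) {
  cat(sprintf("First-order Markov fit (K = %d)\n", x$K))
  print(round(x$P, digits))
  invisible(x)
}

#' Simulate from a fitted first-order Markov chain
#'
#' @param object A `tinda_markov` fit.
#' @param nsim Number of sequences to simulate.
#' @param seed Seed.
#' @param T Samples per sequence (default: the number of transitions the
#'   fit saw plus one).
#' @param ... Unused.
#' @return A [state_cohort()] of `nsim` sequences.
#' @export
simulate.tinda_markov <- function(object, nsim = 1, seed = NULL,
                                  T = sum(object$counts) + 1, ...) {
  P <- object$P
  if (anyNA(P)) stop("cannot simulate from a fit with undefined rows")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  state_cohort(lapply(seq_len(nsim), function(i)
    simulate_markov(P, T = T, fs = object$fs, seed = seeds[i],
                    subject_id = sprintf("markov_sim%02d", i))))
}
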