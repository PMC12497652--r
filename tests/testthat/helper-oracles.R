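# Independent brute-force oracles, written as plain scans so they share no
# code path with the package implementation.

# FO asymmetry by direct per-interval sample counting (1-based arithmetic).
oracle_fo_asymmetry <- function(labels, K) {
  A <- matrix(NA_real_, K, K)
  T <- length(labels)
  for (m in seq_len(K)) {
    starts <- integer(0); ends <- integer(0)
    inside <- FALSE
    for (t in seq_len(T)) {
      if (labels[t] == m && !inside) { starts <- c(starts, t); inside <- TRUE }
      if (labels[t] != m && inside) { ends <- c(ends, t - 1L); inside <- FALSE }
    }
    if (inside) ends <- c(ends, T)
    if (length(starts) < 2L) next
    diffs <- NULL
    for (i in seq_len(length(starts) - 1L)) {
      lo <- ends[i] + 1L          # first sample strictly inside the interval
      hi <- starts[i + 1L] - 1L   # last sample strictly inside
      dur <- hi - lo + 1L
      if (dur < 2L) next
      h <- floor(dur / 2)
      first <- labels[lo:(lo + h - 1L)]
      second <- labels[(hi - h + 1L):hi]
      row <- numeric(K)
      for (n in seq_len(K))
        row[n] <- sum(first == n) / h - sum(second == n) / h
      diffs <- rbind(diffs, row)
    }
    if (!is.null(diffs)) {
      A[m, ] <- colMeans(diffs)
      A[m, m] <- 0
    }
  }
  A
}

# All permutations of 1..n as rows (test-side only, small n).
perm_rows <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perm_rows(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, ifelse(sub >= i, sub + 1L, sub)))
  }
  out
}

# Exhaustive maximum cycle strength over every ordering of K states.
oracle_best_S <- function(A) {
  K <- nrow(A)
  A[is.na(A)] <- 0
  q <- 2 * pi * (seq_len(K) - 1) / K
  beta <- 1 / sum(abs(sin(outer(q, q, "-"))))
  perms <- perm_rows(K)
  best <- -Inf
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    ph <- numeric(K); ph[ord] <- q
    s <- -beta * sum(A * sin(outer(ph, ph, "-")))
    if (s > best) best <- s
  }
  best
}

# Brute-force minimal-cost bijection.
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- perm_rows(n)
  best <- Inf; best_p <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    tc <- sum(cost[cbind(seq_len(n), p)])
    if (tc < best) { best <- tc; best_p <- p }
  }
  list(assignment = best_p, total_cost = best)
}

# Brute-force sliding-window onset count.
oracle_visit_counts <- function(labels, w) {
  T <- length(labels)
  onset <- logical(T)
  onset[1] <- TRUE
  if (T > 1) for (t in 2:T) onset[t] <- labels[t] != labels[t - 1]
  h <- (w - 1) %/% 2
  counts <- integer(T)
  for (t in seq_len(T)) {
    lo <- max(1, t - h); hi <- min(T, t + h)
    counts[t] <- sum(onset[lo:hi])
  }
  counts
}

random_stc <- function(T, K, fs = 250, seed = NULL, subject_id = "rand") {
  if (!is.null(seed)) set.seed(seed)
  state_tc(sample.int(K, T, replace = TRUE), fs = fs, K = K,
           subject_id = subject_id)
}

null_cohort <- function(n_subjects, T, K, fs = 250, seed) {
  set.seed(seed)
  state_cohort(lapply(seq_len(n_subjects), function(i)
    state_tc(sample.int(K, T, replace = TRUE), fs = fs, K = K,
             subject_id = sprintf("null%02d", i))))
}
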