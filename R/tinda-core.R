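#' Split an interval span into equal halves
#'
#' Intervals are partitioned evenly: the first half `T1` precedes the second
#' half `T2`, both contiguous and of equal size. Odd-length intervals drop
#' the single middle sample from both halves so the split stays symmetric.
#' Intervals shorter than 2 samples are unusable.
#'
#' @param start,end Half-open 0-based span `[start, end)`.
#' @return List with integer vectors `t1`, `t2` (sample indices, 0-based)
#'   and logical `usable`.
#' @export
split_interval_halves <- function(start, end) {
  dur <- end - start
  if (dur < 2L) return(list(t1 = integer(0), t2 = integer(0), usable = FALSE))
  h <- dur %/% 2L
  list(t1 = seq.int(start, length.out = h),
       t2 = seq.int(end - h, length.out = h),
       usable = TRUE)
}

# Core kernel shared by compute_fo_asymmetry, segment_restricted_asymmetry
# and the per-bin analysis: FO asymmetry from an explicit list of intervals
# per reference state. intervals_by_state is a list of length K of data
# frames with columns start, end.
fo_asym_from_intervals <- function(labels, K, intervals_by_state,
                                   subject_id = "") {
  A <- matrix(NA_real_, K, K)
  n_used <- integer(K)
  for (m in seq_len(K)) {
    iv <- intervals_by_state[[m]]
    if (is.null(iv) || nrow(iv) == 0L) next
    acc <- numeric(K)
    used <- 0L
    for (i in seq_len(nrow(iv))) {
      sp <- split_interval_halves(iv$start[i], iv$end[i])
      if (!sp$usable) next
      h <- length(sp$t1)
      fo1 <- tabulate(labels[sp$t1 + 1L], nbins = K) / h
      fo2 <- tabulate(labels[sp$t2 + 1L], nbins = K) / h
      acc <- acc + (fo1 - fo2)
      used <- used + 1L
    }
    if (used > 0L) {
      A[m, ] <- acc / used
      A[m, m] <- 0
    }
    n_used[m] <- used
  }
  structure(list(A = A, n_intervals_used = n_used, K = K,
                 subject_id = subject_id),
            class = "fo_asym")
}

#' Fractional-occupancy asymmetry matrix for one subject
#'
#' For each reference state `m`, every interval between consecutive
#' reactivations of `m` is split evenly in half, and the fractional
#' occupancy of every state `n` is contrasted between the first and second
#' half. Entry `A[m, n]` is the unweighted mean over `m`'s usable intervals
#' of `FO(n, first half) - FO(n, second half)`: positive values mean state
#' `n` tends to follow state `m`, negative that it precedes it.
#'
#' Rows of `A` sum to zero (occupancy is conserved between equal-sized
#' halves) and `A[m, m] = 0` because the reference state never occurs
#' strictly inside its own intervals. Reference states with no usable
#' interval yield an `NA` row, never a silent zero.
#'
#' @param stc A [state_tc()].
#' @param min_duration Minimum interval duration in samples for an interval
#'   to be usable (halves require at least 2).
#' @return Object of class `fo_asym`: list with `A` (K x K), per-state
#'   `n_intervals_used`, `K`, `subject_id`.
#' @export
compute_fo_asymmetry <- function(stc, min_duration = 2L) {
  stopifnot(inherits(stc, "state_tc"))
  ivs <- lapply(seq_len(stc$K), function(m) {
    iv <- extract_intervals(stc, m)
    iv[iv$duration_samples >= min_duration, , drop = FALSE]
  })
  fo_asym_from_intervals(stc$labels, stc$K, ivs, subject_id = stc$subject_id)
}

#' FO asymmetry restricted to fixed segments
#'
#' Identical to [compute_fo_asymmetry()] but only intervals fully contained
#' in one of the supplied segments are used — e.g. the fixed-length epochs
#' preceding a task event.
#'
#' @param stc A [state_tc()].
#' @param segments Integer matrix with columns `start`, `end`: half-open
#'   0-based sample ranges.
#' @param min_duration Minimum usable interval duration in samples.
#' @return An `fo_asym` object; all-`NA` (with a warning) when no segment
#'   contains a usable interval.
#' @export
segment_restricted_asymmetry <- function(stc, segments, min_duration = 2L) {
  stopifnot(inherits(stc, "state_tc"))
  stc2 <- state_tc(stc$labels, stc$fs, stc$K, stc$subject_id,
                   segments = segments)
  res <- compute_fo_asymmetry(stc2, min_duration = min_duration)
  if (all(res$n_intervals_used == 0L))
    warning("no usable interval inside any segment for subject ",
            stc$subject_id)
  res
}

#' @export
print.fo_asym <- function(x, digits = 3, ...) {
  cat(sprintf("FO asymmetry matrix '%s' (K = %d)\n", x$subject_id, x$K))
  print(round(x$A, digits))
  cat("intervals used per reference state:",
      paste(x$n_intervals_used, collapse = " "), "\n")
  invisible(x)
}

#' Group-level test of FO asymmetries
#'
#' Each off-diagonal edge `(m, n)` is tested across subjects with a
#' two-tailed dependent-sample t-test of the first-half versus second-half
#' occupancies, i.e. a one-sample t-test of the per-subject asymmetries
#' against zero. The significance level is Bonferroni-corrected over the
#' `K^2 - K` edges (for K = 12: 132 tests, corrected alpha 0.05/132 ~
#' 0.00038). Alternatively a fixed |t| threshold can be supplied, as used
#' for very large cohorts. The signed edge matrix `E` marks significant
#' edges with the sign of the mean asymmetry.
#'
#' Subjects with an undefined entry at an edge are dropped pairwise for that
#' edge. Edges with zero across-subject variance get an undefined t and are
#' treated as nonsignificant.
#'
#' @param matrices List of `fo_asym` objects (>= 3 subjects with defined
#'   values per edge).
#' @param alpha_raw Uncorrected significance level (default 0.05).
#' @param t_threshold Optional absolute t-value threshold used instead of
#'   the corrected alpha.
#' @return Object of class `group_asym`: `mean_A`, `t_stats`, `p_values`,
#'   `alpha` (corrected), `E` (K x K in -1/0/+1), `n_subjects`, `n_eff`
#'   (subjects used per edge), `n_tests`.
#' @export
group_asymmetry_test <- function(matrices, alpha_raw = 0.05,
                                 t_threshold = NULL) {
  stopifnot(length(matrices) >= 1L)
  K <- matrices[[1L]]$K
  arr <- vapply(matrices, function(m) m$A, matrix(0, K, K))
  n_eff <- apply(!is.na(arr), c(1L, 2L), sum)
  mean_A <- apply(arr, c(1L, 2L), mean, na.rm = TRUE)
  mean_A[n_eff == 0L] <- NA_real_
  sd_A <- apply(arr, c(1L, 2L), stats::sd, na.rm = TRUE)
  t_stats <- mean_A / (sd_A / sqrt(n_eff))
  t_stats[!is.finite(t_stats)] <- NA_real_
  p_values <- 2 * stats::pt(-abs(t_stats), df = pmax(n_eff - 1L, 1L))
  diag(t_stats) <- NA_real_
  diag(p_values) <- NA_real_
  n_tests <- K^2 - K
  alpha <- alpha_raw / n_tests
  sig <- if (is.null(t_threshold)) {
    !is.na(p_values) & p_values < alpha
  } else {
    !is.na(t_stats) & abs(t_stats) > t_threshold
  }
  E <- matrix(0L, K, K)
  E[sig & mean_A > 0] <- 1L
  E[sig & mean_A < 0] <- -1L
  structure(list(mean_A = mean_A, t_stats = t_stats, p_values = p_values,
                 alpha = alpha, alpha_raw = alpha_raw,
                 t_threshold = t_threshold, E = E,
                 n_subjects = length(matrices), n_eff = n_eff,
                 n_tests = n_tests, K = K),
            class = "group_asym")
}

#' @export
print.group_asym <- function(x, ...) {
  cat(sprintf("Group FO asymmetry: %d subjects, K = %d\n", x$n_subjects, x$K))
  cat(sprintf("%d edge tests, corrected alpha = %.3g%s\n", x$n_tests, x$alpha,
              if (!is.null(x$t_threshold))
                sprintf(" (|t| > %g threshold in use)", x$t_threshold) else ""))
  cat(sprintf("%d significant edges (%d forward, %d backward)\n",
              sum(x$E != 0L), sum(x$E == 1L), sum(x$E == -1L)))
  invisible(x)
}

#' Export per-subject asymmetry matrices as CSV
#'
#' @param matrices List of `fo_asym` objects.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_asymmetry_csv <- function(matrices, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(matrices, function(m) {
    p <- file.path(dir, paste0("fo_asymmetry_", m$subject_id, ".csv"))
    utils::write.table(m$A, p, sep = ",", row.names = FALSE, col.names = FALSE)
    p
  }, character(1L))
  invisible(paths)
}
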