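#' Bin a subject's intervals by duration percentile
#'
#' For each reference state separately, the intervals between its
#' reactivations are sorted by duration (ties broken by temporal order) and
#' split into `n_bins` contiguous groups of near-equal count (differing by
#' at most one interval). Binning per state keeps every state equally
#' represented within each bin. States with fewer usable intervals than
#' bins are excluded and flagged.
#'
#' @param stc A [state_tc()].
#' @param n_bins Number of percentile bins (default 5).
#' @param min_duration Minimum usable interval duration in samples.
#' @return Object of class `duration_binning`: list with
#'   `intervals_by_state_bin` (list over states of lists over bins of
#'   interval data frames), `mean_duration_ms` (K x n_bins), `counts`
#'   (K x n_bins), `excluded_states`, `n_bins`, `K`.
#' @export
bin_intervals_by_duration <- function(stc, n_bins = 5L, min_duration = 2L) {
  stopifnot(inherits(stc, "state_tc"))
  n_bins <- as.integer(n_bins)
  K <- stc$K
  by_state <- vector("list", K)
  mean_dur <- matrix(NA_real_, K, n_bins)
  counts <- matrix(0L, K, n_bins)
  excluded <- integer(0)
  for (m in seq_len(K)) {
    iv <- extract_intervals(stc, m)
    iv <- iv[iv$duration_samples >= min_duration, , drop = FALSE]
    n <- nrow(iv)
    if (n < n_bins) {
      excluded <- c(excluded, m)
      next
    }
    o <- order(iv$duration_samples, iv$start)
    iv <- iv[o, , drop = FALSE]
    base <- n %/% n_bins
    extra <- n %% n_bins
    sizes <- rep(base, n_bins) + (seq_len(n_bins) > n_bins - extra)
    idx <- rep(seq_len(n_bins), times = sizes)
    by_state[[m]] <- lapply(seq_len(n_bins), function(b) {
      out <- iv[idx == b, , drop = FALSE]
      rownames(out) <- NULL
      out
    })
    mean_dur[m, ] <- vapply(by_state[[m]], function(x) mean(x$duration_ms),
                            numeric(1L))
    counts[m, ] <- sizes
  }
  if (length(excluded))
    message("subject ", stc$subject_id, ": state(s) ",
            paste(excluded, collapse = ", "),
            " have fewer than ", n_bins, " intervals; excluded from binning")
  structure(list(intervals_by_state_bin = by_state,
                 mean_duration_ms = mean_dur, counts = counts,
                 excluded_states = excluded, n_bins = n_bins, K = K,
                 subject_id = stc$subject_id),
            class = "duration_binning")
}

#' Per-duration-bin cycle analysis
#'
#' Reruns the interval-halving asymmetry computation separately on each
#' duration-percentile bin of every subject, then evaluates cycle strength
#' at a fixed layout (normally obtained from full-data optimization) and
#' runs a fixed-layout label-shuffle permutation test per bin. This probes
#' the timescale dependence of the cycle: with dynamics confined to long
#' intervals, S grows with bin index.
#'
#' @param cohort A [state_cohort()].
#' @param layout Fixed [circle_layout()] from the full-data optimization.
#' @param n_bins Number of percentile bins (default 5).
#' @param n_perm Permutations per bin (0 to skip inference).
#' @param alpha_raw Uncorrected alpha for per-bin edge statistics.
#' @param seed Base seed; bin `b` uses `seed + b`.
#' @param min_duration Minimum usable interval duration in samples.
#' @return Object of class `bin_cycle_analysis`: per-bin list with
#'   `asym` (per-subject `fo_asym` list), `group` (`group_asym`),
#'   `S_per_subject`, `S_group`, `perm` (`perm_null` or NULL), plus
#'   `mean_duration_ms` (subject x bin, pooled over states), `layout`.
#' @export
per_bin_cycle_analysis <- function(cohort, layout, n_bins = 5L,
                                   n_perm = 1000L, alpha_raw = 0.05,
                                   seed = NULL, min_duration = 2L) {
  stopifnot(inherits(cohort, "state_cohort"),
            inherits(layout, "circle_layout"))
  binnings <- lapply(cohort, bin_intervals_by_duration, n_bins = n_bins,
                     min_duration = min_duration)
  bins <- lapply(seq_len(n_bins), function(b) {
    asym <- lapply(seq_along(cohort), function(si) {
      bn <- binnings[[si]]
      ivs <- lapply(bn$intervals_by_state_bin, function(st)
        if (is.null(st)) NULL else st[[b]])
      fo_asym_from_intervals(cohort[[si]]$labels, cohort[[si]]$K, ivs,
                             subject_id = cohort[[si]]$subject_id)
    })
    S_per_subject <- vapply(asym, function(a) {
      Ai <- a$A
      Ai[is.na(Ai)] <- 0
      cycle_strength(Ai, layout)
    }, numeric(1L))
    grp <- group_asymmetry_test(asym, alpha_raw = alpha_raw)
    perm <- if (n_perm > 0L) {
      permutation_test_cycle_strength(asym, n_perm = n_perm,
                                      scheme = "fixed_layout",
                                      layout = layout,
                                      seed = if (is.null(seed)) NULL else seed + b)
    } else NULL
    list(asym = asym, group = grp, S_per_subject = S_per_subject,
         S_group = mean(S_per_subject), perm = perm)
  })
  mean_dur <- t(vapply(binnings, function(bn)
    colMeans(bn$mean_duration_ms, na.rm = TRUE), numeric(n_bins)))
  structure(list(bins = bins, mean_duration_ms = mean_dur, layout = layout,
                 n_bins = n_bins, binnings = binnings),
            class = "bin_cycle_analysis")
}

#' @export
print.bin_cycle_analysis <- function(x, ...) {
  cat(sprintf("Per-duration-bin cycle analysis (%d bins)\n", x$n_bins))
  for (b in seq_len(x$n_bins)) {
    bn <- x$bins[[b]]
    cat(sprintf("  bin %d: mean interval %.0f ms, S = %.4f%s\n",
                b, mean(x$mean_duration_ms[, b], na.rm = TRUE), bn$S_group,
                if (!is.null(bn$perm)) sprintf(", p = %.4g", bn$perm$p) else ""))
  }
  invisible(x)
}
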