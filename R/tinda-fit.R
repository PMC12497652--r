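#' Fit the full temporal interval network density analysis
#'
#' The main entry point: given a cohort of discrete state time courses,
#' computes each subject's fractional-occupancy asymmetry matrix, the
#' group-level edge statistics, the circle layout maximizing cycle
#' strength, per-subject and group cycle strength, and (optionally) the
#' label-shuffle permutation test of the optimized cycle strength.
#'
#' @param cohort A [state_cohort()], or a list of [state_tc()] objects.
#' @param alpha_raw Uncorrected significance level for edge tests
#'   (Bonferroni-corrected over `K^2 - K` internally).
#' @param t_threshold Optional |t| threshold replacing the corrected alpha.
#' @param n_perm Permutations for cycle-strength inference (0 disables).
#' @param seed Seed for the permutation stream and local search.
#' @param min_duration Minimum usable interval duration in samples.
#' @param ... Optimizer arguments passed to [optimize_ordering()].
#' @return Object of class `tinda`: per-subject asymmetries (`asym`),
#'   `group` (`group_asym`), `layout` (optimized [circle_layout()]),
#'   `S_per_subject`, `S_group`, `perm` (`perm_null` or `NULL`).
#' @examples
#' cfg <- simulation_config(K = 6, n_subjects = 6, T = 4000, rho = 1,
#'                          seed = 42)
#' fit <- tinda(simulate_semi_markov(cfg), n_perm = 50, seed = 1)
#' print(fit)
#' @export
tinda <- function(cohort, alpha_raw = 0.05, t_threshold = NULL,
                  n_perm = 1000L, seed = NULL, min_duration = 2L, ...) {
  if (!inherits(cohort, "state_cohort")) cohort <- state_cohort(cohort)
  asym <- lapply(cohort, compute_fo_asymmetry, min_duration = min_duration)
  group <- group_asymmetry_test(asym, alpha_raw = alpha_raw,
                                t_threshold = t_threshold)
  mean_A <- group$mean_A
  mean_A[is.na(mean_A)] <- 0
  layout <- optimize_ordering(mean_A, seed = seed, ...)
  S_per_subject <- vapply(asym, function(a) {
    Ai <- a$A
    Ai[is.na(Ai)] <- 0
    cycle_strength(Ai, layout)
  }, numeric(1L))
  perm <- if (n_perm > 0L) {
    permutation_test_cycle_strength(asym, n_perm = n_perm,
                                    scheme = "reoptimize", seed = seed, ...)
  } else NULL
  structure(list(asym = asym, group = group, layout = layout,
                 S_per_subject = S_per_subject,
                 S_group = mean(S_per_subject),
                 S_layout = attr(layout, "S"),
                 perm = perm, K = group$K, fs = cohort[[1L]]$fs,
                 n_subjects = length(cohort)),
            class = "tinda")
}

#' @export
print.tinda <- function(x, ...) {
  cat(sprintf("TINDA fit: %d subjects, K = %d states\n", x$n_subjects, x$K))
  cat(sprintf("Optimized cycle order: %s\n",
              paste(x$layout$ordering, collapse = " -> ")))
  cat(sprintf("Cycle strength: group mean over subjects S = %.4f (group-mean matrix S = %.4f)\n",
              x$S_group, x$S_layout))
  if (!is.null(x$perm))
    cat(sprintf("Label-shuffle permutation test: p = %.4g (%d permutations)\n",
                x$perm$p, x$perm$n_perm))
  invisible(x)
}

#' @export
summary.tinda <- function(object, ...) {
  structure(list(fit = object), class = "summary.tinda")
}

#' @export
print.summary.tinda <- function(x, ...) {
  f <- x$fit
  print(f)
  print(f$group)
  cat("Per-subject cycle strength:\n")
  print(summary(f$S_per_subject))
  invisible(x)
}

#' Extract the group-mean asymmetry matrix
#'
#' @param object A `tinda` fit.
#' @param ... Unused.
#' @return The K x K group-mean FO asymmetry matrix.
#' @export
coef.tinda <- function(object, ...) object$group$mean_A

#' Circle plot of a TINDA fit
#'
#' States at their optimized phases on the unit circle; significant
#' asymmetries drawn as arrows in the direction of net flow.
#'
#' @param x A `tinda` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tinda <- function(x, ...) {
  ph <- x$layout$phases
  # drawn clockwise from the top, matching the convention of increasing
  # phase along the cycle direction
  px <- sin(ph)
  py <- cos(ph)
  graphics::plot(px, py, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
                 asp = 1, pch = 21, bg = "grey80", cex = 3, axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("Cycle (S = %.3f)", x$S_group), ...)
  graphics::text(px, py, labels = seq_len(x$K))
  E <- x$group$E
  idx <- which(E != 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    j <- idx[r, 1L]; k <- idx[r, 2L]
    from <- if (E[j, k] > 0L) j else k
    to <- if (E[j, k] > 0L) k else j
    graphics::arrows(0.9 * px[from], 0.9 * py[from],
                     0.9 * px[to], 0.9 * py[to],
                     length = 0.08, col = "grey40")
  }
  invisible(x)
}

#' Per-subject cycle strengths at the fitted layout
#'
#' @param object A `tinda` fit.
#' @param ... Unused.
#' @return Numeric vector of per-subject S values (deviations of each
#'   subject's rotational flow from the group layout are visible here).
#' @export
residuals.tinda <- function(object, ...) {
  object$S_per_subject - object$S_group
}
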