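#' Circle layout of states
#'
#' Places the `K` states at equally spaced phases on the unit circle. The
#' layout is the carrier of cycle geometry: position `i` (phase
#' `2*pi*(i-1)/K`) holds state `ordering[i]`. Rotation and reflection of the
#' circle are gauge freedoms; [canonicalize_layout()] fixes them.
#'
#' @param ordering Permutation of `1:K`; `ordering[i]` is the state at
#'   position `i`.
#' @return Object of class `circle_layout` with fields `ordering`, `phases`
#'   (per-state angle in radians, indexed by state), `beta`, `K`.
#' @export
circle_layout <- function(ordering) {
  ordering <- as.integer(ordering)
  K <- length(ordering)
  if (!setequal(ordering, seq_len(K)))
    stop("ordering must be a permutation of 1..K")
  phases <- numeric(K)
  phases[ordering] <- 2 * pi * (seq_len(K) - 1L) / K
  structure(list(ordering = ordering, phases = phases,
                 beta = normalization_beta(K), K = K),
            class = "circle_layout")
}

#' @export
print.circle_layout <- function(x, ...) {
  cat(sprintf("Circle layout (K = %d): %s\n", x$K,
              paste(x$ordering, collapse = " -> ")))
  cat(sprintf("beta = %.6g\n", x$beta))
  invisible(x)
}

#' Cycle-strength normalization factor
#'
#' The theoretical maximum raw cycle strength for `K` equally spaced states
#' is attained by a perfect asymmetry of +1 on every clockwise ordered pair
#' and -1 on every counterclockwise pair, giving
#' `sum_{m != n} |sin(q_m - q_n)|`. The normalization `beta` is its inverse,
#' so cycle strength is constrained to `[-1, 1]`.
#'
#' @param K Number of states (>= 3; for K = 2 all phase differences are pi
#'   and the maximum is 0).
#' @return Positive scalar `beta`.
#' @export
normalization_beta <- function(K) {
  K <- as.integer(K)
  if (K < 3L) stop("normalization requires K >= 3")
  q <- 2 * pi * (seq_len(K) - 1L) / K
  raw_max <- sum(abs(sin(outer(q, q, "-"))))
  1 / raw_max
}

#' Cycle strength of an asymmetry matrix on a circle layout
#'
#' Projects every directed edge weight `A[m, n]` onto the tangential
#' direction of the circle and sums:
#' `S = -beta * sum_{m} sum_{n != m} A[m, n] * sin(q_m - q_n)`.
#' `S = +1` for a perfectly clockwise graph (flow in the direction of
#' increasing phase), 0 for a completely stochastic graph, negative for net
#' counterclockwise flow.
#'
#' @param A K x K asymmetry matrix or an `fo_asym` object. Missing entries
#'   are treated as 0 with a warning.
#' @param layout A [circle_layout()] with matching `K`.
#' @return Scalar `S` in `[-1, 1]`.
#' @export
cycle_strength <- function(A, layout) {
  if (inherits(A, "fo_asym")) A <- A$A
  stopifnot(inherits(layout, "circle_layout"))
  if (!is.matrix(A) || nrow(A) != layout$K || ncol(A) != layout$K)
    stop("A must be a ", layout$K, " x ", layout$K, " matrix")
  if (anyNA(A)) {
    warning("undefined asymmetry entries treated as 0 in cycle strength")
    A[is.na(A)] <- 0
  }
  sinM <- sin(outer(layout$phases, layout$phases, "-"))
  -layout$beta * sum(A * sinM)
}

# Raw evaluation used in inner loops: A indexed by ordering against a fixed
# position-phase sine matrix (no object overhead).
cycle_strength_raw <- function(A, ordering, sin_base, beta) {
  -beta * sum(A[ordering, ordering] * sin_base)
}

# All permutations of a vector (small n only).
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(matrix(v, nrow = max(1L, n > 0L)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- all_perms(v[-i])
    out[[i]] <- cbind(v[i], rest)
  }
  do.call(rbind, out)
}

#' Put a layout in canonical form
#'
#' Rotations and reflections of the circle leave |S| unchanged; the
#' canonical form rotates the lowest-numbered state to phase 0 and, when an
#' asymmetry matrix is supplied, orients the circle so `S >= 0`.
#'
#' @param layout A [circle_layout()].
#' @param A Optional asymmetry matrix fixing the orientation.
#' @return A canonical [circle_layout()].
#' @export
canonicalize_layout <- function(layout, A = NULL) {
  ord <- layout$ordering
  if (!is.null(A) && cycle_strength(A, layout) < 0)
    ord <- c(ord[1L], rev(ord[-1L]))
  i <- which(ord == min(ord))
  if (i > 1L) ord <- c(ord[i:length(ord)], ord[seq_len(i - 1L)])
  lay <- circle_layout(ord)
  if (!is.null(A) && cycle_strength(A, lay) < 0)
    lay <- circle_layout(c(ord[1L], rev(ord[-1L])))
  lay
}

#' Optimize the circular ordering of states
#'
#' Permutes the position of each state on the unit circle to maximize cycle
#' strength. For `K <= exhaustive_max` all `(K-1)!/2` canonical orderings
#' (rotation and reflection quotiented out) are enumerated; for larger `K` a
#' seeded multi-restart local search over pairwise position swaps and
#' segment reversals with simulated-annealing acceptance is used. The
#' identity ordering is always a candidate, so the returned `S` is at least
#' `S` of the identity layout.
#'
#' @param A K x K asymmetry matrix or `fo_asym` object (`NA` treated as 0).
#' @param method `"auto"` (exhaustive when `K <= exhaustive_max`),
#'   `"exhaustive"`, or `"local_search"`.
#' @param exhaustive_max Largest `K` for which `"auto"` enumerates.
#' @param restarts,n_iter,t0,cooling Local-search budget: number of
#'   restarts, iterations per restart (default `200 * K`), initial
#'   annealing temperature and geometric cooling factor.
#' @param seed Optional seed for the local search.
#' @return A canonical [circle_layout()] with attribute `S` (the maximal
#'   cycle strength) and `method`.
#' @export
optimize_ordering <- function(A, method = c("auto", "exhaustive",
                                            "local_search"),
                              exhaustive_max = 8L, restarts = 50L,
                              n_iter = NULL, t0 = 0.05, cooling = 0.995,
                              seed = NULL) {
  if (inherits(A, "fo_asym")) A <- A$A
  method <- match.arg(method)
  K <- nrow(A)
  if (K < 3L) stop("ordering optimization requires K >= 3")
  if (anyNA(A)) A[is.na(A)] <- 0
  q <- 2 * pi * (seq_len(K) - 1L) / K
  sin_base <- sin(outer(q, q, "-"))
  beta <- normalization_beta(K)
  if (method == "auto")
    method <- if (K <= exhaustive_max) "exhaustive" else "local_search"

  if (method == "exhaustive") {
    rest <- all_perms(seq_len(K)[-1L])
    # reflection maps (1, a2..aK) to (1, aK..a2); keep one representative
    keep <- rest[, 1L] < rest[, ncol(rest)]
    rest <- rest[keep, , drop = FALSE]
    best_s <- -Inf
    best_ord <- seq_len(K)
    for (r in seq_len(nrow(rest))) {
      ord <- c(1L, rest[r, ])
      s <- cycle_strength_raw(A, ord, sin_base, beta)
      if (abs(s) > best_s) {
        best_s <- abs(s)
        best_ord <- if (s >= 0) ord else c(1L, rev(rest[r, ]))
      }
    }
    lay <- canonicalize_layout(circle_layout(best_ord), A)
    structure(lay, S = cycle_strength(A, lay), method = "exhaustive")
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    if (is.null(n_iter)) n_iter <- 200L * K
    best_ord <- seq_len(K)
    best_s <- cycle_strength_raw(A, best_ord, sin_base, beta)
    for (r in seq_len(restarts)) {
      ord <- if (r == 1L) seq_len(K) else sample.int(K)
      s <- cycle_strength_raw(A, ord, sin_base, beta)
      temp <- t0
      for (it in seq_len(n_iter)) {
        ij <- sort(sample.int(K, 2L))
        cand <- ord
        if (stats::runif(1) < 0.5) {
          cand[ij] <- cand[rev(ij)]                    # position swap
        } else {
          cand[ij[1L]:ij[2L]] <- rev(cand[ij[1L]:ij[2L]])  # segment reversal
        }
        s2 <- cycle_strength_raw(A, cand, sin_base, beta)
        if (s2 >= s || stats::runif(1) < exp((s2 - s) / temp)) {
          ord <- cand
          s <- s2
        }
        if (s > best_s) {
          best_s <- s
          best_ord <- ord
        }
        temp <- temp * cooling
      }
    }
    lay <- canonicalize_layout(circle_layout(best_ord), A)
    structure(lay, S = cycle_strength(A, lay), method = "local_search")
  }
}

# Pairwise-NA-aware group mean of a list of fo_asym objects or matrices.
group_mean_A <- function(matrices) {
  mats <- lapply(matrices, function(m) if (inherits(m, "fo_asym")) m$A else m)
  K <- nrow(mats[[1L]])
  arr <- vapply(mats, identity, matrix(0, K, K))
  mean_A <- apply(arr, c(1L, 2L), mean, na.rm = TRUE)
  mean_A[is.nan(mean_A)] <- NA_real_
  mean_A
}

#' Label-shuffle permutation test of cycle strength
#'
#' A nonzero optimized cycle strength could be a trivial consequence of the
#' ordering optimization. The null distribution is built by permuting each
#' subject's state labels independently (conjugating that subject's
#' asymmetry matrix by a random permutation), recomputing the group-mean
#' asymmetry, and — under `scheme = "reoptimize"` — re-optimizing the state
#' ordering before evaluating S, or — under `scheme = "fixed_layout"`, used
#' for the interval-duration-binned analyses — evaluating S at the supplied
#' layout. The one-sided p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`, so `p >= 1/(n_perm+1)`.
#'
#' @param matrices List of `fo_asym` objects or K x K matrices (>= 2
#'   subjects).
#' @param n_perm Number of permutations (>= 1).
#' @param scheme `"reoptimize"` or `"fixed_layout"`.
#' @param layout [circle_layout()]: the evaluation layout for
#'   `"fixed_layout"`; ignored for `"reoptimize"` (the observed statistic
#'   re-optimizes from the group mean).
#' @param seed Seed for the permutation stream (required for
#'   reproducibility).
#' @param ... Optimizer arguments passed to [optimize_ordering()] under
#'   `"reoptimize"`.
#' @return Object of class `perm_null`: `observed`, `null_values`, `p`,
#'   `scheme`, `seed`, `n_perm`, and the observed `layout`.
#' @export
permutation_test_cycle_strength <- function(matrices, n_perm = 1000L,
                                            scheme = c("reoptimize",
                                                       "fixed_layout"),
                                            layout = NULL, seed = NULL, ...) {
  scheme <- match.arg(scheme)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(matrices) < 2L) stop("need >= 2 subjects")
  mats <- lapply(matrices, function(m) {
    a <- if (inherits(m, "fo_asym")) m$A else m
    a[is.na(a)] <- 0
    a
  })
  K <- nrow(mats[[1L]])
  obs_mean <- group_mean_A(mats)
  if (scheme == "reoptimize") {
    obs_lay <- optimize_ordering(obs_mean, seed = seed, ...)
    observed <- attr(obs_lay, "S")
  } else {
    if (is.null(layout)) stop("scheme 'fixed_layout' requires a layout")
    obs_lay <- layout
    observed <- cycle_strength(obs_mean, layout)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  null_values <- vapply(seq_len(n_perm), function(i) {
    pm <- lapply(mats, function(a) {
      p <- sample.int(K)
      a[p, p]
    })
    m <- Reduce(`+`, pm) / length(pm)
    if (scheme == "reoptimize") {
      attr(optimize_ordering(m, ...), "S")
    } else {
      cycle_strength(m, layout)
    }
  }, numeric(1L))
  p <- (1 + sum(null_values >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null_values = null_values, p = p,
                 scheme = scheme, seed = seed, n_perm = n_perm,
                 layout = obs_lay),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed S = %.4f, p = %.4g (%d permutations)\n",
              x$scheme, x$observed, x$p, x$n_perm))
  cat(sprintf("null mean (sd): %.4f (%.4f)\n", mean(x$null_values),
              stats::sd(x$null_values)))
  invisible(x)
}

# absolute circular difference, wrapped into [0, pi]
circ_dist <- function(x) abs(atan2(sin(x), cos(x)))

#' Phase difference between two circle layouts
#'
#' Mean absolute circular phase difference between matched states of two
#' layouts, compared with a null of uniformly random placements of the
#' second layout's states across the circle (position permutations). Small
#' `delta_theta` with small `p` indicates the same cyclical ordering in both
#' layouts.
#'
#' @param layout_a,layout_b [circle_layout()] objects of equal `K`.
#' @param matching Optional [match_states()] result mapping states of
#'   `layout_a` to states of `layout_b`; identity by default.
#' @param n_perm Number of position permutations (default 10000).
#' @param seed Seed for the permutation stream.
#' @return Object of class `phase_comparison`: `delta_theta` (radians, in
#'   `[0, pi]`), `null_values`, `p` (one-sided, smaller than chance).
#' @export
phase_difference <- function(layout_a, layout_b, matching = NULL,
                             n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(layout_a, "circle_layout"),
            inherits(layout_b, "circle_layout"))
  K <- layout_a$K
  if (layout_b$K != K) stop("layouts must share K")
  map <- if (is.null(matching)) seq_len(K) else matching$assignment
  obs <- mean(circ_dist(layout_a$phases - layout_b$phases[map]))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  null_values <- vapply(seq_len(n_perm), function(i) {
    ph <- layout_b$phases[sample.int(K)]
    mean(circ_dist(layout_a$phases - ph[map]))
  }, numeric(1L))
  p <- (1 + sum(null_values <= obs)) / (n_perm + 1)
  structure(list(delta_theta = obs, null_values = null_values, p = p,
                 n_perm = n_perm, seed = seed),
            class = "phase_comparison")
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf("Mean phase difference: %.3f rad, p = %.4g (%d permutations)\n",
              x$delta_theta, x$p, x$n_perm))
  invisible(x)
}

#' Match two state sets by optimal linear assignment
#'
#' Solves the linear assignment problem minimizing the total cost of a
#' bijection between two equally sized state sets — e.g. with
#' `cost = -cor(coherence_a, coherence_b)` to match states across
#' independently trained models.
#'
#' @param cost Finite square cost matrix; entry `(i, j)` is the cost of
#'   matching state `i` of the first set to state `j` of the second.
#' @return Object of class `state_matching`: `assignment` (integer vector,
#'   `assignment[i]` = matched second-set state) and `total_cost`.
#' @export
match_states <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop("cost must be a square matrix")
  if (!all(is.finite(cost))) stop("cost must be finite")
  shifted <- cost - min(cost)  # solve_LSAP requires nonnegative entries
  sol <- clue::solve_LSAP(shifted)
  assignment <- as.integer(sol)
  structure(list(assignment = assignment,
                 total_cost = sum(cost[cbind(seq_len(nrow(cost)),
                                             assignment)])),
            class = "state_matching")
}

#' Export a circle graph
#'
#' Serializes a layout plus signed edge matrix (and optional group
#' statistics) as an igraph object, with JSON and GraphML writers. Each
#' nonzero `E[j, k]` becomes one directed edge: from `j` to `k` when
#' `E[j, k] = +1`, from `k` to `j` when `E[j, k] = -1`.
#'
#' @param layout A [circle_layout()].
#' @param E K x K signed edge matrix in `{-1, 0, +1}`.
#' @param stats Optional `group_asym` supplying edge weights (`mean_A`).
#' @param file_json,file_graphml Optional output paths.
#' @return The igraph graph, invisibly.
#' @export
export_circle_graph <- function(layout, E, stats = NULL, file_json = NULL,
                                file_graphml = NULL) {
  K <- layout$K
  stopifnot(is.matrix(E), nrow(E) == K, ncol(E) == K)
  idx <- which(E != 0L, arr.ind = TRUE)
  edges <- if (nrow(idx)) {
    data.frame(
      from = ifelse(E[idx] > 0L, idx[, 1L], idx[, 2L]),
      to = ifelse(E[idx] > 0L, idx[, 2L], idx[, 1L]),
      sign = E[idx],
      weight = if (!is.null(stats)) stats$mean_A[idx] else NA_real_)
  } else {
    data.frame(from = integer(0), to = integer(0), sign = integer(0),
               weight = numeric(0))
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = seq_len(K), phase = layout$phases,
                          position = match(seq_len(K), layout$ordering),
                          x = cos(layout$phases), y = sin(layout$phases)))
  if (!is.null(file_graphml))
    igraph::write_graph(g, file_graphml, format = "graphml")
  if (!is.null(file_json)) {
    doc <- list(K = K, ordering = layout$ordering, phases = layout$phases,
                beta = layout$beta, E = E, edges = edges)
    jsonlite::write_json(doc, file_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(g)
}

#' Re-import a circle graph written by [export_circle_graph()]
#'
#' @param file_json Path to the JSON document.
#' @return List with `layout` ([circle_layout()]) and `E`.
#' @export
import_circle_graph <- function(file_json) {
  doc <- jsonlite::read_json(file_json, simplifyVector = TRUE)
  list(layout = circle_layout(doc$ordering),
       E = matrix(as.integer(doc$E), doc$K, doc$K))
}
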