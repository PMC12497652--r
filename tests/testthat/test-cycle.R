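perfect_matrix <- function(K, ordering = seq_len(K)) {
  lay <- circle_layout(ordering)
  q <- lay$phases
  A <- sign(sin(outer(q, q, function(a, b) b - a)))
  diag(A) <- 0
  A
}

test_that("normalization beta matches direct summation", {
  q3 <- 2 * pi * (0:2) / 3
  expect_equal(normalization_beta(3), 1 / sum(abs(sin(outer(q3, q3, "-")))))
  expect_equal(1 / normalization_beta(3), 6 * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(normalization_beta(4), 1 / 8)  # 8 pairs |sin|=1, 4 pairs 0
  expect_error(normalization_beta(2), "K >= 3")
})

test_that("cycle strength hits its analytic extremes and symmetries", {
  for (K in c(3, 5, 12)) {
    lay <- circle_layout(seq_len(K))
    A <- perfect_matrix(K)
    expect_equal(cycle_strength(A, lay), 1, tolerance = 1e-12)
    expect_equal(cycle_strength(matrix(0, K, K), lay), 0)
    # reflection negates S; transpose negates S
    refl <- circle_layout(c(1, rev(2:K)))
    expect_equal(cycle_strength(A, refl), -1, tolerance = 1e-12)
    expect_equal(cycle_strength(t(A), lay), -1, tolerance = 1e-12)
  }
  # rotation invariance on a random matrix
  set.seed(2)
  A <- matrix(rnorm(36), 6, 6); diag(A) <- 0
  lay <- circle_layout(1:6)
  rot <- circle_layout(c(3:6, 1:2))
  expect_equal(abs(cycle_strength(A, lay)), abs(cycle_strength(A, rot)),
               tolerance = 1e-12)
})

test_that("NA asymmetries are zeroed with a warning in cycle strength", {
  A <- matrix(0, 4, 4); A[1, 2] <- NA
  expect_warning(s <- cycle_strength(A, circle_layout(1:4)), "undefined")
  expect_equal(s, 0)
})

test_that("exhaustive ordering optimization matches the full-space oracle", {
  set.seed(31)
  for (rep in 1:10) {
    K <- sample(4:6, 1)
    A <- matrix(rnorm(K * K), K, K); diag(A) <- 0
    lay <- optimize_ordering(A, method = "exhaustive")
    expect_equal(attr(lay, "S"), oracle_best_S(A), tolerance = 1e-10)
    # returned layout actually evaluates to the reported S, in canonical form
    expect_equal(cycle_strength(A, lay), attr(lay, "S"), tolerance = 1e-12)
    expect_equal(lay$ordering[1], 1L)
  }
})

test_that("local search matches the exhaustive oracle on small K", {
  set.seed(17)
  for (rep in 1:10) {
    A <- matrix(rnorm(36), 6, 6); diag(A) <- 0
    lay <- optimize_ordering(A, method = "local_search", restarts = 20,
                             seed = rep)
    expect_equal(attr(lay, "S"), oracle_best_S(A), tolerance = 1e-8)
  }
})

test_that("optimization recovers a planted rotational order", {
  for (seed in 1:5) {
    set.seed(seed)
    ord <- sample.int(6)
    A <- perfect_matrix(6, ord) + matrix(rnorm(36, sd = 0.1), 6, 6)
    diag(A) <- 0
    lay <- optimize_ordering(A, method = "exhaustive")
    pos_true <- match(seq_len(6), ord)
    pos_est <- match(seq_len(6), lay$ordering)
    # up to rotation: position differences constant mod K
    expect_equal(length(unique((pos_est - pos_true) %% 6)), 1)
  }
})

test_that("K=3 orderings are all equivalent up to gauge", {
  set.seed(4)
  A <- matrix(rnorm(9), 3, 3); diag(A) <- 0
  s <- vapply(list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2)), function(o)
    cycle_strength(A, circle_layout(o)), numeric(1))
  expect_equal(max(s) - min(s), 0, tolerance = 1e-12)
})

test_that("permutation p-value respects its lower bound and detects signal", {
  cfg <- simulation_config(K = 5, n_subjects = 6, T = 4000, rho = 2,
                           seed = 61)
  coh <- simulate_semi_markov(cfg)
  asym <- lapply(coh, compute_fo_asymmetry)
  pt <- permutation_test_cycle_strength(asym, n_perm = 99,
                                        scheme = "reoptimize", seed = 5)
  expect_equal(pt$p, 1 / 100)  # strongly cyclical: p at its minimum
  expect_true(all(pt$null_values <= pt$observed))
  expect_error(permutation_test_cycle_strength(asym, n_perm = 0), "n_perm")
})

test_that("fixed-layout permutation null is centered near zero", {
  coh <- null_cohort(6, 3000, 5, seed = 77)
  asym <- lapply(coh, compute_fo_asymmetry)
  pt <- permutation_test_cycle_strength(asym, n_perm = 200,
                                        scheme = "fixed_layout",
                                        layout = circle_layout(1:5), seed = 9)
  expect_lt(abs(mean(pt$null_values)), 3 * sd(pt$null_values) / sqrt(200))
})

test_that("phase differences behave under shifts and random placement", {
  la <- circle_layout(1:12)
  expect_equal(phase_difference(la, la, n_perm = 10, seed = 1)$delta_theta, 0)
  shifted <- circle_layout(c(2:12, 1))
  pd <- phase_difference(la, shifted, n_perm = 10, seed = 1)
  expect_equal(pd$delta_theta, 2 * pi / 12, tolerance = 1e-12)
  # identical layouts: smaller than every random placement
  pd0 <- phase_difference(la, la, n_perm = 500, seed = 3)
  expect_equal(pd0$p, 1 / 501)
  # mean over random pairs approaches pi/2
  set.seed(8)
  ds <- replicate(300, {
    lb <- circle_layout(sample.int(12))
    mean(abs(atan2(sin(la$phases - lb$phases), cos(la$phases - lb$phases))))
  })
  expect_equal(mean(ds), pi / 2, tolerance = 0.05)
})

test_that("state matching solves the assignment problem optimally", {
  cost <- matrix(1, 4, 4); diag(cost) <- 0
  expect_equal(match_states(cost)$assignment, 1:4)

  p <- c(3, 1, 4, 2)
  cost2 <- matrix(1, 4, 4)
  cost2[cbind(1:4, p)] <- 0
  expect_equal(match_states(cost2)$assignment, p)

  set.seed(13)
  for (rep in 1:5) {
    cost3 <- matrix(rnorm(25), 5, 5)
    m <- match_states(cost3)
    o <- oracle_assignment(cost3)
    expect_equal(m$total_cost, o$total_cost, tolerance = 1e-12)
  }
  expect_error(match_states(matrix(1, 2, 3)), "square")
  expect_error(match_states(matrix(c(1, Inf, 1, 1), 2, 2)), "finite")
})

test_that("circle graphs round-trip through JSON and GraphML", {
  lay <- circle_layout(c(1, 3, 2, 4))
  E <- matrix(0L, 4, 4)
  E[1, 2] <- 1L
  E[3, 4] <- -1L
  d <- withr::local_tempdir()
  fj <- file.path(d, "g.json")
  fg <- file.path(d, "g.graphml")
  g <- export_circle_graph(lay, E, file_json = fj, file_graphml = fg)
  expect_equal(igraph::ecount(g), 2)
  back <- import_circle_graph(fj)
  expect_equal(back$layout$ordering, lay$ordering)
  expect_equal(back$E, E)
  g2 <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::ecount(g2), 2)

  # empty edge matrix gives an empty edge list
  g0 <- export_circle_graph(lay, matrix(0L, 4, 4))
  expect_equal(igraph::ecount(g0), 0)
})
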