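test_that("rotational transition matrix is row-stochastic with uniform stationary law", {
  P0 <- rotational_transition_matrix(5, rho = 0)
  expect_true(all(abs(P0[row(P0) != col(P0)] - 0.25) < 1e-12))
  expect_true(all(diag(P0) == 0))

  for (rho in c(0.3, 1, 2.5)) {
    P <- rotational_transition_matrix(6, cycle_order = c(2, 4, 6, 1, 3, 5),
                                      rho = rho)
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12)
    # circulant symmetry: uniform distribution is stationary
    pi_unif <- rep(1 / 6, 6)
    expect_equal(as.numeric(pi_unif %*% P), pi_unif, tolerance = 1e-12)
  }
})

test_that("Markov simulation honours P and is seed-reproducible", {
  # permutation matrix gives a deterministic cycle
  P <- matrix(0, 3, 3)
  P[cbind(1:3, c(2, 3, 1))] <- 1
  s <- simulate_markov(P, 30, seed = 1)
  expect_true(all(diff(match(s$labels, 1:3)) %% 3 == 1))

  s1 <- simulate_markov(rotational_transition_matrix(4, rho = 1), 500,
                        seed = 7)
  s2 <- simulate_markov(rotational_transition_matrix(4, rho = 1), 500,
                        seed = 7)
  expect_identical(s1$labels, s2$labels)

  # law of large numbers: empirical transitions approach P
  P4 <- rotational_transition_matrix(4, rho = 0.8)
  diag(P4) <- 0
  s3 <- simulate_markov(P4, 1e5, seed = 3)
  Phat <- fit_markov(s3)$P
  expect_lt(max(abs(Phat - P4)), 0.02)
})

test_that("semi-Markov cohorts are reproducible and dwell models differ in tails", {
  cfg <- simulation_config(K = 4, n_subjects = 3, T = 3000, rho = 0.5,
                           seed = 10)
  c1 <- simulate_semi_markov(cfg)
  c2 <- simulate_semi_markov(cfg)
  for (i in 1:3) expect_identical(c1[[i]]$labels, c2[[i]]$labels)

  # geometric dwells reduce to a first-order chain: compare dwell histograms
  cfg_geo <- simulation_config(K = 4, n_subjects = 1, T = 40000, rho = 0,
                               dwell = list(model = "geometric", p = 0.25),
                               seed = 12)
  sg <- simulate_semi_markov(cfg_geo)[[1]]
  dg <- extract_visits(sg)$duration_samples
  # matched Markov chain: stay prob 0.75, uniform off-diagonal
  Pm <- matrix(0.25 / 3, 4, 4); diag(Pm) <- 0.75
  sm <- simulate_markov(Pm, 40000, seed = 13)
  dm <- extract_visits(sm)$duration_samples
  expect_gt(suppressWarnings(ks.test(dg, dm)$p.value), 0.01)

  cfg_ln <- simulation_config(K = 4, n_subjects = 1, T = 40000, rho = 0,
                              dwell = list(model = "lognormal",
                                           meanlog = log(4), sdlog = 1.2),
                              seed = 14)
  sl <- simulate_semi_markov(cfg_ln)[[1]]
  dl <- extract_visits(sl)$duration_samples
  kurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
  expect_gt(kurt(dl), kurt(dg))
})

test_that("Markov fit recovers the generator and flags empty rows", {
  s <- simulate_markov(matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3,
                              byrow = TRUE), 300, seed = 2)
  f <- fit_markov(s)
  expect_equal(f$P[cbind(1:3, c(2, 3, 1))], rep(1, 3))
  expect_equal(rowSums(f$P), rep(1, 3))

  s2 <- state_tc(c(1, 1, 2), 250, K = 3)
  expect_warning(f2 <- fit_markov(s2), "no outgoing")
  expect_true(all(is.na(f2$P[3, ])))
})

test_that("fitted chains simulate cohorts of the right shape", {
  cfg <- simulation_config(K = 4, n_subjects = 1, T = 5000, rho = 1,
                           seed = 20)
  s <- simulate_semi_markov(cfg)[[1]]
  f <- fit_markov(s)
  sim <- simulate(f, nsim = 2, seed = 4, T = 1000)
  expect_s3_class(sim, "state_cohort")
  expect_equal(length(sim[[1]]$labels), 1000)
})

test_that("mean recovered cycle strength is nondecreasing in rho", {
  rhos <- c(0, 0.5, 1.5)
  S <- vapply(seq_along(rhos), function(i) {
    cfg <- simulation_config(K = 5, n_subjects = 4, T = 5000, rho = rhos[i],
                             seed = 700 + i)
    coh <- simulate_semi_markov(cfg)
    mean_A <- Reduce(`+`, lapply(coh, function(s) {
      A <- compute_fo_asymmetry(s)$A
      A[is.na(A)] <- 0
      A
    })) / length(coh)
    cycle_strength(mean_A, circle_layout(1:5))
  }, numeric(1))
  expect_true(all(diff(S) > 0))
})

test_that("first-order refits of a long-dwell cyclical generator lose cycle strength", {
  # cyclicity carried by long dwells: gated semi-Markov generator
  cfg <- simulation_config(K = 5, n_subjects = 1, T = 40000, rho = 2,
                           dwell = list(model = "lognormal",
                                        meanlog = log(8), sdlog = 1),
                           dwell_gate = 12, seed = 90)
  s <- simulate_semi_markov(cfg)[[1]]
  lay <- circle_layout(1:5)
  S_semi <- cycle_strength(compute_fo_asymmetry(s)$A, lay)
  refit <- simulate(fit_markov(s), nsim = 1, seed = 91, T = 40000)[[1]]
  S_markov <- cycle_strength(compute_fo_asymmetry(refit)$A, lay)
  expect_lt(S_markov, S_semi)
  expect_gt(S_semi, 0.02)
})
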