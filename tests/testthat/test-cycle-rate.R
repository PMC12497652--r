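test_that("visit counts match a brute-force window scan", {
  # alternating labels: every sample is an onset, interior windows full
  s <- state_tc(rep(c(1, 2), 50), 250, K = 2)
  f <- visit_count_feature(s, w = 5)
  expect_true(all(f$counts[3:98] == 5))

  # constant labels: only windows containing sample 0 see the single onset
  s2 <- state_tc(rep(1, 20), 250)
  f2 <- visit_count_feature(s2, w = 5)
  expect_equal(f2$counts, c(rep(1L, 3), rep(0L, 17)))

  set.seed(19)
  for (rep in 1:4) {
    s3 <- random_stc(500, 3)
    w <- sample(c(3, 7, 15), 1)
    f3 <- visit_count_feature(s3, w = w)
    expect_equal(f3$counts, oracle_visit_counts(s3$labels, w))
  }
})

test_that("quadrant assignment makes contiguous equivariant arcs", {
  lay <- circle_layout(1:12)
  qa <- quadrant_assignment(lay)
  expect_equal(qa$membership, rep(1:4, each = 3))
  # centroid of 3 equally spaced members = middle member's phase
  expect_equal(qa$centroids[1], 2 * pi * 1 / 12, tolerance = 1e-12)

  lay8 <- circle_layout(1:8)
  qa8 <- quadrant_assignment(lay8)
  expect_equal(qa8$centroids[1], pi / 8, tolerance = 1e-12)  # midway

  # rotated layout rotates memberships identically
  rot <- circle_layout(c(4:12, 1:3))
  qar <- quadrant_assignment(rot)
  expect_equal(qar$membership[rot$ordering], rep(1:4, each = 3))
})

test_that("initialization probabilities are normalized and sharpen as tau -> 0", {
  lay <- circle_layout(1:12)
  qa <- quadrant_assignment(lay)
  s <- state_tc(sample.int(12, 200, replace = TRUE), 250, K = 12)
  for (tau in c(0.05, 0.5, 2)) {
    p <- initialize_state_probs(s, lay, tau = tau, quadrants = qa)
    expect_equal(rowSums(p), rep(1, 200), tolerance = 1e-12)
  }
  # a state at centroid 1 becomes one-hot in the cold limit
  s2 <- state_tc(rep(2, 10), 250, K = 12)  # state 2 sits at quadrant-1 centroid
  p2 <- initialize_state_probs(s2, lay, tau = 0.01, quadrants = qa)
  expect_gt(min(p2[, 1]), 0.999)
  # K = 4: single-state arcs put centroids at the state phases, so the
  # state at phase pi is equidistant (pi/2) from centroids 2 and 4
  lay4 <- circle_layout(1:4)
  qa4 <- quadrant_assignment(lay4)
  s3 <- state_tc(rep(3, 5), 250, K = 4)
  p3 <- initialize_state_probs(s3, lay4, tau = 0.5, quadrants = qa4)
  expect_equal(p3[1, 2], p3[1, 4], tolerance = 1e-9)
})

test_that("decoding follows one-hot priors and never violates the sequence", {
  set.seed(23)
  # legal 1->2->3->4 progression with dwell 30
  truth <- rep(rep(1:4, times = 5), each = 30)
  T <- length(truth)
  ip <- matrix(1e-12, T, 4)
  ip[cbind(seq_len(T), truth)] <- 1
  ip <- ip / rowSums(ip)
  counts <- rpois(T, lambda = truth)  # any counts; prior dominates
  f <- structure(list(counts = counts, w = 5, fs = 250),
                 class = "visit_count_feature")
  mm <- decode_metastates(f, ip, p_stay = 0.9)
  expect_equal(mm$path, truth)

  # structural constraint holds for arbitrary noisy priors
  ip2 <- matrix(runif(T * 4), T, 4)
  ip2 <- ip2 / rowSums(ip2)
  mm2 <- decode_metastates(f, ip2, p_stay = 0.7)
  steps <- (diff(mm2$path)) %% 4
  expect_true(all(steps %in% c(0, 1)))
})

test_that("decoding tolerates corrupted initialization", {
  set.seed(29)
  truth <- rep(rep(1:4, times = 10), each = 25)
  T <- length(truth)
  ip <- matrix(0.02, T, 4)
  ip[cbind(seq_len(T), truth)] <- 0.94
  corrupt <- sample.int(T, round(0.2 * T))
  for (t in corrupt) ip[t, ] <- { r <- runif(4); r / sum(r) }
  lam <- c(1, 3, 1, 3)[truth]
  counts <- rpois(T, lam)
  f <- structure(list(counts = counts, w = 5, fs = 250),
                 class = "visit_count_feature")
  mm <- decode_metastates(f, ip, p_stay = 0.95)
  expect_gt(mean(mm$path == truth), 0.9)
})

test_that("cycle durations and rate follow their definition exactly", {
  path <- rep(rep(1:4, times = 10), each = 25)
  cd <- cycle_durations(path, fs = 250)
  expect_equal(cd$mean_duration_ms, 400)
  expect_equal(cd$cycle_rate_hz, 2.5)
  expect_equal(cd$n_completed_cycles, 9)

  expect_warning(cd0 <- cycle_durations(rep(1L, 100), fs = 250), "no completed")
  expect_true(is.na(cd0$cycle_rate_hz))

  # rate is invariant to fs rescaling with durations fixed in ms
  path2 <- rep(rep(1:4, times = 6), each = 50)
  cd_a <- cycle_durations(path2, fs = 500)
  expect_equal(cd_a$mean_duration_ms, 400)
  expect_equal(cd_a$cycle_rate_hz, 2.5)
})

test_that("semi-Markov metastate paths recover 4x the mean dwell", {
  set.seed(37)
  mean_dwell <- 20
  dwells <- rgeom(400, 1 / mean_dwell) + 1
  path <- rep(rep(1:4, length.out = 400), times = dwells)
  cd <- cycle_durations(path, fs = 250)
  expected_ms <- 4 * mean(dwells) / 250 * 1000
  se <- sd(cd$durations_ms) / sqrt(cd$n_completed_cycles)
  expect_lt(abs(cd$mean_duration_ms - expected_ms), 2 * se + 1e-9)
})

test_that("cohort cycle rate runs end to end on a cyclical cohort", {
  cfg <- simulation_config(K = 8, n_subjects = 3, T = 6000, rho = 1.5,
                           seed = 41)
  coh <- simulate_semi_markov(cfg)
  fit <- tinda(coh, n_perm = 0)
  cr <- cohort_cycle_rate(coh, fit$layout)
  expect_equal(nrow(cr), 3)
  expect_true(all(cr$n_completed_cycles > 0))
  expect_true(all(cr$cycle_rate_hz > 0))
})
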