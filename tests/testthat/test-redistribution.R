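test_that("step kernel normalises and matches the hand-computed strip case", {
  L <- strip_landscape(3, cell_size = 10)
  p <- step_probabilities(L, c(log(10), 0, 0), c(1, 2))
  expct <- c(exp(-1), 1, exp(-1)) / (1 + 2 * exp(-1))
  expect_equal(as.vector(p), expct, tolerance = 1e-12)
  # normalisation holds on arbitrary mixed landscapes and parameters
  L2 <- mixed_landscape(6, 7)
  set.seed(2)
  for (i in 1:5) {
    p2 <- step_probabilities(L2, c(rnorm(1, log(20), 1), rnorm(2)),
                             c(sample(6, 1), sample(7, 1)))
    expect_lt(abs(sum(p2) - 1), 1e-12)
    expect_true(all(p2 >= 0))
  }
})

test_that("infinite step length flattens the kernel on uniform habitat", {
  L <- strip_landscape(5)
  p <- step_probabilities(L, c(log(1e9), 0, 0), c(1, 3))
  expect_lt(max(abs(p - 1 / 5)), 1e-6)
})

test_that("kernel is invariant to translating the landscape origin", {
  hab <- mixed_landscape(4, 4)$habitat
  L1 <- jsmm_landscape(hab, 10, origin = c(0, 0))
  L2 <- jsmm_landscape(hab, 10, origin = c(1250, -340))
  th <- c(log(15), 0.3, 0.8)
  expect_equal(step_probabilities(L1, th, c(2, 3)),
               step_probabilities(L2, th, c(2, 3)))
})

test_that("raising forest affinity moves mass onto forest cells", {
  L <- mixed_landscape(5, 5)
  forest <- as.vector(L$habitat == 2L)
  th <- c(log(20), 0.2, 0)
  m0 <- sum(step_probabilities(L, th, c(3, 3))[forest])
  th_up <- th + c(0, 0, 1)
  m1 <- sum(step_probabilities(L, th_up, c(3, 3))[forest])
  expect_gt(m1, m0)
})

test_that("track log-likelihood sums single-step log-probabilities", {
  L <- strip_landscape(3)
  th <- c(log(10), 0, 0)
  # one step
  p <- step_probabilities(L, th, c(1, 2))
  expect_equal(track_loglik(L, th, rbind(c(1, 2), c(1, 1))), log(p[1, 1]))
  # two steps computed from the chain of conditionals
  ll <- track_loglik(L, th, rbind(c(1, 2), c(1, 1), c(1, 2)))
  p_left <- step_probabilities(L, th, c(1, 1))
  expect_equal(ll, log(p[1, 1]) + log(p_left[1, 2]))
  # all 9 two-step paths from the centre form a probability distribution
  tot <- 0
  for (a in 1:3) for (b in 1:3) {
    tot <- tot + exp(track_loglik(L, th, rbind(c(1, 2), c(1, a), c(1, b))))
  }
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("species log-likelihood is invariant to track order", {
  L <- mixed_landscape(5, 5)
  set.seed(8)
  mk <- function(ord) {
    rows <- list()
    for (t in seq_along(ord)) {
      tr <- ord[t]
      rows[[t]] <- tibble::tibble(
        species = "spA", individual = paste0("i", tr), track = tr,
        step = 0:3, row = tr_rows[[tr]], col = tr_cols[[tr]])
    }
    dplyr::bind_rows(rows)
  }
  tr_rows <- replicate(3, sample(5, 4, replace = TRUE), simplify = FALSE)
  tr_cols <- replicate(3, sample(5, 4, replace = TRUE), simplify = FALSE)
  th <- c(log(12), 0.4, -0.2)
  l1 <- redistribution_likelihood(L, mk(1:3))$loglik("spA", th)
  l2 <- redistribution_likelihood(L, mk(c(3, 1, 2)))$loglik("spA", th)
  expect_equal(l1, l2, tolerance = 1e-12)
  # and it equals the sum of per-track log-likelihoods
  l_sum <- sum(vapply(1:3, function(t) {
    track_loglik(L, th, cbind(tr_rows[[t]], tr_cols[[t]]))
  }, numeric(1)))
  expect_equal(l1, l_sum, tolerance = 1e-10)
})

test_that("simulated step frequencies match the analytic kernel", {
  L <- strip_landscape(3)
  th <- c(log(10), 0, 0)
  set.seed(99)
  tk <- simulate_track(L, th, c(1, 2), 40000)
  from_center <- which(tk$col[-nrow(tk)] == 2)
  dest <- tk$col[from_center + 1]
  emp <- tabulate(dest, 3) / length(dest)
  p <- as.vector(step_probabilities(L, th, c(1, 2)))
  expect_lt(0.5 * sum(abs(emp - p)), 0.01)  # total variation
})

test_that("simulation is confined and reproducible", {
  L1 <- jsmm_landscape(matrix(0L, 1, 1), 10)
  set.seed(5)
  tk <- simulate_track(L1, c(log(10), 0, 0), c(1, 1), 10)
  expect_true(all(tk$row == 1 & tk$col == 1))
  L <- mixed_landscape(4, 4)
  set.seed(123)
  a <- simulate_track(L, c(log(10), 0.2, 0.5), c(2, 2), 20)
  set.seed(123)
  b <- simulate_track(L, c(log(10), 0.2, 0.5), c(2, 2), 20)
  expect_identical(a, b)
})

test_that("likelihood prefers the generating parameters over perturbations", {
  L <- mixed_landscape(8, 8)
  th_star <- c(log(15), 0.5, 1)
  set.seed(21)
  better <- 0
  for (r in 1:10) {
    rows <- list()
    for (t in 1:6) {
      tk <- simulate_track(L, th_star, c(sample(8, 1), sample(8, 1)), 5)
      rows[[t]] <- dplyr::mutate(tk, species = "spA",
                                 individual = paste0("i", t), track = t,
                                 .before = 1)
    }
    lik <- redistribution_likelihood(L, dplyr::bind_rows(rows))
    th_pert <- th_star + rnorm(3, 0, 0.7)
    if (lik$loglik("spA", th_star) > lik$loglik("spA", th_pert)) {
      better <- better + 1
    }
  }
  expect_gte(better, 7)
})

test_that("out-of-bounds cells are rejected", {
  L <- strip_landscape(3)
  expect_error(step_probabilities(L, c(log(10), 0, 0), c(2, 1)), "outside")
  expect_error(track_loglik(L, c(log(10), 0, 0), rbind(c(1, 1), c(1, 4))),
               "outside")
})
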