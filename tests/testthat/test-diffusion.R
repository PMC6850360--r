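test_that("generator rates implement harmonic habitat weighting", {
  # homogeneous: all neighbour rates D / h^2, uniform stationary density
  L <- jsmm_landscape(matrix(2L, 3, 3), cell_size = 20)
  g <- build_generator(L, D = 400, k = 2, m = 0)
  expect_equal(unique(g$edge_rate), 400 / 400)
  pi_u <- rep(1 / 9, 9)
  expect_lt(max(abs(as.numeric(pi_u %*% g$Q))), 1e-12)
  # two-habitat 1x2: stationary probabilities in ratio k : 1 (open : forest)
  L2 <- jsmm_landscape(matrix(c(0L, 2L), 1, 2), cell_size = 25)
  g2 <- build_generator(L2, D = 120, k = 3, m = 0)
  ns <- eigen(t(as.matrix(g2$Q)))
  v <- Re(ns$vectors[, which.min(abs(ns$values))])
  expect_equal(v[1] / v[2], 3, tolerance = 1e-10)
  expect_error(build_generator(L2, D = -1, k = 1, m = 0), "D must be")
})

test_that("stationary open:forest ratio equals k on a mixed landscape", {
  hab <- matrix(0L, 4, 4); hab[, 3:4] <- 2L
  L <- jsmm_landscape(hab, cell_size = 25)
  for (k in c(0.5, 2, 4)) {
    g <- build_generator(L, D = 300, k = k, m = 0)
    v <- rep(1 / 16, 16)
    for (i in 1:400) v <- propagate(v, g, 1)
    ratio <- mean(v[as.vector(hab == 0L)]) / mean(v[as.vector(hab == 2L)])
    expect_equal(ratio, k, tolerance = 0.01)
  }
})

test_that("propagation matches the matrix-exponential oracle", {
  skip_if_not_installed("expm")
  L <- mixed_landscape(4, 4, cell_size = 25)
  g <- build_generator(L, D = 500, k = 2.5, m = 0.1)
  v0 <- numeric(16); v0[6] <- 1
  for (dur in c(0.3, 1, 2.5)) {
    v <- propagate(v0, g, dur)
    v_oracle <- as.numeric(v0 %*% expm::expm(as.matrix(g$Q) * dur))
    expect_equal(v, v_oracle, tolerance = 1e-10)
  }
  # duration zero is the exact identity
  expect_identical(propagate(v0, g, 0), v0)
})

test_that("mass is conserved without mortality and decays at rate m with it", {
  L <- mixed_landscape(5, 5, cell_size = 25)
  g0 <- build_generator(L, D = 200, k = 1.5, m = 0)
  v <- numeric(25); v[13] <- 1
  expect_lt(abs(sum(propagate(v, g0, 3)) - 1), 1e-8)
  gm <- build_generator(L, D = 200, k = 1.5, m = 0.3)
  expect_lt(abs(sum(propagate(v, gm, 2)) - exp(-0.6)), 1e-8)
})

test_that("short-time spread reproduces the diffusion law", {
  # large homogeneous grid: per-axis variance 2 D t, MSD 4 D t
  L <- jsmm_landscape(matrix(0L, 41, 41), cell_size = 10)
  D <- 150; t <- 1
  g <- build_generator(L, D, k = 1, m = 0)
  v0 <- numeric(41 * 41); v0[cell_index(L, 21, 21)] <- 1
  v <- propagate(v0, g, t)
  cc <- cell_centers(L)
  msd <- sum(v * ((cc$x - cc$x[cell_index(L, 21, 21)])^2 +
                    (cc$y - cc$y[cell_index(L, 21, 21)])^2))
  expect_gt(msd / (4 * D * t), 0.95)
  expect_lt(msd / (4 * D * t), 1.05)
})

test_that("night capture removes exactly the advertised mass", {
  L <- jsmm_landscape(matrix(0L, 5, 5), cell_size = 25)
  traps <- jsmm_traps(data.frame(trap = "t1", x = 50, y = 50),
                      matrix(1L, 1, 1), radius = 30)
  zones <- jsmm:::trap_zones(L, traps, active = 1)
  v <- rep(1 / 25, 25)
  # q = 0 leaves the density untouched
  r0 <- apply_night_capture(v, zones, 0)
  expect_identical(r0$density, v)
  expect_equal(r0$capture, 0)
  # uniform density: capture probability = q * zone fraction (counting oracle)
  n_zone <- length(zones[[1]])
  r <- apply_night_capture(v, zones, 0.4)
  expect_equal(r$capture[1], 0.4 * n_zone / 25, tolerance = 1e-12)
  expect_equal(sum(v) - sum(r$density), r$capture[1], tolerance = 1e-12)
  # all mass in the zone with q = 1: certain capture, density zeroed
  v1 <- numeric(25); v1[zones[[1]][1]] <- 1
  r1 <- apply_night_capture(v1, zones, 1)
  expect_equal(r1$capture[1], 1)
  expect_equal(sum(r1$density), 0)
})

test_that("overlapping trap zones partition by nearest trap", {
  L <- jsmm_landscape(matrix(0L, 1, 7), cell_size = 10)
  traps <- jsmm_traps(data.frame(trap = c("a", "b"), x = c(20, 40), y = c(0, 0)),
                      matrix(1L, 1, 2), radius = 25)
  zones <- jsmm:::trap_zones(L, traps, active = c(1, 1))
  expect_length(intersect(zones[[1]], zones[[2]]), 0)
  # midpoint cell (x = 30) ties: goes to the lower trap index
  mid <- cell_index(L, 1, 4)
  expect_true(mid %in% zones[[1]])
})

test_that("capture-history likelihoods obey the law of total probability", {
  L <- jsmm_landscape(matrix(c(0L, 0L, 0L, 0L, 2L, 0L, 0L, 0L, 2L), 3, 3),
                      cell_size = 25)
  traps <- jsmm_traps(data.frame(trap = "t1", x = 25, y = 25),
                      matrix(1L, 2, 1), radius = 30)
  th <- c(log(300), log(2), log(0.15), stats::qlogis(0.4))
  hist_ll <- function(rec) individual_loglik(L, traps, th, 0, c(2, 2), rec)
  tot <- exp(hist_ll(NULL)) +
    exp(hist_ll(data.frame(night = 1, trap = 1))) +
    exp(hist_ll(data.frame(night = 2, trap = 1))) +
    exp(hist_ll(data.frame(night = c(1, 2), trap = c(1, 1))))
  expect_lt(abs(tot - 1), 1e-8)
})

test_that("degenerate capture histories have closed forms", {
  L1 <- jsmm_landscape(matrix(c(0L, 0L), 1, 2), cell_size = 25)
  traps <- jsmm_traps(data.frame(trap = "t1", x = 0, y = 0),
                      matrix(1L, 1, 1), radius = 30)
  # no remaining nights: probability one
  expect_equal(individual_loglik(L1, traps, c(log(10), 0, log(0.1),
                                              stats::qlogis(0.3)), 1, c(1, 1)),
               0)
  # frozen individual on the trap cell: recapture probability is exactly q
  th0 <- c(log(1e-9), 0, log(1e-12), stats::qlogis(0.37))
  expect_equal(individual_loglik(L1, traps, th0, 0, c(1, 1),
                                 data.frame(night = 1, trap = 1)),
               log(0.37), tolerance = 1e-9)
  # recapture at an inactive trap is a data error
  traps2 <- jsmm_traps(data.frame(trap = "t1", x = 0, y = 0),
                       matrix(c(0L, 1L), 2, 1), radius = 30)
  expect_error(individual_loglik(L1, traps2, th0, 0, c(1, 1),
                                 data.frame(night = 1, trap = 1)),
               "inactive")
})

test_that("species likelihood is invariant to individual order", {
  L <- jsmm_landscape(matrix(0L, 4, 4), cell_size = 25)
  traps <- jsmm_traps(data.frame(trap = c("t1", "t2"), x = c(25, 50),
                                 y = c(25, 50)),
                      matrix(1L, 4, 2), radius = 30)
  caps <- tibble::tibble(
    individual = c("i1", "i1", "i2", "i3", "i3"),
    species = "spA",
    night = c(0, 2, 1, 0, 3),
    trap = c("t1", "t2", "t2", "t2", "t1"),
    event = c("mark", "recapture", "mark", "mark", "recapture"))
  th <- c(log(400), log(1.5), log(0.1), stats::qlogis(0.3))
  l1 <- diffusion_likelihood(L, traps, caps)$loglik("spA", th)
  l2 <- diffusion_likelihood(L, traps, caps[c(4, 5, 3, 1, 2), ])$loglik("spA", th)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("jump-process simulator agrees with the density solver", {
  L <- jsmm_landscape(matrix(c(0L, 0L, 2L, 2L), 2, 2), cell_size = 25)
  traps <- jsmm_traps(data.frame(trap = "t1", x = 0, y = 0),
                      matrix(1L, 3, 1), radius = 30)
  pars <- c(D = 250, k = 2, m = 0.15, q = 0.5)
  th <- c(log(pars[1]), log(pars[2]), log(pars[3]), stats::qlogis(pars[4]))
  # solver-predicted probability of at least one recapture
  p_never <- exp(individual_loglik(L, traps, th, 0, c(1, 1)))
  p_rec <- 1 - p_never
  set.seed(31)
  n <- 4000
  rel <- tibble::tibble(individual = sprintf("i%04d", 1:n), species = "spA",
                        night = 0L, trap = "t1")
  caps <- simulate_cmr(L, traps, as.list(pars), rel)
  got <- length(unique(caps$individual[caps$event == "recapture"])) / n
  se <- sqrt(p_rec * (1 - p_rec) / n)
  expect_lt(abs(got - p_rec), 3 * se + 0.002)
  # instant mortality: essentially no recaptures
  set.seed(32)
  caps_dead <- simulate_cmr(L, traps, list(250, 2, 50, 0.5), rel[1:300, ])
  expect_lte(sum(caps_dead$event == "recapture"), 1)
  # seeded reproducibility
  set.seed(77); a <- simulate_cmr(L, traps, as.list(pars), rel[1:50, ])
  set.seed(77); b <- simulate_cmr(L, traps, as.list(pars), rel[1:50, ])
  expect_identical(a, b)
})
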