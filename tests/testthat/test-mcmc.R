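# helpers to drive individual updates with everything else held fixed
build_toy_model <- function(lik, traits, C, prior = jsmm_prior(lik$n_p)) {
  jsmm:::make_model(lik, traits, C, prior)
}

fixed_state <- function(model, Theta, Z, Sigma = diag(model$n_p), rho = 0) {
  list(Theta = Theta, Z = Z, Sigma = Sigma, rho = rho,
       rho_idx = which.min(abs(model$prior$rho_grid - rho)),
       Winv = jsmm:::winv_from_eigen(model$eC, rho),
       loglik = vapply(seq_len(model$n_s), function(s)
         jsmm:::eval_loglik(model$lik, model$species[s], Theta[s, ]),
         numeric(1)),
       prop = list(log_scale = rep(log(0.5), model$n_s), n = 0,
                   mean = Theta, M2 = matrix(1e-4, model$n_s, model$n_p)),
       accept = rep(0, model$n_s), accept_n = 0)
}

test_that("identical seeds give bit-identical fits", {
  com <- toy_community(5, 2, rho = 0.5, seed = 4)
  lik <- flat_likelihood(com$traits$species)
  ctl <- jsmm_control(n_chains = 2, n_iter = 250, burn_in = 50, seed = 42)
  f1 <- fit_jsmm(lik, com$traits, com$C, ctl)
  f2 <- fit_jsmm(lik, com$traits, com$C, ctl)
  expect_identical(f1$draws, f2$draws)
  # a different seed gives different draws
  f3 <- fit_jsmm(lik, com$traits, com$C, jsmm_control(
    n_chains = 2, n_iter = 250, burn_in = 50, seed = 43))
  expect_false(identical(f1$draws$Theta, f3$draws$Theta))
})

test_that("Metropolis step recovers the conjugate normal-normal posterior", {
  # one species, one parameter, iid N(theta, 1) data; community layer fixed:
  # prior N(m0, s0^2) via intercept-only Z and fixed Sigma
  set.seed(6)
  y <- rnorm(12, 1.4, 1)
  ys <- list(spA = y)
  lik <- normal_toy_likelihood(ys, sd = 1)
  tr <- trait_design(data.frame(species = "spA"))
  m0 <- 0.5; s0 <- 1.5
  model <- build_toy_model(lik, tr, matrix(1, 1, 1, dimnames = list("spA", "spA")))
  st <- fixed_state(model, Theta = matrix(m0, 1, 1),
                    Z = matrix(m0, 1, 1), Sigma = matrix(s0^2))
  draws <- numeric(6000)
  set.seed(8)
  for (i in seq_len(1000)) {   # warm adaptation
    st <- jsmm:::update_theta_mh(st, model, adapt = TRUE)
  }
  for (i in seq_along(draws)) {
    st <- jsmm:::update_theta_mh(st, model)
    draws[i] <- st$Theta[1, 1]
  }
  post_var <- 1 / (1 / s0^2 + length(y) / 1)
  post_mean <- post_var * (m0 / s0^2 + sum(y) / 1)
  ess <- coda::effectiveSize(coda::mcmc(draws))
  mc_se <- sd(draws) / sqrt(ess)
  expect_lt(abs(mean(draws) - post_mean), 3 * mc_se + 0.01)
  expect_equal(var(draws), post_var, tolerance = 0.15)
})

test_that("vanishing proposal scale drives acceptance to one", {
  com <- toy_community(4, 2, rho = 0, seed = 2)
  lik <- flat_likelihood(com$traits$species)
  model <- build_toy_model(lik, com$traits, com$C)
  st <- fixed_state(model, matrix(0, 4, 2), matrix(0, 2, 2))
  st$prop$log_scale[] <- log(1e-9)
  set.seed(3)
  for (i in 1:50) st <- jsmm:::update_theta_mh(st, model)
  expect_equal(mean(st$accept / st$accept_n), 1, tolerance = 0.01)
})

test_that("NaN likelihoods raise an error instead of silently rejecting", {
  tr <- trait_design(data.frame(species = "spA"))
  lik <- new_jsmm_likelihood("bad", "spA", "p1", "identity",
                             function(sp, th) NaN)
  expect_error(
    fit_jsmm(lik, tr, matrix(1, 1, 1, dimnames = list("spA", "spA")),
             jsmm_control(n_chains = 1, n_iter = 20, burn_in = 5)),
    "NaN")
})

test_that("loadings conditional has the right mean in closed-form regimes", {
  set.seed(14)
  # scalar case: intercept-only, rho = 0, n_p = 1, Sigma = 1:
  # E[Z | Theta] = sum(Theta) / (n_s + 1 / zeta_var)
  n_s <- 6
  tr <- trait_design(data.frame(species = sprintf("s%d", 1:n_s)))
  lik <- flat_likelihood(tr$species, n_p = 1)
  model <- build_toy_model(lik, tr, diag(n_s))
  Theta <- matrix(rnorm(n_s, 2, 1), n_s, 1)
  st <- fixed_state(model, Theta, Z = matrix(0, 1, 1), Sigma = matrix(1))
  zs <- replicate(4000, {
    st2 <- jsmm:::update_z_gibbs(st, model)
    st2$Z[1, 1]
  })
  expected <- sum(Theta) / (n_s + 1 / model$prior$zeta_var)
  expect_lt(abs(mean(zs) - expected), 4 * sd(zs) / sqrt(4000))

  # flat-prior limit: conditional mean approaches the OLS solution
  set.seed(15)
  tr2 <- trait_design(data.frame(species = sprintf("s%d", 1:30),
                                 x = rnorm(30)))
  lik2 <- flat_likelihood(tr2$species, n_p = 2)
  prior2 <- jsmm_prior(2, zeta_var = 1e6)
  model2 <- build_toy_model(lik2, tr2, diag(30), prior2)
  Theta2 <- cbind(1 + 0.5 * tr2$T[, 2] + rnorm(30, 0, 0.3),
                  -1 + rnorm(30, 0, 0.3))
  st2 <- fixed_state(model2, Theta2, Z = matrix(0, 2, 2))
  zdraws <- replicate(2000, as.vector(jsmm:::update_z_gibbs(st2, model2)$Z))
  ols <- qr.solve(tr2$T, Theta2)
  expect_equal(rowMeans(zdraws), as.vector(ols), tolerance = 0.02)
})

test_that("covariance conditional concentrates on the generating matrix", {
  set.seed(16)
  n_s <- 400
  Sigma_star <- matrix(c(0.5, 0.2, 0.2, 0.4), 2, 2)
  tr <- trait_design(data.frame(species = sprintf("s%03d", 1:n_s)))
  lik <- flat_likelihood(tr$species, n_p = 2)
  model <- build_toy_model(lik, tr, diag(n_s))
  skip_if_not_installed("mvtnorm")
  R <- mvtnorm::rmvnorm(n_s, sigma = Sigma_star)
  st <- fixed_state(model, R, Z = matrix(0, 1, 2))
  sig_draws <- replicate(600, jsmm:::update_sigma_gibbs(st, model)$Sigma)
  post_mean <- apply(sig_draws, c(1, 2), mean)
  expect_lt(norm(post_mean - Sigma_star, "F") / norm(Sigma_star, "F"), 0.1)
})

test_that("rho conditional is flat for an identity phylogeny", {
  set.seed(17)
  n_s <- 10
  tr <- trait_design(data.frame(species = sprintf("s%d", 1:n_s)))
  lik <- flat_likelihood(tr$species, n_p = 1)
  model <- build_toy_model(lik, tr, diag(n_s))
  Theta <- matrix(rnorm(n_s), n_s, 1)
  st <- fixed_state(model, Theta, Z = matrix(0, 1, 1))
  rhos <- replicate(3000, jsmm:::update_rho_grid(st, model)$rho)
  # uniform over the grid: mean 1/2, sd sqrt(1/12)
  expect_equal(mean(rhos), 0.5, tolerance = 0.03)
  expect_equal(sd(rhos), sqrt(1 / 12), tolerance = 0.05)
})

test_that("rho conditional recovers strong phylogenetic signal", {
  set.seed(18)
  n_s <- 30
  tr <- trait_design(data.frame(species = sprintf("s%02d", 1:n_s)))
  C <- phylo_correlation(ape::rcoal(n_s, tip.label = tr$species))
  C <- C[tr$species, tr$species]
  lik <- flat_likelihood(tr$species, n_p = 1)
  model <- build_toy_model(lik, tr, C)
  cm <- jsmm_community(matrix(0, 1, 1), matrix(1), 1)
  st <- fixed_state(model, sample_theta_prior(tr, cm, C),
                    Z = matrix(0, 1, 1), rho = 1)
  rhos <- replicate(1500, jsmm:::update_rho_grid(st, model)$rho)
  expect_gt(mean(rhos), 0.8)
})

test_that("two-point grid prefers rho = 0 for independent species", {
  set.seed(19)
  n_s <- 25
  tr <- trait_design(data.frame(species = sprintf("s%02d", 1:n_s)))
  C <- phylo_correlation(ape::rcoal(n_s, tip.label = tr$species))
  C <- C[tr$species, tr$species]
  lik <- flat_likelihood(tr$species, n_p = 1)
  prior <- jsmm_prior(1, rho_grid_size = 2)   # grid {0, 1}
  model <- build_toy_model(lik, tr, C, prior)
  wins <- 0
  for (r in 1:20) {
    Theta <- matrix(rnorm(n_s), n_s, 1)       # rho* = 0 draws
    st <- fixed_state(model, Theta, Z = matrix(0, 1, 1))
    rhos <- replicate(40, jsmm:::update_rho_grid(st, model)$rho)
    if (mean(rhos == 0) > 0.5) wins <- wins + 1
  }
  expect_gt(wins / 20, 0.5)
})

test_that("flat likelihood returns the community prior", {
  com <- toy_community(5, 1, rho = 0.5, seed = 23)
  lik <- flat_likelihood(com$traits$species, n_p = 1)
  fit <- fit_jsmm(lik, com$traits, com$C,
                  jsmm_control(n_chains = 2, n_iter = 4000, burn_in = 1000,
                               seed = 10))
  zd <- posterior_draws(fit, "loadings")
  # loadings marginal reverts to N(0, sqrt(10)); rho to uniform
  expect_equal(sd(zd$value), sqrt(10), tolerance = 0.2)
  expect_equal(mean(fit$draws$rho), 0.5, tolerance = 0.06)
})

test_that("joint fit with a fixed community matches a single-species sampler", {
  # rho = 0 and a diagonal Sigma make the row conditional an independent
  # normal prior, exactly what the single-species sampler uses
  set.seed(25)
  L <- mixed_landscape(6, 6)
  th_star <- c(log(15), 0.3, 0.6)
  rows <- list()
  for (t in 1:4) {
    tk <- simulate_track(L, th_star, c(sample(6, 1), sample(6, 1)), 4)
    rows[[t]] <- dplyr::mutate(tk, species = "spA",
                               individual = paste0("i", t), track = t,
                               .before = 1)
  }
  lik <- redistribution_likelihood(L, dplyr::bind_rows(rows))
  tr <- trait_design(data.frame(species = "spA"))
  model <- build_toy_model(lik, tr, matrix(1, 1, 1,
                                           dimnames = list("spA", "spA")))
  prior_mean <- c(log(20), 0, 0); prior_sd <- rep(1.5, 3)
  st <- fixed_state(model, Theta = matrix(prior_mean, 1, 3),
                    Z = matrix(prior_mean, 1, 3),
                    Sigma = diag(prior_sd^2))
  set.seed(26)
  for (i in 1:800) st <- jsmm:::update_theta_mh(st, model, adapt = TRUE)
  joint_draws <- matrix(NA_real_, 4000, 3)
  for (i in 1:4000) {
    st <- jsmm:::update_theta_mh(st, model)
    joint_draws[i, ] <- st$Theta[1, ]
  }
  single <- fit_single_species(lik, "spA", prior_mean = prior_mean,
                               prior_sd = prior_sd, n_iter = 6000,
                               burn_in = 1500, seed = 27)
  for (p in 1:3) {
    ess_j <- coda::effectiveSize(coda::mcmc(joint_draws[, p]))
    ess_s <- coda::effectiveSize(coda::mcmc(single$draws[, p]))
    se <- sqrt(sd(joint_draws[, p])^2 / ess_j + sd(single$draws[, p])^2 / ess_s)
    expect_lt(abs(mean(joint_draws[, p]) - mean(single$draws[, p])),
              4 * se + 0.02)
  }
})
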