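# Successive-conditional simulator (Geweke-style software validation):
# alternating exact prior redraws of Theta with one Gibbs update must leave
# the joint prior invariant, so the update's marginal draws must match
# direct prior draws in distribution.

geweke_setup <- function(n_s = 10, n_p = 2, seed = 1, zeta_var = 1) {
  # a moderate loading prior keeps the successive chain well mixed so the
  # rank tests see close-to-independent draws; the update code is identical
  set.seed(seed)
  tbl <- data.frame(species = sprintf("s%02d", seq_len(n_s)), x = rnorm(n_s))
  tr <- trait_design(tbl)
  C <- phylo_correlation(ape::rcoal(n_s, tip.label = tr$species))
  C <- C[tr$species, tr$species]
  lik <- flat_likelihood(tr$species, n_p = n_p)
  prior <- jsmm_prior(n_p, zeta_var = zeta_var)
  model <- jsmm:::make_model(lik, tr, C, prior)
  list(model = model, traits = tr, C = C, prior = prior,
       n_s = n_s, n_p = n_p, n_t = ncol(tr$T))
}

# one draw of each community parameter from its prior
geweke_prior_draw <- function(gs) {
  prior <- gs$prior
  Z <- matrix(rnorm(gs$n_t * gs$n_p, 0, sqrt(prior$zeta_var)), gs$n_t, gs$n_p)
  X <- rWishart(1, prior$sigma_df, solve(prior$sigma_scale))[, , 1]
  Sigma <- chol2inv(chol(X))
  rho <- sample(prior$rho_grid, 1)
  list(Z = Z, Sigma = (Sigma + t(Sigma)) / 2, rho = rho)
}

# run the successive-conditional chain updating only `what`; returns thinned
# draws of a scalar functional of the updated block
geweke_chain <- function(gs, what = c("Z", "Sigma", "rho"), n_iter = 3000,
                         thin = 10, seed = 2) {
  what <- match.arg(what)
  set.seed(seed)
  init <- geweke_prior_draw(gs)
  st <- list(Z = init$Z, Sigma = init$Sigma, rho = init$rho,
             rho_idx = which.min(abs(gs$prior$rho_grid - init$rho)),
             Winv = jsmm:::winv_from_eigen(gs$model$eC, init$rho))
  out <- numeric(n_iter %/% thin)
  kept <- 0
  for (it in seq_len(n_iter)) {
    cm <- jsmm_community(st$Z, st$Sigma, st$rho)
    st$Theta <- sample_theta_prior(gs$traits, cm, gs$C)
    st <- switch(what,
      Z = jsmm:::update_z_gibbs(st, gs$model),
      Sigma = jsmm:::update_sigma_gibbs(st, gs$model),
      rho = jsmm:::update_rho_grid(st, gs$model))
    if (it %% thin == 0) {
      kept <- kept + 1
      out[kept] <- switch(what,
        Z = st$Z[1, 1],
        Sigma = log(st$Sigma[1, 1]),
        rho = st$rho)
    }
  }
  out
}

# matched direct prior draws of the same functional
geweke_direct <- function(gs, what, n = 2000, seed = 3) {
  set.seed(seed)
  switch(what,
    Z = rnorm(n, 0, sqrt(gs$prior$zeta_var)),
    Sigma = vapply(seq_len(n), function(i) {
      log(geweke_prior_draw(gs)$Sigma[1, 1])
    }, numeric(1)),
    rho = sample(gs$prior$rho_grid, n, replace = TRUE))
}
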