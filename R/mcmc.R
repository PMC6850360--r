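#' Prior specification for the community layer
#'
#' Weakly-informative defaults, conjugate where the Gibbs steps need it:
#' independent normals on the trait loadings, an inverse-Wishart on the
#' residual covariance, and a uniform prior on the phylogenetic weight
#' discretised to an equispaced grid on \[0, 1\].
#'
#' @param n_p Number of movement parameters (needed for the inverse-Wishart
#'   defaults).
#' @param zeta_var Prior variance of each loading, `zeta ~ N(0, zeta_var)`.
#'   Default 10.
#' @param sigma_df Inverse-Wishart degrees of freedom. Default `n_p + 2`
#'   (prior mean of Sigma is then `sigma_scale`).
#' @param sigma_scale Inverse-Wishart scale matrix. Default identity.
#' @param rho_grid_size Number of grid points for rho. Default 101.
#' @return An object of class `jsmm_prior`.
#' @export
jsmm_prior <- function(n_p, zeta_var = 10, sigma_df = n_p + 2,
                       sigma_scale = diag(n_p), rho_grid_size = 101) {
  assert_that(sigma_df > n_p + 1, "sigma_df must exceed n_p + 1")
  assert_that(rho_grid_size >= 2, "rho grid needs at least 2 points")
  structure(list(n_p = n_p, zeta_var = zeta_var, sigma_df = sigma_df,
                 sigma_scale = as.matrix(sigma_scale),
                 rho_grid = seq(0, 1, length.out = rho_grid_size)),
            class = "jsmm_prior")
}

#' Sampler configuration
#'
#' @param n_chains Number of independent chains. Default 2.
#' @param n_iter Iterations per chain (including burn-in). Default 4000.
#' @param burn_in Iterations discarded (and used for proposal adaptation).
#'   Default `n_iter %/% 4`.
#' @param thin Thinning interval. Default 1.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`. Default 1.
#' @param target_accept Target Metropolis acceptance rate for the adaptive
#'   per-species proposals. Default 0.25.
#' @param init_scale Initial random-walk proposal standard deviation.
#'   Default 0.3.
#' @return An object of class `jsmm_control`.
#' @export
jsmm_control <- function(n_chains = 2, n_iter = 4000, burn_in = n_iter %/% 4,
                         thin = 1, seed = 1, target_accept = 0.25,
                         init_scale = 0.3) {
  assert_that(burn_in < n_iter, "burn_in must be smaller than n_iter")
  assert_that(thin >= 1, "thin must be >= 1")
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = seed, target_accept = target_accept,
                 init_scale = init_scale),
            class = "jsmm_control")
}

# bundle of fixed quantities every update needs
make_model <- function(likelihood, traits, C, prior) {
  validate_traits(traits)
  sp <- traits$species
  if (!is.null(rownames(C))) {
    assert_that(setequal(rownames(C), sp), "C species disagree with trait table")
    C <- C[sp, sp, drop = FALSE]
  } else {
    assert_that(nrow(C) == length(sp), "C dimension disagrees with trait table")
  }
  validate_correlation(C)
  unknown <- setdiff(likelihood$species, sp)
  assert_that(length(unknown) == 0,
              paste("species in data but not in traits:",
                    paste(unknown, collapse = ", ")))
  eC <- sym_eigen(C, floor = 1e-12)
  list(lik = likelihood, traits = traits, Tm = traits$T, C = C, eC = eC,
       prior = prior, n_s = length(sp), n_p = likelihood$n_p,
       n_t = ncol(traits$T), species = sp)
}

winv_from_eigen <- function(eC, rho) {
  w <- rho * eC$values + (1 - rho)
  eC$vectors %*% (t(eC$vectors) / w)
}

# initial state: per-species ML (with a mild ridge so flat likelihoods stay
# bounded), loadings by least squares, Sigma identity, rho at mid-grid
init_state <- function(model, control) {
  n_s <- model$n_s; n_p <- model$n_p
  Theta <- matrix(0, n_s, n_p, dimnames = list(model$species, model$lik$param_names))
  for (s in seq_len(n_s)) {
    sp <- model$species[s]
    obj <- function(th) -eval_loglik(model$lik, sp, th) + 0.005 * sum(th^2)
    par <- tryCatch({
      if (n_p == 1) {
        stats::optimize(function(t) obj(t), c(-20, 20))$minimum
      } else {
        optim(rep(0, n_p), obj, method = "Nelder-Mead",
              control = list(maxit = 300))$par
      }
    }, error = function(e) NULL)
    if (!is.null(par) && all(is.finite(par))) Theta[s, ] <- par
  }
  Z <- qr.solve(crossprod(model$Tm) + 1e-8 * diag(model$n_t),
                crossprod(model$Tm, Theta))
  rho_idx <- which.min(abs(model$prior$rho_grid - 0.5))
  rho <- model$prior$rho_grid[rho_idx]
  state <- list(
    Theta = Theta, Z = Z, Sigma = diag(n_p), rho = rho, rho_idx = rho_idx,
    Winv = winv_from_eigen(model$eC, rho),
    loglik = vapply(seq_len(n_s), function(s)
      eval_loglik(model$lik, model$species[s], Theta[s, ]), numeric(1)),
    prop = list(log_scale = rep(log(control$init_scale), n_s),
                n = 0, mean = Theta, M2 = matrix(1e-4, n_s, n_p)),
    accept = rep(0, n_s), accept_n = 0)
  if (any(!is.finite(state$loglik))) {
    stop_jsmm("non-finite log-likelihood at initialization")
  }
  state
}

#' Metropolis update of the species-specific parameters
#'
#' One sweep over species: each row of `Theta` receives a multivariate
#' normal random-walk proposal, accepted with the Metropolis probability
#' combining the species log-likelihood and the conditional of the
#' hierarchical prior for that row given all other rows. Proposal scales
#' (and, once enough history exists, diagonal covariances) are adapted
#' towards the target acceptance rate during burn-in only.
#'
#' @param state Sampler state (internal structure).
#' @param model Model bundle (internal structure).
#' @param adapt Logical: adapt the proposal (burn-in only).
#' @param target_accept Target acceptance rate.
#' @return Updated state.
#' @keywords internal
update_theta_mh <- function(state, model, adapt = FALSE, target_accept = 0.25) {
  n_s <- model$n_s; n_p <- model$n_p
  M <- model$Tm %*% state$Z
  cholS <- chol(state$Sigma)
  Sinv <- chol2inv(cholS)
  resid <- state$Theta - M
  Winv <- state$Winv
  ldetS <- sum(log(diag(cholS)))
  prop_sd <- sqrt(state$prop$M2 / max(state$prop$n - 1, 1))
  use_emp <- state$prop$n > 100
  for (s in seq_len(n_s)) {
    c_ss <- Winv[s, s]
    mu <- M[s, ] - as.numeric(Winv[s, -s, drop = FALSE] %*%
                                resid[-s, , drop = FALSE]) / c_ss
    sdv <- if (use_emp) pmax(prop_sd[s, ], 1e-3) else rep(1, n_p)
    th0 <- state$Theta[s, ]
    th1 <- th0 + exp(state$prop$log_scale[s]) * sdv * rnorm(n_p)
    ll1 <- eval_loglik(model$lik, model$species[s], th1)
    # conditional prior: N(mu, Sigma / c_ss)
    q0 <- backsolve(cholS, th0 - mu, transpose = TRUE)
    q1 <- backsolve(cholS, th1 - mu, transpose = TRUE)
    lp_diff <- -0.5 * c_ss * (sum(q1^2) - sum(q0^2))
    log_r <- (ll1 - state$loglik[s]) + lp_diff
    acc_p <- min(1, exp(log_r))
    if (is.finite(log_r) && log(runif(1)) < log_r) {
      state$Theta[s, ] <- th1
      state$loglik[s] <- ll1
      resid[s, ] <- th1 - M[s, ]
      state$accept[s] <- state$accept[s] + 1
    }
    if (adapt) {
      g <- (state$prop$n + 1)^-0.6
      state$prop$log_scale[s] <- state$prop$log_scale[s] +
        g * (acc_p - target_accept)
    }
  }
  state$accept_n <- state$accept_n + 1
  if (adapt) {
    # running moments for the diagonal proposal covariance
    n1 <- state$prop$n + 1
    d <- state$Theta - state$prop$mean
    state$prop$mean <- state$prop$mean + d / n1
    state$prop$M2 <- state$prop$M2 + d * (state$Theta - state$prop$mean)
    state$prop$n <- n1
  }
  state
}

#' Gibbs update of the trait loadings
#'
#' Exact draw of `vec(Z)` from its multivariate normal full conditional: the
#' Bayesian generalised-least-squares regression of `Theta` on the trait
#' design with error covariance `Sigma (x) W` and prior
#' `zeta ~ N(0, zeta_var)` elementwise.
#'
#' @inheritParams update_theta_mh
#' @return Updated state.
#' @keywords internal
update_z_gibbs <- function(state, model) {
  Tm <- model$Tm
  A <- crossprod(Tm, state$Winv %*% Tm)
  if (rcond(A) < 1e-12) {
    stop_jsmm("singular trait design: collinear columns in the trait matrix")
  }
  Sinv <- chol2inv(chol(state$Sigma))
  P <- kronecker(Sinv, A) + diag(model$n_t * model$n_p) / model$prior$zeta_var
  b <- as.vector(crossprod(Tm, state$Winv %*% state$Theta) %*% Sinv)
  cp <- chol(P)
  mean_vec <- backsolve(cp, backsolve(cp, b, transpose = TRUE))
  z <- mean_vec + backsolve(cp, rnorm(length(b)))
  state$Z <- matrix(z, model$n_t, model$n_p,
                    dimnames = dimnames(state$Z))
  state
}

#' Gibbs update of the residual covariance
#'
#' Exact inverse-Wishart draw from the full conditional
#' `IW(sigma_df + n_s, sigma_scale + R' W^-1 R)` with `R = Theta - T Z`.
#'
#' @inheritParams update_theta_mh
#' @return Updated state.
#' @keywords internal
update_sigma_gibbs <- function(state, model) {
  R <- state$Theta - model$Tm %*% state$Z
  S <- model$prior$sigma_scale + crossprod(R, state$Winv %*% R)
  S <- (S + t(S)) / 2
  if (!is_spd(S)) stop_jsmm("inverse-Wishart scale matrix not positive definite")
  nu <- model$prior$sigma_df + model$n_s
  X <- rWishart(1, nu, chol2inv(chol(S)))[, , 1]
  Sigma <- chol2inv(chol(X))
  state$Sigma <- (Sigma + t(Sigma)) / 2
  state
}

#' Grid-Gibbs update of the phylogenetic weight
#'
#' Evaluates the full conditional log-density of `rho` on the prior grid
#' (the matrix-normal density of `Theta` as a function of
#' `W = rho C + (1 - rho) I`, all else fixed; the grid prior is uniform) and
#' draws one grid point by inverse-CDF on the normalised weights. The
#' eigenvectors of `C` diagonalise `W` for every `rho`, so the grid sweep
#' costs one eigendecomposition total.
#'
#' @inheritParams update_theta_mh
#' @return Updated state.
#' @keywords internal
update_rho_grid <- function(state, model) {
  eC <- model$eC
  R <- state$Theta - model$Tm %*% state$Z
  Sinv <- chol2inv(chol(state$Sigma))
  Rt <- crossprod(eC$vectors, R)           # n_s x n_p, rotated residuals
  qv <- rowSums((Rt %*% Sinv) * Rt)        # per-eigendirection quadratic form
  grid <- model$prior$rho_grid
  logp <- vapply(grid, function(r) {
    w <- r * eC$values + (1 - r)
    if (any(w <= 0)) return(-Inf)
    -0.5 * (model$n_p * sum(log(w)) + sum(qv / w))
  }, numeric(1))
  if (all(!is.finite(logp))) stop_jsmm("rho conditional is -Inf on the whole grid")
  p <- exp(logp - max(logp))
  cdf <- cumsum(p) / sum(p)
  idx <- findInterval(runif(1), cdf) + 1L
  state$rho_idx <- idx
  state$rho <- grid[idx]
  state$Winv <- winv_from_eigen(eC, state$rho)
  state
}

#' Fit the joint species movement model
#'
#' Metropolis-within-Gibbs sampler for the posterior of the species-specific
#' movement parameters `Theta`, trait loadings `Z`, residual covariance
#' `Sigma` and phylogenetic weight `rho`, given any species-level likelihood
#' (see [redistribution_likelihood()], [diffusion_likelihood()], or
#' [new_jsmm_likelihood()] for custom models). Each iteration cycles a
#' per-species Metropolis update of `Theta` and exact Gibbs draws of `Z`,
#' `Sigma` and `rho`.
#'
#' @param likelihood A `jsmm_likelihood` object.
#' @param traits A [trait_design()] object covering every species in the
#'   likelihood (species with traits but no data are allowed and are imputed
#'   from the community layer).
#' @param C Species correlation matrix from [phylo_correlation()], rows and
#'   columns ordered (or named) as in `traits`.
#' @param control A [jsmm_control()].
#' @param prior A [jsmm_prior()]; defaults to `jsmm_prior(likelihood$n_p)`.
#' @return An object of class `jsmm_fit` with elements `draws` (arrays of
#'   posterior draws indexed iteration x chain x ...), `acceptance`
#'   (per-species Metropolis acceptance rates by chain), `log_posterior`,
#'   and the model ingredients. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] / [posterior_draws()] to explore it.
#' @examples
#' \donttest{
#' L <- jsmm_landscape(matrix(sample(0:2, 100, TRUE), 10, 10), cell_size = 10)
#' sc <- jsmm_scenario(n_species = 5, n_steps = 4, landscape = L, seed = 2)
#' sim <- generate_dataset(sc, model = "redistribution")
#' fit <- fit_jsmm(redistribution_likelihood(L, sim$tracks), sim$traits,
#'                 sim$C, jsmm_control(n_chains = 1, n_iter = 200, seed = 1))
#' glance(fit)
#' }
#' @export
fit_jsmm <- function(likelihood, traits, C, control = jsmm_control(),
                     prior = jsmm_prior(likelihood$n_p)) {
  model <- make_model(likelihood, traits, C, prior)
  n_save <- (control$n_iter - control$burn_in) %/% control$thin
  n_c <- control$n_chains
  dn_sp <- list(NULL, NULL, model$species, likelihood$param_names)
  draws <- list(
    Theta = array(NA_real_, c(n_save, n_c, model$n_s, model$n_p), dimnames = dn_sp),
    Z = array(NA_real_, c(n_save, n_c, model$n_t, model$n_p),
              dimnames = list(NULL, NULL, colnames(model$Tm), likelihood$param_names)),
    Sigma = array(NA_real_, c(n_save, n_c, model$n_p, model$n_p)),
    rho = matrix(NA_real_, n_save, n_c))
  logpost <- matrix(NA_real_, n_save, n_c)
  acceptance <- matrix(NA_real_, model$n_s, n_c,
                       dimnames = list(model$species, NULL))
  for (ch in seq_len(n_c)) {
    set.seed(control$seed + ch - 1)
    state <- init_state(model, control)
    keep <- 0
    for (it in seq_len(control$n_iter)) {
      adapting <- it <= control$burn_in
      state <- update_theta_mh(state, model, adapt = adapting,
                               target_accept = control$target_accept)
      state <- update_z_gibbs(state, model)
      state <- update_sigma_gibbs(state, model)
      state <- update_rho_grid(state, model)
      if (it == control$burn_in) {
        state$accept[] <- 0; state$accept_n <- 0
      }
      if (it > control$burn_in &&
          (it - control$burn_in) %% control$thin == 0) {
        keep <- keep + 1
        draws$Theta[keep, ch, , ] <- state$Theta
        draws$Z[keep, ch, , ] <- state$Z
        draws$Sigma[keep, ch, , ] <- state$Sigma
        draws$rho[keep, ch] <- state$rho
        logpost[keep, ch] <- sum(state$loglik) +
          theta_log_prior(state$Theta, model$traits,
                          jsmm_community(state$Z, state$Sigma, state$rho),
                          model$C)
      }
    }
    acceptance[, ch] <- state$accept / max(state$accept_n, 1)
  }
  structure(list(draws = draws, log_posterior = logpost,
                 acceptance = acceptance, likelihood = likelihood,
                 traits = traits, C = model$C, control = control,
                 prior = prior, species = model$species,
                 param_names = likelihood$param_names,
                 transforms = likelihood$transforms),
            class = "jsmm_fit")
}

#' @export
print.jsmm_fit <- function(x, ...) {
  d <- dim(x$draws$Theta)
  cat(sprintf("<jsmm_fit:%s> %d species, %d parameters, %d draws x %d chains\n",
              x$likelihood$model, d[3], d[4], d[1], d[2]))
  cat(sprintf("  posterior mean rho = %.3f, Pr(rho > 0.5) = %.3f\n",
              mean(x$draws$rho), mean(x$draws$rho > 0.5)))
  invisible(x)
}
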