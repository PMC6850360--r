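#' Single-species posterior fit
#'
#' Fits one species' movement parameters alone, with an independent normal
#' prior on each transformed parameter instead of the community layer. This
#' is the no-borrowing baseline against which the joint model's shrinkage is
#' measured: the joint fit pools information across species through traits
#' and phylogeny, and for data-poor species its posterior is typically
#' tighter than this one.
#'
#' The sampler is a deliberately separate code path from the joint sampler:
#' a plain adaptive random-walk Metropolis on the whole parameter vector.
#'
#' @param likelihood A `jsmm_likelihood` object.
#' @param species Species id to fit.
#' @param prior_mean,prior_sd Mean and standard deviation of the independent
#'   normal prior on each transformed parameter. Defaults 0 and 2.5.
#' @param n_iter,burn_in,seed Sampler settings.
#' @return List with `draws` (matrix, one column per parameter), `accept`
#'   (acceptance rate), and `summary` (tibble of posterior mean/sd/interval
#'   per parameter).
#' @export
fit_single_species <- function(likelihood, species, prior_mean = 0,
                               prior_sd = 2.5, n_iter = 4000,
                               burn_in = n_iter %/% 4, seed = 1) {
  n_p <- likelihood$n_p
  prior_mean <- rep_len(prior_mean, n_p)
  prior_sd <- rep_len(prior_sd, n_p)
  set.seed(seed)
  th <- rep(0, n_p)
  obj <- function(t) -eval_loglik(likelihood, species, t) + 0.005 * sum(t^2)
  fit0 <- tryCatch(optim(th, obj, method = "Nelder-Mead",
                         control = list(maxit = 300)),
                   error = function(e) NULL)
  if (!is.null(fit0) && all(is.finite(fit0$par))) th <- fit0$par
  ll <- eval_loglik(likelihood, species, th)
  lp <- sum(dnorm(th, prior_mean, prior_sd, log = TRUE))
  log_scale <- log(0.3)
  n_keep <- n_iter - burn_in
  draws <- matrix(NA_real_, n_keep, n_p,
                  dimnames = list(NULL, likelihood$param_names))
  acc <- 0
  for (it in seq_len(n_iter)) {
    th1 <- th + exp(log_scale) * rnorm(n_p)
    ll1 <- eval_loglik(likelihood, species, th1)
    lp1 <- sum(dnorm(th1, prior_mean, prior_sd, log = TRUE))
    log_r <- (ll1 + lp1) - (ll + lp)
    acc_p <- min(1, exp(log_r))
    if (is.finite(log_r) && log(runif(1)) < log_r) {
      th <- th1; ll <- ll1; lp <- lp1
      if (it > burn_in) acc <- acc + 1
    }
    if (it <= burn_in) log_scale <- log_scale + it^-0.6 * (acc_p - 0.25)
    if (it > burn_in) draws[it - burn_in, ] <- th
  }
  summary <- tibble::tibble(
    parameter = likelihood$param_names,
    estimate = colMeans(draws),
    std.error = apply(draws, 2, sd),
    conf.low = apply(draws, 2, quantile, 0.025),
    conf.high = apply(draws, 2, quantile, 0.975))
  list(draws = draws, accept = acc / n_keep, summary = summary)
}
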