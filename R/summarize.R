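#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# split-Rhat of one scalar's draws (iterations x chains)
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4 || sd(x) == 0) return(1)
  half <- n %/% 2
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  mu <- colMeans(xs); v <- apply(xs, 2, var)
  B <- nn * var(mu); Wv <- mean(v)
  if (Wv == 0) return(1)
  sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
}

ess_of <- function(x) {
  x <- as.matrix(x)
  sum(apply(x, 2, function(col) {
    if (sd(col) == 0) return(length(col))
    as.numeric(coda::effectiveSize(coda::mcmc(col)))
  }))
}

#' Long tibble of posterior draws
#'
#' @param fit A [fit_jsmm()] result.
#' @param pars Which block: `"theta"` (species parameters), `"loadings"`
#'   (`Z`), `"sigma"`, or `"rho"`.
#' @return Tibble with columns `chain`, `iteration`, block-specific index
#'   columns, and `value` (transformed scale).
#' @export
posterior_draws <- function(fit, pars = c("theta", "loadings", "sigma", "rho")) {
  pars <- match.arg(pars)
  dr <- fit$draws
  n_it <- dim(dr$rho)[1]; n_ch <- dim(dr$rho)[2]
  base <- tidyr::expand_grid(chain = seq_len(n_ch), iteration = seq_len(n_it))
  if (pars == "rho") {
    return(dplyr::mutate(base, value = as.vector(dr$rho[cbind(base$iteration, base$chain)])))
  }
  arr <- switch(pars, theta = dr$Theta, loadings = dr$Z, sigma = dr$Sigma)
  d3 <- dim(arr)[3]; d4 <- dim(arr)[4]
  idx <- tidyr::expand_grid(chain = seq_len(n_ch), iteration = seq_len(n_it),
                            i = seq_len(d3), j = seq_len(d4))
  idx$value <- arr[as.matrix(idx[, c("iteration", "chain", "i", "j")])]
  if (pars == "theta") {
    idx$species <- fit$species[idx$i]
    idx$parameter <- fit$param_names[idx$j]
  } else if (pars == "loadings") {
    idx$trait <- colnames(fit$traits$T)[idx$i]
    idx$parameter <- fit$param_names[idx$j]
  } else {
    idx$row <- fit$param_names[idx$i]
    idx$col <- fit$param_names[idx$j]
  }
  dplyr::select(idx, -"i", -"j")
}

#' Tidy posterior summaries of a joint movement fit
#'
#' @param x A `jsmm_fit`.
#' @param pars Block to summarise: `"theta"`, `"loadings"`, `"sigma"` or
#'   `"rho"`.
#' @param conf_level Credible-interval mass (equal-tailed). Default 0.95.
#' @param natural For `pars = "theta"`: also report the posterior mean on
#'   the natural parameter scale (back-transformed draw-wise).
#' @param ... Unused.
#' @return Tibble with `estimate` (posterior mean), `std.error` (posterior
#'   sd), `conf.low`, `conf.high`, `rhat`, `ess` per term.
#' @method tidy jsmm_fit
#' @export
tidy.jsmm_fit <- function(x, pars = c("theta", "loadings", "sigma", "rho"),
                          conf_level = 0.95, natural = FALSE, ...) {
  pars <- match.arg(pars)
  a <- (1 - conf_level) / 2
  d <- posterior_draws(x, pars)
  keys <- setdiff(names(d), c("chain", "iteration", "value"))
  n_it <- dim(x$draws$rho)[1]; n_ch <- dim(x$draws$rho)[2]
  out <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      estimate = mean(.data$value),
      std.error = sd(.data$value),
      conf.low = quantile(.data$value, a, names = FALSE),
      conf.high = quantile(.data$value, 1 - a, names = FALSE),
      rhat = split_rhat(matrix(.data$value, n_it, n_ch)),
      ess = ess_of(matrix(.data$value, n_it, n_ch)),
      .groups = "drop")
  if (pars == "rho") out <- dplyr::mutate(out, term = "rho", .before = 1)
  if (pars == "theta" && natural) {
    nat <- d |>
      dplyr::mutate(value = dplyr::case_when(
        x$transforms[match(.data$parameter, x$param_names)] == "log" ~ exp(.data$value),
        x$transforms[match(.data$parameter, x$param_names)] == "logit" ~ stats::plogis(.data$value),
        TRUE ~ .data$value)) |>
      dplyr::group_by(.data$species, .data$parameter) |>
      dplyr::summarise(estimate_natural = mean(.data$value), .groups = "drop")
    out <- dplyr::left_join(out, nat, by = c("species", "parameter"))
  }
  out
}

#' One-row summary of a joint movement fit
#'
#' @param x A `jsmm_fit`.
#' @param ... Unused.
#' @return Tibble with chain geometry, worst-case convergence diagnostics,
#'   mean Metropolis acceptance, and the phylogenetic-signal summaries:
#'   posterior mean of `rho`, `Pr(rho > 0.5)`, and `Pr(rho > 0)` under the
#'   grid prior (one minus the mass on the zero grid point).
#' @method glance jsmm_fit
#' @export
glance.jsmm_fit <- function(x, ...) {
  th <- tidy(x, "theta"); zz <- tidy(x, "loadings")
  rho <- as.vector(x$draws$rho)
  tibble::tibble(
    n_species = length(x$species),
    n_params = length(x$param_names),
    n_chains = dim(x$draws$rho)[2],
    n_draws = dim(x$draws$rho)[1],
    mean_accept = mean(x$acceptance),
    max_rhat = max(th$rhat, zz$rhat),
    min_ess = min(th$ess, zz$ess),
    rho_mean = mean(rho),
    pr_rho_gt_half = mean(rho > 0.5),
    pr_rho_positive = mean(rho > 0))
}

#' Trait-effect curves of the expected movement parameters
#'
#' Evaluates the trait-based expectation `M = T Z` over a grid of one
#' continuous trait, holding the other design columns at a reference row
#' (intercept 1, other continuous traits 0 = their mean, indicators 0 =
#' reference level unless fixed via `at`), and summarises the posterior of
#' each movement parameter along the grid.
#'
#' @param fit A `jsmm_fit`.
#' @param trait Name of a continuous design column.
#' @param n_grid Grid resolution. Default 50.
#' @param at Named list fixing other design columns (e.g. an indicator at 1).
#' @param conf_level Interval mass. Default 0.95.
#' @return Tibble: `trait_value` (original trait scale), `parameter`,
#'   `estimate`, `conf.low`, `conf.high`.
#' @export
trait_effects <- function(fit, trait, n_grid = 50, at = list(),
                          conf_level = 0.95) {
  cols <- fit$traits$columns
  j <- match(trait, cols$name)
  assert_that(!is.na(j) && cols$kind[j] == "continuous",
              sprintf("'%s' is not a continuous design column", trait))
  zgrid <- seq(min(fit$traits$T[, j]), max(fit$traits$T[, j]),
               length.out = n_grid)
  x0 <- setNames(numeric(nrow(cols)), cols$name)
  x0["intercept"] <- 1
  for (nm in names(at)) x0[nm] <- at[[nm]]
  X <- matrix(rep(x0, each = n_grid), n_grid)
  X[, j] <- zgrid
  Zd <- fit$draws$Z
  n_it <- dim(Zd)[1]; n_ch <- dim(Zd)[2]
  a <- (1 - conf_level) / 2
  out <- list()
  for (p in seq_along(fit$param_names)) {
    zmat <- matrix(Zd[, , , p], n_it * n_ch, dim(Zd)[3])
    curves <- X %*% t(zmat)                     # n_grid x n_draws
    out[[p]] <- tibble::tibble(
      trait_value = zgrid * cols$scale[j] + cols$center[j],
      parameter = fit$param_names[p],
      estimate = rowMeans(curves),
      conf.low = apply(curves, 1, quantile, a),
      conf.high = apply(curves, 1, quantile, 1 - a))
  }
  dplyr::bind_rows(out)
}

#' Posterior contrasts between trait loadings
#'
#' Posterior probability that one design column's loading exceeds another's,
#' per movement parameter — the standard way to compare categorical guilds
#' (e.g. `Pr(zeta_frugivore > zeta_granivore)` for step length). A contrast
#' whose difference is identically zero (a column with itself) is flagged
#' and reported as 0.5.
#'
#' @param fit A `jsmm_fit`.
#' @param a,b Design column names to contrast (`a` minus `b`).
#' @return Tibble: `parameter`, `pr_greater`, `degenerate`.
#' @export
loading_contrast <- function(fit, a, b) {
  cols <- colnames(fit$traits$T)
  ia <- match(a, cols); ib <- match(b, cols)
  assert_that(!is.na(ia) && !is.na(ib), "unknown design column in contrast")
  Zd <- fit$draws$Z
  out <- lapply(seq_along(fit$param_names), function(p) {
    dif <- as.vector(Zd[, , ia, p]) - as.vector(Zd[, , ib, p])
    degen <- all(dif == 0)
    tibble::tibble(parameter = fit$param_names[p],
                   pr_greater = if (degen) 0.5 else mean(dif > 0),
                   degenerate = degen)
  })
  dplyr::bind_rows(out)
}

#' Full posterior report
#'
#' Per-species posterior means and credible intervals for every movement
#' parameter, the loading summaries, and the phylogenetic-signal summaries;
#' when the true generating values are supplied (from a synthetic data set)
#' coverage columns are added.
#'
#' @param fit A `jsmm_fit`.
#' @param truth Optional list with elements `Theta`, `Z`, `rho` as produced
#'   by [generate_dataset()].
#' @param conf_level Interval mass. Default 0.95.
#' @return List of tibbles: `species`, `loadings`, `phylogeny`.
#' @export
summarize_posterior <- function(fit, truth = NULL, conf_level = 0.95) {
  th <- tidy(fit, "theta", conf_level = conf_level)
  zz <- tidy(fit, "loadings", conf_level = conf_level)
  rho <- as.vector(fit$draws$rho)
  ph <- tibble::tibble(rho_mean = mean(rho),
                       rho_conf_low = quantile(rho, (1 - conf_level) / 2, names = FALSE),
                       rho_conf_high = quantile(rho, 1 - (1 - conf_level) / 2, names = FALSE),
                       pr_rho_gt_half = mean(rho > 0.5),
                       pr_rho_positive = mean(rho > 0))
  if (!is.null(truth)) {
    tt <- tibble::tibble(
      species = rep(rownames(truth$Theta), ncol(truth$Theta)),
      parameter = rep(fit$param_names, each = nrow(truth$Theta)),
      truth = as.vector(truth$Theta))
    th <- dplyr::left_join(th, tt, by = c("species", "parameter")) |>
      dplyr::mutate(covered = .data$truth >= .data$conf.low &
                      .data$truth <= .data$conf.high)
    zt <- tibble::tibble(
      trait = rep(colnames(fit$traits$T), ncol(truth$Z)),
      parameter = rep(fit$param_names, each = nrow(truth$Z)),
      truth = as.vector(truth$Z))
    zz <- dplyr::left_join(zz, zt, by = c("trait", "parameter")) |>
      dplyr::mutate(covered = .data$truth >= .data$conf.low &
                      .data$truth <= .data$conf.high)
    ph$rho_truth <- truth$rho
  }
  list(species = th, loadings = zz, phylogeny = ph)
}

#' Plot posterior intervals of the species movement parameters
#'
#' @param object A `jsmm_fit`.
#' @param ... Unused.
#' @return A ggplot: species on the y axis, one facet per movement
#'   parameter, posterior mean and 95% interval.
#' @method autoplot jsmm_fit
#' @export
autoplot.jsmm_fit <- function(object, ...) {
  th <- tidy(object, "theta")
  ggplot2::ggplot(th, ggplot2::aes(x = .data$estimate, y = .data$species)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "posterior estimate (transformed scale)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot trait-effect curves
#'
#' @param fit A `jsmm_fit`.
#' @param trait Continuous design column to sweep.
#' @param ... Passed to [trait_effects()].
#' @return A ggplot of the posterior mean curve and interval ribbon, one
#'   facet per movement parameter.
#' @export
plot_trait_effects <- function(fit, trait, ...) {
  te <- trait_effects(fit, trait, ...)
  ggplot2::ggplot(te, ggplot2::aes(x = .data$trait_value, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = trait, y = "expected parameter (transformed scale)")
}
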