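#' Single-step redistribution kernel over a habitat grid
#'
#' Probability that an individual currently in `origin` moves, in one step,
#' to each cell of the landscape (the origin cell itself included, at
#' distance zero). The kernel combines exponential distance decay with
#' characteristic step length `alpha` (m) and habitat-affinity multipliers:
#' `p_j` is proportional to
#' `exp(-d_ij / alpha) * exp(beta1 * semiopen_j) * exp(beta2 * forest_j)`,
#' normalised to sum to one over all cells. Open habitat is the reference
#' class (`beta1 = beta2 = 0` there).
#'
#' @param landscape A [jsmm_landscape()].
#' @param params Numeric length-3 vector `c(log_alpha, beta1, beta2)` on the
#'   transformed scale used by the hierarchical layer (`alpha = exp(log_alpha)`).
#' @param origin Length-2 integer `(row, col)` of the current cell.
#' @return Numeric matrix of the landscape's dimensions; entries sum to 1.
#' @examples
#' L <- jsmm_landscape(matrix(0L, 1, 3), cell_size = 10)
#' step_probabilities(L, c(log(10), 0, 0), origin = c(1, 2))
#' @export
step_probabilities <- function(landscape, params, origin) {
  k <- redistribution_kernel_factors(landscape)
  p <- step_prob_rows(k, params, cell_index(landscape, origin[1], origin[2]))
  matrix(as.numeric(p), nrow(landscape$habitat), ncol(landscape$habitat))
}

# cached per-landscape quantities the kernel reuses: habitat indicators and
# cell centre coordinates (distances are computed per requested origin)
redistribution_kernel_factors <- function(landscape) {
  hab <- as.vector(landscape$habitat)
  cc <- cell_centers(landscape)
  list(landscape = landscape, n = length(hab),
       h1 = as.numeric(hab == 1L), h2 = as.numeric(hab == 2L),
       x = cc$x, y = cc$y)
}

# rows of step probabilities for several origin cells at once (linear indices)
step_prob_rows <- function(k, params, origins, log = FALSE) {
  alpha <- exp(params[1])
  assert_that(is.finite(alpha) && alpha > 0, "alpha must be positive")
  logw <- params[2] * k$h1 + params[3] * k$h2
  D <- sqrt(outer(k$x[origins], k$x, `-`)^2 + outer(k$y[origins], k$y, `-`)^2)
  logE <- -D / alpha + matrix(logw, length(origins), k$n, byrow = TRUE)
  m <- max(logw)
  E <- exp(logE - m)
  lognorm <- m + log(rowSums(E))
  if (log) logE - lognorm else exp(logE - lognorm)
}

# tracks tibble -> per-species transition counts on linear cell indices
track_transitions <- function(landscape, tracks) {
  need <- c("species", "individual", "track", "step", "row", "col")
  assert_that(all(need %in% names(tracks)),
              paste("tracks need columns:", paste(need, collapse = ", ")))
  tracks <- dplyr::arrange(tracks, .data$species, .data$individual,
                           .data$track, .data$step)
  idx <- cell_index(landscape, tracks$row, tracks$col)
  g <- paste(tracks$species, tracks$individual, tracks$track, sep = "\r")
  n <- nrow(tracks)
  same <- g[-1] == g[-n]
  from <- idx[-n][same]; to <- idx[-1][same]
  sp <- tracks$species[-n][same]
  steps <- tibble::tibble(species = sp, from = from, to = to)
  assert_that(nrow(steps) > 0, "no movement steps: every track needs >= 2 locations")
  dplyr::count(steps, .data$species, .data$from, .data$to, name = "n")
}

#' Log-likelihood of one movement track
#'
#' Sum over consecutive cell pairs of the log single-step probability from
#' [step_probabilities()]. Steps are treated as independent given the current
#' location; there is no temporal component.
#'
#' @inheritParams step_probabilities
#' @param track Two-column matrix or data frame of `(row, col)` locations in
#'   order; must have at least two rows.
#' @return Scalar log-likelihood.
#' @export
track_loglik <- function(landscape, params, track) {
  track <- as.matrix(track)
  assert_that(nrow(track) >= 2, "a track needs at least two locations")
  idx <- cell_index(landscape, track[, 1], track[, 2])
  k <- redistribution_kernel_factors(landscape)
  origins <- idx[-length(idx)]
  u <- sort(unique(origins))
  logP <- step_prob_rows(k, params, u, log = TRUE)
  sum(logP[cbind(match(origins, u), idx[-1])])
}

#' Simulate a movement track from the redistribution kernel
#'
#' Sequential categorical draws from [step_probabilities()], starting at
#' `origin`. Seed the session RNG for reproducibility.
#'
#' @inheritParams step_probabilities
#' @param n_steps Number of steps (>= 1).
#' @return Tibble with columns `step` (0 = start), `row`, `col`.
#' @export
simulate_track <- function(landscape, params, origin, n_steps) {
  assert_that(n_steps >= 1, "n_steps must be >= 1")
  k <- redistribution_kernel_factors(landscape)
  nr <- nrow(landscape$habitat)
  cur <- cell_index(landscape, origin[1], origin[2])
  out <- integer(n_steps + 1)
  out[1] <- cur
  for (i in seq_len(n_steps)) {
    p <- step_prob_rows(k, params, cur)
    cur <- sample.int(k$n, 1, prob = as.numeric(p))
    out[i + 1] <- cur
  }
  tibble::tibble(step = 0:n_steps,
                 row = ((out - 1L) %% nr) + 1L,
                 col = ((out - 1L) %/% nr) + 1L)
}

#' Redistribution-model species likelihood
#'
#' Packages a landscape and a table of observed tracks into the species
#' likelihood interface consumed by [fit_jsmm()]: three transformed
#' parameters per species (`log_alpha`, `beta_semiopen`, `beta_forest`) and a
#' per-species log-likelihood equal to the sum of log single-step
#' probabilities over all that species' steps.
#'
#' @param landscape A [jsmm_landscape()].
#' @param tracks Tibble of observed locations: columns `species`,
#'   `individual`, `track`, `step` (order within track), `row`, `col`.
#' @return A `jsmm_likelihood` object.
#' @export
redistribution_likelihood <- function(landscape, tracks) {
  k <- redistribution_kernel_factors(landscape)
  trans <- track_transitions(landscape, tracks)
  by_sp <- split(trans, trans$species)
  # cache, per species, its unique origin cells, the distances from those
  # origins to every cell, and the flat (origin, dest) index of each step
  sp_data <- lapply(by_sp, function(d) {
    u <- sort(unique(d$from))
    o_row <- match(d$from, u)
    D <- sqrt(outer(k$x[u], k$x, `-`)^2 + outer(k$y[u], k$y, `-`)^2)
    flat <- (d$to - 1L) * length(u) + o_row
    list(origins = u, D = D, count = d$n, o_row = o_row,
         d_obs = D[flat], dest = d$to)
  })
  loglik <- function(species, theta) {
    d <- sp_data[[species]]
    if (is.null(d)) return(0)
    alpha <- exp(theta[1])
    if (!is.finite(alpha) || alpha <= 0) return(-Inf)
    # normaliser by habitat-weighted row sums; observed entries picked directly
    wvec <- exp(theta[2] * k$h1 + theta[3] * k$h2)
    norm <- exp(-d$D / alpha) %*% wvec
    logw_obs <- theta[2] * k$h1[d$dest] + theta[3] * k$h2[d$dest]
    sum(d$count * (-d$d_obs / alpha + logw_obs - log(norm[d$o_row])))
  }
  new_jsmm_likelihood(
    model = "redistribution",
    species = names(sp_data),
    param_names = c("log_alpha", "beta_semiopen", "beta_forest"),
    transforms = c("log", "identity", "identity"),
    loglik = loglik,
    data = list(landscape = landscape, tracks = tracks, sp_data = sp_data))
}
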