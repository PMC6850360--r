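#' Trap configuration for the capture-recapture observation model
#'
#' @param traps Data frame with columns `trap` (unique id), `x`, `y`
#'   (coordinates in m, on the landscape's coordinate system).
#' @param schedule Nights-by-traps 0/1 matrix (or data frame); column order
#'   must match `traps$trap`. Row `n` gives the traps active on night `n`.
#' @param radius Attraction radius in m around each trap. Default 30: an
#'   active trap captures, with the species' nightly probability `q`, the
#'   individuals located within this circle. Radius and per-night efficiency
#'   are not separately identifiable, so the radius is fixed and `q` is
#'   estimated.
#' @return An object of class `jsmm_traps`.
#' @export
jsmm_traps <- function(traps, schedule, radius = 30) {
  traps <- as.data.frame(traps)
  assert_that(all(c("trap", "x", "y") %in% names(traps)),
              "traps need columns trap, x, y")
  assert_that(!anyDuplicated(traps$trap), "duplicated trap ids")
  schedule <- as.matrix(schedule)
  assert_that(ncol(schedule) == nrow(traps),
              "schedule columns must match the trap table")
  assert_that(all(schedule %in% c(0, 1)), "schedule must be 0/1")
  assert_that(radius > 0, "radius must be > 0")
  colnames(schedule) <- as.character(traps$trap)
  structure(list(traps = traps, schedule = schedule, radius = radius,
                 n_nights = nrow(schedule)),
            class = "jsmm_traps")
}

#' Finite-volume generator of the habitat-selection diffusion
#'
#' Discretises diffusion with edge-mediated habitat selection on the
#' landscape grid as a continuous-time jump process between 4-neighbour
#' cells. With habitat weight `w = k` in open cells and `w = 1` in forest
#' (semi-open treated as forest by default), the jump rate from cell `a` to
#' neighbour `b` is `(D / h^2) * 2 w(b) / (w(a) + w(b))`; the boundary is
#' reflecting, and the mortality rate `m` drains every cell. The stationary
#' density of the no-mortality chain is proportional to `w`, so the
#' open-to-forest density ratio tends to `k` — the defining property of the
#' habitat-selection parameter.
#'
#' @param landscape A [jsmm_landscape()]; cell size `h` is taken from it.
#' @param D Diffusion coefficient, m^2/day (> 0).
#' @param k Relative attractiveness of open over forest habitat (> 0).
#' @param m Mortality rate, 1/day (>= 0).
#' @param semiopen_as Habitat the semi-open class is merged into:
#'   `"forest"` (default) or `"open"`.
#' @return An object of class `jsmm_generator` holding the sparse rate
#'   matrix and the uniformisation constant.
#' @export
build_generator <- function(landscape, D, k, m, semiopen_as = c("forest", "open")) {
  semiopen_as <- match.arg(semiopen_as)
  assert_that(D > 0, "D must be > 0")
  assert_that(k > 0, "k must be > 0")
  assert_that(m >= 0, "m must be >= 0")
  hab <- landscape$habitat
  nr <- nrow(hab); nc <- ncol(hab); N <- nr * nc
  h <- landscape$cell_size
  open <- hab == 0L | (hab == 1L & semiopen_as == "open")
  w <- ifelse(as.vector(open), k, 1)

  idx <- matrix(seq_len(N), nr, nc)
  from <- c(idx[-nr, ], idx[-1, ], idx[, -nc], idx[, -1])
  to   <- c(idx[-1, ], idx[-nr, ], idx[, -1], idx[, -nc])
  rate <- (D / h^2) * 2 * w[to] / (w[from] + w[to])
  Q <- Matrix::sparseMatrix(i = from, j = to, x = rate, dims = c(N, N))
  out_rate <- as.numeric(Matrix::rowSums(Q))
  Q <- Q - Matrix::Diagonal(N, out_rate + m)
  Lambda <- max(out_rate + m)
  # adjacency in flat form (edges sorted by origin) for the jump simulator
  o <- order(from)
  structure(list(Q = Q, Lambda = Lambda, N = N, nr = nr, nc = nc,
                 D = D, k = k, m = m, h = h,
                 edge_to = to[o], edge_rate = rate[o],
                 edge_ptr = c(0L, cumsum(tabulate(from, N))),
                 out_rate = out_rate),
            class = "jsmm_generator")
}

#' Propagate a location density through the diffusion generator
#'
#' Computes `v %*% expm(Q * duration)` by uniformisation: the matrix
#' exponential is expanded as a Poisson mixture of powers of the
#' substochastic matrix `I + Q / Lambda`, truncated where the Poisson tail
#' drops below `1e-14`. Total mass decays only through mortality:
#' with traps off, `sum(v(t)) = sum(v(0)) * exp(-m t)`.
#'
#' @param density Nonnegative vector over cells (column-major order), total
#'   mass at most 1.
#' @param generator A [build_generator()] object.
#' @param duration Time in days (>= 0). `duration = 0` returns the input
#'   unchanged.
#' @return The propagated density vector.
#' @export
propagate <- function(density, generator, duration) {
  assert_that(length(density) == generator$N, "density has wrong length")
  if (min(density) < -1e-12) stop_jsmm("density has negative entries")
  assert_that(duration >= 0, "duration must be >= 0")
  if (duration == 0) return(density)
  lt <- generator$Lambda * duration
  if (lt == 0) return(density)
  B <- generator$Q * (duration / lt)
  K <- max(stats::qpois(1 - 1e-14, lt), 5) + 5
  wts <- stats::dpois(0:K, lt)
  v <- density
  acc <- wts[1] * v
  for (kk in seq_len(K)) {
    v <- as.numeric(v %*% B) + v   # v (I + Q duration / lt)
    acc <- acc + wts[kk + 1] * v
  }
  pmax(acc, 0)
}

# nearest-active-trap partition of the attraction zones for one night's
# active set; ties broken by lowest trap index. Returns a list of cell-index
# vectors, one per trap (empty for inactive traps).
trap_zones <- function(landscape, traps, active) {
  cc <- cell_centers(landscape)
  n_tr <- nrow(traps$traps)
  zones <- vector("list", n_tr)
  act <- which(active > 0)
  if (!length(act)) return(zones)
  d2 <- sapply(act, function(t) {
    (cc$x - traps$traps$x[t])^2 + (cc$y - traps$traps$y[t])^2
  })
  d2 <- matrix(d2, ncol = length(act))
  within <- d2 <= traps$radius^2
  nearest <- max.col(-d2, ties.method = "first")
  covered <- which(rowSums(within) > 0)
  assign_to <- act[nearest[covered]]
  # a covered cell could be nearest to a trap whose radius misses it while a
  # farther active trap covers it; reassign those to their nearest covering trap
  miss <- !within[cbind(covered, nearest[covered])]
  if (any(miss)) {
    for (ii in which(miss)) {
      cands <- which(within[covered[ii], ])
      assign_to[ii] <- act[cands[which.min(d2[covered[ii], cands])]]
    }
  }
  for (t in act) zones[[t]] <- covered[assign_to == t]
  zones
}

#' Apply one night of trapping to a location density
#'
#' Each active trap captures, with probability `q`, the probability mass
#' inside its attraction zone; overlapping zones are partitioned by nearest
#' trap so no mass is double-counted. Captured mass is removed from the
#' density.
#'
#' @param density Cell density vector.
#' @param zones Zone partition from the internal nearest-trap assignment
#'   (list of cell-index vectors per trap).
#' @param q Nightly capture probability in \[0, 1\].
#' @return List with `density` (after removal) and `capture` (named numeric,
#'   capture probability per trap; zero for inactive/uncovered traps).
#' @export
apply_night_capture <- function(density, zones, q) {
  capture <- numeric(length(zones))
  for (t in seq_along(zones)) {
    z <- zones[[t]]
    if (length(z)) {
      capture[t] <- q * sum(density[z])
      density[z] <- density[z] * (1 - q)
    }
  }
  list(density = density, capture = capture)
}

# capture history of one individual: release night/cell plus ordered
# recaptures (night, trap index). The likelihood alternates one-day
# propagation with nightly capture; each recapture contributes the log of
# its capture probability and resets the density to a point mass at the
# trap; the tail contributes log(1 - sum of interval capture probabilities).
individual_loglik_impl <- function(generator, landscape, traps, q, release_night,
                                   release_cell, rec_nights, rec_traps,
                                   zones_cache) {
  n_nights <- traps$n_nights
  v <- numeric(generator$N); v[release_cell] <- 1
  ll <- 0
  caps_since <- 0
  j <- 1
  night <- release_night + 1
  while (night <= n_nights) {
    v <- propagate(v, generator, 1)
    active <- traps$schedule[night, ]
    if (any(active > 0)) {
      key <- paste(which(active > 0), collapse = ",")
      zones <- zones_cache$get(key, active)
      res <- apply_night_capture(v, zones, q)
      if (j <= length(rec_nights) && rec_nights[j] == night) {
        tr <- rec_traps[j]
        if (active[tr] == 0) {
          stop_jsmm(sprintf("recapture at trap %d on night %d, but it was inactive",
                            tr, night))
        }
        if (res$capture[tr] <= 0) return(-Inf)
        ll <- ll + log(res$capture[tr])
        v <- numeric(generator$N)
        v[trap_cell(landscape, traps, tr)] <- 1
        caps_since <- 0
        j <- j + 1
      } else {
        caps_since <- caps_since + sum(res$capture)
        v <- res$density
      }
    }
    night <- night + 1
  }
  if (j <= length(rec_nights)) {
    stop_jsmm("recapture recorded on a night outside the study or at an inactive trap")
  }
  if (caps_since >= 1) return(-Inf)
  ll + log1p(-caps_since)
}

trap_cell <- function(landscape, traps, t) {
  h <- landscape$cell_size
  row <- round((traps$traps$y[t] - landscape$origin[2]) / h) + 1
  col <- round((traps$traps$x[t] - landscape$origin[1]) / h) + 1
  cell_index(landscape, max(1, min(nrow(landscape$habitat), row)),
             max(1, min(ncol(landscape$habitat), col)))
}

new_zone_cache <- function(landscape, traps) {
  env <- new.env(parent = emptyenv())
  list(get = function(key, active) {
    if (is.null(env[[key]])) env[[key]] <- trap_zones(landscape, traps, active)
    env[[key]]
  })
}

#' Log-likelihood of one individual's capture history
#'
#' @param landscape A [jsmm_landscape()].
#' @param traps A [jsmm_traps()].
#' @param params Length-4 transformed parameter vector
#'   `c(log_D, log_k, log_m, logit_q)`.
#' @param release_night Night index (0 allowed: marked before night 1) of the
#'   individual's first release.
#' @param release_cell `(row, col)` of the release location.
#' @param recaptures Data frame with columns `night`, `trap` (index into the
#'   trap table), ordered in time; may have zero rows.
#' @return Scalar log-likelihood.
#' @export
individual_loglik <- function(landscape, traps, params, release_night,
                              release_cell, recaptures = NULL) {
  gen <- build_generator(landscape, exp(params[1]), exp(params[2]), exp(params[3]))
  q <- stats::plogis(params[4])
  zc <- new_zone_cache(landscape, traps)
  rn <- if (is.null(recaptures) || nrow(recaptures) == 0) integer(0) else recaptures$night
  rt <- if (is.null(recaptures) || nrow(recaptures) == 0) integer(0) else recaptures$trap
  individual_loglik_impl(gen, landscape, traps, q, release_night,
                         cell_index(landscape, release_cell[1], release_cell[2]),
                         rn, rt, zc)
}

#' Diffusion capture-recapture species likelihood
#'
#' Packages a landscape, trap configuration and capture table into the
#' species likelihood interface for [fit_jsmm()]: four transformed
#' parameters per species (`log_D`, `log_k`, `log_m`, `logit_q`) and a
#' per-species log-likelihood summing [individual_loglik()] over the marked
#' individuals of that species.
#'
#' @param landscape A [jsmm_landscape()].
#' @param traps A [jsmm_traps()].
#' @param captures Tibble with columns `individual`, `species`, `night`,
#'   `trap` (trap id as in the trap table), `event` (`"mark"` for the first
#'   capture-and-release, `"recapture"` thereafter). Each individual needs
#'   exactly one mark event; recaptures must fall on nights when the trap was
#'   active. Released individuals restart at the capture trap.
#' @return A `jsmm_likelihood` object.
#' @export
diffusion_likelihood <- function(landscape, traps, captures) {
  captures <- as.data.frame(captures)
  need <- c("individual", "species", "night", "trap", "event")
  assert_that(all(need %in% names(captures)),
              paste("captures need columns:", paste(need, collapse = ", ")))
  trap_idx <- match(captures$trap, traps$traps$trap)
  assert_that(!anyNA(trap_idx), "captures reference unknown trap ids")
  captures$trap_i <- trap_idx
  by_ind <- split(captures, captures$individual)
  histories <- lapply(by_ind, function(d) {
    d <- d[order(d$night), ]
    assert_that(sum(d$event == "mark") == 1,
                sprintf("individual '%s' needs exactly one mark event", d$individual[1]))
    assert_that(d$event[1] == "mark",
                sprintf("individual '%s': mark must precede recaptures", d$individual[1]))
    list(species = d$species[1], release_night = d$night[1],
         release_trap = d$trap_i[1],
         rec_nights = d$night[-1], rec_traps = d$trap_i[-1])
  })
  species <- sort(unique(vapply(histories, `[[`, character(1), "species")))
  by_sp <- split(histories, vapply(histories, `[[`, character(1), "species"))
  zc <- new_zone_cache(landscape, traps)
  loglik <- function(sp, theta) {
    hs <- by_sp[[sp]]
    if (is.null(hs)) return(0)
    gen <- build_generator(landscape, exp(theta[1]), exp(theta[2]), exp(theta[3]))
    q <- stats::plogis(theta[4])
    sum(vapply(hs, function(hh) {
      individual_loglik_impl(gen, landscape, traps, q, hh$release_night,
                             trap_cell(landscape, traps, hh$release_trap),
                             hh$rec_nights, hh$rec_traps, zc)
    }, numeric(1)))
  }
  new_jsmm_likelihood(
    model = "diffusion",
    species = species,
    param_names = c("log_D", "log_k", "log_m", "logit_q"),
    transforms = c("log", "log", "log", "logit"),
    loglik = loglik,
    data = list(landscape = landscape, traps = traps, captures = captures))
}

#' Simulate a spatial capture-recapture data set
#'
#' Simulates each individual's movement as the discretised jump process of
#' [build_generator()] (exponential waiting times, 4-neighbour jumps,
#' killing at the mortality rate), applies the nightly trapping process, and
#' returns mark/recapture events in the format [diffusion_likelihood()]
#' consumes. Individuals are "marked" at their release night and location;
#' each recapture re-releases the individual at the capture trap.
#'
#' @param landscape A [jsmm_landscape()].
#' @param traps A [jsmm_traps()].
#' @param params Natural-scale list or vector `c(D, k, m, q)`.
#' @param releases Tibble with columns `individual`, `species`, `night`
#'   (marking night, 0 = before the first night), `trap` (trap id where the
#'   individual was marked and released).
#' @return Tibble of capture events (`individual`, `species`, `night`,
#'   `trap`, `event`), the mark event first.
#' @export
simulate_cmr <- function(landscape, traps, params, releases) {
  D <- params[[1]]; k <- params[[2]]; m <- params[[3]]; q <- params[[4]]
  gen <- build_generator(landscape, D, k, max(m, 1e-12))
  zc <- new_zone_cache(landscape, traps)
  out <- list()
  for (i in seq_len(nrow(releases))) {
    ind <- releases$individual[i]; sp <- releases$species[i]
    t0 <- match(releases$trap[i], traps$traps$trap)
    assert_that(!is.na(t0), "release references an unknown trap id")
    cell <- trap_cell(landscape, traps, t0)
    events <- list(tibble::tibble(individual = ind, species = sp,
                                  night = releases$night[i],
                                  trap = as.character(releases$trap[i]),
                                  event = "mark"))
    alive <- TRUE
    night <- releases$night[i] + 1
    while (alive && night <= traps$n_nights) {
      sim <- simulate_jump_day(gen, cell, m)
      alive <- sim$alive; cell <- sim$cell
      if (!alive) break
      active <- traps$schedule[night, ]
      if (any(active > 0)) {
        key <- paste(which(active > 0), collapse = ",")
        zones <- zc$get(key, active)
        for (t in which(active > 0)) {
          if (cell %in% zones[[t]] && runif(1) < q) {
            events <- c(events, list(tibble::tibble(
              individual = ind, species = sp, night = night,
              trap = as.character(traps$traps$trap[t]), event = "recapture")))
            cell <- trap_cell(landscape, traps, t)
            break
          }
        }
      }
      night <- night + 1
    }
    out[[i]] <- dplyr::bind_rows(events)
  }
  dplyr::bind_rows(out)
}

# one day of the continuous-time jump process with killing; returns the end
# cell and survival status
simulate_jump_day <- function(gen, cell, m) {
  t <- 0
  repeat {
    total <- gen$out_rate[cell] + m
    if (total <= 0) return(list(cell = cell, alive = TRUE))
    dt <- rexp(1, total)
    if (t + dt > 1) return(list(cell = cell, alive = TRUE))
    t <- t + dt
    if (runif(1) < m / total) return(list(cell = cell, alive = FALSE))
    e <- (gen$edge_ptr[cell] + 1L):gen$edge_ptr[cell + 1L]
    cell <- gen$edge_to[e][sample.int(length(e), 1, prob = gen$edge_rate[e])]
  }
}
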