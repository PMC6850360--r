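#' Generate a random patch-mosaic habitat landscape
#'
#' Seeds forest patches as unions of random disks until the forest fraction
#' reaches its target, then scatters semi-open cells (single trees,
#' corridor fragments) over the remaining open matrix. Disk radii are small
#' relative to the grid so the realised fractions land within a few
#' percentage points of the targets.
#'
#' @param nrow,ncol Grid dimensions in cells.
#' @param cell_size Cell side length in m. Default 10.
#' @param forest_frac Target forest fraction. Default 0.4.
#' @param semiopen_frac Target semi-open fraction. Default 0.1.
#' @param patch_radius Maximum disk radius in cells. Default 3.
#' @param origin Coordinates of the centre of cell (1, 1). Default `c(0, 0)`.
#' @return A [jsmm_landscape()]. Uses the session RNG; seed for
#'   reproducibility.
#' @examples
#' set.seed(1)
#' L <- generate_landscape(60, 60, cell_size = 10)
#' mean(L$habitat == 2)  # close to 0.4
#' @export
generate_landscape <- function(nrow, ncol, cell_size = 10, forest_frac = 0.4,
                               semiopen_frac = 0.1, patch_radius = 3,
                               origin = c(0, 0)) {
  assert_that(forest_frac > 0 && forest_frac < 1, "forest_frac must be in (0,1)")
  assert_that(forest_frac + semiopen_frac < 1,
              "habitat fractions must sum to less than 1")
  hab <- matrix(0L, nrow, ncol)
  n <- nrow * ncol
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  guard <- 0
  while (mean(hab == 2L) < forest_frac && guard < 10000) {
    guard <- guard + 1
    cr <- runif(1, 1, nrow); cc <- runif(1, 1, ncol)
    r <- runif(1, 1, patch_radius)
    hab[(rows - cr)^2 + (cols - cc)^2 <= r^2] <- 2L
  }
  open <- which(hab == 0L)
  n_semi <- round(semiopen_frac * n)
  if (n_semi > 0 && length(open) > n_semi) {
    hab[sample(open, n_semi)] <- 1L
  }
  jsmm_landscape(hab, cell_size = cell_size, origin = origin)
}

#' Simulation scenario for the joint movement model
#'
#' Collects everything needed to draw a complete synthetic community and
#' data set: community dimensions and true community-level parameters, the
#' phylogeny shape, the landscape, and the per-species data volume. Defaults
#' describe a mid-sized direct-observation study: 40 species on a 60 x 60
#' grid of 10 m cells with ~40% forest, 5 tracks of 3 steps per species, one
#' continuous trait and a two-level categorical trait, moderate trait
#' effects, residual spread 0.5 on each transformed parameter, and rho = 0.5.
#'
#' @param n_species Number of species.
#' @param model `"redistribution"` or `"diffusion"` (sets `n_p` to 3 or 4).
#' @param n_cont_traits Continuous traits (standardised). Default 1.
#' @param guild_levels Levels of one categorical trait (0 = none). Default 2.
#' @param Z True loadings (`n_t x n_p`); a sensible default is built when
#'   `NULL` (intercepts at field-typical values, modest trait effects).
#' @param Sigma True residual covariance; default `0.25 * I` (sd 0.5).
#' @param rho True phylogenetic weight. Default 0.5.
#' @param tree Phylogeny shape: `"coalescent"` (random ultrametric),
#'   `"balanced"`, or `"ranks"` (taxonomic four-level tree).
#' @param landscape A [jsmm_landscape()] or `NULL` to generate one with
#'   `landscape_spec`.
#' @param landscape_spec List passed to [generate_landscape()] when
#'   `landscape` is `NULL`.
#' @param tracks_per_species,steps_per_track Redistribution data volume;
#'   either scalars or vectors recycled over species, so data-poor species
#'   can be embedded in a data-rich community.
#' @param n_individuals,n_nights,n_traps Diffusion data volume: marked
#'   individuals per species, study nights, traps (placed on a regular grid,
#'   alternating halves active on odd/even nights).
#' @param seed Integer seed used by [generate_dataset()].
#' @return An object of class `jsmm_scenario`.
#' @export
jsmm_scenario <- function(n_species = 40, model = c("redistribution", "diffusion"),
                          n_cont_traits = 1, guild_levels = 2,
                          Z = NULL, Sigma = NULL, rho = 0.5,
                          tree = c("coalescent", "balanced", "ranks"),
                          landscape = NULL,
                          landscape_spec = list(nrow = 60, ncol = 60, cell_size = 10),
                          tracks_per_species = 5, steps_per_track = 3,
                          n_individuals = 20, n_nights = 10, n_traps = 9,
                          seed = 1) {
  model <- match.arg(model)
  tree <- match.arg(tree)
  n_p <- if (model == "redistribution") 3L else 4L
  n_t <- 1L + n_cont_traits + max(guild_levels - 1L, 0L)
  if (is.null(Z)) {
    intercept <- if (model == "redistribution") {
      c(log(25), 0.5, 1.0)                       # 25 m steps, wooded affinity
    } else {
      c(log(2000), 0, log(0.1), stats::qlogis(0.3))  # D m^2/d, k, m 1/d, q
    }
    Z <- matrix(0, n_t, n_p)
    Z[1, ] <- intercept
    extra <- n_t - 1L
    if (extra > 0) {
      # modest, fixed trait effects alternating in sign
      eff <- outer(seq_len(extra), seq_len(n_p),
                   function(i, j) 0.4 * (-1)^(i + j))
      Z[-1, ] <- eff
    }
  }
  if (is.null(Sigma)) Sigma <- diag(0.25, n_p)
  assert_that(nrow(Z) == n_t && ncol(Z) == n_p, "Z has the wrong dimensions")
  structure(list(
    n_species = n_species, model = model, n_p = n_p,
    n_cont_traits = n_cont_traits, guild_levels = guild_levels,
    Z = Z, Sigma = as.matrix(Sigma), rho = rho, tree = tree,
    landscape = landscape, landscape_spec = landscape_spec,
    tracks_per_species = tracks_per_species,
    steps_per_track = steps_per_track,
    n_individuals = n_individuals, n_nights = n_nights, n_traps = n_traps,
    seed = seed), class = "jsmm_scenario")
}

# random ultrametric tree of the requested shape
scenario_tree <- function(scenario, ids) {
  n <- length(ids)
  if (scenario$tree == "ranks") {
    n_fam <- max(2, round(n / 12))
    n_sub <- max(n_fam, round(n / 6))
    n_gen <- max(n_sub, round(n / 3))
    fam_of_sub <- sample(n_fam, n_sub, replace = TRUE)
    sub_of_gen <- sample(n_sub, n_gen, replace = TRUE)
    gen_of_sp <- sample(n_gen, n, replace = TRUE)
    ranks <- data.frame(
      species = ids,
      genus = paste0("g", gen_of_sp),
      subfamily = paste0("u", sub_of_gen[gen_of_sp]),
      family = paste0("f", fam_of_sub[sub_of_gen[gen_of_sp]]))
    return(list(tree = taxonomy_tree(ranks), ranks = ranks))
  }
  tree <- if (scenario$tree == "balanced" && log2(n) %% 1 == 0) {
    tr <- ape::stree(n, "balanced", tip.label = ids)
    ape::compute.brlen(tr, method = "Grafen")
  } else {
    ape::rcoal(n, tip.label = ids)
  }
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  list(tree = tree, ranks = NULL)
}

#' Draw a synthetic community from the hierarchical prior
#'
#' Draws species traits, a phylogeny of the requested shape, and the true
#' species-specific movement parameters from the exact matrix-normal prior
#' ([sample_theta_prior()]). Uses the session RNG.
#'
#' @param scenario A [jsmm_scenario()].
#' @return List: `traits_tbl` (raw trait tibble), `traits`
#'   ([trait_design()]), `tree`, `ranks` (when the tree is taxonomic), `C`,
#'   `Theta` (true transformed parameters), `community`
#'   ([jsmm_community()] of the true `Z`, `Sigma`, `rho`).
#' @export
generate_community <- function(scenario) {
  n <- scenario$n_species
  ids <- sprintf("sp%02d", seq_len(n))
  tbl <- tibble::tibble(species = ids)
  for (k in seq_len(scenario$n_cont_traits)) {
    tbl[[paste0("trait", k)]] <- rnorm(n)
  }
  if (scenario$guild_levels >= 2) {
    tbl$guild <- sample(paste0("guild", seq_len(scenario$guild_levels)),
                        n, replace = TRUE)
    # ensure every level occurs so the design has full column rank
    tbl$guild[seq_len(scenario$guild_levels)] <-
      paste0("guild", seq_len(scenario$guild_levels))
  }
  traits <- trait_design(tbl)
  tr <- scenario_tree(scenario, ids)
  C <- phylo_correlation(tr$tree)[ids, ids]
  community <- jsmm_community(scenario$Z, scenario$Sigma, scenario$rho)
  Theta <- sample_theta_prior(traits, community, C)
  list(traits_tbl = tbl, traits = traits, tree = tr$tree, ranks = tr$ranks,
       C = C, Theta = Theta, community = community)
}

# evenly spaced trap grid over the landscape interior
default_traps <- function(landscape, n_traps, n_nights) {
  nr <- nrow(landscape$habitat); nc <- ncol(landscape$habitat)
  h <- landscape$cell_size
  side <- ceiling(sqrt(n_traps))
  rows <- round(seq(0.15, 0.85, length.out = side) * nr)
  cols <- round(seq(0.15, 0.85, length.out = side) * nc)
  grid <- expand.grid(row = rows, col = cols)[seq_len(n_traps), ]
  traps <- data.frame(
    trap = sprintf("t%02d", seq_len(n_traps)),
    x = landscape$origin[1] + (grid$col - 1) * h,
    y = landscape$origin[2] + (grid$row - 1) * h)
  # alternating halves, the observed field design for nightly trapping
  sched <- matrix(0L, n_nights, n_traps)
  first_half <- seq_len(ceiling(n_traps / 2))
  for (nn in seq_len(n_nights)) {
    sched[nn, ] <- if (nn %% 2 == 1) {
      as.integer(seq_len(n_traps) %in% first_half)
    } else {
      as.integer(!seq_len(n_traps) %in% first_half)
    }
  }
  jsmm_traps(traps, sched, radius = 30)
}

#' Generate a complete synthetic data set
#'
#' Draws the community ([generate_community()]), the landscape (unless one
#' is supplied), and then the observation data under the requested movement
#' model at the community's true parameters: movement tracks simulated from
#' the redistribution kernel, or a spatial capture-recapture study simulated
#' from the habitat-selection diffusion with nightly trapping. Optionally
#' writes every input file in the on-disk formats the package reads, plus a
#' truth file for recovery scoring.
#'
#' @param scenario A [jsmm_scenario()].
#' @param model Overrides the scenario's model if given.
#' @param dir Optional directory: when given, all files are written there
#'   (see [write_dataset()]) and their paths returned in `$files`.
#' @return List bundle: the community elements of [generate_community()],
#'   `landscape`, and either `tracks` or (`traps`, `captures`); `truth`
#'   holds `Z`, `Sigma`, `rho`, `Theta`.
#' @export
generate_dataset <- function(scenario, model = scenario$model, dir = NULL) {
  set.seed(scenario$seed)
  com <- generate_community(scenario)
  landscape <- scenario$landscape
  if (is.null(landscape)) {
    landscape <- do.call(generate_landscape, scenario$landscape_spec)
  }
  n <- scenario$n_species
  ids <- com$traits$species
  bundle <- c(com, list(landscape = landscape, model = model,
                        truth = list(Z = scenario$Z, Sigma = scenario$Sigma,
                                     rho = scenario$rho, Theta = com$Theta)))
  if (model == "redistribution") {
    nr <- nrow(landscape$habitat); nc <- ncol(landscape$habitat)
    n_tracks <- rep_len(scenario$tracks_per_species, n)
    n_steps <- rep_len(scenario$steps_per_track, n)
    tracks <- list()
    for (s in seq_len(n)) {
      for (tr in seq_len(n_tracks[s])) {
        org <- c(sample.int(nr, 1), sample.int(nc, 1))
        tk <- simulate_track(landscape, com$Theta[s, ], org, n_steps[s])
        tracks[[length(tracks) + 1]] <- dplyr::mutate(
          tk, species = ids[s], individual = sprintf("%s_i%02d", ids[s], tr),
          track = tr, .before = 1)
      }
    }
    bundle$tracks <- dplyr::bind_rows(tracks)
  } else {
    traps <- default_traps(landscape, scenario$n_traps, scenario$n_nights)
    natural <- natural_scale(com$Theta, c("log", "log", "log", "logit"))
    caps <- list()
    for (s in seq_len(n)) {
      rel_night <- sample(0:(scenario$n_nights - 2), scenario$n_individuals,
                          replace = TRUE)
      rel_trap <- vapply(rel_night, function(n0) {
        act <- if (n0 == 0) seq_len(nrow(traps$traps)) else which(traps$schedule[n0, ] > 0)
        act[sample.int(length(act), 1)]
      }, integer(1))
      releases <- tibble::tibble(
        individual = sprintf("%s_m%03d", ids[s], seq_len(scenario$n_individuals)),
        species = ids[s], night = rel_night,
        trap = traps$traps$trap[rel_trap])
      caps[[s]] <- simulate_cmr(landscape, traps, as.list(natural[s, ]), releases)
    }
    bundle$traps <- traps
    bundle$captures <- dplyr::bind_rows(caps)
  }
  if (!is.null(dir)) bundle$files <- write_dataset(bundle, dir)
  bundle
}
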