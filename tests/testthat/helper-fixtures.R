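# Shared fixtures, all built in code.

# tiny all-open strip landscape (1 x n cells)
strip_landscape <- function(n = 3, cell_size = 10) {
  jsmm_landscape(matrix(0L, 1, n), cell_size = cell_size)
}

# mixed-habitat block used by kernel and diffusion tests
mixed_landscape <- function(nr = 5, nc = 5, cell_size = 10, seed = 42) {
  set.seed(seed)
  hab <- matrix(sample(0:2, nr * nc, replace = TRUE, prob = c(0.5, 0.1, 0.4)),
                nr, nc)
  hab[1, 1] <- 0L; hab[nr, nc] <- 2L   # both classes always present
  jsmm_landscape(hab, cell_size = cell_size)
}

# small community: traits, coalescent correlation, true community params
toy_community <- function(n_s = 4, n_p = 2, rho = 0.6, seed = 1) {
  set.seed(seed)
  tbl <- data.frame(species = sprintf("s%02d", seq_len(n_s)), x = rnorm(n_s))
  tr <- trait_design(tbl)
  C <- phylo_correlation(ape::rcoal(n_s, tip.label = tr$species))
  C <- C[tr$species, tr$species]
  Z <- matrix(rnorm(2 * n_p), 2, n_p)
  A <- matrix(rnorm(n_p * n_p), n_p)
  Sigma <- crossprod(A) + diag(n_p) * 0.5
  list(traits = tr, C = C, community = jsmm_community(Z, Sigma, rho))
}

# dense-covariance oracle for the Kronecker prior: explicitly builds the
# n_s*n_p covariance and evaluates the normal density by Cholesky
dense_theta_logdens <- function(Theta, traits, community, C) {
  W <- community$rho * C + (1 - community$rho) * diag(nrow(C))
  V <- kronecker(community$Sigma, W)
  M <- traits$T %*% community$Z
  x <- as.vector(Theta - M)
  ch <- chol(V)
  z <- backsolve(ch, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# flat likelihood over a given species set
flat_likelihood <- function(species, n_p = 2) {
  new_jsmm_likelihood("flat", species,
                      param_names = paste0("p", seq_len(n_p)),
                      transforms = rep("identity", n_p),
                      loglik = function(sp, th) 0)
}

# conjugate normal toy: per-species iid N(theta, sd^2) observations
normal_toy_likelihood <- function(ys, sd = 1) {
  new_jsmm_likelihood("normal-toy", names(ys), "mu", "identity",
                      function(sp, th) {
                        y <- ys[[sp]]
                        sum(dnorm(y, th[1], sd, log = TRUE))
                      })
}
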