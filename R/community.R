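#' Community-level parameters of the hierarchical movement prior
#'
#' Bundles the three community-level quantities that govern how species-level
#' movement parameters are distributed: the trait loadings `Z` (one row per
#' trait design column, one column per movement parameter), the residual
#' covariance `Sigma` among movement parameters, and the phylogenetic weight
#' `rho` mixing the phylogenetic correlation `C` with an identity
#' (independent-species) correlation.
#'
#' The model for the `n_s x n_p` matrix of transformed species parameters
#' `Theta` is matrix-normal: `vec(Theta) ~ N(vec(T Z), Sigma (x) W)` with
#' `W = rho * C + (1 - rho) * I`. Vectorisation is column-major (species
#' index varies fastest within each parameter block), so the `W` factor acts
#' on species and `Sigma` on parameters.
#'
#' @param Z Numeric `n_t x n_p` matrix of trait loadings.
#' @param Sigma Symmetric positive-definite `n_p x n_p` matrix.
#' @param rho Scalar in \[0, 1\].
#' @return An object of class `jsmm_community`.
#' @export
jsmm_community <- function(Z, Sigma, rho) {
  Z <- as.matrix(Z); Sigma <- as.matrix(Sigma)
  assert_that(ncol(Z) == ncol(Sigma) && nrow(Sigma) == ncol(Sigma),
              "Z and Sigma disagree on the number of movement parameters")
  assert_that(is_spd(Sigma), "Sigma must be symmetric positive definite")
  assert_that(is.numeric(rho) && length(rho) == 1 && rho >= 0 && rho <= 1,
              "rho must be a scalar in [0, 1]")
  structure(list(Z = Z, Sigma = Sigma, rho = rho), class = "jsmm_community")
}

#' @export
print.jsmm_community <- function(x, ...) {
  cat(sprintf("<jsmm_community> n_t = %d, n_p = %d, rho = %.3f\n",
              nrow(x$Z), ncol(x$Z), x$rho))
  invisible(x)
}

#' Trait-based expectation of the species movement parameters
#'
#' Multiplies the trait design matrix by the loadings: row `s` of the result
#' is the expected (transformed) movement parameter vector for species `s`
#' given its traits. With an intercept-only design every species shares the
#' same expectation.
#'
#' @param traits A [trait_design()] object (or a bare design matrix).
#' @param Z Loadings matrix with one row per design column.
#' @return The `n_s x n_p` expectation matrix.
#' @export
expected_params <- function(traits, Z) {
  Tm <- if (inherits(traits, "jsmm_traits")) traits$T else as.matrix(traits)
  Z <- as.matrix(Z)
  if (ncol(Tm) != nrow(Z)) {
    stop_jsmm(sprintf(
      "shape mismatch: design has %d columns but Z has %d rows",
      ncol(Tm), nrow(Z)))
  }
  Tm %*% Z
}

# mixed species correlation W = rho C + (1 - rho) I, as an eigendecomposition.
# C's eigenvalues are floored at 1e-12 first: taxonomic trees with tied
# species give exactly singular C, and the floor keeps W invertible at rho = 1.
mix_correlation_eigen <- function(C, rho, floor = 1e-12) {
  eC <- sym_eigen(C, floor = floor)
  w <- rho * eC$values + (1 - rho)
  if (any(w <= 0)) {
    stop_jsmm("mixed correlation rho*C + (1-rho)*I is not positive definite")
  }
  list(vectors = eC$vectors, values = w, C_values = eC$values)
}

# core of the Kronecker-factored matrix-normal: given residuals R = Theta - M,
# eigen of W (on species) and Sigma, return the log-density without ever
# forming the n_s*n_p dense covariance. O(n_s^3 + n_p^3).
matnorm_logdens <- function(R, eW, Sigma) {
  n_s <- nrow(R); n_p <- ncol(R)
  eS <- sym_eigen(Sigma)
  assert_that(all(eS$values > 0), "Sigma must be positive definite")
  Rt <- crossprod(eW$vectors, R) %*% eS$vectors        # U' R V
  quad <- sum(sweep(sweep(Rt^2, 1, eW$values, `/`), 2, eS$values, `/`))
  logdet <- n_p * sum(log(eW$values)) + n_s * sum(log(eS$values))
  -0.5 * (n_s * n_p * log(2 * pi) + logdet + quad)
}

#' Log-density of the hierarchical prior on species parameters
#'
#' Evaluates `log N(vec(Theta); vec(T Z), Sigma (x) W)` with
#' `W = rho C + (1 - rho) I`, using the eigendecompositions of `W` (size
#' `n_s`) and `Sigma` (size `n_p`) so the dense `n_s n_p` covariance is never
#' formed.
#'
#' @param Theta `n_s x n_p` matrix of transformed species parameters.
#' @param traits [trait_design()] object (or design matrix) for the same
#'   species, in the same row order.
#' @param community [jsmm_community()] holding `Z`, `Sigma`, `rho`.
#' @param C Phylogenetic correlation matrix from [phylo_correlation()].
#' @return Scalar log-density.
#' @export
theta_log_prior <- function(Theta, traits, community, C) {
  Theta <- as.matrix(Theta)
  M <- expected_params(traits, community$Z)
  assert_that(all(dim(Theta) == dim(M)),
              "Theta dimensions disagree with traits/Z")
  assert_that(nrow(C) == nrow(Theta), "C dimension disagrees with Theta")
  eW <- mix_correlation_eigen(C, community$rho)
  matnorm_logdens(Theta - M, eW, community$Sigma)
}

#' Draw species parameters from the hierarchical prior
#'
#' Exact draw of `Theta` from the matrix-normal prior via the same
#' eigen-factorisation used by [theta_log_prior()].
#'
#' @inheritParams theta_log_prior
#' @return `n_s x n_p` matrix; row names are the species ids when `traits`
#'   carries them.
#' @export
sample_theta_prior <- function(traits, community, C) {
  M <- expected_params(traits, community$Z)
  n_s <- nrow(M); n_p <- ncol(M)
  eW <- mix_correlation_eigen(C, community$rho)
  eS <- sym_eigen(community$Sigma)
  E <- matrix(rnorm(n_s * n_p), n_s, n_p)
  A <- sweep(sweep(E, 1, sqrt(eW$values), `*`), 2, sqrt(pmax(eS$values, 0)), `*`)
  Theta <- M + eW$vectors %*% A %*% t(eS$vectors)
  if (inherits(traits, "jsmm_traits")) rownames(Theta) <- traits$species
  Theta
}

# conditional prior of one species' parameter row given all other rows.
# With precision Sigma^-1 (x) W^-1, row s | rest is N(mu_s, Sigma / Winv[s,s])
# with mu_s = M[s,] - (1 / Winv[s,s]) * sum_{s' != s} Winv[s,s'] (Theta - M)[s',].
row_conditional <- function(s, Theta, M, Winv, Sigma) {
  prec_ss <- Winv[s, s]
  resid <- Theta - M
  cross <- Winv[s, -s, drop = FALSE] %*% resid[-s, , drop = FALSE]
  mu <- M[s, ] - as.numeric(cross) / prec_ss
  list(mean = mu, cov = Sigma / prec_ss)
}
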