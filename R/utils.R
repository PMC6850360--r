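#' @importFrom stats rnorm runif dnorm quantile sd var setNames complete.cases
#'   optim rexp rWishart aggregate dist ppois qnorm cor wilcox.test ecdf
#' @importFrom utils head tail write.csv read.csv
#' @importFrom rlang .data abort
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
stop_jsmm <- function(msg, class = "jsmm_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_jsmm(msg)
  invisible(TRUE)
}

# symmetric-part eigen with small-eigenvalue floor; used for correlation mixing
sym_eigen <- function(S, floor = NULL) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (!is.null(floor)) e$values <- pmax(e$values, floor)
  e
}

is_spd <- function(S, tol = 1e-10) {
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) return(FALSE)
  all(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values > 0)
}

# multivariate normal draw with covariance given by its eigendecomposition
rmvnorm_eig <- function(n, mean, eig) {
  p <- length(mean)
  z <- matrix(rnorm(n * p), n, p)
  sqrt_vals <- sqrt(pmax(eig$values, 0))
  sweep(z %*% sweep(t(eig$vectors), 1, sqrt_vals, `*`), 2, mean, `+`)
}

dmvnorm_log <- function(x, mean, sigma) {
  p <- length(mean)
  ch <- chol(sigma)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}
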