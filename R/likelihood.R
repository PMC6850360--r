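#' Species-level likelihood interface
#'
#' The sampler is agnostic to the movement model: anything providing a
#' per-species log-likelihood of the transformed parameter vector can be
#' fitted. A likelihood object carries the parameter count and names, the
#' transformation of each parameter to its natural scale, the species list,
#' and a function `loglik(species, theta)` returning a finite value or `-Inf`
#' for structurally impossible parameters (`NaN` is treated as a bug and
#' raises an error inside the sampler).
#'
#' @param model Short model label (e.g. `"redistribution"`).
#' @param species Character vector of species ids with data.
#' @param param_names Names of the transformed parameters (length `n_p`).
#' @param transforms One of `"log"`, `"logit"`, `"identity"` per parameter.
#' @param loglik Function `(species, theta) -> numeric(1)`.
#' @param data Arbitrary backing data kept with the object.
#' @return An object of class `jsmm_likelihood`.
#' @export
new_jsmm_likelihood <- function(model, species, param_names, transforms,
                                loglik, data = list()) {
  assert_that(length(param_names) == length(transforms),
              "param_names and transforms must have equal length")
  assert_that(all(transforms %in% c("log", "logit", "identity")),
              "transforms must be log, logit or identity")
  structure(list(model = model, species = as.character(species),
                 n_p = length(param_names), param_names = param_names,
                 transforms = transforms, loglik = loglik, data = data),
            class = "jsmm_likelihood")
}

#' @export
print.jsmm_likelihood <- function(x, ...) {
  cat(sprintf("<jsmm_likelihood:%s> %d species, parameters: %s\n",
              x$model, length(x$species),
              paste(x$param_names, collapse = ", ")))
  invisible(x)
}

# evaluate with the NaN guard the sampler relies on
eval_loglik <- function(lik, species, theta) {
  v <- lik$loglik(species, theta)
  if (is.nan(v)) {
    stop_jsmm(sprintf(
      "likelihood returned NaN for species '%s' at theta = (%s)",
      species, paste(signif(theta, 4), collapse = ", ")))
  }
  v
}

# map a transformed parameter matrix to the natural scale, column-wise
natural_scale <- function(Theta, transforms) {
  out <- Theta
  for (j in seq_along(transforms)) {
    out[, j] <- switch(transforms[j],
      log = exp(Theta[, j]),
      logit = stats::plogis(Theta[, j]),
      identity = Theta[, j])
  }
  out
}
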