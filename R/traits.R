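#' Build the species trait design matrix
#'
#' Converts a per-species trait table into the design matrix of the community
#' layer: an intercept column of ones, continuous traits standardised to mean
#' zero and unit variance, and categorical traits expanded into indicator
#' columns against a reference level (the first factor level).
#'
#' @param data A data frame with one row per species.
#' @param species Name of the column holding unique species identifiers.
#'   Default `"species"`.
#'
#' @return An object of class `jsmm_traits`: a list with elements
#'   `T` (the `n_s x n_t` design matrix, first column all ones),
#'   `species` (character vector of ids, row order of `T`),
#'   `columns` (tibble describing each design column: `name`, `kind` one of
#'   `intercept`/`continuous`/`indicator`, and for standardised columns the
#'   original `center` and `scale`).
#'
#' @details Continuous standardisation is applied by the package rather than
#'   assumed of the caller, and the centring/scaling constants are recorded so
#'   trait-effect curves can be drawn on the original scale. A column with
#'   zero variance is rejected. Missing trait values are rejected.
#'
#' @examples
#' tr <- trait_design(
#'   data.frame(species = c("a", "b", "c"),
#'              mass = c(10, 20, 40), guild = c("gran", "frug", "frug")))
#' tr$T
#' @export
trait_design <- function(data, species = "species") {
  data <- as.data.frame(data)
  assert_that(species %in% names(data),
              sprintf("species id column '%s' not found", species))
  ids <- as.character(data[[species]])
  assert_that(!anyDuplicated(ids), "duplicated species ids in trait table")
  trait_cols <- setdiff(names(data), species)
  assert_that(all(complete.cases(data)), "trait table contains missing values")

  cols <- list(matrix(1, nrow(data), 1))
  meta <- list(tibble::tibble(name = "intercept", kind = "intercept",
                              center = NA_real_, scale = NA_real_))
  for (nm in trait_cols) {
    x <- data[[nm]]
    if (is.numeric(x)) {
      ctr <- mean(x); scl <- sd(x)
      assert_that(scl > 0, sprintf("trait '%s' has zero variance", nm))
      # population-sd convention so var of the stored column is exactly 1
      scl <- sqrt(mean((x - ctr)^2))
      cols <- c(cols, list(matrix((x - ctr) / scl, ncol = 1)))
      meta <- c(meta, list(tibble::tibble(name = nm, kind = "continuous",
                                          center = ctr, scale = scl)))
    } else {
      f <- factor(x)
      assert_that(nlevels(f) >= 2,
                  sprintf("categorical trait '%s' has a single level", nm))
      lev <- levels(f)
      ind <- sapply(lev[-1], function(l) as.numeric(f == l))
      ind <- matrix(ind, nrow = nrow(data))
      cols <- c(cols, list(ind))
      meta <- c(meta, list(tibble::tibble(
        name = paste0(nm, ":", lev[-1]), kind = "indicator",
        center = NA_real_, scale = NA_real_)))
    }
  }
  Tm <- do.call(cbind, cols)
  columns <- dplyr::bind_rows(meta)
  colnames(Tm) <- columns$name
  rownames(Tm) <- ids
  structure(list(T = Tm, species = ids, columns = columns),
            class = "jsmm_traits")
}

#' @export
print.jsmm_traits <- function(x, ...) {
  cat(sprintf("<jsmm_traits> %d species x %d design columns\n",
              nrow(x$T), ncol(x$T)))
  cat("columns:", paste(x$columns$name, collapse = ", "), "\n")
  invisible(x)
}

validate_traits <- function(traits) {
  assert_that(inherits(traits, "jsmm_traits"), "expected a jsmm_traits object")
  Tm <- traits$T
  assert_that(all(Tm[, 1] == 1), "first design column must be the intercept")
  cont <- which(traits$columns$kind == "continuous")
  for (j in cont) {
    assert_that(abs(mean(Tm[, j])) < 1e-8 && abs(mean(Tm[, j]^2) - 1) < 1e-8,
                "continuous trait columns must be standardised")
  }
  invisible(traits)
}
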