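#' Gridded habitat landscape
#'
#' A rectangular grid of habitat codes shared by both movement likelihoods:
#' `0` open, `1` semi-open, `2` forest. Cells are addressed by 1-based
#' `(row, col)` indices; cell centres are `cell_size` apart, with the centre
#' of cell `(1, 1)` at `origin`.
#'
#' @param habitat Integer matrix of habitat codes in `{0, 1, 2}`.
#' @param cell_size Cell side length in metres (> 0). Default 10.
#' @param origin Length-2 numeric, x/y coordinates (m) of the centre of cell
#'   `(1, 1)`. Default `c(0, 0)`.
#' @return An object of class `jsmm_landscape`.
#' @examples
#' L <- jsmm_landscape(matrix(c(0, 0, 2, 2), 2, 2), cell_size = 10)
#' @export
jsmm_landscape <- function(habitat, cell_size = 10, origin = c(0, 0)) {
  habitat <- as.matrix(habitat)
  storage.mode(habitat) <- "integer"
  bad <- which(!habitat %in% c(0L, 1L, 2L))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(habitat))
    stop_jsmm(sprintf("illegal habitat code %s at cell (%d, %d)",
                      habitat[bad[1]], rc[1], rc[2]))
  }
  assert_that(is.numeric(cell_size) && cell_size > 0, "cell_size must be > 0")
  assert_that(length(origin) == 2, "origin must be length 2")
  structure(list(habitat = habitat, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "jsmm_landscape")
}

#' @export
print.jsmm_landscape <- function(x, ...) {
  fr <- table(factor(x$habitat, levels = 0:2))
  cat(sprintf(
    "<jsmm_landscape> %d x %d cells of %g m (open %.0f%%, semi-open %.0f%%, forest %.0f%%)\n",
    nrow(x$habitat), ncol(x$habitat), x$cell_size,
    100 * fr[1] / length(x$habitat), 100 * fr[2] / length(x$habitat),
    100 * fr[3] / length(x$habitat)))
  invisible(x)
}

n_cells <- function(landscape) length(landscape$habitat)

# x/y coordinates (m) of every cell centre, in column-major cell order
cell_centers <- function(landscape) {
  nr <- nrow(landscape$habitat); nc <- ncol(landscape$habitat)
  h <- landscape$cell_size
  list(x = landscape$origin[1] + (rep(seq_len(nc), each = nr) - 1) * h,
       y = landscape$origin[2] + (rep(seq_len(nr), nc) - 1) * h)
}

cell_index <- function(landscape, row, col) {
  nr <- nrow(landscape$habitat); nc <- ncol(landscape$habitat)
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  if (!all(ok)) {
    stop_jsmm(sprintf("cell (%d, %d) outside the %d x %d landscape",
                      row[!ok][1], col[!ok][1], nr, nc))
  }
  (col - 1L) * nr + row
}

#' Tidy landscape raster
#'
#' @param landscape A [jsmm_landscape()].
#' @return Tibble with one row per cell: `row`, `col`, `x`, `y`, `habitat`
#'   (factor open/semi-open/forest).
#' @export
landscape_tbl <- function(landscape) {
  cc <- cell_centers(landscape)
  nr <- nrow(landscape$habitat)
  tibble::tibble(
    row = rep(seq_len(nr), ncol(landscape$habitat)),
    col = rep(seq_len(ncol(landscape$habitat)), each = nr),
    x = cc$x, y = cc$y,
    habitat = factor(c("open", "semi-open", "forest")[as.vector(landscape$habitat) + 1],
                     levels = c("open", "semi-open", "forest")))
}

#' Plot a habitat landscape
#'
#' @param landscape A [jsmm_landscape()].
#' @param tracks Optional track tibble (`individual`, `track`, `row`, `col`)
#'   overlaid as paths.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, tracks = NULL) {
  d <- landscape_tbl(landscape)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$habitat)) +
    ggplot2::scale_fill_manual(values = c(
      "open" = "grey85", "semi-open" = "khaki", "forest" = "darkgreen")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "habitat")
  if (!is.null(tracks)) {
    cc <- landscape
    tt <- dplyr::mutate(tracks,
      x = cc$origin[1] + (.data$col - 1) * cc$cell_size,
      y = cc$origin[2] + (.data$row - 1) * cc$cell_size)
    grp <- interaction(tt$individual, if ("track" %in% names(tt)) tt$track else 1)
    p <- p + ggplot2::geom_path(data = tt,
      ggplot2::aes(group = grp), colour = "red", linewidth = 0.3)
  }
  p
}
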