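#' Read a habitat landscape from an ESRI ASCII grid
#'
#' Accepts the standard header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`) followed by `nrows` rows of integer
#' habitat codes, top row first (highest y). Codes must be 0 (open),
#' 1 (semi-open) or 2 (forest); an illegal code is reported with its cell
#' location.
#'
#' @param path File path.
#' @return A [jsmm_landscape()]; row 1 is the southernmost (lowest y) row so
#'   cell centres increase with row/col index.
#' @export
read_landscape <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  assert_that(all(need %in% names(hdr)),
              paste("ASCII grid header must contain", paste(need, collapse = ", ")))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  assert_that(length(vals) == nr * nc, "ASCII grid body size disagrees with header")
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]   # file stores the top row first
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  jsmm_landscape(m, cell_size = hdr$cellsize,
                 origin = c(xll + hdr$cellsize / 2, yll + hdr$cellsize / 2))
}

#' Write a habitat landscape as an ESRI ASCII grid
#'
#' @param landscape A [jsmm_landscape()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  hab <- landscape$habitat
  h <- landscape$cell_size
  hdr <- c(
    sprintf("ncols %d", ncol(hab)),
    sprintf("nrows %d", nrow(hab)),
    sprintf("xllcorner %.6g", landscape$origin[1] - h / 2),
    sprintf("yllcorner %.6g", landscape$origin[2] - h / 2),
    sprintf("cellsize %.6g", h),
    "NODATA_value -9999")
  body <- apply(hab[nrow(hab):1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read movement tracks from a long-format CSV
#'
#' Expected columns: `species`, `individual`, `track`, `step`, `row`, `col`.
#'
#' @param path File path.
#' @param landscape Optional [jsmm_landscape()] used to bounds-check cells.
#' @return Tibble of locations.
#' @export
read_tracks <- function(path, landscape = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("species", "individual", "track", "step", "row", "col")
  assert_that(all(need %in% names(d)),
              paste("tracks CSV needs columns:", paste(need, collapse = ", ")))
  if (!is.null(landscape)) cell_index(landscape, d$row, d$col)
  d
}

#' Read a trap table, activity schedule, and capture events
#'
#' `read_traps` expects `trap`, `x`, `y` columns; `read_schedule` a CSV with
#' one row per night and one 0/1 column per trap (column order matching the
#' trap table); `read_captures` the event list with `individual`, `species`,
#' `night`, `trap`, `event`.
#'
#' @param traps_path,schedule_path Paths for [jsmm_traps()] ingredients.
#' @param radius Attraction radius passed to [jsmm_traps()].
#' @return `read_cmr_config`: a [jsmm_traps()]; `read_captures`: a tibble.
#' @export
read_cmr_config <- function(traps_path, schedule_path, radius = 30) {
  traps <- readr::read_csv(traps_path, show_col_types = FALSE)
  sched <- as.matrix(readr::read_csv(schedule_path, show_col_types = FALSE))
  jsmm_traps(traps, sched, radius = radius)
}

#' @rdname read_cmr_config
#' @param path Captures CSV path.
#' @export
read_captures <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("individual", "species", "night", "trap", "event")
  assert_that(all(need %in% names(d)),
              paste("captures CSV needs columns:", paste(need, collapse = ", ")))
  d
}

#' Read a species trait table and build the design matrix
#'
#' @param path CSV with a `species` column; remaining columns are traits
#'   (numeric = continuous, text = categorical).
#' @return A [trait_design()] object.
#' @export
read_traits <- function(path) {
  trait_design(readr::read_csv(path, show_col_types = FALSE))
}

#' Read a Newick phylogeny
#'
#' Thin wrapper over [ape::read.tree()] with an explicit parse error.
#'
#' @param path Newick file path.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) {
    stop_jsmm(sprintf("could not parse Newick file '%s'", path))
  }
  tree
}

#' Write a synthetic data bundle to disk
#'
#' Serialises every component of a [generate_dataset()] bundle in the
#' formats the readers consume: traits CSV, Newick tree, correlation CSV,
#' ESRI ASCII landscape, tracks or traps/schedule/captures CSVs, and a truth
#' CSV set for recovery scoring.
#'
#' @param bundle A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- c(traits = p("traits.csv"), tree = p("tree.nwk"),
             landscape = p("landscape.asc"),
             theta = p("truth_theta.csv"), z = p("truth_z.csv"),
             community = p("truth_community.csv"))
  readr::write_csv(bundle$traits_tbl, files["traits"])
  ape::write.tree(bundle$tree, files["tree"])
  write_landscape(bundle$landscape, files["landscape"])
  th <- as.data.frame(bundle$truth$Theta)
  th <- cbind(species = rownames(bundle$truth$Theta), th)
  readr::write_csv(th, files["theta"])
  readr::write_csv(as.data.frame(bundle$truth$Z), files["z"])
  readr::write_csv(
    data.frame(rho = bundle$truth$rho,
               sigma = I(apply(bundle$truth$Sigma, 1, paste, collapse = ";"))),
    files["community"])
  if (!is.null(bundle$tracks)) {
    files["tracks"] <- p("tracks.csv")
    readr::write_csv(bundle$tracks, files["tracks"])
  }
  if (!is.null(bundle$captures)) {
    files["traps"] <- p("traps.csv")
    files["schedule"] <- p("schedule.csv")
    files["captures"] <- p("captures.csv")
    readr::write_csv(bundle$traps$traps, files["traps"])
    readr::write_csv(as.data.frame(bundle$traps$schedule), files["schedule"])
    readr::write_csv(bundle$captures, files["captures"])
  }
  files
}

#' Load and validate a full model input bundle
#'
#' Reads traits, phylogeny and data files, enforces every container's
#' invariants, and reconciles the species sets: species present in the data
#' but missing from the traits or tree are an error (strict default) or
#' dropped with a report when `allow_drop = TRUE`.
#'
#' @param model `"redistribution"` or `"diffusion"`.
#' @param traits_path Traits CSV.
#' @param tree_path Newick tree (or `ranks_path` for a taxonomy CSV with
#'   columns species/genus/subfamily/family).
#' @param landscape_path ESRI ASCII landscape.
#' @param tracks_path Tracks CSV (redistribution).
#' @param traps_path,schedule_path,captures_path CMR inputs (diffusion).
#' @param ranks_path Taxonomic rank CSV, used when `tree_path` is `NULL`.
#' @param radius Trap attraction radius (m).
#' @param allow_drop Drop data for species missing from traits/tree instead
#'   of erroring. Default `FALSE`.
#' @return List with `likelihood` (ready for [fit_jsmm()]), `traits`, `C`,
#'   `landscape`, plus the raw data tables; `dropped` reports any dropped
#'   species ids.
#' @export
read_inputs <- function(model = c("redistribution", "diffusion"),
                        traits_path, tree_path = NULL, landscape_path,
                        tracks_path = NULL, traps_path = NULL,
                        schedule_path = NULL, captures_path = NULL,
                        ranks_path = NULL, radius = 30, allow_drop = FALSE) {
  model <- match.arg(model)
  traits <- read_traits(traits_path)
  tree <- if (!is.null(tree_path)) {
    read_newick(tree_path)
  } else {
    assert_that(!is.null(ranks_path), "need either tree_path or ranks_path")
    taxonomy_tree(readr::read_csv(ranks_path, show_col_types = FALSE))
  }
  missing_tips <- setdiff(traits$species, tree$tip.label)
  assert_that(length(missing_tips) == 0,
              paste("species missing from the tree:",
                    paste(missing_tips, collapse = ", ")))
  C <- phylo_correlation(tree)[traits$species, traits$species]
  landscape <- read_landscape(landscape_path)
  dropped <- character(0)
  if (model == "redistribution") {
    tracks <- read_tracks(tracks_path, landscape)
    unknown <- setdiff(unique(tracks$species), traits$species)
    if (length(unknown)) {
      if (!allow_drop) {
        stop_jsmm(paste("species in tracks but not in traits:",
                        paste(unknown, collapse = ", ")))
      }
      dropped <- unknown
      tracks <- dplyr::filter(tracks, !.data$species %in% unknown)
    }
    lik <- redistribution_likelihood(landscape, tracks)
    data_tbl <- tracks
  } else {
    traps <- read_cmr_config(traps_path, schedule_path, radius = radius)
    captures <- read_captures(captures_path)
    unknown <- setdiff(unique(captures$species), traits$species)
    if (length(unknown)) {
      if (!allow_drop) {
        stop_jsmm(paste("species in captures but not in traits:",
                        paste(unknown, collapse = ", ")))
      }
      dropped <- unknown
      captures <- dplyr::filter(captures, !.data$species %in% unknown)
    }
    lik <- diffusion_likelihood(landscape, traps, captures)
    data_tbl <- captures
  }
  list(likelihood = lik, traits = traits, C = C, landscape = landscape,
       tree = tree, data = data_tbl, dropped = dropped)
}

#' Write posterior draws to labelled CSV archives
#'
#' One long-format CSV per parameter block (`theta.csv`, `loadings.csv`,
#' `sigma.csv`, `rho.csv`) with chain and iteration columns, readable with
#' any CSV tool.
#'
#' @param fit A `jsmm_fit`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_posterior <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  for (block in c("theta", "loadings", "sigma", "rho")) {
    f <- file.path(dir, paste0(block, ".csv"))
    readr::write_csv(posterior_draws(fit, block), f)
    files[block] <- f
  }
  files
}

#' Write a species correlation matrix as labelled CSV
#'
#' @param C Correlation matrix with species dimnames (from
#'   [phylo_correlation()]).
#' @param path Output path; first column `species`, one column per species.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(C, path) {
  d <- as.data.frame(C)
  d <- cbind(species = rownames(C), d)
  readr::write_csv(d, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, before sampling starts, everything needed to reproduce a run:
#' the configuration, the input files with their checksums, the seed, and
#' the package version.
#'
#' @param dir Output directory.
#' @param config List of configuration values (serialised as JSON).
#' @param inputs Named character vector of input file paths.
#' @param seed Integer seed.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, inputs, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  checksums <- vapply(inputs, function(f) {
    if (file.exists(f)) as.character(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(
    package = "jsmm",
    version = as.character(utils::packageVersion("jsmm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config,
    inputs = as.list(checksums))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
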