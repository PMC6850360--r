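#' Phylogenetic correlation matrix from an ultrametric tree
#'
#' Builds the species-by-species correlation matrix whose entry for two
#' species is the proportion of evolutionary history they share: the depth
#' from the root to their most recent common ancestor divided by the total
#' root-to-tip depth. Under a Brownian (diffusion) model of trait evolution
#' this is exactly the correlation of the two species' trait values, which is
#' the role the matrix plays in the community layer.
#'
#' @param tree An ultrametric `phylo` object (e.g. read with
#'   [ape::read.tree()]). Branch lengths required; a root edge, if present,
#'   is ignored (it is shared by every species and cancels from the
#'   proportion). Polytomies are handled naturally.
#' @param tol Relative tolerance for the ultrametricity check on root-to-tip
#'   depths. Default `1e-6`.
#'
#' @return A symmetric correlation matrix with unit diagonal, entries in
#'   \[0, 1\], and `dimnames` set to the tip labels.
#'
#' @details Non-ultrametric trees are rejected rather than normalised: the
#'   proportion of shared history is only well defined when all tips are
#'   equidistant from the root. The error names the most divergent tips.
#'
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylo_correlation(tr)  # A-B share half their history; C shares none
#' @export
phylo_correlation <- function(tree, tol = 1e-6) {
  assert_that(inherits(tree, "phylo"), "expected an ape 'phylo' tree")
  n <- length(tree$tip.label)
  assert_that(n >= 2, "tree must have at least two tips")
  assert_that(!anyDuplicated(tree$tip.label),
              "duplicated tip labels in tree")
  assert_that(!is.null(tree$edge.length), "tree has no branch lengths")
  # unary nodes (e.g. taxonomy chains) confuse MRCA lookup; collapsing them
  # sums the branch lengths and leaves every pairwise MRCA depth unchanged.
  # A unary chain above the first split is shared history and is kept (it
  # ends up in root.edge after collapsing); an explicit root edge in the
  # input, by contrast, is ignored.
  input_root_edge <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  tree <- ape::collapse.singles(tree, root.edge = TRUE)
  shared_stem <- max((if (is.null(tree$root.edge)) 0 else tree$root.edge) -
                       input_root_edge, 0)
  depth <- ape::node.depth.edgelength(tree) + shared_stem  # root = 0
  tip_depth <- depth[seq_len(n)]
  total <- max(tip_depth)
  assert_that(total > 0, "tree has zero total depth")
  rel <- abs(tip_depth - total) / total
  if (any(rel > tol)) {
    bad <- tree$tip.label[order(rel, decreasing = TRUE)]
    stop_jsmm(sprintf(
      "tree is not ultrametric (max relative depth deviation %.3g); most divergent tips: %s",
      max(rel), paste(head(bad, 3), collapse = ", ")))
  }
  anc <- ape::mrca(tree)
  C <- matrix(depth[anc], n, n) / total
  diag(C) <- 1
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  validate_correlation(C)
  C
}

#' Ultrametric taxonomy tree from a rank table
#'
#' When no quantitative phylogeny is available, a taxonomic classification can
#' stand in: species are nested in genus, subfamily and family, and the four
#' levels are given equal branch lengths (each 1/4 of the total depth). Two
#' congeners then correlate at 0.75, two species of the same subfamily but
#' different genera at 0.5, same family different subfamily at 0.25, and
#' different families at 0.
#'
#' @param ranks Data frame with columns `species`, `genus`, `subfamily`,
#'   `family` (character), one row per species, no missing entries.
#'
#' @return An ultrametric `phylo` object of total depth 1 whose tips are the
#'   species ids; pass it to [phylo_correlation()].
#'
#' @examples
#' rk <- data.frame(species = c("s1", "s2", "s3"),
#'                  genus = c("g1", "g1", "g2"),
#'                  subfamily = c("u1", "u1", "u1"),
#'                  family = c("f1", "f1", "f1"))
#' C <- phylo_correlation(taxonomy_tree(rk))
#' C["s1", "s2"]  # congeners: 0.75
#' @export
taxonomy_tree <- function(ranks) {
  ranks <- as.data.frame(ranks)
  need <- c("species", "genus", "subfamily", "family")
  assert_that(all(need %in% names(ranks)),
              paste("rank table needs columns:", paste(need, collapse = ", ")))
  assert_that(all(complete.cases(ranks[need])), "rank table has missing entries")
  assert_that(!anyDuplicated(ranks$species), "duplicated species in rank table")
  # each rank must nest uniquely in the rank above
  chk <- function(child, parent, what) {
    tab <- unique(ranks[, c(child, parent)])
    dup <- tab[[child]][duplicated(tab[[child]])]
    assert_that(length(dup) == 0,
                sprintf("%s '%s' appears under multiple %ss",
                        child, paste(unique(dup), collapse = ", "), parent))
  }
  chk("genus", "subfamily", "subfamily")
  chk("subfamily", "family", "family")

  q <- function(x) {
    bad <- grepl("[(),:;'\\s\\[\\]]", x, perl = TRUE)
    assert_that(!any(bad),
                sprintf("rank labels may not contain Newick metacharacters: %s",
                        paste(unique(x[bad]), collapse = ", ")))
    x
  }
  genus_nwk <- vapply(split(ranks, ranks$genus), function(d) {
    sprintf("(%s)%s:0.25",
            paste0(q(d$species), ":0.25", collapse = ","), q(d$genus[1]))
  }, character(1))
  genus_of <- vapply(split(ranks$subfamily, ranks$genus), `[`, character(1), 1)
  sub_nwk <- vapply(split(names(genus_nwk), genus_of), function(g) {
    sf <- genus_of[g[1]]
    sprintf("(%s)%s:0.25", paste(genus_nwk[g], collapse = ","), q(sf))
  }, character(1))
  sub_of <- vapply(split(ranks$family, ranks$subfamily), `[`, character(1), 1)
  fam_nwk <- vapply(split(names(sub_nwk), sub_of[names(sub_nwk)]), function(s) {
    fam <- sub_of[s[1]]
    sprintf("(%s)%s:0.25", paste(sub_nwk[s], collapse = ","), q(fam))
  }, character(1))
  # root sits above the family level so the family branch counts as shared
  # history; with a single family this yields a (harmless) unary root child
  nwk <- sprintf("(%s)root;", paste(fam_nwk, collapse = ","))
  ape::read.tree(text = nwk)
}

validate_correlation <- function(C, tol = 1e-10) {
  assert_that(is.matrix(C) && nrow(C) == ncol(C), "C must be square")
  assert_that(max(abs(C - t(C))) <= 1e-8, "C must be symmetric")
  assert_that(max(abs(diag(C) - 1)) <= 1e-8, "C must have unit diagonal")
  assert_that(min(C) >= -1e-8 && max(C) <= 1 + 1e-8,
              "C entries must lie in [0, 1]")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) >= -tol, "C must be positive semidefinite")
  invisible(C)
}
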