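#' Visible crown cover from a stem map with height-ranked occlusion
#'
#' Rasterizes a plot at a sub-pixel grid and assigns every cell to the
#' crown disc (centre = stem, radius = crown diameter / 2) of the tallest
#' tree covering it, giving top-of-canopy ("as seen from above") cover per
#' species. Crowns may extend past the plot edge but are clipped to the
#' plot; height ties are broken by tree record order (earlier record wins).
#'
#' @param trees data.frame with `species`, `x_m`, `y_m` (plot-local metres,
#'   origin at the plot's lower-left corner), `crown_diameter_m`,
#'   `height_m`; all trees of one plot.
#' @param plotSide plot edge length (m).
#' @param resolution rasterization cell size (m), at most 0.5.
#' @return list with `perSpecies` (named visible cover fractions),
#'   `total` (total crown fraction), `perTree` (visible fraction per tree
#'   record) and `resolution`.
#' @examples
#' tr <- data.frame(species = "a", x_m = 10, y_m = 10,
#'                  crown_diameter_m = 2, height_m = 10)
#' visibleCrownCover(tr, 20, 0.1)$total  # ~ pi / 400
#' @export
visibleCrownCover <- function(trees, plotSide, resolution = 0.1) {
  stopIfNot(is.numeric(resolution) && length(resolution) == 1L &&
              resolution > 0, "'resolution' must be a positive number")
  stopIfNot(resolution <= 0.5, "'resolution' must be <= 0.5 m (sub-pixel)")
  need <- c("species", "x_m", "y_m", "crown_diameter_m", "height_m")
  stopIfNot(all(need %in% names(trees)),
            "'trees' must have columns %s", paste(need, collapse = ", "))
  stopIfNot(all(trees$crown_diameter_m > 0) && all(trees$height_m > 0),
            "crown diameters and heights must be positive")

  owner <- crownOwnership(trees, plotSide, resolution)
  nCells <- length(owner)
  perTree <- tabulate(owner[owner > 0L], nbins = max(nrow(trees), 1L)) / nCells
  species <- unique(as.character(trees$species))
  perSpecies <- vapply(species, function(sp)
    sum(perTree[trees$species == sp]), numeric(1L))
  list(perSpecies = perSpecies, total = sum(perTree),
       perTree = perTree, resolution = resolution)
}

#' Combine tree-crown cover with rescaled understory cover
#'
#' Understory (plants below the crown layer) is only visible from above on
#' the area not covered by tree crowns, so its percentages are rescaled by
#' `1 - crownFraction` before being added to the visible crown cover. A
#' species present in both layers is summed. Understory rows whose
#' percentages sum above 100 are rescaled to 100 with a warning.
#'
#' @param treeCover named numeric, per-species visible crown cover in
#'   percent (e.g. `100 * visibleCrownCover(...)$perSpecies`).
#' @param understory named numeric, per-species understory percent cover.
#' @param crownFraction total crown fraction in \[0, 1\] (defaults to
#'   `sum(treeCover) / 100`).
#' @return named numeric, combined top-of-canopy percent cover.
#' @examples
#' combineCover(c(oak = 40), c(fern = 50), crownFraction = 0.4)
#' @export
combineCover <- function(treeCover, understory,
                         crownFraction = sum(treeCover) / 100) {
  stopIfNot(crownFraction >= 0 && crownFraction <= 1 + 1e-9,
            "'crownFraction' must lie in [0, 1]")
  crownFraction <- min(crownFraction, 1)
  stopIfNot(all(understory >= 0) && all(treeCover >= 0),
            "cover percentages must be non-negative")
  if (sum(understory) > 100 + 1e-9) {
    warning("understory percentages sum above 100; rescaled to 100")
    understory <- understory / sum(understory) * 100
  }
  species <- union(names(treeCover), names(understory))
  out <- stats::setNames(numeric(length(species)), species)
  out[names(treeCover)] <- treeCover
  out[names(understory)] <- out[names(understory)] +
    understory * (1 - crownFraction)
  out
}

#' Species richness of a cover row
#'
#' Number of species with positive cover; invariant under rescaling.
#'
#' @param cover numeric vector of per-species cover.
#' @return integer count.
#' @export
richness <- function(cover) {
  as.integer(sum(cover > 0))
}

#' Shannon diversity index (nats)
#'
#' `H = -sum p_i log p_i` over relative covers `p_i`; 0 for a monoculture,
#' at most `log(richness)`.
#'
#' @param cover numeric vector of per-species cover; must have positive sum
#'   (all-zero rows are undefined and return NA with a warning).
#' @return numeric H in nats.
#' @examples
#' shannon(rep(25, 4))  # log(4)
#' @export
shannon <- function(cover) {
  s <- sum(cover)
  if (s <= 0) {
    warning("Shannon index undefined for an all-zero cover row")
    return(NA_real_)
  }
  p <- cover[cover > 0] / s
  -sum(p * log(p))
}

#' Phylogenetic covariance matrix of an ultrametric tree
#'
#' `C[i, j]` is the shared root-to-tip path length of tips i and j (the
#' depth of their most recent common ancestor); the diagonal is the tip
#' depth. After normalization by the tree depth the diagonal is 1 and `C`
#' is the phylogenetic correlation matrix used by [pse()]. Computed by a
#' direct traversal: node depths from the edge lengths, tip pairs assigned
#' the depth of the node where their lineages split.
#'
#' @param phylogeny an ultrametric [ape::phylo].
#' @param normalize divide by tree depth so the diagonal is 1 (default
#'   TRUE).
#' @return symmetric positive semidefinite matrix, tips x tips, dimnames =
#'   tip labels.
#' @examples
#' C <- phyloCovariance(simulatePhylogeny(4, seed = 1))
#' diag(C)
#' @export
phyloCovariance <- function(phylogeny, normalize = TRUE) {
  stopIfNot(inherits(phylogeny, "phylo"), "'phylogeny' must be an ape phylo")
  phylogeny <- stats::reorder(phylogeny, "cladewise")  # parents before children
  nTip <- length(phylogeny$tip.label)
  nNode <- nTip + phylogeny$Nnode
  edge <- phylogeny$edge
  len <- phylogeny$edge.length

  depth <- numeric(nNode)
  for (e in seq_len(nrow(edge))) {
    depth[edge[e, 2L]] <- depth[edge[e, 1L]] + len[e]
  }
  tipDepth <- depth[seq_len(nTip)]
  treeDepth <- max(tipDepth)
  stopIfNot(all(abs(tipDepth - treeDepth) <= 1e-9 * max(treeDepth, 1)),
            "'phylogeny' must be ultrametric")

  # tips descending from every node
  kids <- split(edge[, 2L], edge[, 1L])
  tipsUnder <- vector("list", nNode)
  for (i in seq_len(nTip)) tipsUnder[[i]] <- i
  # process internal nodes deepest-first so children are resolved
  internal <- (nTip + 1L):nNode
  for (nd in internal[order(depth[internal], decreasing = TRUE)]) {
    tipsUnder[[nd]] <- unlist(tipsUnder[kids[[as.character(nd)]]],
                              use.names = FALSE)
  }

  C <- matrix(0, nTip, nTip,
              dimnames = list(phylogeny$tip.label, phylogeny$tip.label))
  diag(C) <- tipDepth
  for (nd in internal) {
    ch <- kids[[as.character(nd)]]
    if (length(ch) < 2L) next
    for (a in seq_len(length(ch) - 1L)) for (b in (a + 1L):length(ch)) {
      ta <- tipsUnder[[ch[a]]]; tb <- tipsUnder[[ch[b]]]
      C[ta, tb] <- depth[nd]
      C[tb, ta] <- depth[nd]
    }
  }
  if (normalize) C <- C / treeDepth
  C
}

#' Phylogenetic species evenness
#'
#' Abundance-weighted phylogenetic evenness of a community: with abundance
#' vector m (total M) and phylogenetic correlation matrix C (unit
#' diagonal),
#' `PSE = (M * sum(m * diag(C)) - m' C m) / (M^2 - sum(m^2))`.
#' It equals 1 on a star phylogeny for any abundances and reduces to
#' phylogenetic species variability (PSV) under equal abundances. When a
#' list of trees is supplied, PSE is averaged over them (emulating
#' replicate phylogeny reconstructions).
#'
#' @param cover named numeric, per-species abundance (percent cover); at
#'   least 2 species must have positive cover, otherwise NA with a warning.
#' @param phylogeny an ultrametric [ape::phylo], a list of them, or a
#'   precomputed covariance matrix with unit diagonal.
#' @return numeric PSE in (0, 1\].
#' @examples
#' tr <- simulatePhylogeny(4, seed = 1)
#' pse(c(sp01 = 30, sp02 = 20, sp03 = 10, sp04 = 40), tr)
#' @export
pse <- function(cover, phylogeny) {
  if (is.list(phylogeny) && !inherits(phylogeny, "phylo"))
    return(mean(vapply(phylogeny, function(tr) pse(cover, tr), numeric(1L))))
  C <- if (is.matrix(phylogeny)) phylogeny else phyloCovariance(phylogeny)
  m <- cover[cover > 0]
  if (length(m) < 2L) {
    warning("PSE undefined for fewer than 2 species with positive cover")
    return(NA_real_)
  }
  miss <- setdiff(names(m), rownames(C))
  stopIfNot(length(miss) == 0L, "species missing from the tree: %s",
            paste(miss, collapse = ", "))
  C <- C[names(m), names(m)]
  stopIfNot(max(abs(diag(C) - 1)) <= 1e-8,
            "'C' must have unit diagonal (depth-normalized tree)")
  M <- sum(m)
  (M * sum(m * diag(C)) - drop(m %*% C %*% m)) / (M^2 - sum(m^2))
}

#' Phylogenetic species variability (equal-abundance limit of PSE)
#'
#' `PSV = (n^2 - sum(C)) / (n * (n - 1))` over the species present.
#'
#' @inheritParams pse
#' @return numeric PSV.
#' @export
psv <- function(cover, phylogeny) {
  C <- if (is.matrix(phylogeny)) phylogeny else phyloCovariance(phylogeny)
  sp <- names(cover)[cover > 0]
  if (length(sp) < 2L) {
    warning("PSV undefined for fewer than 2 species")
    return(NA_real_)
  }
  C <- C[sp, sp]
  n <- length(sp)
  (n^2 - sum(C)) / (n * (n - 1))
}

#' Per-plot taxonomic and phylogenetic alpha-diversity
#'
#' Species richness, Shannon index and PSE for every row of a combined
#' cover matrix.
#'
#' @param cover plots x species matrix of combined top-of-canopy percent
#'   cover.
#' @param phylogeny tree(s) passed to [pse()]; a list is averaged over.
#' @return data.frame: `plot_id`, `richness`, `shannon`, `pse`.
#' @export
diversityTable <- function(cover, phylogeny) {
  stopIfNot(is.matrix(cover) && !is.null(colnames(cover)),
            "'cover' must be a matrix with species column names")
  out <- data.frame(plot_id = rownames(cover),
                    richness = apply(cover, 1L, richness),
                    shannon = apply(cover, 1L, shannon),
                    pse = apply(cover, 1L, function(r)
                      pse(stats::setNames(r, colnames(cover)), phylogeny)))
  rownames(out) <- NULL
  out
}

#' Hellinger transformation of a community matrix
#'
#' `y[i, j] = sqrt(cover[i, j] / rowSum_i)`: every transformed row has unit
#' Euclidean norm, making the subsequent Euclidean distance the Hellinger
#' distance (invariant to row totals, bounded by sqrt(2)). Zero-sum rows
#' are excluded with a warning.
#'
#' @param cover plots x species matrix of non-negative cover.
#' @return transformed matrix (possibly with fewer rows).
#' @export
hellingerTransform <- function(cover) {
  stopIfNot(is.matrix(cover) && all(cover >= 0),
            "'cover' must be a non-negative matrix")
  s <- rowSums(cover)
  if (any(s == 0)) {
    warning(sprintf("%d zero-sum rows excluded from the Hellinger transform",
                    sum(s == 0)))
    cover <- cover[s > 0, , drop = FALSE]
    s <- s[s > 0]
  }
  sqrt(cover / s)
}

#' Taxonomic beta-diversity: Hellinger distances among plots
#'
#' Euclidean distances among Hellinger-transformed cover rows; entries lie
#' in \[0, sqrt(2)\], with sqrt(2) for two monocultures of different
#' species.
#'
#' @param x a plots x species cover matrix (transformed internally) or an
#'   already Hellinger-transformed matrix.
#' @param transformed set TRUE if `x` is already transformed.
#' @return symmetric distance matrix with zero diagonal.
#' @examples
#' taxonomicBetaDistances(rbind(a = c(10, 0), b = c(0, 99)))  # sqrt(2)
#' @export
taxonomicBetaDistances <- function(x, transformed = FALSE) {
  h <- if (transformed) x else hellingerTransform(x)
  stopIfNot(nrow(h) >= 2L, "need at least 2 plots")
  as.matrix(stats::dist(h))
}
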