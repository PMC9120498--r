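# Ordinary least squares of y on x with the standard slope t-test.
# Returns NAs (with a message) when the regressor has zero variance.
olsFit <- function(x, y) {
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) {
    if (n >= 3L) message("regressor has zero variance; slope undefined")
    return(data.frame(n = n, slope = NA_real_, intercept = NA_real_,
                      r2 = NA_real_, t = NA_real_, p = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(n = n,
             slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             r2 = sm$r.squared,
             t = sm$coefficients[2L, "t value"],
             p = sm$coefficients[2L, "Pr(>|t|)"])
}

lowerTriangle <- function(m) m[lower.tri(m)]

#' Regression of spectral on taxonomic distances
#'
#' Ordinary least squares of spectral beta-distance on taxonomic
#' (Hellinger) beta-distance for one site. `scope = "pairwise"` uses every
#' unordered plot pair once; `scope = "per-plot"` regresses each plot's
#' mean distance to all other plots (one point per plot). Inference is the
#' standard OLS slope t-test, applied to distance pairs exactly as in the
#' field's practice even though pairs sharing a plot are not independent;
#' `mantel = TRUE` replaces the p-value with a Mantel-style permutation
#' p-value (plots of the taxonomic matrix permuted jointly in rows and
#' columns), which respects that dependence.
#'
#' @param spectral,taxonomic symmetric distance matrices with matching plot
#'   ids in their dimnames.
#' @param scope `"pairwise"` (default) or `"per-plot"`.
#' @param mantel logical; permutation inference instead of the naive
#'   t-test p (pairwise scope only).
#' @param nPerm permutations for `mantel = TRUE` (default 999).
#' @param seed seed for the permutations.
#' @return one-row data.frame: `scope`, `n`, `slope`, `intercept`, `r2`,
#'   `t`, `p`.
#' @examples
#' tax <- as.matrix(dist(1:4)); dimnames(tax) <- list(letters[1:4], letters[1:4])
#' distanceRegression(2 * tax, tax)  # slope 2, r2 1
#' @export
distanceRegression <- function(spectral, taxonomic,
                               scope = c("pairwise", "per-plot"),
                               mantel = FALSE, nPerm = 999, seed = NULL) {
  scope <- match.arg(scope)
  stopIfNot(is.matrix(spectral) && is.matrix(taxonomic),
            "'spectral' and 'taxonomic' must be distance matrices")
  stopIfNot(!is.null(rownames(spectral)) &&
              identical(rownames(spectral), rownames(taxonomic)),
            "matrices must share identical plot ids")
  if (scope == "pairwise") {
    x <- lowerTriangle(taxonomic)
    y <- lowerTriangle(spectral)
  } else {
    n <- nrow(taxonomic)
    x <- (rowSums(taxonomic)) / (n - 1)
    y <- (rowSums(spectral)) / (n - 1)
  }
  out <- olsFit(x, y)
  if (mantel && scope == "pairwise" && !is.na(out$slope)) {
    obs <- stats::cor(x, y)
    n <- nrow(taxonomic)
    perms <- withSeed(seed, replicate(nPerm, {
      p <- sample.int(n)
      stats::cor(lowerTriangle(taxonomic[p, p]), y)
    }))
    out$p <- (1 + sum(abs(perms) >= abs(obs))) / (nPerm + 1)
  }
  cbind(scope = scope, out)
}

#' Pool distance pairs across sites
#'
#' Fits one OLS of spectral on taxonomic distance over the unordered plot
#' pairs of several sites pooled together (the across-sites scope), and
#' optionally returns the per-site fits alongside.
#'
#' @param spectralList,taxonomicList named lists of per-site distance
#'   matrices (matching names and plot ids).
#' @param perSite also return one row per site (default TRUE).
#' @return data.frame with a row `scope = "across-sites"` and, when
#'   requested, one `"per-site"` row per site (site in `site`).
#' @export
pooledDistanceRegression <- function(spectralList, taxonomicList,
                                     perSite = TRUE) {
  stopIfNot(identical(names(spectralList), names(taxonomicList)),
            "site lists must have matching names")
  xs <- unlist(lapply(taxonomicList, lowerTriangle), use.names = FALSE)
  ys <- unlist(lapply(spectralList, lowerTriangle), use.names = FALSE)
  out <- cbind(site = "all", scope = "across-sites", olsFit(xs, ys))
  if (perSite) {
    rows <- lapply(names(spectralList), function(s)
      cbind(site = s,
            distanceRegression(spectralList[[s]], taxonomicList[[s]])))
    out <- rbind(out, do.call(rbind, rows))
  }
  out$scope[out$scope == "pairwise" & out$site != "all"] <- "per-site"
  rownames(out) <- NULL
  out
}

#' Regressions of plant alpha-diversity on spectral alpha-diversity by LAI
#' class
#'
#' Stratifies plots into leaf-area-index classes and fits, per class and
#' per diversity metric (richness, Shannon, PSE), an OLS of the plant
#' metric on SD_alpha. Default class bounds are the printed quartile
#' classes `[0.13, 0.634], (0.634, 1.183], (1.183, 1.84], (1.84, 3.80]`;
#' the first class includes its left endpoint. Classes with fewer than 3
#' plots are skipped with a warning.
#'
#' @param alpha data.frame from [spectralAlpha()] (`plot_id`, `sd_alpha`).
#' @param diversity data.frame from [diversityTable()] (`plot_id`,
#'   `richness`, `shannon`, `pse`).
#' @param lai data.frame with `plot_id`, `lai`.
#' @param breaks increasing numeric class bounds (length k + 1 for k
#'   classes).
#' @return data.frame: `lai_class`, `lower`, `upper`, `metric`, `n`,
#'   `slope`, `intercept`, `r2`, `t`, `p`.
#' @export
laiClassRegressions <- function(alpha, diversity, lai,
                                breaks = c(0.13, 0.634, 1.183, 1.84, 3.80)) {
  stopIfNot(!is.unsorted(breaks, strictly = TRUE),
            "'breaks' must be strictly increasing")
  d <- merge(merge(alpha, diversity, by = "plot_id"), lai, by = "plot_id")
  cls <- cut(d$lai, breaks = breaks, include.lowest = TRUE)
  metrics <- c("richness", "shannon", "pse")
  out <- list()
  for (k in seq_len(length(breaks) - 1L)) {
    sel <- which(as.integer(cls) == k)
    if (length(sel) < 3L) {
      warning(sprintf("LAI class %d has %d plots (< 3); skipped",
                      k, length(sel)))
      next
    }
    for (m in metrics) {
      keep <- sel[!is.na(d[[m]][sel])]
      if (length(keep) < 3L) next
      out[[length(out) + 1L]] <-
        cbind(lai_class = k, lower = breaks[k], upper = breaks[k + 1L],
              metric = m, olsFit(d$sd_alpha[keep], d[[m]][keep]))
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
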