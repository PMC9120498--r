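#' Simulate plot communities along an environmental gradient
#'
#' Plots are placed evenly on a 1-d environmental gradient in \[0, 1\].
#' Species respond with Gaussian niches: species i has a random optimum
#' `opt_i ~ U(0, 1)`, a random niche width, and a random (log-normal)
#' baseline abundance; its expected abundance in a plot at gradient position
#' g is `base_i * exp(-gradientStrength * (g - opt_i)^2 / (2 * width_i^2))`,
#' multiplied by per-plot log-normal noise. Abundances are converted to
#' percent cover summing to `totalCover` per plot. With
#' `gradientStrength = 0` the niche term vanishes and communities are
#' exchangeable (identically distributed) regardless of gradient position.
#'
#' @param nPlots number of plots (>= 2).
#' @param library a [SpeciesLibrary-class]; its species ids name the columns.
#' @param gradientStrength non-negative; 0 = no compositional turnover along
#'   the gradient, 1 = the default strong-turnover setting.
#' @param seed integer seed.
#' @param totalCover per-plot total percent cover target (default 90, so row
#'   sums stay below 100).
#' @param noiseSd standard deviation of the per-plot log-normal abundance
#'   noise (on the log scale; default 0.4).
#' @return list with `cover` (plots x species percent-cover matrix, rows
#'   named `plot01`, ...) and `gradient` (named numeric positions).
#' @examples
#' tr <- simulatePhylogeny(5, seed = 1)
#' lib <- simulateEndmembers(tr, seq(400, 2400, by = 50), seed = 1)
#' cm <- simulateCommunities(6, lib, gradientStrength = 1, seed = 3)
#' rowSums(cm$cover)
#' @export
simulateCommunities <- function(nPlots, library, gradientStrength = 1,
                                seed = NULL, totalCover = 90,
                                noiseSd = 0.4) {
  nPlots <- checkCount(nPlots, "nPlots", min = 2L)
  stopIfNot(is(library, "SpeciesLibrary") && nrow(library@spectra) > 0L,
            "'library' must be a non-empty SpeciesLibrary")
  stopIfNot(length(gradientStrength) == 1L && gradientStrength >= 0,
            "'gradientStrength' must be a single non-negative number")
  stopIfNot(totalCover > 0 && totalCover <= 100,
            "'totalCover' must be in (0, 100]")
  species <- rownames(library@spectra)
  nSp <- length(species)
  withSeed(seed, {
    grad <- if (nPlots == 1L) 0.5 else seq(0, 1, length.out = nPlots)
    opt <- stats::runif(nSp)
    width <- stats::runif(nSp, 0.15, 0.35)
    base <- stats::rlnorm(nSp, meanlog = 0, sdlog = 0.5)
    niche <- exp(-gradientStrength *
                   outer(grad, opt, "-")^2 / rep(2 * width^2, each = nPlots))
    noise <- matrix(stats::rlnorm(nPlots * nSp, 0, noiseSd), nPlots, nSp)
    abun <- sweep(niche, 2L, base, "*") * noise
    cover <- abun / rowSums(abun) * totalCover
    dimnames(cover) <- list(sprintf("plot%02d", seq_len(nPlots)), species)
    names(grad) <- rownames(cover)
    list(cover = cover, gradient = grad)
  })
}
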