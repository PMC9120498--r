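test_that("a fully occluded shorter tree has zero visible cover", {
  trees <- data.frame(species = c("tall", "short"),
                      x_m = 10, y_m = 10,
                      crown_diameter_m = 4, height_m = c(10, 5))
  cc <- visibleCrownCover(trees, 20, 0.1)
  expect_equal(unname(cc$perSpecies["short"]), 0)
  expect_gt(cc$perSpecies[["tall"]], 0)
})

test_that("height ties are broken by record order", {
  trees <- data.frame(species = c("first", "second"),
                      x_m = 10, y_m = 10,
                      crown_diameter_m = 4, height_m = 8)
  cc <- visibleCrownCover(trees, 20, 0.1)
  expect_equal(unname(cc$perSpecies["second"]), 0)
})

test_that("a single centred crown recovers the analytic circle area", {
  trees <- data.frame(species = "a", x_m = 10, y_m = 10,
                      crown_diameter_m = 2, height_m = 10)
  cc <- visibleCrownCover(trees, 20, 0.05)
  expect_equal(cc$total, pi * 1^2 / 400, tolerance = 0.02)
})

test_that("disjoint crowns match the exact polygon-clipping oracle", {
  trees <- data.frame(species = c("a", "b", "c"),
                      x_m = c(4, 12, 19), y_m = c(4, 12, 19),
                      crown_diameter_m = c(3, 4, 3),
                      height_m = c(10, 12, 9))
  cc <- visibleCrownCover(trees, 20, 0.05)
  exact <- unlist(shapelyVisibleAreas(list(trees), 20)[[1]]) / 400
  expect_equal(unname(cc$perTree), exact, tolerance = 0.02)
})

test_that("rasterized cover converges towards finer resolutions", {
  set.seed(41)
  for (i in 1:5) {
    trees <- randomStemMap(5)
    coarse <- visibleCrownCover(trees, 20, 0.2)$total
    fine <- visibleCrownCover(trees, 20, 0.05)$total
    expect_equal(coarse, fine, tolerance = 0.02)
  }
  expect_error(visibleCrownCover(randomStemMap(2), 20, 0.6), "0.5")
  expect_error(visibleCrownCover(randomStemMap(2), 20, -1), "positive")
})

test_that("understory is rescaled to the open area and layers combine", {
  u <- c(fern = 50, moss = 30)
  expect_equal(combineCover(numeric(0), u, 0), u)
  expect_equal(unname(combineCover(c(oak = 100), u, 1)["fern"]), 0)
  comb <- combineCover(c(oak = 40), c(oak = 10, fern = 50), 0.4)
  expect_equal(unname(comb["oak"]), 40 + 10 * 0.6)
  expect_equal(unname(comb["fern"]), 30)
  expect_lte(sum(comb), 100)
  expect_warning(combineCover(c(oak = 10), c(fern = 120, moss = 30), 0.1),
                 "rescaled")
})

test_that("richness counts positive covers and ignores scale", {
  expect_equal(richness(c(0, 0, 0)), 0L)
  expect_equal(richness(c(10, 0, 5)), 2L)
  r <- runif(8)
  expect_equal(richness(r), richness(r * 13.7))
})

test_that("Shannon index matches its closed forms and entropy bound", {
  expect_equal(shannon(c(80, 0, 0)), 0)
  expect_equal(shannon(rep(25, 4)), log(4), tolerance = 1e-12)
  expect_warning(expect_true(is.na(shannon(c(0, 0)))), "undefined")
  set.seed(42)
  for (i in 1:10) {
    row <- runif(6) * rbinom(6, 1, 0.7)
    if (sum(row) == 0) next
    expect_lte(shannon(row), log(richness(row)) + 1e-12)
    expect_equal(shannon(row), vegan::diversity(row, "shannon"),
                 tolerance = 1e-12)
  }
})

test_that("the phylogenetic covariance has unit diagonal and matches ape", {
  tr <- simulatePhylogeny(12, seed = 43)
  C <- phyloCovariance(tr)
  expect_equal(unname(diag(C)), rep(1, 12))
  V <- ape::vcv.phylo(tr)[rownames(C), colnames(C)]
  expect_equal(C, V / max(V), tolerance = 1e-10)
})

test_that("star and cherry trees give their closed-form covariances", {
  C <- phyloCovariance(starTree(5))
  expect_equal(unname(C), diag(5), tolerance = 1e-12)
  # 3 tips, cherry (a,b) splitting at depth 0.5
  tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:1);")
  C3 <- phyloCovariance(tr)
  expect_equal(C3["a", "b"], 0.5)
  expect_equal(C3["a", "c"], 0)
})

test_that("species absent from the tree are reported by name", {
  tr <- simulatePhylogeny(3, seed = 44)
  expect_error(pse(c(sp01 = 10, weird = 5), tr), "weird")
})

test_that("PSE is 1 on star phylogenies and reduces to PSV when even", {
  expect_equal(pse(c(sp01 = 50, sp02 = 10, sp03 = 1), starTree(3)), 1,
               tolerance = 1e-12)
  tr <- simulatePhylogeny(8, seed = 45)
  even <- setNames(rep(12.5, 8), tr$tip.label)
  expect_equal(pse(even, tr), psv(even, tr), tolerance = 1e-12)
})

test_that("PSE matches the literal formula on random abundances", {
  for (seed in 46:48) {
    tr <- simulatePhylogeny(10, seed = seed)
    set.seed(seed)
    m <- setNames(rlnorm(10), tr$tip.label)
    expect_equal(pse(m, tr), bfPSE(m, phyloCovariance(tr)),
                 tolerance = 1e-10)
  }
})

test_that("PSE matches picante where the abundance weightings coincide", {
  # under equal abundances every published PSE variant reduces to PSV
  for (seed in 46:48) {
    tr <- simulatePhylogeny(9, seed = seed)
    m <- setNames(rep(5, 9), tr$tip.label)
    comm <- matrix(m, 1, dimnames = list("p1", names(m)))
    expect_equal(pse(m, tr), picante::pse(comm, tr)$PSEs[[1]],
                 tolerance = 1e-8)
  }
})

test_that("PSE drops as abundance concentrates on one clade", {
  # two clades split at the root: weight w on clade A, 1 - w on clade B
  tr <- ape::read.tree(
    text = "((a:0.2,b:0.2):0.8,(c:0.2,d:0.2):0.8);")
  vals <- vapply(seq(0.5, 0.95, by = 0.05), function(w)
    pse(c(a = w / 2, b = w / 2, c = (1 - w) / 2, d = (1 - w) / 2) * 100, tr),
    numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("PSE averages over a list of replicate phylogenies", {
  trs <- lapply(1:3, function(i) simulatePhylogeny(6, seed = 50 + i))
  m <- setNames(runif(6, 1, 10), trs[[1]]$tip.label)
  expect_equal(pse(m, trs),
               mean(vapply(trs, function(t) pse(m, t), numeric(1))),
               tolerance = 1e-12)
})

test_that("Hellinger transform and distances obey their closed forms", {
  h <- hellingerTransform(rbind(a = c(10, 30), b = c(1, 3)))
  expect_equal(h["a", ], h["b", ], tolerance = 1e-12)  # same composition
  expect_true(all(abs(rowSums(h^2) - 1) < 1e-12))
  d <- taxonomicBetaDistances(rbind(a = c(10, 0), b = c(0, 99)))
  expect_equal(d["a", "b"], sqrt(2), tolerance = 1e-12)
  expect_warning(hellingerTransform(rbind(c(1, 2), c(0, 0))), "zero-sum")
})

test_that("Hellinger distances match the naive oracle and vegan", {
  set.seed(51)
  cover <- matrix(rlnorm(24), 6, 4,
                  dimnames = list(paste0("p", 1:6), paste0("s", 1:4)))
  d <- taxonomicBetaDistances(cover)
  expect_equal(d, bfHellinger(cover), tolerance = 1e-12)
  dv <- as.matrix(dist(vegan::decostand(cover, "hellinger")))
  expect_equal(unname(d), unname(dv), tolerance = 1e-10)
  expect_true(all(d >= 0 & d <= sqrt(2) + 1e-12))
  expect_equal(d, taxonomicBetaDistances(cover * 3), tolerance = 1e-12)
})

test_that("diversityTable assembles the per-plot metrics", {
  tr <- simulatePhylogeny(5, seed = 52)
  cover <- matrix(c(10, 20, 0, 5, 0,
                    25, 25, 25, 25, 0), 2, 5, byrow = TRUE,
                  dimnames = list(c("p1", "p2"), tr$tip.label))
  dt <- diversityTable(cover, tr)
  expect_equal(dt$richness, c(3L, 4L))
  expect_equal(dt$shannon[2], log(4), tolerance = 1e-12)
  expect_equal(dt$pse[1], pse(setNames(cover[1, ], tr$tip.label), tr))
})
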