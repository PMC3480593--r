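tx4 <- c("a", "b", "c", "d")

# two-locus fixture with constant per-pair k and V within each locus
gds2 <- makeGds(
  kList = list(g1 = pairMatrix(tx4, 0.1), g2 = pairMatrix(tx4, 0.3)),
  vList = list(g1 = pairMatrix(tx4, 0.01), g2 = pairMatrix(tx4, 0.02)),
  L = c(g1 = 300, g2 = 100), taxa = tx4)

test_that("no-weight weights are post-deletion length proportions", {
  ws <- noweightWeights(gds2)
  expect_equal(weights(ws), c(g1 = 0.75, g2 = 0.25))

  one <- makeGds(list(g = pairMatrix(tx4, 0.1)), list(g = pairMatrix(tx4, 0.01)),
                 c(g = 50), tx4)
  expect_equal(weights(noweightWeights(one)), c(g = 1))

  ten <- makeGds(setNames(replicate(10, pairMatrix(tx4, .1), simplify = FALSE),
                          paste0("g", 1:10)),
                 setNames(replicate(10, pairMatrix(tx4, .01), simplify = FALSE),
                          paste0("g", 1:10)),
                 setNames(rep(200, 10), paste0("g", 1:10)), tx4)
  expect_equal(unname(weights(noweightWeights(ten))), rep(0.1, 10))
})

test_that("least-squares weights are per-pair inverse variances", {
  ws <- lsWeights(gds2)
  expect_identical(ws@granularity, "per_gene_pair")
  W <- weights(ws)
  expect_equal(unname(W["g1", ]), rep(2 / 3, 6), tolerance = 1e-12)
  expect_equal(unname(W["g2", ]), rep(1 / 3, 6), tolerance = 1e-12)
  expect_equal(unname(colSums(W)), rep(1, 6))

  # equal variances -> equal weights
  eq <- makeGds(list(g1 = pairMatrix(tx4, .1), g2 = pairMatrix(tx4, .2)),
                list(g1 = pairMatrix(tx4, .05), g2 = pairMatrix(tx4, .05)),
                c(g1 = 100, g2 = 100), tx4)
  expect_true(all(abs(weights(lsWeights(eq)) - 0.5) < 1e-12))
})

test_that("inverse-variance weights minimize the pooled variance (grid oracle)", {
  v <- c(0.01, 0.02)
  w <- weights(lsWeights(gds2))[, 1]
  cand <- rbind(simplexGrid(2, 10000), w)
  obj <- cand^2 %*% v
  expect_lte(sum(w^2 * v), min(obj) + 1e-9)
})

test_that("zero-variance estimates dominate strongly but not absolutely", {
  V1 <- pairMatrix(tx4, 0.01); V1["a", "b"] <- V1["b", "a"] <- 0
  gz <- makeGds(list(g1 = pairMatrix(tx4, 0.1), g2 = pairMatrix(tx4, 0.3)),
                list(g1 = V1, g2 = pairMatrix(tx4, 0.02)),
                c(g1 = 300, g2 = 100), tx4)
  W <- weights(lsWeights(gz))
  # the zero-variance gene is charged the smallest resolvable divergence's
  # variance (p* = 1/(2L)), so it dominates the pair without zeroing g2
  vstar <- (1 / 600) / (300 * (1 - 1 / 600))
  expect_equal(unname(W["g1", "a|b"]),
               (1 / vstar) / (1 / vstar + 1 / 0.02), tolerance = 1e-12)
  expect_gt(W["g1", "a|b"], 0.999)
  expect_gt(W["g2", "a|b"], 0)
  expect_equal(unname(W["g1", "a|c"]), 2 / 3, tolerance = 1e-12)

  # fully invariant gene under mls: warned, huge but finite weight, and the
  # informative genes keep enough weight to set the topology
  inv <- makeGds(list(g1 = pairMatrix(tx4, 0), g2 = pairMatrix(tx4, 0.2)),
                 list(g1 = pairMatrix(tx4, 0), g2 = pairMatrix(tx4, 0.004)),
                 c(g1 = 300, g2 = 300), tx4)
  expect_warning(wi <- mlsWeights(inv), "invariant")
  expect_gt(weights(wi)[["g1"]], 0.99)
  expect_lt(weights(wi)[["g1"]], 1)
  D <- pooledMatrix(poolDistances(inv, wi))
  expect_true(all(D[upper.tri(D)] > 0))
})

test_that("modified Tajima-Takezaki weights are mean-k over mean-V, normalized", {
  g <- makeGds(list(g1 = pairMatrix(tx4, 0.1), g2 = pairMatrix(tx4, 0.1)),
               list(g1 = pairMatrix(tx4, 0.001), g2 = pairMatrix(tx4, 0.004)),
               c(g1 = 100, g2 = 100), tx4)
  expect_equal(weights(mttWeights(g)), c(g1 = 0.8, g2 = 0.2), tolerance = 1e-12)

  # identical (mu, v) -> equal weights
  same <- makeGds(list(g1 = pairMatrix(tx4, .2), g2 = pairMatrix(tx4, .2)),
                  list(g1 = pairMatrix(tx4, .01), g2 = pairMatrix(tx4, .01)),
                  c(g1 = 100, g2 = 100), tx4)
  expect_equal(unname(weights(mttWeights(same))), c(0.5, 0.5))

  # all-zero distances: fall back to length weighting with a warning
  zero <- makeGds(list(g1 = pairMatrix(tx4, 0), g2 = pairMatrix(tx4, 0)),
                  list(g1 = pairMatrix(tx4, 0), g2 = pairMatrix(tx4, 0)),
                  c(g1 = 300, g2 = 100), tx4)
  expect_warning(wz <- mttWeights(zero), "no-weight")
  expect_equal(weights(wz), c(g1 = 0.75, g2 = 0.25))
})

test_that("modified TT weights maximize the accuracy index (grid oracle)", {
  set.seed(9)
  mus <- runif(5, 0.05, 0.4)
  vs <- runif(5, 5e-4, 8e-3)
  g <- makeGds(setNames(lapply(mus, pairMatrix, taxa = tx4), paste0("g", 1:5)),
               setNames(lapply(vs, pairMatrix, taxa = tx4), paste0("g", 1:5)),
               setNames(rep(100, 5), paste0("g", 1:5)), tx4)
  w <- weights(mttWeights(g))
  A <- accuracyIndex(w, mus, vs)
  gridA <- apply(simplexGrid(5, 10000), 1, accuracyIndex, mus = mus, vars = vs)
  expect_gte(A, max(gridA) - 1e-9)
})

test_that("modified least-squares weights are inverse mean variances", {
  g <- makeGds(list(g1 = pairMatrix(tx4, 0.1), g2 = pairMatrix(tx4, 0.1)),
               list(g1 = pairMatrix(tx4, 0.002), g2 = pairMatrix(tx4, 0.008)),
               c(g1 = 100, g2 = 100), tx4)
  expect_equal(weights(mlsWeights(g)), c(g1 = 0.8, g2 = 0.2), tolerance = 1e-12)
  w <- weights(mlsWeights(g))
  v <- c(0.002, 0.008)
  obj <- simplexGrid(2, 10000)^2 %*% v
  expect_lte(sum(w^2 * v), min(obj) + 1e-9)

  ten <- makeGds(setNames(replicate(10, pairMatrix(tx4, .1), simplify = FALSE),
                          paste0("g", 1:10)),
                 setNames(replicate(10, pairMatrix(tx4, .01), simplify = FALSE),
                          paste0("g", 1:10)),
                 setNames(rep(100, 10), paste0("g", 1:10)), tx4)
  expect_equal(unname(weights(mlsWeights(ten))), rep(0.1, 10))
})

test_that("a nearly invariant gene draws the largest modified-LS weight", {
  # gene 1: zero differences except pairs involving taxon d (tRNA-Met-like)
  k1 <- pairMatrix(tx4, c(0, 0, 0.02, 0, 0.02, 0.02)) # pairs ab,ac,ad,bc,bd,cd
  v1 <- pairMatrix(tx4, c(0, 0, 2e-4, 0, 2e-4, 2e-4))
  g <- makeGds(list(met = k1, g2 = pairMatrix(tx4, 0.15),
                    g3 = pairMatrix(tx4, 0.2)),
               list(met = v1, g2 = pairMatrix(tx4, 3e-3),
                    g3 = pairMatrix(tx4, 5e-3)),
               c(met = 70, g2 = 300, g3 = 300), tx4)
  w <- weights(mlsWeights(g))
  expect_identical(names(which.max(w)), "met")
  expect_true(is.finite(w[["met"]]) && w[["met"]] < 1)
})

test_that("pooling is a per-pair convex combination of gene distances", {
  # single gene: pooled matrix equals that gene's k
  one <- makeGds(list(g = pairMatrix(tx4, c(.1, .2, .3, .4, .5, .6))),
                 list(g = pairMatrix(tx4, .01)), c(g = 100), tx4)
  D1 <- pooledMatrix(poolDistances(one, noweightWeights(one)))
  expect_equal(D1, distanceMatrix(one, "g"))

  # equal weights: arithmetic mean
  eqw <- new("WeightScheme", method = "mls", granularity = "per_gene",
             weights = c(g1 = 0.5, g2 = 0.5), taxa = tx4)
  expect_equal(unname(pooledMatrix(poolDistances(gds2, eqw))["a", "b"]), 0.2)

  # per-pair LS weights compose with pooling
  Dls <- pooledMatrix(poolDistances(gds2, lsWeights(gds2)))
  expect_equal(unname(Dls["a", "b"]), (2 / 3) * 0.1 + (1 / 3) * 0.3,
               tolerance = 1e-12)

  # convexity on random inputs, plus the equal-information collapse
  set.seed(21)
  for (i in 1:5) {
    kl <- list(g1 = pairMatrix(tx4, runif(6, 0, .5)),
               g2 = pairMatrix(tx4, runif(6, 0, .5)),
               g3 = pairMatrix(tx4, runif(6, 0, .5)))
    vl <- list(g1 = pairMatrix(tx4, runif(6, 1e-4, 1e-2)),
               g2 = pairMatrix(tx4, runif(6, 1e-4, 1e-2)),
               g3 = pairMatrix(tx4, runif(6, 1e-4, 1e-2)))
    g <- makeGds(kl, vl, c(g1 = 100, g2 = 150, g3 = 80), tx4)
    kmin <- pmin(kl$g1, kl$g2, kl$g3); kmax <- pmax(kl$g1, kl$g2, kl$g3)
    for (m in c("noweight", "ls", "mtt", "mls")) {
      D <- pooledMatrix(poolDistances(g, computeWeights(g, m)))
      expect_true(all(D >= kmin - 1e-12 & D <= kmax + 1e-12))
    }
  }
  collapse <- makeGds(list(g1 = pairMatrix(tx4, c(.1, .2, .3, .4, .5, .6)),
                           g2 = pairMatrix(tx4, c(.1, .2, .3, .4, .5, .6))),
                      list(g1 = pairMatrix(tx4, .01),
                           g2 = pairMatrix(tx4, .01)),
                      c(g1 = 100, g2 = 100), tx4)
  Ds <- lapply(c("noweight", "ls", "mtt", "mls"), function(m)
    pooledMatrix(poolDistances(collapse, computeWeights(collapse, m))))
  for (i in 2:4) expect_equal(Ds[[i]], Ds[[1]], tolerance = 1e-12)
})

test_that("weights are normalized within every pair under every method", {
  set.seed(33)
  cfg <- simConfig(tree = "A", nLoci = 6, locusLengths = 120,
                   alphabet = "AA", u = 0.4, a = 0.5)
  gds <- distanceMatrices(simulateDataset(cfg, seed = 33), "poisson",
                          clamp = TRUE)
  for (m in c("noweight", "ls", "mtt", "mls")) {
    ws <- suppressWarnings(computeWeights(gds, m))
    if (ws@granularity == "per_gene") {
      expect_equal(sum(weights(ws)), 1, tolerance = 1e-9)
      expect_true(all(weights(ws) >= 0))
    } else {
      expect_equal(unname(colSums(weights(ws))), rep(1, choose(8, 2)),
                   tolerance = 1e-9)
      expect_true(all(weights(ws) >= 0))
    }
  }
})

test_that("the accuracy index follows its definition and scale invariance", {
  expect_equal(accuracyIndex(1, 0.2, 0.004), 0.2 / sqrt(0.004))
  w <- c(0.8, 0.2); mus <- c(0.1, 0.1); vs <- c(0.001, 0.004)
  A <- accuracyIndex(w, mus, vs)
  expect_equal(A, 0.1 / sqrt(0.64 * 0.001 + 0.04 * 0.004), tolerance = 1e-12)
  expect_equal(A, 3.536, tolerance = 1e-3)
  expect_equal(accuracyIndex(10 * w, mus, vs), A, tolerance = 1e-12)
  expect_error(accuracyIndex(c(0, 0), mus, vs), "all-zero")
})

test_that("the weight report covers every locus and method", {
  rep <- suppressWarnings(weightReport(gds2))
  expect_equal(nrow(rep), 2 * 4)
  expect_true(all(abs(tapply(rep$weight, rep$method, sum) - 1) < 1e-9))
})
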