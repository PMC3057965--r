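test_that("genotype simulation respects the map", {
  map <- data.frame(marker = c("a", "b", "c"), chromosome = "1",
                    position_cM = c(0, 0, 8))
  nam <- simulateNAMGenotypes(map, famSizes = c(F1 = 400), seed = 90)
  g <- genotypes(nam)
  expect_identical(g[1, ], g[2, ])           # 0 cM apart: always identical
  # allele frequency 0.5 within binomial error
  map2 <- makeGridMap(nChrom = 1, chromLength = 20, spacing = 5)
  nam2 <- simulateNAMGenotypes(map2, famSizes = c(F1 = 2000), seed = 91)
  freq <- rowMeans(genotypes(nam2))
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 2000)))
  # realised recombinant fraction matches ril(haldane(5 cM))
  g2 <- genotypes(nam2)
  Rhat <- mean(g2[1, ] != g2[2, ])
  R <- rilScale(haldane(5))
  expect_lt(abs(Rhat - R), 3 * sqrt(R * (1 - R) / 2000))
  # bit-for-bit reproducible
  expect_identical(genotypes(simulateNAMGenotypes(map2, c(F1 = 50), seed = 7)),
                   genotypes(simulateNAMGenotypes(map2, c(F1 = 50), seed = 7)))
})

test_that("two-locus simulated class frequencies match the enumeration oracle", {
  set.seed(92)
  dists <- c(1.3, 4, 12, 25, 60)
  for (i in seq_along(dists)) {
    map <- data.frame(marker = c("a", "b"), chromosome = "1",
                      position_cM = c(0, dists[i]))
    nam <- simulateNAMGenotypes(map, famSizes = c(F1 = 4000), seed = 92 + i)
    g <- genotypes(nam)
    # marginalise the oracle's middle locus: put the QTL on the left marker
    q <- oracleThreeLocusRIL(0, haldane(dists[i]))
    pSame <- (q[1] + q[3]) + (q[6] + q[8])  # haplotypes with equal outer loci
    expect_lt(abs(mean(g[1, ] == g[2, ]) - pSame), 3 * sqrt(0.25 / 4000))
  }
})

test_that("QTL placement follows the two scenarios", {
  sim <- smallSim(a = 0, fams = 2, n = 50, seed = 93)
  nam <- sim$nam
  pq <- placeQTL(nam, "on_marker", 4)
  expect_identical(pq$geno, unname(genotypes(nam)[4, ]))
  expect_equal(pq$position_cM, geneticMap(nam)$position_cM[4])
  # identical flanks copy deterministically
  g <- genotypes(nam)
  iv <- jicim:::.intervalTable(nam)
  k <- iv$left[3]
  same <- g[k, ] == g[k + 1, ]
  pq2 <- placeQTL(nam, "mid_interval", 3, seed = 5)
  expect_identical(pq2$geno[same], unname(g[k, same]))
  # the coin is fair over lines
  bigNam <- simulateNAMGenotypes(
    data.frame(marker = c("a", "b"), chromosome = "1",
               position_cM = c(0, 50)),
    famSizes = c(F1 = 10000), seed = 94)
  gb <- genotypes(bigNam)
  pq3 <- placeQTL(bigNam, "mid_interval", 1, seed = 6)
  diff <- gb[1, ] != gb[2, ]
  fracLeft <- mean(pq3$geno[diff] == gb[1, diff])
  expect_lt(abs(fracLeft - 0.5), 3 * sqrt(0.25 / sum(diff)))
  expect_error(placeQTL(nam, "on_marker", 10000), "out of range")
})

test_that("noise-background phenotypes have the requested variances", {
  fam <- factor(rep(c("F1", "F2"), each = 4000))
  famVar <- c(2.61, 5.41)
  g <- rbinom(8000, 1, 0.5)
  # no QTL: per-family variance ~ V_Pf
  y0 <- phenotypeNoiseBackground(fam, famVar, matrix(0, 1, 2),
                                 matrix(g, ncol = 1), seed = 95)
  v <- tapply(y0, fam, var)
  for (f in 1:2)
    expect_lt(abs(v[f] - famVar[f]),
              3 * famVar[f] * sqrt(2 / 4000))   # chi-square sampling error
  # rare QTL a = 1.5 in the V = 5.41 family adds a^2 on top
  eff <- matrix(c(0, 1.5), 1, 2)
  y1 <- phenotypeNoiseBackground(fam, famVar, eff, matrix(g, ncol = 1),
                                 seed = 96)
  expect_lt(abs(var(y1[fam == "F2"]) - (5.41 + 2.25)),
            3 * 7.66 * sqrt(2 / 4000))
  expect_lt(abs(var(y1[fam == "F1"]) - 2.61), 3 * 2.61 * sqrt(2 / 4000))
  # linked-pair recipe keeps the total variance at V_Pf
  eff2 <- rbind(c(1, 1), c(0.8, 0.8))
  g2 <- cbind(g, rbinom(8000, 1, 0.5))
  y2 <- phenotypeNoiseBackground(fam, famVar, eff2, g2,
                                 mode = "linked_pair", seed = 97)
  v2 <- tapply(y2, fam, var)
  for (f in 1:2)
    expect_lt(abs(v2[f] - famVar[f]), 3 * famVar[f] * sqrt(2 / 4000))
  # degenerate linked pair equals pure noise variance
  y3 <- phenotypeNoiseBackground(fam, famVar, matrix(0, 1, 2),
                                 matrix(g, ncol = 1), mode = "linked_pair",
                                 seed = 95)
  expect_identical(y3, y0)
  expect_error(
    phenotypeNoiseBackground(fam, c(1, 1), rbind(c(1, 1)),
                             matrix(g, ncol = 1), mode = "linked_pair"),
    "infeasible")
})

test_that("real-background phenotypes add the QTL term only where it segregates", {
  set.seed(98)
  fam <- factor(rep(c("F1", "F2"), each = 100))
  y <- rnorm(200)
  g <- rbinom(200, 1, 0.5)
  expect_identical(phenotypeRealBackground(y, fam, c(0, 0), g), y)
  y2 <- phenotypeRealBackground(y, fam, c(0, 1.2), g)
  expect_identical(y2[fam == "F1"], y[fam == "F1"])
  seg <- fam == "F2"
  d <- mean(y2[seg & g == 1]) - mean(y2[seg & g == 0]) -
    (mean(y[seg & g == 1]) - mean(y[seg & g == 0]))
  expect_equal(d, 2 * 1.2, tolerance = 1e-10)
})
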