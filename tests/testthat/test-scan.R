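test_that("degenerate mixture (QTL on a marker) equals closed-form group fits", {
  set.seed(40)
  fam <- factor(rep(c("f1", "f2"), each = 50))
  cls <- rbinom(100, 1, 0.5)
  y <- 2 * cls * rep(c(1, 0.5), each = 50) + rnorm(100, sd = 0.7)
  fit <- emFit(y, fam, classProb = as.numeric(cls))
  expect_true(fit$converged)
  # with 0/1 priors the posterior equals the prior and one M-step is exact
  mu0hat <- sum(tapply(y[cls == 0], fam[cls == 0], sum) /
                  fit$sigma2) / sum(tapply(cls == 0, fam, sum) / fit$sigma2)
  expect_equal(fit$mu0, mu0hat, tolerance = 1e-5)
  for (f in levels(fam))
    expect_equal(unname(fit$mu[f]), mean(y[cls == 1 & fam == f]),
                 tolerance = 1e-8)
})

test_that("F=1 EM matches the brute-force grid oracle", {
  set.seed(41)
  for (rep in 1:3) {
    n <- 60
    p <- runif(n, 0.05, 0.95)
    z <- rbinom(n, 1, p)
    y <- ifelse(z == 1, 1.2, -0.6) + rnorm(n, sd = 1.1)
    fit <- emFit(y, factor(rep("f", n)), p)
    expect_lt(abs(fit$logLA - oracleGridLogL(y, p)), 1e-4)
  }
})

test_that("EM log-likelihood is monotone over iterations", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 80
    fam <- factor(rep(c("a", "b"), each = 40))
    p <- runif(n, 0.02, 0.98)
    y <- rnorm(n) + ifelse(rbinom(n, 1, p) == 1, 1.5, 0)
    tr <- emFit(y, fam, p, trace = TRUE)$trace
    expect_true(all(diff(tr) > -1e-8))
  }
})

test_that("constant phenotype gives zero LOD and equal means", {
  y <- rep(3.3, 40)
  fam <- factor(rep("f", 40))
  p <- runif(40, 0.1, 0.9)
  fit <- emFit(y, fam, p)
  null <- nullFit(y, fam)
  expect_equal(unname(fit$mu["f"]), 3.3, tolerance = 1e-6)
  expect_equal(fit$mu0, 3.3, tolerance = 1e-6)
  expect_equal(lodScore(fit, null), 0)
})

test_that("null fit is the per-family ML normal fit and is additive", {
  f <- nullFit(c(0, 2), factor(c("a", "a")))
  expect_equal(unname(f$mean), 1)
  expect_equal(unname(f$variance), 1)       # ML divisor n
  y <- c(0, 2, 0, 2)
  f2 <- nullFit(y, factor(c("a", "a", "b", "b")))
  expect_equal(f2$logL0, 2 * f$logL0)
  expect_error(nullFit(1, factor("a")), "at least 2")
})

test_that("H0 is dominated by HA on centred random data", {
  set.seed(43)
  for (rep in 1:10) {
    fam <- factor(rep(c("a", "b", "c"), each = 30))
    y <- rnorm(90)
    y <- y - ave(y, fam)
    p <- runif(90, 0.05, 0.95)
    fit <- emFit(y, fam, p)
    null <- nullFit(y, fam)
    expect_gte(fit$logLA, null$logL0 - 1e-6)
  }
})

test_that("mean LOD approximates -(n/2) log10(1 - R2) for F = 1", {
  set.seed(44)
  n <- 200; pve <- 0.185
  a <- sqrt(pve / (1 - pve))   # noise sd 1
  lods <- replicate(60, {
    cls <- rbinom(n, 1, 0.5)
    y <- (2 * cls - 1) * a + rnorm(n)
    fit <- emFit(y, factor(rep("f", n)), as.numeric(cls))
    lodScore(fit, nullFit(y, factor(rep("f", n))))
  })
  expected <- -(n / 2) * log10(1 - pve)
  expect_lt(abs(mean(lods) - expected), 3 * sd(lods) / sqrt(60) + 1.5)
})

test_that("the scan is continuous at markers and matches ICIM for F = 1", {
  sim <- smallSim(a = 1.5, fams = 1, n = 120, seed = 50, famVar = 4)
  srJ <- jicimScan(sim$nam)
  srI <- icimScan(sim$nam)
  expect_equal(lodProfile(srJ)$lod, lodProfile(srI)$lod, tolerance = 1e-8)
  # at an exact marker position the fit equals treating the marker as QTL
  prof <- lodProfile(srJ)
  map <- geneticMap(sim$nam)
  i <- which(prof$chromosome == "1" & prof$position_cM == 30)
  j <- which(map$chromosome == "1" & map$position_cM == 30)
  model <- stepwiseSelect(sim$nam)
  dY <- adjustPhenotype(sim$nam, model, flankMarkers = c(j, j + 1))
  g <- genotypes(sim$nam)[j, ]
  fit <- emFit(dY, lineFamily(sim$nam), as.numeric(g))
  null <- nullFit(dY, lineFamily(sim$nam))
  expect_equal(prof$lod[i], lodScore(fit, null), tolerance = 1e-6)
  expect_error(jicimScan(sim$nam, step = 0), "positive")
})

test_that("LOD profile is invariant to phenotype shift and scale", {
  sim <- smallSim(a = 1.2, fams = 2, n = 80, seed = 51)
  nam <- sim$nam
  base <- lodProfile(jicimScan(nam))$lod
  phenotype(nam) <- phenotype(sim$nam) + 100
  expect_equal(lodProfile(jicimScan(nam))$lod, base, tolerance = 1e-6)
  phenotype(nam) <- phenotype(sim$nam) * 3.7
  expect_equal(lodProfile(jicimScan(nam))$lod, base, tolerance = 1e-6)
})

test_that("a simulated QTL is located near the truth with its effect", {
  hits <- 0; effs <- numeric(0)
  for (s in 1:6) {
    sim <- smallSim(a = 1.5, fams = 3, n = 150, seed = 60 + s,
                    famVar = c(5.41, 5.41, 5.41), qtlFamily = 2)
    sr <- jicimScan(sim$nam)
    prof <- lodProfile(sr)
    peak <- prof[which.max(prof$lod), ]
    if (peak$chromosome == "1" && abs(peak$position_cM - 30) <= 5)
      hits <- hits + 1
    effs <- c(effs, peak$a_F2)
  }
  expect_gte(hits, 5)
  expect_gt(mean(effs), 0.9)     # effect recovered on the a scale, not 2a
  expect_lt(mean(effs), 2.2)
})

test_that("QTL calling follows threshold, decay and merge rules", {
  founders <- "F1"
  mkSR <- function(lod, pos = seq_along(lod) - 1, chrom = "1") {
    prof <- data.frame(chromosome = chrom, position_cM = pos, lod = lod,
                       a_F1 = 0.5)
    new("ScanResult", profile = prof, calls = jicim:::.emptyCalls(founders),
        threshold = numeric(0), step = 1, founders = founders,
        famVar = 2, famSize = 100L)
  }
  # flat profile below threshold: no calls
  sr <- callQTL(mkSR(rep(1, 30)), 3)
  expect_equal(nrow(qtlCalls(sr)), 0)
  # single smooth peak of 23: one call, SI spans the >= 22 region
  lod <- 23 - 0.5 * abs(seq(-10, 10))
  sr <- callQTL(mkSR(lod), 12)
  calls <- qtlCalls(sr)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$lod, 23)
  expect_equal(calls$si_lo, 8)
  expect_equal(calls$si_hi, 12)
  # twin peaks 20 apart with a valley 3 below: two calls
  x <- 0:40
  lod <- pmax(20 - 0.3 * abs(x - 10), 20 - 0.3 * abs(x - 30))
  sr <- callQTL(mkSR(lod, pos = x), 10)
  expect_equal(nrow(qtlCalls(sr)), 2)
  # shallow valley (< 1 LOD): merged into the higher peak
  lod <- pmax(20 - 0.08 * abs(x - 10), 19.8 - 0.08 * abs(x - 30))
  sr <- callQTL(mkSR(lod, pos = x), 10)
  expect_equal(nrow(qtlCalls(sr)), 1)
  expect_equal(qtlCalls(sr)$position_cM, 10)
})
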