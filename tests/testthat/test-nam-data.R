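test_that("toy dataset loads with the expected design", {
  paths <- writeToyFiles()
  nam <- readNAMData(paths["map"], paths["geno"], paths["pheno"])
  d <- namDesign(nam)
  expect_equal(d$F, 3)
  expect_equal(d$N, 30)
  expect_equal(nrow(nam), 6)
  expect_equal(d$families$size, c(10, 10, 10))
  # row order follows the genotype file
  expect_equal(colnames(nam),
               utils::read.delim(paths["geno"])$line)
})

test_that("maize-shaped dataset has 25 families, 5000 lines, 1106 markers", {
  map <- makeGridMap(nChrom = 10, chromLength = 143, spacing = 1.3)
  map <- map[seq_len(1106), ]
  expect_gte(nrow(map), 1106)
  nam <- simulateNAMGenotypes(map, famSizes = rep(200, 25), seed = 3)
  d <- namDesign(nam)
  expect_equal(d$F, 25)
  expect_equal(d$N, 5000)
  expect_equal(nrow(nam), 1106)
})

test_that("inconsistent inputs are hard errors naming the file", {
  paths <- writeToyFiles(dropPhenoRows = 1)
  expect_error(readNAMData(paths["map"], paths["geno"], paths["pheno"]),
               "29")
  # unsorted map
  paths2 <- writeToyFiles()
  map <- utils::read.delim(paths2["map"])
  map$position_cM[2:3] <- map$position_cM[3:2]
  utils::write.table(map, paths2["map"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readNAMData(paths2["map"], paths2["geno"], paths2["pheno"]),
               "not sorted")
  expect_error(readNAMData("nope.tsv", paths2["geno"], paths2["pheno"]),
               "not found")
})

test_that("lines with missing phenotype are dropped with a message", {
  paths <- writeToyFiles()
  ph <- utils::read.delim(paths["pheno"])
  ph$value[c(3, 7)] <- NA
  utils::write.table(ph, paths["pheno"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_message(nam <- readNAMData(paths["map"], paths["geno"],
                                    paths["pheno"]),
                 "2 line")
  expect_equal(ncol(nam), 28)
})

test_that("preprocessing converts heterozygotes and monomorphic family markers", {
  map <- toyMap()
  set.seed(5)
  g <- matrix(rbinom(6 * 20, 1, 0.5), 6, 20)
  fam <- factor(rep(c("f1", "f2"), each = 10))
  g[1, fam == "f1"] <- 0L                   # monomorphic in f1 at marker 1
  g[2, 1] <- 2L                             # one heterozygote
  nam <- NAMExperiment(g, map, fam, rnorm(20))
  out <- preprocessGenotypes(nam)
  counts <- metadata(out)$preprocess
  expect_equal(counts$hetToMissing, 1)
  expect_equal(counts$monomorphicToMissing, 10)
  go <- genotypes(out)
  expect_true(all(is.na(go[1, fam == "f1"])))
  expect_true(is.na(go[2, 1]))
  # clean matrix passes through unchanged
  nam2 <- NAMExperiment(ifelse(is.na(go), 0L, go), map, fam, rnorm(20))
  # make every family-marker polymorphic
  g3 <- genotypes(nam2)
  g3[, c(1, 11)] <- 0L; g3[, c(2, 12)] <- 1L
  assay(nam2, "genotype") <- g3
  out2 <- preprocessGenotypes(nam2)
  expect_identical(genotypes(out2), g3)
  expect_equal(metadata(out2)$preprocess$hetToMissing, 0)
})

test_that("a heterozygote becomes exactly one extra missing", {
  map <- toyMap()
  set.seed(8)
  g <- matrix(rbinom(6 * 20, 1, 0.5), 6, 20)
  g[, 1] <- c(0L, 1L, 0L, 1L, 0L, 1L); g[, 11] <- c(1L, 0L, 1L, 0L, 1L, 0L)
  fam <- factor(rep(c("f1", "f2"), each = 10))
  nam <- NAMExperiment(g, map, fam, rnorm(20))
  base <- sum(is.na(genotypes(preprocessGenotypes(nam))))
  g2 <- g; g2[3, 5] <- 2L
  nam2 <- NAMExperiment(g2, map, fam, rnorm(20))
  expect_equal(sum(is.na(genotypes(preprocessGenotypes(nam2)))), base + 1)
})

test_that("imputation follows the flanking-marker posterior", {
  # tightly flanked by two agreeing calls -> that allele
  map <- data.frame(marker = paste0("m", 1:3), chromosome = "1",
                    position_cM = c(0, 0.5, 1.0))
  set.seed(2)
  nam <- simulateNAMGenotypes(map, famSizes = c(f1 = 40), seed = 2)
  g <- genotypes(nam)
  g[1, ] <- 0L; g[3, ] <- 0L
  g[2, 1] <- NA
  assay(nam, "genotype") <- g
  out <- imputeMissing(nam, seed = 4)
  expect_equal(genotypes(out)[2, 1], 0L)

  # chromosome end, single informative flank -> flank allele (posterior
  # 1 - R > 0.5, verified against the two-locus enumeration oracle)
  g[1, 2] <- NA; g[2, 2] <- 0L; g[3, 2] <- 0L
  assay(nam, "genotype") <- g
  out <- imputeMissing(nam, seed = 4)
  expect_equal(genotypes(out)[1, 2], 0L)
  q <- oracleThreeLocusRIL(haldane(1), 0)
  pSame <- (q[1] + q[2]) / sum(q[1:4])    # P(locus2 = A | locus1 = A)
  expect_gt(pSame, 0.5)

  # observed calls are never altered; imputation is idempotent
  obs <- !is.na(g)
  expect_identical(genotypes(out)[obs], g[obs])
  expect_identical(genotypes(imputeMissing(out, seed = 99)),
                   genotypes(out))
})

test_that("equidistant discordant flanks are a seeded fair coin", {
  map <- data.frame(marker = paste0("m", 1:3), chromosome = "1",
                    position_cM = c(0, 5, 10))
  nam <- simulateNAMGenotypes(map, famSizes = c(f1 = 29), seed = 11)
  g <- genotypes(nam)
  # 14 lines recombine in each interval, so both family-estimated interval
  # fractions are equal and the flanks of the missing call are discordant
  # with exactly tied posteriors
  g[, 2:15] <- matrix(c(0L, 0L, 1L), 3, 14)
  g[, 16:29] <- matrix(c(0L, 1L, 1L), 3, 14)
  g[, 1] <- c(0L, NA, 1L)
  assay(nam, "genotype") <- g
  draws <- vapply(seq_len(1200), function(s)
    genotypes(imputeMissing(nam, seed = s))[2, 1], 0L)
  expect_equal(mean(draws), 0.5, tolerance = 0.045)
  # deterministic given the seed
  expect_identical(genotypes(imputeMissing(nam, seed = 7)),
                   genotypes(imputeMissing(nam, seed = 7)))
})

test_that("a line missing a whole chromosome is coin-assigned with a warning", {
  map <- toyMap()
  set.seed(3)
  nam <- simulateNAMGenotypes(map, famSizes = c(f1 = 20), seed = 3)
  g <- genotypes(nam)
  g[1:3, 5] <- NA
  assay(nam, "genotype") <- g
  expect_warning(out <- imputeMissing(nam, seed = 1), "fair coin")
  expect_false(anyNA(genotypes(out)))
})

test_that("family sizes and marker counts are conserved through the pipeline", {
  paths <- writeToyFiles(nHet = 3, nMiss = 5)
  nam <- loadNAMDataset(paths["map"], paths["geno"], paths["pheno"],
                        seed = 2)
  expect_equal(dim(nam), c(6L, 30L))
  expect_equal(as.integer(table(lineFamily(nam))), rep(10L, 3))
  expect_false(anyNA(genotypes(nam)))
})
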