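# Fixtures are built in code at test time.

toyMap <- function() {
  data.frame(marker = paste0("m", 1:6),
             chromosome = rep(c("1", "2"), each = 3),
             position_cM = c(0, 10, 25, 0, 5, 30),
             stringsAsFactors = FALSE)
}

# 3 families x 10 lines on the toy map; deterministic codes including a few
# heterozygotes and missings. Returns the three file paths.
writeToyFiles <- function(dir = tempfile("toy"), nHet = 2, nMiss = 3,
                          dropPhenoRows = 0) {
  dir.create(dir, showWarnings = FALSE)
  map <- toyMap()
  set.seed(99)
  nam <- jicim::simulateNAMGenotypes(map, famSizes = c(A1 = 10, A2 = 10,
                                                       A3 = 10), seed = 99)
  g <- jicim::genotypes(nam)
  codes <- ifelse(g == 1L, "B", "A")
  if (nHet > 0) codes[cbind(c(1, 4, 2)[seq_len(nHet)],
                            c(2, 5, 9)[seq_len(nHet)])] <- "H"
  # scattered so that no line loses a whole chromosome
  if (nMiss > 0) codes[cbind(c(2, 5, 1, 6, 3)[seq_len(nMiss)],
                             c(3, 8, 14, 21, 27)[seq_len(nMiss)])] <- "-"
  gdf <- data.frame(line = colnames(nam),
                    family = as.character(jicim::lineFamily(nam)),
                    t(codes), check.names = FALSE, stringsAsFactors = FALSE)
  names(gdf)[-(1:2)] <- map$marker
  pheno <- data.frame(line = colnames(nam),
                      family = as.character(jicim::lineFamily(nam)),
                      value = round(stats::rnorm(30, 10, 2), 3))
  if (dropPhenoRows > 0) pheno <- pheno[-seq_len(dropPhenoRows), ]
  paths <- c(map = file.path(dir, "map.tsv"),
             geno = file.path(dir, "geno.tsv"),
             pheno = file.path(dir, "pheno.tsv"))
  utils::write.table(map, paths["map"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gdf, paths["geno"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pheno, paths["pheno"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

# small complete NAMExperiment with a QTL, for scan-level tests
smallSim <- function(a = 1.5, fams = 3, n = 100, seed = 1,
                     famVar = rep(4, fams), qtlFamily = 1,
                     nChrom = 2, chromLength = 60, spacing = 3) {
  qtl <- data.frame(chromosome = "1", position_cM = 30,
                    family = paste0("F", qtlFamily), a = a)
  if (a == 0) qtl <- NULL
  jicim::simulateNAMDataset(nChrom = nChrom, chromLength = chromLength,
                            spacing = spacing, famSizes = rep(n, fams),
                            famVar = famVar, qtl = qtl, seed = seed)
}
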