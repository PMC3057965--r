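#' Read a NAM dataset from map, genotype and phenotype files
#'
#' File dialects (all tab-separated, with header):
#' \itemize{
#'   \item map: \code{marker  chromosome  position_cM}
#'   \item genotype: \code{line  family  <marker1> ... <markerM>} with codes
#'     \code{A} (common parent), \code{B} (founder), \code{H} (heterozygote),
#'     \code{-} (missing)
#'   \item phenotype: \code{line  family  value}
#' }
#' Row order of the returned object follows the genotype file. Family
#' membership is taken from the genotype file; the phenotype file must agree.
#' Lines with missing phenotype are dropped with a message (phenotypes are
#' never imputed). Inconsistencies (dimension mismatches, unknown family
#' labels, unsorted map) are hard errors naming the file.
#'
#' @param mapPath,genoPath,phenoPath file paths
#' @param commonParent name stored as the common parent
#' @return a \linkS4class{NAMExperiment}
#' @examples
#' # small simulated 3-family dataset shipped with the package
#' ex <- function(f) system.file("extdata", f, package = "jicim")
#' nam <- readNAMData(ex("example_map.tsv"), ex("example_geno.tsv"),
#'                    ex("example_pheno.tsv"))
#' nam
#' @export
readNAMData <- function(mapPath, genoPath, phenoPath,
                        commonParent = "common") {
  for (p in c(mapPath, genoPath, phenoPath))
    if (!file.exists(p)) stop("file not found: ", p)
  map <- utils::read.delim(mapPath, stringsAsFactors = FALSE)
  if (!all(c("marker", "chromosome", "position_cM") %in% names(map)))
    stop(mapPath, ": header must be 'marker\tchromosome\tposition_cM'")
  if (anyDuplicated(map$marker))
    stop(mapPath, ": duplicated marker name '",
         map$marker[anyDuplicated(map$marker)], "'")
  for (cc in unique(map$chromosome)) {
    p <- map$position_cM[map$chromosome == cc]
    if (is.unsorted(p))
      stop(mapPath, ": positions on chromosome ", cc, " are not sorted")
  }
  geno <- utils::read.delim(genoPath, stringsAsFactors = FALSE,
                            check.names = FALSE)
  if (!all(c("line", "family") %in% names(geno)[1:2]))
    stop(genoPath, ": first two columns must be 'line' and 'family'")
  markerCols <- names(geno)[-(1:2)]
  if (!identical(markerCols, map$marker))
    stop(genoPath, ": marker columns do not match the map (",
         length(markerCols), " vs ", nrow(map), " markers; first mismatch: ",
         paste(utils::head(setdiff(map$marker, markerCols), 1), collapse = ""), ")")
  codes <- as.matrix(geno[, markerCols, drop = FALSE])
  bad <- !(codes %in% c("A", "B", "H", "-"))
  if (any(bad)) {
    w <- which(bad)[1]
    stop(genoPath, ": invalid genotype code '", codes[w], "' at line record ",
         ((w - 1) %% nrow(codes)) + 1)
  }
  g <- matrix(NA_integer_, nrow(map), nrow(geno),
              dimnames = list(map$marker, geno$line))
  g[t(codes) == "A"] <- 0L
  g[t(codes) == "B"] <- 1L
  g[t(codes) == "H"] <- 2L
  pheno <- utils::read.delim(phenoPath, stringsAsFactors = FALSE)
  if (!all(c("line", "family", "value") %in% names(pheno)))
    stop(phenoPath, ": header must be 'line\tfamily\tvalue'")
  if (nrow(pheno) != nrow(geno))
    stop("genotype file has ", nrow(geno), " lines but phenotype file has ",
         nrow(pheno), " (", genoPath, " vs ", phenoPath, ")")
  mIdx <- match(geno$line, pheno$line)
  if (anyNA(mIdx))
    stop(phenoPath, ": no phenotype for line '",
         geno$line[which(is.na(mIdx))[1]], "'")
  pheno <- pheno[mIdx, ]
  if (!all(pheno$family == geno$family)) {
    w <- which(pheno$family != geno$family)[1]
    stop(phenoPath, ": family label for line '", geno$line[w],
         "' (", pheno$family[w], ") disagrees with the genotype file (",
         geno$family[w], ")")
  }
  keep <- is.finite(pheno$value)
  if (!all(keep))
    message("dropping ", sum(!keep), " line(s) with missing phenotype")
  fam <- factor(geno$family)
  nam <- NAMExperiment(g[, keep, drop = FALSE], map,
                       family = fam[keep],
                       phenotype = pheno$value[keep],
                       commonParent = commonParent)
  nam
}

#' Write a NAM dataset in the three TSV dialects
#'
#' @param nam a \linkS4class{NAMExperiment}
#' @param prefix output path prefix; writes \code{<prefix>_map.tsv},
#'   \code{<prefix>_geno.tsv}, \code{<prefix>_pheno.tsv}
#' @return invisibly, the three paths
#' @export
writeNAMData <- function(nam, prefix) {
  mapf <- paste0(prefix, "_map.tsv")
  genof <- paste0(prefix, "_geno.tsv")
  phenof <- paste0(prefix, "_pheno.tsv")
  utils::write.table(geneticMap(nam), mapf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- genotypes(nam)
  codes <- matrix("-", nrow(g), ncol(g))
  codes[g == 0L] <- "A"; codes[g == 1L] <- "B"; codes[g == 2L] <- "H"
  gdf <- data.frame(line = colnames(nam),
                    family = as.character(lineFamily(nam)),
                    t(codes), check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(gdf)[-(1:2)] <- rownames(nam)
  utils::write.table(gdf, genof, sep = "\t", quote = FALSE, row.names = FALSE)
  pdf <- data.frame(line = colnames(nam),
                    family = as.character(lineFamily(nam)),
                    value = phenotype(nam))
  utils::write.table(pdf, phenof, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(map = mapf, geno = genof, pheno = phenof))
}

#' Preprocess genotype codes
#'
#' Applies the two cleaning rules used before joint mapping: heterozygous
#' calls are converted to missing, and markers that are non-polymorphic
#' within a particular family (only one allele class observed there) have
#' that family's entries at that marker set to missing. Always succeeds.
#'
#' @param nam a \linkS4class{NAMExperiment}
#' @return the object with cleaned genotypes; conversion counts are stored in
#'   \code{metadata(nam)$preprocess} (\code{hetToMissing},
#'   \code{monomorphicToMissing})
#' @export
preprocessGenotypes <- function(nam) {
  g <- genotypes(nam)
  nHet <- sum(g == 2L, na.rm = TRUE)
  g[g == 2L] <- NA_integer_
  fam <- lineFamily(nam)
  nMono <- 0L
  for (f in levels(fam)) {
    idx <- which(fam == f)
    gf <- g[, idx, drop = FALSE]
    nObs0 <- rowSums(gf == 0L, na.rm = TRUE)
    nObs1 <- rowSums(gf == 1L, na.rm = TRUE)
    mono <- (nObs0 == 0L) != (nObs1 == 0L)   # exactly one class observed
    if (any(mono)) {
      nMono <- nMono + sum(!is.na(gf[mono, , drop = FALSE]))
      g[mono, idx] <- NA_integer_
    }
  }
  assay(nam, "genotype") <- g
  metadata(nam)$preprocess <- list(hetToMissing = nHet,
                                   monomorphicToMissing = nMono)
  nam
}

#' Impute missing genotypes within families
#'
#' Assigns every missing call to the common-parent or founder homozygote with
#' the higher posterior probability given the nearest non-missing flanking
#' markers of the same line, using family-estimated recombination fractions
#' (no-interference two-locus selfed-RIL probabilities, composed across the
#' intervening consensus-map intervals). Exact posterior ties are broken by a
#' seeded fair coin; a line missing at every marker of a chromosome is
#' assigned by seeded fair coins with a warning. Observed calls are never
#' altered, so the operation is idempotent.
#'
#' @param nam a preprocessed \linkS4class{NAMExperiment}
#' @param seed integer seed for tie-breaking draws
#' @return the object with a complete genotype matrix
#' @export
imputeMissing <- function(nam, seed = 1L) {
  g <- genotypes(nam)
  if (any(g == 2L, na.rm = TRUE))
    stop("heterozygous codes present; run preprocessGenotypes() first")
  if (!anyNA(g)) return(nam)
  fam <- lineFamily(nam)
  chromIdx <- .chromIndex(nam)
  pos <- rowData(nam)$position_cM
  warnedEmpty <- FALSE
  g <- .withSeed(seed, function() {
    for (ci in chromIdx) {
      gc <- g[ci, , drop = FALSE]
      if (!anyNA(gc)) next
      famR <- .familyIntervalRecomb(gc, fam, pos[ci])   # F x (m-1), RIL scale
      famr <- meioticScale(famR)                         # meiotic, per interval
      m <- length(ci)
      for (j in which(colSums(is.na(gc)) > 0)) {
        v <- gc[, j]
        f <- as.integer(fam[j])
        obs <- which(!is.na(v))
        miss <- which(is.na(v))
        if (!length(obs)) {
          if (!warnedEmpty) {
            warning("line(s) missing at every marker of a chromosome; ",
                    "assigned by seeded fair coin")
            warnedEmpty <<- TRUE
          }
          g[ci, j] <<- as.integer(stats::runif(m) < 0.5)
          next
        }
        rcum <- function(a, b) {      # composed meiotic r between markers a<b
          if (a == b) return(0)
          Reduce(composeRecomb, famr[f, a:(b - 1)], accumulate = FALSE)
        }
        for (i in miss) {
          left <- if (any(obs < i)) max(obs[obs < i]) else NA_integer_
          right <- if (any(obs > i)) min(obs[obs > i]) else NA_integer_
          if (!is.na(left) && !is.na(right)) {
            R1 <- rilScale(min(rcum(left, i), 0.4999999))
            R2 <- rilScale(min(rcum(i, right), 0.4999999))
            pq <- .classProbCore(R1, R2)   # p1 = P(B|B,B), p2 = P(B|B,A)
            pB <- if (v[left] == 1L && v[right] == 1L) pq$p1
                  else if (v[left] == 1L) pq$p2
                  else if (v[right] == 1L) 1 - pq$p2
                  else 1 - pq$p1
          } else {
            fl <- if (!is.na(left)) left else right
            Rfl <- rilScale(min(rcum(min(fl, i), max(fl, i)), 0.4999999))
            pB <- if (v[fl] == 1L) 1 - Rfl else Rfl
          }
          v[i] <- if (abs(pB - 0.5) < 1e-12) as.integer(stats::runif(1) < 0.5)
                  else as.integer(pB > 0.5)
        }
        g[ci, j] <<- v
      }
    }
    g
  })
  assay(nam, "genotype") <- g
  nam
}

#' Convenience loader: read, preprocess and impute in one call
#'
#' @inheritParams readNAMData
#' @param seed imputation seed (see \code{\link{imputeMissing}})
#' @return a complete \linkS4class{NAMExperiment} ready for scanning
#' @export
loadNAMDataset <- function(mapPath, genoPath, phenoPath, seed = 1L,
                           commonParent = "common") {
  nam <- readNAMData(mapPath, genoPath, phenoPath, commonParent = commonParent)
  nam <- preprocessGenotypes(nam)
  imputeMissing(nam, seed = seed)
}
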