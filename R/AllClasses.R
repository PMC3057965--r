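#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   rowData colData colData<-
NULL

#' NAMExperiment: genotypes, map and phenotype of a NAM population
#'
#' Container for a nested association mapping (NAM) dataset: F recombinant
#' inbred line (RIL) families that share one common parent, genotyped on a
#' consensus genetic map and phenotyped for one quantitative trait. Extends
#' \linkS4class{SummarizedExperiment}: rows are markers, columns are lines.
#'
#' The \code{"genotype"} assay is an integer matrix with entries
#' \code{0} (common-parent homozygote, file code \code{A}),
#' \code{1} (founder homozygote, code \code{B}),
#' \code{2} (heterozygote, code \code{H}) and \code{NA} (missing, code
#' \code{-}). \code{rowData} carries \code{chromosome} and \code{position_cM};
#' \code{colData} carries \code{family} (factor) and \code{phenotype}
#' (numeric, trait units).
#'
#' Validity requires unique marker names, markers grouped by chromosome with
#' non-decreasing positions, at least two markers per chromosome, and at
#' least two lines per family.
#'
#' @seealso \code{\link{NAMExperiment}} (constructor),
#'   \code{\link{readNAMData}}, \code{\link{simulateNAMGenotypes}}
#' @export
setClass("NAMExperiment", contains = "SummarizedExperiment")

.validNAMExperiment <- function(object) {
  msg <- character(0)
  if (!("genotype" %in% names(assays(object))))
    msg <- c(msg, "assay 'genotype' is required")
  rd <- rowData(object)
  cd <- colData(object)
  if (!all(c("chromosome", "position_cM") %in% names(rd)))
    msg <- c(msg, "rowData must contain 'chromosome' and 'position_cM'")
  if (!all(c("family", "phenotype") %in% names(cd)))
    msg <- c(msg, "colData must contain 'family' and 'phenotype'")
  if (length(msg))
    return(msg)
  g <- assay(object, "genotype")
  if (!all(g[!is.na(g)] %in% c(0L, 1L, 2L)))
    msg <- c(msg, "genotype codes must be 0 (common), 1 (founder), 2 (het) or NA")
  mn <- rownames(object)
  if (is.null(mn) || anyDuplicated(mn))
    msg <- c(msg, "marker names must be present and unique")
  chrom <- as.character(rd$chromosome)
  pos <- rd$position_cM
  if (anyNA(pos) || !is.numeric(pos))
    msg <- c(msg, "marker positions must be finite numbers (cM)")
  rle_chrom <- rle(chrom)
  if (anyDuplicated(rle_chrom$values))
    msg <- c(msg, "markers of one chromosome must be contiguous")
  if (any(rle_chrom$lengths < 2))
    msg <- c(msg, "every chromosome must carry at least 2 markers")
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (is.unsorted(p))
      msg <- c(msg, sprintf("positions on chromosome %s are not non-decreasing", cc))
  }
  fam <- cd$family
  if (!is.factor(fam))
    msg <- c(msg, "colData$family must be a factor")
  else if (any(table(fam) < 2))
    msg <- c(msg, "every family must have at least 2 lines")
  if (length(msg)) msg else TRUE
}
setValidity("NAMExperiment", .validNAMExperiment)

#' Construct a NAMExperiment
#'
#' @param genotype integer matrix, markers x lines, codes 0/1/2/NA (see
#'   \linkS4class{NAMExperiment}).
#' @param map data.frame with columns \code{marker}, \code{chromosome},
#'   \code{position_cM}, one row per genotype row, in row order.
#' @param family factor (or coercible) of length \code{ncol(genotype)} giving
#'   each line's family.
#' @param phenotype numeric trait values per line (may contain \code{NA};
#'   see \code{\link{readNAMData}} for the dropping policy applied on file
#'   input).
#' @param commonParent,founders optional parent names stored in
#'   \code{metadata}; founders must be one per family level.
#' @return a \linkS4class{NAMExperiment}
#' @examples
#' map <- data.frame(marker = c("m1", "m2"), chromosome = "1",
#'                   position_cM = c(0, 10))
#' g <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L), nrow = 2,
#'             dimnames = list(map$marker, paste0("L", 1:4)))
#' nam <- NAMExperiment(g, map, family = factor(c(1, 1, 2, 2)),
#'                      phenotype = c(1.2, 0.8, 2.1, 1.9))
#' nam
#' @export
NAMExperiment <- function(genotype, map, family, phenotype,
                          commonParent = "common", founders = NULL) {
  genotype <- as.matrix(genotype)
  storage.mode(genotype) <- "integer"
  if (nrow(genotype) != nrow(map))
    stop("genotype has ", nrow(genotype), " rows but map has ", nrow(map),
         " markers")
  rownames(genotype) <- as.character(map$marker)
  family <- droplevels(as.factor(family))
  if (length(family) != ncol(genotype))
    stop("family labels (", length(family), ") do not match the number of lines (",
         ncol(genotype), ")")
  if (length(phenotype) != ncol(genotype))
    stop("phenotype length (", length(phenotype), ") does not match the number of lines (",
         ncol(genotype), ")")
  if (is.null(founders))
    founders <- levels(family)
  if (is.null(colnames(genotype)))
    colnames(genotype) <- paste0("line", seq_len(ncol(genotype)))
  se <- SummarizedExperiment(
    assays = list(genotype = genotype),
    rowData = DataFrame(chromosome = as.character(map$chromosome),
                        position_cM = as.numeric(map$position_cM)),
    colData = DataFrame(family = family,
                        phenotype = as.numeric(phenotype),
                        row.names = colnames(genotype)))
  out <- new("NAMExperiment", se)
  metadata(out)$commonParent <- commonParent
  metadata(out)$founders <- founders
  validObject(out)
  out
}

#' ScanResult: a one-dimensional QTL scan
#'
#' Holds the LOD profile of a JICIM/ICIM genome scan together with declared
#' QTL. \code{profile} has one row per grid position with columns
#' \code{chromosome}, \code{position_cM}, \code{lod} and one additive-effect
#' column \code{a_<founder>} per family; \code{calls} (filled by
#' \code{\link{callQTL}}) has one row per declared QTL with peak position,
#' peak LOD, the one-LOD support interval, per-family additive effects and
#' per-family plus NAM-level phenotypic variance explained.
#'
#' @seealso \code{\link{jicimScan}}, \code{\link{callQTL}}
#' @export
setClass("ScanResult",
         representation(profile = "data.frame",
                        calls = "data.frame",
                        threshold = "numeric",
                        step = "numeric",
                        founders = "character",
                        famVar = "numeric",
                        famSize = "integer"))

#' @describeIn ScanResult LOD profile as a data.frame
#' @param x,object a \code{ScanResult}
#' @export
lodProfile <- function(x) x@profile

#' @describeIn ScanResult declared QTL as a data.frame (empty until
#'   \code{\link{callQTL}} is applied with a threshold)
#' @export
qtlCalls <- function(x) x@calls

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult:", nrow(object@profile), "positions,",
      length(unique(object@profile$chromosome)), "chromosome(s), step",
      object@step, "cM\n")
  cat("  max LOD:", round(max(object@profile$lod), 3), "\n")
  if (length(object@threshold))
    cat("  threshold:", object@threshold, "->", nrow(object@calls),
        "QTL declared\n")
  else cat("  no threshold applied yet (see callQTL)\n")
})

setMethod("show", "NAMExperiment", function(object) {
  d <- namDesign(object)
  cat("NAMExperiment:", d$F, "families,", d$N, "lines,",
      nrow(object), "markers on",
      length(unique(rowData(object)$chromosome)), "chromosome(s)\n")
  g <- assay(object, "genotype")
  cat("  missing genotypes:", sum(is.na(g)),
      " heterozygous:", sum(g == 2L, na.rm = TRUE), "\n")
  cat("  phenotyped lines:", sum(!is.na(colData(object)$phenotype)), "\n")
  invisible(NULL)
})
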