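#' Accessors for NAMExperiment
#'
#' @param x a \linkS4class{NAMExperiment}
#' @name nam-accessors
NULL

#' @describeIn nam-accessors integer marker-by-line genotype matrix
#'   (0 common, 1 founder, 2 het, NA missing)
#' @export
genotypes <- function(x) assay(x, "genotype")

#' @describeIn nam-accessors the consensus genetic map as a data.frame
#'   (\code{marker}, \code{chromosome}, \code{position_cM})
#' @export
geneticMap <- function(x) {
  rd <- rowData(x)
  data.frame(marker = rownames(x),
             chromosome = as.character(rd$chromosome),
             position_cM = rd$position_cM,
             stringsAsFactors = FALSE)
}

#' @describeIn nam-accessors family factor, one entry per line
#' @export
lineFamily <- function(x) colData(x)$family

#' @describeIn nam-accessors numeric phenotype per line (trait units)
#' @export
phenotype <- function(x) {
  y <- colData(x)$phenotype
  names(y) <- colnames(x)
  y
}

#' @describeIn nam-accessors replace the phenotype
#' @param value numeric of length \code{ncol(x)}
#' @export
`phenotype<-` <- function(x, value) {
  stopifnot(length(value) == ncol(x))
  colData(x)$phenotype <- as.numeric(value)
  x
}

#' @describeIn nam-accessors design summary: list with \code{F} (number of
#'   families), \code{N} (total lines), \code{families} (data.frame of
#'   founder and size) and \code{commonParent}
#' @export
namDesign <- function(x) {
  fam <- lineFamily(x)
  sz <- table(fam)
  founders <- metadata(x)$founders
  if (is.null(founders)) founders <- levels(fam)
  list(F = nlevels(fam),
       N = length(fam),
       families = data.frame(founder = founders,
                             family = levels(fam),
                             size = as.integer(sz),
                             stringsAsFactors = FALSE),
       commonParent = metadata(x)$commonParent)
}

## ---- internal helpers shared across modules ----

# chromosome-wise marker index list, in map order
.chromIndex <- function(x) {
  chrom <- as.character(rowData(x)$chromosome)
  split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
}

# signed lines x markers matrix (+1 founder, -1 common); requires imputed codes
.signedGenotypes <- function(x) {
  g <- genotypes(x)
  if (anyNA(g) || any(g == 2L))
    stop("genotypes must be preprocessed and imputed first ",
         "(see preprocessGenotypes and imputeMissing)")
  t(g) * 2L - 1L
}

# evaluate fun() under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, fun) {
  if (is.null(seed))
    return(fun())
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  fun()
}
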