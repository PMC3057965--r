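#' Family variance summary for PVE computation
#'
#' The phenotypic variance used for NAM-level PVE is the family-size
#' weighted average of the per-family phenotypic variances,
#' Vbar_P = sum n_f V_Pf / N. With the ML divisor (n_f, the default) this
#' equals the variance of the family-mean-centred phenotypes exactly;
#' the difference between family means is excluded on purpose, since it
#' reflects cross effects rather than QTL segregation.
#'
#' @param y phenotypes
#' @param family family factor
#' @param ml if TRUE (default) variances use divisor n_f; otherwise n_f - 1
#' @return list with per-family \code{variances}, \code{weights} (n_f/N) and
#'   \code{weightedMean}
#' @export
varianceSummary <- function(y, family, ml = TRUE) {
  family <- droplevels(as.factor(family))
  sp <- split(as.numeric(y), family)
  v <- vapply(sp, function(z) {
    n <- length(z)
    sum((z - mean(z))^2) / if (ml) n else (n - 1)
  }, 0)
  n <- lengths(sp)
  list(variances = v, weights = n / sum(n),
       weightedMean = sum(n * v) / sum(n))
}

#' PVE of a QTL in a biparental (RIL) population
#'
#' The theoretical genetic variance of a QTL with additive effect a (half
#' the difference between the two homozygotes) in a RIL population is a^2,
#' so PVE = 100 a^2 / V_P.
#'
#' @param a additive effect (trait units)
#' @param VP phenotypic variance of the population (trait units squared)
#' @return percent; values above 100 are returned as-is with a warning
#' @export
pveBiparental <- function(a, VP) {
  if (any(VP <= 0)) stop("phenotypic variance must be positive")
  out <- 100 * a^2 / VP
  if (any(out > 100))
    warning("a^2 exceeds the phenotypic variance; PVE > 100% returned as-is")
  out
}

#' PVE of a QTL in a NAM population
#'
#' The F+1 QTL genotypic values are 0 for the common-parent homozygote
#' (frequency 1/2) and 2 a_f for the f-th founder homozygote (frequency
#' n_f / 2N). The genetic variance is the variance of this discrete
#' distribution and PVE = 100 V_G / Vbar_P with Vbar_P the weighted family
#' variance of \code{\link{varianceSummary}}. With F = 1 this reduces
#' exactly to \code{\link{pveBiparental}}.
#'
#' @param effects per-family additive effects a_1..a_F (0 for families where
#'   the QTL does not segregate)
#' @param famSizes family sizes n_1..n_F
#' @param vs a \code{\link{varianceSummary}} or the weighted mean family
#'   variance as a single number
#' @return percent
#' @export
pveNAM <- function(effects, famSizes, vs) {
  if (!length(famSizes)) stop("empty design")
  if (length(effects) != length(famSizes))
    stop("effects and famSizes must have one entry per family")
  VPbar <- if (is.list(vs)) vs$weightedMean else as.numeric(vs)
  if (VPbar <= 0) stop("phenotypic variance must be positive")
  N <- sum(famSizes)
  v <- c(0, 2 * effects)
  p <- c(0.5, famSizes / (2 * N))
  VG <- sum(p * v^2) - sum(p * v)^2
  100 * VG / VPbar
}
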