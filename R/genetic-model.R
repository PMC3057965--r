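#' Map functions and recombination scales
#'
#' \code{haldane} converts a map distance in cM to a meiotic recombination
#' fraction, \code{invHaldane} inverts it. \code{rilScale} converts a meiotic
#' fraction r to the fraction R observed between homozygous loci of a selfed
#' RIL (Haldane-Waddington, R = 2r/(1+2r)); \code{meioticScale} inverts it.
#' \code{composeRecomb} composes two adjacent meiotic fractions under no
#' interference (r12 = r1 + r2 - 2 r1 r2).
#'
#' Crossover counts observed in RILs estimate R, not r; all data-facing
#' fractions in this package are on the RIL scale and conversion to the
#' meiotic scale happens only inside composition and interval splitting.
#'
#' @param d map distance in cM (>= 0)
#' @param r meiotic recombination fraction in [0, 0.5]
#' @param R RIL-scale recombination fraction in [0, 0.5]
#' @param r1,r2 adjacent meiotic fractions
#' @return numeric, vectorised over the input
#' @examples
#' haldane(50)                  # (1 - exp(-1))/2
#' rilScale(0.1)                # 1/6
#' invHaldane(haldane(12.5))    # 12.5
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

#' @rdname haldane
#' @export
invHaldane <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("meiotic fraction must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane
#' @export
rilScale <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("meiotic fraction must be in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' @rdname haldane
#' @export
meioticScale <- function(R) {
  if (any(R < 0 | R > 0.5)) stop("RIL fraction must be in [0, 0.5]")
  R / (2 - 2 * R)
}

#' @rdname haldane
#' @export
composeRecomb <- function(r1, r2) r1 + r2 - 2 * r1 * r2

#' Per-family recombination fraction of a marker interval
#'
#' Estimates the RIL-scale recombination fraction between adjacent markers
#' \code{k} and \code{k+1} as the observed proportion of recombinant lines in
#' one family, clamped to [1e-6, 0.5 - 1e-6]. JICIM uses these per-family
#' estimates, rather than consensus-map distances, to recognise variation in
#' recombination frequency across families.
#'
#' @param nam a preprocessed, imputed \linkS4class{NAMExperiment}
#' @param family family level (as in \code{levels(lineFamily(nam))})
#' @param k row index of the left marker; marker \code{k + 1} must be on the
#'   same chromosome
#' @return RIL-scale fraction in (0, 0.5)
#' @export
estimateFamilyRecomb <- function(nam, family, k) {
  fam <- lineFamily(nam)
  if (!family %in% levels(fam))
    stop("family '", family, "' not present in the dataset")
  chrom <- as.character(rowData(nam)$chromosome)
  if (k < 1 || k + 1 > nrow(nam) || chrom[k] != chrom[k + 1])
    stop("markers ", k, " and ", k + 1, " do not form an interval")
  g <- genotypes(nam)
  idx <- which(fam == family)
  a <- g[k, idx]; b <- g[k + 1, idx]
  ok <- !is.na(a) & !is.na(b) & a != 2L & b != 2L
  if (!any(ok))
    return(rilScale(haldane(rowData(nam)$position_cM[k + 1] -
                            rowData(nam)$position_cM[k])))
  .clampR(mean(a[ok] != b[ok]))
}

.clampR <- function(R, eps = 1e-6) pmin(pmax(R, eps), 0.5 - eps)

# RIL-scale recombination fractions of all intervals of one chromosome,
# for every family: F x (m-1) matrix. Falls back to the consensus-map
# expectation when a family has no informative pairs in an interval.
.familyIntervalRecomb <- function(g, fam, pos) {
  m <- nrow(g)
  F <- nlevels(fam)
  out <- matrix(NA_real_, F, m - 1)
  consensus <- rilScale(haldane(pmax(diff(pos), 0)))
  for (f in seq_len(F)) {
    idx <- which(as.integer(fam) == f)
    gf <- g[, idx, drop = FALSE]
    obs <- !is.na(gf) & gf != 2L
    for (k in seq_len(m - 1)) {
      ok <- obs[k, ] & obs[k + 1, ]
      out[f, k] <- if (any(ok)) mean(gf[k, ok] != gf[k + 1, ok])
                   else consensus[k]
    }
  }
  .clampR(out)
}

#' QTL genotype-class probabilities in a marker interval
#'
#' For a putative QTL between flanking markers, lines of a family fall into
#' four classes by their flanking-marker genotypes: (+,+), (+,-), (-,+),
#' (-,-), where "+" is the founder homozygote. This returns the conditional
#' probability that the QTL genotype is the founder homozygote QfQf given
#' each class, for selfed RILs under no crossover interference.
#'
#' The three-locus fixation distribution of a selfed RIL is determined by
#' its three pairwise margins, each of which is an autonomous two-locus
#' selfing process with the Haldane-Waddington fraction of the corresponding
#' meiotic distance. Writing R1, R2 for the flank-QTL RIL fractions and R13
#' for the RIL fraction of the composed flank-flank meiotic distance, the
#' symmetric haplotype-class probabilities are
#' q_double = (R1 + R2 - R13)/4, q_right = (R2 + R13 - R1)/4,
#' q_left = (R1 + R13 - R2)/4, q_parental = 1/2 - q_left - q_right -
#' q_double, and the conditionals follow.
#'
#' @param rLeft RIL-scale fraction between the left marker and the QTL
#' @param rRight RIL-scale fraction between the QTL and the right marker
#' @return numeric of length 4: \code{p1..p4}, the probability of QfQf given
#'   classes (+,+), (+,-), (-,+), (-,-). \code{p3 = 1 - p2} and
#'   \code{p4 = 1 - p1}.
#' @examples
#' qtlClassProbs(0, rilScale(haldane(5)))   # QTL on the left marker
#' qtlClassProbs(rilScale(haldane(2.5)), rilScale(haldane(2.5)))
#' @export
qtlClassProbs <- function(rLeft, rRight) {
  if (rLeft < 0 || rLeft >= 0.5 || rRight < 0 || rRight >= 0.5)
    stop("RIL-scale fractions must be in [0, 0.5)")
  r1 <- meioticScale(rLeft)
  r2 <- meioticScale(rRight)
  r13 <- composeRecomb(r1, r2)
  if (r13 >= 0.5) stop("interval recombination fraction must be < 0.5")
  R13 <- rilScale(r13)
  q11 <- (rLeft + rRight - R13) / 4    # double recombinant: flanks agree, QTL differs
  q01 <- (rRight + R13 - rLeft) / 4    # recombination right of the QTL only
  q10 <- (rLeft + R13 - rRight) / 4    # recombination left of the QTL only
  q00 <- 0.5 - q01 - q10 - q11         # parental
  p1 <- if (q00 + q11 > 0) q00 / (q00 + q11) else 0.5
  p2 <- if (q01 + q10 > 0) q01 / (q01 + q10) else 0.5
  c(p1 = p1, p2 = p2, p3 = 1 - p2, p4 = 1 - p1)
}

# vectorised core used by the scan and the imputer: given vectors or
# matrices R1, R2 (RIL scale), return list(p1, p2) of the same shape
# (p3, p4 are the complements)
.classProbCore <- function(R1, R2) {
  r13 <- composeRecomb(meioticScale(R1), meioticScale(R2))
  R13 <- rilScale(r13)
  q11 <- (R1 + R2 - R13) / 4
  q01 <- (R2 + R13 - R1) / 4
  q10 <- (R1 + R13 - R2) / 4
  q00 <- 0.5 - q01 - q10 - q11
  d1 <- q00 + q11
  d2 <- q01 + q10
  list(p1 = ifelse(d1 > 0, q00 / d1, 0.5),
       p2 = ifelse(d2 > 0, q01 / d2, 0.5))
}

#' Flank-to-QTL recombination fractions at a scan position
#'
#' Locates the marker interval containing map position \code{x}, estimates
#' the family's RIL-scale interval fraction from its observed crossovers,
#' converts it to a family-specific meiotic length, splits that length by the
#' consensus-map proportion of \code{x} within the interval, and returns the
#' two flank-to-QTL fractions on the RIL scale.
#'
#' @inheritParams estimateFamilyRecomb
#' @param chromosome chromosome identifier
#' @param x scan position in cM (within the chromosome span)
#' @return list with \code{family}, \code{k} (left marker row index),
#'   \code{rLeft}, \code{rRight}, \code{rInterval} (all RIL scale)
#' @export
positionToIntervalRecomb <- function(nam, family, chromosome, x) {
  rd <- rowData(nam)
  idx <- which(as.character(rd$chromosome) == as.character(chromosome))
  if (!length(idx)) stop("chromosome '", chromosome, "' not in the map")
  pos <- rd$position_cM[idx]
  if (x < pos[1] || x > pos[length(pos)])
    stop("position ", x, " cM is outside chromosome ", chromosome,
         " [", pos[1], ", ", pos[length(pos)], "]")
  k <- findInterval(x, pos, rightmost.closed = TRUE)
  if (k == length(pos)) k <- k - 1L
  span <- pos[k + 1] - pos[k]
  lambda <- if (span > 0) (x - pos[k]) / span else 0
  Rint <- estimateFamilyRecomb(nam, family, idx[k])
  sp <- .splitInterval(Rint, lambda)
  list(family = family, k = idx[k], rLeft = sp[1], rRight = sp[2],
       rInterval = Rint)
}

# split a RIL-scale interval fraction at consensus proportion lambda;
# returns c(RLeft, RRight). Meiotic lengths add under Haldane, so the
# composition invariant holds exactly.
.splitInterval <- function(R, lambda) {
  d <- invHaldane(meioticScale(R))
  c(rilScale(haldane(lambda * d)), rilScale(haldane((1 - lambda) * d)))
}
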