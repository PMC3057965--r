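#' EM fit of the JICIM normal mixture at one testing position
#'
#' Line i of family f contributes p_i N(mu_f, s2_f) + (1 - p_i) N(mu0, s2_f)
#' to the likelihood, where p_i is the prior probability of the founder QTL
#' homozygote QfQf given the line's flanking-marker class, mu0 is the
#' common-genotype mean shared across families, and each family has its own
#' variance. The EM algorithm estimates the F+1 means and F variances:
#' the E-step computes per-line posteriors of QfQf; the M-step sets mu_f to
#' the posterior-weighted family mean, mu0 to the precision-weighted
#' (1/s2_f) pooled mean of the complementary posteriors across families, and
#' s2_f to the posterior-weighted within-family second moment about the two
#' means. Responsibilities are initialised from the marker-class priors and
#' variances from the null fit; iteration stops when the relative
#' log-likelihood change is below \code{tol} or after \code{maxit}
#' iterations (the best fit is then returned flagged unconverged).
#'
#' @param dY adjusted phenotypes (see \code{\link{adjustPhenotype}})
#' @param family factor assigning lines to families
#' @param classProb per-line prior probability of QfQf (from
#'   \code{\link{qtlClassProbs}} via the line's flanking-marker class)
#' @param tol relative log-likelihood convergence tolerance
#' @param maxit maximum EM iterations
#' @param trace if TRUE, also return the per-iteration log-likelihoods
#' @return list with \code{mu0}, \code{mu}, \code{sigma2}, \code{logLA},
#'   \code{iterations}, \code{converged} (and \code{trace})
#' @export
emFit <- function(dY, family, classProb, tol = 1e-8, maxit = 200,
                  trace = FALSE) {
  family <- droplevels(as.factor(family))
  stopifnot(length(dY) == length(family), length(classProb) == length(dY))
  fit <- .em_fit_cpp(as.numeric(dY), as.integer(family) - 1L,
                     nlevels(family), as.numeric(classProb),
                     tol, as.integer(maxit), trace)
  names(fit$mu) <- names(fit$sigma2) <- levels(family)
  fit
}

#' Per-family normal fit under the no-QTL null hypothesis
#'
#' Under H0 the adjusted phenotypes of each family follow a single normal
#' distribution; the ML estimates are the family mean and the family
#' variance with divisor n_f.
#'
#' @inheritParams emFit
#' @return list with per-family \code{mean}, \code{variance}, \code{n} and
#'   the total log-likelihood \code{logL0}
#' @export
nullFit <- function(dY, family) {
  family <- droplevels(as.factor(family))
  if (any(table(family) < 2)) stop("every family needs at least 2 lines")
  fit <- .null_fit_cpp(as.numeric(dY), as.integer(family) - 1L,
                       nlevels(family))
  names(fit$mean) <- names(fit$variance) <- names(fit$n) <- levels(family)
  fit
}

#' LOD score from an alternative and a null fit
#'
#' LOD = (logLA - logL0) / ln 10, clamped at 0.
#'
#' @param fit an \code{\link{emFit}} result
#' @param null a \code{\link{nullFit}} result on the same data
#' @return non-negative LOD score
#' @export
lodScore <- function(fit, null) {
  max(0, (fit$logLA - null$logL0) / log(10))
}

## ---- scan plan: genotype-dependent precomputation, reusable across
##      phenotype permutations and simulation replicates ----

.scanPlan <- function(nam, step = 1) {
  g <- genotypes(nam)
  if (anyNA(g) || any(g == 2L))
    stop("genotypes must be preprocessed and imputed before scanning")
  fam <- lineFamily(nam)
  pos <- rowData(nam)$position_cM
  chromIdx <- .chromIndex(nam)
  plans <- lapply(names(chromIdx), function(cc) {
    ci <- chromIdx[[cc]]
    m <- length(ci)
    p <- pos[ci]
    grid <- seq(p[1], p[m], by = step)
    if (grid[length(grid)] < p[m]) grid <- c(grid, p[m])
    k <- findInterval(grid, p, rightmost.closed = TRUE)
    k[k >= m] <- m - 1L
    span <- p[k + 1] - p[k]
    lambda <- ifelse(span > 0, (grid - p[k]) / span, 0)
    gc <- g[ci, , drop = FALSE]
    famR <- .familyIntervalRecomb(gc, fam, p)        # F x (m-1), RIL scale
    dInt <- invHaldane(meioticScale(famR))           # family meiotic lengths, cM
    npos <- length(grid)
    F <- nlevels(fam)
    D <- dInt[, k, drop = FALSE]                     # F x npos
    L <- matrix(lambda, F, npos, byrow = TRUE)
    R1 <- rilScale(haldane(L * D))
    R2 <- rilScale(haldane((1 - L) * D))
    cp <- .classProbCore(R1, R2)                     # F x npos each
    p1 <- cp$p1
    p2 <- cp$p2
    pf <- array(0, c(4, F, npos))
    pf[1, , ] <- 1 - p1   # class (A,A): P(QfQf) = p4
    pf[2, , ] <- 1 - p2   # class (A,B): p3
    pf[3, , ] <- p2       # class (B,A): p2
    pf[4, , ] <- p1       # class (B,B): p1
    cls <- t(2L * gc[-m, , drop = FALSE] + gc[-1, , drop = FALSE])  # N x (m-1)
    list(chrom = cc, markerIdx = ci, pos = p, grid = grid,
         k = k, pf = pf, cls = cls, famR = famR)
  })
  list(chromPlans = plans, family = fam, F = nlevels(fam),
       N = length(fam), step = step)
}

.scanWithPlan <- function(nam, plan, model, tol = 1e-8, maxit = 200) {
  fam <- plan$family
  fi <- as.integer(fam) - 1L
  F <- plan$F
  base <- adjustPhenotype(nam, model)
  profiles <- lapply(plan$chromPlans, function(cp) {
    nint <- length(cp$pos) - 1L
    dY <- matrix(base, plan$N, nint)
    touched <- which(cp$markerIdx[-length(cp$markerIdx)] %in% model$markers |
                     cp$markerIdx[-1] %in% model$markers)
    for (k in touched)
      dY[, k] <- adjustPhenotype(nam, model,
                                 flankMarkers = cp$markerIdx[c(k, k + 1)])
    res <- .scan_core_cpp(dY, cp$cls, fi, F, as.numeric(cp$pf),
                          as.integer(cp$k) - 1L, tol, as.integer(maxit))
    eff <- (res$mu - res$mu0) / 2
    colnames(eff) <- paste0("a_", levels(fam))
    cbind(data.frame(chromosome = cp$chrom, position_cM = cp$grid,
                     lod = res$lod, stringsAsFactors = FALSE),
          eff)
  })
  do.call(rbind, profiles)
}

#' Step 2 of JICIM: one-dimensional genome scan
#'
#' Scans the genome on a cM grid. At each position the flanking interval is
#' located, per-family QTL-class probabilities are computed from
#' family-estimated recombination fractions (\code{\link{qtlClassProbs}}),
#' phenotypes are adjusted for all selected cofactors except the two
#' flanking markers, and the mixture of \code{\link{emFit}} is compared with
#' the null of \code{\link{nullFit}} to give a LOD score and per-family
#' additive effects a_f = (mu_f - mu0)/2.
#'
#' @param nam an imputed \linkS4class{NAMExperiment}
#' @param model a \code{\link{stepwiseSelect}} fit; fitted automatically if
#'   NULL
#' @param step scan step in cM (default 1, the conventional grid)
#' @param pIn,pOut stepwise thresholds used when \code{model} is NULL
#' @param threshold optional LOD threshold; when given,
#'   \code{\link{callQTL}} is applied before returning
#' @param tol,maxit EM controls (see \code{\link{emFit}})
#' @return a \linkS4class{ScanResult}
#' @examples
#' sim <- simulateNAMDataset(nChrom = 2, chromLength = 60, spacing = 10,
#'                           famSizes = c(60, 60), famVar = c(1, 1),
#'                           qtl = data.frame(chromosome = "1",
#'                                            position_cM = 30,
#'                                            family = "F1", a = 1.2),
#'                           seed = 7)
#' sr <- jicimScan(sim$nam, step = 2)
#' head(lodProfile(sr))
#' @export
jicimScan <- function(nam, model = NULL, step = 1, pIn = 1e-4, pOut = 2e-4,
                      threshold = NULL, tol = 1e-8, maxit = 200) {
  if (step <= 0) stop("scan step must be positive")
  if (is.null(model))
    model <- stepwiseSelect(nam, pIn = pIn, pOut = pOut)
  plan <- .scanPlan(nam, step)
  profile <- .scanWithPlan(nam, plan, model, tol, maxit)
  fam <- lineFamily(nam)
  vs <- varianceSummary(phenotype(nam), fam)
  sr <- new("ScanResult", profile = profile,
            calls = .emptyCalls(levels(fam)),
            threshold = numeric(0), step = step,
            founders = levels(fam),
            famVar = vs$variances, famSize = as.integer(table(fam)))
  if (!is.null(threshold))
    sr <- callQTL(sr, threshold)
  sr
}

#' Single-family inclusive composite interval mapping (ICIM)
#'
#' The F = 1 special case of \code{\link{jicimScan}}: a two-component normal
#' mixture with one variance, scanned on the same grid.
#'
#' @inheritParams jicimScan
#' @return a \linkS4class{ScanResult}
#' @export
icimScan <- function(nam, model = NULL, step = 1, pIn = 1e-4, pOut = 2e-4,
                     threshold = NULL, tol = 1e-8, maxit = 200) {
  if (nlevels(lineFamily(nam)) != 1L)
    stop("icimScan requires a single-family (biparental) dataset")
  jicimScan(nam, model = model, step = step, pIn = pIn, pOut = pOut,
            threshold = threshold, tol = tol, maxit = maxit)
}

.emptyCalls <- function(founders) {
  base <- data.frame(chromosome = character(0), position_cM = numeric(0),
                     lod = numeric(0), si_lo = numeric(0), si_hi = numeric(0),
                     stringsAsFactors = FALSE)
  for (f in founders) base[[paste0("a_", f)]] <- numeric(0)
  for (f in founders) base[[paste0("pve_", f)]] <- numeric(0)
  base$pve_nam <- numeric(0)
  base
}

# Shared peak-declaration rule: weak local maxima above the threshold whose
# one-LOD region does not overlap a higher accepted peak's region; support
# interval = maximal contiguous region with lod >= peak - 1. Returns one row
# per declared peak with the profile row index.
.declarePeaks <- function(profile, threshold) {
  rows <- integer(0); los <- numeric(0); his <- numeric(0)
  for (cc in unique(profile$chromosome)) {
    sel <- which(profile$chromosome == cc)
    lod <- profile$lod[sel]
    n <- length(lod)
    if (n < 2) next
    isMax <- lod >= threshold &
      c(TRUE, lod[-1] >= lod[-n]) &
      c(lod[-n] >= lod[-1], TRUE)
    cand <- which(isMax)
    if (!length(cand)) next
    cand <- cand[order(-lod[cand], cand)]   # desc LOD, ties leftmost
    regions <- list()
    for (i in cand) {
      lo <- i; hi <- i
      while (lo > 1 && lod[lo - 1] >= lod[i] - 1) lo <- lo - 1
      while (hi < n && lod[hi + 1] >= lod[i] - 1) hi <- hi + 1
      if (any(vapply(regions, function(r) lo <= r[2] && hi >= r[1], TRUE)))
        next   # merges into a higher peak sharing the support region
      regions[[length(regions) + 1]] <- c(lo, hi)
      rows <- c(rows, sel[i]); los <- c(los, sel[lo]); his <- c(his, sel[hi])
    }
  }
  ord <- order(rows)
  data.frame(chromosome = profile$chromosome[rows][ord],
             position_cM = profile$position_cM[rows][ord],
             lod = profile$lod[rows][ord],
             si_lo = profile$position_cM[los][ord],
             si_hi = profile$position_cM[his][ord],
             row = rows[ord],
             stringsAsFactors = FALSE)
}

#' Declare QTL from a LOD profile
#'
#' A local maximum above the threshold is declared a QTL when the LOD decays
#' by at least 1 on both sides of the peak (one-sided at chromosome ends).
#' Its one-LOD support interval is the maximal contiguous region around the
#' peak with LOD >= peak - 1; two maxima sharing one support region merge
#' into the higher peak. Per-family additive effects are read off the
#' profile at the peak; per-family PVE is 100 a_f^2 / V_Pf and the NAM-level
#' PVE comes from \code{\link{pveNAM}}.
#'
#' @param sr a \linkS4class{ScanResult}
#' @param threshold LOD threshold (e.g. from \code{\link{gwerThreshold}})
#' @return the \code{ScanResult} with \code{qtlCalls(sr)} filled
#' @export
callQTL <- function(sr, threshold) {
  profile <- sr@profile
  founders <- sr@founders
  effCols <- paste0("a_", founders)
  pk <- .declarePeaks(profile, threshold)
  if (nrow(pk)) {
    vpbar <- sum(sr@famVar * sr@famSize) / sum(sr@famSize)
    A <- as.matrix(profile[pk$row, effCols, drop = FALSE])
    calls <- pk[, c("chromosome", "position_cM", "lod", "si_lo", "si_hi")]
    for (j in seq_along(founders)) calls[[effCols[j]]] <- A[, j]
    for (j in seq_along(founders))
      calls[[paste0("pve_", founders[j])]] <- 100 * A[, j]^2 / sr@famVar[j]
    calls$pve_nam <- apply(A, 1, pveNAM, famSizes = sr@famSize, vs = vpbar)
    rownames(calls) <- NULL
    sr@calls <- calls
  } else {
    sr@calls <- .emptyCalls(founders)
  }
  sr@threshold <- threshold
  sr
}
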