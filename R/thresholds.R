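#' Residual permutation of a NAM phenotype
#'
#' Fits overall and family means to the phenotype, permutes the residuals
#' globally across all lines (residuals are exchangeable across families
#' under the no-QTL null once family means are removed), and adds them back
#' to the fitted part. The fitted family means are unchanged and the
#' permuted vector carries the identical multiset of residuals.
#'
#' @param y phenotypes
#' @param family family factor
#' @param seed optional seed; when NULL the current RNG stream is used
#' @return permuted phenotype vector
#' @export
permuteResiduals <- function(y, family, seed = NULL) {
  family <- droplevels(as.factor(family))
  fit <- stats::ave(as.numeric(y), family)
  res <- as.numeric(y) - fit
  .withSeed(seed, function() fit + sample(res))
}

#' Permutation threshold for the step-1 marker-entry probability
#'
#' For each permuted phenotype the smallest marker-association P-value over
#' all markers is recorded (marker association = family-nested group F-test
#' against the family-means model, the same statistic that drives the first
#' stepwise entry). The threshold is the empirical alpha-quantile of these
#' minima: a per-marker entry probability that keeps the genome-wide type I
#' error of step 1 at alpha.
#'
#' @param nam an imputed \linkS4class{NAMExperiment}
#' @param reps number of permutations (>= 100)
#' @param alpha genome-wide type I error
#' @param seed RNG seed
#' @return the probability threshold, with the per-rep minima in
#'   \code{attr(, "minP")}
#' @export
stepwisePThreshold <- function(nam, reps = 1000, alpha = 0.05, seed = 1L) {
  if (reps < 100) stop("at least 100 permutations are required")
  X <- .signedGenotypes(nam)
  storage.mode(X) <- "double"
  y <- unname(phenotype(nam))
  fam <- lineFamily(nam)
  famRows <- split(seq_along(y), fam)
  N <- length(y); F <- nlevels(fam)
  minP <- .withSeed(seed, function()
    vapply(seq_len(reps), function(r) {
      ystar <- permuteResiduals(y, fam)
      min(.markerGroupP(X, ystar, famRows, N, F), na.rm = TRUE)
    }, 0))
  out <- unname(stats::quantile(minP, alpha, type = 1))
  attr(out, "minP") <- minP
  out
}

#' Genome-wide k-error-rate (GWER(k)) LOD threshold
#'
#' Permutation threshold guarding against more than k false-positive QTL
#' per genome scan. For each permuted phenotype the full JICIM pipeline
#' (stepwise cofactor selection, then the interval scan) is rerun and all
#' peaks are collected with the same declaration rule as
#' \code{\link{callQTL}} (threshold 0, one-LOD decay); the per-rep statistic
#' is the (k+1)-th largest peak LOD (0 when there are fewer peaks) and the
#' threshold is its empirical (1 - alpha) quantile. k = 0 reduces to the
#' classical genome-wide maximum-LOD permutation threshold.
#'
#' @inheritParams stepwisePThreshold
#' @param k number of tolerated false positives (>= 0)
#' @param step,pIn,pOut scan and stepwise controls passed through
#' @return list with \code{k}, \code{alpha}, \code{reps}, \code{seed},
#'   \code{threshold} and the per-rep \code{stats}
#' @export
gwerThreshold <- function(nam, k = 2, reps = 1000, alpha = 0.05, seed = 1L,
                          step = 1, pIn = 1e-4, pOut = 2e-4) {
  if (k < 0) stop("k must be non-negative")
  plan <- .scanPlan(nam, step)
  y <- unname(phenotype(nam))
  fam <- lineFamily(nam)
  stats_ <- .withSeed(seed, function()
    vapply(seq_len(reps), function(r) {
      ystar <- permuteResiduals(y, fam)
      nam2 <- nam
      phenotype(nam2) <- ystar
      model <- stepwiseSelect(nam2, pIn = pIn, pOut = pOut)
      profile <- .scanWithPlan(nam2, plan, model)
      .kthPeakLod(profile, k)
    }, 0))
  list(k = k, alpha = alpha, reps = reps, seed = seed,
       threshold = unname(stats::quantile(stats_, 1 - alpha, type = 7)),
       stats = stats_)
}

# (k+1)-th largest declared-peak LOD of a profile (0 if fewer peaks),
# using the callQTL declaration rule at threshold 0
.kthPeakLod <- function(profile, k) {
  peaks <- .declarePeaks(profile, .Machine$double.eps)$lod
  if (length(peaks) <= k) 0 else sort(peaks, decreasing = TRUE)[k + 1]
}
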