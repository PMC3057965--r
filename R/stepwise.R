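#' Step 1 of JICIM: stepwise selection of family-nested marker cofactors
#'
#' Fits the fixed-effects model Y = mu + u_f + sum_j x_ijf beta_jf + e by
#' forward-backward stepwise regression. Family effects are always in the
#' model. Candidate terms are whole markers: marker j contributes one
#' family-nested column per family (x_ijf = +1 founder allele, -1 common
#' parent allele, 0 outside family f; the common parent is the reference
#' level), and enters or leaves as a group judged by a partial F-test with F
#' numerator degrees of freedom. A group enters when its p-value is below
#' \code{pIn}; after each entry any included group with p-value above
#' \code{pOut} is removed. Coefficients of unselected markers are exactly 0.
#'
#' Because every column of the model is supported on a single family, the
#' fit decomposes into per-family least squares, which is how it is
#' computed. Ties in the entry test are broken by the smallest marker index;
#' the selection is deterministic given the input. A candidate marker that is
#' aliased within every family is skipped with a warning.
#'
#' @param nam an imputed \linkS4class{NAMExperiment}
#' @param pIn entry probability threshold (default 1e-4)
#' @param pOut removal probability threshold (default 2e-4)
#' @param maxTerms cap on the number of selected marker groups
#'   (default \code{floor(N/10)})
#' @return an object of class \code{jicimStepwise}: selected marker indices
#'   and names, per-family coefficients, family intercepts, fitted values and
#'   residuals
#' @seealso \code{\link{adjustPhenotype}}, \code{\link{jicimScan}}
#' @export
stepwiseSelect <- function(nam, pIn = 1e-4, pOut = 2e-4, maxTerms = NULL) {
  X <- .signedGenotypes(nam)
  storage.mode(X) <- "double"
  y <- unname(phenotype(nam))
  if (anyNA(y)) stop("phenotype contains missing values")
  fam <- lineFamily(nam)
  famRows <- split(seq_along(y), fam)
  N <- length(y); F <- nlevels(fam); m <- ncol(X)
  if (is.null(maxTerms)) maxTerms <- max(1L, floor(N / 10))
  sel <- integer(0)
  warnedAlias <- FALSE

  fitState <- function(sel) {
    qrs <- lapply(famRows, function(rows)
      qr(cbind(1, X[rows, sel, drop = FALSE])))
    res <- unlist(lapply(seq_len(F), function(f)
      qr.resid(qrs[[f]], y[famRows[[f]]])), use.names = FALSE)
    resid <- numeric(N)
    resid[unlist(famRows, use.names = FALSE)] <- res
    pTot <- sum(vapply(qrs, function(q) q$rank, 0L))
    list(qrs = qrs, resid = resid, rss = sum(resid^2), pTot = pTot)
  }
  groupStats <- function(st, candidates) {
    dropRSS <- numeric(length(candidates))
    df1 <- integer(length(candidates))
    for (f in seq_len(F)) {
      rows <- famRows[[f]]
      qrf <- st$qrs[[f]]
      Q <- qr.Q(qrf)[, seq_len(qrf$rank), drop = FALSE]
      C <- X[rows, candidates, drop = FALSE]
      Z <- C - Q %*% crossprod(Q, C)
      den <- colSums(Z^2)
      num <- drop(crossprod(Z, st$resid[rows]))
      ok <- den > 1e-8 * length(rows)
      dropRSS <- dropRSS + ifelse(ok, num^2 / pmax(den, 1e-300), 0)
      df1 <- df1 + ok
    }
    df2 <- N - st$pTot - df1
    fstat <- (dropRSS / pmax(df1, 1L)) /
      (pmax(st$rss - dropRSS, 0) / pmax(df2, 1L))
    # df clamped inside pf: entries with df1 = 0 are discarded by the mask
    p <- ifelse(df1 > 0 & df2 > 0,
                stats::pf(fstat, pmax(df1, 1L), pmax(df2, 1L),
                          lower.tail = FALSE), NA_real_)
    list(p = p, df1 = df1)
  }

  st <- fitState(sel)
  repeat {
    candidates <- setdiff(seq_len(m), sel)
    if (!length(candidates) || length(sel) >= maxTerms) break
    gs <- groupStats(st, candidates)
    if (any(is.na(gs$p)) && !warnedAlias) {
      warning("candidate marker group(s) aliased in every family; skipped")
      warnedAlias <- TRUE
    }
    usable <- which(!is.na(gs$p))
    if (!length(usable)) break
    best <- usable[which.min(gs$p[usable])]   # which.min: smallest index on ties
    if (gs$p[best] >= pIn) break
    sel <- sort(c(sel, candidates[best]))
    st <- fitState(sel)
    # backward sweep
    repeat {
      if (length(sel) < 2) break
      pvals <- vapply(seq_along(sel), function(i) {
        st0 <- fitState(sel[-i])
        df1 <- max(st$pTot - st0$pTot, 1L)  # columns the group contributes
        df2 <- N - st$pTot
        fstat <- (max(st0$rss - st$rss, 0) / df1) / (st$rss / max(df2, 1L))
        stats::pf(fstat, df1, df2, lower.tail = FALSE)
      }, 0)
      worst <- which.max(pvals)
      if (pvals[worst] <= pOut) break
      sel <- sel[-worst]
      st <- fitState(sel)
    }
  }

  coefs <- lapply(seq_len(F), function(f) {
    b <- qr.coef(st$qrs[[f]], y[famRows[[f]]])
    b[is.na(b)] <- 0
    b
  })
  intercepts <- vapply(coefs, `[`, 0, 1)
  beta <- matrix(0, length(sel), F,
                 dimnames = list(colnames(X)[sel], levels(fam)))
  if (length(sel))
    for (f in seq_len(F)) beta[, f] <- coefs[[f]][-1]
  nf <- lengths(famRows)
  mu <- sum(nf * intercepts) / N
  fitted <- y - st$resid
  structure(list(markers = sel,
                 markerNames = colnames(X)[sel],
                 beta = beta,
                 intercepts = stats::setNames(intercepts, levels(fam)),
                 mu = mu,
                 u = stats::setNames(intercepts - mu, levels(fam)),
                 fitted = fitted,
                 residuals = st$resid,
                 rss = st$rss,
                 pIn = pIn, pOut = pOut,
                 family = fam, N = N, F = F),
            class = "jicimStepwise")
}

#' @export
print.jicimStepwise <- function(x, ...) {
  cat("JICIM step-1 stepwise model:", length(x$markers),
      "marker cofactor group(s) selected (pIn =", x$pIn,
      ", pOut =", x$pOut, ")\n")
  if (length(x$markers))
    cat("  markers:", paste(x$markerNames, collapse = ", "), "\n")
  invisible(x)
}

#' Adjust phenotypes for the scan through a fitted step-1 model
#'
#' Computes dY_i = y_i - b_f(i) - sum over selected markers j not flanking
#' the current scan interval of x_ijf beta_jf. Effects of the two markers
#' flanking the scan interval are deliberately retained (not subtracted),
#' so the local QTL signal survives the background correction.
#'
#' The subtracted family effect b_f is the family's all-common baseline,
#' b_f = c_f - sum_j beta_jf (the fitted value of a line carrying the
#' common-parent allele at every selected marker), not the family mean.
#' The mixture of step 2 assumes one common-genotype mean mu0 shared across
#' families -- the QTL genotypic values are 0 for the common homozygote and
#' 2 a_f for the founder homozygote -- and only baseline-centring makes the
#' common classes of different families comparable: centring on family
#' means would shift a segregating family's common class to -a_f while
#' leaving non-segregating families at 0, attenuating the joint signal of
#' rare QTL. With a single family the two conventions differ by a constant
#' and the LOD is unchanged. When no markers are selected the adjustment
#' reduces to family centring.
#'
#' @param nam the \linkS4class{NAMExperiment} the model was fitted on
#' @param model a \code{jicimStepwise} fit
#' @param flankMarkers integer row indices of the flanking markers of the
#'   current scan interval (0, 1 or 2 values); their effects are not removed
#' @return numeric vector of adjusted phenotypes
#' @export
adjustPhenotype <- function(nam, model, flankMarkers = integer(0)) {
  if (length(flankMarkers) && (any(flankMarkers < 1) ||
                               any(flankMarkers > nrow(nam))))
    stop("flank marker indices out of range")
  fi <- as.integer(model$family)
  dY <- model$residuals
  if (length(model$markers))
    dY <- dY + colSums(model$beta)[fi]   # intercept -> all-common baseline
  back <- intersect(model$markers, flankMarkers)
  if (length(back)) {
    X <- .signedGenotypes(nam)
    for (j in back)
      dY <- dY + X[, j] * model$beta[match(j, model$markers), fi]
  }
  dY
}

# marker-association p-values against the family-means model (the first
# forward sweep); shared by stepwiseSelect and the permutation threshold
.markerGroupP <- function(X, y, famRows, N, F) {
  m <- ncol(X)
  dropRSS <- numeric(m)
  df1 <- integer(m)
  rss <- 0
  resid <- numeric(N)
  for (rows in famRows) {
    r <- y[rows] - mean(y[rows])
    resid[rows] <- r
    rss <- rss + sum(r^2)
  }
  for (rows in famRows) {
    C <- X[rows, , drop = FALSE]
    Z <- C - matrix(colMeans(C), nrow = length(rows), ncol = m, byrow = TRUE)
    den <- colSums(Z^2)
    num <- drop(crossprod(Z, resid[rows]))
    ok <- den > 1e-8 * length(rows)
    dropRSS <- dropRSS + ifelse(ok, num^2 / pmax(den, 1e-300), 0)
    df1 <- df1 + ok
  }
  df2 <- N - F - df1
  fstat <- (dropRSS / pmax(df1, 1L)) / (pmax(rss - dropRSS, 0) / pmax(df2, 1L))
  ifelse(df1 > 0 & df2 > 0,
         stats::pf(fstat, pmax(df1, 1L), pmax(df2, 1L), lower.tail = FALSE),
         NA_real_)
}
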