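#' Was a true QTL detected within a support-interval window?
#'
#' TRUE iff some declared QTL on the true chromosome has its peak within
#' \code{si/2} cM of the true position (a window of length \code{si}
#' centred at the truth).
#'
#' @param calls calls data.frame (\code{\link{qtlCalls}})
#' @param chromosome,position true QTL location
#' @param si window length in cM
#' @return logical
#' @export
detectedWithinSI <- function(calls, chromosome, position, si) {
  if (!nrow(calls)) return(FALSE)
  any(calls$chromosome == as.character(chromosome) &
        abs(calls$position_cM - position) <= si / 2)
}

#' Detection-power experiment for a single (possibly rare) QTL
#'
#' Simulates a NAM population once, then per replicate places a QTL (at a
#' marker or at an interval midpoint), draws a noise-background phenotype,
#' runs the full JICIM (or ICIM when F = 1) pipeline, and scores detection
#' within each requested support-interval window centred at the true
#' position. One replicate corresponds to one QTL placement; when
#' \code{reps} is smaller than the number of markers (or intervals) the
#' placements are a seeded random subset without replacement, otherwise
#' every position is used once.
#'
#' @inheritParams makeGridMap
#' @param famSizes,famVar family sizes and per-family phenotypic variances
#' @param effects per-family additive effects of the QTL (0 where it does
#'   not segregate; a rare QTL has one nonzero entry)
#' @param scenario \code{"on_marker"} or \code{"mid_interval"}
#' @param siList support-interval lengths in cM
#' @param reps number of replicates (placements)
#' @param threshold LOD threshold for declaration (e.g. a published GWER(k)
#'   value or \code{\link{gwerThreshold}}\code{$threshold})
#' @param step,pIn,pOut scan and stepwise controls
#' @param seed RNG seed governing the whole experiment
#' @return data.frame of class \code{jicimPower} with one row per SI:
#'   scenario, effect (largest |a_f|), si, reps, power, binomial se;
#'   per-replicate detail in \code{attr(, "detail")}
#' @export
runPowerExperiment <- function(nChrom = 10, chromLength = 140, spacing = 1.3,
                               famSizes = rep(200, 25),
                               famVar = rep(1, length(famSizes)),
                               effects, scenario = c("on_marker",
                                                     "mid_interval"),
                               siList = c(1, 2, 5, 10), reps = 100,
                               threshold, step = 1, pIn = 1e-4, pOut = 2e-4,
                               seed = 1L) {
  scenario <- match.arg(scenario)
  map <- makeGridMap(nChrom, chromLength, spacing)
  nam <- simulateNAMGenotypes(map, famSizes, seed = seed)
  fam <- lineFamily(nam)
  F <- nlevels(fam)
  if (length(effects) != F) stop("one effect per family is required")
  plan <- .scanPlan(nam, step)
  total <- if (scenario == "on_marker") nrow(nam)
           else nrow(.intervalTable(nam))
  if (reps > total)
    stop("reps may not exceed the number of ",
         if (scenario == "on_marker") "markers" else "intervals", " (", total, ")")
  effMat <- matrix(effects, 1, F)
  det <- matrix(NA, reps, length(siList))
  truthPos <- numeric(reps)
  truthChrom <- character(reps)
  .withSeed(seed + 1L, function() {
    placements <- if (reps < total) sample.int(total, reps) else seq_len(total)
    for (r in seq_len(reps)) {
      pq <- placeQTL(nam, scenario, placements[r])
      y <- phenotypeNoiseBackground(fam, famVar, effMat,
                                    matrix(pq$geno, ncol = 1), mode = "noise")
      nam2 <- nam
      phenotype(nam2) <- y
      model <- stepwiseSelect(nam2, pIn = pIn, pOut = pOut)
      profile <- .scanWithPlan(nam2, plan, model)
      calls <- .declarePeaks(profile, threshold)
      det[r, ] <<- vapply(siList, function(si)
        detectedWithinSI(calls, pq$chromosome, pq$position_cM, si), TRUE)
      truthPos[r] <<- pq$position_cM
      truthChrom[r] <<- pq$chromosome
    }
  })
  power <- colMeans(det)
  out <- data.frame(scenario = scenario, effect = max(abs(effects)),
                    si = siList, reps = reps, power = power,
                    se = sqrt(power * (1 - power) / reps))
  attr(out, "detail") <- list(detected = det, position = truthPos,
                              chromosome = truthChrom, seed = seed)
  class(out) <- c("jicimPower", class(out))
  out
}

#' Linked-QTL dissection experiment
#'
#' Simulates a NAM population with two linked QTL anchored on markers of one
#' chromosome under the variance-preserving recipe (error variance
#' V_Pf - a1f^2 - a2f^2), reruns JICIM per replicate, and collects the
#' declared QTL of every run.
#'
#' @inheritParams runPowerExperiment
#' @param effects1,effects2 per-family additive effects of the two QTL
#' @param chromosome,pos1,pos2 chromosome and cM anchors; each QTL is placed
#'   on the nearest marker
#' @return list with \code{calls} (per-replicate list of calls data.frames),
#'   \code{truth} (2-row data.frame) and \code{threshold}
#' @export
runLinkedQTLExperiment <- function(nChrom = 10, chromLength = 140,
                                   spacing = 1.3, famSizes = rep(200, 25),
                                   famVar = rep(1, length(famSizes)),
                                   effects1, effects2, chromosome = "2",
                                   pos1 = 77, pos2 = 97, reps = 100,
                                   threshold, step = 1, pIn = 1e-4,
                                   pOut = 2e-4, seed = 1L) {
  map <- makeGridMap(nChrom, chromLength, spacing)
  nam <- simulateNAMGenotypes(map, famSizes, seed = seed)
  fam <- lineFamily(nam)
  F <- nlevels(fam)
  rd <- rowData(nam)
  onChrom <- which(as.character(rd$chromosome) == as.character(chromosome))
  m1 <- onChrom[which.min(abs(rd$position_cM[onChrom] - pos1))]
  m2 <- onChrom[which.min(abs(rd$position_cM[onChrom] - pos2))]
  g <- genotypes(nam)
  qg <- cbind(g[m1, ], g[m2, ])
  effMat <- rbind(matrix(effects1, 1, F), matrix(effects2, 1, F))
  truth <- data.frame(chromosome = as.character(chromosome),
                      position_cM = rd$position_cM[c(m1, m2)])
  plan <- .scanPlan(nam, step)
  callsList <- .withSeed(seed + 1L, function()
    lapply(seq_len(reps), function(r) {
      y <- phenotypeNoiseBackground(fam, famVar, effMat, qg,
                                    mode = "linked_pair")
      nam2 <- nam
      phenotype(nam2) <- y
      model <- stepwiseSelect(nam2, pIn = pIn, pOut = pOut)
      profile <- .scanWithPlan(nam2, plan, model)
      .declarePeaks(profile, threshold)
    }))
  list(calls = callsList, truth = truth, threshold = threshold)
}

#' Summarise linked-QTL dissection runs
#'
#' Histograms declared-QTL positions into cM bins on the truth chromosome
#' and reports the fraction of replicates that separate the two QTL
#' properly: at least two declared QTL, with one peak within \code{window}
#' cM of each true position (two distinct peaks).
#'
#' @param callsList list of per-replicate calls data.frames
#' @param truth 2-row data.frame (\code{chromosome}, \code{position_cM})
#' @param bins numeric break points in cM for the histogram
#' @param window half-window (cM) for matching a peak to a truth position
#' @return list with \code{counts} (named per bin), \code{separation}
#'   (fraction of replicates) and \code{nCalls} per replicate
#' @export
linkedQTLSummary <- function(callsList, truth, bins = seq(0, 140, by = 5),
                             window = 2.5) {
  stopifnot(nrow(truth) == 2)
  cc <- as.character(truth$chromosome[1])
  pos <- unlist(lapply(callsList, function(d)
    d$position_cM[d$chromosome == cc]), use.names = FALSE)
  counts <- table(cut(pos, breaks = bins, right = FALSE))
  sep <- vapply(callsList, function(d) {
    p <- d$position_cM[d$chromosome == cc]
    if (length(p) < 2) return(FALSE)
    i1 <- which(abs(p - truth$position_cM[1]) <= window)
    i2 <- which(abs(p - truth$position_cM[2]) <= window)
    length(i1) > 0 && length(i2) > 0 && length(union(i1, i2)) >= 2
  }, TRUE)
  list(counts = counts, separation = mean(sep),
       nCalls = vapply(callsList, nrow, 0L))
}
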