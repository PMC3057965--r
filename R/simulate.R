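#' Regular consensus map for simulation
#'
#' @param nChrom number of chromosomes
#' @param chromLength chromosome length in cM
#' @param spacing marker spacing in cM
#' @return map data.frame (\code{marker}, \code{chromosome},
#'   \code{position_cM})
#' @export
makeGridMap <- function(nChrom = 10, chromLength = 140, spacing = 1.3) {
  maps <- lapply(seq_len(nChrom), function(cc) {
    pos <- seq(0, chromLength, by = spacing)
    data.frame(marker = sprintf("c%d_m%d", cc, seq_along(pos)),
               chromosome = as.character(cc), position_cM = pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Simulate NAM RIL genotypes on a consensus map
#'
#' Each line's chromosome is generated as a first-order Markov chain on the
#' RIL-observable scale: the first marker is common-parent or founder with
#' probability 1/2 each, and successive markers switch with probability
#' R = rilScale(haldane(spacing)). Chromosomes and lines are independent.
#' All families share the same process (every marker segregates 1:1 in
#' every family).
#'
#' @param map consensus map data.frame (see \code{\link{makeGridMap}})
#' @param famSizes integer vector of family sizes; names (or \code{F1..FK})
#'   become the family levels
#' @param seed RNG seed
#' @return a \linkS4class{NAMExperiment} with phenotype NA
#' @export
simulateNAMGenotypes <- function(map, famSizes, seed = 1L) {
  if (is.null(names(famSizes)))
    names(famSizes) <- paste0("F", seq_along(famSizes))
  N <- sum(famSizes)
  chromLevels <- unique(map$chromosome)
  g <- .withSeed(seed, function() {
    blocks <- lapply(chromLevels, function(cc) {
      pos <- map$position_cM[map$chromosome == cc]
      m <- length(pos)
      R <- rilScale(haldane(pmax(diff(pos), 0)))
      first <- as.integer(stats::runif(N) < 0.5)
      if (m == 1) return(matrix(first, 1, N))
      S <- matrix(stats::runif(N * (m - 1)), N, m - 1) <
        matrix(R, N, m - 1, byrow = TRUE)
      cum <- if (m == 2) S + 0L else t(apply(S, 1, cumsum))
      flips <- cbind(0L, cum)
      t((first + flips) %% 2L)
    })
    do.call(rbind, blocks)
  })
  storage.mode(g) <- "integer"
  fam <- factor(rep(names(famSizes), famSizes), levels = names(famSizes))
  NAMExperiment(g, map, family = fam,
                phenotype = rep(NA_real_, N),
                founders = names(famSizes))
}

#' Place a QTL on the map under one of the two scan scenarios
#'
#' \code{on_marker}: the QTL coincides with marker \code{index}; every
#' line's QTL genotype is that marker's genotype. \code{mid_interval}: the
#' QTL sits at the midpoint of interval \code{index} (the interval between
#' the index-th adjacent marker pair of the genome, never spanning a
#' chromosome break); each line's QTL genotype is copied from its left
#' flanking marker with probability 0.5 and from its right flank otherwise.
#'
#' @param nam an imputed \linkS4class{NAMExperiment}
#' @param scenario \code{"on_marker"} or \code{"mid_interval"}
#' @param index marker index (on_marker) or interval index (mid_interval)
#' @param seed seed for the per-line fair coins of \code{mid_interval}
#' @return list with \code{chromosome}, \code{position_cM} and \code{geno}
#'   (0/1 per line)
#' @export
placeQTL <- function(nam, scenario = c("on_marker", "mid_interval"),
                     index, seed = NULL) {
  scenario <- match.arg(scenario)
  g <- genotypes(nam)
  rd <- rowData(nam)
  if (scenario == "on_marker") {
    if (index < 1 || index > nrow(nam)) stop("marker index out of range")
    return(list(chromosome = as.character(rd$chromosome[index]),
                position_cM = rd$position_cM[index],
                geno = unname(g[index, ])))
  }
  iv <- .intervalTable(nam)
  if (index < 1 || index > nrow(iv)) stop("interval index out of range")
  k <- iv$left[index]
  gl <- g[k, ]; gr <- g[k + 1, ]
  geno <- .withSeed(seed, function() {
    useLeft <- stats::runif(ncol(nam)) < 0.5
    ifelse(useLeft, gl, gr)
  })
  list(chromosome = as.character(rd$chromosome[k]),
       position_cM = (rd$position_cM[k] + rd$position_cM[k + 1]) / 2,
       geno = as.integer(unname(geno)))
}

# genome-wide table of marker intervals (left marker row index per interval)
.intervalTable <- function(nam) {
  ci <- .chromIndex(nam)
  left <- unlist(lapply(ci, function(ix) ix[-length(ix)]), use.names = FALSE)
  data.frame(left = left)
}

#' Simulated phenotype on an independent-noise background
#'
#' y_i = sum_q a_qf(i) x_qi + e_i with x = +1 (founder) / -1 (common) and
#' e_i ~ N(0, s2_f). In \code{"noise"} mode the family variances are used as
#' error variances directly (the QTL variance comes on top); in
#' \code{"linked_pair"} mode the error variance is V_Pf - sum_q a_qf^2, so
#' the total family variance stays at V_Pf, and it must be positive.
#'
#' @param family family factor per line
#' @param famVar per-family phenotypic variances V_Pf (trait units squared)
#' @param effects matrix of additive effects, one row per QTL, one column
#'   per family (a vector is taken as a single QTL)
#' @param qtlGeno 0/1 matrix of QTL genotypes, one column per QTL (a vector
#'   is taken as a single QTL)
#' @param mode \code{"noise"} or \code{"linked_pair"}
#' @param seed RNG seed
#' @return numeric phenotype vector
#' @export
phenotypeNoiseBackground <- function(family, famVar, effects, qtlGeno,
                                     mode = c("noise", "linked_pair"),
                                     seed = NULL) {
  mode <- match.arg(mode)
  family <- droplevels(as.factor(family))
  F <- nlevels(family)
  if (length(famVar) != F)
    stop("famVar must have one variance per family")
  effects <- matrix(effects, ncol = F)
  qtlGeno <- as.matrix(qtlGeno)
  if (ncol(qtlGeno) != nrow(effects))
    stop("one qtlGeno column per QTL (row of effects) is required")
  if (nrow(qtlGeno) != length(family))
    stop("qtlGeno rows must match the number of lines")
  s2 <- famVar
  if (mode == "linked_pair") {
    s2 <- famVar - colSums(effects^2)
    if (any(s2 <= 0))
      stop("infeasible variance recipe: V_Pf - sum(a^2) must be positive ",
           "in every family")
  }
  fi <- as.integer(family)
  genetic <- rowSums((2 * qtlGeno - 1) * t(effects[, fi, drop = FALSE]))
  .withSeed(seed, function() genetic + stats::rnorm(length(fi),
                                                    sd = sqrt(s2)[fi]))
}

#' Simulated phenotype on a real-phenotype background
#'
#' Adds a_f(i) x_i (x = +1 founder / -1 common) to observed phenotypes:
#' the simulation recipe that keeps the genuine genetic architecture as
#' background when real data are available.
#'
#' @param y observed phenotypes
#' @param family family factor per line
#' @param effects per-family additive effects of the added QTL
#' @param qtlGeno 0/1 QTL genotype per line
#' @return numeric phenotype vector
#' @export
phenotypeRealBackground <- function(y, family, effects, qtlGeno) {
  family <- droplevels(as.factor(family))
  if (length(y) != length(family) || length(qtlGeno) != length(y))
    stop("y, family and qtlGeno must have one entry per line")
  if (length(effects) != nlevels(family))
    stop("one effect per family is required")
  as.numeric(y) + effects[as.integer(family)] * (2 * as.numeric(qtlGeno) - 1)
}

#' One-call NAM dataset simulation
#'
#' Builds a regular map, simulates genotypes, places the requested QTL
#' (on the nearest marker when the position coincides with one, else by the
#' mid-interval coin rule) and draws noise-background phenotypes.
#'
#' @inheritParams makeGridMap
#' @param famSizes,famVar family sizes and phenotypic variances
#' @param qtl data.frame with columns \code{chromosome},
#'   \code{position_cM}, \code{family}, \code{a} (one row per QTL-family
#'   effect; a QTL segregating in several families takes several rows)
#' @param mode variance recipe of \code{\link{phenotypeNoiseBackground}}
#' @param seed RNG seed
#' @return list with \code{nam} (phenotyped \linkS4class{NAMExperiment}) and
#'   \code{truth} (the qtl table with realised positions)
#' @export
simulateNAMDataset <- function(nChrom = 10, chromLength = 140, spacing = 1.3,
                               famSizes = rep(200, 25),
                               famVar = rep(1, length(famSizes)),
                               qtl = NULL, mode = "noise", seed = 1L) {
  map <- makeGridMap(nChrom, chromLength, spacing)
  nam <- simulateNAMGenotypes(map, famSizes, seed = seed)
  fam <- lineFamily(nam)
  F <- nlevels(fam)
  truth <- NULL
  if (!is.null(qtl) && nrow(qtl)) {
    key <- paste(qtl$chromosome, qtl$position_cM)
    uq <- !duplicated(key)
    effects <- matrix(0, sum(uq), F, dimnames = list(NULL, levels(fam)))
    qg <- matrix(0L, ncol(nam), sum(uq))
    loci <- qtl[uq, c("chromosome", "position_cM"), drop = FALSE]
    rd <- rowData(nam)
    for (q in seq_len(sum(uq))) {
      rows <- which(key == key[uq][q])
      effects[q, as.character(qtl$family[rows])] <- qtl$a[rows]
      onChrom <- which(as.character(rd$chromosome) ==
                         as.character(loci$chromosome[q]))
      hit <- onChrom[abs(rd$position_cM[onChrom] -
                           loci$position_cM[q]) < 1e-8]
      if (length(hit)) {
        pq <- placeQTL(nam, "on_marker", hit[1])
      } else {
        iv <- .intervalTable(nam)
        k <- onChrom[findInterval(loci$position_cM[q],
                                  rd$position_cM[onChrom])]
        pq <- placeQTL(nam, "mid_interval", match(k, iv$left),
                       seed = seed + q)
      }
      qg[, q] <- pq$geno
      loci$position_cM[q] <- pq$position_cM
    }
    truth <- qtl
    truth$position_cM <- loci$position_cM[match(key, key[uq])]
    phenotype(nam) <- phenotypeNoiseBackground(fam, famVar, effects, qg,
                                               mode = mode, seed = seed + 1000L)
  } else {
    phenotype(nam) <- phenotypeNoiseBackground(
      fam, famVar, matrix(0, 1, F), matrix(0L, ncol(nam), 1),
      seed = seed + 1000L)
  }
  list(nam = nam, truth = truth)
}
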