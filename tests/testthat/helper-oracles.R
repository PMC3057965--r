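# Independent oracles used by the test suite. These deliberately avoid the
# package's own closed forms: the three-locus oracle iterates the exact
# selfing Markov chain to fixation, and the EM oracle maximises the mixture
# likelihood by brute-force grid refinement.

# Gamete distribution of a three-locus diplotype (haplotypes h1, h2 as
# integers 0..7, bit order locus1,2,3) with meiotic recombination r1, r2
# and no interference.
.oracleGameteDist <- function(h1, h2, r1, r2) {
  b1 <- c(bitwAnd(h1, 4L) > 0, bitwAnd(h1, 2L) > 0, bitwAnd(h1, 1L) > 0)
  b2 <- c(bitwAnd(h2, 4L) > 0, bitwAnd(h2, 2L) > 0, bitwAnd(h2, 1L) > 0)
  p <- numeric(8)
  for (start in 0:1) for (s1 in 0:1) for (s2 in 0:1) {
    pr <- 0.5 * (if (s1) r1 else 1 - r1) * (if (s2) r2 else 1 - r2)
    c1 <- start; c2 <- xor(c1 == 1, s1 == 1); c3 <- xor(c2, s2 == 1)
    gam <- c(if (c1 == 1) b2[1] else b1[1],
             if (c2) b2[2] else b1[2],
             if (c3) b2[3] else b1[3])
    idx <- sum(gam * c(4, 2, 1)) + 1
    p[idx] <- p[idx] + pr
  }
  p
}

# Exact fixation probabilities of the 8 three-locus haplotypes for a selfed
# RIL started from the AAA/BBB F1, by absorption of the 36-state chain of
# unordered haplotype pairs.
oracleThreeLocusRIL <- function(r1, r2) {
  pairs <- list()
  for (a in 0:7) for (b in a:7) pairs[[length(pairs) + 1]] <- c(a, b)
  np <- length(pairs)
  Tm <- matrix(0, np, np)
  for (i in seq_len(np)) {
    g <- .oracleGameteDist(pairs[[i]][1], pairs[[i]][2], r1, r2)
    for (a in 0:7) for (b in 0:7) {
      pa <- sort(c(a, b))
      j <- which(vapply(pairs, function(p) all(p == pa), TRUE))
      Tm[i, j] <- Tm[i, j] + g[a + 1] * g[b + 1]
    }
  }
  absIdx <- which(vapply(pairs, function(p) p[1] == p[2], TRUE))
  trIdx <- setdiff(seq_len(np), absIdx)
  B <- solve(diag(length(trIdx)) - Tm[trIdx, trIdx], Tm[trIdx, absIdx])
  start <- which(vapply(pairs, function(p) all(p == c(0, 7)), TRUE))
  out <- numeric(8)
  out[vapply(pairs[absIdx], `[`, 0L, 1) + 1] <- B[which(trIdx == start), ]
  out   # P(fixed haplotype = 000..111), 1-based index = bits + 1
}

# Conditional P(QTL = founder | flanking-marker class), classes ordered
# (+,+), (+,-), (-,+), (-,-) with "+" = founder allele, from the
# enumeration above. Inputs are RIL-scale flank-QTL fractions.
oracleClassProbs <- function(RLeft, RRight) {
  r1 <- RLeft / (2 - 2 * RLeft)
  r2 <- RRight / (2 - 2 * RRight)
  q <- oracleThreeLocusRIL(r1, r2)   # bits: left, qtl, right
  pr <- function(l, m, r) q[4 * l + 2 * m + r + 1]
  c(pr(1, 1, 1) / (pr(1, 1, 1) + pr(1, 0, 1)),
    pr(1, 1, 0) / (pr(1, 1, 0) + pr(1, 0, 0)),
    pr(0, 1, 1) / (pr(0, 1, 1) + pr(0, 0, 1)),
    pr(0, 1, 0) / (pr(0, 1, 0) + pr(0, 0, 0)))
}

# Brute-force maximum of the F=1 mixture log-likelihood over
# (mu0, mu1, sigma2): one dense global pass, then nested grid refinement
# around the running optimum; independent of EM.
oracleGridLogL <- function(y, p, rounds = 5, n = 21) {
  ll <- function(mu0, mu1, s2) {
    sum(log(p * stats::dnorm(y, mu1, sqrt(s2)) +
              (1 - p) * stats::dnorm(y, mu0, sqrt(s2))))
  }
  sweep1 <- function(g0, g1, gs, best, c0, c1, sv) {
    for (a in g0) for (b in g1) for (s in gs) {
      v <- ll(a, b, s)
      if (v > best) { best <- v; c0 <- a; c1 <- b; sv <- s }
    }
    list(best = best, c0 = c0, c1 = c1, sv = sv)
  }
  vtot <- stats::var(y) * (length(y) - 1) / length(y)
  rng <- range(y)
  st <- sweep1(seq(rng[1], rng[2], length.out = 41),
               seq(rng[1], rng[2], length.out = 41),
               seq(vtot / 20, vtot * 1.2, length.out = 25),
               -Inf, mean(y), mean(y), vtot)
  w0 <- diff(rng) / 20; ws <- vtot / 8
  for (r in seq_len(rounds)) {
    st <- sweep1(seq(st$c0 - w0, st$c0 + w0, length.out = n),
                 seq(st$c1 - w0, st$c1 + w0, length.out = n),
                 seq(max(st$sv - ws, st$sv / 10), st$sv + ws,
                     length.out = n),
                 st$best, st$c0, st$c1, st$sv)
    w0 <- w0 * 3 / (n - 1)
    ws <- ws * 3 / (n - 1)
  }
  st$best
}
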