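# Independent oracles used across tests.  These deliberately re-derive the
# quantities by brute force / exact arithmetic, on paths disjoint from the
# package implementation.

# two-sided signed-rank p by enumerating all 2^m sign assignments of the
# nonzero values (zeros mid-ranked with the rest, Pratt style)
bruteSignedRankP <- function(x) {
  r <- rank(abs(x))
  nz <- x != 0
  ranks <- r[nz]
  W <- sum(r[nz & x > 0])
  mu <- sum(ranks) / 2
  m <- length(ranks)
  hits <- 0
  for (bits in 0:(2^m - 1)) {
    sel <- bitwAnd(bitwShiftR(bits, 0:(m - 1)), 1L) == 1L
    w <- sum(ranks[sel])
    if (abs(w - mu) >= abs(W - mu) - 1e-9) hits <- hits + 1
  }
  hits / 2^m
}

# exact hypergeometric upper tail by full enumeration of all C(N, n) draws
enumHyperP <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)  # items 1..K are the "successes"
}

# exact hypergeometric upper tail via prime-factorized binomials: each term
# C(K,j) C(N-K,n-j) / C(N,n) is assembled from exact prime exponents
# (Legendre's formula), so the only rounding is one final double conversion
primeHyperP <- function(N, K, n, k) {
  sieve <- rep(TRUE, max(N, 2))
  sieve[1] <- FALSE
  for (p in 2:floor(sqrt(max(N, 4))))
    if (sieve[p]) sieve[seq(p * p, length(sieve), p)] <- FALSE
  primes <- which(sieve)
  factExp <- function(m, p) {
    e <- 0; q <- p
    while (q <= m) { e <- e + m %/% q; q <- q * p }
    e
  }
  chooseExp <- function(m, j, p) factExp(m, p) - factExp(j, p) -
    factExp(m - j, p)
  total <- 0
  for (j in max(k, n - (N - K)):min(n, K)) {
    ex <- vapply(primes, function(p)
      chooseExp(K, j, p) + chooseExp(N - K, n - j, p) - chooseExp(N, n, p),
      numeric(1))
    total <- total + prod(primes^ex)
  }
  total
}

# hand risk-table log-rank chi-square for two groups, no ties assumed
handLogrank <- function(times, events, groups) {
  g1 <- levels(factor(groups))[1]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(times[events == 1]))) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & groups == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small labelled expression set: first half tumors, second half normals
makeTinyRse <- function(values, biotype = NULL, cohort = "T1") {
  if (is.null(biotype))
    biotype <- rep("lncRNA", nrow(values))
  n <- ncol(values)
  riskExpressionSet(values, biotype = biotype,
                    sampleType = rep(c("tumor", "normal"), each = n / 2),
                    cohort = cohort)
}

# shared small simulation for expensive fixtures (computed once per run)
cachedSim <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- simulateCohorts(simulationConfig(seed = 101L))
    sim
  }
})

# one cohort's pipeline stages on the cached simulation
cohortStages <- function(sim, co, B = 200L, seed = 7L) {
  rse <- quantifyCohort(sim$counts[[co]], sim$annotation,
                        sim$clinical[sim$clinical$cohort == co, ],
                        cohort = co)
  de <- tTestDE(rse)
  delta <- computeDeltaE(rse, de)
  list(rse = rse, de = de, delta = delta,
       pathways = testPathways(delta, sim$pathways, B = B, seed = seed))
}
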