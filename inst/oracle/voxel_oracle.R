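# Self-contained brute-force reference implementations used by
# scripts/acceptance.R to cross-check the package's voxel metrics.
# Deliberately independent of the package code paths.

oracleRandomPair <- function(seed, maxDim = 20L, density = 0.08) {
  set.seed(seed)
  d <- sample(4:maxDim, 3, replace = TRUE)
  g <- array(as.integer(stats::runif(prod(d)) < density), dim = d)
  p <- array(as.integer(stats::runif(prod(d)) < density), dim = d)
  p[g == 1L & stats::runif(prod(d)) < 0.5] <- 1L
  list(gt = g, pred = p)
}

oracleBruteDice <- function(g, p) {
  inter <- 0; sg <- 0; sp <- 0
  for (i in seq_along(g)) {
    a <- g[i] > 0; b <- p[i] > 0
    if (a) sg <- sg + 1
    if (b) sp <- sp + 1
    if (a && b) inter <- inter + 1
  }
  if (sg + sp == 0) return(1)
  2 * inter / (sg + sp)
}
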