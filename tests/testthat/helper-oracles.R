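# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own code paths: Dice by an
# explicit voxel loop, connected components by iterative label
# propagation over shifted arrays, overlap counting by exhaustive
# pairwise comparison.

randomMaskPair <- function(seed, maxDim = 20L, density = 0.08) {
  set.seed(seed)
  d <- sample(4:maxDim, 3, replace = TRUE)
  g <- array(as.integer(stats::runif(prod(d)) < density), dim = d)
  p <- array(as.integer(stats::runif(prod(d)) < density), dim = d)
  # add some correlated structure so overlaps occur
  p[g == 1L & stats::runif(prod(d)) < 0.5] <- 1L
  list(gt = g, pred = p, dim = d)
}

# brute-force voxel-loop Dice
bruteDice <- function(g, p) {
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

shiftArr <- function(a, dx, dy, dz, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# connected components of a binary mask by iterative max-label
# propagation (independent of the package's flood fill)
oracleLabel <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  fg <- mask > 0L
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  maxS <- c(`6` = 1L, `18` = 2L, `26` = 3L)[[as.character(connectivity)]]
  offs <- offs[s > 0 & s <= maxS, , drop = FALSE]
  lab <- array(seq_along(fg), d)
  lab[!fg] <- 0L
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs))) {
      sh <- shiftArr(lab, offs$dx[k], offs$dy[k], offs$dz[k])
      new <- pmax(new, sh)
    }
    new[!fg] <- 0L
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# FNV / FPV in mL by the zero-overlap component definition, using the
# propagation labeller
oracleFnvFpv <- function(g, p, spacing = c(1, 1, 1), connectivity = 26L) {
  vv <- prod(spacing) / 1000
  gl <- oracleLabel(g, connectivity)
  pl <- oracleLabel(p, connectivity)
  fnv <- 0
  for (id in setdiff(unique(as.vector(gl)), 0L)) {
    vox <- gl == id
    if (!any(p[vox] > 0L)) fnv <- fnv + sum(vox) * vv
  }
  fpv <- 0
  for (id in setdiff(unique(as.vector(pl)), 0L)) {
    vox <- pl == id
    if (!any(g[vox] > 0L)) fpv <- fpv + sum(vox) * vv
  }
  c(fnv = fnv, fpv = fpv)
}

# a small, fast phantom spec used where the default would be overkill
tinySpec <- function(countDist = "poisson", counts = NULL) {
  cp <- data.frame(
    compartment_id = 1:5,
    category = c("T", "N", "N", "M", "M"),
    label = c("lung", "ipsilateral_hilar", "ipsilateral_mediastinal",
              "liver", "bone"),
    x0 = c(2, 22, 2, 22, 2), x1 = c(18, 38, 18, 38, 18),
    y0 = c(2, 2, 22, 22, 2), y1 = c(18, 18, 38, 38, 18),
    z0 = c(2, 2, 2, 2, 22), z1 = c(18, 18, 18, 18, 38),
    count_dist = countDist,
    count_param = if (is.null(counts)) c(1, 0.8, 0.8, 0.8, 0.8) else counts,
    stringsAsFactors = FALSE)
  PhantomSpec(gridShape = c(40, 40, 40), voxelSpacing = c(3, 3, 3),
              compartments = cp, radiusRange = c(4, 9),
              invasionProbability = 0)
}

lesionRow <- function(id, category, station = NA, diameter = NA,
                      invasion = NA) {
  data.frame(lesion_id = id, category = category,
             station_or_organ = station, diameter_mm = diameter,
             invasion = invasion, stringsAsFactors = FALSE)
}

refCounts <- function(file) {
  read.csv(system.file("extdata", "nsclc306", file, package = "TNMseg"),
           stringsAsFactors = FALSE)
}
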