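# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately use the naive
# definition of each quantity, not the package's algorithms.

# exhaustive Otsu: try every candidate level, compute between-class variance
# directly from the raw sample
otsuBrute <- function(x) {
  lev <- sort(unique(x))
  if (length(lev) < 2) return(NA_real_)
  best <- -Inf
  bestT <- NA_real_
  for (i in seq_len(length(lev) - 1)) {
    t <- lev[i]
    lo <- x[x <= t]
    hi <- x[x > t]
    w0 <- length(lo) / length(x)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) {
      best <- sb
      bestT <- (lev[i] + lev[i + 1]) / 2  # midpoint between occupied levels
    }
  }
  bestT
}

# recursive flood fill connected-component count on a logical 3D array
floodFillCount <- function(mask, connectivity = 26) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  n <- 0L
  idx <- which(mask & !visited, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    if (visited[idx[s, 1], idx[s, 2], idx[s, 3]]) next
    n <- n + 1L
    stack <- list(idx[s, ])
    visited[idx[s, 1], idx[s, 2], idx[s, 3]] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        w <- v + unlist(offs[k, ])
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && !visited[w[1], w[2], w[3]]) {
          visited[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  n
}

# O(n^2) maximum pairwise distance
feretBrute <- function(pts) {
  best <- 0
  n <- nrow(pts)
  for (i in seq_len(n)) for (j in seq_len(n))
    best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  best
}

# AUC as the explicit fraction of concordant (pos > neg) pairs, ties 1/2
aucPairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
fisherBrute <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  pObs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# two-sided Mann-Whitney p by full enumeration of group assignments
mwBrute <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  W <- function(ia) sum(rank(pooled)[ia]) - na * (na + 1) / 2
  obs <- W(seq_len(na))
  combos <- combn(length(pooled), na)
  ws <- apply(combos, 2, W)
  centre <- na * length(b) / 2
  mean(abs(ws - centre) >= abs(obs - centre) - 1e-9)
}

# closed-form prolate spheroid surface area (semi-axes a > b = c)
prolateSurface <- function(a, b) {
  e <- sqrt(1 - (b / a)^2)
  2 * pi * b^2 * (1 + a / (b * e) * asin(e))
}

# build a SegmentedObject directly from voxel coordinates (test fixture)
makeObject <- function(coords, voxelSize = c(1, 1, 1), channel = "mito_green",
                       intensities = NULL) {
  coords <- matrix(as.integer(coords), ncol = 3,
                   dimnames = list(NULL, c("z", "y", "x")))
  if (is.null(intensities))
    intensities <- matrix(100, nrow(coords), 3,
                          dimnames = list(NULL,
                            c("th", "mito_green", "red_reporter")))
  new("SegmentedObject", channel = channel, coords = coords,
      intensities = intensities, voxelSize = as.numeric(voxelSize))
}

# digitized sphere object: voxel centres within radius r (voxel units)
sphereObject <- function(r, voxelSize = c(1, 1, 1)) {
  n <- 2 * r + 5
  c0 <- (n + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  keep <- (g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2
  makeObject(as.matrix(g[keep, ]), voxelSize)
}

# stack spec for noise-free scenarios
cleanStackSpec <- function(shapes, shapeZyx = c(20, 40, 40),
                           voxelSizeZyx = c(0.34, 0.24, 0.24), ...) {
  stackSpec(shapeZyx = shapeZyx, voxelSizeZyx = voxelSizeZyx,
            shapes = shapes, psfSigmaZyx = c(0, 0, 0), poissonScale = 0,
            gaussianSd = 0, ...)
}

# colocalization scenario: green spheres in a TH region plus generator-placed
# red puncta; shot-noise-limited (no read noise) so signal-free background is
# exactly zero
colocScenario <- function(colocFraction, seed, nPuncta = 6) {
  centers <- expand.grid(y = c(5, 11.4, 18), x = c(7, 16))
  greens <- lapply(seq_len(6), function(i)
    sphereShape(c(3.2, centers$y[i], centers$x[i]), 1.0))
  sp <- stackSpec(shapeZyx = c(20, 96, 96),
                  shapes = greens,
                  thSomas = list(ellipsoidShape(c(3.23, 11.4, 11.4),
                                                c(2.6, 10.2, 10.2),
                                                intensity = 120,
                                                channel = "th")),
                  redPuncta = list(n = nPuncta, radius = 0.4,
                                   intensity = 200),
                  colocFraction = colocFraction, gaussianSd = 0)
  generateStack(sp, seed = seed)
}
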