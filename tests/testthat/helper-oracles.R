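# Independent oracles used across the suite.

# Otsu by exhaustive search: for every candidate threshold, compute class
# weights and means directly from the pixels and score the between-class
# variance.
otsu_bruteforce <- function(x) {
  x <- as.numeric(x)
  cand <- sort(unique(x))
  cand <- cand[-length(cand)]           # at least one pixel above
  sb <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    w0 <- length(lo) / length(x)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, 0)
  lvl <- sort(unique(x))
  best <- which.max(sb)
  (lvl[best] + lvl[best + 1]) / 2   # midpoint between the two classes
}

# connected components by explicit flood fill (stack-based)
floodfill_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sh <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    sh <- c(sh, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    stack <- start
    seen[start] <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1) %% nr + 1; cc <- (p - 1) %/% nr + 1
      for (s in sh) {
        r2 <- r + s[1]; c2 <- cc + s[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1) * nr + r2
        if (mask[q] && !seen[q]) { seen[q] <- TRUE; stack <- c(stack, q) }
      }
    }
  }
  count
}

# brute-force minimum pixel-centre distance between two pixel index sets
pairdist_bruteforce <- function(idxA, idxB, dm) {
  ra <- (idxA - 1) %% dm[1] + 1; ca <- (idxA - 1) %/% dm[1] + 1
  rb <- (idxB - 1) %% dm[1] + 1; cb <- (idxB - 1) %/% dm[1] + 1
  sqrt(min(outer(ra, rb, "-")^2 + outer(ca, cb, "-")^2))
}

# effective resistance between two nodes of the full cleft star network
# (point nodes retained), solved densely -- independent of the package's
# star-mesh (Kron) reduction
cleft_resistance_oracle <- function(mesh, from, to) {
  cn <- mesh@cleftNodes[mesh@cleftNodes$type != "bath", ]
  ex <- mesh@extracellular
  D <- mesh@shape$depth / 1e4
  w <- ifelse(cn$type == "junctional", ex$junctionalWidth * 1e-7,
              ex$lateralWidth / 1e4)
  sig <- ifelse(cn$type == "junctional", ex$sigmaEffJunctional,
                ex$sigmaEffLateral)
  Gh <- sig * w * D / (cn$len / 2 / 1e4)
  e1x <- ifelse(cn$axis == "v", cn$fixed, cn$lo)
  e1y <- ifelse(cn$axis == "v", cn$lo, cn$fixed)
  e2x <- ifelse(cn$axis == "v", cn$fixed, cn$hi)
  e2y <- ifelse(cn$axis == "v", cn$hi, cn$fixed)
  key <- c(paste(round(e1x, 6), round(e1y, 6)),
           paste(round(e2x, 6), round(e2y, 6)))
  pts <- unique(key)
  nSeg <- nrow(cn); nPts <- length(pts)
  n <- nSeg + nPts
  G <- matrix(0, n, n)
  add <- function(G, i, j, g) {
    G[i, j] <- G[i, j] - g; G[j, i] <- G[j, i] - g
    G[i, i] <- G[i, i] + g; G[j, j] <- G[j, j] + g
    G
  }
  for (i in seq_len(nSeg)) {
    G <- add(G, i, nSeg + match(key[i], pts), Gh[i])
    G <- add(G, i, nSeg + match(key[nSeg + i], pts), Gh[i])
  }
  # bath edges (out-of-plane drainage), mirrored from the model definition
  Gb <- 4 * sig * w * (cn$len / 1e4) / D
  nb <- n + 1
  Gfull <- matrix(0, nb, nb)
  Gfull[1:n, 1:n] <- G
  for (i in seq_len(nSeg)) Gfull <- add(Gfull, i, nb, Gb[i])
  keep <- setdiff(seq_len(nb), to)
  I <- numeric(nb); I[from] <- 1; I[to] <- -1
  phi <- numeric(nb)
  phi[keep] <- solve(Gfull[keep, keep], I[keep])
  phi[from] - phi[to]
}

small_config <- function(...) {
  modelConfig(nRows = 2, nCols = 3, ...)
}
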