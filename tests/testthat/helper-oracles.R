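# Independent numeric oracles used to cross-check package implementations.
# Everything here is deliberately written from first principles and shares
# no code path with the package.

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# direct atan2 torsion formula (degrees), IUPAC sign convention, atoms
# a-b-c-d (checked against biotite's dihedral on reference geometries)
torsionOracle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  y <- sum(.cross3(n1, n2) * b2 / sqrt(sum(b2^2)))
  atan2(y, sum(n1 * n2)) * 180 / pi
}

rotFromQuat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

randomRotation <- function() rotFromQuat(rnorm(4))

# minimal-RMSD oracle: dense random quaternion search with iterative local
# refinement (no SVD); accurate to well below 1e-3 A on small point sets
quatRmsdOracle <- function(mobile, reference, nStart = 1500L,
                           nRefine = 300L, nLevels = 12L) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  rmsdFor <- function(R) sqrt(mean(rowSums((X %*% R - Y)^2)))
  bestQ <- c(1, 0, 0, 0)
  bestR <- rmsdFor(diag(3))
  qs <- matrix(rnorm(4L * nStart), ncol = 4L)
  for (i in seq_len(nStart)) {
    r <- rmsdFor(rotFromQuat(qs[i, ]))
    if (r < bestR) { bestR <- r; bestQ <- qs[i, ] / sqrt(sum(qs[i, ]^2)) }
  }
  scale <- 0.3
  for (lev in seq_len(nLevels)) {
    for (i in seq_len(nRefine)) {
      q <- bestQ + rnorm(4, sd = scale)
      r <- rmsdFor(rotFromQuat(q))
      if (r < bestR) { bestR <- r; bestQ <- q / sqrt(sum(q^2)) }
    }
    scale <- scale / 2
  }
  bestR
}

# Ward agglomeration oracle via the Lance-Williams recurrence on squared
# dissimilarities (the ward.D2 convention); returns the k-cluster partition
wardOracle <- function(m, k) {
  n <- nrow(m)
  D <- m^2
  diag(D) <- Inf
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  while (sum(active) > k) {
    idx <- which(active)
    best <- c(NA, NA); bestVal <- Inf
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      if (D[i, j] < bestVal) { bestVal <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    for (l in idx) {
      if (l == i || l == j) next
      nl <- sizes[l]
      D[i, l] <- D[l, i] <-
        ((ni + nl) * D[i, l] + (nj + nl) * D[j, l] - nl * D[i, j]) /
        (ni + nj + nl)
    }
    sizes[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    D[j, ] <- D[, j] <- Inf
  }
  out <- integer(n)
  lab <- 0L
  for (i in which(active)) { lab <- lab + 1L; out[members[[i]]] <- lab }
  out
}

# two labelings describe the same partition?
samePartition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

randIndex <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa == sb) agree <- agree + 1
  }
  agree / choose(n, 2)
}
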