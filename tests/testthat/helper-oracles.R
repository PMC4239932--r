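# Independent oracles used across the suite. These deliberately use naive
# algorithms (loops, enumeration, quadratic programming by grid/dual
# enumeration) so they share no code with the package implementations.

# 8-connected component labeling by iterative label propagation.
labelOracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))  # unique provisional labels
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || jj < 1 || ii > nr || jj > nc) next
        if (mask[ii, jj] && lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# background flood fill from the border (4-connected background,
# matching the convention that diagonal background leakage does not
# connect a hole to the exterior)
fillOracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  queue <- which(!mask & (row(mask) %in% c(1L, nr) |
                          col(mask) %in% c(1L, nc)))
  outside[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1L]; queue <- queue[-1L]
    i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + d[1L]; jj <- j + d[2L]
      if (ii < 1L || jj < 1L || ii > nr || jj > nc) next
      if (!mask[ii, jj] && !outside[ii, jj]) {
        outside[ii, jj] <- TRUE
        queue <- c(queue, (jj - 1L) * nr + ii)
      }
    }
  }
  !outside
}

# Maximum-margin separator for small separable 2-D point sets by
# enumeration: the optimal hard-margin hyperplane is supported either by
# one point per class (margin midline of the closest pair realizing it)
# or by two points of one class and one of the other. Returns unit normal
# w and offset b with w.x + b > 0 for the positive class.
svmOracle2d <- function(X, y) {
  stopifnot(ncol(X) == 2L)
  pos <- which(y > 0); neg <- which(y <= 0)
  best <- NULL; bestMargin <- -Inf
  consider <- function(w, b) {
    w <- unname(w)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) return()
    w <- w / nw; b <- b / nw
    d <- as.numeric(X %*% w + b)
    if (all(d[pos] > 0) && all(d[neg] < 0)) {
      mar <- min(abs(d))
      if (mar > bestMargin) {
        bestMargin <<- mar; best <<- list(w = w, b = b, margin = mar)
      }
    }
  }
  # pair supports: perpendicular bisector midline
  for (p in pos) for (n in neg) {
    w <- X[p, ] - X[n, ]
    b <- -sum(w * (X[p, ] + X[n, ]) / 2)
    consider(w, b)
  }
  # triple supports: two same-class points define the direction
  triple <- function(iA, iB, iC) {
    # margin boundary parallel to segment AB (same class), C opposite
    ab <- X[iB, ] - X[iA, ]
    w <- c(-ab[2L], ab[1L])
    # orient w from C's class toward AB's class not known yet; midline
    # between line through A,B and point C
    bAB <- -sum(w * X[iA, ])
    bC <- -sum(w * X[iC, ])
    consider(w, (bAB + bC) / 2)
    consider(-w, -(bAB + bC) / 2)
  }
  if (length(pos) >= 2L)
    for (a in seq_along(pos)) for (b2 in seq_along(pos)) for (n in neg)
      if (a < b2) triple(pos[a], pos[b2], n)
  if (length(neg) >= 2L)
    for (a in seq_along(neg)) for (b2 in seq_along(neg)) for (p in pos)
      if (a < b2) triple(neg[a], neg[b2], p)
  best
}

# least-squares regression oracle for full-rank PLS comparison
lsBetaOracle <- function(X, y) {
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  as.numeric(solve(crossprod(Xc), crossprod(Xc, yc)))
}

# rasterize an analytic region given an indicator f(x, y) on an n x n
# grid centered at the origin
rasterShape <- function(n, f) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  matrix(f(g$r - (n + 1) / 2, g$c - (n + 1) / 2), n, n)
}
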