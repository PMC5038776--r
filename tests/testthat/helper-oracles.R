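# Independent reference implementations used as oracles: plain scalar
# loops with no windowed tricks, kept deliberately separate from the
# package's vectorized code paths.

# per-pixel scalar-loop SCM (printed index scheme: theta at step n absorbs
# the pulse of step n-1; the pulse at step n compares against theta of n-1)
scmOracle <- function(O, params) {
  nr <- nrow(O); nc <- ncol(O)
  r <- params@linkRadius
  W <- linkingKernel(r)
  F <- matrix(0, nr, nc); Th <- matrix(0, nr, nc); Y <- matrix(0, nr, nc)
  pulses <- array(0L, c(nr, nc, params@nMax))
  for (n in seq_len(params@nMax)) {
    Fn <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      L <- 0
      for (dk in -r:r) for (dl in -r:r) {
        w <- W[dk + r + 1L, dl + r + 1L]
        if (w == 0) next
        ii <- i + dk; jj <- j + dl
        y <- if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) Y[ii, jj] else 0
        L <- L + w * y
      }
      Fn[i, j] <- params@f * F[i, j] + O[i, j] + O[i, j] * L
    }
    Yn <- matrix(0, nr, nc)
    Thn <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      Thn[i, j] <- params@g * Th[i, j] + params@h * Y[i, j]
      Yn[i, j] <- if (Fn[i, j] > Th[i, j]) 1 else 0
    }
    F <- Fn; Th <- Thn; Y <- Yn
    pulses[, , n] <- as.integer(Yn)
  }
  pulses
}

# edge-inclusive symmetric mirror index
mirrorIdx <- function(i, n) {
  if (i < 1L) return(1L - i)
  if (i > n) return(2L * n + 1L - i)
  i
}

# brute-force patchwise binary entropy of a pulse stack, in bits
entropyOracle <- function(pulses, lp) {
  d <- dim(pulses)
  area <- (2 * lp + 1)^2
  out <- array(0, d)
  for (n in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    k <- 0L
    for (dk in -lp:lp) for (dl in -lp:lp)
      k <- k + pulses[mirrorIdx(i + dk, d[1]), mirrorIdx(j + dl, d[2]), n]
    p1 <- k / area
    out[i, j, n] <- if (p1 == 0 || p1 == 1) 0 else
      -p1 * log2(p1) - (1 - p1) * log2(1 - p1)
  }
  out
}

# brute-force patch sum of squared firing times (local energy)
energyOracle <- function(t, lp) {
  nr <- nrow(t); nc <- ncol(t)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (dk in -lp:lp) for (dl in -lp:lp)
      s <- s + t[mirrorIdx(i + dk, nr), mirrorIdx(j + dl, nc)]^2
    out[i, j] <- s
  }
  out
}

# per-window scalar helpers for the sliding-window metrics
ssimWin <- function(x, y, c1 = 2e-6, c2 = 2e-6) {
  mx <- mean(x); my <- mean(y)
  vx <- var(as.vector(x)); vy <- var(as.vector(y))
  cxy <- cov(as.vector(x), as.vector(y))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

uiqiWin <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- var(as.vector(x)); vy <- var(as.vector(y))
  cxy <- cov(as.vector(x), as.vector(y))
  den <- (vx + vy) * (mx^2 + my^2)
  if (den > 1e-12) return(4 * cxy * mx * my / den)
  if (vx < 1e-12 && vy < 1e-12 && abs(mx - my) < 1e-9) 1 else 0
}

windowCorners <- function(nr, nc, w, step) {
  expand.grid(i = seq(1, nr - w + 1, by = step),
              j = seq(1, nc - w + 1, by = step))
}

qsOracle <- function(a, b, u, w = 8, step = 1) {
  a <- a / 255; b <- b / 255; u <- u / 255
  g <- windowCorners(nrow(a), ncol(a), w, step)
  q <- mapply(function(i, j) {
    wa <- a[i:(i + w - 1), j:(j + w - 1)]
    wb <- b[i:(i + w - 1), j:(j + w - 1)]
    wu <- u[i:(i + w - 1), j:(j + w - 1)]
    va <- var(as.vector(wa)); vb <- var(as.vector(wb))
    lam <- if (va + vb > 0) va / (va + vb) else 0.5
    if (ssimWin(wa, wb) >= 0.75)
      lam * ssimWin(wa, wu) + (1 - lam) * ssimWin(wb, wu)
    else max(ssimWin(wa, wu), ssimWin(wb, wu))
  }, g$i, g$j)
  mean(q)
}

qlFactorOracle <- function(a, b, u, w = 8, step = 1) {
  g <- windowCorners(nrow(a), ncol(a), w, step)
  vals <- mapply(function(i, j) {
    wa <- a[i:(i + w - 1), j:(j + w - 1)]
    wb <- b[i:(i + w - 1), j:(j + w - 1)]
    wu <- u[i:(i + w - 1), j:(j + w - 1)]
    va <- var(as.vector(wa)); vb <- var(as.vector(wb))
    lam <- if (va + vb > 0) va / (va + vb) else 0.5
    c(combo = lam * ssimWin(wa, wu) + (1 - lam) * ssimWin(wb, wu),
      cw = max(va, vb))
  }, g$i, g$j)
  if (sum(vals["cw", ]) == 0) return(mean(vals["combo", ]))
  sum(vals["cw", ] * vals["combo", ]) / sum(vals["cw", ])
}

sobelOracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- gy <- matrix(0, nr, nc)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dcol
  ky <- t(kx)                                               # d/drow
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    sx <- sy <- 0
    for (dk in -1:1) for (dl in -1:1) {
      v <- m[mirrorIdx(i + dk, nr), mirrorIdx(j + dl, nc)]
      sx <- sx + kx[dk + 2, dl + 2] * v
      sy <- sy + ky[dk + 2, dl + 2] * v
    }
    gx[i, j] <- sx; gy[i, j] <- sy
  }
  list(gx = gx, gy = gy)
}

qlOracle <- function(a, b, u, w = 8, step = 1) {
  a <- a / 255; b <- b / 255; u <- u / 255
  gm <- function(m) { s <- sobelOracle(m); sqrt(s$gx^2 + s$gy^2) }
  qlFactorOracle(a, b, u, w, step) *
    qlFactorOracle(gm(a), gm(b), gm(u), w, step)
}

qtOracle <- function(a, b, u, w = 8, step = 1) {
  a <- a / 255; b <- b / 255; u <- u / 255
  g <- windowCorners(nrow(a), ncol(a), w, step)
  q <- mapply(function(i, j) {
    wa <- a[i:(i + w - 1), j:(j + w - 1)]
    wb <- b[i:(i + w - 1), j:(j + w - 1)]
    wu <- u[i:(i + w - 1), j:(j + w - 1)]
    cau <- cov(as.vector(wa), as.vector(wu))
    cbu <- cov(as.vector(wb), as.vector(wu))
    sim <- if (cau + cbu != 0) cau / (cau + cbu) else 0.5
    sim <- min(max(sim, 0), 1)
    sim * uiqiWin(wa, wu) + (1 - sim) * uiqiWin(wb, wu)
  }, g$i, g$j)
  mean(q)
}

# straight-line scalar reimplementation of the whole fusion pipeline
fuseOracle <- function(A, B, config) {
  pa <- scmOracle(A / 255, config@scm)
  pb <- scmOracle(B / 255, config@scm)
  lp <- config@lp
  va <- entropyOracle(pa, lp)
  vb <- entropyOracle(pb, lp)
  nr <- nrow(A); nc <- ncol(A)
  sEn <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d2 <- 0
    for (n in seq_len(dim(pa)[3])) d2 <- d2 + (va[i, j, n] - vb[i, j, n])^2
    sEn[i, j] <- 1 - sqrt(d2) / config@constants@cs1
  }
  ta <- apply(pa, c(1, 2), sum)
  tb <- apply(pb, c(1, 2), sum)
  ea <- energyOracle(ta, lp)
  eb <- energyOracle(tb, lp)
  area <- (2 * lp + 1)^2
  xi <- function(t) {
    out <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      s <- 0
      for (dk in -lp:lp) for (dl in -lp:lp)
        s <- s + t[mirrorIdx(i + dk, nr), mirrorIdx(j + dl, nc)]
      out[i, j] <- atan((s - area * t[i, j]) / max(t[i, j], 1e-6))
    }
    out
  }
  xa <- xi(ta); xb <- xi(tb)
  U <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    w <- sEn[i, j] * (1 - abs(xa[i, j] - xb[i, j]) / config@constants@cs2)
    U[i, j] <- if (ea[i, j] > eb[i, j])
      w * A[i, j] + (1 - w) * B[i, j]
    else
      (1 - w) * A[i, j] + w * B[i, j]
  }
  U
}

# two-level random stimulus on the 8-bit lattice, normalized
randomStimulus <- function(seed, nr = 16, nc = 16) {
  set.seed(seed)
  matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc) / 255
}

randomImage <- function(seed, nr = 32, nc = 32) {
  set.seed(seed)
  matrix(sample(0:255, nr * nc, replace = TRUE) + 0, nr, nc)
}
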