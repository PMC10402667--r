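# Brute-force per-pixel generalized gradient: explicit double loop over the
# four nearest neighbours, independent of the vectorized implementation.
bruteGradient <- function(d, pitch, agg = "sum") {
  nr <- nrow(d)
  nc <- ncol(d)
  g <- matrix(0, nr, nc)
  offsets <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      terms <- numeric(0)
      for (off in offsets) {
        ii <- i + off[1L]
        jj <- j + off[2L]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc)
          terms <- c(terms, ((d[i, j] - d[ii, jj]) / pitch)^2)
      }
      g[i, j] <- sqrt(if (agg == "mean") mean(terms) else sum(terms))
    }
  }
  g
}

# Exhaustive per-pixel region classification, independent of segmentRegions.
bruteClassify <- function(dosePct, gradVals, doseThr, gradThr) {
  cls <- matrix("", nrow(dosePct), ncol(dosePct))
  for (i in seq_len(nrow(dosePct))) {
    for (j in seq_len(ncol(dosePct))) {
      hd <- dosePct[i, j] >= doseThr
      lg <- gradVals[i, j] < gradThr
      cls[i, j] <- paste0(if (hd) "HD" else "LD", if (lg) "LG" else "HG")
    }
  }
  cls
}

# Small plateau composite pair used across tests: flat top of value d0 with
# penumbral shoulders, built directly (not via the synthetic generator).
flatPlateau <- function(n = 32L, half = 6, sigmaPx = 3, d0 = 100,
                        pitch = 0.336) {
  u <- pmax(0, abs(seq_len(n) - (n + 1) / 2) - half)
  prof <- exp(-u^2 / (2 * sigmaPx^2))
  CompositeImage(d0 * outer(prof, prof), pixelPitchMm = pitch,
                 fractionIndex = 1L, nArcs = 1L)
}
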