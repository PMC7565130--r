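# Shared fixtures and independent brute-force oracles. Oracles are written
# against the definitions directly (flood fill by repeated dilation,
# product-limit by hand, log-rank by observed-minus-expected summation) and
# never call the package code paths they check.

# volume with one or more rectangular SUV blocks in a zero background
block_volume <- function(dim = c(10, 10, 10), blocks, spacing = c(4, 4, 4)) {
  a <- array(0, dim)
  for (b in blocks) a[b$x, b$y, b$z] <- b$suv
  suv_volume(a, spacing = spacing)
}

# brute-force 26-connected flood fill: dilate the seed set until fixpoint
oracle_flood_fill <- function(mask, seed1) {   # seed1 is 1-based
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  comp <- array(FALSE, d)
  comp[seed1[1], seed1[2], seed1[3]] <- TRUE
  repeat {
    cur <- which(comp, arr.ind = TRUE)
    nb <- cur[rep(seq_len(nrow(cur)), each = 26), ] + off[rep(1:26, nrow(cur)), ]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    grow <- nb[mask[nb] & !comp[nb], , drop = FALSE]
    if (nrow(grow) == 0) break
    comp[grow] <- TRUE
  }
  which(comp, arr.ind = TRUE)
}

# product-limit estimator from first principles (event-before-censoring ties)
oracle_km <- function(time, event, at) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  for (t in tt[tt <= at]) {
    n_risk <- sum(time >= t)
    d_ev <- sum(time == t & event == 1)
    s <- s * (1 - d_ev / n_risk)
  }
  s
}

# two-group log-rank chi-square by direct observed-minus-expected summation
oracle_logrank <- function(time, event, g) {
  g <- as.integer(as.factor(g))
  tt <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in tt) {
    n <- sum(time >= t); n1 <- sum(time >= t & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# VOI from a bare SUV vector (voxel geometry irrelevant to the histogram)
suv_voi <- function(suvs, voxel_volume = 0.064) {
  lesion_voi(cbind(seq_along(suvs) - 1L, 0L, 0L), suvs, voxel_volume)
}

# three-component Gaussian SUV mixture, floored at the segmentation threshold
mixture_suvs <- function(n_per = c(80, 70, 50), means = c(3, 5.5, 9), sd = 0.3) {
  pmax(rnorm(sum(n_per), rep(means, n_per), sd), 2.5)
}
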