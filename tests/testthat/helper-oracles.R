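# Independent oracles used to freeze expected values: each one takes a
# different computational route than the implementation it checks.

# Hardy-Weinberg exact p via the Wigginton-style recurrence on heterozygote
# counts (the package enumerates log-multinomial probabilities instead).
oracleHweP <- function(nHomRef, nHet, nHomAlt) {
  nRef <- 2 * nHomRef + nHet
  nAlt <- 2 * nHomAlt + nHet
  rare <- min(nRef, nAlt)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- numeric(length(hets))
  mid <- which.min(abs(hets - rare * (nRef + nAlt - rare) / (nRef + nAlt)))
  pr[mid] <- 1
  homRare <- function(h) (rare - h) / 2
  homCommon <- function(h) (max(nRef, nAlt) - h) / 2
  if (mid < length(hets)) for (k in mid:(length(hets) - 1)) {
    h <- hets[k]
    pr[k + 1] <- pr[k] * 4 * homRare(h) * homCommon(h) / ((h + 1) * (h + 2))
  }
  if (mid > 1) for (k in mid:2) {
    h <- hets[k]
    pr[k - 1] <- pr[k] * h * (h - 1) / (4 * (homRare(h) + 1) * (homCommon(h) + 1))
  }
  pr <- pr / sum(pr)
  pObs <- pr[match(nHet, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

# Brute-force double-loop Moran's I and Geary's C.
oracleMoran <- function(x, W) {
  n <- length(x); z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

oracleGeary <- function(x, W) {
  n <- length(x); z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * (x[i] - x[j])^2
  ((n - 1) / (2 * sum(W))) * num / sum(z^2)
}

# All permutations of 1:n (recursive), for exhaustive randomization nulls.
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- allPermutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0
  for (k in 1:n) for (s in seq_len(nrow(sub))) {
    r <- r + 1
    rest <- setdiff(1:n, k)
    out[r, ] <- c(k, rest[sub[s, ]])
  }
  out
}

# Pair-counting AUC: concordant case-control pairs + half ties.
oracleAuc <- function(y, s) {
  cases <- s[y == 1]; ctrls <- s[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# All-pairs semivariogram binning.
oracleSemivariogram <- function(lat, lon, z, edges) {
  n <- length(z)
  g <- rep(NA_real_, length(edges) - 1); np <- integer(length(edges) - 1)
  acc <- numeric(length(edges) - 1)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- greatCircleKm(lat[i], lon[i], lat[j], lon[j])
    for (k in seq_len(length(edges) - 1)) {
      lo <- edges[k]; hi <- edges[k + 1]
      inBin <- if (k == 1) d >= lo && d <= hi else d > lo && d <= hi
      if (inBin) {
        acc[k] <- acc[k] + (z[i] - z[j])^2
        np[k] <- np[k] + 1
      }
    }
  }
  ok <- np > 0
  list(gamma = acc[ok] / (2 * np[ok]), np = np[ok])
}

# Mid-ranks by explicit averaging over tied positions.
oracleMidrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}
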