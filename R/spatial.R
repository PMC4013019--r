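# Spatial autocorrelation of population values: great-circle distances,
# spatial weights, Moran's I, Geary's C, randomization tests,
# distance-class correlograms.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised)
#' @return distance(s) in km
#' @export
greatCircleKm <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180) ||
      any(!is.finite(c(lat1, lon1, lat2, lon2))))
    ecoStop("ecogrs_invalid_argument", "invalid coordinates")
  distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                r = EARTH_RADIUS_KM * 1000) / 1000
}

# Full pairwise distance matrix (km) for coordinate vectors.
distanceMatrixKm <- function(lat, lon) {
  n <- length(lat)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    D[i, j] <- D[j, i] <- greatCircleKm(lat[i], lon[i], lat[j], lon[j])
  }
  D
}

#' Build a spatial weight matrix
#'
#' Schemes: `"inverse-distance"` (w_ij = 1/d_ij in km), `"binary"`
#' (w_ij = 1 iff d_ij <= threshold), `"class"` (w_ij = 1 iff threshold\[1\]
#' < d_ij <= threshold\[2\]). Optional row standardization divides each
#' row by its sum (rows with zero sum are left at zero). The diagonal is
#' always zero.
#'
#' @param lat,lon population coordinates (decimal degrees, n >= 3)
#' @param scheme weighting scheme
#' @param threshold distance threshold(s) in km for the binary/class
#'   schemes
#' @param rowStandardize divide rows by their sums (default TRUE for
#'   inverse-distance, FALSE otherwise)
#' @return A [SpatialWeights-class]
#' @export
buildWeights <- function(lat, lon,
                         scheme = c("inverse-distance", "binary", "class"),
                         threshold = NULL,
                         rowStandardize = scheme == "inverse-distance") {
  scheme <- match.arg(scheme)
  n <- length(lat)
  if (n < 3)
    ecoStop("ecogrs_invalid_argument", "need at least 3 locations")
  D <- distanceMatrixKm(lat, lon)
  off <- row(D) != col(D)
  if (scheme == "inverse-distance") {
    if (any(D[off] == 0)) {
      dup <- which(D == 0 & off, arr.ind = TRUE)[1, ]
      ecoStop("ecogrs_invalid_argument",
              sprintf("duplicate coordinates at locations %d and %d",
                      dup[1], dup[2]))
    }
    W <- ifelse(off, 1 / D, 0)
  } else if (scheme == "binary") {
    if (is.null(threshold))
      ecoStop("ecogrs_invalid_argument", "binary scheme needs a threshold")
    W <- ifelse(off & D <= threshold, 1, 0)
  } else {
    if (length(threshold) != 2)
      ecoStop("ecogrs_invalid_argument", "class scheme needs two thresholds")
    W <- ifelse(off & D > threshold[1] & D <= threshold[2], 1, 0)
  }
  if (sum(W) <= 0)
    ecoStop("ecogrs_invalid_argument", "weight matrix is all zero")
  rowStandardize <- isTRUE(rowStandardize)
  if (rowStandardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  new("SpatialWeights", W = W, scheme = scheme,
      rowStandardized = rowStandardize)
}

#' @rdname weightMatrix
#' @param x a [SpatialWeights-class]
#' @export
setMethod("weightMatrix", "SpatialWeights", function(x) x@W)

setMethod("show", "SpatialWeights", function(object) {
  cat(sprintf("SpatialWeights: %d x %d, scheme '%s'%s, S0 = %.4g\n",
              nrow(object@W), ncol(object@W), object@scheme,
              if (object@rowStandardized) " (row-standardized)" else "",
              sum(object@W)))
})

statInputs <- function(values, W) {
  if (is(W, "SpatialWeights")) W <- weightMatrix(W)
  values <- as.numeric(values)
  if (length(values) != nrow(W))
    ecoStop("ecogrs_invalid_argument", "value/weight dimension mismatch")
  if (var(values) == 0)
    ecoStop("ecogrs_undefined_result", "values have zero variance")
  list(z = values - mean(values), W = W, n = length(values), S0 = sum(W))
}

#' Moran's I
#'
#' `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#'
#' @param values numeric vector with positive variance
#' @param W a [SpatialWeights-class] or plain weight matrix
#' @return Moran's I
#' @export
moransI <- function(values, W) {
  s <- statInputs(values, W)
  (s$n / s$S0) * drop(crossprod(s$z, s$W %*% s$z)) / sum(s$z^2)
}

#' Geary's C
#'
#' `C = ((n-1)/(2 S0)) * sum_ij w_ij (x_i - x_j)^2 / sum_i (x_i - xbar)^2`.
#'
#' @inheritParams moransI
#' @return Geary's C
#' @export
gearysC <- function(values, W) {
  s <- statInputs(values, W)
  num <- sum(rowSums(s$W) * s$z^2) + sum(colSums(s$W) * s$z^2) -
    2 * drop(crossprod(s$z, s$W %*% s$z))
  ((s$n - 1) / (2 * s$S0)) * num / sum(s$z^2)
}

# Statistic values for a matrix of permuted (centered) value columns.
statColumns <- function(Z, W, S0, statistic) {
  n <- nrow(Z)
  ss <- colSums(Z^2)
  cross <- colSums(Z * (W %*% Z))
  if (statistic == "moran") {
    (n / S0) * cross / ss
  } else {
    num <- colSums(rowSums(W) * Z^2) + colSums(colSums(W) * Z^2) - 2 * cross
    ((n - 1) / (2 * S0)) * num / ss
  }
}

#' Randomization test for spatial autocorrelation
#'
#' Permutes the values over the locations and computes
#' `p = (1 + #\{permuted statistic at least as extreme\}) / (nPerm + 1)`.
#' The default alternative is one-sided positive autocorrelation:
#' "greater" for Moran's I and "less" for Geary's C.
#'
#' @param values numeric vector (n >= 4, positive variance)
#' @param W a [SpatialWeights-class]
#' @param statistic "moran" or "geary"
#' @param nPerm number of permutations (default 999, >= 99)
#' @param alternative "greater", "less" or "two.sided" (default depends
#'   on the statistic)
#' @param seed integer seed for the permutations
#' @return An [AutocorrResult-class]
#' @export
randomizationTest <- function(values, W, statistic = c("moran", "geary"),
                              nPerm = 999, alternative = NULL, seed = 1) {
  statistic <- match.arg(statistic)
  if (length(values) < 4)
    ecoStop("ecogrs_invalid_argument", "need at least 4 locations")
  if (nPerm < 99)
    ecoStop("ecogrs_invalid_argument", "use at least 99 permutations")
  if (is.null(alternative))
    alternative <- if (statistic == "moran") "greater" else "less"
  alternative <- match.arg(alternative, c("greater", "less", "two.sided"))
  s <- statInputs(values, W)
  obs <- if (statistic == "moran") moransI(values, W) else gearysC(values, W)
  with_seed(seed, {
    P <- replicate(nPerm, sample(s$z))
  })
  perm <- statColumns(P, s$W, s$S0, statistic)
  eps <- 1e-12
  extreme <- switch(alternative,
    greater = perm >= obs - eps,
    less = perm <= obs + eps,
    two.sided = abs(perm - mean(perm)) >= abs(obs - mean(perm)) - eps)
  p <- (1 + sum(extreme)) / (nPerm + 1)
  new("AutocorrResult", statistic = statistic, observed = obs,
      permMean = mean(perm), p = p, nPerm = as.integer(nPerm),
      alternative = alternative, seed = as.integer(seed))
}

setMethod("show", "AutocorrResult", function(object) {
  cat(sprintf("%s randomization test: observed = %.4f, null mean = %.4f, p = %.4g (%s, %d permutations)\n",
              if (object@statistic == "moran") "Moran's I" else "Geary's C",
              object@observed, object@permMean, object@p,
              object@alternative, object@nPerm))
})

#' Distance-class correlogram
#'
#' Splits the n(n-1)/2 pairwise great-circle distances into `nClasses`
#' equal-count (quantile) classes (ties broken by stable pair order) and
#' computes, per class, Moran's I and Geary's C with binary weights
#' selecting the class pairs, plus two-sided permutation p-values.
#'
#' @param lat,lon population coordinates (decimal degrees)
#' @param values population values (e.g. mean GRS)
#' @param nClasses number of distance classes (default 6)
#' @param nPerm permutations per class (default 999)
#' @param seed integer seed
#' @return data.frame: class, d_min_km, d_max_km, n_pairs, moran_i,
#'   geary_c, p_i, p_c.
#' @export
correlogram <- function(lat, lon, values, nClasses = 6, nPerm = 999,
                        seed = 1) {
  n <- length(values)
  nPairs <- n * (n - 1) / 2
  if (nPairs < nClasses)
    ecoStop("ecogrs_invalid_argument", "fewer pairs than distance classes")
  D <- distanceMatrixKm(lat, lon)
  ut <- which(upper.tri(D))
  dists <- D[ut]
  ord <- order(dists)  # stable: ties keep pair-index order
  bounds <- floor(seq(0, nPairs, length.out = nClasses + 1))
  out <- vector("list", nClasses)
  for (k in seq_len(nClasses)) {
    sel <- ord[(bounds[k] + 1):bounds[k + 1]]
    if (length(sel) == 0)
      ecoStop("ecogrs_invalid_argument",
              "empty distance class; use fewer classes")
    W <- matrix(0, n, n)
    W[ut[sel]] <- 1
    W <- W + t(W)
    Wobj <- new("SpatialWeights", W = W, scheme = "class",
                rowStandardized = FALSE)
    ri <- randomizationTest(values, Wobj, "moran", nPerm,
                            alternative = "two.sided",
                            seed = deriveSeed(seed, k))
    rc <- randomizationTest(values, Wobj, "geary", nPerm,
                            alternative = "two.sided",
                            seed = deriveSeed(seed, k + nClasses))
    out[[k]] <- data.frame(
      class = k, d_min_km = min(dists[sel]), d_max_km = max(dists[sel]),
      n_pairs = length(sel), moran_i = ri@observed, geary_c = rc@observed,
      p_i = ri@p, p_c = rc@p)
  }
  do.call(rbind, out)
}
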