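# Ordinary kriging of population values with a spherical semivariogram.
# Great-circle distances feed the variogram and the kriging system
# directly; no map projection is applied.

#' Empirical semivariogram
#'
#' `gamma(h) = (1/(2 N(h))) * sum over pairs in the lag bin of
#' (z_i - z_j)^2`, with equal-width bins up to `maxLagKm` (default half
#' the maximum pairwise distance). Empty bins are omitted.
#'
#' @param lat,lon site coordinates (decimal degrees, n >= 5)
#' @param values site values
#' @param nLags number of lag bins (default 10)
#' @param maxLagKm maximum lag distance in km (optional)
#' @return An [EmpiricalVariogram-class]
#' @export
empiricalSemivariogram <- function(lat, lon, values, nLags = 10,
                                   maxLagKm = NULL) {
  n <- length(values)
  if (n < 5)
    ecoStop("ecogrs_invalid_argument", "need at least 5 sites")
  D <- distanceMatrixKm(lat, lon)
  ut <- upper.tri(D)
  d <- D[ut]
  dz2 <- (outer(values, values, "-")^2)[ut]
  if (is.null(maxLagKm)) maxLagKm <- max(d) / 2
  edges <- seq(0, maxLagKm, length.out = nLags + 1)
  bin <- cut(d, edges, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bin)
  gamma <- tapply(dz2[keep], bin[keep], function(x) sum(x) / (2 * length(x)))
  np <- tapply(dz2[keep], bin[keep], length)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- as.integer(names(gamma))
  new("EmpiricalVariogram", h = centers[idx], gamma = as.numeric(gamma),
      np = as.integer(np), maxLag = maxLagKm)
}

#' Spherical semivariogram function
#'
#' `gamma(h) = c0 + c1 (1.5 h/a - 0.5 (h/a)^3)` for `h <= a` and
#' `c0 + c1` beyond the range; `gamma(0) = 0` by convention (the nugget
#' acts only at h > 0).
#'
#' @param h distances (km)
#' @param model a [VariogramModel-class]
#' @return semivariances
#' @export
sphericalGamma <- function(h, model) {
  g <- ifelse(h <= model@a,
              model@c0 + model@c1 * (1.5 * h / model@a - 0.5 * (h / model@a)^3),
              model@c0 + model@c1)
  g[h == 0] <- 0
  g
}

#' Fit a spherical variogram model by weighted least squares
#'
#' Minimizes `sum N(h) (gammaHat(h) - gamma(h; c0, c1, a))^2` with bounds
#' c0 >= 0, c1 >= 0, 0 < a <= 2 maxLag, using L-BFGS-B from a coarse
#' multi-start grid (c0 in \{0, .25, .5\} var, c1 in \{.5, 1\} var, a in
#' \{.25, .5, 1\} maxLag); the best objective wins. An all-zero
#' empirical variogram returns the flat model (c0 = c1 = 0) flagged.
#'
#' @param emp an [EmpiricalVariogram-class] with >= 3 non-empty bins
#' @return A [VariogramModel-class]
#' @export
fitSpherical <- function(emp) {
  if (length(emp@h) < 3)
    ecoStop("ecogrs_invalid_argument", "need at least 3 non-empty lag bins")
  if (all(emp@gamma == 0))
    return(new("VariogramModel", c0 = 0, c1 = 0, a = emp@maxLag, flat = TRUE))
  obj <- function(par) {
    m <- new("VariogramModel", c0 = par[1], c1 = par[2], a = par[3],
             flat = FALSE)
    sum(emp@np * (emp@gamma - sphericalGamma(emp@h, m))^2)
  }
  v <- max(emp@gamma)
  lower <- c(0, 0, 1e-6)
  upper <- c(Inf, Inf, 2 * emp@maxLag)
  best <- NULL
  for (c0 in c(0, 0.25, 0.5) * v)
    for (c1 in c(0.5, 1) * v)
      for (a in c(0.25, 0.5, 1) * emp@maxLag) {
        fit <- tryCatch(
          optim(c(c0, max(c1, 1e-8), a), obj, method = "L-BFGS-B",
                lower = lower, upper = upper),
          error = function(e) NULL)
        if (!is.null(fit) && (is.null(best) || fit$value < best$value))
          best <- fit
      }
  if (is.null(best))
    ecoStop("ecogrs_undefined_result", "variogram fit failed from all starts")
  new("VariogramModel", c0 = best$par[1], c1 = best$par[2],
      a = best$par[3], flat = FALSE)
}

setMethod("show", "VariogramModel", function(object) {
  cat(sprintf("Spherical variogram: nugget = %.4g, partial sill = %.4g, range = %.4g km%s\n",
              object@c0, object@c1, object@a,
              if (object@flat) " (flat)" else ""))
})

#' Ordinary kriging on a regular geographic grid
#'
#' Solves, per grid node, the ordinary kriging system
#' `[Gamma 1; 1' 0] [lambda; mu] = [gamma0; 1]` with
#' `Gamma_ij = gamma(d_ij)` and `gamma0_i = gamma(d_i,node)` on
#' great-circle distances; the prediction is `lambda' z` and the kriging
#' variance `lambda' gamma0 + mu` (tiny negative values are clipped to
#' 0). All sites are used at every node. The default grid is the
#' bounding box of the sites padded by 5% per side with a common cell
#' size such that the longer side has 100 nodes.
#'
#' @param lat,lon site coordinates (n >= 3, no duplicates)
#' @param values site values
#' @param model a fitted [VariogramModel-class]
#' @param gridLat,gridLon node coordinates (optional; default as above)
#' @param nGrid nodes along the longer bounding-box side (default 100)
#' @param pad bounding-box padding fraction per side (default 0.05)
#' @return A [KrigingGrid-class]
#' @export
ordinaryKrige <- function(lat, lon, values, model, gridLat = NULL,
                          gridLon = NULL, nGrid = 100, pad = 0.05) {
  n <- length(values)
  if (n < 3)
    ecoStop("ecogrs_invalid_argument", "need at least 3 sites")
  D <- distanceMatrixKm(lat, lon)
  if (any(D[upper.tri(D)] == 0)) {
    dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)[1, ]
    ecoStop("ecogrs_invalid_argument",
            sprintf("duplicate coordinates at sites %d and %d",
                    dup[1], dup[2]))
  }
  if (is.null(gridLat) || is.null(gridLon)) {
    latSpan <- diff(range(lat)); lonSpan <- diff(range(lon))
    cell <- max(latSpan, lonSpan) * (1 + 2 * pad) / (nGrid - 1)
    gridLat <- seq(min(lat) - pad * latSpan, max(lat) + pad * latSpan,
                   by = cell)
    gridLon <- seq(min(lon) - pad * lonSpan, max(lon) + pad * lonSpan,
                   by = cell)
  }
  A <- rbind(cbind(sphericalGamma(D, model), 1), c(rep(1, n), 0))
  Ainv <- tryCatch(solve(A), error = function(e)
    ecoStop("ecogrs_invalid_argument", "singular kriging system"))
  nodes <- expand.grid(lat = gridLat, lon = gridLon)
  G0 <- matrix(0, n, nrow(nodes))
  for (i in seq_len(n))
    G0[i, ] <- sphericalGamma(
      greatCircleKm(lat[i], lon[i], nodes$lat, nodes$lon), model)
  B <- rbind(G0, 1)
  L <- Ainv %*% B
  pred <- drop(crossprod(L[seq_len(n), , drop = FALSE], values))
  kv <- colSums(L[seq_len(n), , drop = FALSE] * G0) + L[n + 1, ]
  kv[kv < 0 & kv > -1e-9] <- 0
  new("KrigingGrid", lat = gridLat, lon = gridLon,
      pred = matrix(pred, length(gridLat), length(gridLon)),
      krigVar = matrix(kv, length(gridLat), length(gridLon)))
}

setMethod("show", "KrigingGrid", function(object) {
  cat(sprintf("KrigingGrid: %d x %d nodes, lat [%.3f, %.3f], lon [%.3f, %.3f]\n",
              length(object@lat), length(object@lon),
              min(object@lat), max(object@lat),
              min(object@lon), max(object@lon)))
  cat(sprintf("  predictions in [%.4g, %.4g]\n",
              min(object@pred), max(object@pred)))
})

#' Write a kriging grid as an ESRI ASCII grid
#'
#' Writes `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value -9999` followed by the prediction values row-major from
#' north to south. The grid must be regular with equal lat/lon spacing.
#'
#' @param grid a [KrigingGrid-class]
#' @param path output file
#' @param what "pred" (default) or "var"
#' @return the path, invisibly
#' @export
writeAsciiGrid <- function(grid, path, what = c("pred", "var")) {
  what <- match.arg(what)
  dLat <- diff(grid@lat); dLon <- diff(grid@lon)
  if (length(dLat) && (max(dLat) - min(dLat)) > 1e-9 * max(abs(dLat)))
    ecoStop("ecogrs_invalid_argument", "irregular latitude spacing")
  if (length(dLon) && (max(dLon) - min(dLon)) > 1e-9 * max(abs(dLon)))
    ecoStop("ecogrs_invalid_argument", "irregular longitude spacing")
  cell <- if (length(dLat)) dLat[1] else dLon[1]
  if (length(dLon) && abs(dLon[1] - cell) > 1e-9 * cell)
    ecoStop("ecogrs_invalid_argument", "cells must be square (lat/lon spacing equal)")
  M <- if (what == "pred") grid@pred else grid@krigVar
  M <- M[rev(seq_along(grid@lat)), , drop = FALSE]  # north first
  M[is.na(M)] <- -9999
  hdr <- c(sprintf("ncols %d", length(grid@lon)),
           sprintf("nrows %d", length(grid@lat)),
           sprintf("xllcorner %.10g", min(grid@lon) - cell / 2),
           sprintf("yllcorner %.10g", min(grid@lat) - cell / 2),
           sprintf("cellsize %.10g", cell),
           "NODATA_value -9999")
  body <- apply(M, 1, function(r) paste(sprintf("%.8g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [writeAsciiGrid]
#'
#' @param path file path
#' @return A [KrigingGrid-class] with the variance grid set to `NA`.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  vals <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                   tolower(vapply(hdr, `[`, "", 1)))
  nc <- vals[["ncols"]]; nr <- vals[["nrows"]]; cell <- vals[["cellsize"]]
  M <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  M[M == vals[["nodata_value"]]] <- NA
  M <- M[rev(seq_len(nr)), , drop = FALSE]  # back to south-first rows
  lat0 <- vals[["yllcorner"]] + cell / 2
  lon0 <- vals[["xllcorner"]] + cell / 2
  new("KrigingGrid",
      lat = lat0 + cell * (seq_len(nr) - 1),
      lon = lon0 + cell * (seq_len(nc) - 1),
      pred = M, krigVar = matrix(NA_real_, nr, nc))
}
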