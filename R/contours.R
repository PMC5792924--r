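#' Extract isoglosses from a field state
#'
#' Marching-squares level set of the frequency field `f = p(m)` at 1/2,
#' with linear interpolation between cell centres. Contours are classified
#' closed (loops) or open (terminating at the land boundary or grid edge).
#' Signed curvature (positive where the contour bows toward the interior
#' of the A-domain, `f > 1/2`) and outward unit normals (pointing away
#' from the A-domain) are attached per vertex.
#'
#' @param state a [FieldState-class].
#' @param raster the [PopulationRaster-class] fixing the geometry.
#' @param params a [ModelParams-class].
#' @param level level-set value (default 1/2, the isogloss definition).
#' @return A list of [IsoglossContour-class] (empty when `f` never crosses
#'   the level).
#' @export
extractIsoglosses <- function(state, raster, params, level = 0.5) {
  f <- frequencyField(state, params)
  rng <- suppressWarnings(range(f, na.rm = TRUE))
  if (!(rng[1] < level && rng[2] > level)) return(list())
  cc <- cellCenters(raster)
  lines <- contourLines(cc$x, cc$y, f, levels = level)
  lapply(lines, function(ln) .makeContour(cbind(ln$x, ln$y), f, raster))
}

.makeContour <- function(V, f, raster) {
  n <- nrow(V)
  closed <- n > 2 && all(abs(V[1, ] - V[n, ]) < 1e-9)
  ## tangents/curvature via central differences along the polyline
  idx <- seq_len(n)
  nxt <- if (closed) c(idx[-1], 2L) else c(idx[-1], n)
  prv <- if (closed) c(n - 1L, idx[-n]) else c(1L, idx[-n])
  dx <- V[nxt, 1] - V[prv, 1]
  dy <- V[nxt, 2] - V[prv, 2]
  len <- pmax(sqrt(dx^2 + dy^2), 1e-12)
  tx <- dx / len; ty <- dy / len
  ## curvature magnitude from the turn of the tangent per arc length
  d2x <- V[nxt, 1] - 2 * V[idx, 1] + V[prv, 1]
  d2y <- V[nxt, 2] - 2 * V[idx, 2] + V[prv, 2]
  cross <- dx * d2y - dy * d2x
  kap <- 4 * cross / len^3  # signed wrt the traversal orientation
  ## normals: rotate the tangent; orient away from the A-domain by
  ## sampling f a fraction of a cell along each candidate
  nx0 <- -ty; ny0 <- tx
  h <- raster@cellSize
  fA <- .sampleField(f, raster, V[, 1] + 0.5 * h * nx0, V[, 2] + 0.5 * h * ny0)
  flip <- !is.na(fA) & fA >= 0.5
  nx0[flip] <- -nx0[flip]; ny0[flip] <- -ny0[flip]
  ## bowing toward A-interior: curvature centre on the A side
  sgn <- ifelse(flip, 1, -1)
  new("IsoglossContour", vertices = V, closed = closed,
      curvature = kap * sgn, normal = cbind(nx0, ny0))
}

## bilinear sample of a gridded field at physical coordinates
.sampleField <- function(f, raster, x, y) {
  d <- dim(f)
  gx <- (x - raster@origin[1]) / raster@cellSize + 0.5
  gy <- (y - raster@origin[2]) / raster@cellSize + 0.5
  i0 <- pmin(pmax(floor(gx), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(gy), 1), d[2] - 1)
  wx <- pmin(pmax(gx - i0, 0), 1)
  wy <- pmin(pmax(gy - j0, 0), 1)
  v00 <- f[cbind(i0, j0)]; v10 <- f[cbind(i0 + 1, j0)]
  v01 <- f[cbind(i0, j0 + 1)]; v11 <- f[cbind(i0 + 1, j0 + 1)]
  (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
    (1 - wx) * wy * v01 + wx * wy * v11
}

setMethod("show", "IsoglossContour", function(object) {
  cat(sprintf("IsoglossContour: %d vertices, %s, length %.3g\n",
              nrow(object@vertices), ifelse(object@closed, "closed", "open"),
              contourLength(object)))
})

#' Polyline length of a contour
#'
#' @param contour an [IsoglossContour-class].
#' @return Total arc length.
#' @export
contourLength <- function(contour) {
  V <- contour@vertices
  sum(sqrt(diff(V[, 1])^2 + diff(V[, 2])^2))
}

#' Total isogloss length of a state
#'
#' @inheritParams extractIsoglosses
#' @return Sum of the arc lengths of all level-1/2 contours.
#' @export
totalIsoglossLength <- function(state, raster, params) {
  sum(vapply(extractIsoglosses(state, raster, params), contourLength,
             numeric(1)))
}

#' Mean radius of a closed contour
#'
#' Mean and standard deviation of the vertex distances to `center`; the
#' standard deviation quantifies circularity.
#'
#' @param contour a closed [IsoglossContour-class].
#' @param center length-2 numeric.
#' @return List with `mean` and `sd`.
#' @export
measureRadius <- function(contour, center) {
  if (!contour@closed) stop("measureRadius requires a closed contour")
  V <- contour@vertices[-1, , drop = FALSE]  # first == last on closed loops
  r <- sqrt((V[, 1] - center[1])^2 + (V[, 2] - center[2])^2)
  list(mean = mean(r), sd = sd(r))
}

#' Position of a quasi-1-D front
#'
#' Averages the frequency field over the transverse direction and locates
#' the half-crossing of the resulting profile by linear interpolation.
#' Errors when the profile crosses 1/2 more than once (multiple fronts).
#'
#' @param state a [FieldState-class].
#' @param raster the geometry.
#' @param params a [ModelParams-class].
#' @param axis 1 when the front moves along x, 2 along y.
#' @return Physical front position.
#' @export
frontPosition <- function(state, raster, params, axis = 1) {
  f <- frequencyField(state, params)
  prof <- if (axis == 1) rowMeans(f, na.rm = TRUE) else colMeans(f, na.rm = TRUE)
  co <- cellCenters(raster)
  xs <- if (axis == 1) co$x else co$y
  s <- prof - 0.5
  cr <- which(s[-length(s)] * s[-1] < 0)
  cr <- cr[!is.na(cr)]
  exact <- which(s == 0)
  if (length(cr) + length(exact) > 1) stop("multiple fronts detected")
  if (length(exact) == 1) return(xs[exact])
  if (length(cr) == 0) stop("no front: profile does not cross 1/2")
  k <- cr[1]
  xs[k] + (xs[k + 1] - xs[k]) * (0.5 - prof[k]) / (prof[k + 1] - prof[k])
}

#' Front speed from a time sequence of states
#'
#' Least-squares slope of the front position against time, after
#' discarding an initial burn-in fraction of the snapshots.
#'
#' @param snapshots list of [FieldState-class] at increasing times.
#' @param raster the geometry.
#' @param params a [ModelParams-class].
#' @param axis direction of front motion (see [frontPosition()]).
#' @param burnIn fraction of early snapshots to discard.
#' @return Speed in length units per memory timescale.
#' @export
measureFrontSpeed <- function(snapshots, raster, params, axis = 1,
                              burnIn = 0.3) {
  ts <- vapply(snapshots, function(s) s@t, numeric(1))
  xs <- vapply(snapshots, frontPosition, numeric(1),
               raster = raster, params = params, axis = axis)
  keep <- ts >= min(ts) + burnIn * (max(ts) - min(ts))
  if (sum(keep) < 2) stop("not enough snapshots after burn-in")
  unname(coef(lm(xs[keep] ~ ts[keep]))[2])
}

#' Write contours as GeoJSON
#'
#' Contours are written as a `FeatureCollection` of `LineString`s in grid
#' coordinates, with `closed` as a feature property.
#'
#' @param contours list of [IsoglossContour-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
contoursToGeoJSON <- function(contours, path) {
  feats <- lapply(contours, function(ct) {
    list(type = "Feature",
         properties = list(closed = ct@closed),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(ct@vertices, 1, c,
                                                    simplify = FALSE))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
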