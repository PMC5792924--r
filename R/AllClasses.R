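#' @import methods
#' @importFrom stats coef lm optimize runif rbinom sd uniroot integrate cutree dist hclust setNames
#' @importFrom grDevices contourLines
#' @importFrom utils head tail
NULL

#' Model parameters for the dialect field equations
#'
#' Container for the five parameters of the memory-field model: the
#' short-range (local) interaction scale `sigma`, the long-range
#' (metropolitan) interaction scale `gamma`, the conformity number `beta`
#' (`beta >= 1`; values above 1 favour the locally most common variant and
#' generate surface tension at isoglosses), the inherent bias `alpha`
#' (`alpha = 1` means no bias; `alpha > 1` disfavours variant A), and the
#' memory timescale `tau`. Time is expressed in units of `tau` throughout,
#' so solvers operate with `tau = 1`.
#'
#' @slot sigma numeric, short-range interaction length (> 0).
#' @slot gamma numeric, metropolitan interaction length (> 0).
#' @slot beta numeric, conformity number (>= 1).
#' @slot alpha numeric, inherent bias (> 0).
#' @slot tau numeric, memory timescale (> 0).
#' @export
setClass("ModelParams",
  representation(sigma = "numeric", gamma = "numeric", beta = "numeric",
                 alpha = "numeric", tau = "numeric"),
  prototype(sigma = 5, gamma = 25, beta = 1.1, alpha = 1, tau = 1))

setValidity("ModelParams", function(object) {
  msg <- character()
  if (length(object@sigma) != 1 || !is.finite(object@sigma) || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive number")
  if (length(object@gamma) != 1 || !is.finite(object@gamma) || object@gamma <= 0)
    msg <- c(msg, "gamma must be a single positive number")
  if (length(object@beta) != 1 || !is.finite(object@beta) || object@beta < 1)
    msg <- c(msg, "beta must be a single number >= 1")
  if (length(object@alpha) != 1 || !is.finite(object@alpha) || object@alpha <= 0)
    msg <- c(msg, "alpha must be a single positive number")
  if (length(object@tau) != 1 || !is.finite(object@tau) || object@tau <= 0)
    msg <- c(msg, "tau must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' A Gaussian city on the population landscape
#'
#' Describes one population centre: peak density `omega` over a Gaussian
#' core of scale `radius`, optionally surrounded by a unit-amplitude, more
#' slowly decaying hinterland of scale `backgroundRadius` representing
#' outlying towns and villages.
#'
#' @slot center numeric length-2, position of the city centre.
#' @slot omega numeric, peak core density (> 0).
#' @slot radius numeric, core Gaussian scale R (> 0).
#' @slot backgroundRadius numeric, hinterland scale B (NA when absent;
#'   must exceed `radius` when present).
#' @export
setClass("CitySpec",
  representation(center = "numeric", omega = "numeric", radius = "numeric",
                 backgroundRadius = "numeric"),
  prototype(center = c(0, 0), omega = 1, radius = 1, backgroundRadius = NA_real_))

setValidity("CitySpec", function(object) {
  msg <- character()
  if (length(object@center) != 2 || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a finite length-2 vector")
  if (!isTRUE(object@omega > 0)) msg <- c(msg, "omega must be > 0")
  if (!isTRUE(object@radius > 0)) msg <- c(msg, "radius must be > 0")
  if (!is.na(object@backgroundRadius) && object@backgroundRadius <= object@radius)
    msg <- c(msg, "backgroundRadius must exceed radius")
  if (length(msg)) msg else TRUE
})

#' Gridded population density with land mask
#'
#' A regular square grid of population densities together with a logical
#' land mask and the physical edge length of a cell. `values[i, j]` is the
#' density at the cell centred on `(x_i, y_j)` with
#' `x_i = origin[1] + (i - 1/2) * cellSize` and similarly for `y`.
#' Densities are zero off land. The `boundary` slot selects periodic or
#' closed (coastline) boundary handling for all operators built on the
#' raster.
#'
#' @slot values numeric matrix of densities (>= 0), x along rows.
#' @slot cellSize numeric, physical cell edge length (> 0).
#' @slot landMask logical matrix with the dimensions of `values`.
#' @slot boundary character, `"closed"` or `"periodic"`.
#' @slot origin numeric length-2, physical coordinates of the grid corner.
#' @export
setClass("PopulationRaster",
  representation(values = "matrix", cellSize = "numeric", landMask = "matrix",
                 boundary = "character", origin = "numeric"),
  prototype(values = matrix(1, 1, 1), cellSize = 1,
            landMask = matrix(TRUE, 1, 1), boundary = "closed",
            origin = c(0, 0)))

setValidity("PopulationRaster", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (!identical(dim(object@values), dim(object@landMask)))
    msg <- c(msg, "values and landMask dimensions disagree")
  if (!is.logical(object@landMask)) msg <- c(msg, "landMask must be logical")
  if (length(object@cellSize) != 1 || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (!object@boundary %in% c("closed", "periodic"))
    msg <- c(msg, "boundary must be 'closed' or 'periodic'")
  v <- object@values[object@landMask]
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "densities must be finite and >= 0 on land")
  if (any(object@values[!object@landMask] != 0))
    msg <- c(msg, "densities must be exactly 0 off land")
  if (length(object@origin) != 2) msg <- c(msg, "origin must have length 2")
  if (length(msg)) msg else TRUE
})

#' Fraction of metropolitan speakers per cell
#'
#' Grid of the local fraction `M(r)` of speakers behaving as metropolitans
#' (making long-range contacts), in `[0, 1]`, on the same geometry as its
#' parent [PopulationRaster-class].
#'
#' @slot values numeric matrix in `[0, 1]`.
#' @export
setClass("MetropolitanField",
  representation(values = "matrix"),
  prototype(values = matrix(0, 1, 1)))

setValidity("MetropolitanField", function(object) {
  v <- object@values[is.finite(object@values)]
  if (any(v < 0 | v > 1)) "values must lie in [0, 1]" else TRUE
})

#' Discretized interaction operator
#'
#' Linear operator taking any scalar field on land cells to its spatial
#' average under the two-kernel interaction density: a Gaussian short-range
#' component (scale `sigma`) acting between all pairs and a Lorentzian
#' long-range component (scale `gamma`) acting between metropolitans, both
#' weighted by the population density of the listened-to cell and
#' row-normalized over land. Application is convolution-based (FFT), so
#' large grids are handled without forming the dense matrix; use
#' [denseWeights()] to materialize the row-stochastic matrix on small
#' grids.
#'
#' @slot raster the [PopulationRaster-class] the operator was built on.
#' @slot M numeric matrix, metropolitan fraction per cell.
#' @slot params the [ModelParams-class] used (sigma, gamma).
#' @slot fftG,fftL complex matrices, transforms of the two kernels on the
#'   padded grid.
#' @slot pad integer length-2, padded grid dimensions.
#' @slot norm numeric matrix, per-row normalizers N(r).
#' @export
setClass("InteractionOperator",
  representation(raster = "PopulationRaster", M = "matrix",
                 params = "ModelParams", fftG = "matrix", fftL = "matrix",
                 pad = "integer", norm = "matrix"))

#' Memory field state
#'
#' The memory field `m(r, t)` on the raster grid (values in `[0, 1]` on
#' land, `NA` off land) together with the elapsed time in units of the
#' memory timescale. The usage frequency field is the derived view
#' `f = p(m)` through the conformity map.
#'
#' @slot m numeric matrix of memories.
#' @slot t numeric, elapsed time (>= 0).
#' @export
setClass("FieldState",
  representation(m = "matrix", t = "numeric"),
  prototype(m = matrix(0.5, 1, 1), t = 0))

setValidity("FieldState", function(object) {
  v <- object@m[is.finite(object@m)]
  msg <- character()
  if (any(v < 0 | v > 1)) msg <- c(msg, "memories must lie in [0, 1]")
  if (length(object@t) != 1 || object@t < 0) msg <- c(msg, "t must be >= 0")
  if (length(msg)) msg else TRUE
})

#' An extracted isogloss contour
#'
#' A polyline along which the frequency field crosses 1/2, with linear
#' interpolation between grid cells. `closed` contours have coinciding
#' first and last vertices; open contours terminate at the land boundary.
#' Discrete signed curvature (positive where the contour bows toward the
#' A-domain interior) and outward unit normals are evaluated per vertex.
#'
#' @slot vertices numeric matrix with columns x, y.
#' @slot closed logical, whether the polyline is a loop.
#' @slot curvature numeric vector, signed curvature per vertex.
#' @slot normal numeric matrix, outward unit normal per vertex.
#' @export
setClass("IsoglossContour",
  representation(vertices = "matrix", closed = "logical",
                 curvature = "numeric", normal = "matrix"))

#' Network of cities for the hierarchical-diffusion reduction
#'
#' Cities reduced to points with metropolitan-core populations, coupled by
#' gravity-weighted long-range interaction: the weight of city j in the
#' language sample of city i decays as a Lorentzian of their separation.
#'
#' @slot positions numeric matrix (n x 2) of city centres.
#' @slot populations numeric vector of core populations P_i (> 0).
#' @slot params [ModelParams-class]; `gamma`, `beta`, `alpha` are used.
#' @slot coreFactor numeric, the core-radius multiplier c (default 1).
#' @slot radii numeric vector of core radii R_i (NA allowed when only the
#'   ODE reduction is used).
#' @export
setClass("CityNetwork",
  representation(positions = "matrix", populations = "numeric",
                 params = "ModelParams", coreFactor = "numeric",
                 radii = "numeric"))

setValidity("CityNetwork", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (ncol(object@positions) != 2) msg <- c(msg, "positions must be n x 2")
  if (length(object@populations) != n)
    msg <- c(msg, "populations length must match positions")
  if (any(object@populations <= 0)) msg <- c(msg, "populations must be > 0")
  if (n > 1) {
    d <- as.matrix(dist(object@positions))
    if (any(d[upper.tri(d)] == 0)) msg <- c(msg, "coincident cities")
  }
  if (length(msg)) msg else TRUE
})

#' Per-city memory and frequency trajectories
#'
#' Result of integrating the city ODE system: times, per-city memories
#' `m_i(t)` and the derived frequencies `f_i(t) = p(m_i)`.
#'
#' @slot times numeric vector.
#' @slot m numeric matrix, one column per city.
#' @slot f numeric matrix, one column per city.
#' @export
setClass("CityTrajectory",
  representation(times = "numeric", m = "matrix", f = "matrix"))

#' A stochastic lattice of individual speakers
#'
#' Occupied sites of a periodic integer lattice, each holding one speaker's
#' memory, connected by an embedded random geometric network (link
#' probability Gaussian in separation). Mixing events swap memories between
#' random occupied sites; immigration events overwrite memories with an
#' incoming value.
#'
#' @slot coords integer matrix (n x 2) of occupied site coordinates (1-based).
#' @slot memory numeric vector of per-speaker memories in `[0, 1]`.
#' @slot adjacency a sparse symmetric adjacency matrix (may be 0 x 0 before
#'   [buildEmbeddedNetwork()] is called).
#' @slot dims integer length-2 lattice dimensions.
#' @slot t numeric, elapsed time.
#' @export
setClass("AgentLattice",
  representation(coords = "matrix", memory = "numeric", adjacency = "ANY",
                 dims = "integer", t = "numeric"))

setValidity("AgentLattice", function(object) {
  msg <- character()
  if (length(object@memory) != nrow(object@coords))
    msg <- c(msg, "one memory per occupied site required")
  v <- object@memory
  if (any(v < 0 | v > 1)) msg <- c(msg, "memories must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Labelled dialect map
#'
#' Cluster label per scored location, together with the location
#' coordinates (grid indices) and the geometry they refer to.
#'
#' @slot labels integer vector of cluster labels (1..nC).
#' @slot cells integer matrix (n x 2) of grid indices of the scored cells.
#' @slot dims integer length-2 grid dimensions.
#' @export
setClass("DialectMap",
  representation(labels = "integer", cells = "matrix", dims = "integer"))
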