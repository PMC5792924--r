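#' Sample an agent lattice from an occupation-probability raster
#'
#' Each lattice site `(x, y)` is independently occupied by one speaker
#' with probability `rho_xy` (use the `"capped"` density mode, which keeps
#' probabilities in `[0, 1]`). Initial memories are set from `memory`.
#'
#' @param raster a [PopulationRaster-class] whose values lie in `[0, 1]`.
#' @param seed integer seed for the occupancy draw.
#' @param memory scalar initial memory, or a matrix with the raster's
#'   dimensions from which occupied sites take their value.
#' @return An [AgentLattice-class] (without a contact network yet; see
#'   [buildEmbeddedNetwork()]).
#' @export
sampleLattice <- function(raster, seed = NULL, memory = 0.5) {
  v <- raster@values
  if (any(v > 1)) stop("occupation probabilities must be <= 1 (use capped mode)")
  if (!is.null(seed)) set.seed(seed)
  occ <- matrix(runif(length(v)) < v, nrow(v), ncol(v)) & raster@landMask
  coords <- which(occ, arr.ind = TRUE)
  mem <- if (is.matrix(memory)) memory[occ] else rep(memory, nrow(coords))
  new("AgentLattice", coords = unname(coords), memory = as.numeric(mem),
      adjacency = Matrix::sparseMatrix(i = integer(), j = integer(),
                                       dims = c(nrow(coords), nrow(coords))),
      dims = dim(v), t = 0)
}

setMethod("show", "AgentLattice", function(object) {
  cat(sprintf(
    "AgentLattice: %d speakers on %d x %d sites, %d links, t=%g\n",
    nrow(object@coords), object@dims[1], object@dims[2],
    as.integer(Matrix::nnzero(object@adjacency) / 2), object@t))
})

#' Build the embedded contact network
#'
#' Every pair of occupied sites is linked independently with probability
#' `exp(-(dx^2 + dy^2) / (2 sigma^2))`, using minimum-image (periodic)
#' displacements. Pairs farther apart than `6 sigma` are skipped (link
#' probability below 2e-8). The adjacency is symmetric with no
#' self-links.
#'
#' @param lattice an [AgentLattice-class].
#' @param sigma interaction scale in lattice units.
#' @param seed integer seed for the link draws.
#' @return The lattice with its `adjacency` slot filled.
#' @export
buildEmbeddedNetwork <- function(lattice, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  co <- lattice@coords
  n <- nrow(co)
  dims <- lattice@dims
  cut <- 6 * sigma
  bs <- max(ceiling(cut), 1L)
  nbx <- max(1L, as.integer(ceiling(dims[1] / bs)))
  nby <- max(1L, as.integer(ceiling(dims[2] / bs)))
  bx <- pmin((co[, 1] - 1L) %/% bs + 1L, nbx)
  by <- pmin((co[, 2] - 1L) %/% bs + 1L, nby)
  bin <- (by - 1L) * nbx + bx
  members <- split(seq_len(n), bin)
  binOf <- as.integer(names(members))
  ii <- integer(0); jj <- integer(0)
  ## neighbouring bin offsets; periodic wrap in bin space (deduplicated,
  ## so small bin grids do not revisit the same bin pair)
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  for (k in seq_along(members)) {
    b <- binOf[k]
    b_x <- (b - 1L) %% nbx + 1L
    b_y <- (b - 1L) %/% nbx + 1L
    A <- members[[k]]
    nbrs <- unique((( (b_y - 1L + offs$dy) %% nby) * nbx +
                    ((b_x - 1L + offs$dx) %% nbx)) + 1L)
    for (b2 in nbrs) {
      if (b2 < b) next  # each bin pair once
      B <- members[[as.character(b2)]]
      if (is.null(B)) next
      if (b2 == b) {
        if (length(A) < 2) next
        i1 <- rep(seq_along(A), times = rev(seq_along(A)) - 1L)
        j1 <- sequence(rev(seq_along(A))[-1]) +
          rep(seq_along(A), times = rev(seq_along(A)) - 1L)
        pr <- cbind(A[i1], A[j1])
      } else {
        pr <- cbind(rep(A, each = length(B)), rep(B, length(A)))
      }
      dx <- abs(co[pr[, 1], 1] - co[pr[, 2], 1])
      dy <- abs(co[pr[, 1], 2] - co[pr[, 2], 2])
      dx <- pmin(dx, dims[1] - dx)
      dy <- pmin(dy, dims[2] - dy)
      d2 <- as.numeric(dx)^2 + as.numeric(dy)^2
      ok <- d2 <= cut^2
      if (!any(ok)) next
      p <- exp(-d2[ok] / (2 * sigma^2))
      keep <- runif(length(p)) < p
      if (any(keep)) {
        ii <- c(ii, pr[ok, 1][keep])
        jj <- c(jj, pr[ok, 2][keep])
      }
    }
  }
  adj <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                              dims = c(n, n))
  lattice@adjacency <- adj
  lattice
}

#' One deterministic step of the agent memory dynamics
#'
#' Each speaker relaxes toward the mean usage frequency of their network
#' neighbours: `m <- m + dt (mean_{nb} p(m_nb) - m)`. Speakers without
#' neighbours relax toward their own `p(m)` (self-term only).
#'
#' @param lattice an [AgentLattice-class] with adjacency built.
#' @param params a [ModelParams-class] (`alpha`, `beta` used).
#' @param dt time step (<= 1).
#' @return The advanced lattice.
#' @export
stepAgents <- function(lattice, params, dt = 0.1) {
  stopifnot(dt <= 1)
  m <- lattice@memory
  f <- conformityMap(m, params)
  deg <- Matrix::rowSums(lattice@adjacency)
  tgt <- ifelse(deg > 0,
                as.numeric(lattice@adjacency %*% f) / pmax(deg, 1), f)
  m2 <- m + dt * (tgt - m)
  lattice@memory <- pmin(pmax(m2, 0), 1)
  lattice@t <- lattice@t + dt
  lattice
}

#' Random memory exchanges (population mixing)
#'
#' Each occupied site is independently selected with probability
#' `epsilon * dt`; each selected site swaps memories with a partner drawn
#' uniformly at random from the other occupied sites. Swaps are applied
#' as exchanges, so the multiset of memory values is exactly conserved.
#'
#' @param lattice an [AgentLattice-class].
#' @param epsilon mixing rate per speaker per memory timescale.
#' @param dt time step (`epsilon * dt <= 1`).
#' @return The lattice after the exchanges.
#' @export
applyMixing <- function(lattice, epsilon, dt = 0.1) {
  stopifnot(epsilon >= 0, epsilon * dt <= 1)
  n <- length(lattice@memory)
  if (n < 2) stop("mixing requires at least 2 occupied sites")
  if (epsilon == 0) return(lattice)
  sel <- which(runif(n) < epsilon * dt)
  m <- lattice@memory
  for (k in sel) {
    j <- sample.int(n - 1L, 1L)
    if (j >= k) j <- j + 1L
    tmp <- m[k]; m[k] <- m[j]; m[j] <- tmp
  }
  lattice@memory <- m
  lattice
}

#' Immigration of outside speakers
#'
#' Each occupied site independently has its speaker replaced with
#' probability `nu * dt`; the replacement carries memory `value`
#' (default 0: a pure B speaker).
#'
#' @param lattice an [AgentLattice-class].
#' @param nu replacement rate per speaker per memory timescale.
#' @param dt time step (`nu * dt <= 1`).
#' @param value incoming memory value.
#' @return The lattice after replacements.
#' @export
applyImmigration <- function(lattice, nu, dt = 0.1, value = 0) {
  stopifnot(nu >= 0, nu * dt <= 1)
  if (nu == 0) return(lattice)
  sel <- runif(length(lattice@memory)) < nu * dt
  lattice@memory[sel] <- value
  lattice
}

#' Simulate the stochastic agent model
#'
#' Interleaves the deterministic memory step with Bernoulli-thinned mixing
#' and immigration events (rates `epsilon dt` and `nu dt` per step, an
#' O(dt) approximation of the continuous-time rules).
#'
#' @param lattice an [AgentLattice-class] with adjacency built.
#' @param params a [ModelParams-class].
#' @param tEnd simulation end time.
#' @param dt time step.
#' @param epsilon mixing rate: scalar or function of time (for ramps).
#' @param nu immigration rate.
#' @param immigrantMemory memory of incoming speakers.
#' @param seed optional seed set before the run.
#' @param recordEvery interval at which `summarize(lattice)` is recorded.
#' @param summarize function of the lattice returning a numeric vector.
#' @return List with `lattice` (final) and `records` (data frame of time
#'   plus the summaries, or `NULL`).
#' @export
simulateAgents <- function(lattice, params, tEnd, dt = 0.1, epsilon = 0,
                           nu = 0, immigrantMemory = 0, seed = NULL,
                           recordEvery = NULL, summarize = NULL) {
  if (!is.null(seed)) set.seed(seed)
  epsFun <- if (is.function(epsilon)) epsilon else function(t) epsilon
  steps <- round(tEnd / dt)
  recs <- list()
  nextRec <- 0
  for (s in seq_len(steps)) {
    lattice <- stepAgents(lattice, params, dt)
    e <- epsFun(lattice@t)
    if (e > 0) lattice <- applyMixing(lattice, e, dt)
    if (nu > 0) lattice <- applyImmigration(lattice, nu, dt, immigrantMemory)
    if (!is.null(recordEvery) && lattice@t >= nextRec - 1e-9) {
      recs[[length(recs) + 1L]] <- c(t = lattice@t, summarize(lattice))
      nextRec <- nextRec + recordEvery
    }
  }
  list(lattice = lattice,
       records = if (length(recs)) as.data.frame(do.call(rbind, recs)) else NULL)
}

#' Variant-preference raster of a lattice
#'
#' A site is counted as an A-user when `p(m) >= 1/2`. Unoccupied sites
#' are `NA`.
#'
#' @param lattice an [AgentLattice-class].
#' @param params a [ModelParams-class].
#' @return Logical matrix with the lattice dimensions.
#' @export
preferenceRaster <- function(lattice, params) {
  out <- matrix(NA, lattice@dims[1], lattice@dims[2])
  out[lattice@coords] <- conformityMap(lattice@memory, params) >= 0.5
  out
}
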