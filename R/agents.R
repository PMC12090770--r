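#' @include AllClasses.R AllGenerics.R
NULL

#' Radius of a spherical cell from its mass
#'
#' Inverts mass = (4/3) pi rho r^3.
#'
#' @param mass wet mass (pg).
#' @param rho cell mass density (pg/um^3); 1.1 is a typical wet density.
#' @return radius (um).
#' @export
massToRadius <- function(mass, rho) (3 * mass / (4 * pi * rho))^(1 / 3)

#' Create a population of bacterial agents
#'
#' @param species character vector of species ids.
#' @param x,y center coordinates (um); the bottom wall is at y = 0.
#' @param mass wet mass (pg); radii follow from \code{cellDensity}.
#' @param cellDensity wet density rho (pg/um^3), default 1.1.
#' @param attached logical biofilm-membership flag(s).
#' @param angle planktonic heading (radians); drawn uniformly when missing.
#' @param id integer ids; autonumbered when missing.
#' @return an \linkS4class{AgentSet}.
#' @export
newAgents <- function(species, x, y, mass, cellDensity = 1.1,
                      attached = FALSE, angle = NULL, id = NULL) {
  n <- length(x)
  if (is.null(angle)) angle <- stats::runif(n, 0, 2 * pi)
  if (is.null(id)) id <- seq_len(n)
  d <- data.frame(id = as.integer(id),
                  species = rep_len(as.character(species), n),
                  x = as.numeric(x), y = as.numeric(y),
                  mass = rep_len(as.numeric(mass), n),
                  radius = massToRadius(rep_len(as.numeric(mass), n),
                                        cellDensity),
                  dirx = cos(angle), diry = sin(angle),
                  attached = rep_len(as.logical(attached), n))
  new("AgentSet", data = d, cellDensity = cellDensity)
}

#' Accessors for AgentSet
#'
#' @param x an \linkS4class{AgentSet}.
#' @param bySpecies for \code{totalBiomass}: return per-species totals.
#' @param ... unused.
#' @name agent-accessors
#' @aliases nAgents agentData totalBiomass
NULL

#' @rdname agent-accessors
setMethod("nAgents", "AgentSet", function(x) nrow(x@data))
#' @rdname agent-accessors
setMethod("agentData", "AgentSet", function(x) x@data)
#' @rdname agent-accessors
setMethod("totalBiomass", "AgentSet", function(x, bySpecies = FALSE, ...) {
  if (!bySpecies) return(sum(x@data$mass))
  vapply(split(x@data$mass, x@data$species), sum, numeric(1))
})

setMethod("show", "AgentSet", function(object) {
  d <- object@data
  cat("AgentSet:", nrow(d), "agents (", sum(d$attached), "attached ) of",
      length(unique(d$species)), "species; total biomass",
      format(sum(d$mass), digits = 6), "pg\n")
})

replaceAgentData <- function(agents, d) {
  agents@data <- d
  agents
}

## minimum-image x difference on a periodic domain of the given width
wrapDx <- function(dx, width) dx - width * round(dx / width)

#' Displacement distance between two agents
#'
#' The sum of the radii minus the center-to-center distance (minimum-image
#' along the periodic x axis); positive iff the spheres intersect, zero for
#' tangency. Coincident centers return the maximal overlap (the radius sum).
#'
#' @param agents an \linkS4class{AgentSet}.
#' @param i,j row indices of the two agents.
#' @param width periodic domain width (um).
#' @return displacement distance (um).
#' @export
displacementDistance <- function(agents, i, j, width) {
  d <- agents@data
  dx <- wrapDx(d$x[i] - d$x[j], width)
  dy <- d$y[i] - d$y[j]
  (d$radius[i] + d$radius[j]) - sqrt(dx^2 + dy^2)
}

## all intersecting pairs: data.frame(i, j, overlap, ux, uy) where (ux, uy)
## is the unit vector from j to i (the push direction for agent i);
## coincident centers get a deterministic direction hashed from the id pair
overlappingPairs <- function(agents, width, tol = 0) {
  d <- agents@data
  n <- nrow(d)
  if (n < 2) return(data.frame(i = integer(), j = integer(),
                               overlap = numeric(), ux = numeric(),
                               uy = numeric()))
  dx <- wrapDx(outer(d$x, d$x, "-"), width)
  dy <- outer(d$y, d$y, "-")
  dist2 <- dx^2 + dy^2
  rsum <- outer(d$radius, d$radius, "+")
  hit <- which(upper.tri(dist2) & dist2 < (rsum - tol)^2, arr.ind = TRUE)
  if (!nrow(hit)) return(data.frame(i = integer(), j = integer(),
                                    overlap = numeric(), ux = numeric(),
                                    uy = numeric()))
  i <- hit[, 1]; j <- hit[, 2]
  dd <- sqrt(dist2[hit])
  ov <- rsum[hit] - dd
  ux <- ifelse(dd > 0, dx[hit] / dd, 0)
  uy <- ifelse(dd > 0, dy[hit] / dd, 0)
  co <- dd == 0
  if (any(co)) {
    ang <- 2 * pi * (((d$id[i[co]] * 37L + d$id[j[co]] * 91L) %% 997L) / 997)
    ux[co] <- cos(ang); uy[co] <- sin(ang)
  }
  data.frame(i = i, j = j, overlap = ov, ux = ux, uy = uy)
}

#' One Jacobi-style shoving iteration
#'
#' For every agent, half the displacement distance to each intersecting
#' neighbor is accumulated along the center-to-center line, pointing away
#' from the neighbor; all candidate positions are computed from the current
#' positions and then applied together, so the result is independent of
#' agent order. An agent shoved into the bottom wall is clipped at
#' y = radius (resting on the wall) while keeping its tangential motion,
#' so wall-resting agents can still slide sideways; x wraps periodically.
#'
#' @param agents an \linkS4class{AgentSet}.
#' @param width periodic domain width (um).
#' @return list with the updated \code{agents} and \code{maxOverlap}, the
#'   largest displacement distance found before the iteration.
#' @export
shoveIteration <- function(agents, width) {
  d <- agents@data
  pr <- overlappingPairs(agents, width)
  if (!nrow(pr))
    return(list(agents = agents, maxOverlap = if (nrow(d) > 1)
      maxOverlapOf(agents, width) else -Inf))
  push <- pr$overlap / 2
  vx <- numeric(nrow(d)); vy <- numeric(nrow(d))
  ## agent i is pushed along +u (away from j), agent j along -u
  vx <- vx + tapplySum(pr$i, push * pr$ux, nrow(d)) -
    tapplySum(pr$j, push * pr$ux, nrow(d))
  vy <- vy + tapplySum(pr$i, push * pr$uy, nrow(d)) -
    tapplySum(pr$j, push * pr$uy, nrow(d))
  ## bottom wall: clip at y = radius, keep the tangential component
  ## (a ray-stop that also cancels the x motion deadlocks wall-resting
  ## agents that are squeezed diagonally downward)
  d$x <- (d$x + vx) %% width
  d$y <- pmax(d$y + vy, d$radius)
  out <- replaceAgentData(agents, d)
  list(agents = out, maxOverlap = max(pr$overlap))
}

tapplySum <- function(idx, val, n) {
  out <- numeric(n)
  s <- tapply(val, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

maxOverlapOf <- function(agents, width) {
  pr <- overlappingPairs(agents, width, tol = -Inf)
  if (!nrow(pr)) return(-Inf)
  max(pr$overlap)
}

#' Resolve all agent overlaps by iterated shoving
#'
#' Repeats \code{\link{shoveIteration}} until no pair has a positive
#' displacement distance (within \code{tol}) or the repetition cap is hit.
#' Non-convergence is reported in the return value, never raised.
#'
#' @param agents an \linkS4class{AgentSet}.
#' @param width periodic domain width (um).
#' @param maxIter repetition cap (default 10).
#' @param tol overlap below which a pair counts as resolved (um).
#' @return list(agents, iterations, converged).
#' @export
resolveCollisions <- function(agents, width, maxIter = 10, tol = 1e-6) {
  it <- 0L
  repeat {
    pr <- overlappingPairs(agents, width, tol = tol)
    if (!nrow(pr)) return(list(agents = agents, iterations = it,
                               converged = TRUE))
    if (it >= maxIter) return(list(agents = agents, iterations = it,
                                   converged = FALSE))
    agents <- shoveIteration(agents, width)$agents
    it <- it + 1L
  }
}

#' Move planktonic agents
#'
#' Each unattached agent advances \code{stepLength} um along its heading
#' (x wrapped periodically, stopped at the bottom wall), then the heading is
#' rotated by a normally distributed angle. An agent becomes attached — a
#' biofilm member, no longer moving on its own — on first contact with the
#' bottom wall or with any attached agent; attachment propagates through
#' contact chains within the call.
#'
#' @param agents an \linkS4class{AgentSet}.
#' @param width periodic domain width (um).
#' @param stepLength step (um), default 5.
#' @param rotationSd heading rotation standard deviation (degrees).
#' @return the updated \linkS4class{AgentSet}.
#' @export
planktonicMove <- function(agents, width, stepLength = 5, rotationSd = 30) {
  d <- agents@data
  mv <- which(!d$attached)
  if (length(mv)) {
    ny <- d$y[mv] + stepLength * d$diry[mv]
    ## stop at the bottom wall (they attach there)
    ny <- pmax(ny, d$radius[mv])
    d$x[mv] <- (d$x[mv] + stepLength * d$dirx[mv]) %% width
    d$y[mv] <- ny
    rot <- stats::rnorm(length(mv), 0, rotationSd) * pi / 180
    ang <- atan2(d$diry[mv], d$dirx[mv]) + rot
    d$dirx[mv] <- cos(ang); d$diry[mv] <- sin(ang)
  }
  agents <- replaceAgentData(agents, d)
  updateAttachment(agents, width)
}

## attachment fixpoint: contact with the wall or an attached agent attaches;
## newly attached agents can attach their own contacts
updateAttachment <- function(agents, width, contactTol = 1e-9) {
  d <- agents@data
  if (!nrow(d)) return(agents)
  touchWall <- d$y <= d$radius + contactTol
  d$attached <- d$attached | touchWall
  if (any(d$attached) && any(!d$attached)) {
    pr <- overlappingPairs(agents, width, tol = -contactTol)
    repeat {
      newi <- pr$i[d$attached[pr$j] & !d$attached[pr$i]]
      newj <- pr$j[d$attached[pr$i] & !d$attached[pr$j]]
      if (!length(newi) && !length(newj)) break
      d$attached[c(newi, newj)] <- TRUE
    }
  }
  replaceAgentData(agents, d)
}

#' Grow agents exponentially
#'
#' Mass follows m(t + dt) = m(t) exp(mu dt); radii are recomputed from the
#' sphere mass-radius relation.
#'
#' @param agents an \linkS4class{AgentSet}.
#' @param mu growth rate(s) (1/h), one value or one per agent, >= 0.
#' @param dt timestep (h).
#' @return the grown \linkS4class{AgentSet}.
#' @export
grow <- function(agents, mu, dt) {
  if (any(mu < 0)) stop("growth rates must be nonnegative")
  d <- agents@data
  d$mass <- d$mass * exp(rep_len(mu, nrow(d)) * dt)
  d$radius <- massToRadius(d$mass, agents@cellDensity)
  replaceAgentData(agents, d)
}

#' Divide agents above the size threshold
#'
#' An agent whose size exceeds the threshold splits into two equally sized
#' offspring (half the parent mass each, conserving biomass), placed at the
#' parent's center plus and minus its child radius along a random unit
#' vector. Offspring inherit species and attachment; any created overlap is
#' removed by the next \code{\link{resolveCollisions}} call.
#'
#' @param agents an \linkS4class{AgentSet}.
#' @param threshold division threshold; by default a radius of 2 um.
#' @param on "radius" (um) or "mass" (pg).
#' @return the updated \linkS4class{AgentSet}.
#' @export
divideAgents <- function(agents, threshold = 2, on = c("radius", "mass")) {
  on <- match.arg(on)
  d <- agents@data
  size <- if (on == "radius") d$radius else d$mass
  split <- which(size > threshold)
  if (!length(split)) return(agents)
  par <- d[split, , drop = FALSE]
  cm <- par$mass / 2
  cr <- massToRadius(cm, agents@cellDensity)
  ang <- stats::runif(nrow(par), 0, 2 * pi)
  nextId <- max(d$id) + seq_len(2 * nrow(par))
  children <- function(sgn, ids) {
    kid <- par
    kid$id <- ids
    kid$mass <- cm
    kid$radius <- cr
    kid$x <- par$x + sgn * cr * cos(ang)
    kid$y <- pmax(par$y + sgn * cr * sin(ang), cr)
    ha <- stats::runif(nrow(par), 0, 2 * pi)
    kid$dirx <- cos(ha); kid$diry <- sin(ha)
    kid
  }
  d <- rbind(d[-split, , drop = FALSE],
             children(+1, nextId[seq_len(nrow(par))]),
             children(-1, nextId[nrow(par) + seq_len(nrow(par))]))
  rownames(d) <- NULL
  replaceAgentData(agents, d)
}

#' Remove agents sloughed above the maximum biofilm height
#'
#' Agents whose sphere lies entirely above the height limit
#' (y - radius > maxHeight) are removed, modelling shear loss to the lumen.
#'
#' @param agents an \linkS4class{AgentSet}.
#' @param maxHeight biofilm height limit (um), positive.
#' @return list(agents, removed): the surviving set and a named count of
#'   removed agents per species.
#' @export
sloughAgents <- function(agents, maxHeight) {
  stopifnot(maxHeight > 0)
  d <- agents@data
  gone <- d$y - d$radius > maxHeight
  removed <- if (any(gone)) table(d$species[gone]) else table(character())
  agents <- replaceAgentData(agents, d[!gone, , drop = FALSE])
  list(agents = agents, removed = removed)
}
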