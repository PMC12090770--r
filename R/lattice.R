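#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a lattice grid
#'
#' @param nx,ny cell counts along the periodic x axis and the vertical y axis.
#' @param cellSize lattice cell edge (um), default 10.
#' @return a \linkS4class{LatticeGrid} with an all-false biofilm mask.
#' @export
LatticeGrid <- function(nx, ny, cellSize = 10) {
  new("LatticeGrid", nx = as.integer(nx), ny = as.integer(ny),
      cellSize = as.numeric(cellSize),
      biofilmMask = matrix(FALSE, as.integer(nx), as.integer(ny)))
}

setMethod("show", "LatticeGrid", function(object) {
  cat("LatticeGrid: ", object@nx, " x ", object@ny, " cells of ",
      object@cellSize, " um (", object@nx * object@cellSize, " x ",
      object@ny * object@cellSize, " um); ", sum(object@biofilmMask),
      " biofilm cells\n", sep = "")
})

#' @param grid a \linkS4class{LatticeGrid}.
#' @rdname LatticeGrid
#' @export
gridWidth <- function(grid) grid@nx * grid@cellSize

#' @rdname LatticeGrid
#' @export
gridHeight <- function(grid) grid@ny * grid@cellSize

#' Construct a boundary specification
#'
#' @param top top-edge condition; only "dirichlet" is meaningful (fixed
#'   luminal concentration; 0 models outflow of secreted products).
#' @param topValue top Dirichlet value (mM).
#' @param bottom "neumann" (zero flux, the default for extracellular
#'   metabolites), "dirichlet" (e.g. mucosal oxygen supply) or "sink"
#'   (Robin-type host absorption with mass-transfer coefficient
#'   \code{bottomValue} in um/h).
#' @param bottomValue bottom value (mM for dirichlet, um/h for sink).
#' @return a \linkS4class{BoundarySpec}.
#' @export
boundarySpec <- function(top = "dirichlet", topValue = 0,
                         bottom = "neumann", bottomValue = 0) {
  new("BoundarySpec", top = top, topValue = as.numeric(topValue),
      bottom = bottom, bottomValue = as.numeric(bottomValue))
}

#' Construct a metabolite field
#'
#' @param metabolite environment metabolite id.
#' @param grid the \linkS4class{LatticeGrid}.
#' @param Dbulk bulk diffusion coefficient (um^2/h).
#' @param boundary a \linkS4class{BoundarySpec}.
#' @param biofilmFactor diffusivity multiplier inside biofilm (default 0.6).
#' @param S,R optional initial concentration (mM) and source (mM/h) matrices.
#' @return a \linkS4class{MetaboliteField}.
#' @export
metaboliteField <- function(metabolite, grid, Dbulk, boundary,
                            biofilmFactor = 0.6, S = NULL, R = NULL) {
  z <- matrix(0, grid@nx, grid@ny)
  new("MetaboliteField", metabolite = as.character(metabolite),
      S = if (is.null(S)) z else S, Dbulk = as.numeric(Dbulk),
      biofilmFactor = as.numeric(biofilmFactor),
      R = if (is.null(R)) z else R, boundary = boundary)
}

setMethod("show", "MetaboliteField", function(object) {
  cat("MetaboliteField '", object@metabolite, "': mean ",
      format(mean(object@S), digits = 6), " mM, D ", object@Dbulk,
      " um^2/h (x", object@biofilmFactor, " in biofilm)\n", sep = "")
})

## cell index of each agent; errors if any center is outside the domain
agentCells <- function(agents, grid) {
  d <- agents@data
  h <- grid@cellSize
  ix <- floor((d$x %% gridWidth(grid)) / h) + 1L
  iy <- floor(d$y / h) + 1L
  if (any(iy < 1L | iy > grid@ny))
    stop("agent center outside the lattice (y out of range)")
  cbind(ix = ix, iy = iy)
}

#' Rasterize agent biomass onto the lattice
#'
#' Each agent's dry biomass (wet mass times the dry-weight fraction) is
#' assigned to the lattice cell containing its center, per species. The
#' biofilm mask is the set of cells holding any attached biomass.
#'
#' @param agents an \linkS4class{AgentSet}.
#' @param grid a \linkS4class{LatticeGrid}.
#' @param dryWeightFraction gDW per g wet mass (default 0.3).
#' @return list with \code{biomass} (named list species -> nx x ny matrix of
#'   gDW) and \code{grid} (the grid with its biofilm mask refreshed).
#' @export
rasterize <- function(agents, grid, dryWeightFraction = 0.3) {
  d <- agents@data
  species <- sort(unique(d$species))
  out <- lapply(species, function(s) matrix(0, grid@nx, grid@ny))
  names(out) <- species
  mask <- matrix(FALSE, grid@nx, grid@ny)
  if (nrow(d)) {
    cells <- agentCells(agents, grid)
    gdw <- d$mass * 1e-12 * dryWeightFraction
    lin <- cells[, "ix"] + (cells[, "iy"] - 1L) * grid@nx
    for (s in species) {
      sel <- d$species == s
      m <- out[[s]]
      acc <- tapply(gdw[sel], lin[sel], sum)
      m[as.integer(names(acc))] <- acc
      out[[s]] <- m
    }
    att <- d$attached
    mask[unique(lin[att])] <- TRUE
  }
  grid@biofilmMask <- mask
  list(biomass = out, grid = grid)
}

#' Accumulate per-cell metabolite source terms from agent fluxes
#'
#' Converts per-agent exchange fluxes (mmol/gDW/h, negative = uptake) into
#' net volumetric source terms R (mM/h) per lattice cell: each agent
#' contributes flux x its dry biomass, divided by the cell volume.
#'
#' @param fluxTable data.frame(agent, metabolite, flux) of exchange fluxes
#'   on environment metabolites; \code{agent} matches agent ids.
#' @param agents the \linkS4class{AgentSet} the fluxes belong to.
#' @param grid a \linkS4class{LatticeGrid}.
#' @param dryWeightFraction gDW per g wet mass.
#' @param slabDepth out-of-plane cell depth (um) defining cell volume.
#' @return named list metabolite -> nx x ny matrix of R (mM/h).
#' @export
accumulateSources <- function(fluxTable, agents, grid,
                              dryWeightFraction = 0.3, slabDepth = 10) {
  cellVolL <- grid@cellSize^2 * slabDepth * 1e-15
  mets <- unique(fluxTable$metabolite)
  out <- lapply(mets, function(m) matrix(0, grid@nx, grid@ny))
  names(out) <- mets
  if (!nrow(fluxTable) || !nAgents(agents)) return(out)
  d <- agents@data
  cells <- agentCells(agents, grid)
  lin <- cells[, "ix"] + (cells[, "iy"] - 1L) * grid@nx
  names(lin) <- as.character(d$id)
  gdw <- d$mass * 1e-12 * dryWeightFraction
  names(gdw) <- as.character(d$id)
  key <- as.character(fluxTable$agent)
  contrib <- fluxTable$flux * gdw[key] / cellVolL
  cellOf <- lin[key]
  for (m in mets) {
    sel <- fluxTable$metabolite == m
    acc <- tapply(contrib[sel], cellOf[sel], sum)
    mm <- out[[m]]
    mm[as.integer(names(acc))] <- acc
    out[[m]] <- mm
  }
  out
}

#' Per-cell diffusivity map
#'
#' Bulk diffusivity everywhere, reduced by \code{biofilmFactor} (default
#' 0.6) inside biofilm cells. Face diffusivities used by the solver are
#' harmonic means of the two adjacent cells.
#'
#' @param grid a \linkS4class{LatticeGrid} (its biofilm mask is used).
#' @param Dbulk bulk diffusion coefficient (um^2/h).
#' @param biofilmFactor multiplier inside the biofilm.
#' @return nx x ny matrix of cell diffusivities.
#' @export
diffusionMap <- function(grid, Dbulk, biofilmFactor = 0.6) {
  D <- matrix(Dbulk, grid@nx, grid@ny)
  D[grid@biofilmMask] <- biofilmFactor * Dbulk
  D
}

harmonicMean <- function(a, b) 2 * a * b / (a + b)

## assemble the 5-point finite-volume system A S = b for one metabolite:
## sum_faces D_f (S_nb - S_c) / h^2 + boundary terms + R_c = 0
assembleSystem <- function(field, grid, Dmap) {
  nx <- grid@nx; ny <- grid@ny; h <- grid@cellSize
  N <- nx * ny
  bd <- field@boundary
  Dv <- as.vector(Dmap)
  i <- rep(seq_len(nx), ny)
  j <- rep(seq_len(ny), each = nx)
  c0 <- seq_len(N)
  b <- -as.vector(field@R)
  dg <- numeric(N)
  I <- J <- vector("list", 4); X <- vector("list", 4)

  ## x faces, periodic (nx == 1 sums the two self-entries with the diagonal,
  ## a net zero — consistent with a field flat in x)
  for (k in 1:2) {
    di <- c(-1L, 1L)[k]
    nb <- ((i - 1L + di) %% nx) + 1L + (j - 1L) * nx
    a <- harmonicMean(Dv[c0], Dv[nb]) / h^2
    I[[k]] <- c0; J[[k]] <- nb; X[[k]] <- a
    dg <- dg - a
  }
  ## south face (j > 1)
  has <- j > 1L
  nb <- c0[has] - nx
  a <- harmonicMean(Dv[c0[has]], Dv[nb]) / h^2
  I[[3]] <- c0[has]; J[[3]] <- nb; X[[3]] <- a
  dg[has] <- dg[has] - a
  ## north face (j < ny)
  has <- j < ny
  nb <- c0[has] + nx
  a <- harmonicMean(Dv[c0[has]], Dv[nb]) / h^2
  I[[4]] <- c0[has]; J[[4]] <- nb; X[[4]] <- a
  dg[has] <- dg[has] - a
  ## top boundary: Dirichlet through a half-cell
  topc <- c0[j == ny]
  aT <- 2 * Dv[topc] / h^2
  dg[topc] <- dg[topc] - aT
  b[topc] <- b[topc] - aT * bd@topValue
  ## bottom boundary
  botc <- c0[j == 1L]
  if (bd@bottom == "dirichlet") {
    aB <- 2 * Dv[botc] / h^2
    dg[botc] <- dg[botc] - aB
    b[botc] <- b[botc] - aB * bd@bottomValue
  } else if (bd@bottom == "sink") {
    dg[botc] <- dg[botc] - bd@bottomValue / h
  } # neumann: no term

  A <- Matrix::sparseMatrix(i = c(unlist(I), c0), j = c(unlist(J), c0),
                            x = c(unlist(X), dg), dims = c(N, N))
  list(A = A, b = b)
}

#' Solve a metabolite field to diffusive steady state
#'
#' Solves the discrete reaction-diffusion balance div(D grad S) + R = 0 on
#' the lattice (5-point finite-volume stencil, harmonic-mean face
#' diffusivities, periodic in x) with the field's boundary conditions, via a
#' sparse direct solve. Negative concentrations (possible when sinks exceed
#' diffusive supply) are clamped at zero and counted.
#'
#' @param field a \linkS4class{MetaboliteField} with its source matrix set.
#' @param grid a \linkS4class{LatticeGrid}.
#' @param Dmap optional per-cell diffusivity (defaults to
#'   \code{\link{diffusionMap}} of the field's parameters).
#' @return list(field, clamped): the field with \code{S} updated, and the
#'   number of cells clamped at zero.
#' @export
solveSteadyState <- function(field, grid,
                             Dmap = diffusionMap(grid, field@Dbulk,
                                                 field@biofilmFactor)) {
  sys <- assembleSystem(field, grid, Dmap)
  S <- tryCatch(as.numeric(Matrix::solve(sys$A, sys$b)),
                error = function(e)
                  stop("steady-state system for metabolite '",
                       field@metabolite, "' could not be solved: ",
                       conditionMessage(e)))
  clamped <- sum(S < 0)
  S[S < 0] <- 0
  field@S <- matrix(S, grid@nx, grid@ny)
  list(field = field, clamped = clamped)
}

#' Discrete flux balance of a solved field
#'
#' Returns the net boundary influx and the integrated source of a solved
#' steady-state field; their sum closes to zero (up to solver tolerance)
#' whenever no clamping occurred — the discrete conservation property of the
#' finite-volume scheme.
#'
#' @param field a solved \linkS4class{MetaboliteField}.
#' @param grid the \linkS4class{LatticeGrid} it was solved on.
#' @param Dmap optional per-cell diffusivity map.
#' @return list(boundaryIn, sourceIn, residual) in mM um^2/h per unit depth.
#' @export
fluxBalance <- function(field, grid,
                        Dmap = diffusionMap(grid, field@Dbulk,
                                            field@biofilmFactor)) {
  h <- grid@cellSize; nx <- grid@nx; ny <- grid@ny
  S <- field@S; bd <- field@boundary
  cellArea <- h^2
  top <- sum(2 * Dmap[, ny] / h^2 * (bd@topValue - S[, ny])) * cellArea
  bottom <- 0
  if (bd@bottom == "dirichlet")
    bottom <- sum(2 * Dmap[, 1] / h^2 * (bd@bottomValue - S[, 1])) * cellArea
  else if (bd@bottom == "sink")
    bottom <- sum(-bd@bottomValue / h * S[, 1]) * cellArea
  sourceIn <- sum(field@R) * cellArea
  list(boundaryIn = top + bottom, sourceIn = sourceIn,
       residual = top + bottom + sourceIn)
}
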