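#' @import methods
#' @importFrom Matrix sparseMatrix Matrix
NULL

## ---------------------------------------------------------------------------
## Metabolic layer
## ---------------------------------------------------------------------------

#' GEMModel: a constraint-based metabolic model
#'
#' A stoichiometric model of one species: metabolites, reactions with flux
#' bounds (mmol/gDW/h; the biomass reaction in 1/h), a designated biomass
#' objective, and a map from exchange reactions to the environment metabolites
#' they move. Exchange flux follows the community sign convention:
#' negative = uptake, positive = secretion.
#'
#' @slot speciesId single species identifier.
#' @slot mets character vector of metabolite ids.
#' @slot rxns character vector of reaction ids.
#' @slot S stoichiometric matrix (metabolites x reactions), sparse.
#' @slot lb,ub numeric flux bounds, one per reaction.
#' @slot objectiveId id of the biomass reaction.
#' @slot exchangeMap named character: exchange reaction id -> environment
#'   metabolite id.
#' @slot gpr named character of optional gene-protein-reaction strings.
#' @exportClass GEMModel
setClass("GEMModel",
  representation(speciesId = "character", mets = "character",
                 rxns = "character", S = "Matrix",
                 lb = "numeric", ub = "numeric",
                 objectiveId = "character", exchangeMap = "character",
                 gpr = "character"))

setValidity("GEMModel", function(object) {
  msg <- character()
  if (length(object@speciesId) != 1L) msg <- c(msg, "speciesId must be length 1")
  if (nrow(object@S) != length(object@mets) ||
      ncol(object@S) != length(object@rxns))
    msg <- c(msg, "S dimensions must match metabolites x reactions")
  if (anyDuplicated(object@rxns)) msg <- c(msg, "duplicated reaction ids")
  if (anyDuplicated(object@mets)) msg <- c(msg, "duplicated metabolite ids")
  if (length(object@lb) != length(object@rxns) ||
      length(object@ub) != length(object@rxns))
    msg <- c(msg, "bounds must have one entry per reaction")
  else if (any(object@lb > object@ub))
    msg <- c(msg, sprintf("lower bound exceeds upper bound for: %s",
                          paste(object@rxns[object@lb > object@ub],
                                collapse = ", ")))
  if (!(object@objectiveId %in% object@rxns))
    msg <- c(msg, sprintf("objective reaction '%s' is not a declared reaction",
                          object@objectiveId))
  if (length(object@exchangeMap)) {
    bad <- setdiff(names(object@exchangeMap), object@rxns)
    if (length(bad))
      msg <- c(msg, sprintf("exchangeMap keys are not declared reactions: %s",
                            paste(bad, collapse = ", ")))
    ok <- intersect(names(object@exchangeMap), object@rxns)
    nmet <- vapply(ok, function(r)
      sum(object@S[, match(r, object@rxns)] != 0), integer(1))
    if (any(nmet != 1L))
      msg <- c(msg, sprintf(
        "exchange reactions must touch exactly one metabolite: %s",
        paste(ok[nmet != 1L], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' FluxResult: one LP solution over a GEMModel
#'
#' @slot fluxes named numeric flux vector (mmol/gDW/h).
#' @slot growthRate objective value (1/h); equals the biomass flux.
#' @slot status "optimal" or "infeasible".
#' @exportClass FluxResult
setClass("FluxResult",
  representation(fluxes = "numeric", growthRate = "numeric",
                 status = "character"))

setValidity("FluxResult", function(object) {
  if (!object@status %in% c("optimal", "infeasible"))
    return("status must be 'optimal' or 'infeasible'")
  TRUE
})

#' FVAResult: flux variability intervals
#'
#' @slot intervals numeric matrix (reactions x 2, columns "min"/"max").
#' @slot fraction fraction of the FBA optimum the objective was held at.
#' @exportClass FVAResult
setClass("FVAResult",
  representation(intervals = "matrix", fraction = "numeric"))

setValidity("FVAResult", function(object) {
  if (ncol(object@intervals) != 2L)
    return("intervals must have two columns (min, max)")
  if (any(object@intervals[, 1] > object@intervals[, 2] + 1e-6,
          na.rm = TRUE))
    return("interval minimum exceeds maximum")
  if (length(object@fraction) != 1L || object@fraction <= 0 ||
      object@fraction > 1)
    return("fraction must be a single value in (0, 1]")
  TRUE
})

#' UptakeKinetics: Michaelis-Menten uptake parameters
#'
#' Per (species, metabolite) pair: the saturating uptake rate \code{vmax}
#' (mmol/gDW/h, nonnegative; 0 forbids uptake) and the half-saturation
#' constant \code{km} (mM).
#'
#' @slot table data.frame with columns species, metabolite, vmax, km.
#' @exportClass UptakeKinetics
setClass("UptakeKinetics", representation(table = "data.frame"))

setValidity("UptakeKinetics", function(object) {
  tb <- object@table
  need <- c("species", "metabolite", "vmax", "km")
  if (!all(need %in% names(tb)))
    return(paste("kinetics table needs columns:", paste(need, collapse = ", ")))
  if (nrow(tb) && any(tb$vmax < 0)) return("vmax must be nonnegative")
  if (nrow(tb) && any(tb$km <= 0)) return("km must be positive")
  if (anyDuplicated(tb[c("species", "metabolite")]))
    return("duplicate (species, metabolite) kinetics entries")
  TRUE
})

## ---------------------------------------------------------------------------
## Agent layer
## ---------------------------------------------------------------------------

#' AgentSet: a population of spherical bacterial agents
#'
#' Column-oriented container for discrete agents: position (um), wet mass
#' (pg), radius (um, tied to mass through the configured cell mass density),
#' a planktonic heading, and an attachment flag (biofilm membership).
#'
#' @slot data data.frame with columns id, species, x, y, mass, radius,
#'   dirx, diry, attached.
#' @slot cellDensity cell wet-mass density rho (pg/um^3) used by the
#'   mass-radius invariant radius = (3 mass / (4 pi rho))^(1/3).
#' @exportClass AgentSet
setClass("AgentSet",
  representation(data = "data.frame", cellDensity = "numeric"))

setValidity("AgentSet", function(object) {
  d <- object@data
  need <- c("id", "species", "x", "y", "mass", "radius", "dirx", "diry",
            "attached")
  if (!all(need %in% names(d)))
    return(paste("agent data needs columns:", paste(need, collapse = ", ")))
  if (length(object@cellDensity) != 1L || object@cellDensity <= 0)
    return("cellDensity must be a single positive value")
  if (nrow(d)) {
    if (any(d$mass <= 0)) return("agent mass must be positive")
    if (any(d$radius <= 0)) return("agent radius must be positive")
    r <- massToRadius(d$mass, object@cellDensity)
    if (any(abs(d$radius - r) > 1e-8 * pmax(1, r)))
      return("radius inconsistent with mass and cell density")
    if (any(d$y < 0)) return("agent centers must satisfy y >= 0")
    if (anyDuplicated(d$id)) return("duplicated agent ids")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Environment layer
## ---------------------------------------------------------------------------

#' LatticeGrid: the 2D finite-volume discretization
#'
#' @slot nx,ny cell counts along x (periodic) and y (bottom wall at y = 0).
#' @slot cellSize lattice cell edge (um), 10 by default.
#' @slot biofilmMask logical nx x ny matrix: cells holding attached biomass.
#' @exportClass LatticeGrid
setClass("LatticeGrid",
  representation(nx = "integer", ny = "integer", cellSize = "numeric",
                 biofilmMask = "matrix"))

setValidity("LatticeGrid", function(object) {
  if (object@nx < 1L || object@ny < 1L) return("nx and ny must be >= 1")
  if (object@cellSize <= 0) return("cellSize must be positive")
  if (!identical(dim(object@biofilmMask), c(object@nx, object@ny)))
    return("biofilmMask must be nx x ny")
  TRUE
})

#' BoundarySpec: per-metabolite boundary conditions
#'
#' Sides are always periodic. The top edge is Dirichlet (a fixed luminal
#' concentration; 0 models product outflow into the lumen). The bottom edge
#' is one of zero-flux Neumann, Dirichlet (e.g. oxygen supplied by the
#' mucosa), or a Robin-type absorptive sink with mass-transfer coefficient
#' \code{bottomValue} (um/h), modelling host uptake of SCFAs.
#'
#' @slot top,bottom type strings; top in "dirichlet", bottom in
#'   c("neumann", "dirichlet", "sink").
#' @slot topValue,bottomValue boundary value (mM for Dirichlet, um/h for
#'   the sink rate, ignored for Neumann).
#' @exportClass BoundarySpec
setClass("BoundarySpec",
  representation(top = "character", topValue = "numeric",
                 bottom = "character", bottomValue = "numeric"))

setValidity("BoundarySpec", function(object) {
  if (!identical(object@top, "dirichlet"))
    return("top boundary must be 'dirichlet' (use value 0 for outflow)")
  if (!object@bottom %in% c("neumann", "dirichlet", "sink"))
    return("bottom boundary must be 'neumann', 'dirichlet' or 'sink'")
  if (object@bottom == "sink" && object@bottomValue < 0)
    return("sink rate must be nonnegative")
  TRUE
})

#' MetaboliteField: one metabolite's concentration field
#'
#' @slot metabolite environment metabolite id.
#' @slot S concentration per cell (mM), nx x ny.
#' @slot Dbulk bulk diffusion coefficient (um^2/h).
#' @slot biofilmFactor diffusivity multiplier inside biofilm (default 0.6).
#' @slot R net volumetric source per cell (mM/h).
#' @slot boundary a \linkS4class{BoundarySpec}.
#' @exportClass MetaboliteField
setClass("MetaboliteField",
  representation(metabolite = "character", S = "matrix", Dbulk = "numeric",
                 biofilmFactor = "numeric", R = "matrix",
                 boundary = "BoundarySpec"))

setValidity("MetaboliteField", function(object) {
  if (object@Dbulk <= 0) return("Dbulk must be positive")
  if (object@biofilmFactor <= 0 || object@biofilmFactor > 1)
    return("biofilmFactor must be in (0, 1]")
  if (!identical(dim(object@S), dim(object@R)))
    return("S and R must have the same dimensions")
  TRUE
})

## ---------------------------------------------------------------------------
## Orchestration
## ---------------------------------------------------------------------------

#' SpeciesSpec: per-species parameter bundle
#'
#' @slot speciesId species identifier, must match the model's.
#' @slot model the species' \linkS4class{GEMModel}.
#' @slot initialCount agents seeded at t = 0.
#' @slot initialMass wet mass (pg) of seeded agents.
#' @slot color plotting color.
#' @exportClass SpeciesSpec
setClass("SpeciesSpec",
  representation(speciesId = "character", model = "GEMModel",
                 initialCount = "integer", initialMass = "numeric",
                 color = "character"))

setValidity("SpeciesSpec", function(object) {
  if (!identical(object@speciesId, object@model@speciesId))
    return("speciesId must match the model's speciesId")
  if (object@initialCount < 0L) return("initialCount must be >= 0")
  if (object@initialMass <= 0) return("initialMass must be positive")
  TRUE
})

#' SimulationConfig: a complete scenario description
#'
#' All tunables of one simulation: domain geometry, species and their
#' metabolic models, tracked metabolites with diffusion and boundary
#' specifications, Michaelis-Menten uptake kinetics, agent mechanics
#' parameters, time stepping, and the steady-state stopping rule.
#'
#' @slot nx,ny lattice cell counts; \code{cellSize} um per cell.
#' @slot cellSize lattice resolution (um), default 10.
#' @slot maxHeight biofilm sloughing height (um).
#' @slot slabDepth out-of-plane depth (um) giving lattice cells a volume.
#' @slot dryWeightFraction gDW per g wet mass.
#' @slot cellDensity agent wet density (pg/um^3).
#' @slot species list of \linkS4class{SpeciesSpec}.
#' @slot metabolites named list; each element a list with Dbulk (um^2/h),
#'   boundary (\linkS4class{BoundarySpec}) and optional biofilmFactor.
#' @slot kinetics an \linkS4class{UptakeKinetics}.
#' @slot stepLength planktonic step (um), default 5.
#' @slot rotationSd planktonic heading rotation SD (degrees).
#' @slot divisionThreshold size threshold triggering division.
#' @slot divisionOn "radius" (um, default) or "mass" (pg).
#' @slot dt timestep (h); \code{maxSteps} step cap.
#' @slot maxSteps maximum number of timesteps.
#' @slot steadyTol,steadyWindow steady-state detection: max relative change
#'   of species biomass and metabolite means over the window.
#' @slot seed RNG seed.
#' @slot outputInterval snapshot cadence (steps).
#' @slot shoveMaxIter shoving repetition cap per phase (default 10).
#' @slot fvaFraction default suboptimal-FVA fraction.
#' @slot planktonicFBA whether unattached agents also feed (default TRUE).
#' @slot sourceIterations fixed-point couplings of fluxes and fields per
#'   step (1 = fluxes held fixed; >1 re-solves uptake on updated fields).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nx = "integer", ny = "integer", cellSize = "numeric",
                 maxHeight = "numeric", slabDepth = "numeric",
                 dryWeightFraction = "numeric", cellDensity = "numeric",
                 species = "list", metabolites = "list",
                 kinetics = "UptakeKinetics",
                 stepLength = "numeric", rotationSd = "numeric",
                 divisionThreshold = "numeric", divisionOn = "character",
                 dt = "numeric", maxSteps = "integer",
                 steadyTol = "numeric", steadyWindow = "integer",
                 seed = "integer", outputInterval = "integer",
                 shoveMaxIter = "integer", fvaFraction = "numeric",
                 planktonicFBA = "logical", sourceIterations = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (!length(object@species)) msg <- c(msg, "at least one species required")
  if (!all(vapply(object@species, is, logical(1), "SpeciesSpec")))
    msg <- c(msg, "species must be a list of SpeciesSpec")
  if (!length(object@metabolites))
    msg <- c(msg, "at least one tracked metabolite required")
  for (nm in names(object@metabolites)) {
    m <- object@metabolites[[nm]]
    if (!is.list(m) || is.null(m$Dbulk) || is.null(m$boundary))
      msg <- c(msg, sprintf("metabolite '%s' needs Dbulk and boundary", nm))
    else if (!is(m$boundary, "BoundarySpec"))
      msg <- c(msg, sprintf("metabolite '%s' boundary must be a BoundarySpec", nm))
  }
  if (object@maxHeight <= 0) msg <- c(msg, "maxHeight must be positive")
  if (!object@divisionOn %in% c("radius", "mass"))
    msg <- c(msg, "divisionOn must be 'radius' or 'mass'")
  if (object@steadyWindow < 2L) msg <- c(msg, "steadyWindow must be >= 2")
  if (length(msg)) msg else TRUE
})

#' SimulationState: the full mutable world at one timestep
#'
#' @slot timestep current step index (0 after seeding).
#' @slot agents the \linkS4class{AgentSet}.
#' @slot grid the \linkS4class{LatticeGrid} (carries the biofilm mask).
#' @slot fields named list of \linkS4class{MetaboliteField}.
#' @slot abundance matrix (timestep+1 rows x species): total wet biomass (pg).
#' @slot meanConc matrix (timestep+1 rows x metabolites): domain means (mM).
#' @slot agentFlux data.frame of the last step's per-agent exchange fluxes
#'   (agent, species, metabolite, flux) on environment metabolites.
#' @slot agentGrowth named numeric: last per-agent growth rates (1/h).
#' @slot log list of counters (clamped cells, LP infeasibilities, sloughed).
#' @exportClass SimulationState
setClass("SimulationState",
  representation(timestep = "integer", agents = "AgentSet",
                 grid = "LatticeGrid", fields = "list",
                 abundance = "matrix", meanConc = "matrix",
                 agentFlux = "data.frame", agentGrowth = "numeric",
                 log = "list"))

setValidity("SimulationState", function(object) {
  if (nrow(object@abundance) != object@timestep + 1L)
    return("abundance series length must equal timestep + 1")
  if (nrow(object@meanConc) != object@timestep + 1L)
    return("meanConc series length must equal timestep + 1")
  TRUE
})

## ---------------------------------------------------------------------------
## Analysis
## ---------------------------------------------------------------------------

#' CrossFeedingGraph: species + environment exchange digraph
#'
#' @slot edges data.frame(from, to, metabolite, weight): mean exchange flux
#'   magnitudes routed producer -> consumer, with net surplus or deficit
#'   routed to or from the "environment" node.
#' @slot nodes character: species ids plus "environment".
#' @exportClass CrossFeedingGraph
setClass("CrossFeedingGraph",
  representation(edges = "data.frame", nodes = "character"))

setValidity("CrossFeedingGraph", function(object) {
  e <- object@edges
  need <- c("from", "to", "metabolite", "weight")
  if (!all(need %in% names(e)))
    return(paste("edges needs columns:", paste(need, collapse = ", ")))
  if (nrow(e) && any(e$weight <= 0)) return("edge weights must be positive")
  if (!"environment" %in% object@nodes)
    return("nodes must include 'environment'")
  TRUE
})

#' ShiftTable: per-reaction FVA range-shift statistics
#'
#' @slot table data.frame(reaction, minLB, maxUB, shift, significant,
#'   reportable, gpr).
#' @slot percentile the significance quantile level (default 0.95).
#' @slot reportThreshold absolute shift (mmol/gDW/h) above which a reaction
#'   is listed in reports (default 2).
#' @exportClass ShiftTable
setClass("ShiftTable",
  representation(table = "data.frame", percentile = "numeric",
                 reportThreshold = "numeric"))

setValidity("ShiftTable", function(object) {
  tb <- object@table
  need <- c("reaction", "minLB", "maxUB", "shift", "significant")
  if (!all(need %in% names(tb)))
    return(paste("table needs columns:", paste(need, collapse = ", ")))
  if (nrow(tb) && any(tb$minLB > tb$maxUB + 1e-9))
    return("minLB must not exceed maxUB")
  TRUE
})
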