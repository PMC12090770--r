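#' @include AllClasses.R AllGenerics.R
NULL

scenarioDefaults <- function() {
  path <- system.file("extdata", "scenario-defaults.yaml", package = "mucosim")
  yaml::read_yaml(path)
}

#' Construct a per-species specification
#'
#' @param model the species' \linkS4class{GEMModel}.
#' @param initialCount agents seeded at t = 0.
#' @param initialMass seed wet mass (pg).
#' @param color plotting color.
#' @return a \linkS4class{SpeciesSpec}.
#' @export
speciesSpec <- function(model, initialCount = 10, initialMass = 15,
                        color = "grey40") {
  new("SpeciesSpec", speciesId = model@speciesId, model = model,
      initialCount = as.integer(initialCount),
      initialMass = as.numeric(initialMass), color = color)
}

setMethod("show", "SpeciesSpec", function(object) {
  cat("SpeciesSpec '", object@speciesId, "': ", object@initialCount,
      " seed agents of ", object@initialMass, " pg\n", sep = "")
})

#' Construct a simulation configuration
#'
#' Assembles a complete scenario. Every argument left NULL takes the package
#' default recorded in \code{inst/extdata/scenario-defaults.yaml} (the single
#' source of defaults).
#'
#' @param nx,ny lattice cell counts.
#' @param maxHeight biofilm sloughing height (um); must leave headroom below
#'   the domain top (\code{ny * cellSize}) for planktonic agents.
#' @param species list of \linkS4class{SpeciesSpec}.
#' @param metabolites named list: each entry a list with \code{Dbulk}
#'   (um^2/h), \code{boundary} (a \linkS4class{BoundarySpec}) and optional
#'   \code{biofilmFactor}.
#' @param kinetics an \linkS4class{UptakeKinetics}.
#' @param cellSize,slabDepth,dryWeightFraction,cellDensity,stepLength
#'   see \linkS4class{SimulationConfig}.
#' @param rotationSd,divisionThreshold,divisionOn,dt,maxSteps,steadyTol
#'   see \linkS4class{SimulationConfig}.
#' @param steadyWindow,seed,outputInterval,shoveMaxIter,fvaFraction
#'   see \linkS4class{SimulationConfig}.
#' @param planktonicFBA,sourceIterations see \linkS4class{SimulationConfig}.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nx, ny, maxHeight, species, metabolites,
                             kinetics = uptakeKinetics(),
                             cellSize = NULL, slabDepth = NULL,
                             dryWeightFraction = NULL, cellDensity = NULL,
                             stepLength = NULL, rotationSd = NULL,
                             divisionThreshold = NULL, divisionOn = NULL,
                             dt = NULL, maxSteps = NULL, steadyTol = NULL,
                             steadyWindow = NULL, seed = NULL,
                             outputInterval = NULL, shoveMaxIter = NULL,
                             fvaFraction = NULL, planktonicFBA = NULL,
                             sourceIterations = NULL) {
  def <- scenarioDefaults()
  pick <- function(x, name) if (is.null(x)) def[[name]] else x
  for (nm in names(metabolites)) {
    if (is.null(metabolites[[nm]]$biofilmFactor))
      metabolites[[nm]]$biofilmFactor <- def$biofilmFactor
  }
  new("SimulationConfig",
      nx = as.integer(nx), ny = as.integer(ny),
      cellSize = as.numeric(pick(cellSize, "cellSize")),
      maxHeight = as.numeric(maxHeight),
      slabDepth = as.numeric(pick(slabDepth, "slabDepth")),
      dryWeightFraction = as.numeric(pick(dryWeightFraction,
                                          "dryWeightFraction")),
      cellDensity = as.numeric(pick(cellDensity, "cellDensity")),
      species = species, metabolites = metabolites, kinetics = kinetics,
      stepLength = as.numeric(pick(stepLength, "stepLength")),
      rotationSd = as.numeric(pick(rotationSd, "rotationSd")),
      divisionThreshold = as.numeric(pick(divisionThreshold,
                                          "divisionThreshold")),
      divisionOn = as.character(pick(divisionOn, "divisionOn")),
      dt = as.numeric(pick(dt, "dt")),
      maxSteps = as.integer(pick(maxSteps, "maxSteps")),
      steadyTol = as.numeric(pick(steadyTol, "steadyTol")),
      steadyWindow = as.integer(pick(steadyWindow, "steadyWindow")),
      seed = as.integer(pick(seed, "seed")),
      outputInterval = as.integer(pick(outputInterval, "outputInterval")),
      shoveMaxIter = as.integer(pick(shoveMaxIter, "shoveMaxIter")),
      fvaFraction = as.numeric(pick(fvaFraction, "fvaFraction")),
      planktonicFBA = as.logical(pick(planktonicFBA, "planktonicFBA")),
      sourceIterations = as.integer(pick(sourceIterations,
                                         "sourceIterations")))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@nx, "x", object@ny, " cells (",
      object@cellSize, " um), ", length(object@species), " species, ",
      length(object@metabolites), " metabolites, dt ", object@dt,
      " h, up to ", object@maxSteps, " steps\n", sep = "")
})

configSpeciesIds <- function(config)
  vapply(config@species, function(s) s@speciesId, character(1))
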