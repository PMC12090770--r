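#' @include AllClasses.R AllGenerics.R config.R
NULL

#' Accessors for SimulationState
#'
#' @param x a \linkS4class{SimulationState}.
#' @name state-accessors
#' @aliases abundanceSeries concentrationSeries
NULL

#' @rdname state-accessors
setMethod("abundanceSeries", "SimulationState", function(x) x@abundance)
#' @rdname state-accessors
setMethod("concentrationSeries", "SimulationState", function(x) x@meanConc)

setMethod("show", "SimulationState", function(object) {
  cat("SimulationState at step ", object@timestep, ": ",
      nAgents(object@agents), " agents, ", length(object@fields),
      " metabolite fields\n", sep = "")
})

emptyFluxTable <- function() {
  data.frame(agent = integer(), species = character(),
             metabolite = character(), flux = numeric())
}

#' Seed the initial simulation state
#'
#' Places each species' configured number of agents uniformly at random in
#' the domain (unattached, random headings), resolves any seeding overlaps
#' with one collision-resolution pass, and solves every metabolite field
#' once with zero sources (the boundary-driven profile).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param setSeed seed the RNG from \code{config@seed} first (default TRUE).
#' @return a \linkS4class{SimulationState} at timestep 0.
#' @export
seedInitial <- function(config, setSeed = TRUE) {
  if (setSeed) set.seed(config@seed)
  validObject(config)
  grid <- LatticeGrid(config@nx, config@ny, config@cellSize)
  W <- gridWidth(grid)
  sp <- configSpeciesIds(config)
  counts <- vapply(config@species, function(s) s@initialCount, integer(1))
  masses <- vapply(config@species, function(s) s@initialMass, numeric(1))
  n <- sum(counts)
  rmax <- massToRadius(max(masses), config@cellDensity)
  if (n * pi * rmax^2 > 0.7 * W * config@maxHeight)
    stop("requested seeding density exceeds close packing")
  agents <- newAgents(species = rep(sp, counts),
                      x = stats::runif(n, 0, W),
                      y = stats::runif(n, rmax,
                                       max(config@maxHeight, 2 * rmax)),
                      mass = rep(masses, counts),
                      cellDensity = config@cellDensity)
  if (n > 0) agents <- resolveCollisions(agents, W, config@shoveMaxIter)$agents
  fields <- list()
  clamped <- 0L
  for (nm in names(config@metabolites)) {
    m <- config@metabolites[[nm]]
    f <- metaboliteField(nm, grid, m$Dbulk, m$boundary, m$biofilmFactor)
    sol <- solveSteadyState(f, grid)
    fields[[nm]] <- sol$field
    clamped <- clamped + sol$clamped
  }
  abundance <- matrix(vapply(sp, function(s)
    sum(agents@data$mass[agents@data$species == s]), numeric(1)),
    nrow = 1, dimnames = list(NULL, sp))
  meanConc <- matrix(vapply(fields, function(f) mean(f@S), numeric(1)),
                     nrow = 1, dimnames = list(NULL, names(fields)))
  new("SimulationState", timestep = 0L, agents = agents, grid = grid,
      fields = fields, abundance = abundance, meanConc = meanConc,
      agentFlux = emptyFluxTable(), agentGrowth = numeric(),
      log = list(clamped = clamped, infeasible = 0L, sloughed = 0,
                 shoveIterations = integer()))
}

## per-(species, cell) metabolic solve with caching; returns per-agent growth
## rates, the per-agent exchange-flux table, and an infeasibility count
solveMetabolism <- function(agents, fields, config, grid) {
  d <- agents@data
  sp <- configSpeciesIds(config)
  models <- lapply(config@species, function(s) s@model)
  names(models) <- sp
  mu <- numeric(nrow(d))
  names(mu) <- as.character(d$id)
  fluxTab <- emptyFluxTable()
  infeasible <- 0L
  if (!nrow(d)) return(list(mu = mu, fluxTable = fluxTab, infeasible = 0L))
  cells <- agentCells(agents, grid)
  lin <- cells[, "ix"] + (cells[, "iy"] - 1L) * grid@nx
  feed <- if (config@planktonicFBA) rep(TRUE, nrow(d)) else d$attached
  key <- paste(d$species, lin)
  rows <- list()
  for (grp in unique(key[feed])) {
    idx <- which(key == grp & feed)
    s <- d$species[idx[1]]
    cell <- lin[idx[1]]
    localConcs <- vapply(fields, function(f) f@S[cell], numeric(1))
    m <- constrainUptake(models[[s]], localConcs, config@kinetics)
    sol <- pfba(m)
    if (sol@status != "optimal") {
      infeasible <- infeasible + length(idx)
      next  # growth 0, zero exchange fluxes; the agent persists
    }
    g <- max(sol@growthRate, 0)
    mu[idx] <- g
    ex <- exchangeFluxes(m, sol)
    ex <- ex[ex != 0]
    if (length(ex))
      rows[[grp]] <- data.frame(agent = rep(d$id[idx], each = length(ex)),
                                species = s,
                                metabolite = rep(names(ex), length(idx)),
                                flux = rep(unname(ex), length(idx)))
  }
  if (length(rows)) fluxTab <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(mu = mu, fluxTable = fluxTab, infeasible = infeasible)
}

## cap each cell's consumption at the mass available over one timestep:
## scales whole-cell flux solutions (and growth rates) by a common factor so
## stoichiometry stays consistent; returns the scaled pieces
capConsumption <- function(R, fluxTable, mu, agents, fields, grid, dt) {
  if (!length(R) || !nrow(fluxTable))
    return(list(R = R, fluxTable = fluxTable, mu = mu))
  factor <- matrix(1, grid@nx, grid@ny)
  for (m in names(R)) {
    cons <- -pmin(R[[m]], 0)
    avail <- fields[[m]]@S / dt
    f <- ifelse(cons > 0, pmin(1, avail / cons), 1)
    factor <- pmin(factor, f)
  }
  if (all(factor >= 1)) return(list(R = R, fluxTable = fluxTable, mu = mu))
  for (m in names(R)) R[[m]] <- R[[m]] * factor
  cells <- agentCells(agents, grid)
  lin <- cells[, "ix"] + (cells[, "iy"] - 1L) * grid@nx
  names(lin) <- as.character(agents@data$id)
  fac <- factor[lin[as.character(fluxTable$agent)]]
  fluxTable$flux <- fluxTable$flux * fac
  mu <- mu * as.vector(factor[lin[names(mu)]])
  list(R = R, fluxTable = fluxTable, mu = mu)
}

#' Advance the simulation by one timestep
#'
#' Executes the three sequential phases: (1) movement — planktonic agents
#' step and turn, collisions are resolved; (2) solute equilibrium — biomass
#' is rasterized, each agent's uptake bounds are constrained by its cell's
#' concentrations, parsimonious FBA yields growth rates and exchange fluxes,
#' sources are accumulated (capped at the mass available per step) and every
#' metabolite field is re-solved to steady state; (3) growth and division —
#' agents grow exponentially at their own rates, divide above the size
#' threshold, collisions are resolved again, and agents above the maximum
#' biofilm height are sloughed.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param config the \linkS4class{SimulationConfig}.
#' @param hooks optional function(phase, state) called before each phase
#'   with phase in c("movement", "solute", "growth") — instrumentation only.
#' @return the advanced \linkS4class{SimulationState}.
#' @export
simStep <- function(state, config, hooks = NULL) {
  agents <- state@agents
  grid <- state@grid
  W <- gridWidth(grid)
  log <- state@log

  ## -- phase 1: movement ----------------------------------------------------
  if (!is.null(hooks)) hooks("movement", state)
  phase <- "movement"
  res <- tryCatch({
    agents <- planktonicMove(agents, W, config@stepLength, config@rotationSd)
    rc <- resolveCollisions(agents, W, config@shoveMaxIter)
    log$shoveIterations <- c(log$shoveIterations, rc$iterations)
    rc$agents
  }, error = function(e) stop("[", phase, " phase] ", conditionMessage(e)))
  agents <- res

  ## -- phase 2: solute equilibrium ------------------------------------------
  if (!is.null(hooks)) hooks("solute", state)
  phase <- "solute"
  fields <- state@fields
  metab <- tryCatch({
    for (iter in seq_len(config@sourceIterations)) {
      ras <- rasterize(agents, grid, config@dryWeightFraction)
      grid <- ras$grid
      ms <- solveMetabolism(agents, fields, config, grid)
      R <- accumulateSources(ms$fluxTable, agents, grid,
                             config@dryWeightFraction, config@slabDepth)
      capped <- capConsumption(R, ms$fluxTable, ms$mu, agents, fields,
                               grid, config@dt)
      maxRel <- 0
      for (nm in names(fields)) {
        f <- fields[[nm]]
        f@R <- if (nm %in% names(capped$R)) capped$R[[nm]]
               else matrix(0, grid@nx, grid@ny)
        sol <- solveSteadyState(f, grid)
        rel <- max(abs(sol$field@S - fields[[nm]]@S) /
                     pmax(fields[[nm]]@S, 1e-9))
        maxRel <- max(maxRel, rel)
        fields[[nm]] <- sol$field
        log$clamped <- log$clamped + sol$clamped
      }
      if (maxRel < 1e-3) break
    }
    log$infeasible <- log$infeasible + ms$infeasible
    list(mu = capped$mu, fluxTable = capped$fluxTable)
  }, error = function(e) stop("[", phase, " phase] ", conditionMessage(e)))

  ## -- phase 3: growth and division ------------------------------------------
  if (!is.null(hooks)) hooks("growth", state)
  phase <- "growth"
  agents <- tryCatch({
    mu <- metab$mu[as.character(agents@data$id)]
    mu[is.na(mu)] <- 0
    agents <- grow(agents, mu, config@dt)
    agents <- divideAgents(agents, config@divisionThreshold, config@divisionOn)
    agents <- resolveCollisions(agents, W, config@shoveMaxIter)$agents
    sl <- sloughAgents(agents, config@maxHeight)
    log$sloughed <- log$sloughed + sum(sl$removed)
    sl$agents
  }, error = function(e) stop("[", phase, " phase] ", conditionMessage(e)))

  sp <- configSpeciesIds(config)
  ab <- vapply(sp, function(s)
    sum(agents@data$mass[agents@data$species == s]), numeric(1))
  mc <- vapply(fields, function(f) mean(f@S), numeric(1))
  new("SimulationState", timestep = state@timestep + 1L, agents = agents,
      grid = grid, fields = fields,
      abundance = rbind(state@abundance, ab),
      meanConc = rbind(state@meanConc, mc),
      agentFlux = metab$fluxTable, agentGrowth = metab$mu, log = log)
}

## relative fluctuation of each series column over the trailing window
windowFluctuation <- function(series, window) {
  tail <- series[seq(nrow(series) - window + 1L, nrow(series)), ,
                 drop = FALSE]
  apply(tail, 2, function(v) (max(v) - min(v)) / max(mean(v), 1e-12))
}

#' Run a simulation to steady state
#'
#' Iterates \code{\link{simStep}} from the seeded state until either the
#' step cap is reached or a steady state is detected: the relative change of
#' every species' total biomass and of every metabolite's domain-mean
#' concentration stays below \code{steadyTol} across the trailing
#' \code{steadyWindow} steps.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param hooks optional phase instrumentation, see \code{\link{simStep}}.
#' @param verbose print progress every 25 steps.
#' @return list with \code{state} (final \linkS4class{SimulationState}),
#'   \code{steady} (logical), \code{stepsRun}, and \code{report} (the final
#'   window fluctuations and run counters).
#' @export
runSimulation <- function(config, hooks = NULL, verbose = FALSE) {
  state <- seedInitial(config)
  steady <- FALSE
  while (state@timestep < config@maxSteps) {
    state <- simStep(state, config, hooks)
    if (verbose && state@timestep %% 25L == 0L)
      message("step ", state@timestep, ": ", nAgents(state@agents), " agents")
    if (state@timestep >= config@steadyWindow) {
      fl <- c(windowFluctuation(state@abundance, config@steadyWindow),
              windowFluctuation(state@meanConc, config@steadyWindow))
      if (all(fl < config@steadyTol)) { steady <- TRUE; break }
    }
  }
  fl <- if (state@timestep >= config@steadyWindow)
    c(windowFluctuation(state@abundance, config@steadyWindow),
      windowFluctuation(state@meanConc, config@steadyWindow))
  else NULL
  list(state = state, steady = steady, stepsRun = state@timestep,
       report = list(fluctuations = fl, log = state@log))
}
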