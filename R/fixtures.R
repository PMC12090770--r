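#' @include AllClasses.R AllGenerics.R config.R
NULL

#' Toy producer model: glucose to acetate and biomass
#'
#' A minimal (four-reaction) constraint-based model with a hand-verifiable
#' optimum: glucose uptake feeds one conversion producing biomass and
#' acetate, so the FBA optimum is exactly
#' \code{glcUptakeMax * biomassYield} and acetate secretion at the optimum is
#' \code{glcUptakeMax * acetateYield}. Mirrors a primary fermenter that
#' consumes glucose and secretes acetate for downstream species.
#'
#' @param glcUptakeMax maximal glucose uptake (mmol/gDW/h), positive.
#' @param acetateYield acetate produced per glucose (mmol/mmol).
#' @param biomassYield biomass produced per glucose (1/h per mmol/gDW/h).
#' @param speciesId species identifier.
#' @return a \linkS4class{GEMModel}.
#' @examples
#' growthRate(fba(makeProducer(10, 2, 0.5)))  # 5
#' @export
makeProducer <- function(glcUptakeMax = 10, acetateYield = 2,
                         biomassYield = 0.08, speciesId = "producer") {
  stopifnot(glcUptakeMax >= 0, acetateYield > 0, biomassYield > 0)
  GEMModel(speciesId, reactions = list(
    list(id = "EX_glucose", stoichiometry = c(glc = -1),
         lb = -glcUptakeMax, ub = 1000),
    list(id = "CONV", lb = 0, ub = 1000,
         stoichiometry = c(glc = -1, ac = acetateYield, bio = biomassYield)),
    list(id = "EX_acetate", stoichiometry = c(ac = -1), lb = 0, ub = 1000),
    list(id = "BIOMASS", stoichiometry = c(bio = -1), lb = 0, ub = 1000,
         gpr = "bioA")),
    objectiveId = "BIOMASS",
    exchangeMap = c(EX_glucose = "glucose", EX_acetate = "acetate"))
}

#' Toy consumer model: glucose plus acetate to butyrate and biomass
#'
#' A cross-feeding beneficiary: it grows slowly on glucose alone and much
#' faster when acetate (a producer's fermentation product) is available,
#' secreting butyrate from both routes. The FBA optimum is
#' \code{glcUptakeMax * biomassYieldGlc + acUptakeMax * biomassYieldAc} when
#' both substrates are available.
#'
#' @param glcUptakeMax,acUptakeMax maximal uptakes (mmol/gDW/h).
#' @param butyrateYield butyrate per acetate consumed (mmol/mmol; the
#'   glucose route uses twice this, one butyrate per glucose at 0.5).
#' @param biomassYieldGlc,biomassYieldAc biomass per substrate.
#' @param speciesId species identifier.
#' @return a \linkS4class{GEMModel}.
#' @export
makeConsumer <- function(glcUptakeMax = 2, acUptakeMax = 10,
                         butyrateYield = 0.5, biomassYieldGlc = 0.05,
                         biomassYieldAc = 0.06, speciesId = "consumer") {
  stopifnot(glcUptakeMax >= 0, acUptakeMax >= 0)
  GEMModel(speciesId, reactions = list(
    list(id = "EX_glucose", stoichiometry = c(glc = -1),
         lb = -glcUptakeMax, ub = 1000),
    list(id = "EX_acetate", stoichiometry = c(ac = -1),
         lb = -acUptakeMax, ub = 1000),
    list(id = "CONVG", lb = 0, ub = 1000,
         stoichiometry = c(glc = -1, bio = biomassYieldGlc,
                           but = 2 * butyrateYield)),
    list(id = "CONVA", lb = 0, ub = 1000,
         stoichiometry = c(ac = -1, bio = biomassYieldAc,
                           but = butyrateYield)),
    list(id = "EX_butyrate", stoichiometry = c(but = -1), lb = 0, ub = 1000),
    list(id = "BIOMASS", stoichiometry = c(bio = -1), lb = 0, ub = 1000,
         gpr = "bioB")),
    objectiveId = "BIOMASS",
    exchangeMap = c(EX_glucose = "glucose", EX_acetate = "acetate",
                    EX_butyrate = "butyrate"))
}

#' Toy aerotolerant model: oxygen-boosted glucose growth
#'
#' Grows anaerobically on glucose at a low yield and much faster through an
#' oxygen-consuming route, so its fitness tracks the local oxygen supply —
#' the facultative-anaerobe analogue used in the two-region oxygen scenario.
#'
#' @param glcUptakeMax maximal glucose uptake (mmol/gDW/h).
#' @param o2PerGlc oxygen consumed per glucose on the aerobic route.
#' @param biomassYieldAnaerobic,biomassYieldAerobic biomass per glucose on
#'   each route.
#' @param speciesId species identifier.
#' @return a \linkS4class{GEMModel}.
#' @export
makeAerotolerant <- function(glcUptakeMax = 10, o2PerGlc = 6,
                             biomassYieldAnaerobic = 0.02,
                             biomassYieldAerobic = 0.3,
                             speciesId = "aerotolerant") {
  GEMModel(speciesId, reactions = list(
    list(id = "EX_glucose", stoichiometry = c(glc = -1),
         lb = -glcUptakeMax, ub = 1000),
    list(id = "EX_oxygen", stoichiometry = c(o2 = -1), lb = -1000, ub = 0),
    list(id = "CONV_AN", lb = 0, ub = 1000,
         stoichiometry = c(glc = -1, bio = biomassYieldAnaerobic)),
    list(id = "CONV_AER", lb = 0, ub = 1000,
         stoichiometry = c(glc = -1, o2 = -o2PerGlc,
                           bio = biomassYieldAerobic)),
    list(id = "BIOMASS", stoichiometry = c(bio = -1), lb = 0, ub = 1000)),
    objectiveId = "BIOMASS",
    exchangeMap = c(EX_glucose = "glucose", EX_oxygen = "oxygen"))
}

scfaBoundary <- function(absorb = FALSE)
  boundarySpec(topValue = 0,
               bottom = if (absorb) "sink" else "neumann",
               bottomValue = if (absorb) 50 else 0)

#' Ready-made cross-feeding scenarios
#'
#' Complete runnable configurations at desk scale:
#' \describe{
#'   \item{pair_crossfeed}{a glucose-fermenting acetate producer plus an
#'     acetate-dependent butyrate producer on a glucose gradient.}
#'   \item{triple_with_slow_grower}{the pair plus a slow-growing glucose
#'     specialist that is not expected to form dense clusters.}
#'   \item{two_region_oxygen}{the pair plus an aerotolerant species, with a
#'     mucosal (bottom-edge Dirichlet) oxygen supply whose level
#'     distinguishes gut regions; SCFAs are absorbed at the bottom.}
#' }
#'
#' @param name scenario name.
#' @param oxygenBottom bottom-edge oxygen concentration (mM), only for
#'   two_region_oxygen.
#' @param includeProducer drop the producer for cross-feeding controls.
#' @param ... overrides forwarded to \code{\link{simulationConfig}}
#'   (e.g. \code{maxSteps}, \code{seed}).
#' @return a \linkS4class{SimulationConfig}.
#' @export
makeScenario <- function(name = c("pair_crossfeed",
                                  "triple_with_slow_grower",
                                  "two_region_oxygen"),
                         oxygenBottom = 0.2, includeProducer = TRUE, ...) {
  name <- match.arg(name)
  producer <- speciesSpec(makeProducer(), initialCount = 12,
                          initialMass = 15, color = "#1b9e77")
  consumer <- speciesSpec(makeConsumer(), initialCount = 12,
                          initialMass = 15, color = "#d95f02")
  species <- if (includeProducer) list(producer, consumer)
             else list(consumer)
  mets <- list(
    glucose = list(Dbulk = 2.4e6, boundary = boundarySpec(topValue = 10)),
    acetate = list(Dbulk = 3.2e6, boundary = scfaBoundary()),
    butyrate = list(Dbulk = 3.0e6, boundary = scfaBoundary()))
  ## consumer glucose vmax is 0: in the scenarios the consumer is an
  ## obligate acetate cross-feeder (it only grows when a producer supplies
  ## acetate), even though its model keeps a low-yield glucose route
  kin <- data.frame(
    species = c("producer", "consumer", "consumer"),
    metabolite = c("glucose", "glucose", "acetate"),
    vmax = c(10, 0, 10), km = c(0.5, 0.5, 0.1))
  if (name == "triple_with_slow_grower") {
    slow <- speciesSpec(makeProducer(glcUptakeMax = 2, acetateYield = 0.2,
                                     biomassYield = 0.01,
                                     speciesId = "slowgrower"),
                        initialCount = 12, initialMass = 15,
                        color = "#7570b3")
    species <- c(species, list(slow))
    kin <- rbind(kin, data.frame(species = "slowgrower",
                                 metabolite = "glucose", vmax = 2, km = 0.5))
  }
  if (name == "two_region_oxygen") {
    aero <- speciesSpec(makeAerotolerant(), initialCount = 12,
                        initialMass = 15, color = "#e7298a")
    species <- c(species, list(aero))
    mets$acetate$boundary <- scfaBoundary(absorb = TRUE)
    mets$butyrate$boundary <- scfaBoundary(absorb = TRUE)
    mets$oxygen <- list(Dbulk = 7e6,
                        boundary = boundarySpec(topValue = 0,
                                                bottom = "dirichlet",
                                                bottomValue = oxygenBottom))
    kin <- rbind(kin,
                 data.frame(species = "aerotolerant",
                            metabolite = c("glucose", "oxygen"),
                            vmax = c(10, 30), km = c(0.5, 0.01)))
  }
  kin <- kin[kin$species %in% vapply(species, function(s) s@speciesId,
                                     character(1)), , drop = FALSE]
  args <- list(nx = 20L, ny = 10L, maxHeight = 60, species = species,
               metabolites = mets,
               kinetics = uptakeKinetics(kin$species, kin$metabolite,
                                         kin$vmax, kin$km),
               maxSteps = 150L)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}
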