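#' @include AllClasses.R
NULL

#' @rdname fba
#' @export
setGeneric("fba", function(model, ...) standardGeneric("fba"))

#' @rdname pfba
#' @export
setGeneric("pfba", function(model, ...) standardGeneric("pfba"))

#' @rdname fva
#' @export
setGeneric("fva", function(model, ...) standardGeneric("fva"))

#' @rdname constrainUptake
#' @export
setGeneric("constrainUptake",
           function(model, localConcs, kinetics, ...)
             standardGeneric("constrainUptake"))

#' @rdname gem-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname gem-accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname gem-accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname gem-accessors
#' @export
setGeneric("bounds", function(x) standardGeneric("bounds"))

#' @rdname gem-accessors
#' @export
setGeneric("objectiveId", function(x) standardGeneric("objectiveId"))

#' @rdname gem-accessors
#' @export
setGeneric("exchangeMap", function(x) standardGeneric("exchangeMap"))

#' @rdname gem-accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname flux-accessors
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname flux-accessors
#' @export
setGeneric("growthRate", function(x) standardGeneric("growthRate"))

#' @rdname flux-accessors
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))

#' @rdname flux-accessors
#' @export
setGeneric("fluxIntervals", function(x) standardGeneric("fluxIntervals"))

#' @rdname agent-accessors
#' @export
setGeneric("nAgents", function(x) standardGeneric("nAgents"))

#' @rdname agent-accessors
#' @export
setGeneric("agentData", function(x) standardGeneric("agentData"))

#' @rdname agent-accessors
#' @export
setGeneric("totalBiomass", function(x, ...) standardGeneric("totalBiomass"))

#' @rdname analysis-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname analysis-accessors
#' @export
setGeneric("shiftTable", function(x) standardGeneric("shiftTable"))

#' @rdname state-accessors
#' @export
setGeneric("abundanceSeries", function(x) standardGeneric("abundanceSeries"))

#' @rdname state-accessors
#' @export
setGeneric("concentrationSeries",
           function(x) standardGeneric("concentrationSeries"))
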