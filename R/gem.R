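#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a constraint-based metabolic model
#'
#' @param speciesId species identifier.
#' @param reactions list of reactions, each a list with elements \code{id},
#'   \code{stoichiometry} (named numeric, metabolite -> signed coefficient),
#'   \code{lb}, \code{ub} (mmol/gDW/h) and optional \code{gpr}.
#' @param objectiveId id of the biomass reaction to maximize.
#' @param exchangeMap named character mapping exchange reaction ids to
#'   environment metabolite ids.
#' @return a validated \linkS4class{GEMModel}.
#' @examples
#' m <- GEMModel("toy",
#'   reactions = list(
#'     list(id = "EX_glc", stoichiometry = c(glc = -1), lb = -10, ub = 1000),
#'     list(id = "CONV", stoichiometry = c(glc = -1, bio = 0.5), lb = 0, ub = 1000),
#'     list(id = "BIOMASS", stoichiometry = c(bio = -1), lb = 0, ub = 1000)),
#'   objectiveId = "BIOMASS", exchangeMap = c(EX_glc = "glucose"))
#' growthRate(fba(m))
#' @export
GEMModel <- function(speciesId, reactions, objectiveId,
                     exchangeMap = character()) {
  rxns <- vapply(reactions, `[[`, character(1), "id")
  mets <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  ii <- jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoichiometry
    ii <- c(ii, match(names(st), mets)); jj <- c(jj, rep(j, length(st)))
    xx <- c(xx, as.numeric(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), length(rxns)),
                            dimnames = list(mets, rxns))
  lb <- vapply(reactions, function(r) as.numeric(r$lb), numeric(1))
  ub <- vapply(reactions, function(r) as.numeric(r$ub), numeric(1))
  gpr <- vapply(reactions, function(r)
    if (is.null(r$gpr)) NA_character_ else as.character(r$gpr), character(1))
  names(gpr) <- rxns
  new("GEMModel", speciesId = as.character(speciesId), mets = mets,
      rxns = rxns, S = S, lb = lb, ub = ub,
      objectiveId = as.character(objectiveId),
      exchangeMap = exchangeMap,
      gpr = gpr[!is.na(gpr)])
}

#' Accessors for GEMModel
#'
#' @param x a \linkS4class{GEMModel} (or, for \code{speciesId}, any object
#'   carrying a species identifier).
#' @return the corresponding component: ids, the sparse stoichiometric
#'   matrix, a two-column bounds matrix, or the exchange map.
#' @name gem-accessors
#' @aliases reactionIds metaboliteIds stoichiometry bounds objectiveId
#'   exchangeMap speciesId
NULL

#' @rdname gem-accessors
setMethod("reactionIds", "GEMModel", function(x) x@rxns)
#' @rdname gem-accessors
setMethod("metaboliteIds", "GEMModel", function(x) x@mets)
#' @rdname gem-accessors
setMethod("stoichiometry", "GEMModel", function(x) x@S)
#' @rdname gem-accessors
setMethod("bounds", "GEMModel", function(x)
  cbind(lb = x@lb, ub = x@ub, deparse.level = 0) |>
    `dimnames<-`(list(x@rxns, c("lb", "ub"))))
#' @rdname gem-accessors
setMethod("objectiveId", "GEMModel", function(x) x@objectiveId)
#' @rdname gem-accessors
setMethod("exchangeMap", "GEMModel", function(x) x@exchangeMap)
#' @rdname gem-accessors
setMethod("speciesId", "GEMModel", function(x) x@speciesId)

setMethod("show", "GEMModel", function(object) {
  cat("GEMModel '", object@speciesId, "': ", length(object@rxns),
      " reactions, ", length(object@mets), " metabolites, ",
      length(object@exchangeMap), " exchanges; objective '",
      object@objectiveId, "'\n", sep = "")
})

#' Accessors for FluxResult and FVAResult
#'
#' @param x a \linkS4class{FluxResult} or \linkS4class{FVAResult}.
#' @name flux-accessors
#' @aliases fluxes growthRate solverStatus fluxIntervals
NULL

#' @rdname flux-accessors
setMethod("fluxes", "FluxResult", function(x) x@fluxes)
#' @rdname flux-accessors
setMethod("growthRate", "FluxResult", function(x) x@growthRate)
#' @rdname flux-accessors
setMethod("solverStatus", "FluxResult", function(x) x@status)
#' @rdname flux-accessors
setMethod("fluxIntervals", "FVAResult", function(x) x@intervals)

setMethod("show", "FluxResult", function(object) {
  cat("FluxResult: status ", object@status, ", growth rate ",
      format(object@growthRate, digits = 6), " 1/h over ",
      length(object@fluxes), " reactions\n", sep = "")
})

setMethod("show", "FVAResult", function(object) {
  cat("FVAResult: ", nrow(object@intervals),
      " reactions at fraction ", object@fraction, "\n", sep = "")
})

#' Michaelis-Menten uptake kinetics table
#'
#' @param species,metabolite,vmax,km parallel vectors defining per
#'   (species, metabolite) saturating uptake rates (mmol/gDW/h) and
#'   half-saturation constants (mM).
#' @return an \linkS4class{UptakeKinetics}.
#' @export
uptakeKinetics <- function(species = character(), metabolite = character(),
                           vmax = numeric(), km = numeric()) {
  new("UptakeKinetics",
      table = data.frame(species = as.character(species),
                         metabolite = as.character(metabolite),
                         vmax = as.numeric(vmax), km = as.numeric(km)))
}

setMethod("show", "UptakeKinetics", function(object) {
  cat("UptakeKinetics:", nrow(object@table), "entries\n")
})

infeasibleResult <- function(model) {
  fl <- rep(0, length(model@rxns)); names(fl) <- model@rxns
  new("FluxResult", fluxes = fl, growthRate = 0, status = "infeasible")
}

#' Flux balance analysis
#'
#' Maximizes the biomass objective subject to steady-state mass balance
#' (S v = 0) and the model's flux bounds. A malformed model raises a
#' validation error; an LP with no feasible flux vector returns a result
#' with status "infeasible" (growth rate 0, zero fluxes).
#'
#' @param model a \linkS4class{GEMModel}.
#' @param ... unused.
#' @return a \linkS4class{FluxResult}.
#' @export
setMethod("fba", "GEMModel", function(model, ...) {
  validObject(model)
  n <- length(model@rxns)
  obj <- as.numeric(model@rxns == model@objectiveId)
  sol <- lpSolveBounded(obj, model@S, rep(0, nrow(model@S)),
                        model@lb, model@ub, maximize = TRUE)
  if (sol$status != "optimal") return(infeasibleResult(model))
  fl <- sol$x; names(fl) <- model@rxns
  new("FluxResult", fluxes = fl,
      growthRate = unname(fl[model@objectiveId]), status = "optimal")
})

#' Parsimonious flux balance analysis
#'
#' Among flux vectors attaining the FBA-optimal objective value, returns one
#' minimizing total absolute flux (the l1 norm), via the standard splitting
#' of each reaction into irreversible forward/backward halves. The solver's
#' deterministic pivoting makes the returned representative reproducible.
#'
#' @param model a \linkS4class{GEMModel}.
#' @param ... unused.
#' @return a \linkS4class{FluxResult} with \code{growthRate} equal to the
#'   FBA optimum.
#' @export
setMethod("pfba", "GEMModel", function(model, ...) {
  base <- fba(model)
  if (base@status != "optimal") return(base)
  n <- length(model@rxns)
  S <- as.matrix(model@S)
  ## v = p - q with p, q >= 0; bounds chosen so p - q spans [lb, ub] exactly
  plb <- pmax(model@lb, 0); pub <- pmax(model@ub, 0)
  qlb <- pmax(-model@ub, 0); qub <- pmax(-model@lb, 0)
  obj <- as.numeric(model@rxns == model@objectiveId)
  Aeq <- rbind(cbind(S, -S), c(obj, -obj))
  beq <- c(rep(0, nrow(S)), base@growthRate)
  sol <- lpSolveBounded(rep(1, 2 * n), Aeq, beq,
                        c(plb, qlb), c(pub, qub), maximize = FALSE)
  if (sol$status != "optimal") return(infeasibleResult(model))
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  names(v) <- model@rxns
  new("FluxResult", fluxes = v,
      growthRate = unname(v[model@objectiveId]), status = "optimal")
})

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject to
#' mass balance, the model's bounds, and the objective held at or above
#' \code{fraction} of its FBA optimum (suboptimal FVA; the conventional
#' fraction is 0.9).
#'
#' @param model a \linkS4class{GEMModel}.
#' @param fraction objective fraction in (0, 1].
#' @param reactionIds optional subset of reaction ids (default: all).
#' @param ... unused.
#' @return an \linkS4class{FVAResult}.
#' @export
setMethod("fva", "GEMModel",
          function(model, fraction = 0.9, reactionIds = NULL, ...) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single value in (0, 1]")
  base <- fba(model)
  if (base@status != "optimal")
    stop("FVA requires a feasible model (FBA was infeasible)")
  if (is.null(reactionIds)) reactionIds <- model@rxns
  miss <- setdiff(reactionIds, model@rxns)
  if (length(miss)) stop("unknown reactions: ", paste(miss, collapse = ", "))
  n <- length(model@rxns)
  S <- as.matrix(model@S)
  obj <- as.numeric(model@rxns == model@objectiveId)
  ## slack s >= 0 turns c'v >= f*mu into the equality c'v - s = f*mu
  Aeq <- rbind(cbind(S, 0), c(obj, -1))
  beq <- c(rep(0, nrow(S)), fraction * base@growthRate)
  lb <- c(model@lb, 0); ub <- c(model@ub, 1e6)
  iv <- matrix(NA_real_, length(reactionIds), 2,
               dimnames = list(reactionIds, c("min", "max")))
  for (r in reactionIds) {
    e <- as.numeric(c(model@rxns == r, 0))
    lo <- lpSolveBounded(e, Aeq, beq, lb, ub, maximize = FALSE)
    hi <- lpSolveBounded(e, Aeq, beq, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem failed for reaction ", r)
    iv[r, ] <- c(lo$value, hi$value)
  }
  ## guard against solver round-off inverting degenerate intervals
  flip <- iv[, 1] > iv[, 2]
  if (any(flip)) iv[flip, ] <- cbind(rowMeans(iv[flip, , drop = FALSE]),
                                     rowMeans(iv[flip, , drop = FALSE]))
  new("FVAResult", intervals = iv, fraction = fraction)
})

#' Constrain uptake bounds from local metabolite concentrations
#'
#' Sets the lower (uptake) bound of each exchange reaction with a kinetics
#' entry to \code{-vmax * S / (km + S)}, the Michaelis-Menten rate at the
#' local concentration \code{S}; a metabolite absent from \code{localConcs}
#' or at zero concentration yields a bound of 0 (no uptake). Secretion
#' (upper) bounds are untouched. Exchange reactions without a kinetics entry
#' keep the model's default bound (reported via a message when
#' \code{options(mucosim.verbose = TRUE)}).
#'
#' @param model a \linkS4class{GEMModel}.
#' @param localConcs named numeric, environment metabolite -> mM (>= 0).
#' @param kinetics an \linkS4class{UptakeKinetics}.
#' @param ... unused.
#' @return the model with updated uptake bounds.
#' @export
setMethod("constrainUptake", "GEMModel",
          function(model, localConcs, kinetics, ...) {
  if (any(localConcs < 0)) stop("local concentrations must be nonnegative")
  tb <- kinetics@table
  tb <- tb[tb$species == model@speciesId, , drop = FALSE]
  missing <- character()
  for (rxn in names(model@exchangeMap)) {
    met <- model@exchangeMap[[rxn]]
    k <- tb[tb$metabolite == met, , drop = FALSE]
    if (!nrow(k)) { missing <- c(missing, met); next }
    S <- if (met %in% names(localConcs)) localConcs[[met]] else 0
    j <- match(rxn, model@rxns)
    newlb <- if (S > 0) -k$vmax[1] * S / (k$km[1] + S) else 0
    model@lb[j] <- min(newlb, model@ub[j])
  }
  if (length(missing) && isTRUE(getOption("mucosim.verbose", FALSE)))
    message("no kinetics for '", model@speciesId, "' on: ",
            paste(unique(missing), collapse = ", "),
            " (model default bounds kept)")
  model
})

#' Exchange fluxes on environment metabolites
#'
#' Maps a flux solution through the model's exchange map, returning one flux
#' per environment metabolite (negative = uptake, positive = secretion).
#'
#' @param model a \linkS4class{GEMModel}.
#' @param result a \linkS4class{FluxResult} over the same model.
#' @return named numeric, environment metabolite -> mmol/gDW/h.
#' @export
exchangeFluxes <- function(model, result) {
  v <- result@fluxes[names(model@exchangeMap)]
  names(v) <- unname(model@exchangeMap)
  v
}
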