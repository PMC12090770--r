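#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for analysis containers
#'
#' @param x a \linkS4class{CrossFeedingGraph} or \linkS4class{ShiftTable}.
#' @name analysis-accessors
#' @aliases edgeTable shiftTable
NULL

#' @rdname analysis-accessors
setMethod("edgeTable", "CrossFeedingGraph", function(x) x@edges)
#' @rdname analysis-accessors
setMethod("shiftTable", "ShiftTable", function(x) x@table)

setMethod("show", "CrossFeedingGraph", function(object) {
  cat("CrossFeedingGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges over",
      length(unique(object@edges$metabolite)), "metabolites\n")
})

setMethod("show", "ShiftTable", function(object) {
  cat("ShiftTable:", nrow(object@table), "reactions,",
      sum(object@table$significant), "above the",
      object@percentile, "quantile\n")
})

#' Build a cross-feeding graph from per-agent exchange fluxes
#'
#' Per species and metabolite, the mean exchange flux across that species'
#' agents is computed; species with positive mean secretion are connected to
#' species with negative mean uptake through that metabolite, transfers
#' apportioned proportionally, and any net surplus (secretion exceeding
#' community uptake) or deficit is routed to or from an extra "environment"
#' node. Metabolites whose mean concentration is below the threshold are
#' excluded, as is anything on the exclusion list.
#'
#' @param fluxTable data.frame(agent, species, metabolite, flux): per-agent
#'   exchange fluxes (negative = uptake).
#' @param concentrations named numeric of mean concentrations (mM) used for
#'   thresholding.
#' @param concThreshold minimum concentration (mM), default 0.1.
#' @param exclude metabolite ids to drop (e.g. amino acids).
#' @return a \linkS4class{CrossFeedingGraph}.
#' @export
crossFeedingGraph <- function(fluxTable, concentrations,
                              concThreshold = 0.1, exclude = character()) {
  stopifnot(nrow(fluxTable) > 0)
  keep <- names(concentrations)[concentrations >= concThreshold]
  keep <- setdiff(keep, exclude)
  ft <- fluxTable[fluxTable$metabolite %in% keep, , drop = FALSE]
  species <- sort(unique(fluxTable$species))
  edges <- data.frame(from = character(), to = character(),
                      metabolite = character(), weight = numeric())
  addEdge <- function(from, to, met, w) {
    if (w > 1e-12)
      edges <<- rbind(edges, data.frame(from = from, to = to,
                                        metabolite = met, weight = w))
  }
  for (met in unique(ft$metabolite)) {
    sub <- ft[ft$metabolite == met, , drop = FALSE]
    ## mean across ALL of a species' agents, including non-exchanging ones,
    ## would need the agent roster; mean across reported fluxes is used, and
    ## callers pass complete per-agent tables from the simulation state
    m <- vapply(split(sub$flux, sub$species), mean, numeric(1))
    prod <- m[m > 0]; cons <- -m[m < 0]
    P <- sum(prod); U <- sum(cons)
    transfer <- min(P, U)
    for (p in names(prod)) for (c in names(cons))
      addEdge(p, c, met, transfer * (prod[[p]] / P) * (cons[[c]] / U))
    if (P > U) for (p in names(prod))
      addEdge(p, "environment", met, (P - U) * prod[[p]] / P)
    if (U > P) for (c in names(cons))
      addEdge("environment", c, met, (U - P) * cons[[c]] / U)
  }
  rownames(edges) <- NULL
  new("CrossFeedingGraph", edges = edges,
      nodes = c(species, "environment"))
}

#' Convert a cross-feeding graph to igraph
#'
#' @param graph a \linkS4class{CrossFeedingGraph}.
#' @return an \pkg{igraph} directed graph with edge attributes
#'   \code{metabolite} and \code{weight}.
#' @export
asIgraph <- function(graph) {
  igraph::graph_from_data_frame(graph@edges, directed = TRUE,
                                vertices = data.frame(name = graph@nodes))
}

#' Write a cross-feeding graph
#'
#' @param graph a \linkS4class{CrossFeedingGraph}.
#' @param path output file.
#' @param format "edgelist" (tab-delimited from/to/metabolite/weight) or
#'   "graphml".
#' @return the path, invisibly.
#' @export
writeGraph <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist")
    utils::write.table(graph@edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  else
    igraph::write_graph(asIgraph(graph), path, format = "graphml")
  invisible(path)
}

#' Kernel-density map of agent positions
#'
#' 2D Gaussian kernel density over the domain, periodic along x (kernel
#' images at multiples of the width) and reflected at the bottom (y = 0) and
#' top (y = height) walls so the density integrates to one over the domain.
#' Bandwidths default to Scott's rule per axis.
#'
#' @param x,y agent coordinates (um); at least 2 points.
#' @param width,height domain extent (um).
#' @param bandwidth length-2 numeric (um); Scott's rule when NULL.
#' @param gridN evaluation grid resolution (cells per axis), default 64.
#' @return list(x, y, z): grid coordinates and the density matrix
#'   (length(x) rows), or NULL with a warning for fewer than 2 points.
#' @export
kdeMap <- function(x, y, width, height, bandwidth = NULL, gridN = 64) {
  n <- length(x)
  if (n < 2) {
    warning("kernel density undefined for fewer than 2 agents")
    return(NULL)
  }
  if (is.null(bandwidth)) {
    scott <- function(v) {
      s <- stats::sd(v)
      if (s == 0) s <- max(diff(range(v)) / 4, 1)
      s * n^(-1 / 6)
    }
    bandwidth <- c(scott(x), scott(y))
  }
  gx <- seq(0, width, length.out = gridN + 1)[-(gridN + 1)] + width / gridN / 2
  gy <- seq(0, height, length.out = gridN + 1)[-(gridN + 1)] +
    height / gridN / 2
  ## periodic images in x
  kimg <- ceiling(4 * bandwidth[1] / width)
  zx <- matrix(0, gridN, n)
  for (k in -kimg:kimg)
    zx <- zx + outer(gx, x + k * width,
                     function(a, b) stats::dnorm(a - b, sd = bandwidth[1]))
  ## reflection in y at 0 and height
  zy <- outer(gy, y, function(a, b) stats::dnorm(a - b, sd = bandwidth[2])) +
    outer(gy, y, function(a, b) stats::dnorm(a + b, sd = bandwidth[2])) +
    outer(gy, y, function(a, b)
      stats::dnorm(a - (2 * height - b), sd = bandwidth[2]))
  z <- (zx %*% t(zy)) / n
  list(x = gx, y = gy, z = z)
}

#' Normalize SCFA concentrations to fractions
#'
#' Divides each short-chain fatty acid concentration by the sum over all of
#' them, for composition comparisons across scenarios.
#'
#' @param concentrations named nonnegative numeric (mM), at least one
#'   positive.
#' @return named fractions summing to one.
#' @export
normalizeScfa <- function(concentrations) {
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  s <- sum(concentrations)
  if (s <= 0) stop("all SCFA concentrations are zero; fractions undefined")
  concentrations / s
}

#' Suboptimal FVA across all agents of one species
#'
#' Re-applies each agent's last environmental constraints (its lattice
#' cell's metabolite concentrations through the Michaelis-Menten uptake
#' bounds) and runs flux variability analysis at the given objective
#' fraction. Agents in identical cells share one solve.
#'
#' @param state a \linkS4class{SimulationState} from a completed run.
#' @param config the \linkS4class{SimulationConfig} used.
#' @param species species id to analyse.
#' @param fraction FVA objective fraction, default 0.9.
#' @return named list (agent id -> \linkS4class{FVAResult}); infeasible
#'   agents are skipped with a warning.
#' @export
fvaPerAgent <- function(state, config, species, fraction = 0.9) {
  model <- NULL
  for (s in config@species) if (s@speciesId == species) model <- s@model
  if (is.null(model)) stop("unknown species: ", species)
  d <- state@agents@data
  idx <- which(d$species == species)
  if (!length(idx)) return(list())
  cells <- agentCells(state@agents, state@grid)
  lin <- cells[, "ix"] + (cells[, "iy"] - 1L) * state@grid@nx
  cache <- list()
  out <- list()
  skipped <- 0L
  for (i in idx) {
    key <- as.character(lin[i])
    if (is.null(cache[[key]])) {
      localConcs <- vapply(state@fields, function(f) f@S[lin[i]], numeric(1))
      m <- constrainUptake(model, localConcs, config@kinetics)
      cache[[key]] <- if (fba(m)@status == "optimal")
        fva(m, fraction = fraction) else NA
    }
    if (identical(cache[[key]], NA)) { skipped <- skipped + 1L; next }
    out[[as.character(d$id[i])]] <- cache[[key]]
  }
  if (skipped) warning(skipped, " agents skipped (infeasible)")
  out
}

#' Flux-range-shift statistics across agents
#'
#' For each reaction, collects the per-agent FVA interval ends and reports
#' the minimum lower bound and maximum upper bound across agents, plus the
#' range shift: the larger of the across-agent spreads of the lower ends and
#' of the upper ends — zero exactly when all agents agree. Reactions whose
#' shift reaches the 95th percentile of all shifts are flagged significant;
#' those above \code{reportThreshold} (default 2 mmol/gDW/h) are flagged
#' reportable. An alternative definition, the across-agent spread of
#' interval widths, is available via \code{definition = "width"}.
#'
#' @param fvaResults list of \linkS4class{FVAResult} (one per agent, same
#'   reactions); at least 2.
#' @param reportThreshold absolute shift cutoff for reporting (mmol/gDW/h).
#' @param percentile significance quantile, default 0.95.
#' @param definition "ends" (default) or "width".
#' @param gpr optional named character of GPR annotations per reaction.
#' @return a \linkS4class{ShiftTable}.
#' @export
shiftAnalysis <- function(fvaResults, reportThreshold = 2,
                          percentile = 0.95,
                          definition = c("ends", "width"), gpr = NULL) {
  definition <- match.arg(definition)
  stopifnot(length(fvaResults) >= 2)
  rxns <- rownames(fvaResults[[1]]@intervals)
  lbs <- vapply(fvaResults, function(r) r@intervals[rxns, 1],
                numeric(length(rxns)))
  ubs <- vapply(fvaResults, function(r) r@intervals[rxns, 2],
                numeric(length(rxns)))
  if (length(rxns) == 1L) { lbs <- t(lbs); ubs <- t(ubs) }
  minLB <- apply(lbs, 1, min)
  maxUB <- apply(ubs, 1, max)
  shift <- if (definition == "ends")
    pmax(apply(lbs, 1, max) - minLB, maxUB - apply(ubs, 1, min))
  else {
    w <- ubs - lbs
    apply(w, 1, max) - apply(w, 1, min)
  }
  cut <- stats::quantile(shift, percentile)
  tb <- data.frame(reaction = rxns, minLB = minLB, maxUB = maxUB,
                   shift = shift, significant = shift >= cut,
                   reportable = shift > reportThreshold,
                   gpr = if (is.null(gpr)) NA_character_
                         else unname(gpr[rxns]),
                   row.names = NULL)
  new("ShiftTable", table = tb, percentile = percentile,
      reportThreshold = reportThreshold)
}

#' Wilcoxon signed-rank test with an exact tied-rank distribution
#'
#' Two-sided paired signed-rank test. Zero differences are removed and tied
#' absolute differences receive mid-ranks. For 25 or fewer nonzero pairs the
#' null distribution of the rank sum is computed exactly by convolution over
#' the (possibly tied) ranks; above that a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y paired samples of equal length; at least 5 nonzero
#'   differences.
#' @param exactMax largest n solved exactly (default 25).
#' @return list(statistic, p.value, n, method); statistic is V, the sum of
#'   ranks of positive differences.
#' @export
wilcoxonSignedRank <- function(x, y, exactMax = 25) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; no signal")
    return(list(statistic = 0, p.value = 1, n = 0L, method = "degenerate"))
  }
  if (n < 5) stop("need at least 5 nonzero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exactMax) {
    ## exact null distribution by convolution: ranks are multiples of 1/2
    ## (mid-ranks), so work on doubled, integer-valued ranks
    r2 <- as.integer(round(2 * r))
    maxS <- sum(r2)
    prob <- c(1, numeric(maxS))  # prob[s + 1] = #assignments with sum s
    for (ri in r2) {
      shifted <- c(numeric(ri), prob[seq_len(maxS + 1 - ri)])
      prob <- prob + shifted
    }
    prob <- prob / 2^n
    v2 <- as.integer(round(2 * V))
    pLo <- sum(prob[seq_len(v2 + 1)])          # P(V <= v)
    pHi <- sum(prob[seq(v2 + 1, maxS + 1)])    # P(V >= v)
    p <- min(1, 2 * min(pLo, pHi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = V, p.value = p, n = n, method = method)
}
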