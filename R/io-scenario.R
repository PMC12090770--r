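#' @include AllClasses.R AllGenerics.R config.R fixtures.R
NULL

## scenario YAML schema: known keys per section, used for validation
scenarioSchema <- list(
  domain = c("nx", "ny", "cellSize", "maxHeight"),
  species = c("id", "model", "initialCount", "initialMass", "color"),
  metabolites = c("Dbulk", "biofilmFactor", "top", "bottom"),
  kinetics = c("species", "metabolite", "vmax", "km"),
  time = c("dt", "maxSteps", "steadyTol", "steadyWindow"),
  agents = c("stepLength", "rotationSd", "divisionThreshold", "divisionOn",
             "cellDensity", "dryWeightFraction", "slabDepth"),
  run = c("seed", "outputInterval", "shoveMaxIter", "fvaFraction",
          "planktonicFBA", "sourceIterations"))

#' Read a scenario configuration file
#'
#' Parses the documented YAML schema (sections \code{domain},
#' \code{species}, \code{metabolites}, \code{kinetics}, \code{time},
#' \code{agents}, \code{run}) into a \linkS4class{SimulationConfig}.
#' Species models are loaded from paths relative to the scenario file
#' (\code{.json} toy format or \code{.xml} SBML) or built from the fixture
#' generators via \code{"fixture:producer"}, \code{"fixture:consumer"},
#' \code{"fixture:aerotolerant"}. Validation reports every offending key at
#' once.
#'
#' @param path scenario YAML file.
#' @return a \linkS4class{SimulationConfig}.
#' @export
readScenario <- function(path) {
  y <- yaml::read_yaml(path)
  errs <- character()
  known <- c("domain", "species", "metabolites", "kinetics", "time",
             "agents", "run")
  errs <- c(errs, sprintf("unknown top-level key '%s'",
                          setdiff(names(y), known)))
  checkKeys <- function(x, allowed, where)
    sprintf("unknown key '%s' in %s", setdiff(names(x), allowed), where)
  errs <- c(errs, checkKeys(y$domain, scenarioSchema$domain, "domain"))
  for (need in c("nx", "ny", "maxHeight"))
    if (is.null(y$domain[[need]]))
      errs <- c(errs, sprintf("domain is missing '%s'", need))
  if (!length(y$species)) errs <- c(errs, "at least one species required")
  for (i in seq_along(y$species)) {
    s <- y$species[[i]]
    errs <- c(errs, checkKeys(s, scenarioSchema$species,
                              sprintf("species[%d]", i)))
    if (is.null(s$model))
      errs <- c(errs, sprintf("species[%d] is missing 'model'", i))
  }
  for (nm in names(y$metabolites)) {
    m <- y$metabolites[[nm]]
    errs <- c(errs, checkKeys(m, scenarioSchema$metabolites,
                              sprintf("metabolites.%s", nm)))
    if (is.null(m$Dbulk))
      errs <- c(errs, sprintf("metabolites.%s is missing 'Dbulk'", nm))
  }
  for (i in seq_along(y$kinetics))
    errs <- c(errs, checkKeys(y$kinetics[[i]], scenarioSchema$kinetics,
                              sprintf("kinetics[%d]", i)))
  for (sec in c("time", "agents", "run"))
    errs <- c(errs, checkKeys(y[[sec]], scenarioSchema[[sec]], sec))
  if (length(errs))
    stop("invalid scenario '", path, "':\n  ",
         paste(errs, collapse = "\n  "))

  loadModel <- function(ref) {
    if (startsWith(ref, "fixture:")) {
      builder <- switch(sub("^fixture:", "", ref),
                        producer = makeProducer, consumer = makeConsumer,
                        aerotolerant = makeAerotolerant,
                        stop("unknown fixture model: ", ref))
      return(builder())
    }
    f <- if (file.exists(ref)) ref else file.path(dirname(path), ref)
    if (grepl("\\.json$", f)) readGEMJson(f) else readSBML(f)
  }
  species <- lapply(y$species, function(s) {
    m <- loadModel(s$model)
    if (!is.null(s$id)) m@speciesId <- s$id
    speciesSpec(m, initialCount = s$initialCount %||% 10,
                initialMass = s$initialMass %||% 15,
                color = s$color %||% "grey40")
  })
  mets <- lapply(y$metabolites, function(m)
    list(Dbulk = m$Dbulk, biofilmFactor = m$biofilmFactor,
         boundary = boundarySpec(
           topValue = m$top$value %||% 0,
           bottom = m$bottom$type %||% "neumann",
           bottomValue = m$bottom$value %||% 0)))
  kin <- do.call(rbind, lapply(y$kinetics, as.data.frame))
  kinetics <- if (is.null(kin)) uptakeKinetics()
    else uptakeKinetics(kin$species, kin$metabolite, kin$vmax, kin$km)
  opt <- c(y$domain[c("cellSize")], y$time, y$agents, y$run)
  opt <- opt[!vapply(opt, is.null, logical(1))]
  do.call(simulationConfig,
          c(list(nx = y$domain$nx, ny = y$domain$ny,
                 maxHeight = y$domain$maxHeight, species = species,
                 metabolites = mets, kinetics = kinetics), opt))
}

#' Write a scenario plus its models to files
#'
#' Serializes a fixture scenario as one YAML file and one toy-model JSON per
#' species, so the command-line \code{run} subcommand can execute it.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir output directory (created if needed).
#' @return the scenario file path, invisibly.
#' @export
writeScenarioFiles <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  species <- lapply(config@species, function(s) {
    mf <- paste0("model_", s@speciesId, ".json")
    writeGEMJson(s@model, file.path(dir, mf))
    list(id = s@speciesId, model = mf, initialCount = s@initialCount,
         initialMass = s@initialMass, color = s@color)
  })
  mets <- lapply(config@metabolites, function(m)
    list(Dbulk = m$Dbulk, biofilmFactor = m$biofilmFactor,
         top = list(value = m$boundary@topValue),
         bottom = list(type = m$boundary@bottom,
                       value = m$boundary@bottomValue)))
  kt <- config@kinetics@table
  y <- list(
    domain = list(nx = config@nx, ny = config@ny,
                  cellSize = config@cellSize, maxHeight = config@maxHeight),
    species = species, metabolites = mets,
    kinetics = lapply(seq_len(nrow(kt)), function(i) as.list(kt[i, ])),
    time = list(dt = config@dt, maxSteps = config@maxSteps,
                steadyTol = config@steadyTol,
                steadyWindow = config@steadyWindow),
    agents = list(stepLength = config@stepLength,
                  rotationSd = config@rotationSd,
                  divisionThreshold = config@divisionThreshold,
                  divisionOn = config@divisionOn,
                  cellDensity = config@cellDensity,
                  dryWeightFraction = config@dryWeightFraction,
                  slabDepth = config@slabDepth),
    run = list(seed = config@seed, outputInterval = config@outputInterval,
               shoveMaxIter = config@shoveMaxIter,
               fvaFraction = config@fvaFraction,
               planktonicFBA = config@planktonicFBA,
               sourceIterations = config@sourceIterations))
  out <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(y, out)
  invisible(out)
}

## deterministic md5 of the full configuration (models included)
hashConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dump <- list(
    scalars = sapply(c("nx", "ny", "cellSize", "maxHeight", "slabDepth",
                       "dryWeightFraction", "cellDensity", "stepLength",
                       "rotationSd", "divisionThreshold", "divisionOn",
                       "dt", "maxSteps", "steadyTol", "steadyWindow", "seed",
                       "outputInterval", "shoveMaxIter", "fvaFraction",
                       "planktonicFBA", "sourceIterations"),
                     function(s) as.character(slot(config, s))),
    species = lapply(config@species, function(s)
      list(id = s@speciesId, count = s@initialCount, mass = s@initialMass,
           rxns = s@model@rxns, lb = s@model@lb, ub = s@model@ub,
           S = as.numeric(s@model@S))),
    metabolites = lapply(config@metabolites, function(m)
      list(D = m$Dbulk, bf = m$biofilmFactor, top = m$boundary@topValue,
           bottom = m$boundary@bottom, bv = m$boundary@bottomValue)),
    kinetics = config@kinetics@table)
  writeLines(jsonlite::toJSON(dump, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write simulation outputs to a directory
#'
#' Writes delimited-text snapshots: the final agent table, the abundance and
#' mean-concentration series, the final metabolite fields (one row per cell)
#' and per-agent exchange fluxes, plus a JSON run manifest carrying the
#' configuration hash, seed, step range and file inventory.
#'
#' @param result the list returned by \code{\link{runSimulation}}.
#' @param config the \linkS4class{SimulationConfig} that produced it.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeOutputs <- function(result, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  state <- result$state
  wt <- function(d, f) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  files <- character()
  ad <- state@agents@data
  ad$timestep <- state@timestep
  files <- c(files, wt(ad, "agents.tsv"))
  ab <- data.frame(timestep = seq_len(nrow(state@abundance)) - 1L,
                   state@abundance, check.names = FALSE)
  files <- c(files, wt(ab, "series_abundance.tsv"))
  mc <- data.frame(timestep = seq_len(nrow(state@meanConc)) - 1L,
                   state@meanConc, check.names = FALSE)
  files <- c(files, wt(mc, "series_concentration.tsv"))
  fld <- do.call(rbind, lapply(names(state@fields), function(nm) {
    f <- state@fields[[nm]]
    g <- state@grid
    data.frame(metabolite = nm, timestep = state@timestep,
               ix = rep(seq_len(g@nx), g@ny),
               iy = rep(seq_len(g@ny), each = g@nx),
               concentration = as.vector(f@S))
  }))
  files <- c(files, wt(fld, "fields.tsv"))
  files <- c(files, wt(state@agentFlux, "fluxes.tsv"))
  manifest <- list(configHash = hashConfig(config), seed = config@seed,
                   startStep = 0L, endStep = state@timestep,
                   steady = result$steady,
                   packageVersion = as.character(
                     utils::packageVersion("mucosim")),
                   rVersion = R.version.string,
                   files = files)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read and check a run manifest
#'
#' @param dir a run output directory.
#' @return the manifest list; errors if any inventoried file is missing.
#' @export
runManifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  missing <- m$files[!file.exists(file.path(dir, m$files))]
  if (length(missing))
    stop("manifest lists missing files: ", paste(missing, collapse = ", "))
  m
}

parseCliArgs <- function(args) {
  out <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      out[[substring(a, 3)]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: \code{run --config F --out D [--seed N]} executes a scenario
#' and writes outputs; \code{analyze --in D --out D2 [--conc-threshold T]}
#' computes the cross-feeding edge list and SCFA fractions from a run
#' directory; \code{fixtures --name N --out D} materializes a built-in
#' scenario as files; \code{validate --config F} checks a scenario file.
#' Installed as the \code{inst/scripts/mucosim} Rscript.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
mucosimCLI <- function(args) {
  if (!length(args)) {
    message("usage: mucosim <run|analyze|fixtures|validate> [options]")
    return(invisible(1L))
  }
  cmd <- args[[1]]
  opt <- parseCliArgs(args[-1])
  switch(cmd,
    run = {
      config <- readScenario(opt$config)
      if (!is.null(opt$seed)) config@seed <- as.integer(opt$seed)
      res <- runSimulation(config)
      writeOutputs(res, config, opt$out)
      message("run finished after ", res$stepsRun, " steps (steady: ",
              res$steady, "); outputs in ", opt$out)
    },
    analyze = {
      indir <- opt$`in`
      runManifest(indir)
      flux <- utils::read.table(file.path(indir, "fluxes.tsv"),
                                header = TRUE, sep = "\t")
      conc <- utils::read.table(file.path(indir, "series_concentration.tsv"),
                                header = TRUE, sep = "\t", check.names = FALSE)
      last <- unlist(conc[nrow(conc), -1])
      outdir <- opt$out %||% indir
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      if (nrow(flux)) {
        g <- crossFeedingGraph(flux, last,
                               concThreshold =
                                 as.numeric(opt$`conc-threshold` %||% 0.1))
        writeGraph(g, file.path(outdir, "crossfeeding_edges.tsv"))
        writeGraph(g, file.path(outdir, "crossfeeding.graphml"), "graphml")
      }
      scfa <- last[names(last) %in% c("acetate", "propionate", "butyrate",
                                      "succinate")]
      if (length(scfa) && sum(scfa) > 0)
        utils::write.table(
          data.frame(scfa = names(scfa), fraction = normalizeScfa(scfa)),
          file.path(outdir, "scfa_fractions.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
      message("analysis written to ", outdir)
    },
    fixtures = {
      config <- makeScenario(opt$name %||% "pair_crossfeed")
      f <- writeScenarioFiles(config, opt$out)
      message("scenario written to ", f)
    },
    validate = {
      config <- readScenario(opt$config)
      validObject(config)
      message("scenario OK: ", length(config@species), " species, ",
              length(config@metabolites), " metabolites")
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
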