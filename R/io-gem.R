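#' @include AllClasses.R AllGenerics.R
NULL

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

stripPrefix <- function(x, prefix)
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)

## environment-metabolite name for an exchange reaction: the part after EX_
envMetaboliteOf <- function(rxnId, metId) {
  id <- stripPrefix(rxnId, "EX_")
  if (nzchar(id) && id != rxnId) sub("_e$", "", id)
  else sub("_e$", "", stripPrefix(metId, "M_"))
}

#' Read an SBML Level 3 FBC model
#'
#' Parses reactions, stoichiometry, flux bounds (resolved through the
#' fbc bound parameters), the active FBC objective, and gene-product
#' association strings. Exchange reactions are detected by the "EX_" id
#' prefix or by touching exactly one non-boundary metabolite while involving
#' a boundary-condition species; their environment metabolite id is taken
#' from the reaction id (the part after "EX_", compartment suffix stripped).
#'
#' @param path SBML file.
#' @param defaultBound bound applied, with a warning, to reactions lacking
#'   fbc bound attributes.
#' @return a \linkS4class{GEMModel}.
#' @export
readSBML <- function(path, defaultBound = 1000) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) stop("no <model> element in ", path)
  modelId <- xml2::xml_attr(model, "id")

  params <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  pval <- as.numeric(xml2::xml_attr(params, "value"))
  names(pval) <- xml2::xml_attr(params, "id")

  spNodes <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  spIds <- xml2::xml_attr(spNodes, "id")
  boundarySp <- xml2::xml_attr(spNodes, "boundaryCondition") %in%
    c("true", "1")
  names(boundarySp) <- spIds

  objNode <- xml2::xml_find_first(
    model, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(objNode, "xml_missing"))
    stop("SBML model has no FBC objective")
  objectiveRxn <- stripPrefix(xml2::xml_attr(objNode, "reaction",
                                             ns = character()), "R_")

  rxNodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  reactions <- list()
  exchangeMap <- character()
  warned <- FALSE
  for (node in rxNodes) {
    rid <- stripPrefix(xml2::xml_attr(node, "id"), "R_")
    parts <- function(which, sign) {
      refs <- xml2::xml_find_all(node, paste0("./s:", which,
                                              "/s:speciesReference"), ns)
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      keep <- !boundarySp[sp]
      stats::setNames(sign * st[keep], stripPrefix(sp[keep], "M_"))
    }
    st <- c(parts("listOfReactants", -1), parts("listOfProducts", +1))
    st <- tapply(st, names(st), sum)  # merge duplicated participants
    lbRef <- xml2::xml_attr(node, "lowerFluxBound")
    ubRef <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lbRef) && lbRef %in% names(pval)) pval[[lbRef]] else NA
    ub <- if (!is.na(ubRef) && ubRef %in% names(pval)) pval[[ubRef]] else NA
    if (is.na(lb) || is.na(ub)) {
      rev <- xml2::xml_attr(node, "reversible") %in% c("true", "1")
      if (is.na(lb)) lb <- if (rev) -defaultBound else 0
      if (is.na(ub)) ub <- defaultBound
      if (!warned) {
        warning("missing flux bounds in ", basename(path),
                "; defaults applied")
        warned <- TRUE
      }
    }
    gprNode <- xml2::xml_find_first(
      node, "./fbc:geneProductAssociation/fbc:geneProductRef", ns)
    gpr <- if (!inherits(gprNode, "xml_missing"))
      xml2::xml_attr(gprNode, "geneProduct", ns = character()) else NULL
    reactions[[rid]] <- list(id = rid, stoichiometry = st, lb = lb, ub = ub,
                             gpr = gpr)
    ## the objective (biomass drain) also touches one metabolite but is
    ## not an exchange
    isExchange <- startsWith(rid, "EX_") ||
      (length(st) == 1L && rid != objectiveRxn)
    if (isExchange && length(st) >= 1L)
      exchangeMap[rid] <- envMetaboliteOf(rid, names(st)[1])
  }
  GEMModel(modelId, unname(reactions), objectiveRxn, exchangeMap)
}

#' Write a model as SBML Level 3 FBC
#'
#' Emits the fields a \linkS4class{GEMModel} carries (stoichiometry, bound
#' parameters, active objective, single-gene GPR references); together with
#' \code{\link{readSBML}} this round-trips losslessly for those fields.
#'
#' @param model a \linkS4class{GEMModel}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSBML <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  ln <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1"',
                   ' fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model@speciesId)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="M_%s" compartment="c"',
                   ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                   ' constant="false"/>'), esc(model@mets)),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>',
            esc(model@rxns), num(model@lb)),
    sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>',
            esc(model@rxns), num(model@ub)),
    '    </listOfParameters>')
  gp <- unique(unname(model@gpr))
  if (length(gp)) {
    ln <- c(ln, '    <fbc:listOfGeneProducts>',
            sprintf(paste0('      <fbc:geneProduct fbc:id="%s"',
                           ' fbc:label="%s"/>'), esc(gp), esc(gp)),
            '    </fbc:listOfGeneProducts>')
  }
  ln <- c(ln, '    <listOfReactions>')
  for (j in seq_along(model@rxns)) {
    rid <- model@rxns[j]
    st <- model@S[, j]
    st <- st[st != 0]
    ln <- c(ln, sprintf(paste0('      <reaction id="R_%s" reversible="%s"',
                               ' fast="false" fbc:lowerFluxBound="lb_%s"',
                               ' fbc:upperFluxBound="ub_%s">'),
                        esc(rid), tolower(model@lb[j] < 0), esc(rid),
                        esc(rid)))
    if (rid %in% names(model@gpr))
      ln <- c(ln, '        <fbc:geneProductAssociation>',
              sprintf('          <fbc:geneProductRef fbc:geneProduct="%s"/>',
                      esc(model@gpr[[rid]])),
              '        </fbc:geneProductAssociation>')
    ref <- function(mets, coef)
      sprintf(paste0('          <speciesReference species="M_%s"',
                     ' stoichiometry="%s" constant="true"/>'),
              esc(mets), num(coef))
    neg <- st < 0
    if (any(neg)) ln <- c(ln, '        <listOfReactants>',
                          ref(names(st)[neg], -st[neg]),
                          '        </listOfReactants>')
    if (any(!neg)) ln <- c(ln, '        <listOfProducts>',
                           ref(names(st)[!neg], st[!neg]),
                           '        </listOfProducts>')
    ln <- c(ln, '      </reaction>')
  }
  ln <- c(ln,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf(paste0('          <fbc:fluxObjective fbc:reaction="R_%s"',
                   ' fbc:coefficient="1"/>'), esc(model@objectiveId)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(ln, path)
  invisible(path)
}

#' Read / write the plain-JSON toy-model format
#'
#' A documented JSON representation of a \linkS4class{GEMModel}: fields
#' \code{species_id}, \code{reactions} (objects with \code{id},
#' \code{stoichiometry}, \code{lb}, \code{ub}, optional \code{gpr}),
#' \code{objective_id} and \code{exchange_map}.
#'
#' @param path JSON file.
#' @return \code{readGEMJson}: a \linkS4class{GEMModel};
#'   \code{writeGEMJson}: the path, invisibly.
#' @export
readGEMJson <- function(path) {
  j <- jsonlite::read_json(path)
  need <- c("species_id", "reactions", "objective_id")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop("toy model file missing fields: ", paste(miss, collapse = ", "))
  reactions <- lapply(j$reactions, function(r)
    list(id = r$id, stoichiometry = unlist(r$stoichiometry),
         lb = r$lb, ub = r$ub, gpr = r$gpr))
  GEMModel(j$species_id, reactions, j$objective_id,
           unlist(j$exchange_map) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param model a \linkS4class{GEMModel}.
#' @rdname readGEMJson
#' @export
writeGEMJson <- function(model, path) {
  reactions <- lapply(seq_along(model@rxns), function(j) {
    st <- model@S[, j]
    st <- st[st != 0]
    r <- list(id = model@rxns[j], stoichiometry = as.list(st),
              lb = model@lb[j], ub = model@ub[j])
    if (model@rxns[j] %in% names(model@gpr))
      r$gpr <- unname(model@gpr[[model@rxns[j]]])
    r
  })
  jsonlite::write_json(
    list(species_id = model@speciesId, reactions = reactions,
         objective_id = model@objectiveId,
         exchange_map = as.list(model@exchangeMap)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
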