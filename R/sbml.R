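## SBML Level 3 export / import of the model specification
##
## The document carries the nine dynamic species, every rate constant, total
## and kinase activity as parameters, the 21 mass-action reactions with
## explicit MathML kinetic laws, assignment rules for the free pools and the
## pMELTtot readout, and the variant flags in a package annotation namespace.

KP_NS <- "https://kinetophos.invalid/sbml"

sbml_reactions <- function() {
  # reactants/products as named stoichiometries over species ids; modifiers
  # enter the rate law only.  Rate = product of `rate` ids (parameters,
  # species, or free-pool rule targets).
  list(
    list(id = "pp1_bind",    rate = c("kbPP1", "RVSFfree", "PP1free"),  d = c(PP1act = 1)),
    list(id = "pp1_release", rate = c("kdPP1", "PP1act"),               d = c(PP1act = -1)),
    list(id = "pp2a_bind_cplx", rate = c("kbPP2A", "pMELT_pBUBR1", "PP2Afree"),
         d = c(PP2Aact = 1, pMELT_pBUBR1 = -1)),
    list(id = "pp2a_release_cplx", rate = c("kdPP2A", "PP2Aact"),
         d = c(PP2Aact = -1, pMELT_pBUBR1 = 1)),
    list(id = "precplx_bind_pmelt", rate = c("kbBUBR1", "pBUBR1_PP2A", "pMELT"),
         d = c(PP2Aact = 1, pBUBR1_PP2A = -1, pMELT = -1)),
    list(id = "cplx_release_bubr1", rate = c("kdBUBR1", "PP2Aact"),
         d = c(PP2Aact = -1, pMELT = 1, pBUBR1_PP2A = 1)),
    list(id = "pp2a_bind_pbubr1", rate = c("kbPP2A", "pBUBR1free", "PP2Afree"),
         d = c(pBUBR1free = -1, pBUBR1_PP2A = 1)),
    list(id = "pp2a_release_pbubr1", rate = c("kdPP2A", "pBUBR1_PP2A"),
         d = c(pBUBR1_PP2A = -1, pBUBR1free = 1)),
    list(id = "bubr1_phos_free", rate = c("kpBUBR1_free", "BUBR1free", "CDK1"),
         d = c(pBUBR1free = 1)),
    list(id = "pbubr1_bind_pmelt", rate = c("kbBUBR1", "pBUBR1free", "pMELT"),
         d = c(pBUBR1free = -1, pMELT = -1, pMELT_pBUBR1 = 1)),
    list(id = "pbubr1_release", rate = c("kdBUBR1", "pMELT_pBUBR1"),
         d = c(pMELT_pBUBR1 = -1, pMELT = 1, pBUBR1free = 1)),
    list(id = "bubr1_bind_pmelt", rate = c("kbBUBR1", "BUBR1free", "pMELT"),
         d = c(pMELT = -1, pMELT_BUBR1 = 1)),
    list(id = "bubr1_release", rate = c("kdBUBR1", "pMELT_BUBR1"),
         d = c(pMELT_BUBR1 = -1, pMELT = 1)),
    list(id = "melt_phos", rate = c("kpMELT", "MELTfree", "MPS1"),
         d = c(pMELT = 1)),
    list(id = "melt_dephos", rate = c("kdpMELT", "pMELT", "PPact"),
         d = c(pMELT = -1)),
    list(id = "bubr1_phos_cplx", rate = c("kpBUBR1", "pMELT_BUBR1", "CDK1"),
         d = c(pMELT_BUBR1 = -1, pMELT_pBUBR1 = 1)),
    list(id = "bubr1_dephos_cplx", rate = c("kdpBUBR1", "pMELT_pBUBR1", "PPact"),
         d = c(pMELT_pBUBR1 = -1, pMELT_BUBR1 = 1)),
    list(id = "rvsf_phos", rate = c("kpRVSF", "RVSFfree", "AurB"),
         d = c(pRVSF = 1)),
    list(id = "rvsf_dephos", rate = c("kdpRVSF", "pRVSF", "PPact"),
         d = c(pRVSF = -1)),
    list(id = "ndc80_phos", rate = c("kpNDC80", "NDC80free", "AurB"),
         d = c(pNDC80 = 1)),
    list(id = "ndc80_dephos", rate = c("kdpNDC80", "pNDC80", "PPact"),
         d = c(pNDC80 = -1))
  )
}

mathml_times <- function(ids) {
  inner <- paste0("<ci> ", ids, " </ci>", collapse = "")
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
         "<apply><times/>", inner, "</apply></math>")
}

#' Export a model specification as SBML Level 3
#'
#' Writes species, parameters (rates, totals, kinase activities), the full
#' mass-action reaction list with MathML kinetic laws, assignment rules for
#' the conservation-derived free pools, the pooled phosphatase activity and
#' the pMELTtot readout, plus the variant as an annotation.
#'
#' @param spec A `kp_model`.
#' @param path Output file.
#' @param initial Initial species amounts (default all zero).
#' @return The path, invisibly.
#' @export
export_sbml <- function(spec, path, initial = network_state()) {
  stopifnot(inherits(spec, "kp_model"))
  v <- spec$variant
  num <- function(x) formatC(x, format = "g", digits = 17)

  species <- paste0(
    '      <species id="', species_names(), '" compartment="kt" ',
    'initialAmount="', num(initial[species_names()]),
    '" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
    collapse = "\n")

  pars <- c(spec$params, spec$totals, spec$kinases)
  parameters <- paste0(
    '      <parameter id="', names(pars), '" value="', num(pars),
    '" constant="true"/>', collapse = "\n")
  rule_targets <- c("PP1free", "PP2Afree", "BUBR1free", "MELTfree",
                    "RVSFfree", "NDC80free", "PPact", "pMELTtot")
  rule_pars <- paste0('      <parameter id="', rule_targets,
                      '" value="0" constant="false"/>', collapse = "\n")

  minus <- function(tot, terms) {
    paste0("<apply><minus/><ci> ", tot, " </ci><apply><plus/>",
           paste0("<ci> ", terms, " </ci>", collapse = ""),
           "</apply></apply>")
  }
  rules_math <- c(
    PP1free  = minus("PP1tot", "PP1act"),
    PP2Afree = minus("PP2Atot", c("PP2Aact", "pBUBR1_PP2A")),
    BUBR1free = minus("BUBR1tot", c("pBUBR1free", "pMELT_BUBR1",
                                    "pMELT_pBUBR1", "pBUBR1_PP2A", "PP2Aact")),
    MELTfree = minus("MELTtot", c("pMELT", "pMELT_BUBR1", "pMELT_pBUBR1",
                                  "PP2Aact")),
    RVSFfree = minus("RVSFtot", c("pRVSF", "PP1act")),
    NDC80free = minus("NDC80tot", "pNDC80"),
    PPact = paste0("<apply><plus/><ci> PP1act </ci><ci> PP2Aact </ci></apply>"),
    pMELTtot = paste0("<apply><plus/><ci> pMELT </ci><ci> pMELT_BUBR1 </ci>",
                      "<ci> pMELT_pBUBR1 </ci><ci> PP2Aact </ci></apply>")
  )
  rules <- paste0(
    '      <assignmentRule variable="', names(rules_math), '">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">', rules_math,
    "</math></assignmentRule>", collapse = "\n")

  rxn_xml <- vapply(sbml_reactions(), function(r) {
    d <- r$d
    reac <- names(d)[d < 0]; prod <- names(d)[d > 0]
    sr <- function(ids, side)
      if (!length(ids)) "" else paste0(
        "        <listOf", side, "s>\n",
        paste0('          <speciesReference species="', ids,
               '" stoichiometry="1" constant="true"/>', collapse = "\n"),
        "\n        </listOf", side, "s>\n")
    mods <- setdiff(intersect(r$rate, species_names()), c(reac, prod))
    mod <- if (!length(mods)) "" else paste0(
      "        <listOfModifiers>\n",
      paste0('          <modifierSpeciesReference species="', mods, '"/>',
             collapse = "\n"),
      "\n        </listOfModifiers>\n")
    paste0('      <reaction id="', r$id, '" reversible="false">\n',
           sr(reac, "Reactant"), sr(prod, "Product"), mod,
           "        <kineticLaw>", mathml_times(r$rate), "</kineticLaw>\n",
           "      </reaction>")
  }, character(1))

  ann <- paste0(
    '    <annotation><kp:variant xmlns:kp="', KP_NS, '" label="', v$label,
    '" catalyticallyDeadPP2A="', tolower(v$catalytically_dead_pp2a),
    '" clampedPP2Aact="',
    if (is.null(v$clamped_PP2Aact)) "" else num(v$clamped_PP2Aact), '"',
    if (length(v$totals_overrides)) paste0(' totalsOverrides="',
      paste(names(v$totals_overrides), v$totals_overrides, sep = "=",
            collapse = ";"), '"') else "",
    if (length(v$param_overrides)) paste0(' paramOverrides="',
      paste(names(v$param_overrides), num(v$param_overrides), sep = "=",
            collapse = ";"), '"') else "",
    "/></annotation>")

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
    '  <model id="kinetophos_network" name="Kinetochore phosphatase network">\n',
    ann, "\n",
    "    <listOfCompartments>\n",
    '      <compartment id="kt" spatialDimensions="3" size="1" constant="true"/>\n',
    "    </listOfCompartments>\n",
    "    <listOfSpecies>\n", species, "\n    </listOfSpecies>\n",
    "    <listOfParameters>\n", parameters, "\n", rule_pars,
    "\n    </listOfParameters>\n",
    "    <listOfRules>\n", rules, "\n    </listOfRules>\n",
    "    <listOfReactions>\n", paste(rxn_xml, collapse = "\n"),
    "\n    </listOfReactions>\n",
    "  </model>\n</sbml>\n")
  # validate well-formedness before writing
  xml2::read_xml(doc)
  writeLines(doc, path)
  invisible(path)
}

#' Import a model specification from SBML written by [export_sbml()]
#'
#' Parameters, totals and kinase activities are read back bit-exactly; the
#' variant is reconstructed from the annotation.  A document lacking any of
#' the nine dynamic species is rejected with the species named.
#'
#' @param path SBML file.
#' @return A `kp_model`.
#' @export
import_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML: ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  ids <- xml2::xml_attr(sp, "id")
  missing <- setdiff(species_names(), ids)
  if (length(missing))
    stop("SBML model at listOfSpecies is missing species: ",
         paste(missing, collapse = ", "), call. = FALSE)

  pn <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  vals <- stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                          xml2::xml_attr(pn, "id"))
  need <- c(parameter_names(), total_names(), kinase_names())
  miss <- setdiff(need, names(vals))
  if (length(miss))
    stop("SBML model at listOfParameters is missing: ",
         paste(miss, collapse = ", "), call. = FALSE)

  va <- xml2::xml_find_first(doc, ".//*[local-name() = 'variant']")
  variant <- make_variant("WT")
  if (!inherits(va, "xml_missing")) {
    parse_kv <- function(s) {
      if (is.na(s) || !nzchar(s)) return(numeric())
      kv <- strsplit(strsplit(s, ";")[[1L]], "=")
      stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                      vapply(kv, `[`, "", 1L))
    }
    clamp <- xml2::xml_attr(va, "clampedPP2Aact")
    variant <- model_variant(
      label = xml2::xml_attr(va, "label"),
      totals_overrides = parse_kv(xml2::xml_attr(va, "totalsOverrides")),
      param_overrides = parse_kv(xml2::xml_attr(va, "paramOverrides")),
      catalytically_dead_pp2a =
        identical(xml2::xml_attr(va, "catalyticallyDeadPP2A"), "true"),
      clamped_PP2Aact = if (is.na(clamp) || !nzchar(clamp)) NULL
                        else as.numeric(clamp))
  }
  model_spec(params = vals[parameter_names()], totals = vals[total_names()],
             kinases = vals[kinase_names()], variant = variant)
}
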