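## Minimal SBML (Level 3 Version 1) serialization of the minimal coupled
## model, for interoperability with standard simulators. This is a purposely
## small writer/reader covering exactly this model family: species with
## initial concentrations, global parameters, reactions with MathML kinetic
## laws generated from R expression trees. It is not a general SBML engine.

## R expression -> MathML node list (content MathML).
expr_to_mathml <- function(e, doc) {
  build <- function(e) {
    if (is.numeric(e)) return(paste0("<cn>", format(e, digits = 15), "</cn>"))
    if (is.name(e)) return(paste0("<ci>", as.character(e), "</ci>"))
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      args <- lapply(as.list(e)[-1L], build)
      if (op == "(") return(args[[1L]])
      tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                    "/" = "divide", "^" = "power",
                    stop("unsupported operator in kinetic law: ", op))
      return(paste0("<apply><", tag, "/>",
                    paste(unlist(args), collapse = ""), "</apply>"))
    }
    stop("unsupported kinetic-law expression element")
  }
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
         build(e), "</math>")
}

## Kinetic-law expressions of the minimal model, referencing global
## parameter ids.
minimal_model_expressions <- function(model) {
  pgi <- quote(
    pgi_vf * (G6P / pgi_k_G6P - F6P / (pgi_k_G6P * pgi_keq)) *
      (G6P / pgi_k_G6P + F6P / pgi_k_F6P)^(pgi_h - 1) /
      (1 + (G6P / pgi_k_G6P + F6P / pgi_k_F6P)^pgi_h))
  pfk <- quote(
    pfk_vf * ((F6P / pfk_k_F6P)^pfk_h * (ATP_eff / pfk_k_ATP)^pfk_h) /
      ((1 + (PEP / pfk_k_PEP)^pfk_h) / (1 + pfk_alpha * (PEP / pfk_k_PEP)^pfk_h) +
         (F6P / pfk_k_F6P)^pfk_h + (ATP_eff / pfk_k_ATP)^pfk_h +
         (F6P / pfk_k_F6P)^pfk_h * (ATP_eff / pfk_k_ATP)^pfk_h))
  # ATP_eff is MgATP (total ATP times the rapid-equilibrium Mg-bound
  # fraction) or the total pool, fixed at export time:
  atp_eff <- if (model$atp_species == "MgATP") quote(ATP * mgatp_frac)
             else quote(ATP)
  pfk <- eval(call("substitute", pfk, list(ATP_eff = atp_eff)))
  hyd <- if (model$hydrolysis == "mgatp") quote(k_hyd * ATP * mgatp_frac)
         else quote(k_hyd * ADP * mgadp_frac)
  list(PGI = pgi, PFK = pfk, HYD = hyd)
}

#' Export the minimal model as SBML
#'
#' Writes an SBML L3V1 document with the model's species (initial
#' concentrations from `y0`), global parameters and the three reactions
#' (PGI, PFK, background hydrolysis) with MathML kinetic laws. The
#' rapid-equilibrium Mg speciation is folded into constant Mg-bound
#' fractions (`mgatp_frac`, `mgadp_frac`), exactly as the model evaluates
#' them with clamped free Mg2+.
#'
#' @param model a [minimal_model()].
#' @param y0 named initial concentrations, mM.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, y0, path) {
  stopifnot(inherits(model, "minimal_model"))
  full0 <- stats::setNames(rep(0, length(model$species)), model$species)
  full0[names(y0)] <- y0
  fa <- (model$K_mgatp / 1000) * model$free_mg
  fd <- (model$K_mgadp / 1000) * model$free_mg
  pars <- c(pgi_vf = vf_volumetric(model$pgi),
            pgi_k_G6P = model$pgi$half_sat[[1L]],
            pgi_k_F6P = model$pgi$half_sat[[2L]],
            pgi_h = model$pgi$h, pgi_keq = model$pgi$keq,
            pfk_vf = vf_volumetric(model$pfk),
            pfk_k_F6P = model$pfk$half_sat[[1L]],
            pfk_k_ATP = model$pfk$half_sat[[2L]],
            pfk_k_PEP = model$pfk$half_sat[[3L]],
            pfk_h = model$pfk$h, pfk_alpha = model$pfk$alpha,
            k_hyd = model$k_hyd, free_mg = model$free_mg,
            K_mgatp = model$K_mgatp, K_mgadp = model$K_mgadp,
            mgatp_frac = fa / (1 + fa), mgadp_frac = fd / (1 + fd))
  exprs <- minimal_model_expressions(model)
  rxn <- list(
    PGI = list(reactants = "G6P", products = "F6P", modifiers = character(),
               reversible = "true"),
    PFK = list(reactants = c("F6P", "ATP"), products = c("FBP", "ADP"),
               modifiers = "PEP", reversible = "false"),
    HYD = list(reactants = "ADP", products = c("AMP", "Pi"),
               modifiers = if (model$hydrolysis == "mgatp") "ATP"
                           else character(),
               reversible = "false"))

  sp_xml <- paste(sprintf(
    '<species id="%s" compartment="cell" initialConcentration="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    names(full0), format(full0, digits = 15)), collapse = "\n      ")
  par_xml <- paste(sprintf(
    '<parameter id="%s" value="%s" constant="true"/>',
    names(pars), format(unname(pars), digits = 15)), collapse = "\n      ")
  refs <- function(ids, tag)
    if (!length(ids)) "" else paste0(
      "<listOf", tag, "s>",
      paste(sprintf(
        if (tag == "Modifier")
          '<modifierSpeciesReference species="%s"/>'
        else
          '<speciesReference species="%s" stoichiometry="1" constant="true"/>',
        ids), collapse = ""),
      "</listOf", tag, "s>")
  rxn_xml <- paste(vapply(names(rxn), function(id) {
    r <- rxn[[id]]
    paste0('<reaction id="', id, '" reversible="', r$reversible,
           '" fast="false">',
           refs(r$reactants, "Reactant"), refs(r$products, "Product"),
           refs(r$modifiers, "Modifier"),
           "<kineticLaw>", expr_to_mathml(exprs[[id]]), "</kineticLaw>",
           "</reaction>")
  }, ""), collapse = "\n      ")

  doc <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="minimal_pgi_pfk" name="Minimal coupled PGI-PFK model" substanceUnits="millimole" timeUnits="minute" extentUnits="millimole">
    <annotation>
      <nmrkin xmlns="https://nmrkin.invalid/sbml" hydrolysis="%s" atp_species="%s"/>
    </annotation>
    <listOfCompartments>
      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      %s
    </listOfSpecies>
    <listOfParameters>
      %s
    </listOfParameters>
    <listOfReactions>
      %s
    </listOfReactions>
  </model>
</sbml>', model$hydrolysis, model$atp_species, sp_xml, par_xml, rxn_xml)
  xml2::write_xml(xml2::read_xml(doc), path)  # validates well-formedness
  invisible(path)
}

#' Import a minimal model from SBML written by [write_sbml()]
#'
#' Reads back species initial concentrations and global parameters and
#' reconstructs the [minimal_model()] (the kinetic-law algebra is fixed by
#' the model family; the annotation records the hydrolysis and ATP-pool
#' conventions).
#'
#' @param path SBML file from [write_sbml()].
#' @return List with `model` (a `minimal_model`) and `y0` (named vector).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  y0 <- stats::setNames(
    as.numeric(xml2::xml_attr(sp, "initialConcentration")),
    xml2::xml_attr(sp, "id"))
  pr <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(pr, "value")),
                          xml2::xml_attr(pr, "id"))
  ann <- xml2::xml_find_first(doc, ".//*[local-name()='nmrkin']")
  hyd <- xml2::xml_attr(ann, "hydrolysis")
  atp <- xml2::xml_attr(ann, "atp_species")
  pgi <- rate_law_params(
    vf = pars[["pgi_vf"]],
    half_sat = c(G6P = pars[["pgi_k_G6P"]], F6P = pars[["pgi_k_F6P"]]),
    h = pars[["pgi_h"]], keq = pars[["pgi_keq"]])
  pfk <- rate_law_params(
    vf = pars[["pfk_vf"]],
    half_sat = c(F6P = pars[["pfk_k_F6P"]], ATP = pars[["pfk_k_ATP"]],
                 PEP = pars[["pfk_k_PEP"]]),
    h = pars[["pfk_h"]], alpha = pars[["pfk_alpha"]])
  model <- minimal_model(pgi = pgi, pfk = pfk,
                         K_mgatp = pars[["K_mgatp"]],
                         K_mgadp = pars[["K_mgadp"]],
                         free_mg = pars[["free_mg"]],
                         k_hyd = pars[["k_hyd"]],
                         hydrolysis = if (is.na(hyd)) "mgatp" else hyd,
                         atp_species = if (is.na(atp)) "MgATP" else atp)
  list(model = model, y0 = y0)
}
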