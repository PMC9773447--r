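# Model serialisation: SBML Level 3 and a human-readable reaction list.

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

mathml_times <- function(const, species) {
  cn <- sprintf("<cn> %.12g </cn>", const)
  if (!length(species)) {
    return(paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
                  cn, "</math>"))
  }
  cis <- paste(sprintf("<ci> %s </ci>", sbml_id(species)), collapse = " ")
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         "<apply><times/>", cn, " ", cis, "</apply></math>")
}

sbml_reaction <- function(id, reactants, products, math) {
  ref <- function(tag, sp) {
    if (!length(sp)) return("")
    paste0("<listOf", tag, "s>",
           paste(sprintf("<speciesReference species=\"%s\" stoichiometry=\"1\" constant=\"true\"/>",
                         vapply(sp, sbml_id, "")), collapse = ""),
           "</listOf", tag, "s>")
  }
  paste0("<reaction id=\"", sbml_id(id), "\" reversible=\"false\">",
         ref("Reactant", reactants), ref("Product", products),
         "<kineticLaw>", math, "</kineticLaw></reaction>")
}

# the model's reactions as a list of (id, reactants, products, rate
# description) rows; shared by both exporters
model_reaction_list <- function(model) {
  p <- model$params
  out <- list()
  for (cc in model$categories) {
    uf <- paste0("UF.", cc); mfp <- paste0("MFP.", cc); fp <- paste0("FP.", cc)
    out[[paste0("R1_", cc)]] <- list(
      reactants = character(), products = uf,
      const = p$v_syn[[cc]], species = character(),
      text = sprintf("-> %s  @ v_syn = %.4g", uf, p$v_syn[[cc]]))
    if (p$p_correct[[cc]] > 0) {
      out[[paste0("R4_", cc)]] <- list(
        reactants = c(uf, "DsbAo"), products = c(fp, "DsbAr"),
        const = p$p_correct[[cc]] * p$k45[[cc]], species = c(uf, "DsbAo"),
        text = sprintf("%s + DsbAo -> %s + DsbAr  @ %.4g * %s * DsbAo",
                       uf, fp, p$p_correct[[cc]] * p$k45[[cc]], uf))
    }
    if (p$p_correct[[cc]] < 1) {
      out[[paste0("R5_", cc)]] <- list(
        reactants = c(uf, "DsbAo"), products = c(mfp, "DsbAr"),
        const = (1 - p$p_correct[[cc]]) * p$k45[[cc]], species = c(uf, "DsbAo"),
        text = sprintf("%s + DsbAo -> %s + DsbAr  @ %.4g * %s * DsbAo",
                       uf, mfp, (1 - p$p_correct[[cc]]) * p$k45[[cc]], uf))
      out[[paste0("R6_", cc)]] <- list(
        reactants = c(mfp, "DsbCGr"), products = c(fp, "DsbCGr"),
        const = p$f_success * p$k678[[cc]], species = c(mfp, "DsbCGr"),
        text = sprintf("%s + DsbCGr -> %s + DsbCGr  @ %.4g * %s * DsbCGr",
                       mfp, fp, p$f_success * p$k678[[cc]], mfp))
      out[[paste0("R7_", cc)]] <- list(
        reactants = c(mfp, "DsbCGr"), products = c(mfp, "DsbCGr"),
        const = p$f_futile * p$k678[[cc]], species = c(mfp, "DsbCGr"),
        text = sprintf("%s + DsbCGr -> %s + DsbCGr (futile)  @ %.4g * %s * DsbCGr",
                       mfp, mfp, p$f_futile * p$k678[[cc]], mfp))
      out[[paste0("R8_", cc)]] <- list(
        reactants = c(mfp, "DsbCGr"), products = c(uf, "DsbCGo"),
        const = p$f_reduce * p$k678[[cc]], species = c(mfp, "DsbCGr"),
        text = sprintf("%s + DsbCGr -> %s + DsbCGo  @ %.4g * %s * DsbCGr",
                       mfp, uf, p$f_reduce * p$k678[[cc]], mfp))
    }
  }
  out$R2 <- list(reactants = "DsbBr", products = "DsbBo",
                 const = p$k2, species = "DsbBr",
                 text = sprintf("DsbBr -> DsbBo (quinone clamped)  @ %.4g * DsbBr", p$k2))
  out$R3 <- list(reactants = c("DsbAr", "DsbBo"), products = c("DsbAo", "DsbBr"),
                 const = p$k3, species = c("DsbAr", "DsbBo"),
                 text = sprintf("DsbAr + DsbBo -> DsbAo + DsbBr  @ %.4g * DsbAr * DsbBo", p$k3))
  out$R9 <- list(reactants = c("DsbCGo", "DsbDr"), products = c("DsbCGr", "DsbDo"),
                 const = p$k9, species = c("DsbCGo", "DsbDr"),
                 text = sprintf("DsbCGo + DsbDr -> DsbCGr + DsbDo  @ %.4g * DsbCGo * DsbDr", p$k9))
  out$R10 <- list(reactants = "DsbDo", products = "DsbDr",
                  const = p$k10, species = "DsbDo",
                  text = sprintf("DsbDo -> DsbDr (thioredoxin clamped)  @ %.4g * DsbDo", p$k10))
  out
}

#' Export the model as SBML Level 3
#'
#' Serialises the reaction network (with branch reactions written out
#' explicitly, including the futile cycle) as SBML Level 3 Version 1 with
#' mass-action kinetic laws in substance units of molecules.
#'
#' @param model A `dsb_model`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_sbml <- function(model, path) {
  stopifnot(inherits(model, "dsb_model"))
  species <- vapply(model$species, function(s) {
    sprintf(paste0("<species id=\"%s\" compartment=\"periplasm\" ",
                   "initialAmount=\"%.12g\" hasOnlySubstanceUnits=\"true\" ",
                   "boundaryCondition=\"false\" constant=\"false\"/>"),
            sbml_id(s), model$initial[[s]])
  }, "")
  rl <- model_reaction_list(model)
  reactions <- vapply(names(rl), function(id) {
    r <- rl[[id]]
    math <- if (length(r$species)) mathml_times(r$const, r$species)
            else mathml_times(r$const, character())
    sbml_reaction(id, r$reactants, r$products, math)
  }, "")
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" level=\"3\" version=\"1\">\n",
    "<model id=\"oxidative_folding\" name=\"E. coli periplasmic oxidative folding\">\n",
    "<listOfCompartments><compartment id=\"periplasm\" spatialDimensions=\"3\" size=\"1\" constant=\"true\"/></listOfCompartments>\n",
    "<listOfSpecies>", paste(species, collapse = "\n"), "</listOfSpecies>\n",
    "<listOfReactions>", paste(reactions, collapse = "\n"), "</listOfReactions>\n",
    "</model>\n</sbml>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Export the model as a human-readable reaction list
#'
#' @param model A `dsb_model`.
#' @param path Optional output path; if `NULL` the lines are returned.
#' @return Character vector of reaction lines (invisibly if written).
#' @export
export_reaction_list <- function(model, path = NULL) {
  stopifnot(inherits(model, "dsb_model"))
  rl <- model_reaction_list(model)
  lines <- sprintf("%-8s %s", names(rl), vapply(rl, `[[`, "", "text"))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write a trajectory as TSV
#' @param traj A `dsb_trajectory`.
#' @param path Output path.
#' @param fluxes Include per-reaction fluxes alongside species.
#' @export
write_trajectory <- function(traj, path, fluxes = FALSE) {
  stopifnot(inherits(traj, "dsb_trajectory"))
  tab <- data.frame(time = traj$time, traj$state, check.names = FALSE)
  if (fluxes) tab <- cbind(tab, traj$fluxes)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
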