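#' Read / write sensor time-course tables
#'
#' The CSV dialect shared by the simulator, the puncta pipeline and the
#' fitting stage: columns `condition_id`, `time_h`, `AP`, `AL` and
#' optionally `AP_sd`, `AL_sd`.
#'
#' @param path CSV file path.
#' @return `read_timecourses()`: a data frame.
#' @export
read_timecourses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("condition_id", "time_h", "AP", "AL")
  if (!all(needed %in% names(df)))
    stop("time-course CSV needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_timecourses
#' @param observations Data frame in the time-course dialect.
#' @export
write_timecourses <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a perturbation design matrix
#'
#' `condition_id` plus one 0/1 activity column per agent.
#'
#' @param path CSV file path.
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"condition_id" %in% names(df))
    stop("design CSV needs a condition_id column", call. = FALSE)
  df
}

#' @rdname read_design
#' @param design Design data frame.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' Serialise agent libraries and hypothesis families as YAML
#'
#' The library is written as one entry per agent listing its
#' (target, direction, strength) assignments; a hypothesis family as the
#' list of canonical ids with their per-drug modes.
#'
#' @param library A [modifier_table()].
#' @param path Output `.yaml` path.
#' @export
write_agent_library <- function(library, path) {
  validate_modifiers(library)
  out <- lapply(split(library, library$agent), function(rows) {
    lapply(seq_len(nrow(rows)), function(i)
      list(target = rows$target[i], direction = rows$direction[i],
           strength = if (is.na(rows$strength[i])) "free"
                      else rows$strength[i]))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_agent_library
#' @export
read_agent_library <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(names(raw), function(agent) {
    do.call(rbind, lapply(raw[[agent]], function(a)
      data.frame(agent = agent, target = a$target, direction = a$direction,
                 strength = if (identical(a$strength, "free")) NA_real_
                            else as.numeric(a$strength))))
  }))
  modifier_table(rows$agent, rows$target, rows$direction, rows$strength)
}

#' @rdname write_agent_library
#' @param hypotheses List of [mode_hypothesis()] objects.
#' @export
write_hypotheses <- function(hypotheses, path) {
  yaml::write_yaml(lapply(hypotheses, function(h)
    list(id = h$id, modes = as.list(h$modes))), path)
  invisible(path)
}

#' Write a fit report as JSON
#'
#' @param fit A `flux_fit` object.
#' @param path Output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(list(hypothesis_id = fit$hypothesis_id,
                            parameters = as.list(fit$par),
                            objective = fit$objective,
                            n_free_params = fit$n_free,
                            converged = fit$converged,
                            rng_seed = fit$seed,
                            iterations_used = fit$iterations),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a hypothesis ranking as CSV
#'
#' @param ranking A `flux_ranking` object.
#' @param path Output CSV path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.csv(ranking$table, path, row.names = FALSE)
  invisible(path)
}

#' Read / write 16-bit single-channel TIFF images
#'
#' Thin wrappers over EBImage; pixel values are photon-count-scale integers
#' (0..65535).
#'
#' @param path TIFF file path.
#' @return `read_channel_tiff()`: numeric matrix of counts.
#' @export
read_channel_tiff <- function(path) {
  img <- EBImage::readImage(path)
  round(as_matrix_image(img) * 65535)
}

#' @rdname read_channel_tiff
#' @param img Numeric matrix of counts in 0..65535.
#' @export
write_channel_tiff <- function(img, path) {
  EBImage::writeImage(EBImage::Image(img / 65535), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Export a concrete model instance as SBML Level 3
#'
#' Writes the single-compartment mass-action model (species AP, AL, SINK;
#' reactions formation, conversion, degradation with the effective rate
#' constants under the supplied activity vector) for interoperability with
#' COPASI-class tools. Requires the suggested package `xml2`.
#'
#' @param params A [flux_params()] vector.
#' @param path Output `.xml` path.
#' @param modifiers,activity Optional perturbation (see
#'   [effective_rates()]).
#' @export
export_sbml <- function(params, path, modifiers = NULL, activity = NULL) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("export_sbml requires the 'xml2' package", call. = FALSE)
  r <- effective_rates(params, modifiers, activity)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "autophagic_flux")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in c("AP", "AL", "SINK"))
    xml2::xml_add_child(sps, "species", id = s, compartment = "cell",
                        initialAmount = "0", hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in names(r))
    xml2::xml_add_child(pars, "parameter", id = nm,
                        value = format(r[[nm]], digits = 15),
                        constant = "true")
  rxns <- xml2::xml_add_child(model, "listOfReactions")
  add_rxn <- function(id, reactants, products, law) {
    rx <- xml2::xml_add_child(rxns, "reaction", id = id, reversible = "false")
    if (length(reactants)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in reactants)
        xml2::xml_add_child(lr, "speciesReference", species = s,
                            stoichiometry = "1", constant = "true")
    }
    lp <- xml2::xml_add_child(rx, "listOfProducts")
    for (s in products)
      xml2::xml_add_child(lp, "speciesReference", species = s,
                          stoichiometry = "1", constant = "true")
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    if (length(law) == 1) {
      xml2::xml_add_child(math, "ci", law)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (ci in law) xml2::xml_add_child(ap, "ci", ci)
    }
  }
  add_rxn("formation", character(0), "AP", "r_form")
  add_rxn("conversion", "AP", "AL", c("r_conv", "AP"))
  add_rxn("degradation", "AL", "SINK", c("r_deg", "AL"))
  xml2::write_xml(doc, path)
  invisible(path)
}
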