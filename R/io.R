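## Formats: CSV measurement tables, declarative YAML model files, and
## SBML Level 2 Version 4 export/import.

#' Write a measurement dataset as CSV
#'
#' Comma-separated, header row, UTF-8, '.' decimal.
#'
#' @param dataset data frame (an \code{egfr_dataset} or measurement table).
#' @param path output file.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
}

#' Read and validate a measurement dataset
#'
#' Accepts either the replicate-level table written by
#' \code{write_dataset} or a collapsed measurement table.  Malformed rows
#' are reported with their line numbers.
#'
#' @param path CSV file.
#' @return Validated data frame.
#' @export
read_dataset <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "protein", "dose", "time", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  num_cols <- intersect(c("dose", "time", "value", "raw", "replicate"),
                        names(tab))
  for (cl in num_cols) {
    v <- tab[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("non-numeric '%s' at line(s) %s", cl,
                     paste(bad + 1L, collapse = ", ")))
      tab[[cl]] <- conv
    }
  }
  bad_dose <- which(!is.na(tab$dose) & tab$dose < 0)
  if (length(bad_dose))
    stop("negative dose at line(s) ", paste(bad_dose + 1L, collapse = ", "))
  bad_t <- which(!is.na(tab$time) & tab$time < 0)
  if (length(bad_t))
    stop("negative time at line(s) ", paste(bad_t + 1L, collapse = ", "))
  keycols <- intersect(c("cell_line", "protein", "dose", "time",
                         "replicate"), names(tab))
  key <- do.call(paste, c(tab[keycols], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated measurement key at line(s) ",
         paste(dup + 1L, collapse = ", "))
  tab
}

## ---- declarative YAML model files -------------------------------------

#' Write a network (with variants) to a declarative YAML model file
#'
#' The file round-trips losslessly through \code{read_network_yaml}.
#'
#' @param network an \code{egfr_network}.
#' @param path output file.
#' @param variant_settings optional named list of variant settings to
#'   embed.
#' @export
write_network_yaml <- function(network, path, variant_settings = NULL) {
  sp <- network$species
  doc <- list(
    species = lapply(seq_len(nrow(sp)), function(i) list(
      id = sp$id[i], display_name = sp$display_name[i],
      initial_concentration = sp$initial_concentration[i],
      is_dynamic = sp$is_dynamic[i])),
    reactions = lapply(network$reactions, function(r) {
      out <- list(step = r$step, law = r$law,
                  reactants = as.list(r$reactants),
                  products = as.list(r$products),
                  params = as.list(r$params))
      if (!is.null(r$modifier)) out$modifier <- r$modifier
      out
    }),
    parameters = list(values = as.list(network$parameters$values),
                      bounds = lapply(seq_len(nrow(network$parameters$bounds)),
                        function(i) as.list(network$parameters$bounds[i, ]))),
    reference_topology = isTRUE(attr(network, "reference_topology")))
  names(doc$parameters$bounds) <- rownames(network$parameters$bounds)
  if (!is.null(variant_settings))
    doc$variants <- lapply(variant_settings, function(s) list(
      initial_overrides = as.list(s$initial_overrides %||% numeric(0)),
      parameter_multipliers = as.list(s$parameter_multipliers %||%
                                        numeric(0))))
  yaml::write_yaml(doc, path)
}

#' Read a network from a declarative YAML model file
#'
#' @param path YAML file written by \code{write_network_yaml} (or hand
#'   authored with the same schema).
#' @return List with elements \code{network} and (possibly NULL)
#'   \code{variant_settings}.
#' @export
read_network_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  sp <- do.call(rbind, lapply(doc$species, function(s)
    data.frame(id = s$id, display_name = s$display_name,
               initial_concentration = s$initial_concentration,
               is_dynamic = s$is_dynamic, stringsAsFactors = FALSE)))
  rx <- lapply(doc$reactions, function(r)
    .reaction(r$step, r$law, unlist(r$reactants), unlist(r$products),
              unlist(r$params), modifier = r$modifier))
  vals <- unlist(doc$parameters$values)
  bounds <- do.call(rbind, lapply(doc$parameters$bounds, unlist))
  ps <- parameter_set(vals, bounds)
  net <- structure(list(species = sp, reactions = rx, parameters = ps),
                   class = "egfr_network")
  attr(net, "reference_topology") <- isTRUE(doc$reference_topology)
  validate_network(net)
  vs <- NULL
  if (!is.null(doc$variants))
    vs <- lapply(doc$variants, function(s) list(
      initial_overrides = unlist(s$initial_overrides) %||% numeric(0),
      parameter_multipliers = unlist(s$parameter_multipliers) %||%
        numeric(0)))
  list(network = net, variant_settings = vs)
}

## ---- SBML --------------------------------------------------------------

.sbml_mathml <- function(reaction) {
  cn <- function(x) sprintf("<cn> %.17g </cn>", x)
  ci <- function(x) sprintf("<ci> %s </ci>", x)
  times2 <- function(...) paste0("<apply><times/>", paste0(...), "</apply>")
  minus2 <- function(a, b) paste0("<apply><minus/>", a, b, "</apply>")
  plus2 <- function(a, b) paste0("<apply><plus/>", a, b, "</apply>")
  divide2 <- function(a, b) paste0("<apply><divide/>", a, b, "</apply>")
  pw <- function(s, n) if (n == 1) ci(s) else
    paste0("<apply><power/>", ci(s), cn(n), "</apply>")
  r <- reaction
  if (r$law == "michaelis_menten") {
    S <- names(r$reactants)[1]
    V <- if (!is.null(r$modifier))
      times2(ci(r$params[["kcat"]]), ci(r$modifier))
    else ci(r$params[["V"]])
    body <- divide2(times2(V, ci(S)), plus2(ci(r$params[["Km"]]), ci(S)))
  } else {
    fwd <- do.call(times2, c(list(ci(r$params[["kf"]])),
                             lapply(names(r$reactants), function(s)
                               pw(s, r$reactants[[s]]))))
    if (r$law == "mass_action_reversible") {
      bwd <- do.call(times2, c(list(ci(r$params[["kr"]])),
                               lapply(names(r$products), function(s)
                                 pw(s, r$products[[s]]))))
      body <- minus2(fwd, bwd)
    } else body <- fwd
  }
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body,
         "</math>")
}

#' Export a variant (or bare network) as SBML Level 2 Version 4
#'
#' Species, reactions with stoichiometry and modifiers, kinetic laws as
#' MathML, and global parameters are written.  The clamped EGF bath and
#' the constant phosphatase pools are flagged with
#' \code{boundaryCondition}.  A structured annotation records the rate-law
#' type of every reaction so the document re-imports losslessly.
#'
#' @param x an \code{egfr_variant} or \code{egfr_network}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
export_sbml <- function(x, path) {
  if (inherits(x, "egfr_variant")) {
    eff <- .variant_effective(x, egf_dose = 0, gefitinib_alpha = 1)
    net <- x$network
    inits <- c(eff$state, eff$constants)
    params <- eff$params
    model_id <- paste0("EGFR_ERK_", x$name)
  } else {
    net <- x
    sp <- net$species
    inits <- setNames(sp$initial_concentration, sp$id)
    params <- net$parameters$values
    model_id <- "EGFR_ERK"
  }
  sp <- net$species
  esc <- function(s) gsub("&", "&amp;", s, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    sprintf('<model id="%s">', model_id),
    '<listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>',
    "<listOfSpecies>")
  for (i in seq_len(nrow(sp))) {
    boundary <- !sp$is_dynamic[i] || sp$id[i] == "EGF"
    lines <- c(lines, sprintf(
      '<species id="%s" name="%s" compartment="cell" initialConcentration="%.17g" boundaryCondition="%s"/>',
      sp$id[i], esc(sp$display_name[i]), inits[[sp$id[i]]],
      tolower(boundary)))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfParameters>")
  for (nm in names(params))
    lines <- c(lines, sprintf('<parameter id="%s" value="%.17g"/>', nm,
                              params[[nm]]))
  lines <- c(lines, "</listOfParameters>", "<listOfReactions>")
  for (r in net$reactions) {
    rev <- r$law == "mass_action_reversible"
    lines <- c(lines, sprintf(
      '<reaction id="step_%d" reversible="%s">', r$step, tolower(rev)),
      sprintf('<annotation><egfrpath:law xmlns:egfrpath="https://egfrpath.invalid/ns" type="%s"/></annotation>',
              r$law),
      "<listOfReactants>")
    for (s in names(r$reactants))
      lines <- c(lines, sprintf(
        '<speciesReference species="%s" stoichiometry="%g"/>', s,
        r$reactants[[s]]))
    lines <- c(lines, "</listOfReactants>", "<listOfProducts>")
    for (s in names(r$products))
      lines <- c(lines, sprintf(
        '<speciesReference species="%s" stoichiometry="%g"/>', s,
        r$products[[s]]))
    lines <- c(lines, "</listOfProducts>")
    if (!is.null(r$modifier))
      lines <- c(lines, "<listOfModifiers>",
                 sprintf('<modifierSpeciesReference species="%s"/>',
                         r$modifier),
                 "</listOfModifiers>")
    lines <- c(lines, "<kineticLaw>", .sbml_mathml(r), "</kineticLaw>",
               "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  # validate well-formedness
  xml2::read_xml(path)
  invisible(path)
}

#' Import an SBML document written by \code{export_sbml}
#'
#' Reconstructs the network (species, reactions, rate laws, parameters)
#' from the document.  Rate-law types are taken from the structured
#' annotation; parameter-name roles are recovered from the MathML.
#'
#' @param path SBML file.
#' @return An \code{egfr_network} whose simulation (interpreted engine)
#'   matches the exporting model.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  sp <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    display_name = xml2::xml_attr(sp_nodes, "name"),
    initial_concentration = as.numeric(
      xml2::xml_attr(sp_nodes, "initialConcentration")),
    is_dynamic = TRUE, stringsAsFactors = FALSE)
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") == "true"
  # boundary species other than the clamped EGF bath are constant pools
  sp$is_dynamic <- !(boundary & sp$id != "EGF")

  p_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter",
                                ns)
  vals <- setNames(as.numeric(xml2::xml_attr(p_nodes, "value")),
                   xml2::xml_attr(p_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  rx <- lapply(rx_nodes, function(nd) {
    step <- as.integer(sub("step_", "", xml2::xml_attr(nd, "id")))
    law <- xml2::xml_attr(
      xml2::xml_find_first(nd, ".//*[local-name()='law']"), "type")
    getref <- function(xp) {
      refs <- xml2::xml_find_all(nd, xp, ns)
      setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
               xml2::xml_attr(refs, "species"))
    }
    reac <- getref(".//s:listOfReactants/s:speciesReference")
    prod <- getref(".//s:listOfProducts/s:speciesReference")
    modn <- xml2::xml_find_first(nd,
      ".//s:listOfModifiers/s:modifierSpeciesReference", ns)
    modifier <- if (inherits(modn, "xml_missing")) NULL
                else xml2::xml_attr(modn, "species")
    # recover parameter roles from the MathML identifiers
    cis <- xml2::xml_text(xml2::xml_find_all(nd,
      ".//*[local-name()='math']//*[local-name()='ci']"))
    cis <- trimws(cis)
    pref <- cis[cis %in% names(vals)]
    params <- if (law == "michaelis_menten") {
      km <- pref[grepl("^Km", pref)]
      other <- setdiff(pref, km)
      if (is.null(modifier)) c(V = other, Km = km)
      else c(kcat = other, Km = km)
    } else if (law == "mass_action_reversible") {
      c(kf = pref[1], kr = pref[2])
    } else c(kf = pref[1])
    .reaction(step, law, reac, prod, params, modifier = modifier)
  })
  rx <- rx[order(vapply(rx, `[[`, numeric(1), "step"))]
  net <- structure(list(species = sp, reactions = rx,
                        parameters = parameter_set(vals)),
                   class = "egfr_network")
  mm <- vapply(rx, function(r) r$law == "michaelis_menten", logical(1))
  if (setequal(which(mm), c(4, 11, 15:27)) && length(rx) == 27)
    attr(net, "reference_topology") <- TRUE
  validate_network(net)
  net
}

#' Structural diff between two networks
#'
#' Compares species inventories, reaction count, per-step rate laws,
#' stoichiometry and parameter values; used to audit an imported model
#' against the built-in reference.
#'
#' @param a,b \code{egfr_network}s.
#' @param tol relative tolerance for numeric comparisons.
#' @return Character vector of differences (length 0 when structurally
#'   identical).
#' @export
diff_networks <- function(a, b, tol = 1e-12) {
  out <- character(0)
  sa <- a$species$id; sb <- b$species$id
  if (length(setdiff(sa, sb)))
    out <- c(out, paste("species only in first:",
                        paste(setdiff(sa, sb), collapse = ", ")))
  if (length(setdiff(sb, sa)))
    out <- c(out, paste("species only in second:",
                        paste(setdiff(sb, sa), collapse = ", ")))
  if (length(a$reactions) != length(b$reactions))
    out <- c(out, sprintf("reaction count %d vs %d", length(a$reactions),
                          length(b$reactions)))
  n <- min(length(a$reactions), length(b$reactions))
  releq <- function(x, y) abs(x - y) <= tol * pmax(abs(x), abs(y), 1)
  for (i in seq_len(n)) {
    ra <- a$reactions[[i]]; rb <- b$reactions[[i]]
    if (ra$law != rb$law)
      out <- c(out, sprintf("step %d law %s vs %s", ra$step, ra$law,
                            rb$law))
    if (!identical(sort(names(ra$reactants)), sort(names(rb$reactants))) ||
        !identical(sort(names(ra$products)), sort(names(rb$products))))
      out <- c(out, sprintf("step %d stoichiometry differs", ra$step))
    if (!identical(ra$modifier, rb$modifier))
      out <- c(out, sprintf("step %d modifier differs", ra$step))
  }
  common <- intersect(names(a$parameters$values), names(b$parameters$values))
  off <- common[!releq(a$parameters$values[common],
                       b$parameters$values[common])]
  if (length(off))
    out <- c(out, paste("parameter values differ:",
                        paste(off, collapse = ", ")))
  ia <- setNames(a$species$initial_concentration, sa)[intersect(sa, sb)]
  ib <- setNames(b$species$initial_concentration, sb)[intersect(sa, sb)]
  offi <- names(ia)[!releq(ia, ib)]
  if (length(offi))
    out <- c(out, paste("initial concentrations differ:",
                        paste(offi, collapse = ", ")))
  out
}
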