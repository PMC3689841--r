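#' Write a time course as tidy delimited text
#'
#' Columns: time_min, species_id, compartment, value.  The file carries a
#' provenance header (package version, model and parameter hashes) as
#' comment lines.
#'
#' @param tc a \code{time_course}
#' @param path output path (tab-separated)
#' @export
write_time_course <- function(tc, path) {
  df <- as.data.frame(tc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(tc$model), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  comp <- stats::setNames(x$species$compartment, x$species$id)
  ids <- colnames(x$mat)
  data.frame(
    time_min = rep(x$time, times = length(ids)),
    species_id = rep(ids, each = length(x$time)),
    compartment = rep(unname(comp[ids]), each = length(x$time)),
    value = as.vector(x$mat),
    stringsAsFactors = FALSE)
}

#' Read a tidy time-course file back into a time_course-like object
#'
#' The numeric content round-trips bit-exactly (values are written with
#' full precision).
#'
#' @param path file written by \code{\link{write_time_course}}
#' @return list with \code{time}, \code{mat}, \code{species} (no model)
#' @export
read_time_course <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  ids <- unique(df$species_id)
  tgrid <- unique(df$time_min)
  mat <- matrix(df$value, nrow = length(tgrid), ncol = length(ids),
                dimnames = list(NULL, ids))
  comp <- df$compartment[match(ids, df$species_id)]
  structure(list(time = tgrid, mat = mat,
                 species = data.frame(id = ids, compartment = comp,
                                      stringsAsFactors = FALSE)),
            class = "time_course")
}

#' Read / write blot datasets as delimited text
#'
#' Two columns: time_min, intensity; observable and source are carried in
#' comment header lines.
#'
#' @param data a \code{blot_dataset}
#' @param path file path
#' @export
write_blot_dataset <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# observable: %s", data$observable),
               sprintf("# source: %s", data$source)), con)
  utils::write.table(
    data.frame(time_min = data$time_min, intensity = data$intensity),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blot_dataset
#' @export
read_blot_dataset <- function(path) {
  hdr <- readLines(path, n = 10)
  obs <- sub("^# observable: ", "", grep("^# observable:", hdr, value = TRUE))
  src <- sub("^# source: ", "", grep("^# source:", hdr, value = TRUE))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#")
  blot_dataset(df$time_min, df$intensity,
               observable = if (length(obs)) obs else "pR2",
               source = if (length(src)) src else basename(path))
}

# Short stable hash (sum-based; no external digest dependency) used only
# for provenance labels.
mini_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 12)),
             collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * seq_along(v)) %% .Machine$integer.max)
}

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("vegfr2akt")),
           error = function(e) "dev")
}

provenance_lines <- function(model) {
  c(sprintf("# vegfr2akt %s", pkg_version()),
    sprintf("# model_hash: %s", mini_hash(model$reactions)),
    sprintf("# param_hash: %s", mini_hash(model$params)))
}

## ---- SBML Level 3 export / import ------------------------------------

sbml_compartments <- c(medium = "medium", surface = "surface",
                       internal = "endosome", degraded = "degraded",
                       cytosol = "cytosol")

#' Export the model to SBML Level 3
#'
#' Writes species (with compartments medium, surface, endosome, cytosol,
#' degraded and initial amounts in molecules/cell), global parameters, and
#' reactions with mass-action kinetic laws in MathML.  Reversible
#' reactions carry a kf*reactants - kr*products rate.
#'
#' @param model an \code{nw_model}
#' @param path output .xml path
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) x
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '  <model id="vegfr2_gab_akt" substanceUnits="item" timeUnits="second">',
    "    <listOfCompartments>")
  for (cmp in unique(sbml_compartments))
    lines <- c(lines, sprintf(
      '      <compartment id="%s" constant="true" spatialDimensions="3" size="1"/>', cmp))
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$species))) {
    id <- model$species$id[i]
    cmp <- sbml_compartments[[model$species$compartment[i]]]
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="%s" initialAmount="%.17g" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
      esc(id), cmp, model$init[[id]]))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (nm in names(model$params))
    lines <- c(lines, sprintf(
      '      <parameter id="%s" value="%.17g" constant="true"/>',
      nm, model$params[[nm]]))
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  ci <- function(x) sprintf("<ci> %s </ci>", x)
  prod_term <- function(k, specs) {
    terms <- c(ci(k), vapply(specs, ci, ""))
    if (length(terms) == 1L) terms else
      paste0("<apply><times/>", paste(terms, collapse = ""), "</apply>")
  }
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      '      <reaction id="r%d" reversible="%s">',
      r$id, if (r$reversible) "true" else "false"))
    lines <- c(lines, "        <listOfReactants>")
    for (s in r$reactants)
      lines <- c(lines, sprintf(
        '          <speciesReference species="%s" stoichiometry="1" constant="true"/>', s))
    lines <- c(lines, "        </listOfReactants>",
               "        <listOfProducts>")
    for (s in r$products)
      lines <- c(lines, sprintf(
        '          <speciesReference species="%s" stoichiometry="1" constant="true"/>', s))
    lines <- c(lines, "        </listOfProducts>")
    math <- if (r$reversible)
      paste0("<apply><minus/>", prod_term(r$kf, r$reactants),
             prod_term(r$kr, r$products), "</apply>")
    else prod_term(r$kf, r$reactants)
    lines <- c(lines,
               "        <kineticLaw>",
               '          <math xmlns="http://www.w3.org/1998/Math/MathML">',
               paste0("            ", math),
               "          </math>",
               "        </kineticLaw>",
               "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Import an SBML file written by \code{\link{write_sbml}}
#'
#' Parses compartments, species (with initial amounts), parameters and
#' reactions (reactants, products, reversibility and the rate-constant
#' identifiers of the mass-action law).
#'
#' @param path .xml path
#' @return list with \code{species} data.frame, \code{params} named
#'   vector, \code{init} named vector and \code{reactions} list.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core",
          m = "http://www.w3.org/1998/Math/MathML")
  sp_nodes <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)
  init <- stats::setNames(
    as.numeric(xml2::xml_attr(sp_nodes, "initialAmount")), species$id)
  par_nodes <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", ns)
  params <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx_nodes, function(n) {
    reac <- xml2::xml_attr(
      xml2::xml_find_all(n, ".//s:listOfReactants/s:speciesReference", ns),
      "species")
    prod <- xml2::xml_attr(
      xml2::xml_find_all(n, ".//s:listOfProducts/s:speciesReference", ns),
      "species")
    cis <- xml2::xml_text(xml2::xml_find_all(n, ".//m:ci", ns))
    cis <- trimws(cis)
    kf <- setdiff(cis, c(reac, prod))[1]
    rev <- identical(xml2::xml_attr(n, "reversible"), "true")
    kr <- if (rev) {
      ks <- setdiff(cis, c(reac, prod))
      if (length(ks) > 1L) ks[2] else NA_character_
    } else NA_character_
    list(id = as.integer(sub("^r", "", xml2::xml_attr(n, "id"))),
         reactants = reac, products = prod, kf = kf, kr = kr,
         reversible = rev)
  })
  list(species = species, params = params, init = init,
       reactions = reactions)
}
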