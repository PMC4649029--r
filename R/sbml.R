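#' Read a kinetic model from an SBML file
#'
#' Parses an SBML Level 2/3 document with kinetic laws into a
#' [kinetic_model]. Species flagged `boundaryCondition="true"` or
#' `constant="true"` are excluded from the dynamic state and treated as fixed
#' boundary parameters available to the rate laws, following the SBML
#' convention that constant metabolites do not belong in the ODE state.
#' Species order follows document order, so matrices from separate runs are
#' comparable.
#'
#' Supported MathML constructs in kinetic laws: `plus`, `minus`, `times`,
#' `divide`, `power`, `exp`, `ln`, `log`, `root`, `abs`, numbers (including
#' e-notation and rationals), identifiers, `pi` and `exponentiale`. Reaction-
#' local parameters shadow global ones. Unsupported constructs (function
#' definitions, assignment/rate rules, events, piecewise expressions, time
#' symbols) raise an error naming the construct rather than approximating.
#'
#' @param path path to an SBML XML file.
#' @return A [kinetic_model]; boundary species and their fixed values are in
#'   `$boundary`.
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing")) stop("no <model> element in ", path)

  for (construct in c("listOfRules", "listOfEvents", "listOfFunctionDefinitions")) {
    if (!inherits(xml2::xml_find_first(doc, paste0(".//", construct)), "xml_missing")) {
      stop(sprintf("unsupported SBML construct <%s> in %s", construct, path))
    }
  }

  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  comp_size <- stats::setNames(
    vapply(comp_nodes, function(x) {
      s <- xml2::xml_attr(x, "size")
      if (is.na(s)) s <- xml2::xml_attr(x, "volume")
      if (is.na(s)) 1 else as.numeric(s)
    }, 0),
    xml2::xml_attr(comp_nodes, "id"))

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) stop("no species in ", path)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_bc <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true" |
    xml2::xml_attr(sp_nodes, "constant") %in% "true"
  sp_init <- vapply(seq_along(sp_nodes), function(i) {
    v <- xml2::xml_attr(sp_nodes[[i]], "initialConcentration")
    if (!is.na(v)) return(as.numeric(v))
    v <- xml2::xml_attr(sp_nodes[[i]], "initialAmount")
    vol <- comp_size[sp_comp[i]]
    if (is.na(vol)) vol <- 1
    if (!is.na(v)) as.numeric(v) / vol else 0
  }, 0)

  dynamic <- !sp_bc
  species_ids <- sp_id[dynamic]
  n <- length(species_ids)
  if (n == 0L) stop("all species are boundary/constant; no dynamic state")
  boundary <- stats::setNames(sp_init[!dynamic], sp_id[!dynamic])

  par_nodes <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  parameters <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                                xml2::xml_attr(par_nodes, "id"))
  # compartment ids usable as symbols in kinetic laws
  parameters <- c(parameters, comp_size[setdiff(names(comp_size), names(parameters))])

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  r <- length(rx_nodes)
  if (r == 0L) stop("no reactions in ", path)
  stoich <- matrix(0, n, r, dimnames = list(species_ids, xml2::xml_attr(rx_nodes, "id")))
  rates <- vector("list", r)
  reversible <- !(xml2::xml_attr(rx_nodes, "reversible") %in% "false")
  modifiers <- vector("list", r)
  local_parameters <- vector("list", r)

  for (j in seq_len(r)) {
    rx <- rx_nodes[[j]]
    rid <- xml2::xml_attr(rx, "id")
    add_refs <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rx, xpath)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        i <- match(sp, species_ids)
        if (!is.na(i)) stoich[i, j] <<- stoich[i, j] + sign * st
      }
    }
    add_refs("./listOfReactants/speciesReference", -1)
    add_refs("./listOfProducts/speciesReference", +1)
    modifiers[[j]] <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfModifiers/modifierSpeciesReference"), "species")
    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    if (inherits(kl, "xml_missing")) {
      stop(sprintf("reaction '%s' has no kinetic law", rid))
    }
    lp <- xml2::xml_find_all(
      kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")
    local_parameters[[j]] <- stats::setNames(
      as.numeric(xml2::xml_attr(lp, "value")), xml2::xml_attr(lp, "id"))
    math <- xml2::xml_find_first(kl, "./math")
    if (inherits(math, "xml_missing")) {
      stop(sprintf("reaction '%s' has a kinetic law without <math>", rid))
    }
    kids <- xml2::xml_children(math)
    if (length(kids) != 1L) {
      stop(sprintf("reaction '%s': expected a single MathML expression", rid))
    }
    rates[[j]] <- mathml_to_expr(kids[[1]], where = rid)
  }

  sizes <- comp_size[sp_comp[dynamic]]
  sizes[is.na(sizes)] <- 1
  kinetic_model(species_ids = species_ids, stoichiometry = stoich, rates = rates,
                parameters = parameters, reversible = reversible,
                modifiers = modifiers, initial_state = sp_init[dynamic],
                boundary = boundary, local_parameters = local_parameters,
                compartment_sizes = as.numeric(sizes),
                id = xml2::xml_attr(model_node, "id"))
}

# Recursive MathML -> R expression translator for the supported construct set.
#' @noRd
mathml_to_expr <- function(node, where = "?") {
  name <- xml2::xml_name(node)
  txt <- function(x) trimws(xml2::xml_text(x))
  if (name == "ci") return(as.name(txt(node)))
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type %in% c("e-notation", "rational")) {
      parts <- strsplit(txt(node), "\\s+")[[1]]
      parts <- parts[parts != ""]
      a <- as.numeric(parts[1]); b <- as.numeric(parts[2])
      return(if (type == "e-notation") a * 10^b else a / b)
    }
    return(as.numeric(txt(node)))
  }
  if (name == "pi") return(pi)
  if (name == "exponentiale") return(exp(1))
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr, where = where)
    combine <- function(fun, xs) Reduce(function(a, b) call(fun, a, b), xs)
    return(switch(op,
      plus = if (length(args) == 0) 0 else combine("+", args),
      times = if (length(args) == 0) 1 else combine("*", args),
      minus = if (length(args) == 1) call("-", args[[1]]) else combine("-", args),
      divide = combine("/", args),
      power = combine("^", args),
      exp = call("exp", args[[1]]),
      abs = call("abs", args[[1]]),
      ln = call("log", args[[1]]),
      log = if (length(args) == 1) call("log10", args[[1]]) else
        call("log", args[[2]], base = args[[1]]),
      root = if (length(args) == 1) call("sqrt", args[[1]]) else
        call("^", args[[2]], call("/", 1, args[[1]])),
      stop(sprintf("unsupported MathML construct <%s> in kinetic law of '%s'",
                   op, where))
    ))
  }
  stop(sprintf("unsupported MathML element <%s> in kinetic law of '%s'",
               name, where))
}
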