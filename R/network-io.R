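# Network definition files: a small YAML/JSON schema holding species names,
# the parameter registry, the initial state and the reaction list. Custom
# (function-valued) propensities cannot be serialised.

.network_to_list <- function(network) {
  reactions <- lapply(network$reactions, function(r) {
    p <- r$propensity
    if (p$kind == "custom")
      stop("custom propensities cannot be written to a definition file")
    spec <- switch(p$kind,
                   mass_action = list(kind = p$kind, rate = p$rate),
                   list(kind = p$kind, b = p$b, km = p$km, k0 = p$k0,
                        hill = p$hill, regulator = p$regulator))
    c(list(consume = r$consume, produce = r$produce), spec)
  })
  list(species = network$species,
       parameters = as.list(network$params),
       initial_state = network$x0,
       reactions = reactions)
}

.network_from_list <- function(x) {
  reactions <- lapply(x$reactions, function(r) {
    prop <- switch(r$kind,
                   mass_action = mass_action(r$rate),
                   hill_activating = hill_activating(r$b, r$km, r$k0,
                                                     r$hill, r$regulator),
                   hill_repressing = hill_repressing(r$b, r$km, r$k0,
                                                     r$hill, r$regulator),
                   stop("unknown propensity kind in file: ", r$kind))
    reaction(unlist(r$consume), unlist(r$produce), prop)
  })
  reaction_network(reactions, unlist(x$parameters),
                   unlist(x$initial_state),
                   species = unlist(x$species))
}

#' Read / write network definition files
#'
#' The file format (YAML or JSON, chosen from the extension) round-trips a
#' network losslessly: species names, reactions as consume/produce vectors
#' with a propensity kind and its registry references, the parameter
#' registry and the initial state.
#'
#' @param network a [reaction_network()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_network()` returns a [reaction_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  x <- .network_to_list(network)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported extension (use .yaml/.yml/.json): ", path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else stop("unsupported extension (use .yaml/.yml/.json): ", path)
  .network_from_list(x)
}
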