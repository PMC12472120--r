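# Bipartite species-reaction graph export.
#
# Nodes are the model's species and reactions; edges carry the role of
# each participation. Reactant and modifier edges point species ->
# reaction; product edges point reaction -> species. The bipartite form
# is lossless with respect to roles, unlike a species-species
# projection.

#' Build the species-reaction graph of a model
#'
#' @param model An `sbml_model`.
#' @return A `model_graph` with `nodes` (id, kind, label) and `edges`
#'   (source, target, role), in document order.
#' @export
#' @examples
#' g <- model_to_graph(parse_sbml(generate_fixture("decay")$sbml))
#' nrow(g$nodes); nrow(g$edges)
model_to_graph <- function(model) {
  sp_nodes <- data.frame(
    id = vapply(model$species, `[[`, character(1), "id"),
    kind = rep("species", length(model$species)),
    label = vapply(model$species, function(s) {
      if (nzchar(s$name)) s$name else s$id
    }, character(1)),
    stringsAsFactors = FALSE)
  rx_nodes <- data.frame(
    id = vapply(model$reactions, `[[`, character(1), "id"),
    kind = rep("reaction", length(model$reactions)),
    label = vapply(model$reactions, `[[`, character(1), "id"),
    stringsAsFactors = FALSE)
  edges <- list()
  for (rx in model$reactions) {
    for (sr in rx$reactants) {
      edges[[length(edges) + 1L]] <- c(sr$species_id, rx$id, "reactant")
    }
    for (sr in rx$products) {
      edges[[length(edges) + 1L]] <- c(rx$id, sr$species_id, "product")
    }
    for (m in rx$modifiers) {
      edges[[length(edges) + 1L]] <- c(m, rx$id, "modifier")
    }
  }
  edge_df <- if (length(edges) == 0) {
    data.frame(source = character(0), target = character(0),
               role = character(0), stringsAsFactors = FALSE)
  } else {
    em <- do.call(rbind, edges)
    data.frame(source = em[, 1], target = em[, 2], role = em[, 3],
               stringsAsFactors = FALSE)
  }
  structure(list(nodes = rbind(sp_nodes, rx_nodes), edges = edge_df),
            class = "model_graph")
}

#' Serialize a model graph as JSON
#'
#' Schema: `{nodes:[{id,kind,label}], edges:[{source,target,role}]}`.
#'
#' @param graph A `model_graph`.
#' @param path Optional output file.
#' @return JSON text.
#' @export
graph_to_json <- function(graph, path = NULL) {
  doc <- list(
    nodes = lapply(seq_len(nrow(graph$nodes)), function(i) {
      as.list(graph$nodes[i, c("id", "kind", "label")])
    }),
    edges = lapply(seq_len(nrow(graph$edges)), function(i) {
      as.list(graph$edges[i, c("source", "target", "role")])
    })
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.model_graph <- function(x, ...) {
  cat(sprintf("<model_graph: %d node(s), %d edge(s)>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
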