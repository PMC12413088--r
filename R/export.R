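SUBNETWORK_FORMATS <- c("json", "graphml", "cytoscape-json")

#' Serialize a query subnetwork
#'
#' Serializes a `query_subnetwork` to one of three text formats. Nodes
#' carry a `role` attribute (`source` / `intermediate` / `annotated`);
#' edges carry a `type` (`physical` / `regulatory`) and, for regulatory
#' edges, their true direction. Cytoscape JSON follows the
#' `elements = {nodes, edges}` dialect.
#'
#' @param result a `query_subnetwork`.
#' @param format one of `"json"`, `"graphml"`, `"cytoscape-json"`.
#' @return A single character string with the serialized document.
#' @export
export_subnetwork <- function(result, format = "json") {
  if (!format %in% SUBNETWORK_FORMATS) {
    stop("unknown format '", format, "'; supported: ",
         paste(SUBNETWORK_FORMATS, collapse = ", "))
  }
  stopifnot(inherits(result, "query_subnetwork"))
  switch(format,
         "json" = export_json(result),
         "graphml" = export_graphml(result),
         "cytoscape-json" = export_cytoscape(result))
}

export_json <- function(result) {
  doc <- list(
    query = unclass(result$spec),
    paths = lapply(result$paths, identity),
    nodes = result$nodes,
    edges = result$edges)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

export_graphml <- function(result) {
  n <- result$nodes
  e <- result$edges
  header <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="role" for="node" attr.name="role" attr.type="string"/>',
    '  <key id="type" for="edge" attr.name="type" attr.type="string"/>',
    '  <graph id="subnetwork" edgedefault="undirected">')
  node_xml <- if (nrow(n) > 0) {
    sprintf('    <node id="%s"><data key="role">%s</data></node>',
            xml_escape(n$id), xml_escape(n$role))
  } else character()
  edge_xml <- if (nrow(e) > 0) {
    sprintf(paste0('    <edge source="%s" target="%s" directed="%s">',
                   '<data key="type">%s</data></edge>'),
            xml_escape(e$source), xml_escape(e$target),
            ifelse(e$directed, "true", "false"), xml_escape(e$type))
  } else character()
  paste(c(header, node_xml, edge_xml, "  </graph>", "</graphml>", ""),
        collapse = "\n")
}

export_cytoscape <- function(result) {
  n <- result$nodes
  e <- result$edges
  nodes <- lapply(seq_len(nrow(n)), function(i) {
    list(data = list(id = n$id[i], role = n$role[i]))
  })
  edges <- lapply(seq_len(nrow(e)), function(i) {
    list(data = list(id = paste0("e", i), source = e$source[i],
                     target = e$target[i], type = e$type[i],
                     directed = e$directed[i]))
  })
  as.character(jsonlite::toJSON(
    list(elements = list(nodes = nodes, edges = edges)),
    auto_unbox = TRUE, pretty = TRUE))
}

#' Write a serialized subnetwork to a file
#'
#' @inheritParams export_subnetwork
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(result, path, format = "json") {
  writeLines(export_subnetwork(result, format), path)
  invisible(path)
}

#' Parse a serialized subnetwork back into node and edge tables
#'
#' Round-trip reader used to verify exports: recovers node roles and typed
#' edges from any of the three formats.
#'
#' @param text serialized document (a single string or lines).
#' @param format the format it was written in.
#' @return List with `nodes` (id, role) and `edges` (source, target, type,
#'   directed) data.frames, plus `paths` for the JSON format.
#' @export
import_subnetwork <- function(text, format = "json") {
  if (!format %in% SUBNETWORK_FORMATS) {
    stop("unknown format '", format, "'; supported: ",
         paste(SUBNETWORK_FORMATS, collapse = ", "))
  }
  text <- paste(text, collapse = "\n")
  empty_nodes <- data.frame(id = character(), role = character(),
                            stringsAsFactors = FALSE)
  empty_edges <- data.frame(source = character(), target = character(),
                            type = character(), directed = logical(),
                            stringsAsFactors = FALSE)
  if (format == "json") {
    doc <- jsonlite::fromJSON(text, simplifyDataFrame = TRUE)
    nodes <- if (length(doc$nodes) > 0) doc$nodes else empty_nodes
    edges <- if (length(doc$edges) > 0) doc$edges else empty_edges
    paths <- lapply(doc$paths, as.character)
    return(list(nodes = nodes, edges = edges, paths = paths))
  }
  if (format == "cytoscape-json") {
    doc <- jsonlite::fromJSON(text, simplifyDataFrame = TRUE)
    nd <- doc$elements$nodes$data
    ed <- doc$elements$edges$data
    nodes <- if (length(nd) > 0) {
      data.frame(id = nd$id, role = nd$role, stringsAsFactors = FALSE)
    } else empty_nodes
    edges <- if (length(ed) > 0) {
      data.frame(source = ed$source, target = ed$target, type = ed$type,
                 directed = ed$directed, stringsAsFactors = FALSE)
    } else empty_edges
    return(list(nodes = nodes, edges = edges))
  }
  # graphml
  doc <- xml2::read_xml(text)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  nodes <- if (length(node_els) > 0) {
    data.frame(
      id = xml2::xml_attr(node_els, "id"),
      role = xml2::xml_text(xml2::xml_find_first(node_els, "./g:data", ns)),
      stringsAsFactors = FALSE)
  } else empty_nodes
  edges <- if (length(edge_els) > 0) {
    data.frame(
      source = xml2::xml_attr(edge_els, "source"),
      target = xml2::xml_attr(edge_els, "target"),
      type = xml2::xml_text(xml2::xml_find_first(edge_els, "./g:data", ns)),
      directed = xml2::xml_attr(edge_els, "directed") == "true",
      stringsAsFactors = FALSE)
  } else empty_edges
  list(nodes = nodes, edges = edges)
}
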