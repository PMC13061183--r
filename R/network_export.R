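# Severity-coded interaction network: drugs as nodes sized by their total
# interaction burden, edges weighted by pair frequency and colored by
# severity. Export targets are Cytoscape-compatible (GraphML, SIF).

#' Severity-to-color map used in network exports
#' @export
SEVERITY_COLORS <- c(contraindicated = "red", major = "orange",
                     moderate = "green")

#' Build the interaction network from a screen result
#'
#' Edges are the observed interacting pairs ranked by descending frequency
#' (ties broken by pair name) and truncated to the `top_k` most frequent;
#' node totals are recomputed over the RETAINED edges only, so node size and
#' edge weights always agree in the exported figure.
#'
#' @param sr a `screen_result` with at least one interaction.
#' @param top_k number of edges to keep, or `Inf` for all.
#' @param class_table optional data.table/data.frame `drug,
#'   therapeutic_class` used to annotate nodes (not inferred).
#' @return object of class `interaction_network`: list with `nodes` (`drug`,
#'   `total_interaction_count`, optional `therapeutic_class`), `edges`
#'   (`first`, `second`, `severity`, `frequency`, `color`).
#' @export
build_network <- function(sr, top_k = Inf, class_table = NULL) {
  stopifnot(inherits(sr, "screen_result"))
  if (nrow(sr$per_pair) == 0L) stop("empty screen result", call. = FALSE)
  edges <- data.table::copy(sr$per_pair)[order(-frequency, first, second)]
  if (is.finite(top_k)) edges <- utils::head(edges, top_k)
  edges[, color := SEVERITY_COLORS[severity]]

  long <- data.table::rbindlist(list(
    edges[, list(drug = first, frequency)],
    edges[, list(drug = second, frequency)]))
  nodes <- long[, list(total_interaction_count = sum(frequency)), by = "drug"]
  data.table::setorderv(nodes, "drug")
  if (!is.null(class_table)) {
    ct <- data.table::as.data.table(class_table)
    stopifnot(all(c("drug", "therapeutic_class") %in% names(ct)))
    nodes <- ct[nodes, on = "drug"]
    data.table::setcolorder(nodes, c("drug", "total_interaction_count"))
  }
  structure(list(nodes = nodes[], edges = edges[]),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", nrow(x$nodes), "drugs,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a network to GraphML, SIF, or edge CSV
#'
#' GraphML carries node and edge attributes (`total_interaction_count`,
#' `therapeutic_class` if present; `frequency`, `severity`, `color`) and
#' round-trips losslessly through [read_graphml()]. SIF uses the severity as
#' the relation label (one line per edge). The edge CSV has header
#' `drug_a,drug_b,severity,frequency`.
#'
#' @param net an `interaction_network`.
#' @param path output file path.
#' @param format "graphml", "sif", or "edge-csv".
#' @return invisibly, `path`.
#' @export
write_graph <- function(net, path, format = c("graphml", "sif", "edge-csv")) {
  stopifnot(inherits(net, "interaction_network"))
  format <- match.arg(format)
  switch(format,
         graphml = write_graphml(net, path),
         sif = writeLines(sprintf("%s\t%s\t%s", net$edges$first,
                                  net$edges$severity, net$edges$second), path),
         `edge-csv` = data.table::fwrite(
           net$edges[, list(drug_a = first, drug_b = second, severity,
                            frequency)], path))
  invisible(path)
}

write_graphml <- function(net, path) {
  has_class <- "therapeutic_class" %in% names(net$nodes)
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keydef <- function(id, dom, name, type) {
    k <- xml2::xml_add_child(doc, "key")
    xml2::xml_set_attrs(k, c(id = id, `for` = dom, attr.name = name,
                             attr.type = type))
  }
  keydef("d0", "node", "total_interaction_count", "long")
  if (has_class) keydef("d1", "node", "therapeutic_class", "string")
  keydef("d2", "edge", "frequency", "long")
  keydef("d3", "edge", "severity", "string")
  keydef("d4", "edge", "color", "string")
  g <- xml2::xml_add_child(doc, "graph", id = "ddi", edgedefault = "undirected")
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = net$nodes$drug[i])
    dat <- xml2::xml_add_child(nd, "data", key = "d0")
    xml2::xml_set_text(dat, as.character(net$nodes$total_interaction_count[i]))
    if (has_class && !is.na(net$nodes$therapeutic_class[i])) {
      dat <- xml2::xml_add_child(nd, "data", key = "d1")
      xml2::xml_set_text(dat, net$nodes$therapeutic_class[i])
    }
  }
  for (i in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = net$edges$first[i],
                              target = net$edges$second[i])
    for (kv in list(c("d2", as.character(net$edges$frequency[i])),
                    c("d3", net$edges$severity[i]),
                    c("d4", net$edges$color[i]))) {
      dat <- xml2::xml_add_child(ed, "data", key = kv[1])
      xml2::xml_set_text(dat, kv[2])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GraphML file written by [write_graph()]
#'
#' @param path GraphML file.
#' @return an `interaction_network` with the same nodes, edges, attributes.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, "./key")
  keymap <- setNames(xml2::xml_attr(keys, "attr.name"),
                     xml2::xml_attr(keys, "id"))
  get_data <- function(node) {
    ds <- xml2::xml_find_all(node, "./data")
    setNames(xml2::xml_text(ds), keymap[xml2::xml_attr(ds, "key")])
  }
  nodes <- xml2::xml_find_all(doc, "./graph/node")
  nd <- data.table::rbindlist(lapply(nodes, function(n) {
    d <- get_data(n)
    out <- list(drug = xml2::xml_attr(n, "id"),
                total_interaction_count = as.integer(d[["total_interaction_count"]]))
    if ("therapeutic_class" %in% names(d)) {
      out$therapeutic_class <- d[["therapeutic_class"]]
    }
    out
  }), fill = TRUE)
  data.table::setorderv(nd, "drug")
  edges <- xml2::xml_find_all(doc, "./graph/edge")
  ed <- data.table::rbindlist(lapply(edges, function(e) {
    d <- get_data(e)
    list(first = xml2::xml_attr(e, "source"),
         second = xml2::xml_attr(e, "target"),
         severity = d[["severity"]],
         frequency = as.integer(d[["frequency"]]),
         color = d[["color"]])
  }))
  structure(list(nodes = nd[], edges = ed[]), class = "interaction_network")
}
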