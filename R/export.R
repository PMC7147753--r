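#' Export a cascade graph
#'
#' Writes the cascade in one of four formats. Nodes carry stage index, time
#' value, correlation, indegree and outdegree; edges carry their type
#' (within / cross).
#'
#' * `edge-table` — a tab-delimited edge file (`source`, `source_stage`,
#'   `target`, `target_stage`, `type`) plus a companion
#'   `<path>.nodes.tsv` holding the node attributes at full precision;
#'   [import_cascade_edge_table()] reproduces the cascade graph exactly.
#' * `sif` — Cytoscape simple-interaction format, one
#'   `source regulates target` line per edge; isolated nodes appear as
#'   single-field lines.
#' * `graphml` — GraphML with all attributes, via [igraph::write_graph()].
#' * `cytoscape-json` — Cytoscape.js elements JSON.
#'
#' @param cascade a [build_cascade()] result.
#' @param path output path (the edge table adds `<path>.nodes.tsv`).
#' @param format one of `"edge-table"`, `"sif"`, `"graphml"`,
#'   `"cytoscape-json"`.
#' @return `path`, invisibly.
#' @export
export_cascade <- function(cascade, path,
                           format = c("edge-table", "sif", "graphml",
                                      "cytoscape-json")) {
  stopifnot(inherits(cascade, "trc"))
  format <- match.arg(format)
  nodes <- cascade$nodes
  edges <- cascade$edges

  if (format == "edge-table") {
    header <- paste(c("source", "source_stage", "target", "target_stage",
                      "type"), collapse = "\t")
    rows <- if (nrow(edges) > 0L)
      paste(edges$source, edges$source_stage, edges$target,
            edges$target_stage, edges$type, sep = "\t")
    else character()
    writeLines(c(header, rows), path)
    nheader <- paste(c("gene", "stage", "time_value", "correlation",
                       "indegree", "outdegree"), collapse = "\t")
    nrows <- if (nrow(nodes) > 0L)
      paste(nodes$gene, nodes$stage, format_full_precision(nodes$time_value),
            format_full_precision(nodes$correlation), nodes$indegree,
            nodes$outdegree, sep = "\t")
    else character()
    writeLines(c(nheader, nrows), paste0(path, ".nodes.tsv"))
    return(invisible(path))
  }

  if (format == "sif") {
    lines <- if (nrow(edges) > 0L)
      paste(edges$source, "regulates", edges$target, sep = "\t")
    else character()
    isolated <- setdiff(nodes$gene, c(edges$source, edges$target))
    writeLines(c(lines, isolated), path)
    return(invisible(path))
  }

  if (format == "graphml") {
    g <- cascade_igraph(cascade)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }

  # cytoscape-json
  node_elems <- lapply(seq_len(nrow(nodes)), function(i) {
    list(data = list(id = nodes$gene[i], stage = nodes$stage[i],
                     time_value = nodes$time_value[i],
                     correlation = nodes$correlation[i],
                     indegree = nodes$indegree[i],
                     outdegree = nodes$outdegree[i]))
  })
  edge_elems <- lapply(seq_len(nrow(edges)), function(i) {
    list(data = list(id = paste0("e", i), source = edges$source[i],
                     target = edges$target[i], type = edges$type[i]))
  })
  jsonlite::write_json(list(elements = list(nodes = node_elems,
                                            edges = edge_elems)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cascade as an igraph object
#'
#' @param cascade a [build_cascade()] result.
#' @return a directed [igraph::graph] with node and edge attributes.
#' @export
cascade_igraph <- function(cascade) {
  stopifnot(inherits(cascade, "trc"))
  vert <- data.frame(name = cascade$nodes$gene,
                     stage = cascade$nodes$stage,
                     time_value = cascade$nodes$time_value,
                     correlation = cascade$nodes$correlation,
                     indegree = cascade$nodes$indegree,
                     outdegree = cascade$nodes$outdegree,
                     stringsAsFactors = FALSE)
  ed <- data.frame(from = cascade$edges$source, to = cascade$edges$target,
                   type = cascade$edges$type, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = vert)
}

#' Re-import an edge-table cascade export
#'
#' Reads the pair of files written by [export_cascade()] with
#' `format = "edge-table"` back into a `trc` object; export followed by
#' import is the identity on the cascade graph.
#'
#' @param path the edge-table path given to [export_cascade()].
#' @return a `trc` object (without `params`).
#' @export
import_cascade_edge_table <- function(path) {
  npath <- paste0(path, ".nodes.tsv")
  if (!file.exists(path) || !file.exists(npath))
    stop_trc("edge-table export not found at ", path,
             " (+ .nodes.tsv)", class = "trc_usage_error")
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "integer",
                                            "character", "integer",
                                            "character"))
  names(edges) <- c("source", "source_stage", "target", "target_stage",
                    "type")
  nodes <- utils::read.table(npath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "integer",
                                            "numeric", "numeric",
                                            "integer", "integer"))
  names(nodes) <- c("gene", "stage", "time_value", "correlation",
                    "indegree", "outdegree")
  stage_indices <- sort(unique(nodes$stage))
  tv <- rep(NA_real_, max(c(nodes$stage, 0L)))
  tv[nodes$stage] <- nodes$time_value
  structure(list(nodes = nodes, edges = edges,
                 stage_indices = stage_indices, time_values = tv,
                 params = NULL),
            class = "trc")
}
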