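# Serialisation of enrichment results: ranked TSV table and network
# formats (GraphML, SIF, node-link JSON) that preserve the pruned ontology
# structure.

fmt_float <- function(x) {
  ifelse(is.na(x), "", trimws(formatC(signif(x, 6), format = "g", digits = 6)))
}

#' Write the ranked enrichment table
#'
#' TSV with header columns exactly `class_id, name, k, n, K, N, p_raw,
#' p_adj, sample_pct, fold`; floats at 6 significant digits; `fold` is an
#' empty cell when undefined (K = 0).
#'
#' @param rows enrichment rows (sorted per the pipeline contract).
#' @param dest destination file path.
#' @export
write_enrichment_table <- function(rows, dest) {
  cols <- c("class_id", "name", "k", "n", "K", "N", "p_raw", "p_adj",
            "sample_pct", "fold")
  if (is.null(rows$name)) rows$name <- rows$class_id
  out <- data.frame(
    class_id = rows$class_id,
    name = rows$name,
    k = rows$k, n = rows$n, K = rows$K, N = rows$N,
    p_raw = fmt_float(rows$p_raw),
    p_adj = fmt_float(rows$p_adj),
    sample_pct = fmt_float(rows$sample_pct),
    fold = fmt_float(rows$fold),
    stringsAsFactors = FALSE
  )
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(out)) do.call(paste, c(out, sep = "\t")))
  writeLines(lines, dest)
}

# per-node attribute frame shared by the graph writers
graph_node_attrs <- function(rg) {
  t <- rg$graph$terms
  s <- rg$stats
  pick <- function(col) {
    if (is.null(s)) rep(NA_real_, nrow(t)) else s[[col]][match(t$id, s$class_id)]
  }
  data.frame(
    id = t$id,
    name = t$name,
    p_raw = pick("p_raw"),
    p_adj = pick("p_adj"),
    fold = pick("fold"),
    sample_pct = pick("sample_pct"),
    is_molecule = !is.na(t$inchi),
    stringsAsFactors = FALSE
  )
}

graph_edge_attrs <- function(rg) {
  e <- rg$graph$edges
  cc <- vapply(seq_len(nrow(e)), function(i) {
    length(rg$collapsed_paths[[edge_key(e$child[i], e$parent[i])]] %||% character())
  }, integer(1))
  cbind(e, collapsed_count = cc)
}

write_graphml <- function(rg, dest) {
  nodes <- graph_node_attrs(rg)
  edges <- graph_edge_attrs(rg)
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    list(id = "d0", dom = "node", name = "name", type = "string"),
    list(id = "d1", dom = "node", name = "p_raw", type = "double"),
    list(id = "d2", dom = "node", name = "p_adj", type = "double"),
    list(id = "d3", dom = "node", name = "fold", type = "double"),
    list(id = "d4", dom = "node", name = "sample_pct", type = "double"),
    list(id = "d5", dom = "node", name = "is_molecule", type = "boolean"),
    list(id = "d6", dom = "edge", name = "relation", type = "string"),
    list(id = "d7", dom = "edge", name = "collapsed_count", type = "int")
  )
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k$id, "for" = k$dom,
                        attr.name = k$name, attr.type = k$type)
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  add_data <- function(node, key, value) {
    if (is.na(value)) return(invisible())
    d <- xml2::xml_add_child(node, "data", key = key)
    xml2::xml_text(d) <- as.character(value)
  }
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = nodes$id[i])
    add_data(nd, "d0", nodes$name[i])
    add_data(nd, "d1", nodes$p_raw[i])
    add_data(nd, "d2", nodes$p_adj[i])
    add_data(nd, "d3", nodes$fold[i])
    add_data(nd, "d4", nodes$sample_pct[i])
    add_data(nd, "d5", tolower(as.character(nodes$is_molecule[i])))
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(graph, "edge",
                              source = edges$child[i], target = edges$parent[i])
    add_data(ed, "d6", edges$relation[i])
    add_data(ed, "d7", edges$collapsed_count[i])
  }
  xml2::write_xml(doc, dest)
}

write_sif <- function(rg, dest) {
  e <- rg$graph$edges
  writeLines(if (nrow(e)) paste(e$child, e$relation, e$parent, sep = "\t")
             else character(), dest)
}

write_node_link_json <- function(rg, dest) {
  nodes <- graph_node_attrs(rg)
  edges <- graph_edge_attrs(rg)
  payload <- list(
    directed = TRUE,
    nodes = nodes,
    links = if (nrow(edges)) {
      data.frame(source = edges$child, target = edges$parent,
                 relation = edges$relation,
                 collapsed_count = edges$collapsed_count,
                 stringsAsFactors = FALSE)
    } else {
      list()
    }
  )
  jsonlite::write_json(payload, dest, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' Write a result graph in a network format
#'
#' GraphML carries node attributes (`name`, `p_raw`, `p_adj`, `fold`,
#' `sample_pct`, `is_molecule`) and edge attributes (`relation`,
#' `collapsed_count`). SIF is the lossy `child<TAB>relation<TAB>parent`
#' form (one line per edge). Node-link JSON mirrors the GraphML
#' attributes.
#'
#' @param rg a `result_graph`.
#' @param format `"graphml"`, `"sif"` or `"node_link_json"`.
#' @param dest destination file path.
#' @export
write_result_graph <- function(rg, format = c("graphml", "sif", "node_link_json"),
                               dest) {
  format <- match.arg(format)
  switch(format,
    graphml = write_graphml(rg, dest),
    sif = write_sif(rg, dest),
    node_link_json = write_node_link_json(rg, dest)
  )
  invisible(dest)
}

#' Write the full export bundle for an analysis result
#'
#' @param result list returned by [run_analysis()].
#' @param out_dir output directory (created if missing).
#' @param formats subset of `c("tsv", "graphml", "sif", "node_link_json")`.
#' @return named character vector of written paths.
#' @export
export_bundle <- function(result, out_dir,
                          formats = c("tsv", "graphml", "sif", "node_link_json")) {
  stopifnot(all(formats %in% c("tsv", "graphml", "sif", "node_link_json")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  if ("tsv" %in% formats) {
    p <- file.path(out_dir, "table.tsv")
    write_enrichment_table(result$rows, p)
    written["tsv"] <- p
  }
  ext <- c(graphml = "graphml", sif = "sif", node_link_json = "json")
  for (f in intersect(formats, names(ext))) {
    p <- file.path(out_dir, paste0("graph.", ext[[f]]))
    write_result_graph(result$graph, f, p)
    written[f] <- p
  }
  written
}
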