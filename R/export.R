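#' Convert an emotion network to igraph
#'
#' @param net an [emotion_network()].
#' @return an igraph directed graph whose vertices are the full roster (with
#'   degree attributes) and whose edges carry `weight`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "emotion_network"))
  tab <- degree_indices(net)
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = as.character(net$roster)))
  idx <- match(igraph::V(g)$name, tab$character)
  igraph::V(g)$weighted_indegree <- tab$weighted_indegree[idx]
  igraph::V(g)$weighted_outdegree <- tab$weighted_outdegree[idx]
  igraph::V(g)$weighted_degree <- tab$weighted_degree[idx]
  g <- igraph::set_graph_attr(g, "emotion", net$emotion)
  g
}

# Visual encodings: node size follows weighted indegree (emotion received),
# node darkness follows weighted outdegree (emotion expressed), both min-max
# scaled to [0,1] with the all-equal case pinned at 0.5; edge thickness is
# proportional to weight (weight / max weight).
styled_attributes <- function(net) {
  tab <- degree_indices(net)
  minmax <- function(x) {
    if (length(x) == 0) return(numeric(0))
    r <- range(x)
    if (r[1] == r[2]) rep(0.5, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  nodes <- data.frame(character = tab$character,
                      weighted_indegree = tab$weighted_indegree,
                      weighted_outdegree = tab$weighted_outdegree,
                      weighted_degree = tab$weighted_degree,
                      size = minmax(tab$weighted_indegree),
                      darkness = minmax(tab$weighted_outdegree),
                      stringsAsFactors = FALSE)
  edges <- net$edges
  edges$thickness <- if (nrow(edges)) edges$weight / max(edges$weight) else numeric(0)
  list(nodes = nodes, edges = edges)
}

#' Export an emotion network with visual encodings
#'
#' Writes the network in GraphML, GEXF (1.2) or DOT with numeric visual
#' attributes rather than a rendered picture: node `size` proportional to
#' min-max-scaled weighted indegree (how much emotion a character receives),
#' node `darkness` to scaled weighted outdegree (how much it expresses),
#' edge `thickness` proportional to weight; direction is preserved. Raw
#' degree values travel along as node attributes. Run configuration, when
#' supplied, is embedded as graph-level metadata so any output file states
#' how it was produced.
#'
#' @param net an [emotion_network()].
#' @param path output file path.
#' @param format `"graphml"`, `"gexf"` or `"dot"`.
#' @param config optional named list of run settings (threshold, n_boot,
#'   seed, aggregator, ...) embedded as metadata.
#' @return `path`, invisibly.
#' @export
export_styled <- function(net, path, format = c("graphml", "gexf", "dot"),
                          config = NULL) {
  stopifnot(inherits(net, "emotion_network"))
  format <- match.arg(format)
  sty <- styled_attributes(net)
  if (format == "gexf") {
    write_gexf(net, sty, path, config)
    return(invisible(path))
  }
  g <- as_igraph(net)
  idx <- match(igraph::V(g)$name, sty$nodes$character)
  igraph::V(g)$size <- sty$nodes$size[idx]
  igraph::V(g)$darkness <- sty$nodes$darkness[idx]
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$thickness <- sty$edges$thickness
  }
  for (k in names(config)) {
    g <- igraph::set_graph_attr(g, k, as.character(config[[k]]))
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# Minimal deterministic GEXF 1.2 writer (directed, weighted, with the
# size/darkness/degree node attributes).
write_gexf <- function(net, sty, path, config = NULL) {
  attr_defs <- c("weighted_indegree", "weighted_outdegree",
                 "weighted_degree", "size", "darkness")
  desc <- if (length(config)) {
    paste(sprintf("%s=%s", names(config),
                  vapply(config, function(v) as.character(v)[1], character(1))),
          collapse = "; ")
  } else ""
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    sprintf('  <meta><creator>emonet</creator><description>%s</description></meta>',
            xml_escape(desc)),
    sprintf('  <graph defaultedgetype="directed" label="%s">',
            xml_escape(net$emotion)),
    '    <attributes class="node">',
    sprintf('      <attribute id="%d" title="%s" type="double"/>',
            seq_along(attr_defs) - 1L, attr_defs),
    '    </attributes>',
    '    <nodes>')
  for (i in seq_len(nrow(sty$nodes))) {
    nd <- sty$nodes[i, ]
    vals <- sprintf('          <attvalue for="%d" value="%s"/>',
                    seq_along(attr_defs) - 1L,
                    fmt_num(as.numeric(nd[attr_defs])))
    lines <- c(lines,
               sprintf('      <node id="%d" label="%s">', i - 1L,
                       xml_escape(nd$character)),
               '        <attvalues>', vals, '        </attvalues>',
               '      </node>')
  }
  lines <- c(lines, '    </nodes>', '    <edges>')
  if (nrow(sty$edges)) {
    src <- match(sty$edges$source, sty$nodes$character) - 1L
    tgt <- match(sty$edges$target, sty$nodes$character) - 1L
    lines <- c(lines,
               sprintf('      <edge id="%d" source="%d" target="%d" weight="%s"/>',
                       seq_len(nrow(sty$edges)) - 1L, src, tgt,
                       fmt_num(sty$edges$weight)))
  }
  lines <- c(lines, '    </edges>', '  </graph>', '</gexf>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an emotion network back from GraphML or GEXF
#'
#' Inverse of [export_styled()]: reconstructs the network (roster in file
#' order, weighted directed edges) from an exported file.
#'
#' @param path file path.
#' @param format `"graphml"` or `"gexf"`; guessed from the extension when
#'   missing.
#' @return an [emotion_network()].
#' @export
read_emotion_network <- function(path, format = c("auto", "graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gexf$", path, ignore.case = TRUE)) "gexf" else "graphml"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    emo <- igraph::graph_attr(g, "emotion")
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- if (nrow(el)) {
      data.frame(source = el$from, target = el$to, weight = el$weight,
                 stringsAsFactors = FALSE)
    } else data.frame(source = character(0), target = character(0),
                      weight = numeric(0))
    return(emotion_network(emo, igraph::V(g)$name, edges))
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)
  emo <- xml2::xml_attr(graph, "label")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  ids <- xml2::xml_attr(node_els, "id")
  labels <- xml2::xml_attr(node_els, "label")
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- if (length(edge_els)) {
    data.frame(source = labels[match(xml2::xml_attr(edge_els, "source"), ids)],
               target = labels[match(xml2::xml_attr(edge_els, "target"), ids)],
               weight = as.numeric(xml2::xml_attr(edge_els, "weight")),
               stringsAsFactors = FALSE)
  } else data.frame(source = character(0), target = character(0),
                    weight = numeric(0))
  emotion_network(emo, labels, edges)
}
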