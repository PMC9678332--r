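#' Read a corpus from CSV files
#'
#' Files are UTF-8, comma-delimited, RFC-4180 quoted, with a header row. The
#' empty string encodes a null `parent_id`/`topic`. The corpus is validated on
#' read: schema problems (missing columns, unknown `kind`) and referential
#' problems (dangling `parent_id`, inconsistent roots) raise errors naming the
#' offending columns or tweet ids.
#'
#' @param users_path,tweets_path Paths to `users.csv` and `tweets.csv`.
#' @return A validated [corpus()] object with row order preserved.
#' @export
read_corpus <- function(users_path, tweets_path) {
  chr <- readr::cols(.default = readr::col_character())
  users <- readr::read_csv(users_path, col_types = chr,
                           na = character(), progress = FALSE)
  tweets <- readr::read_csv(tweets_path, col_types = chr,
                            na = "", progress = FALSE)
  miss <- c(setdiff(c("user_id", "stakeholder_type", "profile_text"),
                    names(users)),
            setdiff(c("tweet_id", "author_id", "kind", "parent_id",
                      "root_original_id", "topic", "alpha"), names(tweets)))
  if (length(miss)) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")),
          class = "echonet_schema_error")
  }
  tweets$alpha <- as.numeric(tweets$alpha)
  users$profile_text[is.na(users$profile_text)] <- ""
  corp <- corpus(users, tweets)
  report <- validate_corpus(corp)
  if (nrow(report)) {
    ref <- report[report$rule %in%
                    c("parent_exists", "root_resolves", "root_is_original"), ]
    cls <- if (nrow(ref)) "echonet_integrity_error" else "echonet_schema_error"
    shown <- head(report, 10)
    abort(paste0(
      "Corpus failed validation (", nrow(report), " violation(s)):\n",
      paste(sprintf("  [%s] %s: %s", shown$rule, shown$record_id,
                    shown$detail), collapse = "\n")),
      class = cls)
  }
  corp
}

#' Write a corpus to CSV files with a provenance sidecar
#'
#' Writes `users.csv` and `tweets.csv` under `dir`, plus `provenance.json`
#' recording counts, the generator seed when present, and the write timestamp.
#'
#' @param corp An [corpus()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corp, dir) {
  stopifnot(inherits(corp, "echo_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(corp$users, file.path(dir, "users.csv"), na = "")
  readr::write_csv(corp$tweets, file.path(dir, "tweets.csv"), na = "")
  prov <- list(
    n_users = nrow(corp$users),
    n_tweets = nrow(corp$tweets),
    seed = attr(corp, "seed"),
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  prov <- prov[!vapply(prov, is.null, logical(1))]
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Export an interaction graph to a standard interchange format
#'
#' Supported formats: `"graphml"`, `"gexf"`, and `"edgelist"` (whitespace-
#' delimited `from to weight` lines). GraphML and GEXF preserve the node
#' attribute (topic or attitude) and edge weights; the plain edge list carries
#' structure and weights only.
#'
#' @param graph An igraph object as produced by [build_info_network()] or
#'   [build_user_network()].
#' @param path Output file path.
#' @param format One of `"graphml"`, `"gexf"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @seealso [import_graph()]
#' @export
export_graph <- function(graph, path, format = c("graphml", "gexf", "edgelist")) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) {
    abort("Cannot export an empty graph.", class = "echonet_empty_error")
  }
  if (!is.character(format) || !format[1] %in% c("graphml", "gexf", "edgelist")) {
    abort(sprintf("Unsupported export format '%s'.", format[1]),
          class = "echonet_usage_error")
  }
  format <- match.arg(format)
  switch(format,
    graphml = igraph::write_graph(graph, path, format = "graphml"),
    edgelist = igraph::write_graph(graph, path, format = "ncol",
                                   weights = "weight"),
    gexf = write_gexf(graph, path)
  )
  invisible(path)
}

#' Re-import a graph written by [export_graph()]
#'
#' @param path File path.
#' @param format One of `"graphml"`, `"gexf"`, `"edgelist"`.
#' @param directed For `"edgelist"` only: whether to read a directed graph.
#' @return An igraph object.
#' @export
import_graph <- function(path, format = c("graphml", "gexf", "edgelist"),
                         directed = FALSE) {
  format <- match.arg(format)
  switch(format,
    graphml = igraph::read_graph(path, format = "graphml"),
    edgelist = igraph::read_graph(path, format = "ncol", names = TRUE,
                                  directed = directed, weights = "yes"),
    gexf = read_gexf(path)
  )
}

# Minimal GEXF 1.2 writer/reader: one string node attribute + edge weights.
write_gexf <- function(graph, path) {
  attrs <- setdiff(igraph::vertex_attr_names(graph), "name")
  attr_name <- if (length(attrs)) attrs[[1]] else NULL
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  g <- xml2::xml_add_child(
    doc, "graph",
    defaultedgetype = if (igraph::is_directed(graph)) "directed" else
      "undirected")
  if (!is.null(attr_name)) {
    ats <- xml2::xml_add_child(g, "attributes", class = "node")
    xml2::xml_add_child(ats, "attribute", id = "0", title = attr_name,
                        type = "string")
  }
  nodes <- xml2::xml_add_child(g, "nodes")
  ids <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  vals <- if (!is.null(attr_name))
    as.character(igraph::vertex_attr(graph, attr_name)) else NULL
  for (i in seq_along(ids)) {
    nd <- xml2::xml_add_child(nodes, "node", id = ids[i], label = ids[i])
    if (!is.null(vals)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "0", value = vals[i])
    }
  }
  edges <- xml2::xml_add_child(g, "edges")
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  for (i in seq_len(nrow(el))) {
    xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                        source = el[i, 1], target = el[i, 2],
                        weight = format(w[i], scientific = FALSE))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  g <- xml2::xml_find_first(doc, ".//graph")
  directed <- identical(xml2::xml_attr(g, "defaultedgetype"), "directed")
  attr_title <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//attributes[@class='node']/attribute"),
    "title")
  node_xml <- xml2::xml_find_all(doc, ".//nodes/node")
  ids <- xml2::xml_attr(node_xml, "id")
  vals <- xml2::xml_attr(
    xml2::xml_find_first(node_xml, ".//attvalue"), "value")
  edge_xml <- xml2::xml_find_all(doc, ".//edges/edge")
  from <- xml2::xml_attr(edge_xml, "source")
  to <- xml2::xml_attr(edge_xml, "target")
  w <- as.numeric(xml2::xml_attr(edge_xml, "weight"))
  w[is.na(w)] <- 1
  gr <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = directed,
    vertices = data.frame(name = ids))
  if (!is.na(attr_title) && length(vals) == length(ids)) {
    gr <- igraph::set_vertex_attr(gr, attr_title, value = vals)
  }
  gr
}
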