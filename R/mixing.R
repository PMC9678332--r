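#' Mixing matrix of a categorical node attribute
#'
#' The mixing matrix `e` holds the fraction of total edge weight running
#' between each ordered pair of attribute categories: `e[i, j]` is the weight
#' of edges from category `i` to category `j` divided by the total weight.
#' Each undirected edge contributes half its weight to `(i, j)` and half to
#' `(j, i)`, so `e` is symmetric for undirected graphs and the grand total is
#' always 1. The row sums `a` and column sums `b` are the source and target
#' marginals. With `weighted = FALSE` every edge counts once regardless of
#' weight.
#'
#' @param graph An igraph whose vertices carry the attribute.
#' @param attribute Vertex attribute name; defaults to the graph's recorded
#'   `attribute` (topic or attitude).
#' @param weighted Use edge weights as multiplicities (default `TRUE`).
#' @return An `echo_mixing` object: list with `categories`, matrix `e`,
#'   marginals `a` and `b`, and flags `directed`/`weighted`.
#' @seealso [assortativity()]
#' @export
mixing_matrix <- function(graph, attribute = NULL, weighted = TRUE) {
  stopifnot(igraph::is_igraph(graph))
  attribute <- attribute %||% igraph::graph_attr(graph, "attribute") %||%
    "attitude"
  vals <- igraph::vertex_attr(graph, attribute)
  if (is.null(vals) || anyNA(vals)) {
    bad <- if (is.null(vals)) igraph::V(graph)$name else
      igraph::V(graph)$name[is.na(vals)]
    abort(paste0("Vertices missing attribute '", attribute, "': ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "echonet_attribute_error")
  }
  categories <- sort(unique(vals))
  k <- length(categories)
  e <- matrix(0, k, k, dimnames = list(categories, categories))
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el)) {
    w <- if (weighted) (igraph::E(graph)$weight %||% rep(1, nrow(el))) else
      rep(1, nrow(el))
    ci <- match(vals[el[, 1]], categories)
    cj <- match(vals[el[, 2]], categories)
    if (igraph::is_directed(graph)) {
      for (idx in seq_along(w)) {
        e[ci[idx], cj[idx]] <- e[ci[idx], cj[idx]] + w[idx]
      }
    } else {
      for (idx in seq_along(w)) {
        e[ci[idx], cj[idx]] <- e[ci[idx], cj[idx]] + w[idx] / 2
        e[cj[idx], ci[idx]] <- e[cj[idx], ci[idx]] + w[idx] / 2
      }
    }
    e <- e / sum(e)
  }
  structure(list(categories = categories, e = e,
                 a = rowSums(e), b = colSums(e),
                 directed = igraph::is_directed(graph), weighted = weighted,
                 n_edges = nrow(el),
                 layer = igraph::graph_attr(graph, "layer"),
                 mode = igraph::graph_attr(graph, "mode"),
                 attribute = attribute),
            class = "echo_mixing")
}

#' @export
print.echo_mixing <- function(x, ...) {
  cat(sprintf("<echo_mixing> %d categories, %s, %s edges\n",
              length(x$categories),
              if (x$directed) "directed" else "undirected",
              if (x$weighted) "weighted" else "unweighted"))
  print(round(x$e, 4))
  invisible(x)
}

#' Categorical assortativity coefficient
#'
#' Newman's assortativity for a categorical attribute,
#' \deqn{r = \frac{\sum_i e_{ii} - \sum_i a_i b_i}{1 - \sum_i a_i b_i},}
#' computed from a mixing matrix. `r = 1` means edges only join
#' same-category nodes (a perfect echo chamber); `r <= 0` means no
#' assortment. When all edge weight sits in one category the denominator
#' vanishes and the result is flagged degenerate with `r = NA`.
#'
#' @param m An [mixing_matrix()] result, or an igraph (in which case the
#'   mixing matrix is computed first with `...` passed through).
#' @param ... Passed to [mixing_matrix()] when `m` is a graph.
#' @return An `echo_assort` object: list with `r`, `degenerate`, and the
#'   layer/mode/attribute tags.
#' @examples
#' g <- igraph::make_graph(~ a - b, c - d, simplify = FALSE)
#' igraph::V(g)$group <- c("X", "X", "Y", "Y")
#' assortativity(mixing_matrix(g, "group"))$r # 1: two same-group components
#' @export
assortativity <- function(m, ...) {
  if (igraph::is_igraph(m)) m <- mixing_matrix(m, ...)
  stopifnot(inherits(m, "echo_mixing"))
  tr <- sum(diag(m$e))
  ab <- sum(m$a * m$b)
  degenerate <- abs(1 - ab) < 1e-12
  r <- if (degenerate) NA_real_ else (tr - ab) / (1 - ab)
  structure(list(r = r, degenerate = degenerate, layer = m$layer,
                 mode = m$mode, attribute = m$attribute,
                 weighted = m$weighted),
            class = "echo_assort")
}

#' @export
print.echo_assort <- function(x, ...) {
  cat(sprintf("<echo_assort> r = %s%s\n",
              if (x$degenerate) "NA (degenerate: single category)" else
                format(x$r, digits = 4),
              if (!is.null(x$layer))
                sprintf(" [%s/%s, %s]", x$layer, x$mode, x$attribute) else ""))
  invisible(x)
}

#' Topology summary of an interaction graph
#'
#' Unweighted structural summaries: density (ordered pairs for directed
#' graphs, unordered for undirected), average local clustering coefficient
#' (nodes of degree < 2 contribute 0), transitivity (3 x triangles over
#' connected triples on the undirected projection), and — for directed graphs
#' — reciprocity, the fraction of directed edges whose reverse also exists.
#'
#' @param graph An igraph.
#' @return A one-row tibble: `layer`, `mode`, `nodes`, `edges`, `density`,
#'   `avg_clustering`, `transitivity`, `reciprocity` (`NA` for undirected
#'   graphs).
#' @export
topology_summary <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) {
    abort("Graph is empty.", class = "echonet_empty_error")
  }
  lc <- local_clustering(graph)
  trans <- igraph::transitivity(simple_projection(graph), type = "global")
  tibble(
    layer = igraph::graph_attr(graph, "layer") %||% NA_character_,
    mode = igraph::graph_attr(graph, "mode") %||% NA_character_,
    nodes = igraph::vcount(graph),
    edges = igraph::ecount(graph),
    density = igraph::edge_density(graph, loops = FALSE) %||% NA_real_,
    avg_clustering = mean(lc),
    transitivity = if (is.nan(trans)) 0 else trans,
    reciprocity = if (igraph::is_directed(graph))
      igraph::reciprocity(graph, ignore.loops = TRUE, mode = "default") else
        NA_real_
  )
}

simple_projection <- function(graph) {
  igraph::simplify(igraph::as_undirected(graph, mode = "collapse"),
                   remove.multiple = TRUE, remove.loops = TRUE)
}

local_clustering <- function(graph) {
  und <- simple_projection(graph)
  lc <- igraph::transitivity(und, type = "local", isolates = "zero")
  lc[is.nan(lc)] <- 0
  setNames(lc, igraph::V(und)$name)
}

#' Per-node degree and clustering table
#'
#' Weighted in-/out-degree (sums of incident edge weights by direction; for
#' undirected graphs both equal the weighted degree) and the local clustering
#' coefficient on the undirected unweighted projection.
#'
#' @param graph An igraph.
#' @return A tibble: `node`, `in_degree`, `out_degree`, `clustering`.
#' @export
node_degrees <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) {
    abort("Graph is empty.", class = "echonet_empty_error")
  }
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  tibble(
    node = igraph::V(graph)$name,
    in_degree = as.numeric(igraph::strength(graph, mode = "in", weights = w,
                                            loops = FALSE)),
    out_degree = as.numeric(igraph::strength(graph, mode = "out", weights = w,
                                             loops = FALSE)),
    clustering = as.numeric(local_clustering(graph))
  )
}
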