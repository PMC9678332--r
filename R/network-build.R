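mode_kinds <- function(mode = c("global", "retweet", "comment")) {
  mode <- match.arg(mode)
  switch(mode, global = c("retweet", "comment"), retweet = "retweet",
         comment = "comment")
}

#' Build the information representational network
#'
#' Undirected weighted graph over original tweets: an edge joins originals
#' `i` and `j` when at least one user interacted (through the chosen
#' relation) with both, and its weight is the number of *distinct* common
#' users — repeated interactions by the same user do not inflate the weight.
#' Interactions are attributed to the original at the root of their parent
#' chain. Every original tweet appears as a node (isolated when nobody shares
#' an audience with it) and carries its topic as the node attribute.
#'
#' @param corp An [corpus()] object.
#' @param mode `"retweet"`, `"comment"`, or `"global"` (both relations).
#' @return An undirected igraph with vertex attributes `name` (tweet id) and
#'   `topic`, edge attribute `weight`, and graph attributes `layer`/`mode`.
#' @export
build_info_network <- function(corp, mode = c("global", "retweet", "comment")) {
  stopifnot(inherits(corp, "echo_corpus"))
  mode <- match.arg(mode)
  tw <- corp$tweets
  if (nrow(tw) == 0) {
    abort("Corpus has no tweets.", class = "echonet_empty_error")
  }
  originals <- tw[tw$kind == "original", ]
  inter <- tw[tw$kind %in% mode_kinds(mode), ]
  pairs <- distinct(tibble(user = inter$author_id,
                           root = inter$root_original_id))
  edges <- pairs |>
    inner_join(pairs, by = "user", relationship = "many-to-many") |>
    filter(.data$root.x < .data$root.y) |>
    count(.data$root.x, .data$root.y, name = "weight")
  g <- igraph::graph_from_data_frame(
    rename(edges, from = "root.x", to = "root.y"),
    directed = FALSE,
    vertices = tibble(name = originals$tweet_id, topic = originals$topic))
  igraph::graph_attr(g, "layer") <- "information"
  igraph::graph_attr(g, "mode") <- mode
  igraph::graph_attr(g, "attribute") <- "topic"
  g
}

#' Build the user communication flow network
#'
#' Directed weighted graph over users: an edge runs from user `i` to user `j`
#' with weight equal to the number of times `i` retweeted or commented on a
#' tweet *authored by* `j` — the author of the immediate parent, not of the
#' root original, so retweeting someone's retweet credits the retweeter.
#' Self-interactions are dropped. Nodes are users who authored at least one
#' tweet in the corpus (so never-interacting authors appear as isolated
#' nodes; set `include_isolated = FALSE` to restrict to users touched by the
#' chosen relation). Each node carries the user's attitude, derived from
#' their tweets' sentiment labels.
#'
#' @param corp An [corpus()] object.
#' @param mode `"retweet"`, `"comment"`, or `"global"`.
#' @param include_isolated Keep authors with no interaction in this mode as
#'   isolated nodes (default `TRUE`).
#' @param band A [sentiment_band()] for the attitude attribute.
#' @return A directed igraph with vertex attributes `name` (user id) and
#'   `attitude`, edge attribute `weight`, graph attributes `layer`/`mode`.
#' @export
build_user_network <- function(corp, mode = c("global", "retweet", "comment"),
                               include_isolated = TRUE,
                               band = sentiment_band()) {
  stopifnot(inherits(corp, "echo_corpus"))
  mode <- match.arg(mode)
  tw <- corp$tweets
  if (nrow(tw) == 0) {
    abort("Corpus has no tweets.", class = "echonet_empty_error")
  }
  inter <- tw[tw$kind %in% mode_kinds(mode) & !is.na(tw$parent_id), ]
  parent_author <- tw$author_id[match(inter$parent_id, tw$tweet_id)]
  if (anyNA(parent_author) && nrow(inter)) {
    abort(paste0("Interactions reference parents that are missing: ",
                 paste(head(inter$tweet_id[is.na(parent_author)], 5),
                       collapse = ", ")),
          class = "echonet_integrity_error")
  }
  edges <- tibble(from = inter$author_id, to = parent_author) |>
    filter(.data$from != .data$to) |>
    count(.data$from, .data$to, name = "weight")

  labels <- tibble(author_id = tw$author_id,
                   label = sentiment_label(tw$alpha, band))
  att <- labels |>
    group_by(.data$author_id) |>
    summarise(attitude = user_attitude(.data$label), .groups = "drop")
  nodes <- if (include_isolated) att$author_id else
    union(edges$from, edges$to)
  vertices <- tibble(name = nodes) |>
    left_join(att, by = c(name = "author_id"))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  igraph::graph_attr(g, "layer") <- "user"
  igraph::graph_attr(g, "mode") <- mode
  igraph::graph_attr(g, "attribute") <- "attitude"
  g
}
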