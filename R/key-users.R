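#' Detect opinion leaders
#'
#' Opinion leaders are the users in the top `percentile` of weighted
#' in-degree *and* the top `percentile` of local clustering coefficient on
#' the global user network (intersection rule; the union is available for
#' sensitivity analysis). Cuts are rank-based: the threshold is the metric
#' value at rank `ceiling(n * percentile / 100)` in descending order and ties
#' at the boundary are included, so the selection is deterministic.
#'
#' @param metrics A tibble from [node_degrees()] (columns `node`,
#'   `in_degree`, `clustering`).
#' @param percentile Cut in percent, in (0, 50].
#' @param rule `"intersection"` (default) or `"union"`.
#' @return Character vector of leader node names.
#' @export
detect_opinion_leaders <- function(metrics, percentile = 5,
                                   rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  if (nrow(metrics) == 0) {
    abort("Empty metrics table.", class = "echonet_empty_error")
  }
  if (percentile <= 0 || percentile > 50) {
    abort("`percentile` must lie in (0, 50].", class = "echonet_config_error")
  }
  top <- function(x) {
    k <- ceiling(nrow(metrics) * percentile / 100)
    cut <- sort(x, decreasing = TRUE)[k]
    x >= cut
  }
  keep <- if (rule == "intersection") {
    top(metrics$in_degree) & top(metrics$clustering)
  } else {
    top(metrics$in_degree) | top(metrics$clustering)
  }
  metrics$node[keep]
}

#' Detect structural-hole spanners
#'
#' Spanners are the non-leader users in the bottom `percentile` of aggregate
#' constraint. The cut is taken over all non-isolated users first (isolated
#' nodes have undefined constraint and can never span holes), then leaders
#' are removed — "the other users in the bottom tail". Boundary ties are
#' included.
#'
#' @param sh A [sh_table()] result (or its `metrics` tibble).
#' @param leaders Character vector from [detect_opinion_leaders()].
#' @param percentile Cut in percent, in (0, 50].
#' @return Character vector of spanner node names; disjoint from `leaders`.
#' @export
detect_spanners <- function(sh, leaders = character(), percentile = 5) {
  metrics <- if (is.data.frame(sh)) sh else sh$metrics
  if (percentile <= 0 || percentile > 50) {
    abort("`percentile` must lie in (0, 50].", class = "echonet_config_error")
  }
  if (nrow(metrics) == 0) return(character())
  k <- ceiling(nrow(metrics) * percentile / 100)
  cut <- sort(metrics$constraint)[k]
  bottom <- metrics$node[metrics$constraint <= cut]
  setdiff(bottom, leaders)
}
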