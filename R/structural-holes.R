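# Symmetrized weight lookup: adjacency list of z'_ij = z_ij + z_ji.
symmetrized_adjacency <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  n <- igraph::vcount(graph)
  if (nrow(el)) {
    # listing both orientations symmetrizes directed weights and gives each
    # undirected edge its two incidences
    df <- tibble(i = c(el[, 1], el[, 2]), j = c(el[, 2], el[, 1]),
                 w = c(w, w))
    df <- df |> filter(.data$i != .data$j) |>
      group_by(.data$i, .data$j) |> summarise(w = sum(.data$w), .groups = "drop")
  } else {
    df <- tibble(i = integer(), j = integer(), w = numeric())
  }
  split_idx <- split(seq_len(nrow(df)), factor(df$i, levels = seq_len(n)))
  lapply(split_idx, function(rows) setNames(df$w[rows], df$j[rows]))
}

# proportional tie strengths p_i. over ego i's contacts
prop_ties <- function(adj, i) {
  zi <- adj[[i]]
  if (!length(zi)) return(numeric())
  zi / sum(zi)
}

#' Ego tie profile: proportional strengths and dyadic constraints
#'
#' For ego `i` with symmetrized tie strengths
#' \eqn{z'_{ij} = z_{ij} + z_{ji}}, the proportional strength is
#' \eqn{p_{ij} = z'_{ij} / \sum_k z'_{ik}} and the dyadic constraint is
#' \eqn{c_{ij} = (p_{ij} + \sum_{q \ne i,j} p_{iq} p_{qj})^2}: the extent to
#' which ego's investment in contact `j` is direct or flows through shared
#' third parties.
#'
#' @param graph An igraph (directed weights are symmetrized).
#' @param ego Vertex name or index.
#' @return A list with `ego`, `contacts`, `p` (named), `c` (named dyadic
#'   constraints); `NULL` fields and `isolated = TRUE` for isolated egos.
#' @export
tie_profile <- function(graph, ego) {
  stopifnot(igraph::is_igraph(graph))
  idx <- as.integer(igraph::V(graph)[ego])
  adj <- symmetrized_adjacency(graph)
  p_all <- lapply(seq_along(adj), function(i) prop_ties(adj, i))
  tie_profile_impl(p_all, idx, igraph::V(graph)$name)
}

tie_profile_impl <- function(p_all, idx, names_vec) {
  p <- p_all[[idx]]
  if (!length(p)) {
    return(list(ego = names_vec[idx], contacts = character(), p = NULL,
                c = NULL, isolated = TRUE))
  }
  contacts <- as.integer(names(p))
  cvec <- numeric(length(contacts))
  for (jj in seq_along(contacts)) {
    j <- contacts[jj]
    indirect <- 0
    for (qq in seq_along(contacts)) {
      q <- contacts[qq]
      if (q == j) next
      pqj <- p_all[[q]][as.character(j)]
      if (!is.na(pqj) && length(pqj)) indirect <- indirect + p[[qq]] * pqj
    }
    cvec[jj] <- (p[[jj]] + indirect)^2
  }
  list(ego = names_vec[idx], contacts = names_vec[contacts],
       p = setNames(as.numeric(p), names_vec[contacts]),
       c = setNames(cvec, names_vec[contacts]), isolated = FALSE)
}

#' Burt's structural-hole indices for one ego
#'
#' Computes, on symmetrized weights:
#' * effective size \eqn{S_i = N - \sum_j \sum_q p_{iq} m_{jq}} with
#'   \eqn{m_{jq} = z'_{jq} / \max_k z'_{jk}} and `q` ranging over ego's other
#'   contacts — the number of non-redundant contacts;
#' * efficiency \eqn{E_i = S_i / N};
#' * aggregate constraint \eqn{C_i = \sum_j c_{ij}} (may exceed 1 for small,
#'   interlocked ego networks — e.g. a triangle node has `C = 1.125`);
#' * hierarchy, the Coleman–Theil concentration
#'   \eqn{H_i = \sum_j (c_{ij}/(C_i/N)) \ln(c_{ij}/(C_i/N)) / (N \ln N)},
#'   0 when constraint is spread evenly over contacts (and by convention when
#'   `N = 1`), 1 when concentrated in a single contact.
#'
#' @param graph An igraph.
#' @param ego Vertex name or index.
#' @return A one-row tibble: `node`, `n_contacts`, `effective_size`,
#'   `efficiency`, `constraint`, `hierarchy`; isolated egos yield a row of
#'   `NA` metrics with `n_contacts = 0`.
#' @export
sh_metrics <- function(graph, ego) {
  idx <- as.integer(igraph::V(graph)[ego])
  adj <- symmetrized_adjacency(graph)
  p_all <- lapply(seq_along(adj), function(i) prop_ties(adj, i))
  sh_metrics_impl(adj, p_all, idx, igraph::V(graph)$name)
}

sh_metrics_impl <- function(adj, p_all, idx, names_vec) {
  tp <- tie_profile_impl(p_all, idx, names_vec)
  if (tp$isolated) {
    return(tibble(node = names_vec[idx], n_contacts = 0L,
                  effective_size = NA_real_, efficiency = NA_real_,
                  constraint = NA_real_, hierarchy = NA_real_))
  }
  p <- tp$p
  contacts <- match(tp$contacts, names_vec)
  N <- length(contacts)
  redundancy <- 0
  for (jj in seq_len(N)) {
    j <- contacts[jj]
    zj <- adj[[j]]
    if (!length(zj)) next
    maxz <- max(zj)
    for (qq in seq_len(N)) {
      q <- contacts[qq]
      if (q == j) next
      zjq <- as.numeric(zj[as.character(q)])
      if (!is.na(zjq) && length(zjq)) {
        redundancy <- redundancy + p[[qq]] * (zjq / maxz)
      }
    }
  }
  S <- N - redundancy
  C <- sum(tp$c)
  H <- if (N == 1) 0 else {
    ratio <- tp$c / (C / N)
    sum(ratio * log(ratio)) / (N * log(N))
  }
  tibble(node = tp$ego, n_contacts = N, effective_size = S,
         efficiency = S / N, constraint = C, hierarchy = as.numeric(H))
}

#' Structural-hole indices for every node
#'
#' Batch version of [sh_metrics()] over all non-isolated nodes; isolated
#' nodes (no in- or out-neighbor) are listed separately since their indices
#' are undefined and they can never be structural-hole spanners.
#'
#' @param graph An igraph.
#' @return A list with `metrics` (tibble, one row per non-isolated node) and
#'   `isolated` (character vector of node names).
#' @export
sh_table <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0) {
    abort("Graph is empty.", class = "echonet_empty_error")
  }
  adj <- symmetrized_adjacency(graph)
  p_all <- lapply(seq_along(adj), function(i) prop_ties(adj, i))
  names_vec <- igraph::V(graph)$name
  n <- igraph::vcount(graph)
  isolated <- which(lengths(adj) == 0)
  rows <- lapply(setdiff(seq_len(n), isolated), function(i) {
    sh_metrics_impl(adj, p_all, i, names_vec)
  })
  list(metrics = if (length(rows)) bind_rows(rows) else
         tibble(node = character(), n_contacts = integer(),
                effective_size = numeric(), efficiency = numeric(),
                constraint = numeric(), hierarchy = numeric()),
       isolated = names_vec[isolated])
}
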