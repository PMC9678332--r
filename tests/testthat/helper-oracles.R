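# Independent oracles: direct-summation implementations kept deliberately
# separate from the package internals (dense matrices and explicit loops).

# Assortativity by direct edge enumeration.
oracle_assortativity <- function(graph, attribute, weighted = TRUE) {
  vals <- igraph::vertex_attr(graph, attribute)
  cats <- sort(unique(vals))
  k <- length(cats)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight
  if (is.null(w) || !weighted) w <- rep(1, nrow(el))
  M <- matrix(0, k, k)
  for (idx in seq_len(nrow(el))) {
    i <- match(vals[el[idx, 1]], cats)
    j <- match(vals[el[idx, 2]], cats)
    if (igraph::is_directed(graph)) {
      M[i, j] <- M[i, j] + w[idx]
    } else {
      M[i, j] <- M[i, j] + w[idx] / 2
      M[j, i] <- M[j, i] + w[idx] / 2
    }
  }
  e <- M / sum(M)
  tr <- sum(diag(e))
  ab <- sum(rowSums(e) * colSums(e))
  if (abs(1 - ab) < 1e-12) return(NA_real_)
  (tr - ab) / (1 - ab)
}

# Second independent route: expand integer weights into parallel edges and
# use igraph's own nominal assortativity.
igraph_assortativity <- function(graph, attribute) {
  vals <- igraph::vertex_attr(graph, attribute)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  stopifnot(all(w == round(w)))
  exp_el <- el[rep(seq_len(nrow(el)), w), , drop = FALSE]
  g2 <- igraph::graph_from_edgelist(exp_el,
                                    directed = igraph::is_directed(graph))
  g2 <- igraph::add_vertices(g2, max(0, igraph::vcount(graph) -
                                       igraph::vcount(g2)))
  igraph::assortativity_nominal(g2, as.integer(factor(vals, sort(unique(vals)))),
                                directed = igraph::is_directed(graph))
}

# Burt indices from a dense symmetrized weight matrix, explicit triple loops.
oracle_sh <- function(graph, ego_name) {
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, attr = if (
    "weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
    sparse = FALSE)
  # For undirected graphs A is symmetric so A + t(A) doubles every weight;
  # p, m and c are ratios of Z entries, hence invariant to that scaling.
  Z <- A + t(A)
  diag(Z) <- 0
  i <- match(ego_name, igraph::V(graph)$name)
  contacts <- which(Z[i, ] > 0)
  N <- length(contacts)
  if (N == 0) return(NULL)
  p <- function(a, b) Z[a, b] / sum(Z[a, ])
  cvec <- numeric(N)
  for (jj in seq_len(N)) {
    j <- contacts[jj]
    ind <- 0
    for (q in contacts) {
      if (q != j) ind <- ind + p(i, q) * p(q, j)
    }
    cvec[jj] <- (p(i, j) + ind)^2
  }
  red <- 0
  for (j in contacts) {
    for (q in contacts) {
      if (q == j) next
      m_jq <- Z[j, q] / max(Z[j, -j])
      red <- red + p(i, q) * m_jq
    }
  }
  S <- N - red
  C <- sum(cvec)
  H <- if (N == 1) 0 else {
    ratio <- cvec / (C / N)
    sum(ratio * log(ratio)) / (N * log(N))
  }
  list(p = vapply(contacts, function(j) p(i, j), numeric(1)),
       c = cvec, effective_size = S, efficiency = S / N,
       constraint = C, hierarchy = H)
}

# Pearson chi-square by direct O/E summation.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Random connected-ish weighted graph with a categorical attribute.
random_attr_graph <- function(n, directed = FALSE, p = 0.5, k_cat = 2,
                              max_w = 3) {
  repeat {
    g <- igraph::sample_gnp(n, p, directed = directed)
    if (igraph::ecount(g) > 0) break
  }
  igraph::E(g)$weight <- sample(max_w, igraph::ecount(g), replace = TRUE)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  igraph::V(g)$group <- sample(LETTERS[seq_len(k_cat)], n, replace = TRUE)
  g
}
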