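# Small hand-built corpus exercising every interaction pattern:
#   o1 (u1, conspiracy), o2 (u2, means), o3 (u2, means)
#   u3 retweets o1 twice and o2 once       -> info edge o1-o2, 1 common user
#   u4 comments on o1 twice                -> user edge u4 -> u1, weight 2
#   u5 retweets u3's retweet r1 of o1      -> user edge u5 -> u3 (immediate
#                                             parent), root o1
#   u6 authors o3 and nothing else; nobody touches o3 (isolated everywhere)
tiny_corpus <- function() {
  users <- tibble::tibble(
    user_id = paste0("u", 1:6),
    stakeholder_type = "common_personnel",
    profile_text = c("city hospital", "", "independent blogger",
                     "", "", "government office"))
  tweets <- tibble::tibble(
    tweet_id = c("o1", "o2", "o3", "r1", "r2", "r3", "c1", "c2", "r4"),
    author_id = c("u1", "u2", "u6", "u3", "u3", "u3", "u4", "u4", "u5"),
    kind = c("original", "original", "original", "retweet", "retweet",
             "retweet", "comment", "comment", "retweet"),
    parent_id = c(NA, NA, NA, "o1", "o1", "o2", "o1", "o1", "r1"),
    root_original_id = c("o1", "o2", "o3", "o1", "o1", "o2", "o1", "o1", "o1"),
    topic = c("conspiracy", "means", "means", "conspiracy", "conspiracy",
              "means", "conspiracy", "conspiracy", "conspiracy"),
    alpha = c(0.9, 0.2, 0.5, 0.9, 0.9, 0.2, 0.1, 0.1, 0.9))
  echonet::corpus(users, tweets)
}

named_star <- function(n_leaves) {
  edges <- as.vector(rbind("ctr", paste0("l", seq_len(n_leaves))))
  igraph::make_graph(edges, directed = FALSE)
}

small_config <- function(...) {
  echonet::generator_config(n_users = 300, seed = 99, ...)
}
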