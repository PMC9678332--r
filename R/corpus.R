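#' Interaction corpus container
#'
#' An `echo_corpus` bundles the two tables every network and role analysis
#' derives from: a users table (`user_id`, `stakeholder_type`, `profile_text`)
#' and a tweets table (`tweet_id`, `author_id`, `kind`, `parent_id`,
#' `root_original_id`, `topic`, `alpha`). `alpha` is the sentiment positive
#' probability in \[0, 1\] supplied by an external sentiment model; `topic` is
#' one of [topic_vocabulary()]. Original tweets have no parent; retweets and
#' comments point at an existing parent tweet and inherit the topic of the
#' original at the root of their parent chain.
#'
#' @param users A data frame with columns `user_id`, `stakeholder_type`,
#'   `profile_text`.
#' @param tweets A data frame with columns `tweet_id`, `author_id`, `kind`,
#'   `parent_id`, `root_original_id`, `topic`, `alpha`.
#' @return An object of class `echo_corpus`: a list with tibbles `users` and
#'   `tweets`.
#' @seealso [validate_corpus()], [read_corpus()], [write_corpus()]
#' @export
corpus <- function(users, tweets) {
  users <- as_tibble(users)
  tweets <- as_tibble(tweets)
  need_u <- c("user_id", "stakeholder_type", "profile_text")
  need_t <- c("tweet_id", "author_id", "kind", "parent_id",
              "root_original_id", "topic", "alpha")
  miss_u <- setdiff(need_u, names(users))
  miss_t <- setdiff(need_t, names(tweets))
  if (length(miss_u) || length(miss_t)) {
    abort(paste0("Corpus is missing required columns: ",
                 paste(c(miss_u, miss_t), collapse = ", ")),
          class = "echonet_schema_error")
  }
  bad_kind <- setdiff(unique(tweets$kind), kind_vocabulary())
  if (length(bad_kind)) {
    abort(paste0("Unknown tweet kind(s): ", paste(bad_kind, collapse = ", "),
                 ". Allowed: ", paste(kind_vocabulary(), collapse = ", ")),
          class = "echonet_schema_error")
  }
  structure(list(users = users[need_u], tweets = tweets[need_t]),
            class = "echo_corpus")
}

#' @export
print.echo_corpus <- function(x, ...) {
  n_kind <- table(factor(x$tweets$kind, kind_vocabulary()))
  cat("<echo_corpus>\n")
  cat(sprintf("  users:  %d\n", nrow(x$users)))
  cat(sprintf("  tweets: %d (%d originals, %d retweets, %d comments)\n",
              nrow(x$tweets), n_kind[["original"]], n_kind[["retweet"]],
              n_kind[["comment"]]))
  invisible(x)
}

#' Validate the structural invariants of a corpus
#'
#' Checks referential and structural integrity only (id uniqueness, kind and
#' topic vocabularies, parent references, root resolution through the parent
#' chain, topic inheritance from the root original, `alpha` range, author
#' existence). Content-level filtering — e.g. whether a comment is
#' "meaningful" — is out of scope: such filters are editorial, not structural.
#'
#' @param corp An [corpus()] object.
#' @return A tibble of violations with columns `rule`, `record_id`, `detail`;
#'   zero rows when the corpus is valid. Violations are data, not errors.
#' @examples
#' corp <- generate_echo_corpus(generator_config(n_users = 50, seed = 1))
#' validate_corpus(corp) # 0 rows
#' @export
validate_corpus <- function(corp) {
  stopifnot(inherits(corp, "echo_corpus"))
  users <- corp$users
  tw <- corp$tweets
  v <- list()
  viol <- function(rule, ids, detail) {
    tibble(rule = rule, record_id = as.character(ids), detail = detail)
  }

  dup_u <- users$user_id[duplicated(users$user_id)]
  if (length(dup_u)) v[[length(v) + 1]] <-
    viol("user_id_unique", unique(dup_u), "duplicated user_id")
  dup_t <- tw$tweet_id[duplicated(tw$tweet_id)]
  if (length(dup_t)) v[[length(v) + 1]] <-
    viol("tweet_id_unique", unique(dup_t), "duplicated tweet_id")

  bad_kind <- !tw$kind %in% kind_vocabulary()
  if (any(bad_kind)) v[[length(v) + 1]] <-
    viol("kind_vocabulary", tw$tweet_id[bad_kind], "kind not in vocabulary")

  bad_author <- !tw$author_id %in% users$user_id
  if (any(bad_author)) v[[length(v) + 1]] <-
    viol("author_exists", tw$tweet_id[bad_author], "author_id not in users")

  bad_alpha <- is.na(tw$alpha) | tw$alpha < 0 | tw$alpha > 1
  if (any(bad_alpha)) v[[length(v) + 1]] <-
    viol("alpha_range", tw$tweet_id[bad_alpha], "alpha outside [0, 1]")

  is_orig <- tw$kind == "original"
  bad_op <- is_orig & !is.na(tw$parent_id)
  if (any(bad_op)) v[[length(v) + 1]] <-
    viol("original_no_parent", tw$tweet_id[bad_op], "original with parent_id")
  bad_ot <- is_orig & (is.na(tw$topic) | !tw$topic %in% topic_vocabulary())
  if (any(bad_ot)) v[[length(v) + 1]] <-
    viol("original_topic", tw$tweet_id[bad_ot],
         "original without a valid topic")
  bad_or <- is_orig & tw$root_original_id != tw$tweet_id
  bad_or[is.na(bad_or)] <- TRUE
  bad_or <- bad_or & is_orig
  if (any(bad_or)) v[[length(v) + 1]] <-
    viol("original_root_self", tw$tweet_id[bad_or],
         "original whose root_original_id is not itself")

  inter <- !is_orig
  miss_parent <- inter & is.na(tw$parent_id)
  if (any(miss_parent)) v[[length(v) + 1]] <-
    viol("interaction_has_parent", tw$tweet_id[miss_parent],
         "retweet/comment without parent_id")
  dangling <- inter & !is.na(tw$parent_id) & !tw$parent_id %in% tw$tweet_id
  if (any(dangling)) v[[length(v) + 1]] <-
    viol("parent_exists", tw$tweet_id[dangling],
         "parent_id references no tweet")

  # root resolution and topic inheritance, via the parent's recorded root
  idx <- match(tw$parent_id, tw$tweet_id)
  ok_chain <- inter & !is.na(tw$parent_id) & !is.na(idx)
  if (any(ok_chain)) {
    expected_root <- tw$root_original_id[idx[ok_chain]]
    bad_root <- tw$root_original_id[ok_chain] != expected_root |
      is.na(tw$root_original_id[ok_chain])
    if (any(bad_root)) v[[length(v) + 1]] <-
      viol("root_resolves", tw$tweet_id[ok_chain][bad_root],
           "root_original_id does not match the parent chain")
    root_idx <- match(tw$root_original_id[ok_chain], tw$tweet_id)
    not_orig <- is.na(root_idx) | tw$kind[root_idx] != "original"
    if (any(not_orig)) v[[length(v) + 1]] <-
      viol("root_is_original", tw$tweet_id[ok_chain][not_orig],
           "root_original_id is not an original tweet")
    root_topic <- tw$topic[root_idx]
    bad_topic <- is.na(root_idx) | is.na(tw$topic[ok_chain]) |
      tw$topic[ok_chain] != root_topic
    if (any(bad_topic)) v[[length(v) + 1]] <-
      viol("topic_inheritance", tw$tweet_id[ok_chain][bad_topic],
           "topic differs from the root original's topic")
  }

  if (length(v)) bind_rows(v) else
    tibble(rule = character(), record_id = character(), detail = character())
}
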