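#' Topic-based echoer/bridger coding
#'
#' A user is a topic-based *echoer* when all tweets they created, retweeted,
#' or commented on carry a single topic, and a *bridger* when their activity
#' spans two or more topics. A user with a single original tweet and no
#' interactions is an echoer (one topic).
#'
#' @param corp An [corpus()] object.
#' @return A tibble `user_id`, `n_topics`, `topic_role`; only users with at
#'   least one topic-labeled activity appear (the role is undefined
#'   otherwise).
#' @export
topic_roles <- function(corp) {
  stopifnot(inherits(corp, "echo_corpus"))
  corp$tweets |>
    distinct(.data$author_id, .data$topic) |>
    count(.data$author_id, name = "n_topics") |>
    mutate(topic_role = if_else(.data$n_topics == 1, "echoer", "bridger")) |>
    rename(user_id = "author_id")
}

#' Attitude-based echoer/bridger coding
#'
#' A user is an attitude-based *echoer* when every interaction partner —
#' the author of the immediate parent of each retweet/comment the user sent —
#' shares the user's own attitude; interacting with any differently-minded
#' partner makes them a *bridger*. Users with no outgoing interactions
#' (isolators included) are vacuously echoers.
#'
#' @param corp An [corpus()] object.
#' @param attitudes A tibble `user_id`, `attitude` (e.g. from
#'   [user_roles()]); computed from the corpus when `NULL`.
#' @param band A [sentiment_band()].
#' @return A tibble `user_id`, `attitude`, `attitude_role`, covering every
#'   user with a defined attitude (i.e. every tweet author).
#' @export
attitude_roles <- function(corp, attitudes = NULL, band = sentiment_band()) {
  stopifnot(inherits(corp, "echo_corpus"))
  tw <- corp$tweets
  if (is.null(attitudes)) {
    attitudes <- tibble(author_id = tw$author_id,
                        label = sentiment_label(tw$alpha, band)) |>
      group_by(.data$author_id) |>
      summarise(attitude = user_attitude(.data$label), .groups = "drop") |>
      rename(user_id = "author_id")
  }
  inter <- tw[tw$kind %in% c("retweet", "comment") & !is.na(tw$parent_id), ]
  partner <- tibble(
    user_id = inter$author_id,
    partner_id = tw$author_id[match(inter$parent_id, tw$tweet_id)]) |>
    filter(.data$user_id != .data$partner_id) |>
    left_join(attitudes, by = c(partner_id = "user_id")) |>
    rename(partner_attitude = "attitude")
  crossers <- partner |>
    left_join(attitudes, by = "user_id") |>
    filter(.data$partner_attitude != .data$attitude) |>
    distinct(.data$user_id)
  attitudes |>
    mutate(attitude_role = if_else(.data$user_id %in% crossers$user_id,
                                   "bridger", "echoer"))
}

#' Combined per-user echo roles
#'
#' @param corp An [corpus()] object.
#' @param band A [sentiment_band()].
#' @return A tibble `user_id`, `n_topics`, `topic_role`, `attitude`,
#'   `attitude_role` for all users with topic-labeled activity.
#' @export
echo_roles <- function(corp, band = sentiment_band()) {
  inner_join(topic_roles(corp), attitude_roles(corp, band = band),
             by = "user_id")
}
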