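#' Sentiment band for discretizing positive probabilities
#'
#' A tweet's sentiment positive probability `alpha` is discretized into three
#' labels: negative when `alpha <= neg_max`, positive when
#' `alpha >= pos_min`, neutral in between. The default symmetric band
#' (0.4, 0.6) keeps a genuine neutral region; both thresholds are exposed
#' because published threshold choices for three-way sentiment vary.
#'
#' @param neg_max Upper bound of the negative band.
#' @param pos_min Lower bound of the positive band.
#' @return A `sentiment_band` list.
#' @export
sentiment_band <- function(neg_max = 0.4, pos_min = 0.6) {
  if (!(0 <= neg_max && neg_max < pos_min && pos_min <= 1)) {
    abort("Need 0 <= neg_max < pos_min <= 1.", class = "echonet_config_error")
  }
  structure(list(neg_max = neg_max, pos_min = pos_min),
            class = "sentiment_band")
}

#' Discretize sentiment positive probabilities into labels
#'
#' @param alpha Numeric vector of positive probabilities in \[0, 1\].
#' @param band A [sentiment_band()].
#' @return Character vector in `{negative, neutral, positive}`.
#' @examples
#' sentiment_label(c(0.1, 0.5, 0.95))
#' @export
sentiment_label <- function(alpha, band = sentiment_band()) {
  if (any(is.na(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    abort("`alpha` must lie in [0, 1].", class = "echonet_domain_error")
  }
  case_when(
    alpha <= band$neg_max ~ "negative",
    alpha >= band$pos_min ~ "positive",
    .default = "neutral"
  )
}

#' Aggregate a user's sentiment labels into an attitude
#'
#' The user's attitude is their modal sentiment label across all tweets they
#' wrote (originals, retweets, comments). A tie for the mode means the user
#' expresses no dominant stance and resolves to neutral.
#'
#' @param labels Character vector of sentiment labels (at least one).
#' @return One of `"negative"`, `"neutral"`, `"positive"`.
#' @examples
#' user_attitude(c("positive", "positive", "negative"))
#' user_attitude(c("positive", "negative")) # tie -> neutral
#' @export
user_attitude <- function(labels) {
  if (length(labels) == 0) {
    abort("Cannot derive an attitude from zero labels.",
          class = "echonet_undefined_error")
  }
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) "neutral" else top
}

#' Per-user activity counts
#'
#' Tallies, for every user in the corpus, the counts the behavior taxonomy is
#' defined over: original tweets posted, retweets/comments sent, and
#' retweets/comments received on any tweet the user authored (receipt follows
#' the immediate parent, so a retweet of a user's retweet counts as received
#' by that user).
#'
#' @param corp An [corpus()] object.
#' @return A tibble with columns `user_id`, `tweets_posted`, `retweets_sent`,
#'   `retweets_received`, `comments_sent`, `comments_received`.
#' @export
activity_counts <- function(corp) {
  stopifnot(inherits(corp, "echo_corpus"))
  tw <- corp$tweets
  parent_author <- tw$author_id[match(tw$parent_id, tw$tweet_id)]
  tally <- function(ids) {
    t <- table(factor(ids, levels = corp$users$user_id))
    as.integer(t)
  }
  tibble(
    user_id = corp$users$user_id,
    tweets_posted = tally(tw$author_id[tw$kind == "original"]),
    retweets_sent = tally(tw$author_id[tw$kind == "retweet"]),
    retweets_received = tally(parent_author[tw$kind == "retweet"]),
    comments_sent = tally(tw$author_id[tw$kind == "comment"]),
    comments_received = tally(parent_author[tw$kind == "comment"])
  )
}

#' Classify users by the behavior taxonomy
#'
#' Applies the eight-category behavior taxonomy. The written criteria are not
#' mutually exclusive, so a fixed precedence produces exactly one label per
#' user: automatic, isolator, speaker tiers (retweets received at least 100x
#' / 10x / 3x the user's original tweets), networker, monologist, retweeter,
#' replicator, then common. Mean-based rules compare against population means
#' computed over all users including zeros; any ratio whose denominator is
#' zero evaluates false.
#'
#' @param counts A tibble from [activity_counts()]; optional logical columns
#'   `duplicate_comment_flag` and `profile_blank_flag` feed the automatic
#'   rule (both must hold).
#' @param means Optional named list of population means (`tweets_posted`,
#'   `retweets_received`); computed from `counts` when `NULL`.
#' @return `counts` with a `behavior` column (one of
#'   [behavior_vocabulary()]).
#' @examples
#' counts <- tibble::tibble(user_id = "u1", tweets_posted = 10L,
#'   retweets_sent = 0L, retweets_received = 1500L,
#'   comments_sent = 0L, comments_received = 0L)
#' classify_behavior(counts)$behavior # high_speaker
#' @export
classify_behavior <- function(counts, means = NULL) {
  counts <- as_tibble(counts)
  if (is.null(means)) {
    means <- list(tweets_posted = mean(counts$tweets_posted),
                  retweets_received = mean(counts$retweets_received))
  }
  dup <- if ("duplicate_comment_flag" %in% names(counts))
    counts$duplicate_comment_flag else rep(FALSE, nrow(counts))
  blank <- if ("profile_blank_flag" %in% names(counts))
    counts$profile_blank_flag else rep(FALSE, nrow(counts))
  ratio <- function(num, den) if_else(den > 0, num / den, NA_real_)
  ge <- function(x, t) !is.na(x) & x >= t
  le <- function(x, t) !is.na(x) & x <= t

  tp <- counts$tweets_posted
  rs <- counts$retweets_sent
  rr <- counts$retweets_received
  cs <- counts$comments_sent
  cr <- counts$comments_received
  rr_tp <- ratio(rr, tp)
  rr_rs <- ratio(rr, rs)
  rs_tp <- ratio(rs, tp)
  cs_tp <- ratio(cs, tp)

  counts$behavior <- case_when(
    dup & blank ~ "automatic",
    rs == 0 & rr == 0 & cs == 0 & cr == 0 ~ "isolator",
    ge(rr_tp, 100) ~ "high_speaker",
    ge(rr_tp, 10) ~ "medium_speaker",
    ge(rr_tp, 3) ~ "low_speaker",
    tp >= means$tweets_posted & rr >= means$retweets_received &
      ge(rr_rs, 0.5) ~ "networker",
    tp >= means$tweets_posted & le(rr_tp, 0.3) ~ "monologist",
    tp >= means$tweets_posted & ge(rs_tp, 0.5) ~ "retweeter",
    ge(cs_tp, 0.6) ~ "replicator",
    .default = "common"
  )
  counts
}

#' Load the stakeholder keyword lexicon
#'
#' The lexicon maps eleven stakeholder types to keyword lists, in matching
#' priority order; the fallback type `common_personnel` has no keywords. The
#' packaged default covers government, hospital, traditional media, We-media,
#' platform accounts, social organizations, medical and common companies,
#' educational institutions, and medical personnel. Users can edit a copy of
#' the YAML and pass its path.
#'
#' @param path Optional path to a YAML lexicon; defaults to the packaged one.
#' @return A named list of keyword character vectors, in priority order.
#' @export
stakeholder_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stakeholder_lexicon.yaml",
                                package = "echonet")
  lex <- yaml::read_yaml(path)
  lex <- lapply(lex, function(x) as.character(unlist(x)))
  non_fallback <- names(lex) != "common_personnel"
  if (any(lengths(lex[non_fallback]) == 0)) {
    abort("Every non-fallback stakeholder type needs at least one keyword.",
          class = "echonet_config_error")
  }
  lex
}

#' Match profile text to a stakeholder type
#'
#' Case-insensitive substring matching of lexicon keywords against the
#' concatenated profile text (authentication, introduction, tags); the first
#' type in lexicon order with any matching keyword wins; unmatched profiles
#' fall back to `common_personnel`.
#'
#' @param profile_text Character vector of profile texts.
#' @param lexicon A lexicon from [stakeholder_lexicon()].
#' @return Character vector of stakeholder types.
#' @examples
#' match_stakeholder(c("works at a hospital", ""))
#' @export
match_stakeholder <- function(profile_text, lexicon = stakeholder_lexicon()) {
  text <- tolower(profile_text)
  out <- rep("common_personnel", length(text))
  undecided <- rep(TRUE, length(text))
  for (type in names(lexicon)) {
    kws <- tolower(lexicon[[type]])
    if (!length(kws)) next
    hit <- rep(FALSE, length(text))
    for (kw in kws) hit <- hit | grepl(kw, text, fixed = TRUE)
    out[undecided & hit] <- type
    undecided <- undecided & !hit
  }
  out
}

#' Full per-user role table
#'
#' Combines attitude (modal sentiment label over the user's tweets, ties to
#' neutral), behavior category, and stakeholder type for every user. Users
#' who authored no tweets get attitude `NA`.
#'
#' @param corp An [corpus()] object.
#' @param band A [sentiment_band()].
#' @param lexicon A [stakeholder_lexicon()].
#' @return A tibble: `user_id`, activity counts, `behavior`, `attitude`,
#'   `stakeholder`.
#' @export
user_roles <- function(corp, band = sentiment_band(),
                       lexicon = stakeholder_lexicon()) {
  stopifnot(inherits(corp, "echo_corpus"))
  counts <- classify_behavior(activity_counts(corp))
  labels <- tibble(author_id = corp$tweets$author_id,
                   label = sentiment_label(corp$tweets$alpha, band))
  att <- labels |>
    group_by(.data$author_id) |>
    summarise(attitude = user_attitude(.data$label), .groups = "drop")
  counts |>
    left_join(att, by = c(user_id = "author_id")) |>
    mutate(stakeholder = match_stakeholder(corp$users$profile_text, lexicon))
}
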