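#' Configuration for the synthetic corpus generator
#'
#' The generator plants homophily by a memoryless per-interaction mixture
#' rule: with probability `h` the interaction partner is chosen among
#' same-attribute candidates, otherwise the partner attribute is drawn from
#' the marginal category distribution. Under this rule the expected
#' assortativity coefficient of the resulting network equals `h` exactly for
#' any category distribution (see [expected_assortativity()]), which makes the
#' generator an analytic oracle for the whole measurement pipeline. Topic
#' homophily (information layer) and attitude homophily (user layer) are
#' applied independently.
#'
#' Per-user activity counts are negative-binomial (heavy-tailed) around
#' archetype-specific means; archetypes mirror the behavior taxonomy the
#' classifier recovers (speakers, networkers, monologists, retweeters,
#' replicators, isolators, common users). Isolators send and receive nothing.
#' Speaker-authored originals get a popularity multiplier when interaction
#' targets are drawn, so that the high retweets-received tiers are reachable.
#'
#' @param n_users Number of users (positive integer).
#' @param topic_probs Named 13-vector of topic probabilities over
#'   [topic_vocabulary()]; must sum to 1.
#' @param attitude_probs Named 3-vector (positive, negative, neutral); must
#'   sum to 1.
#' @param h_topic,h_attitude Homophily strengths in \[0, 1\].
#' @param archetype_mix Named fractions over the seven archetypes; sums to 1.
#' @param activity_rates Data frame with columns `archetype`, `originals`,
#'   `retweets`, `comments`: mean counts per user of each activity.
#' @param label_fidelity Probability that a tweet's sentiment band matches its
#'   author's latent attitude (1 = noiseless sentiment model).
#' @param speaker_boost Popularity multiplier for speaker-authored originals
#'   when sampling interaction targets.
#' @param p_deep Fraction of comments attached to a retweet rather than
#'   directly to an original (exercises multi-step parent chains).
#' @param nb_size Negative-binomial size (dispersion) of activity counts;
#'   smaller is heavier-tailed.
#' @param band [sentiment_band()] used to place `alpha` draws.
#' @param seed Integer seed; identical (config, seed) reproduces the corpus
#'   exactly.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_users = 1000,
                             topic_probs = default_topic_probs(),
                             attitude_probs = default_attitude_probs(),
                             h_topic = 0.3,
                             h_attitude = 0.3,
                             archetype_mix = default_archetype_mix(),
                             activity_rates = default_activity_rates(),
                             label_fidelity = 1,
                             speaker_boost = 50,
                             p_deep = 0.15,
                             nb_size = 1.2,
                             band = sentiment_band(),
                             seed = 1L) {
  if (length(n_users) != 1 || is.na(n_users) || n_users < 1) {
    abort("`n_users` must be a positive integer.",
          class = "echonet_config_error")
  }
  assert_prob_vector(topic_probs, "topic_probs", len = 13)
  assert_prob_vector(attitude_probs, "attitude_probs", len = 3)
  if (is.null(names(topic_probs))) names(topic_probs) <- topic_vocabulary()
  if (is.null(names(attitude_probs)))
    names(attitude_probs) <- attitude_vocabulary()
  for (h in c(h_topic = h_topic, h_attitude = h_attitude)) {
    if (is.na(h) || h < 0 || h > 1) {
      abort("Homophily strengths must lie in [0, 1].",
            class = "echonet_config_error")
    }
  }
  assert_prob_vector(unlist(archetype_mix), "archetype_mix", len = 7)
  activity_rates <- as_tibble(activity_rates)
  stopifnot(all(c("archetype", "originals", "retweets", "comments") %in%
                  names(activity_rates)))
  rates <- as.matrix(activity_rates[c("originals", "retweets", "comments")])
  if (anyNA(rates) || any(rates < 0)) {
    abort("Activity rates must be non-negative.",
          class = "echonet_config_error")
  }
  structure(list(
    n_users = as.integer(n_users), topic_probs = topic_probs,
    attitude_probs = attitude_probs, h_topic = h_topic,
    h_attitude = h_attitude, archetype_mix = unlist(archetype_mix),
    activity_rates = activity_rates, label_fidelity = label_fidelity,
    speaker_boost = speaker_boost, p_deep = p_deep, nb_size = nb_size,
    band = band, seed = as.integer(seed)
  ), class = "generator_config")
}

#' @rdname generator_config
#' @export
default_archetype_mix <- function() {
  c(speaker = 0.01, networker = 0.03, monologist = 0.05, retweeter = 0.08,
    replicator = 0.08, isolator = 0.15, common = 0.60)
}

#' @rdname generator_config
#' @export
default_activity_rates <- function() {
  tibble(
    archetype = c("speaker", "networker", "monologist", "retweeter",
                  "replicator", "isolator", "common"),
    originals = c(8, 4, 5, 2, 2, 2, 0.8),
    retweets  = c(0.5, 3, 0.3, 6, 1, 0, 1.2),
    comments  = c(0.5, 2, 0.3, 1, 6, 0, 1.2)
  )
}

#' Read or write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_generator_config()` returns a [generator_config()];
#'   `write_generator_config()` returns `path` invisibly.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$activity_rates)) {
    y$activity_rates <- bind_rows(lapply(y$activity_rates, as_tibble))
  }
  if (!is.null(y$band)) y$band <- sentiment_band(y$band$neg_max, y$band$pos_min)
  for (nm in c("topic_probs", "attitude_probs", "archetype_mix")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  do.call(generator_config, y)
}

#' @rdname read_generator_config
#' @param config A [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  y <- unclass(config)
  # named vectors must become maps or yaml silently drops the names
  for (nm in c("topic_probs", "attitude_probs", "archetype_mix")) {
    y[[nm]] <- as.list(y[[nm]])
  }
  y$activity_rates <- unname(split(as.data.frame(y$activity_rates),
                                   seq_len(nrow(y$activity_rates))))
  y$band <- list(neg_max = config$band$neg_max, pos_min = config$band$pos_min)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Expected assortativity under the planted-homophily mixture rule
#'
#' When each interaction picks a same-category partner with probability `h`
#' and otherwise draws the partner category from the marginal distribution
#' \eqn{\pi}, the mixing matrix is \eqn{e_{ii} = \pi_i(h + (1-h)\pi_i)},
#' \eqn{e_{ij} = (1-h)\pi_i\pi_j}, so Newman's coefficient reduces to
#' \deqn{r = \frac{h + (1-h)\sum\pi^2 - \sum\pi^2}{1 - \sum\pi^2} = h}
#' for every category distribution. This closed form is what makes parameter
#' recovery a meaningful end-to-end check.
#'
#' @param h Homophily strength in \[0, 1\].
#' @return `h`, the expected assortativity coefficient.
#' @examples
#' expected_assortativity(0.5)
#' @export
expected_assortativity <- function(h) {
  if (any(is.na(h)) || any(h < 0) || any(h > 1)) {
    abort("`h` must lie in [0, 1].", class = "echonet_domain_error")
  }
  h
}

default_stakeholder_mix <- function() {
  c(common_personnel = 0.70, we_media = 0.08, traditional_media = 0.05,
    government = 0.04, common_company = 0.04, medical_personnel = 0.03,
    hospital = 0.02, platform_account = 0.01, social_organization = 0.01,
    medical_company = 0.01, educational_institution = 0.01)
}

# one unambiguous keyword per type for generated profiles
stakeholder_profile_seed <- function() {
  c(government = "government office", hospital = "hospital",
    traditional_media = "newspaper", we_media = "blogger",
    platform_account = "Sina Weibo", social_organization = "association",
    medical_company = "vaccine manufacturer", common_company = "company",
    educational_institution = "campus", medical_personnel = "doctor",
    common_personnel = "")
}

#' Generate the synthetic user table
#'
#' Assigns each user a latent attitude (from `attitude_probs`), a behavior
#' archetype (from `archetype_mix`), a preferred topic (from `topic_probs`,
#' the anchor of topic homophily), and a stakeholder type with a matching
#' profile keyword.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `user_id`, `stakeholder_type`,
#'   `profile_text`, `attitude`, `archetype`, `topic_pref`.
#' @export
generate_users <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_users
  withr::with_seed(config$seed, {
    mix <- default_stakeholder_mix()
    seeds <- stakeholder_profile_seed()
    stype <- sample(names(mix), n, replace = TRUE, prob = mix)
    tibble(
      user_id = sprintf("u%06d", seq_len(n)),
      stakeholder_type = stype,
      profile_text = unname(seeds[stype]),
      attitude = sample(names(config$attitude_probs), n, replace = TRUE,
                        prob = config$attitude_probs),
      archetype = sample(names(config$archetype_mix), n, replace = TRUE,
                         prob = config$archetype_mix),
      topic_pref = sample(names(config$topic_probs), n, replace = TRUE,
                          prob = config$topic_probs)
    )
  })
}

# alpha within the band implied by a label; bands kept clear of thresholds
draw_alpha <- function(labels, band) {
  n <- length(labels)
  lo <- c(negative = 0, neutral = band$neg_max + 0.01,
          positive = band$pos_min + 0.01)
  hi <- c(negative = band$neg_max - 0.01, neutral = band$pos_min - 0.01,
          positive = 1)
  runif(n, lo[labels], hi[labels])
}

mixture_draw <- function(own, h, categories, probs) {
  n <- length(own)
  use_own <- runif(n) < h
  out <- sample(categories, n, replace = TRUE, prob = probs)
  out[use_own] <- own[use_own]
  out
}

noisy_labels <- function(latent, fidelity) {
  n <- length(latent)
  flip <- runif(n) >= fidelity
  if (any(flip)) {
    alts <- vapply(latent[flip], function(a) {
      sample(setdiff(attitude_vocabulary(), a), 1)
    }, character(1))
    latent[flip] <- alts
  }
  latent
}

#' Generate the synthetic tweet table for a user table
#'
#' Draws per-user activity counts, writes the original tweets, then assigns
#' every retweet/comment a target by the independent topic/attitude mixture
#' rules: the desired topic is the chooser's preferred topic with probability
#' `h_topic` (else a fresh draw from `topic_probs`), the desired partner
#' attitude is the chooser's attitude with probability `h_attitude` (else a
#' fresh draw from `attitude_probs`); the target is then sampled among
#' originals matching both, weighted by author popularity. A `p_deep` fraction
#' of comments is attached to a matching retweet instead of the original, so
#' parent chains of depth two occur. Isolator-authored tweets are never
#' targeted and isolators send nothing.
#'
#' @param users A table from [generate_users()].
#' @param config The same [generator_config()].
#' @return An [corpus()] object (with the generator seed as attribute).
#' @export
generate_corpus <- function(users, config) {
  stopifnot(inherits(config, "generator_config"), nrow(users) >= 1)
  rates <- config$activity_rates
  if (any(as.matrix(rates[c("originals", "retweets", "comments")]) < 0)) {
    abort("Activity rates must be non-negative.",
          class = "echonet_config_error")
  }
  seed2 <- as.integer((config$seed + 1L) %% .Machine$integer.max)
  tweets <- withr::with_seed(seed2, {
    n <- nrow(users)
    ri <- match(users$archetype, rates$archetype)
    n_orig <- rnbinom(n, size = config$nb_size, mu = rates$originals[ri])
    n_rt <- rnbinom(n, size = config$nb_size, mu = rates$retweets[ri])
    n_cm <- rnbinom(n, size = config$nb_size, mu = rates$comments[ri])
    # isolators must author something for roles to be defined, and nothing else
    iso <- users$archetype == "isolator"
    n_orig[iso] <- pmax(n_orig[iso], 1L)
    n_rt[iso] <- 0L
    n_cm[iso] <- 0L

    # originals -------------------------------------------------------------
    o_author <- rep(seq_len(n), n_orig)
    n_o <- length(o_author)
    o_topic <- mixture_draw(users$topic_pref[o_author], config$h_topic,
                            names(config$topic_probs), config$topic_probs)
    o_label <- noisy_labels(users$attitude[o_author], config$label_fidelity)
    originals <- tibble(
      tweet_id = sprintf("t%07d", seq_len(n_o)),
      author_id = users$user_id[o_author],
      kind = "original",
      parent_id = NA_character_,
      root_original_id = sprintf("t%07d", seq_len(n_o)),
      topic = o_topic,
      alpha = draw_alpha(o_label, config$band)
    )

    # interaction target pools: non-isolator-authored originals -------------
    pool <- originals
    pool$author_idx <- o_author
    pool <- pool[!iso[o_author], , drop = FALSE]
    pool$att <- users$attitude[pool$author_idx]
    pool$w <- if_else(users$archetype[pool$author_idx] == "speaker",
                      config$speaker_boost, 1)

    c_author <- c(rep(seq_len(n), n_rt), rep(seq_len(n), n_cm))
    kind <- rep(c("retweet", "comment"), c(sum(n_rt), sum(n_cm)))
    n_i <- length(c_author)
    if (n_i > 0 && nrow(pool) > 0) {
      want_topic <- mixture_draw(users$topic_pref[c_author], config$h_topic,
                                 names(config$topic_probs),
                                 config$topic_probs)
      want_att <- mixture_draw(users$attitude[c_author], config$h_attitude,
                               names(config$attitude_probs),
                               config$attitude_probs)
      target <- sample_targets(pool, want_topic, want_att, c_author)
      keep <- !is.na(target)
      c_author <- c_author[keep]; kind <- kind[keep]
      want_topic <- want_topic[keep]; want_att <- want_att[keep]
      target <- target[keep]
      n_i <- length(target)
      i_label <- noisy_labels(users$attitude[c_author], config$label_fidelity)
      inter <- tibble(
        tweet_id = sprintf("t%07d", n_o + seq_len(n_i)),
        author_id = users$user_id[c_author],
        kind = kind,
        parent_id = pool$tweet_id[target],
        root_original_id = pool$root_original_id[target],
        topic = pool$topic[target],
        alpha = draw_alpha(i_label, config$band)
      )
      inter <- deepen_comments(inter, users, c_author, want_topic, want_att,
                               config)
      bind_rows(originals, inter)
    } else {
      originals
    }
  })
  corp <- corpus(users[c("user_id", "stakeholder_type", "profile_text")],
                 tweets)
  attr(corp, "seed") <- config$seed
  corp
}

# Vectorized target sampling by (topic, attitude) cell with popularity
# weights; falls back to topic-only, then any candidate, when a cell is
# empty. Self-targets are redrawn, then dropped if unavoidable.
sample_targets <- function(pool, want_topic, want_att, chooser) {
  n_i <- length(want_topic)
  target <- rep(NA_integer_, n_i)
  cell <- paste(want_topic, want_att)
  pool_cell <- paste(pool$topic, pool$att)
  cand_by_cell <- split(seq_len(nrow(pool)), pool_cell)
  cand_by_topic <- split(seq_len(nrow(pool)), pool$topic)
  idx_by_cell <- split(seq_len(n_i), cell)
  for (cl in names(idx_by_cell)) {
    ids <- idx_by_cell[[cl]]
    cand <- cand_by_cell[[cl]]
    if (is.null(cand)) {
      tp <- sub(" .*$", "", cl)
      cand <- cand_by_topic[[tp]]
    }
    if (is.null(cand)) cand <- seq_len(nrow(pool))
    target[ids] <- if (length(cand) == 1L) rep(cand, length(ids)) else
      sample(cand, length(ids), replace = TRUE, prob = pool$w[cand])
  }
  # redraw accidental self-targets
  for (tries in 1:5) {
    selfhit <- which(pool$author_idx[target] == chooser)
    if (!length(selfhit)) break
    for (i in selfhit) {
      cand <- cand_by_cell[[cell[i]]]
      if (is.null(cand)) cand <- seq_len(nrow(pool))
      cand <- cand[pool$author_idx[cand] != chooser[i]]
      target[i] <- if (length(cand) == 0L) NA_integer_ else
        if (length(cand) == 1L) cand else
          sample(cand, 1, prob = pool$w[cand])
    }
    target[is.na(target)] <- NA_integer_
    break
  }
  bad <- !is.na(target) & pool$author_idx[target] == chooser
  target[bad] <- NA_integer_
  target
}

# Re-parent a p_deep fraction of comments onto a retweet matching the same
# desired (topic, partner-attitude) cell, keeping the mixture rule intact.
deepen_comments <- function(inter, users, c_author, want_topic, want_att,
                            config) {
  is_cm <- inter$kind == "comment"
  rt_rows <- which(inter$kind == "retweet")
  if (!any(is_cm) || !length(rt_rows) || config$p_deep <= 0) return(inter)
  pick <- which(is_cm & runif(nrow(inter)) < config$p_deep)
  if (!length(pick)) return(inter)
  rt_att <- users$attitude[c_author[rt_rows]]
  rt_cell <- paste(inter$topic[rt_rows], rt_att)
  rt_by_cell <- split(rt_rows, rt_cell)
  for (i in pick) {
    cand <- rt_by_cell[[paste(want_topic[i], want_att[i])]]
    cand <- cand[c_author[cand] != c_author[i]]
    if (!length(cand)) next
    j <- if (length(cand) == 1L) cand else sample(cand, 1)
    inter$parent_id[i] <- inter$tweet_id[j]
    inter$root_original_id[i] <- inter$root_original_id[j]
    inter$topic[i] <- inter$topic[j]
  }
  inter
}

#' Generate a complete synthetic corpus in one call
#'
#' @param config A [generator_config()].
#' @return An [corpus()] object.
#' @examples
#' corp <- generate_echo_corpus(generator_config(n_users = 200, seed = 42))
#' corp
#' @export
generate_echo_corpus <- function(config) {
  generate_corpus(generate_users(config), config)
}
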