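#' Controlled vocabularies
#'
#' The analysis uses three fixed vocabularies: the 13-topic coding scheme
#' derived from the Health Belief Model constructs (susceptibility, severity,
#' benefits, barriers, cues to action), the three attitude labels, and the
#' three tweet kinds.
#'
#' @return A character vector of allowed labels.
#' @examples
#' topic_vocabulary()
#' @export
topic_vocabulary <- function() {
  c(
    "risk",                # risk of getting infected
    "severity",            # severity of infection / of refusing vaccination
    "effectiveness",       # effectiveness of vaccination
    "adverse_effects",
    "cost",
    "fake_vaccines",       # counterfeit vaccines, fraudulent information
    "safety",              # safety, infectivity, standardization
    "conspiracy",
    "means",               # means to get vaccinated
    "dos_donts",
    "domestic",            # domestic development/production/vaccination
    "foreign",
    "personal_experience"
  )
}

#' @rdname topic_vocabulary
#' @export
attitude_vocabulary <- function() c("positive", "negative", "neutral")

#' @rdname topic_vocabulary
#' @export
kind_vocabulary <- function() c("original", "retweet", "comment")

#' Behavior taxonomy labels, in classification precedence order
#'
#' Most-specific rules first: automated accounts and isolators, then the
#' influential tiers (speakers, networkers), then the broadcaster types
#' (monologist, retweeter, replicator), with `common` as the fallback.
#'
#' @return Character vector of the ten behavior categories.
#' @export
behavior_vocabulary <- function() {
  c("automatic", "isolator",
    "high_speaker", "medium_speaker", "low_speaker",
    "networker", "monologist", "retweeter", "replicator", "common")
}

#' Default topic mixture for the synthetic generator
#'
#' The three dominant topics (domestic 24.46%, foreign 20.40%, conspiracy
#' 16.46%) follow the shares observed in large vaccine-discourse corpora; the
#' remaining 38.68% is spread over the other ten topics with a geometric decay
#' (ratio 0.8), a simple heavy-ish tail in the absence of published per-topic
#' counts.
#'
#' @return Named numeric vector over [topic_vocabulary()] summing to 1.
#' @export
default_topic_probs <- function() {
  topics <- topic_vocabulary()
  probs <- setNames(numeric(13), topics)
  probs["domestic"]   <- 0.2446
  probs["foreign"]    <- 0.2040
  probs["conspiracy"] <- 0.1646
  rest <- setdiff(topics, c("domestic", "foreign", "conspiracy"))
  w <- 0.8^(seq_along(rest) - 1)
  probs[rest] <- (1 - sum(probs)) * w / sum(w)
  probs
}

#' Default attitude mixture for the synthetic generator
#'
#' 42.51% positive and 13.12% negative, matching the attitude shares reported
#' for large Chinese vaccine-discourse corpora; the remainder is neutral.
#'
#' @return Named numeric vector (positive, negative, neutral) summing to 1.
#' @export
default_attitude_probs <- function() {
  c(positive = 0.4251, negative = 0.1312, neutral = 1 - 0.4251 - 0.1312)
}

assert_prob_vector <- function(p, name, len = NULL, tol = 1e-9) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
    abort(sprintf("`%s` must be a non-negative numeric probability vector.", name),
          class = "echonet_config_error")
  }
  if (!is.null(len) && length(p) != len) {
    abort(sprintf("`%s` must have length %d, got %d.", name, len, length(p)),
          class = "echonet_config_error")
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12f).", name, sum(p)),
          class = "echonet_config_error")
  }
  invisible(p)
}
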