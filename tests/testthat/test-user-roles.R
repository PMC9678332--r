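test_that("sentiment labels follow the band thresholds", {
  expect_equal(sentiment_label(c(0.95, 0.5, 0.1)),
               c("positive", "neutral", "negative"))
  expect_equal(sentiment_label(c(0.4, 0.6)), c("negative", "positive"))
  expect_error(sentiment_label(1.2), class = "echonet_domain_error")
  expect_error(sentiment_band(0.7, 0.6), class = "echonet_config_error")
})

test_that("user attitude is the modal label with ties to neutral", {
  expect_equal(user_attitude(c("positive", "positive", "negative")),
               "positive")
  expect_equal(user_attitude(c("positive", "negative")), "neutral")
  expect_equal(user_attitude("neutral"), "neutral")
  expect_error(user_attitude(character()), class = "echonet_undefined_error")
})

counts_row <- function(tp = 0L, rs = 0L, rr = 0L, cs = 0L, cr = 0L) {
  tibble::tibble(user_id = "u", tweets_posted = tp, retweets_sent = rs,
                 retweets_received = rr, comments_sent = cs,
                 comments_received = cr)
}

test_that("behavior taxonomy assigns the expected categories", {
  means <- list(tweets_posted = 5, retweets_received = 10)
  beh <- function(...) classify_behavior(counts_row(...), means)$behavior
  expect_equal(beh(tp = 10L, rr = 1500L), "high_speaker") # ratio 150
  expect_equal(beh(tp = 10L, rr = 150L), "medium_speaker")
  expect_equal(beh(tp = 10L, rr = 40L), "low_speaker")
  expect_equal(beh(tp = 3L), "isolator") # all four interaction counts zero
  expect_equal(beh(tp = 6L, rr = 12L, rs = 24L), "networker")
  expect_equal(beh(tp = 6L, rr = 1L, cr = 1L), "monologist")
  expect_equal(beh(tp = 6L, rs = 3L, rr = 3L, cr = 1L), "retweeter")
  expect_equal(beh(tp = 2L, cs = 2L, rr = 1L), "replicator")
  expect_equal(beh(tp = 1L, rs = 1L, rr = 1L, cs = 0L, cr = 0L), "common")
})

test_that("precedence resolves overlapping broadcaster rules", {
  # both the retweeter (rs/tp = 0.6) and replicator (cs/tp = 0.7) rules fire;
  # retweeter precedes (rr/tp = 0.5 keeps the monologist rule out)
  means <- list(tweets_posted = 10, retweets_received = 100)
  row <- counts_row(tp = 10L, rs = 6L, cs = 7L, rr = 5L)
  expect_equal(classify_behavior(row, means)$behavior, "retweeter")
})

test_that("zero denominators make ratio rules false, never errors", {
  means <- list(tweets_posted = 0, retweets_received = 0)
  # tp = 0: speaker/monologist/retweeter/replicator ratios all undefined,
  # so the high received count cannot make this user a speaker
  row <- counts_row(tp = 0L, rr = 50L, rs = 100L)
  expect_equal(classify_behavior(row, means)$behavior, "networker")
  # rs = 0 blocks the networker ratio as well
  row2 <- counts_row(tp = 0L, rr = 0L, cr = 5L)
  expect_equal(classify_behavior(row2, means)$behavior, "common")
})

test_that("ratio-driven categories are invariant to uniform scaling", {
  withr::with_seed(7, {
    counts <- tibble::tibble(
      user_id = sprintf("u%03d", 1:60),
      tweets_posted = rpois(60, 3),
      retweets_sent = rpois(60, 2),
      retweets_received = rpois(60, 8),
      comments_sent = rpois(60, 2),
      comments_received = rpois(60, 2))
  })
  base <- classify_behavior(counts)
  doubled <- counts |>
    dplyr::mutate(dplyr::across(-"user_id", ~ .x * 2L))
  expect_equal(classify_behavior(doubled)$behavior, base$behavior)
})

test_that("every user gets exactly one behavior and one stakeholder", {
  corp <- generate_echo_corpus(small_config())
  roles <- user_roles(corp)
  expect_equal(nrow(roles), nrow(corp$users))
  expect_true(all(roles$behavior %in% behavior_vocabulary()))
  expect_false(anyNA(roles$behavior))
  expect_false(anyNA(roles$stakeholder))
})

test_that("stakeholder keywords match by priority with a fallback", {
  expect_equal(match_stakeholder("Affiliated hospital of X"), "hospital")
  expect_equal(match_stakeholder(""), "common_personnel")
  expect_equal(match_stakeholder("government-run hospital"), "government")
  expect_equal(match_stakeholder(c("medical enterprise", "tech company")),
               c("medical_company", "common_company"))
  # generator profiles recover their planted stakeholder types
  users <- generate_users(small_config())
  expect_equal(match_stakeholder(users$profile_text), users$stakeholder_type)
})

test_that("isolator archetypes classify as isolators", {
  corp <- generate_echo_corpus(generator_config(n_users = 600, seed = 31))
  users <- generate_users(generator_config(n_users = 600, seed = 31))
  roles <- user_roles(corp)
  iso <- users$user_id[users$archetype == "isolator"]
  frac <- mean(roles$behavior[roles$user_id %in% iso] == "isolator")
  expect_gte(frac, 0.9)
})
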