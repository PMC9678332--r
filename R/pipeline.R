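#' Run the full echo-chamber analysis pipeline
#'
#' End-to-end orchestration on one corpus: validation, the six interaction
#' networks (information and user layers in retweet/comment/global modes),
#' topology summaries, weighted and unweighted assortativity for every
#' network, per-user roles (behavior, stakeholder, attitude), structural-hole
#' indices on the global user network, opinion-leader and spanner detection,
#' echoer/bridger coding, association rules in both directions for leaders,
#' spanners, and all key users pooled, and the chi-square comparisons of
#' leaders vs spanners (behavior composition, topic-bridger share,
#' attitude-bridger share). The run is deterministic for a fixed corpus and
#' configuration.
#'
#' @param corp An [corpus()] object.
#' @param leader_percentile,spanner_percentile Key-user cuts in percent.
#' @param leader_rule `"intersection"` or `"union"` of the two top cuts.
#' @param band A [sentiment_band()].
#' @param lexicon A [stakeholder_lexicon()].
#' @return An `echo_report` list; see Details. Modes with no interactions are
#'   flagged in `empty_modes` rather than failing.
#' @export
run_pipeline <- function(corp, leader_percentile = 5, spanner_percentile = 5,
                         leader_rule = "intersection",
                         band = sentiment_band(),
                         lexicon = stakeholder_lexicon()) {
  stopifnot(inherits(corp, "echo_corpus"))
  violations <- validate_corpus(corp)
  if (nrow(violations)) {
    abort(sprintf("Corpus failed validation (%d violations) at stage 'validate'.",
                  nrow(violations)),
          class = "echonet_integrity_error")
  }

  modes <- c("retweet", "comment", "global")
  nets <- list(
    information = lapply(setNames(modes, modes), function(m)
      build_info_network(corp, m)),
    user = lapply(setNames(modes, modes), function(m)
      build_user_network(corp, m, band = band))
  )
  empty_modes <- unlist(lapply(names(nets), function(layer) {
    ms <- names(nets[[layer]])[vapply(nets[[layer]],
                                      function(g) igraph::ecount(g) == 0,
                                      logical(1))]
    if (length(ms)) paste(layer, ms, sep = "/") else character()
  }))

  topology <- bind_rows(lapply(nets, function(layer)
    bind_rows(lapply(layer, topology_summary))))

  assort <- bind_rows(lapply(nets, function(layer) bind_rows(lapply(layer,
    function(g) {
      bind_rows(lapply(c(TRUE, FALSE), function(wt) {
        a <- assortativity(g, weighted = wt)
        tibble(layer = a$layer, mode = a$mode, attribute = a$attribute,
               weighted = wt, r = a$r, degenerate = a$degenerate)
      }))
    }))))

  roles <- user_roles(corp, band = band, lexicon = lexicon)
  guser <- nets$user$global
  degrees <- node_degrees(guser)
  sh <- sh_table(guser)
  leaders <- detect_opinion_leaders(degrees, leader_percentile, leader_rule)
  leaders_union <- detect_opinion_leaders(degrees, leader_percentile, "union")
  spanners <- detect_spanners(sh, leaders, spanner_percentile)
  eroles <- echo_roles(corp, band = band)

  groups <- list(opinion_leader = leaders, spanner = spanners)
  association <- bind_rows(
    association_rules(eroles, groups, "echoer"),
    association_rules(eroles, groups, "bridger"))

  key_tab <- eroles |>
    filter(.data$user_id %in% c(leaders, spanners)) |>
    mutate(key_role = if_else(.data$user_id %in% leaders,
                              "opinion_leader", "spanner"))
  chi <- list()
  topic_tab <- with(key_tab, table(key_role, topic_role))
  if (all(dim(topic_tab) == c(2, 2)) && all(rowSums(topic_tab) > 0) &&
      all(colSums(topic_tab) > 0)) {
    chi$topic_role <- chi_square_test(topic_tab)
  }
  att_tab <- with(key_tab, table(key_role, attitude_role))
  if (all(dim(att_tab) == c(2, 2)) && all(rowSums(att_tab) > 0) &&
      all(colSums(att_tab) > 0)) {
    chi$attitude_role <- chi_square_test(att_tab)
  }
  beh <- roles |>
    filter(.data$user_id %in% c(leaders, spanners)) |>
    mutate(key_role = if_else(.data$user_id %in% leaders,
                              "opinion_leader", "spanner"))
  beh_tab <- with(beh, table(behavior, key_role))
  beh_tab <- beh_tab[rowSums(beh_tab) > 0, , drop = FALSE]
  if (nrow(beh_tab) >= 2 && ncol(beh_tab) == 2 && all(colSums(beh_tab) > 0)) {
    chi$behavior <- chi_square_test(beh_tab)
  }

  structure(list(
    n_users = nrow(corp$users), n_tweets = nrow(corp$tweets),
    empty_modes = empty_modes,
    topology = topology, assortativity = assort,
    roles = roles, degrees = degrees,
    sh_metrics = sh$metrics, sh_isolated = sh$isolated,
    key_users = list(opinion_leaders = leaders,
                     opinion_leaders_union = leaders_union,
                     spanners = spanners),
    echo_roles = eroles,
    association = association,
    chi_square = chi,
    config = list(leader_percentile = leader_percentile,
                  spanner_percentile = spanner_percentile,
                  leader_rule = leader_rule, band = unclass(band))
  ), class = "echo_report")
}

#' @export
print.echo_report <- function(x, ...) {
  cat("<echo_report>\n")
  cat(sprintf("  corpus: %d users, %d tweets\n", x$n_users, x$n_tweets))
  cat(sprintf("  opinion leaders: %d (%s rule; union cut: %d); spanners: %d\n",
              length(x$key_users$opinion_leaders),
              x$config$leader_rule,
              length(x$key_users$opinion_leaders_union),
              length(x$key_users$spanners)))
  cat("  weighted assortativity:\n")
  aw <- x$assortativity[x$assortativity$weighted, ]
  for (i in seq_len(nrow(aw))) {
    cat(sprintf("    %s/%s (%s): r = %s\n", aw$layer[i], aw$mode[i],
                aw$attribute[i],
                ifelse(is.na(aw$r[i]), "NA", sprintf("%.3f", aw$r[i]))))
  }
  invisible(x)
}

#' Serialize a pipeline report as a JSON + CSV bundle
#'
#' Writes `report.json` (summary quantities, key-user sets, chi-square
#' results) plus tidy CSVs (`topology.csv`, `assortativity.csv`, `roles.csv`,
#' `sh_metrics.csv`, `echo_roles.csv`, `association.csv`) under `dir`.
#'
#' @param report An `echo_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "echo_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("topology", "assortativity", "roles", "sh_metrics",
               "echo_roles", "association")) {
    readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  js <- list(
    n_users = report$n_users, n_tweets = report$n_tweets,
    empty_modes = report$empty_modes,
    key_users = report$key_users,
    chi_square = lapply(report$chi_square, function(ct) list(
      statistic = ct$statistic, df = ct$df, p_value = ct$p_value,
      p_display = ct$p_value_display)),
    config = report$config
  )
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
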