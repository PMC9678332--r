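#' Support and confidence from pre-tabulated counts
#'
#' For the rule "topic-based role implies attitude-based role":
#' support = `n_joint / n_total` (users playing the role in both layers over
#' the whole group) and confidence = `n_joint / n_antecedent` (over the users
#' playing the topic-based role). Confidence is `NA` when the antecedent
#' count is zero.
#'
#' @param counts A data frame with columns `group`, `n_total`,
#'   `n_antecedent`, `n_joint`.
#' @return The input tibble with `support` and `confidence` columns (full
#'   precision; round for display).
#' @examples
#' association_from_counts(tibble::tibble(
#'   group = "leaders", n_total = 386, n_antecedent = 248, n_joint = 234))
#' @export
association_from_counts <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("n_total", "n_antecedent", "n_joint") %in% names(counts)))
  if (any(counts$n_joint > counts$n_antecedent) ||
      any(counts$n_antecedent > counts$n_total)) {
    abort("Counts must satisfy n_joint <= n_antecedent <= n_total.",
          class = "echonet_domain_error")
  }
  counts |>
    mutate(
      support = .data$n_joint / .data$n_total,
      confidence = if_else(.data$n_antecedent > 0,
                           .data$n_joint / .data$n_antecedent, NA_real_))
}

#' Association between topic-based and attitude-based roles, by user group
#'
#' For each group of users (e.g. opinion leaders, structural-hole spanners)
#' and a direction (`"bridger"` or `"echoer"`), tallies the group size, the
#' users whose topic role equals the direction (antecedent), and the users
#' playing the direction in both layers (joint), then computes support and
#' confidence. A pooled `Total` row sums the group counts.
#'
#' @param roles A tibble from [echo_roles()].
#' @param groups Named list of user-id character vectors.
#' @param direction `"bridger"` or `"echoer"`.
#' @return A tibble with one row per group plus `Total`.
#' @export
association_rules <- function(roles, groups,
                              direction = c("bridger", "echoer")) {
  direction <- match.arg(direction)
  missing <- setdiff(unique(unlist(groups)), roles$user_id)
  if (length(missing)) {
    abort(paste0("Echo roles undefined for grouped user(s): ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "echonet_undefined_error")
  }
  rows <- purrr::imap(groups, function(ids, nm) {
    sub <- roles[roles$user_id %in% ids, ]
    tibble(group = nm,
           n_total = nrow(sub),
           n_antecedent = sum(sub$topic_role == direction),
           n_joint = sum(sub$topic_role == direction &
                           sub$attitude_role == direction))
  })
  tab <- bind_rows(rows)
  total <- tibble(group = "Total",
                  n_total = sum(tab$n_total),
                  n_antecedent = sum(tab$n_antecedent),
                  n_joint = sum(tab$n_joint))
  association_from_counts(bind_rows(tab, total)) |>
    mutate(direction = direction, .before = 1)
}

#' Pearson chi-square test with posthoc cell diagnostics
#'
#' Pearson's chi-square on an r x c contingency table without continuity
#' correction, with adjusted standardized residuals per cell and
#' Bonferroni-corrected posthoc flags (cells whose two-sided normal p-value,
#' multiplied by the number of cells, is below `alpha`).
#'
#' @param table A numeric matrix (or table) of counts.
#' @param alpha Posthoc significance level (default 0.05).
#' @return An `echo_chisq` object: `statistic`, `df`, `p_value`, `stdres`
#'   (adjusted standardized residuals), `posthoc_significant` (logical
#'   matrix), `observed`, `expected`.
#' @examples
#' chi_square_test(matrix(c(248, 2316, 138, 807), nrow = 2))
#' @export
chi_square_test <- function(table, alpha = 0.05) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Contingency table has a zero marginal row or column.",
          class = "echonet_degenerate_error")
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  stdres <- ht$stdres
  cell_p <- 2 * pnorm(-abs(stdres))
  structure(list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = max(ht$p.value, 1e-15),
    p_value_display = if (ht$p.value < 0.001) "<.001" else
      sprintf("%.3f", ht$p.value),
    stdres = stdres,
    posthoc_significant = cell_p * length(table) < alpha,
    observed = ht$observed,
    expected = ht$expected
  ), class = "echo_chisq")
}

#' @export
print.echo_chisq <- function(x, ...) {
  cat(sprintf("<echo_chisq> X2(%d) = %.3f, P %s\n", x$df, x$statistic,
              if (x$p_value_display == "<.001") "<.001" else
                paste0("= ", x$p_value_display)))
  invisible(x)
}
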