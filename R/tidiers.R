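#' Tidy a mixing matrix into long form
#'
#' @param x An [mixing_matrix()] result.
#' @param ... Unused.
#' @return A tibble `from`, `to`, `proportion` (edge-weight fraction).
#' @export
tidy.echo_mixing <- function(x, ...) {
  as_tibble(as.data.frame.table(x$e, responseName = "proportion")) |>
    rename(from = "Var1", to = "Var2") |>
    mutate(across(c("from", "to"), as.character))
}

#' @rdname tidy.echo_mixing
#' @export
glance.echo_mixing <- function(x, ...) {
  a <- assortativity(x)
  tibble(categories = length(x$categories), n_edges = x$n_edges,
         directed = x$directed, weighted = x$weighted,
         diag_share = sum(diag(x$e)), r = a$r, degenerate = a$degenerate)
}

#' Tidy an assortativity result
#'
#' @param x An `echo_assort` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.echo_assort <- function(x, ...) {
  tibble(layer = x$layer %||% NA_character_, mode = x$mode %||% NA_character_,
         attribute = x$attribute %||% NA_character_, weighted = x$weighted,
         r = x$r, degenerate = x$degenerate)
}

#' Tidy a chi-square result into per-cell diagnostics
#'
#' @param x An [chi_square_test()] result.
#' @param ... Unused.
#' @return A tibble with one row per cell: observed, expected, adjusted
#'   standardized residual, and the Bonferroni posthoc flag.
#' @export
tidy.echo_chisq <- function(x, ...) {
  obs <- as.data.frame.table(x$observed, responseName = "observed")
  names(obs)[1:2] <- c("row", "col")
  obs$expected <- as.vector(x$expected)
  obs$stdres <- as.vector(x$stdres)
  obs$posthoc_significant <- as.vector(x$posthoc_significant)
  as_tibble(obs) |> mutate(across(c("row", "col"), as.character))
}

#' @rdname tidy.echo_chisq
#' @export
glance.echo_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         p_display = x$p_value_display)
}

#' Tidy a pipeline report: the assortativity table
#'
#' @param x An `echo_report`.
#' @param ... Unused.
#' @return The layer/mode assortativity tibble.
#' @export
tidy.echo_report <- function(x, ...) x$assortativity

#' @rdname tidy.echo_report
#' @export
glance.echo_report <- function(x, ...) {
  tibble(n_users = x$n_users, n_tweets = x$n_tweets,
         n_leaders = length(x$key_users$opinion_leaders),
         n_spanners = length(x$key_users$spanners),
         n_echo_coded = nrow(x$echo_roles))
}
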