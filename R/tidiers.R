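# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy an attractor landscape
#'
#' @param x A `bn_landscape` from [find_attractors()] or
#'   [enumerate_attractors()].
#' @param ... Unused.
#' @return A tibble with one row per attractor: `attractor` (canonical
#'   sequence of state keys), `length`, `basin_count`, `basin_fraction`
#'   and `is_primary`.
#' @export
tidy.bn_landscape <- function(x, ...) {
  tibble::tibble(
    attractor = vapply(x$attractors, function(a) a$id, character(1)),
    length = vapply(x$attractors, function(a) length(a$states), integer(1)),
    basin_count = vapply(x$attractors, function(a) a$basin_count,
                         numeric(1)),
    basin_fraction = vapply(x$attractors, function(a) a$basin_fraction,
                            numeric(1)),
    is_primary = seq_along(x$attractors) == x$primary_index
  )
}

#' @rdname tidy.bn_landscape
#' @export
glance.bn_landscape <- function(x, ...) {
  tibble::tibble(
    n_attractors = length(x$attractors),
    sample_size = x$sample_size,
    mode = x$mode,
    primary_basin_fraction = primary_attractor(x)$basin_fraction,
    primary_length = length(primary_attractor(x)$states)
  )
}

#' Tidy a decomposition
#'
#' @param x A `bn_decomposition` from [decompose()].
#' @param ... Unused.
#' @return The per-edge classification: `source`, `target`, `class`
#'   (`core`/`neighbor`) and `provenance` (`retained`, `insignificant` or
#'   `candidate_deleted`).
#' @export
tidy.bn_decomposition <- function(x, ...) x$provenance

#' @rdname tidy.bn_decomposition
#' @export
glance.bn_decomposition <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$provenance),
    n_core = nrow(x$core_edges),
    n_neighbor = nrow(x$neighbor_edges),
    n_insignificant = sum(x$provenance$provenance == "insignificant"),
    sample_size = x$sample_size,
    primary_length = length(x$primary$states),
    primary_basin_fraction = x$primary$basin_fraction,
    initial_state_seed = x$seeds$initial_state_seed,
    deletion_seed = x$seeds$deletion_seed
  )
}

#' Tidy a null-ensemble comparison
#'
#' @param x A `bn_null_ensemble` from [null_comparison()].
#' @param ... Unused.
#' @return `tidy()`: one row per null replicate; `glance()`: the observed
#'   value, null summary and one-sided p-value.
#' @export
tidy.bn_null_ensemble <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_values),
                 statistic = x$statistic,
                 value = x$null_values)
}

#' @rdname tidy.bn_null_ensemble
#' @export
glance.bn_null_ensemble <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    observed = unname(x$observed[1L]),
    null_mean = mean(x$null_values),
    null_sd = sd(x$null_values),
    replicates = length(x$null_values),
    direction = x$direction,
    p_value = x$p_value,
    degenerate_null = x$degenerate_null
  )
}

#' Plot an attractor landscape
#'
#' Bar chart of basin fractions per attractor, the primary attractor
#' highlighted.
#'
#' @param object A `bn_landscape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_landscape <- function(object, ...) {
  d <- tidy(object)
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$basin_fraction,
                                  fill = .data$is_primary)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey40")) +
    ggplot2::labs(x = "attractor (by basin rank)", y = "basin fraction",
                  title = sprintf("%d attractors from %d initial states (%s)",
                                  nrow(d), object$sample_size,
                                  object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a decomposition's node scores
#'
#' Histogram of per-node evolvability scores for a decomposition.
#'
#' @param object A `bn_decomposition`.
#' @param net The decomposed [boolean_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_decomposition <- function(object, net, ...) {
  sc <- node_scores(net, object)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$evolvability)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.1),
                            fill = "grey30", color = "white") +
    ggplot2::labs(x = "node evolvability score", y = "nodes",
                  title = sprintf("core %d / neighbor %d edges",
                                  nrow(object$core_edges),
                                  nrow(object$neighbor_edges))) +
    ggplot2::theme_minimal()
}

#' Plot a null-ensemble comparison
#'
#' Null distribution of the statistic with the observed value marked.
#'
#' @param object A `bn_null_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_null_ensemble <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey60", color = "white") +
    ggplot2::geom_vline(xintercept = unname(object$observed[1L]),
                        color = "#b2182b", linewidth = 1) +
    ggplot2::labs(x = object$statistic, y = "null replicates",
                  title = sprintf("observed vs %d nulls, one-sided p = %.3g",
                                  length(object$null_values),
                                  object$p_value)) +
    ggplot2::theme_minimal()
}
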