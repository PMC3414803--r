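# broom-style tidiers and ggplot2 autoplot methods.

#' @exportS3Method generics::tidy
tidy.famint_partition <- function(x, ...) {
  x$assignment |>
    mutate(family_size = x$family_sizes[.data$famint + 1L])
}

#' @exportS3Method generics::glance
glance.famint_partition <- function(x, ...) {
  tibble(n_proteins = nrow(x$assignment),
         n_families = length(x$family_sizes),
         n_singletons = sum(x$family_sizes == 1L),
         largest_family = max(x$family_sizes),
         inflation = x$inflation, iccc = x$iccc, converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.famint_sweep <- function(x, ...) {
  as_tibble(x)[, c("inflation", "n_families", "n_singletons", "iccc",
                   "converged")]
}

#' @exportS3Method generics::glance
glance.famint_sweep <- function(x, ...) {
  p <- attr(x, "selected_partition")
  glance(p) |> mutate(n_grid_points = nrow(x), .before = 1)
}

#' @exportS3Method generics::tidy
tidy.host_graph <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.host_graph <- function(x, ...) {
  comps <- host_components(x)
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_components = length(comps),
         largest_component = if (length(comps)) max(lengths(comps)) else 0L,
         total_weight = sum(x$edges$weight))
}

#' Plot the ICCC profile of an inflation sweep
#'
#' @param object A `famint_sweep`.
#' @param ... Unused.
#' @return A ggplot: ICCC against inflation with the selected point marked.
#' @exportS3Method ggplot2::autoplot
autoplot.famint_sweep <- function(object, ...) {
  df <- tidy(object)
  sel <- attr(object, "selected_inflation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inflation, y = .data$iccc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "inflation factor", y = "ICCC",
                  title = sprintf("ICCC inflation sweep (selected %.1f)",
                                  sel)) +
    ggplot2::theme_minimal()
}

#' Plot the family size distribution of a partition
#'
#' @param object A `famint_partition`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.famint_partition <- function(object, ...) {
  df <- tibble(famint = seq_along(object$family_sizes) - 1L,
               size = object$family_sizes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$famint, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "family (size rank)", y = "members",
                  title = "Family size distribution") +
    ggplot2::theme_minimal()
}

#' Plot a host-sharing network on a circular layout
#'
#' Deterministic circular layout; edge width is proportional to the number
#' of shared families.
#'
#' @param object A `host_graph`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.host_graph <- function(object, ...) {
  labs <- sort(object$nodes$label)
  k <- length(labs)
  theta <- 2 * pi * (seq_len(k) - 1) / max(k, 1)
  pos <- tibble(label = labs, x = cos(theta), y = sin(theta))
  e <- object$edges |>
    left_join(pos, by = c(from = "label")) |>
    left_join(pos, by = c(to = "label"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, linewidth = .data$weight),
      colour = "grey60", alpha = 0.7) +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y),
                        size = 2) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                                    label = .data$label), size = 2.6) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::coord_equal(xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Hosts linked by shared families")
}
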