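#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for context-statistics and spectrum objects
#'
#' `tidy()` returns the underlying tibble (one row per context or per
#' substitution); `glance()` returns a one-row summary.
#'
#' @param x A `ctxmut_stats` or `ctxmut_spectrum` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ctxmut_stats
#' @export
tidy.ctxmut_stats <- function(x, ...) {
  out <- x
  attr(out, "contrasts") <- NULL
  class(out) <- setdiff(class(out), "ctxmut_stats")
  tibble::as_tibble(out)
}

#' @rdname tidy.ctxmut_stats
#' @method glance ctxmut_stats
#' @export
glance.ctxmut_stats <- function(x, ...) {
  tibble::tibble(
    n_contexts = nrow(x),
    n_defined = sum(x$flag == "ok"),
    n_events_max = max(x$n),
    median_bias = stats::median(x$mutation_bias, na.rm = TRUE),
    max_minimal_contrast = max(x$minimal_contrast, na.rm = TRUE)
  )
}

#' @rdname tidy.ctxmut_stats
#' @method tidy ctxmut_spectrum
#' @export
tidy.ctxmut_spectrum <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ctxmut_spectrum")
  tibble::as_tibble(out)
}

#' @rdname tidy.ctxmut_stats
#' @method glance ctxmut_spectrum
#' @export
glance.ctxmut_spectrum <- function(x, ...) {
  tibble::tibble(
    n_events = sum(x$n),
    transitions = sum(x$fraction[x$class == "transition"]),
    transversions = sum(x$fraction[x$class == "transversion"]),
    ts_tv_ratio = sum(x$fraction[x$class == "transition"]) /
      sum(x$fraction[x$class == "transversion"])
  )
}

#' Plot mutation bias against minimal contrast
#'
#' The standard representation of context-dependent mutagenesis: each point
#' is one mutation context, x the minimal contrast (excess unexplained by
#' any subcontext), y the mutation bias (total excess over the single-base
#' rate), both on log scales so the null sits at (1, 1). Complementary
#' contexts are expected to land in near-coincident pairs on
#' strand-symmetric data.
#'
#' @param object A `ctxmut_stats` table.
#' @param min_count Hide contexts with fewer events than this.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctxmut_stats
#' @export
autoplot.ctxmut_stats <- function(object, min_count = 1, ...) {
  dat <- dplyr::filter(scatter_data(object),
    .data$n >= min_count, .data$mutation_bias > 0, .data$minimal_contrast > 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$minimal_contrast, .data$mutation_bias)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "minimal contrast", y = "mutation bias")
}

#' @rdname autoplot.ctxmut_stats
#' @method autoplot ctxmut_spectrum
#' @export
autoplot.ctxmut_spectrum <- function(object, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
    substitution = factor(.data$substitution, levels = .data$substitution))
  ggplot2::ggplot(dat, ggplot2::aes(.data$substitution, .data$fraction, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of mutations", fill = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
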