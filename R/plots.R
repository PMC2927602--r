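#' Plot a bound/unbound mobility profile
#'
#' Line plot of per-residue RMSF along the chain, bound and unbound forms
#' overlaid.
#'
#' @param object A `paired_profile` from [bound_unbound_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.paired_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("rmsf_bound", "rmsf_unbound"),
                              names_to = "form", values_to = "rmsf",
                              names_prefix = "rmsf_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$resno, y = .data$rmsf,
                                     colour = .data$form)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (model units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bound-vs-unbound scatter with interpolating lines
#'
#' Reproduces the semi-interface mobility scatter: unbound RMSF on x, bound
#' on y, one through-origin interpolating line per group, with the `y = x`
#' reference dashed.
#'
#' @param object A `scatter_fit` from [scatter_and_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scatter_fit <- function(object, ...) {
  sl <- dplyr::filter(object$slopes, !is.na(.data$slope))
  ggplot2::ggplot(object$scatter,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(
      data = sl,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$group)
    ) +
    ggplot2::labs(x = "unbound RMSF (model units)",
                  y = "bound RMSF (model units)", colour = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot normalized cumulative RMSF distributions
#'
#' @param object A `distribution_summary`, or a named list of them (one
#'   curve per set, e.g. semi-interface vs other surface residues).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.distribution_summary <- function(object, ...) {
  plot_cumulative(list(all = object))
}

#' @rdname autoplot.distribution_summary
#' @param summaries Named list of `distribution_summary` objects.
#' @export
plot_cumulative <- function(summaries) {
  curves <- dplyr::bind_rows(
    lapply(names(summaries), function(nm)
      dplyr::mutate(summaries[[nm]]$cdf, set = nm))
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$rmsf,
                                       y = .data$cumulative,
                                       colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "RMSF (model units)",
                  y = "cumulative fraction of residues", colour = NULL) +
    ggplot2::theme_minimal()
}
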