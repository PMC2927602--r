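#' Summary of an RMSF distribution
#'
#' Mean, spread, fraction of residues below a mobility threshold, and the
#' normalized cumulative distribution on a fixed grid, for a set of RMSF
#' values (model units). The standard deviation uses the population
#' convention (divide by n). The default threshold 1.0 marks intermediate
#' mobility on the model's adimensional scale.
#'
#' @param rmsf Numeric vector of RMSF values (e.g. a `mobility_profile`
#'   column restricted to a residue set).
#' @param threshold Mobility threshold for `fraction_below`.
#' @param grid Grid on which the cumulative distribution is evaluated;
#'   defaults to 201 points from 0 to `max(rmsf)`.
#' @return A `distribution_summary`: list with `n`, `mean`, `sd`,
#'   `fraction_below`, `threshold`, and `cdf` (tibble `rmsf`, `cumulative`).
#' @export
#' @examples
#' s <- summarize_distribution(c(0.5, 1.5))
#' c(s$mean, s$fraction_below)
summarize_distribution <- function(rmsf, threshold = 1.0, grid = NULL) {
  rmsf <- as.numeric(rmsf)
  if (length(rmsf) == 0) stop("empty residue set", call. = FALSE)
  if (any(!is.finite(rmsf)) || any(rmsf < 0))
    stop("RMSF values must be finite and non-negative", call. = FALSE)
  if (is.null(grid)) grid <- seq(0, max(rmsf), length.out = 201)
  m <- mean(rmsf)
  structure(
    list(
      n = length(rmsf),
      mean = m,
      sd = sqrt(mean((rmsf - m)^2)),
      fraction_below = mean(rmsf < threshold),
      threshold = threshold,
      cdf = tibble::tibble(
        rmsf = grid,
        cumulative = vapply(grid, function(g) mean(rmsf <= g), numeric(1))
      )
    ),
    class = "distribution_summary"
  )
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat("RMSF distribution: n =", x$n,
      " mean =", signif(x$mean, 4),
      " sd =", signif(x$sd, 4),
      " fraction below", x$threshold, "=", signif(x$fraction_below, 4), "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.distribution_summary <- function(x, ...) {
  tibble::tibble(n = x$n, mean = x$mean, sd = x$sd,
                 fraction_below = x$fraction_below,
                 threshold = x$threshold)
}

#' Bound-vs-unbound scatter with interpolating slopes
#'
#' Assembles per-residue (unbound RMSF, bound RMSF) pairs for a residue set
#' (typically the semi-interface of each complex) and fits, per group, the
#' interpolating line through the origin by least squares (slope
#' `sum(xy)/sum(x^2)`), the natural choice when slopes are read against the
#' reference lines `y = x` and `y = x/2`. A free-intercept fit is available
#' with `intercept = TRUE`. Pairs violating the bound <= unbound constraint
#' by more than `violation_tol` are flagged in the returned scatter table.
#'
#' @param paired A `paired_profile` tibble (or any tibble with
#'   `rmsf_unbound`, `rmsf_bound`), optionally pre-filtered to the residue
#'   set of interest and carrying grouping columns.
#' @param group Name of the grouping column, or `NULL` for a single group.
#' @param intercept Fit a free intercept instead of constraining the line
#'   through the origin.
#' @param violation_tol Tolerance on `rmsf_bound <= rmsf_unbound`.
#' @return A `scatter_fit`: list with `scatter` (tibble `x` = unbound, `y` =
#'   bound, group, `violates`) and `slopes` (tibble: group, `slope`,
#'   `intercept`, `n`; slope `NA` for groups with fewer than 2 points).
#' @export
scatter_and_fit <- function(paired, group = NULL, intercept = FALSE,
                            violation_tol = 1e-6) {
  stopifnot(all(c("rmsf_unbound", "rmsf_bound") %in% names(paired)))
  grp <- if (is.null(group)) rep("all", nrow(paired))
         else as.character(paired[[group]])
  scatter <- tibble::tibble(
    x = paired$rmsf_unbound, y = paired$rmsf_bound, group = grp,
    violates = paired$rmsf_bound > paired$rmsf_unbound + violation_tol
  )
  slopes <- scatter |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2)
        return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                              n = nrow(d)))
      fit <- if (intercept) stats::lm(y ~ x, data = d)
             else stats::lm(y ~ 0 + x, data = d)
      cf <- stats::coef(fit)
      tibble::tibble(slope = unname(cf[["x"]]),
                     intercept = if (intercept) unname(cf[[1]]) else 0,
                     n = nrow(d))
    }) |>
    dplyr::ungroup()
  structure(list(scatter = scatter, slopes = slopes,
                 intercept_fit = intercept),
            class = "scatter_fit")
}

#' @export
print.scatter_fit <- function(x, ...) {
  cat("Bound-vs-unbound scatter:", nrow(x$scatter), "residues,",
      sum(x$scatter$violates), "constraint violations\n")
  print(x$slopes)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scatter_fit <- function(x, ...) x$slopes

#' Classify the mobility scenario of a residue set
#'
#' Labels a set of (unbound, bound) RMSF pairs with the three-way scheme:
#' `A` - fluctuations small in both forms (points near the origin); `B` -
#' small bound, large unbound (points along the x axis); `C` - large in both
#' (points in the region y < x away from the origin). "Small" and "large"
#' are resolved by comparing a location statistic (the median by default) of
#' each coordinate with `mobility_threshold`; statistic and threshold are
#' always reported with the label.
#'
#' @param scatter A `scatter_fit`, or a tibble with columns `x` (unbound)
#'   and `y` (bound).
#' @param mobility_threshold Threshold separating small from large RMSF
#'   (model units, default 1.0).
#' @param stat Location statistic, `"median"` or `"mean"`.
#' @return A tibble: `label` (`"A"`, `"B"` or `"C"`), `x_stat`, `y_stat`,
#'   `mobility_threshold`, `stat`, `n`.
#' @export
#' @examples
#' classify_scenario(tibble::tibble(x = c(2, 2.1), y = c(0.3, 0.2)))
classify_scenario <- function(scatter, mobility_threshold = 1.0,
                              stat = c("median", "mean")) {
  stat <- match.arg(stat)
  d <- if (inherits(scatter, "scatter_fit")) scatter$scatter else scatter
  stopifnot(all(c("x", "y") %in% names(d)), nrow(d) >= 1)
  f <- if (stat == "median") stats::median else mean
  xs <- f(d$x); ys <- f(d$y)
  label <- if (xs < mobility_threshold && ys < mobility_threshold) "A"
           else if (ys < mobility_threshold) "B"
           else "C"
  tibble::tibble(label = label, x_stat = xs, y_stat = ys,
                 mobility_threshold = mobility_threshold, stat = stat,
                 n = nrow(d))
}
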