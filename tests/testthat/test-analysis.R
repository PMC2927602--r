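test_that("distribution summaries match hand computations and behave as
           proper CDFs", {
  s <- summarize_distribution(c(0.5, 1.5))
  expect_equal(s$mean, 1.0)
  expect_equal(s$fraction_below, 0.5)
  expect_equal(s$sd, 0.5)            # population convention

  const <- summarize_distribution(rep(0.7, 10))
  expect_equal(const$sd, 0)

  set.seed(1)
  s2 <- summarize_distribution(rexp(200))
  expect_true(all(diff(s2$cdf$cumulative) >= 0))
  expect_equal(s2$cdf$cumulative[nrow(s2$cdf)], 1)

  expect_error(summarize_distribution(numeric(0)), "empty")
})

test_that("through-origin slopes match the closed form and flag constraint
           violations", {
  ident <- tibble::tibble(rmsf_unbound = c(1, 2, 3),
                          rmsf_bound = c(1, 2, 3))
  expect_equal(scatter_and_fit(ident)$slopes$slope, 1)

  half <- tibble::tibble(rmsf_unbound = c(2, 4, 6),
                         rmsf_bound = c(1, 2, 3))
  expect_equal(scatter_and_fit(half)$slopes$slope, 0.5)

  set.seed(7)
  for (rep in 1:10) {
    x <- runif(40, 0.2, 3)
    y <- pmin(x, x * runif(40, 0.3, 1))
    fit <- scatter_and_fit(tibble::tibble(rmsf_unbound = x,
                                          rmsf_bound = y))
    expect_lt(abs(fit$slopes$slope - sum(x * y) / sum(x^2)), 1e-10)
  }

  bad <- tibble::tibble(rmsf_unbound = c(1, 1), rmsf_bound = c(1.5, 0.5))
  expect_identical(scatter_and_fit(bad)$scatter$violates, c(TRUE, FALSE))

  lone <- tibble::tibble(rmsf_unbound = 1, rmsf_bound = 0.5)
  expect_true(is.na(scatter_and_fit(lone)$slopes$slope))

  free <- scatter_and_fit(tibble::tibble(rmsf_unbound = c(1, 2, 3),
                                         rmsf_bound = c(1.1, 1.9, 3.1)),
                          intercept = TRUE)
  expect_false(free$slopes$intercept == 0)
})

test_that("denser interfaces depress the bound/unbound slope relative to
           sparse ones", {
  family_slope <- function(target, seeds) {
    rows <- lapply(seeds, function(s) {
      d <- make_dimer(synthetic_dimer_spec(16, 16, target,
                                           geometry = "helix_pair",
                                           seed = s))
      pp <- bound_unbound_profiles(d)
      ic <- interchain_contacts(d, 7.5)
      pp[pp$resno %in% unique(ic$resno_first), ]
    })
    paired <- dplyr::bind_rows(rows)
    fit <- scatter_and_fit(paired)
    # closed-form re-check on every fit
    expect_lt(abs(fit$slopes$slope -
                    sum(fit$scatter$x * fit$scatter$y) /
                    sum(fit$scatter$x^2)), 1e-10)
    fit$slopes$slope
  }
  dense <- family_slope(20, 1:4)
  sparse <- family_slope(5, 1:4)
  expect_lt(dense, sparse)
})

test_that("scenario labels follow the threshold semantics", {
  near_origin <- tibble::tibble(x = rep(0.3, 5), y = rep(0.2, 5))
  expect_identical(classify_scenario(near_origin)$label, "A")

  x_axis <- tibble::tibble(x = rep(2.0, 5), y = rep(0.3, 5))
  expect_identical(classify_scenario(x_axis)$label, "B")

  both_large <- tibble::tibble(x = rep(2.0, 5), y = rep(1.8, 5))
  expect_identical(classify_scenario(both_large)$label, "C")

  out <- classify_scenario(near_origin, mobility_threshold = 0.25)
  expect_identical(out$label, "B")
  expect_identical(out$mobility_threshold, 0.25)
  expect_identical(out$stat, "median")
})

test_that("plot builders return ggplot objects", {
  d <- fix_globule_dimer(seed = 3)
  pp <- bound_unbound_profiles(d)
  expect_s3_class(ggplot2::autoplot(pp), "ggplot")
  fit <- scatter_and_fit(pp)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(ggplot2::autoplot(summarize_distribution(pp$rmsf_bound)),
                  "ggplot")
})
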