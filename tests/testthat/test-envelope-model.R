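test_that("gradient binning satisfies the category constraints", {
  cats <- bin_gradient(runif(60), binning_config())
  expect_equal(lengths(cats), rep(20, 3), ignore_attr = TRUE)

  cats65 <- bin_gradient(runif(65), binning_config())
  expect_equal(unname(lengths(cats65)), c(17, 16, 16, 16))

  expect_equal(unname(lengths(bin_gradient(runif(45)))), rep(15, 3))

  for (n in c(10, 21, 41, 200, 499)) {
    x <- withr::with_seed(n, runif(n))
    cats <- bin_gradient(x, binning_config())
    sizes <- lengths(cats)
    expect_equal(sort(unlist(cats)), seq_len(n), ignore_attr = TRUE)  # partition
    expect_lte(max(sizes), 20)
    expect_gte(length(cats), 3)
    expect_lte(diff(range(sizes)), 1)
    # contiguity in sorted order: category x-ranges do not interleave
    maxima <- vapply(cats, function(i) max(x[i]), numeric(1))
    minima <- vapply(cats, function(i) min(x[i]), numeric(1))
    expect_true(all(head(maxima, -1) <= minima[-1]))
  }

  expect_error(bin_gradient(runif(2)), "at least 3")
})

test_that("percentile envelopes use type-7 interpolation and are order statistics", {
  x <- rep(1, 100)
  cats <- list(seq_len(100))
  expect_equal(percentile_envelope(x, rep(7, 100), cats)$q, 7)
  expect_equal(percentile_envelope(x, 1:100, cats)$q, 95.05)

  shuffled <- withr::with_seed(1, sample(1:100))
  expect_equal(percentile_envelope(x, shuffled, cats)$q, 95.05)

  # against the manual sort-and-interpolate oracle on random vectors
  for (i in 1:200) {
    v <- withr::with_seed(i, rpois(sample(5:60, 1), 20))
    got <- percentile_envelope(seq_along(v), v, list(seq_along(v)))$q
    expect_equal(got, oracle_quantile7(v, 0.95), tolerance = 1e-12)
  }

  # representative x is the category median
  pts <- percentile_envelope(c(1, 2, 10), c(0, 0, 0), list(1:3))
  expect_equal(pts$x, 2)
  expect_equal(pts$n_obs, 3)
})

test_that("noise-free envelopes recover their generating polynomials", {
  x <- 1:10
  lin <- tibble::tibble(category = 1:10, x = x, q = exp(0.2 * x), n_obs = rep(7, 10))
  f <- fit_envelope_glm(lin)
  expect_equal(f$degree, 1)
  expect_equal(f$coefficients[2], 0.2, tolerance = 1e-6)
  expect_equal(f$shape, "monotone_up")

  # direct likelihood maximisation oracle agrees with the glm route
  nll <- function(b) {
    mu <- exp(b[1] + b[2] * x)
    -sum(lin$n_obs * (lin$q * log(mu) - mu))
  }
  opt <- optim(c(0, 0.1), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(f$coefficients, unname(opt$par), tolerance = 1e-3)

  quad <- tibble::tibble(category = 1:10, x = x,
                         q = exp(3 + 0.8 * x - 0.08 * x^2), n_obs = rep(7, 10))
  f2 <- fit_envelope_glm(quad)
  expect_equal(f2$degree, 2)
  vertex <- -f2$coefficients[2] / (2 * f2$coefficients[3])
  expect_equal(vertex, 5, tolerance = 1e-6)  # analytic vertex of the truth
  expect_equal(f2$shape, "unimodal")
  expect_equal(f2$peaks$x[1], 5, tolerance = 0.02)

  const <- tibble::tibble(category = 1:10, x = x, q = rep(20, 10), n_obs = rep(7, 10))
  f0 <- fit_envelope_glm(const)
  expect_equal(f0$degree, 0)
  expect_lt(f0$deviance_explained, 1e-8)
  expect_equal(f0$shape, "flat")
  expect_equal(predict_envelope(f0, 5), 20, tolerance = 1e-8)
})

test_that("fits are invariant to shifting the gradient origin", {
  x <- 1:12
  q <- exp(2 + 0.5 * x - 0.05 * x^2)
  pts <- tibble::tibble(category = 1:12, x = x, q = q, n_obs = rep(5, 12))
  f <- fit_envelope_glm(pts)
  shifted <- dplyr::mutate(pts, x = x + 100)
  fs <- fit_envelope_glm(shifted)
  expect_equal(fs$peaks$x, f$peaks$x + 100, tolerance = 1e-4)
  expect_equal(fs$deviance_explained, f$deviance_explained, tolerance = 1e-10)
})

test_that("degenerate envelope inputs raise informative errors", {
  few <- tibble::tibble(category = 1:2, x = 1:2, q = c(1, 2), n_obs = c(5, 5))
  expect_error(fit_envelope_glm(few), "fewer envelope points")
  same_x <- tibble::tibble(category = 1:5, x = rep(3, 5), q = 1:5, n_obs = rep(5, 5))
  expect_error(fit_envelope_glm(same_x), "all equal")
})

test_that("shape characterisation distinguishes monotone, unimodal and other", {
  x <- 1:10
  up <- fit_envelope_glm(tibble::tibble(category = 1:10, x = x,
                                        q = exp(0.3 * x), n_obs = rep(5, 10)))
  expect_equal(up$shape, "monotone_up")
  down <- fit_envelope_glm(tibble::tibble(category = 1:10, x = x,
                                          q = exp(3 - 0.3 * x), n_obs = rep(5, 10)))
  expect_equal(down$shape, "monotone_down")

  # log-cubic rising at both ends with an interior max and min: two abundance
  # maxima in range (interior + right boundary) -> "other"
  logmu <- function(x) 0.05 * (x - 5)^3 - 0.6 * (x - 5) + 2
  cub <- fit_envelope_glm(
    tibble::tibble(category = 1:11, x = 0:10, q = exp(logmu(0:10)), n_obs = rep(5, 11)),
    envelope_config(deviance_gain = 0)
  )
  expect_equal(cub$degree, 3)
  expect_equal(cub$shape, "other")
  expect_equal(nrow(cub$peaks), 2)
  # grid-search oracle: count local maxima of the true mean incl. boundaries
  grid <- seq(0, 10, length.out = 2001)
  mu <- exp(logmu(grid))
  n_max <- sum(mu[2:2000] > mu[1:1999] & mu[2:2000] >= mu[3:2001]) +
    (mu[1] > mu[2]) + (mu[2001] > mu[2000])
  expect_equal(n_max, 2)
})

test_that("the suite fits every taxon-variable pair and recovers truth shapes", {
  design <- gradient_design(n_samples = 500, seed = 21)
  meta <- generate_environment(design)
  shapes <- c(up1 = "monotone_up", up2 = "monotone_up", up3 = "monotone_up",
              dn1 = "monotone_down", dn2 = "monotone_down", dn3 = "monotone_down",
              un1 = "unimodal", un2 = "unimodal", un3 = "unimodal",
              fl1 = "flat", fl2 = "flat", bi1 = "bimodal")
  truth <- purrr::imap(shapes, function(s, id) {
    response_curve(s, base_abundance = 150, rate = 0.25, peak = 28, width = 2.5)
  })
  counts <- generate_counts(meta, truth, seed = 22)
  suite <- run_envelope_suite(counts, meta,
                              variables = c("temperature", "depth", "salinity"))
  td <- tidy(suite)
  expect_equal(nrow(td), 36)  # 12 taxa x 3 variables
  expect_true(all(td$status == "ok"))

  # shape recovery on the informative gradient (temperature)
  temp <- td[td$variable == "temperature", ]
  expected <- unname(ifelse(shapes == "bimodal", "other", shapes))
  agreement <- sum(temp$shape[match(names(shapes), temp$taxon)] == expected)
  expect_gte(agreement, 10)

  # a taxon absent from every sample is flagged, not fitted
  zero <- counts
  zero[zero$otu_id == "fl1", -1] <- 0
  suite0 <- run_envelope_suite(zero, meta, variables = "temperature")
  expect_equal(tidy(suite0)$status[tidy(suite0)$taxon == "fl1"], "skipped_all_zero")

  expect_error(run_envelope_suite(counts, meta, variables = "oxygen"), "oxygen")
})

test_that("tidy, glance and autoplot expose suite results", {
  design <- gradient_design(n_samples = 90, seed = 31)
  meta <- generate_environment(design)
  truth <- list(a = response_curve("monotone_up"), b = response_curve("unimodal"))
  counts <- generate_counts(meta, truth, seed = 32)
  suite <- run_envelope_suite(counts, meta, variables = "temperature",
                              binning = binning_config(max_per_bin = 10))
  td <- tidy(suite)
  expect_s3_class(td, "tbl_df")
  expect_named(glance(suite),
               c("n_fits", "n_ok", "n_flat", "n_monotone_up", "n_monotone_down",
                 "n_unimodal", "n_other", "mean_deviance_explained"))
  fit <- suite$fits$fit[[1]]
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(suite, variable = "temperature"), "ggplot")
  expect_s3_class(tidy(fit), "tbl_df")
})
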