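#' Configuration objects for envelope species distribution models
#'
#' `binning_config()` controls how an environmental gradient is divided into
#' categories: no category may exceed `max_per_bin` observations (default 20)
#' and there must be at least `min_bins` categories (default 3) of roughly
#' equal size. `envelope_config()` controls the envelope extraction and model
#' fit: the envelope percentile (default the 95th), the maximum polynomial
#' degree of the log-mean (default 3), and the deviance-explained gain
#' (default 0.01, i.e. one percentage point) a higher-degree term must deliver
#' — on top of lowering the AIC — to be admitted.
#'
#' @param max_per_bin Maximum observations per category (>= 1).
#' @param min_bins Minimum number of categories (>= 2).
#' @return A `binning_config` / `envelope_config` list.
#' @export
binning_config <- function(max_per_bin = 20L, min_bins = 3L) {
  stopifnot(max_per_bin >= 1, min_bins >= 2)
  structure(list(max_per_bin = as.integer(max_per_bin), min_bins = as.integer(min_bins)),
            class = "binning_config")
}

#' @rdname binning_config
#' @param percentile Envelope quantile, strictly in (0, 1).
#' @param max_degree Largest candidate polynomial degree (>= 1).
#' @param deviance_gain Minimum increase in deviance explained (as a fraction;
#'   0.01 = one percentage point) required to admit a higher degree.
#' @param abundance_unit Unit of the abundances offered to the model;
#'   bookkeeping recorded in each fit.
#' @param representative How each category is summarised on the x axis:
#'   the median of its observations (default) or the midpoint of its range.
#' @export
envelope_config <- function(percentile = 0.95, max_degree = 3L,
                            deviance_gain = 0.01,
                            abundance_unit = c("rarefied_counts", "relative"),
                            representative = c("median", "midpoint")) {
  stopifnot(percentile > 0, percentile < 1, max_degree >= 1, deviance_gain >= 0)
  structure(
    list(percentile = percentile, max_degree = as.integer(max_degree),
         deviance_gain = deviance_gain,
         abundance_unit = match.arg(abundance_unit),
         representative = match.arg(representative)),
    class = "envelope_config"
  )
}

#' Divide an environmental gradient into equal-frequency categories
#'
#' Splits the observations, taken in sorted order of `x` (ties broken by a
#' stable sort), into `k = max(min_bins, ceiling(n / max_per_bin))` contiguous
#' categories whose sizes differ by at most one. This satisfies the category
#' constraints of the maximum-abundance procedure: no more than `max_per_bin`
#' observations per category and roughly equal numbers in at least `min_bins`
#' categories.
#'
#' @param x Numeric vector of environmental values.
#' @param config A [binning_config()].
#' @return List of integer index vectors, one per category, partitioning
#'   `seq_along(x)` and contiguous in sorted-`x` order.
#' @export
bin_gradient <- function(x, config = binning_config()) {
  n <- length(x)
  if (n < config$min_bins) {
    abort(sprintf("need at least %d observations to form %d categories",
                  config$min_bins, config$min_bins))
  }
  k <- max(config$min_bins, ceiling(n / config$max_per_bin))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ord <- order(x)                      # order() is stable for ties
  split(ord, rep(seq_len(k), times = sizes))
}

#' Extract per-category percentile envelopes
#'
#' For each category, computes the envelope quantile (by default the 95th
#' percentile, linear interpolation between order statistics) of one taxon's
#' abundances, the category's representative x (median of its observations),
#' and the number of observations, which later weights the regression.
#'
#' @param x Environmental values aligned with `abundance`.
#' @param abundance One taxon's abundances, same length as `x`.
#' @param categories Output of [bin_gradient()] on `x`.
#' @param config An [envelope_config()].
#' @return Tibble of envelope points: `category`, `x`, `q`, `n_obs`.
#' @export
percentile_envelope <- function(x, abundance, categories, config = envelope_config()) {
  stopifnot(length(x) == length(abundance))
  if (any(lengths(categories) == 0)) abort("empty category")
  purrr::imap_dfr(categories, function(idx, i) {
    tibble::tibble(
      category = as.integer(i),
      x = if (config$representative == "median") median(x[idx]) else mean(range(x[idx])),
      q = unname(quantile(abundance[idx], probs = config$percentile, type = 7)),
      n_obs = length(idx)
    )
  })
}

# continuous-Poisson log-likelihood (gamma-function extension), used for AIC
# on non-integer envelope responses
pois_cont_loglik <- function(y, mu, w) {
  sum(w * (ifelse(y > 0, y * log(mu), 0) - mu - lgamma(y + 1)))
}

# expand coefficients of a polynomial in z = (x - center)/scale into
# coefficients in x (constant first)
rescale_poly <- function(beta, center, scale) {
  deg <- length(beta) - 1
  out <- numeric(deg + 1)
  for (j in 0:deg) {
    bj <- beta[j + 1] / scale^j
    for (k in 0:j) {
      out[k + 1] <- out[k + 1] + bj * choose(j, k) * (-center)^(j - k)
    }
  }
  out
}

#' Fit a maximum-abundance envelope GLM with degree selection
#'
#' Fits the category envelope points with a generalized linear model: log link,
#' Poisson likelihood, and the number of observations in each category as
#' weights. Candidate log-mean polynomials of degree 1 up to
#' `config$max_degree` are fitted on centered-and-scaled x for conditioning; a
#' higher degree is admitted only when it lowers the AIC *and* raises the
#' proportion of deviance explained by more than `config$deviance_gain`,
#' judged against the best model admitted so far; among admitted models the
#' one explaining the most deviance is returned. When no degree passes the
#' rule against the intercept-only model, degree 0 is reported. The 95th-percentile response is generally non-integer, so the
#' likelihood is maximised in its continuous (quasi-)Poisson form and the AIC
#' uses the gamma-function extension of the Poisson log-likelihood.
#'
#' @param points Envelope points from [percentile_envelope()].
#' @param config An [envelope_config()].
#' @param taxon,variable Optional labels stored in the fit.
#' @param x_range Range over which the fitted response is characterised;
#'   defaults to the range of the points' x.
#' @return An `envelope_fit` object; see [tidy.envelope_fit()].
#' @export
fit_envelope_glm <- function(points, config = envelope_config(),
                             taxon = NA_character_, variable = NA_character_,
                             x_range = range(points$x)) {
  stopifnot(all(c("x", "q", "n_obs") %in% names(points)))
  n <- nrow(points)
  if (stats::var(points$x) == 0) abort("representative x values are all equal")
  max_deg <- min(config$max_degree, n - 2L)
  if (max_deg < 1) abort("fewer envelope points than model parameters")
  center <- mean(points$x); scale <- sd(points$x)
  z <- (points$x - center) / scale
  dat <- data.frame(q = points$q, z = z, w = points$n_obs)

  fit_degree <- function(d) {
    form <- if (d == 0) q ~ 1 else q ~ poly(z, degree = d, raw = TRUE)
    g <- suppressWarnings(glm(form, family = quasipoisson(link = "log"),
                              data = dat, weights = w))
    if (!g$converged) abort(sprintf("degree-%d fit did not converge", d))
    ll <- pois_cont_loglik(dat$q, fitted(g), dat$w)
    list(degree = d, glm = g, aic = -2 * ll + 2 * (d + 1),
         deviance = g$deviance, null_deviance = g$null.deviance,
         dev_expl = 1 - g$deviance / g$null.deviance)
  }

  cand <- purrr::map(0:max_deg, fit_degree)
  # forward admission against the best model so far: a candidate degree is
  # admitted only if it both lowers the AIC and lifts deviance explained by
  # more than the configured gain; the scan continues past a rejected degree
  # so that, e.g., a symmetric quadratic response is reachable even though the
  # linear term alone explains nothing
  current <- cand[[1]]                      # intercept-only baseline
  for (d in seq_len(max_deg)) {
    trial <- cand[[d + 1]]
    admit <- trial$aic < current$aic &&
      (trial$dev_expl - current$dev_expl) > config$deviance_gain
    if (admit) current <- trial
  }

  beta_z <- unname(coef(current$glm))
  coefficients <- rescale_poly(beta_z, center, scale)
  fit <- structure(
    list(taxon = taxon, variable = variable,
         degree = current$degree, coefficients = coefficients,
         coefficients_scaled = beta_z, center = center, scale = scale,
         deviance_explained = max(0, current$dev_expl),
         aic = current$aic,
         candidate_aic = purrr::map_dbl(cand, "aic"),
         candidate_dev_expl = purrr::map_dbl(cand, "dev_expl"),
         points = points, x_range = x_range,
         abundance_unit = config$abundance_unit),
    class = "envelope_fit"
  )
  shp <- characterize_shape(fit, x_range)
  fit$shape <- shp$shape
  fit$peaks <- shp$peaks
  fit
}

#' Evaluate a fitted envelope mean
#'
#' @param fit An `envelope_fit`.
#' @param x Environmental values.
#' @return Fitted envelope abundance at each `x`.
#' @export
predict_envelope <- function(fit, x) {
  z <- (x - fit$center) / fit$scale
  logmu <- Reduce(`+`, purrr::imap(fit$coefficients_scaled, function(b, j) b * z^(j - 1)))
  exp(logmu)
}

#' Classify the shape of a fitted envelope response
#'
#' Evaluates the fitted mean on a dense grid over the observed range and
#' labels the response: `flat` when the relative variation of the fitted mean
#' is below `flat_tol` (default 1%); `monotone_up` / `monotone_down` when the
#' grid derivative keeps one sign; `unimodal` when there is exactly one
#' abundance maximum and it is interior; `other` for two or more maxima
#' (counting boundary maxima), the degree-limited approximation of bimodality.
#'
#' @param fit An `envelope_fit`.
#' @param x_range Length-2 range over which to characterise the response.
#' @param n_grid Grid resolution.
#' @param flat_tol Relative-variation threshold for `flat`.
#' @return List with `shape` and a `peaks` tibble (`x`, `abundance`,
#'   `interior`), one row per local abundance maximum.
#' @export
characterize_shape <- function(fit, x_range = fit$x_range, n_grid = 512L,
                               flat_tol = 0.01) {
  grid <- seq(x_range[1], x_range[2], length.out = n_grid)
  mu <- predict_envelope(fit, grid)
  rng <- range(mu)
  peaks_at <- function(idx, interior) {
    tibble::tibble(x = grid[idx], abundance = mu[idx], interior = interior)
  }
  if (max(rng) <= 0 || diff(rng) / max(rng) < flat_tol) {
    return(list(shape = "flat", peaks = peaks_at(integer(0), logical(0))))
  }
  d <- diff(mu)
  tol <- 1e-10 * max(mu)
  if (all(d >= -tol)) {
    return(list(shape = "monotone_up", peaks = peaks_at(n_grid, FALSE)))
  }
  if (all(d <= tol)) {
    return(list(shape = "monotone_down", peaks = peaks_at(1L, FALSE)))
  }
  interior <- which(mu[2:(n_grid - 1)] > mu[1:(n_grid - 2)] &
                    mu[2:(n_grid - 1)] >= mu[3:n_grid]) + 1L
  boundary <- c(if (mu[1] > mu[2]) 1L, if (mu[n_grid] > mu[n_grid - 1]) n_grid)
  peaks <- dplyr::bind_rows(
    peaks_at(interior, rep(TRUE, length(interior))),
    peaks_at(boundary, rep(FALSE, length(boundary)))
  ) |> dplyr::arrange(.data$x)
  shape <- if (nrow(peaks) == 1 && peaks$interior[1]) "unimodal" else "other"
  list(shape = shape, peaks = peaks)
}

#' Run the envelope model suite over taxa and gradient variables
#'
#' The full maximum-abundance procedure for every (taxon, variable) pair:
#' bin each gradient into equal-frequency categories, extract the
#' 95th-percentile envelope per category, fit the weighted Poisson log-link
#' polynomial with AIC-plus-deviance-gain degree selection, and classify the
#' response shape. Taxa absent from every sample, and fits that fail, are
#' reported with a reason instead of a fit. Fully deterministic given inputs.
#'
#' @param table Count-table tibble (typically rarefaction-averaged counts,
#'   taxa already aggregated to the desired level).
#' @param metadata Metadata tibble with `sample_id` and the gradient columns.
#' @param variables Gradient columns to model (default depth, temperature,
#'   salinity).
#' @param config An [envelope_config()].
#' @param binning A [binning_config()].
#' @return An `envelope_suite` object; `tidy()` it for one row per fit.
#' @export
run_envelope_suite <- function(table, metadata,
                               variables = c("depth", "temperature", "salinity"),
                               config = envelope_config(),
                               binning = binning_config()) {
  missing <- setdiff(variables, names(metadata))
  if (length(missing) > 0) {
    abort(paste0("variables absent from metadata: ", paste(missing, collapse = ", ")))
  }
  m <- as_count_matrix(table)
  ids <- colnames(m)
  meta <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(meta$sample_id)) abort("metadata is missing samples present in the table")

  rows <- purrr::map_dfr(variables, function(v) {
    x <- meta[[v]]
    categories <- bin_gradient(x, binning)
    purrr::map_dfr(rownames(m), function(taxon) {
      ab <- m[taxon, ]
      if (all(ab == 0)) {
        return(tibble::tibble(taxon = taxon, variable = v, status = "skipped_all_zero",
                              fit = list(NULL)))
      }
      res <- tryCatch({
        pts <- percentile_envelope(x, ab, categories, config)
        fit <- fit_envelope_glm(pts, config, taxon = taxon, variable = v,
                                x_range = range(x))
        tibble::tibble(taxon = taxon, variable = v, status = "ok", fit = list(fit))
      }, error = function(e) {
        tibble::tibble(taxon = taxon, variable = v,
                       status = paste0("failed: ", conditionMessage(e)),
                       fit = list(NULL))
      })
      res
    })
  })
  structure(list(fits = rows, config = config, binning = binning), class = "envelope_suite")
}

#' @export
print.envelope_fit <- function(x, ...) {
  cat(sprintf("<envelope_fit> %s ~ %s: degree %d, deviance explained %.3f, shape %s\n",
              x$taxon, x$variable, x$degree, x$deviance_explained, x$shape))
  invisible(x)
}

#' @export
print.envelope_suite <- function(x, ...) {
  ok <- sum(x$fits$status == "ok")
  cat(sprintf("<envelope_suite> %d fits attempted, %d ok\n", nrow(x$fits), ok))
  invisible(x)
}

#' Tidy an envelope fit
#'
#' @param x An `envelope_fit`.
#' @param ... Unused.
#' @return One-row tibble: taxon, variable, degree, per-degree coefficients
#'   (list column), deviance explained, AIC, shape, and the location/height of
#'   the highest fitted peak.
#' @method tidy envelope_fit
#' @export
tidy.envelope_fit <- function(x, ...) {
  pk <- x$peaks
  top <- if (nrow(pk) > 0) pk[which.max(pk$abundance), ] else
    tibble::tibble(x = NA_real_, abundance = NA_real_)
  tibble::tibble(
    taxon = x$taxon, variable = x$variable, degree = x$degree,
    coefficients = list(x$coefficients),
    deviance_explained = x$deviance_explained, aic = x$aic,
    shape = x$shape, peak_x = top$x[1], peak_abundance = top$abundance[1],
    n_peaks = nrow(pk)
  )
}

#' @method glance envelope_fit
#' @export
glance.envelope_fit <- function(x, ...) {
  tibble::tibble(degree = x$degree, deviance_explained = x$deviance_explained,
                 aic = x$aic, n_points = nrow(x$points), shape = x$shape)
}

#' Tidy an envelope suite
#'
#' @param x An `envelope_suite`.
#' @param ... Unused.
#' @return Tibble with one row per attempted fit; failed or skipped taxa keep
#'   their status and `NA` model columns.
#' @method tidy envelope_suite
#' @export
tidy.envelope_suite <- function(x, ...) {
  purrr::pmap_dfr(x$fits, function(taxon, variable, status, fit) {
    if (is.null(fit)) {
      tibble::tibble(taxon = taxon, variable = variable, status = status,
                     degree = NA_integer_, deviance_explained = NA_real_,
                     aic = NA_real_, shape = NA_character_,
                     peak_x = NA_real_, peak_abundance = NA_real_,
                     n_peaks = NA_integer_)
    } else {
      dplyr::bind_cols(tidy(fit)[, c("taxon", "variable")],
                       tibble::tibble(status = status),
                       tidy(fit)[, -(1:2)] |> dplyr::select(-"coefficients"))
    }
  })
}

#' @method glance envelope_suite
#' @export
glance.envelope_suite <- function(x, ...) {
  td <- tidy(x)
  ok <- td[td$status == "ok", ]
  tibble::tibble(
    n_fits = nrow(td), n_ok = nrow(ok),
    n_flat = sum(ok$shape == "flat"),
    n_monotone_up = sum(ok$shape == "monotone_up"),
    n_monotone_down = sum(ok$shape == "monotone_down"),
    n_unimodal = sum(ok$shape == "unimodal"),
    n_other = sum(ok$shape == "other"),
    mean_deviance_explained = mean(ok$deviance_explained)
  )
}

#' Plot a fitted maximum-abundance envelope
#'
#' Envelope points (sized by the category weight) with the fitted response
#' curve, in the style of maximum-abundance model figures: the envelope traces
#' the taxon's potential abundance along the gradient.
#'
#' @param object An `envelope_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot envelope_fit
#' @export
autoplot.envelope_fit <- function(object, ...) {
  grid <- seq(object$x_range[1], object$x_range[2], length.out = 256)
  curve_df <- tibble::tibble(x = grid, mu = predict_envelope(object, grid))
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_obs), alpha = 0.7) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(y = .data$mu), linewidth = 0.8) +
    ggplot2::labs(
      x = object$variable, y = "envelope abundance",
      title = sprintf("%s (degree %d, %s)", object$taxon, object$degree, object$shape),
      size = "n obs"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an envelope suite as small multiples
#'
#' @param object An `envelope_suite`.
#' @param variable Gradient variable to display.
#' @param ... Unused.
#' @return A ggplot object faceted by taxon.
#' @method autoplot envelope_suite
#' @export
autoplot.envelope_suite <- function(object, variable = NULL, ...) {
  fits <- object$fits[object$fits$status == "ok", ]
  if (!is.null(variable)) fits <- fits[fits$variable == variable, ]
  if (nrow(fits) == 0) abort("no successful fits to plot")
  pts <- purrr::map_dfr(fits$fit, function(f) {
    dplyr::mutate(f$points, taxon = f$taxon, variable = f$variable)
  })
  curves <- purrr::map_dfr(fits$fit, function(f) {
    grid <- seq(f$x_range[1], f$x_range[2], length.out = 128)
    tibble::tibble(taxon = f$taxon, variable = f$variable,
                   x = grid, mu = predict_envelope(f, grid))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_obs), alpha = 0.6) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$mu), linewidth = 0.7) +
    ggplot2::facet_wrap(~taxon, scales = "free_y") +
    ggplot2::labs(x = "environmental gradient", y = "envelope abundance",
                  size = "n obs") +
    ggplot2::theme_minimal()
}
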