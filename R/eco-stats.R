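#' Euclidean environmental distance between samples
#'
#' Z-score standardises the selected environmental variables, then computes
#' pairwise Euclidean distances, the usual environmental counterpart to
#' community dissimilarity matrices. Samples with missing values in any
#' selected variable are an error (they must be excluded explicitly, as the
#' study did for stations lacking nutrient data).
#'
#' @param metadata Metadata tibble with `sample_id` and numeric columns.
#' @param variables Columns to include.
#' @return Symmetric matrix with sample ids as dimnames and zero diagonal.
#' @export
env_distance <- function(metadata, variables) {
  missing <- setdiff(variables, names(metadata))
  if (length(missing) > 0) {
    abort(paste0("variables absent from metadata: ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(metadata[variables])
  bad <- !stats::complete.cases(x)
  if (any(bad)) {
    abort(paste0("samples with missing environmental values: ",
                 paste(metadata$sample_id[bad], collapse = ", ")))
  }
  z <- scale(x)
  z[, apply(x, 2, sd) == 0] <- 0        # constant variables carry no distance
  d <- as.matrix(stats::dist(z))
  dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  d
}

upper_tri_vec <- function(m) m[upper.tri(m)]

#' Mantel test between two distance matrices
#'
#' Correlates the upper triangles of two distance matrices over the same
#' samples and assesses significance by jointly permuting the rows and columns
#' of the second matrix. The one-tailed permutation p-value uses the +1
#' correction: `p = (1 + #\{r* >= r\}) / (1 + n_perm)`. With `exact = TRUE`
#' (feasible up to 7 samples) all distinct permutations are enumerated
#' instead of sampled.
#'
#' @param d1,d2 Symmetric distance matrices with identical dimnames (order may
#'   differ; `d2` is aligned by label).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param method Correlation flavour: `"pearson"` (default) or `"spearman"`
#'   for a rank-based statistic.
#' @param exact Enumerate all permutations instead of sampling.
#' @return A `maxenv_mantel` object with `statistic`, `p_value`, `n_perm`,
#'   `method`, `n_samples`; see `tidy()` / `glance()`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L,
                        method = c("pearson", "spearman"), exact = FALSE) {
  method <- match.arg(method)
  l1 <- rownames(d1); l2 <- rownames(d2)
  if (is.null(l1) || is.null(l2) || !setequal(l1, l2)) {
    abort("distance matrices must carry identical sample labels")
  }
  d2 <- d2[l1, l1]
  n <- nrow(d1)
  v1 <- upper_tri_vec(d1)
  stat <- function(perm) cor(v1, upper_tri_vec(d2[perm, perm]), method = method)
  r_obs <- stat(seq_len(n))
  if (exact) {
    perms <- all_permutations(n)
    r_null <- purrr::map_dbl(perms[-1], stat)   # drop identity
    n_perm <- length(r_null)
  } else {
    stopifnot(n_perm >= 1)
    r_null <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat(sample(n)), numeric(1))
    })
  }
  p <- (1 + sum(r_null >= r_obs)) / (1 + n_perm)
  structure(
    list(statistic = r_obs, p_value = p, n_perm = n_perm, method = method,
         n_samples = n, exact = exact, seed = seed),
    class = "maxenv_mantel"
  )
}

# all permutations of 1..n, identity first (n <= 7)
all_permutations <- function(n) {
  if (n > 7) abort("exact enumeration is limited to 7 samples")
  rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    purrr::flatten(purrr::map(seq_along(v), function(i) {
      purrr::map(rec(v[-i]), function(p) c(v[i], p))
    }))
  }
  rec(seq_len(n))
}

#' @export
print.maxenv_mantel <- function(x, ...) {
  cat(sprintf("Mantel test (%s): r = %.4f, p = %.4g (%s%d permutations, n = %d)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "all " else "", x$n_perm, x$n_samples))
  invisible(x)
}

#' @method tidy maxenv_mantel
#' @export
tidy.maxenv_mantel <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_perm = x$n_perm, method = x$method, n_samples = x$n_samples)
}

#' @method glance maxenv_mantel
#' @export
glance.maxenv_mantel <- function(x, ...) tidy(x)

#' Seawater density at atmospheric pressure
#'
#' One-atmosphere International Equation of State of Seawater (EOS-80,
#' Millero & Poisson 1981 coefficients): density in kg/m3 from practical
#' salinity and temperature. `seawater_sigma_t()` subtracts 1000 kg/m3.
#'
#' @param salinity Practical salinity (PSU).
#' @param temperature Temperature (degC).
#' @return Density in kg/m3 (sigma-t for `seawater_sigma_t`).
#' @export
seawater_density <- function(salinity, temperature) {
  t <- temperature; s <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  rho_w + a * s + b * s^1.5 + c0 * s^2
}

#' @rdname seawater_density
#' @export
seawater_sigma_t <- function(salinity, temperature) {
  seawater_density(salinity, temperature) - 1000
}

#' Mixed layer depth from a hydrographic profile
#'
#' The turbulence proxy: the shallowest depth at which density exceeds the
#' density at a reference depth by a fixed threshold (default +0.125 kg/m3
#' relative to 10 m, a standard oceanographic criterion), with linear
#' interpolation between profile levels. If the threshold is never exceeded
#' the maximum profile depth is returned (fully mixed cast). A deep mixed
#' layer indicates an actively mixed, turbulent water column; a shallow one a
#' stratified, stable column.
#'
#' @param profile Profile tibble with `depth` and either a `density` column or
#'   `temperature` + `salinity` (density then computed via
#'   [seawater_density()]).
#' @param criterion Density excess over the reference level (kg/m3).
#' @param reference_depth Reference level (m); the profile must span it.
#' @return Mixed layer depth in m.
#' @export
mixed_layer_depth <- function(profile, criterion = 0.125, reference_depth = 10) {
  stopifnot(is.data.frame(profile), "depth" %in% names(profile))
  if (is.unsorted(profile$depth, strictly = TRUE)) {
    abort("profile depths must be strictly increasing")
  }
  if (max(profile$depth) < reference_depth || min(profile$depth) > reference_depth) {
    abort(sprintf("profile does not span the reference depth (%g m)", reference_depth))
  }
  dens <- if ("density" %in% names(profile)) {
    profile$density
  } else {
    seawater_density(profile$salinity, profile$temperature)
  }
  depth <- profile$depth
  ref_dens <- approx(depth, dens, xout = reference_depth)$y
  target <- ref_dens + criterion
  below <- depth >= reference_depth
  d_sub <- depth[below]; rho_sub <- dens[below]
  exceeded <- which(rho_sub >= target)
  if (length(exceeded) == 0) return(max(depth))
  i <- exceeded[1]
  if (i == 1) return(d_sub[1])
  # linear interpolation between the bracketing levels
  d0 <- d_sub[i - 1]; d1 <- d_sub[i]
  r0 <- rho_sub[i - 1]; r1 <- rho_sub[i]
  d0 + (target - r0) / (r1 - r0) * (d1 - d0)
}

#' Classify turbulence-by-nutrient scenarios
#'
#' Formalises the four-quadrant framework relating community regimes to water
#' column physics: turbulence is high when the mixed layer depth reaches
#' `mld_threshold` (deep mixing), nutrients are high when the nutrient
#' concentration reaches `nutrient_threshold`. Quadrants carry the region-by-
#' season names of the study system: deep mixing with low nutrients =
#' North_Spring, stratified and oligotrophic = North_Fall, stratified with
#' high nutrients (lateral intrusion) = South_Fall, mixed and nutrient-rich =
#' South_Spring.
#'
#' @param mld Mixed layer depth(s), m.
#' @param nutrient Nutrient concentration(s), same length.
#' @param mld_threshold Turbulence cutoff (m); defaults to the median of `mld`.
#' @param nutrient_threshold Nutrient cutoff; defaults to the median of
#'   `nutrient`.
#' @return Tibble with `mld`, `nutrient`, `turbulence`, `nutrients`, `name`.
#' @export
scenario_classify <- function(mld, nutrient,
                              mld_threshold = median(mld),
                              nutrient_threshold = median(nutrient)) {
  stopifnot(length(mld) == length(nutrient),
            mld_threshold > 0, nutrient_threshold > 0)
  mld <- unname(mld); nutrient <- unname(nutrient)
  turbulence <- ifelse(mld >= mld_threshold, "high", "low")
  nutrients <- ifelse(nutrient >= nutrient_threshold, "high", "low")
  name <- dplyr::case_when(
    turbulence == "high" & nutrients == "low" ~ "North_Spring",
    turbulence == "low" & nutrients == "low" ~ "North_Fall",
    turbulence == "low" & nutrients == "high" ~ "South_Fall",
    TRUE ~ "South_Spring"
  )
  tibble::tibble(mld = mld, nutrient = nutrient,
                 turbulence = turbulence, nutrients = nutrients, name = name)
}

#' Within-group community dissimilarity
#'
#' Mean, median and spread of the within-group pairwise dissimilarities for
#' each group (e.g. scenario), with a ranking by mean — the summary used to
#' ask which regimes harbour the most variable communities. Groups with fewer
#' than two samples have no within-group pair and are dropped with a warning.
#'
#' @param dm Distance matrix with sample dimnames.
#' @param groups Named character vector, sample id -> group label.
#' @return Tibble `group`, `n_samples`, `n_pairs`, `mean`, `median`, `sd`,
#'   `rank` (1 = most dissimilar).
#' @export
within_group_dissimilarity <- function(dm, groups) {
  ids <- rownames(dm)
  missing <- setdiff(ids, names(groups))
  if (length(missing) > 0) {
    abort(paste0("samples without a group label: ", paste(missing, collapse = ", ")))
  }
  labs <- unname(groups[ids])
  out <- purrr::map_dfr(unique(labs), function(g) {
    members <- ids[labs == g]
    if (length(members) < 2) {
      warn(sprintf("group '%s' has fewer than 2 samples; excluded", g))
      return(tibble::tibble())
    }
    v <- upper_tri_vec(dm[members, members, drop = FALSE])
    tibble::tibble(group = g, n_samples = length(members), n_pairs = length(v),
                   mean = mean(v), median = median(v), sd = sd(v))
  })
  if (nrow(out) > 0) out$rank <- rank(-out$mean, ties.method = "min")
  out
}
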