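#' Design of a synthetic environmental gradient
#'
#' Declares the sampling design the synthetic community emulates: a set of
#' stations spanning temperature, salinity and depth ranges typical of a
#' subtropical semi-enclosed sea (defaults follow the Red Sea photic zone:
#' 22-34 degC, 36.5-40.5 PSU, 0-200 m).
#'
#' @param n_samples Number of samples (>= 4).
#' @param temperature_range,salinity_range,depth_range Length-2 numeric
#'   intervals (min < max) in degC, PSU and m.
#' @param seed Integer seed used by [generate_environment()].
#' @return A `gradient_design` list.
#' @export
gradient_design <- function(n_samples = 60L,
                            temperature_range = c(22, 34),
                            salinity_range = c(36.5, 40.5),
                            depth_range = c(0, 200),
                            seed = 1L) {
  check_range <- function(r, what) {
    if (length(r) != 2 || !is.numeric(r) || !(r[1] < r[2])) {
      abort(sprintf("invalid design: %s must be a non-degenerate interval (min < max)", what))
    }
  }
  if (n_samples < 4) abort("invalid design: n_samples must be at least 4")
  check_range(temperature_range, "temperature_range")
  check_range(salinity_range, "salinity_range")
  check_range(depth_range, "depth_range")
  structure(
    list(
      n_samples = as.integer(n_samples),
      temperature_range = temperature_range,
      salinity_range = salinity_range,
      depth_range = depth_range,
      seed = as.integer(seed)
    ),
    class = "gradient_design"
  )
}

#' Generate per-sample environmental metadata
#'
#' Draws `n_samples` stations from a [gradient_design()]: temperature, salinity
#' and sampling depth uniform over their declared ranges (no sampling
#' distribution is imposed beyond the ranges), nutrient concentrations
#' (nitrate, nitrite, phosphate, silicate, in umol/L) increasing with depth
#' with multiplicative lognormal noise — the familiar nutricline pattern —
#' and design labels: region (north/south halves), season (fall/spring
#' alternating), and depth layer (surface above 60 m, otherwise DCM).
#'
#' @param design A [gradient_design()].
#' @return Tibble with one row per sample: `sample_id`, `region`, `season`,
#'   `depth_layer`, `depth`, `temperature`, `salinity`, `nitrate`, `nitrite`,
#'   `phosphate`, `silicate`.
#' @export
generate_environment <- function(design) {
  stopifnot(inherits(design, "gradient_design"))
  n <- design$n_samples
  withr::with_seed(design$seed, {
    depth <- runif(n, design$depth_range[1], design$depth_range[2])
    temperature <- runif(n, design$temperature_range[1], design$temperature_range[2])
    salinity <- runif(n, design$salinity_range[1], design$salinity_range[2])
    depth_frac <- (depth - design$depth_range[1]) / diff(design$depth_range)
    nitrate <- (0.05 + 4 * depth_frac) * exp(rnorm(n, 0, 0.2))
    nitrite <- (0.01 + 0.2 * depth_frac) * exp(rnorm(n, 0, 0.2))
    phosphate <- nitrate / 16 * exp(rnorm(n, 0, 0.1))
    silicate <- (0.5 + 2.5 * depth_frac) * exp(rnorm(n, 0, 0.2))
  })
  tibble::tibble(
    sample_id = sprintf("sample_%03d", seq_len(n)),
    region = rep(c("north", "south"), times = c(ceiling(n / 2), floor(n / 2))),
    season = rep(c("fall", "spring"), length.out = n),
    depth_layer = ifelse(depth < 60, "surface", "dcm"),
    depth = depth,
    temperature = temperature,
    salinity = salinity,
    nitrate = nitrate,
    nitrite = nitrite,
    phosphate = phosphate,
    silicate = silicate
  )
}

#' Parameterised taxon response curve
#'
#' The mean-abundance response of one taxon to one environmental variable,
#' used as simulation ground truth. Shapes on the log-mean scale:
#'
#' * `flat` — constant mean `base_abundance`.
#' * `monotone_up` / `monotone_down` — log-linear, `log mu = log(base) +
#'   rate * (x - ref)` with positive / negative `rate`.
#' * `unimodal` — log-quadratic (Gaussian niche), interior optimum at `peak`
#'   with niche breadth `width`.
#' * `bimodal` — exponential of the sum of two Gaussian bumps on the log-mean,
#'   giving two interior abundance maxima (e.g. the two thermal peaks near 24
#'   and 30 degC described for *Prochlorococcus* ecotypes). A degree-limited
#'   polynomial cannot represent this shape, which is exactly why it is
#'   offered to the fitter.
#'
#' @param shape One of `"flat"`, `"monotone_up"`, `"monotone_down"`,
#'   `"unimodal"`, `"bimodal"`.
#' @param variable Metadata column the curve responds to.
#' @param base_abundance Expected reads at the reference condition.
#' @param rate Log-slope per unit of `variable` (monotone shapes).
#' @param ref Reference value of `variable` (monotone shapes).
#' @param peak Optimum location (unimodal), in `variable` units.
#' @param width Niche breadth (unimodal), same units.
#' @param peaks,widths,amplitudes Length-2 parameters of the two log-mean
#'   bumps (bimodal).
#' @return A `response_curve` object.
#' @export
response_curve <- function(shape = c("flat", "monotone_up", "monotone_down",
                                     "unimodal", "bimodal"),
                           variable = "temperature",
                           base_abundance = 100,
                           rate = 0.25, ref = 28,
                           peak = 28, width = 3,
                           peaks = c(24, 30), widths = c(1.5, 1.5),
                           amplitudes = c(3, 2.5)) {
  shape <- match.arg(shape)
  stopifnot(base_abundance > 0)
  params <- switch(shape,
    flat = list(),
    monotone_up = list(rate = abs(rate), ref = ref),
    monotone_down = list(rate = -abs(rate), ref = ref),
    unimodal = list(peak = peak, width = width),
    bimodal = list(peaks = peaks, widths = widths, amplitudes = amplitudes)
  )
  structure(
    list(shape = shape, variable = variable,
         base_abundance = base_abundance, params = params),
    class = "response_curve"
  )
}

#' Evaluate a response curve's mean function
#'
#' @param curve A [response_curve()].
#' @param x Numeric values of the curve's environmental variable.
#' @return Expected abundance (reads) at each `x`.
#' @export
curve_mean <- function(curve, x) {
  stopifnot(inherits(curve, "response_curve"))
  p <- curve$params
  b <- curve$base_abundance
  switch(curve$shape,
    flat = rep(b, length(x)),
    monotone_up = ,
    monotone_down = b * exp(p$rate * (x - p$ref)),
    unimodal = b * exp(-(x - p$peak)^2 / (2 * p$width^2)),
    bimodal = b * exp(
      p$amplitudes[1] * exp(-(x - p$peaks[1])^2 / (2 * p$widths[1]^2)) +
      p$amplitudes[2] * exp(-(x - p$peaks[2])^2 / (2 * p$widths[2]^2))
    )
  )
}

#' Generate an OTU count table from known response curves
#'
#' Draws one count per (taxon, sample) with mean equal to the taxon's response
#' curve evaluated at the sample's environment. Noise is Poisson by default
#' (matching the Poisson likelihood used downstream) or negative binomial for
#' overdispersion robustness checks. An optional per-taxon zero-inflation
#' ("sparsity") knob emulates the empirical occupancy pattern that most OTUs
#' occur in few samples: each taxon receives a dropout probability drawn from
#' Beta(sparsity, 1), and that fraction of its samples is zeroed. With
#' `sparsity = 0` (default) counts are exactly curve-mean distributed.
#'
#' @param metadata Metadata tibble (one row per sample, `sample_id` column).
#' @param truth Named list of [response_curve()]s, one per OTU.
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param dispersion NB size parameter is `1/dispersion`; larger means more
#'   overdispersed. Ignored for Poisson.
#' @param sparsity Non-negative zero-inflation strength (0 disables).
#' @param seed Integer seed.
#' @return Count-table tibble with one row per OTU in `truth`.
#' @export
generate_counts <- function(metadata, truth, noise = c("poisson", "negative_binomial"),
                            dispersion = 0.5, sparsity = 0, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(is.data.frame(metadata), length(truth) > 0)
  vars <- unique(purrr::map_chr(truth, "variable"))
  missing <- setdiff(vars, names(metadata))
  if (length(missing) > 0) {
    abort(paste0("response-curve variable(s) absent from metadata: ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(metadata)
  withr::with_seed(seed, {
    m <- vapply(truth, function(curve) {
      mu <- curve_mean(curve, metadata[[curve$variable]])
      y <- if (noise == "poisson") rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
      if (sparsity > 0) {
        dropout <- stats::rbeta(1, sparsity, 1)
        y[runif(n) < dropout] <- 0L
      }
      as.double(y)
    }, double(n))
  })
  m <- t(m)
  rownames(m) <- names(truth)
  colnames(m) <- metadata$sample_id
  count_table(m)
}

#' Generate a random rooted binary phylogeny over OTU ids
#'
#' Topology from [ape::rtree()] (random binary, rooted); branch lengths drawn
#' from a positive-valued law (default exponential with unit mean).
#'
#' @param otu_ids Character vector of >= 2 unique leaf names.
#' @param seed Integer seed.
#' @param branch_length Function `n -> n` positive branch lengths.
#' @return An [ape] `phylo` object whose tip labels are `otu_ids`.
#' @export
generate_tree <- function(otu_ids, seed = 1L, branch_length = function(n) rexp(n, 1)) {
  if (length(otu_ids) < 2) abort("need at least 2 OTU ids")
  if (anyDuplicated(otu_ids)) abort("duplicate OTU ids")
  tree <- withr::with_seed(seed, {
    tr <- ape::rtree(length(otu_ids), rooted = TRUE, br = branch_length)
    # rtree permutes labels t1..tn; map that permutation onto otu_ids
    tr$tip.label <- otu_ids[as.integer(sub("^t", "", tr$tip.label))]
    tr
  })
  if (any(tree$edge.length <= 0)) abort("branch-length law produced non-positive lengths")
  tree
}

#' Build a hydrographic depth profile from layer nodes
#'
#' Linearly interpolates temperature and salinity between user-declared nodes
#' onto a regular depth grid, producing a CTD-style cast usable by
#' [mixed_layer_depth()]. Two-layer structures are declared with two nodes per
#' layer (constant within, step between).
#'
#' @param layers Data frame with numeric columns `depth` (strictly increasing
#'   from near-surface), `temperature`, `salinity`.
#' @param resolution Output grid spacing in m.
#' @return Tibble `depth`, `temperature`, `salinity` — a profile table.
#' @export
generate_profile <- function(layers, resolution = 1) {
  stopifnot(is.data.frame(layers),
            all(c("depth", "temperature", "salinity") %in% names(layers)))
  if (nrow(layers) < 1) abort("profile needs at least one layer node")
  if (is.unsorted(layers$depth, strictly = TRUE)) {
    abort("layer depths must be strictly increasing")
  }
  if (nrow(layers) == 1) {
    return(tibble::tibble(depth = layers$depth, temperature = layers$temperature,
                          salinity = layers$salinity))
  }
  grid <- seq(min(layers$depth), max(layers$depth), by = resolution)
  if (grid[length(grid)] < max(layers$depth)) grid <- c(grid, max(layers$depth))
  tibble::tibble(
    depth = grid,
    temperature = approx(layers$depth, layers$temperature, xout = grid)$y,
    salinity = approx(layers$depth, layers$salinity, xout = grid)$y
  )
}

#' Simulate a full synthetic community with ground truth
#'
#' Bundles the generators into one seeded call: environmental metadata from a
#' [gradient_design()], a random phylogeny, and an OTU table in which a small
#' set of "focal" taxa follow named response-curve shapes while the remaining
#' background taxa are sparse, low-abundance flat responders (lognormal base
#' abundances, occupancy thinned by `sparsity`) — reproducing the empirical
#' pattern of a few cosmopolitan and many rare OTUs.
#'
#' @param design A [gradient_design()].
#' @param n_otus Total OTUs including focal taxa.
#' @param focal_shapes Named character vector of shapes for the focal taxa;
#'   names become OTU ids.
#' @param sparsity Zero-inflation strength for background taxa.
#' @param noise Count noise model, as in [generate_counts()].
#' @return A `synthetic_community` list: `counts`, `metadata`, `tree`, `truth`.
#' @export
simulate_community <- function(design = gradient_design(),
                               n_otus = 96L,
                               focal_shapes = c(
                                 syn_up = "monotone_up", sar11_down = "monotone_down",
                                 bathy_mid = "unimodal", proch_bimodal = "bimodal",
                                 cosmo_flat = "flat"
                               ),
                               sparsity = 3,
                               noise = "poisson") {
  metadata <- generate_environment(design)
  n_background <- n_otus - length(focal_shapes)
  stopifnot(n_background >= 0)
  tr <- design$temperature_range
  focal <- purrr::imap(focal_shapes, function(shape, id) {
    response_curve(shape, variable = "temperature", base_abundance = 120,
                   rate = 0.25, ref = mean(tr),
                   peak = mean(tr), width = diff(tr) / 4,
                   peaks = tr[1] + diff(tr) * c(0.2, 0.7))
  })
  background <- withr::with_seed(design$seed + 1L, {
    bases <- exp(rnorm(n_background, log(8), 1))
    purrr::map(seq_len(n_background), function(i) {
      response_curve("flat", base_abundance = bases[i])
    })
  })
  names(background) <- sprintf("bg_%03d", seq_len(n_background))
  truth <- c(focal, background)
  counts_focal <- generate_counts(metadata, focal, noise = noise,
                                  sparsity = 0, seed = design$seed + 2L)
  out <- counts_focal
  if (n_background > 0) {
    counts_bg <- generate_counts(metadata, background, noise = noise,
                                 sparsity = sparsity, seed = design$seed + 3L)
    out <- dplyr::bind_rows(counts_focal, counts_bg)
  }
  tree <- generate_tree(out$otu_id, seed = design$seed + 4L)
  structure(
    list(counts = out, metadata = metadata, tree = tree, truth = truth),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "<synthetic_community> %d OTUs x %d samples; %d focal response curves\n",
    nrow(x$counts), length(sample_ids(x$counts)),
    sum(purrr::map_chr(x$truth, "shape") != "flat")
  ))
  invisible(x)
}
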