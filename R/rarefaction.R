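#' Drop samples below a sequencing-depth threshold
#'
#' Samples whose total read count is below `depth` are removed; the remaining
#' table keeps all OTU rows (pruning empty OTUs is a separate, explicit step).
#' Mirrors the usual pre-rarefaction filter: samples that cannot be rarefied
#' to the target depth are excluded from analysis.
#'
#' @param table Count-table tibble.
#' @param depth Minimum total reads a sample must reach to be retained.
#' @return Count-table tibble with the surviving sample columns. If no sample
#'   survives, a zero-sample table is returned with a warning.
#' @export
filter_min_depth <- function(table, depth) {
  m <- as_count_matrix(table)
  keep <- colSums(m) >= depth
  if (!any(keep)) {
    warn(sprintf("no sample reaches %d reads; returning empty table", as.integer(depth)))
  }
  dplyr::bind_cols(
    tibble::tibble(otu_id = rownames(m)),
    tibble::as_tibble(m[, keep, drop = FALSE])
  )
}

#' Rarefy every sample to a fixed depth (one draw)
#'
#' Subsamples each sample's reads without replacement down to exactly `depth`
#' reads, the standard correction for uneven sequencing effort. The draw is
#' delegated to [vegan::rrarefy()] under a local seed, so results are
#' reproducible and the global RNG state is left untouched.
#'
#' @param table Count-table tibble; every sample total must be >= `depth`.
#' @param depth Target reads per sample.
#' @param seed Integer seed for the subsampling draw.
#' @return Count-table tibble; every sample column sums to exactly `depth` and
#'   no entry exceeds its input value.
#' @export
rarefy_once <- function(table, depth, seed = 1L) {
  m <- as_count_matrix(table)
  tot <- colSums(m)
  short <- tot < depth
  if (any(short)) {
    abort(paste0(
      "samples below rarefaction depth ", depth, ": ",
      paste(colnames(m)[short], collapse = ", ")
    ))
  }
  # rrarefy warns whenever the smallest positive count exceeds 1, which is
  # routine for OTU tables; preconditions are already enforced above
  sub <- withr::with_seed(seed, suppressWarnings(vegan::rrarefy(t(m), sample = depth)))
  out <- t(sub)
  dimnames(out) <- dimnames(m)
  dplyr::bind_cols(tibble::tibble(otu_id = rownames(out)), tibble::as_tibble(out))
}

#' Multiple rarefaction
#'
#' Repeats [rarefy_once()] `n_replicates` times; replicate `r` uses seed
#' `seed + r`, so the full list is reproducible and each replicate draws from
#' its own stream. Downstream diversity metrics are computed per replicate and
#' then averaged (see [diversity_over_replicates()]).
#'
#' @param table Count-table tibble (already filtered to `depth`).
#' @param depth Target reads per sample.
#' @param n_replicates Number of independent rarefied tables (study default 100).
#' @param seed Base integer seed.
#' @return List of `n_replicates` count-table tibbles.
#' @export
rarefy_replicates <- function(table, depth, n_replicates = 100L, seed = 1L) {
  stopifnot(n_replicates >= 1)
  purrr::map(seq_len(n_replicates), function(r) rarefy_once(table, depth, seed = seed + r))
}
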