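#' Prevalence (occupancy) summary of a count table
#'
#' For each query, counts OTUs present (count > 0) in strictly more than
#' (`direction = "above"`) or strictly fewer than (`direction = "below"`)
#' `threshold * n_samples` samples — the ">90% of samples" / "<10% of samples"
#' style summaries used to describe cosmopolitan versus rare OTUs.
#'
#' @param table Count-table tibble.
#' @param thresholds Occupancy fractions, each strictly between 0 and 1.
#' @param direction Character vector recycled against `thresholds`; `"above"`
#'   counts OTUs with occupancy strictly greater than the threshold, `"below"`
#'   strictly smaller.
#' @return Tibble with columns `threshold`, `direction`, `n_otus`, `fraction`
#'   (of all OTUs in the table).
#' @export
prevalence_summary <- function(table, thresholds = c(0.9, 0.1),
                               direction = c("above", "below")) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("prevalence thresholds must lie strictly between 0 and 1")
  }
  m <- as_count_matrix(table)
  if (ncol(m) == 0L || nrow(m) == 0L) abort("count table is empty")
  direction <- rep_len(match.arg(direction, several.ok = TRUE), length(thresholds))
  occupancy <- rowSums(m > 0)
  n <- ncol(m)
  purrr::map2_dfr(thresholds, direction, function(thr, dir) {
    hit <- if (dir == "above") occupancy > thr * n else occupancy < thr * n
    tibble::tibble(
      threshold = thr, direction = dir,
      n_otus = sum(hit), fraction = sum(hit) / nrow(m)
    )
  })
}

#' Shared-OTU counts across sample groups
#'
#' Venn-style intersection counts: for every non-empty subset of group labels,
#' the number of OTUs detected (count > 0) in at least one sample of *every*
#' group in the subset. The full intersection answers questions like "how many
#' OTUs are shared between all regions/depths/seasons".
#'
#' @param table Count-table tibble.
#' @param groups Named character vector mapping every sample id to a group label.
#' @param max_set_size Largest subset size to report (defaults to all groups).
#' @return Tibble with columns `group_set` (labels joined by `&`), `n_groups`,
#'   `n_otus`, `fraction` of all OTUs.
#' @export
shared_otu_counts <- function(table, groups, max_set_size = NULL) {
  m <- as_count_matrix(table)
  samples <- colnames(m)
  missing <- setdiff(samples, names(groups))
  if (length(missing) > 0) {
    abort(paste0("samples without a group label: ", paste(missing, collapse = ", ")))
  }
  labels <- sort(unique(unname(groups[samples])))
  # presence of each OTU in each group: detected in >= 1 member sample
  present <- vapply(labels, function(g) {
    rowSums(m[, samples[groups[samples] == g], drop = FALSE] > 0) > 0
  }, logical(nrow(m)))
  if (is.null(max_set_size)) max_set_size <- length(labels)
  purrr::map_dfr(seq_len(max_set_size), function(k) {
    sets <- combn(labels, k, simplify = FALSE)
    purrr::map_dfr(sets, function(set) {
      shared <- rowSums(present[, set, drop = FALSE]) == length(set)
      tibble::tibble(
        group_set = paste(set, collapse = " & "), n_groups = k,
        n_otus = sum(shared), fraction = sum(shared) / nrow(m)
      )
    })
  })
}
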