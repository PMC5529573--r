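#' Build a count table from a matrix
#'
#' A count table is the package's tabular representation of an OTU-by-sample
#' read-count matrix: a tibble whose first column, `otu_id`, holds OTU
#' identifiers and whose remaining columns are one non-negative integer column
#' per sample. It mirrors the classic tab-separated OTU table (rows = OTUs,
#' columns = samples) used throughout amplicon workflows.
#'
#' @param x Numeric matrix of non-negative counts with OTUs in rows and
#'   samples in columns. Dimnames supply identifiers; missing dimnames get
#'   `otu_1..n` / `sample_1..m`.
#' @return A count-table tibble.
#' @examples
#' m <- matrix(c(5, 0, 2, 7), 2, 2, dimnames = list(c("o1", "o2"), c("s1", "s2")))
#' count_table(m)
#' @export
count_table <- function(x) {
  stopifnot(is.matrix(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("otu_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sample_", seq_len(ncol(x)))
  validate_counts_matrix(x)
  dplyr::bind_cols(
    tibble::tibble(otu_id = rownames(x)),
    tibble::as_tibble(x)
  )
}

validate_counts_matrix <- function(x) {
  if (any(x < 0)) abort("count table has negative entries")
  if (any(x != round(x))) abort("count table has non-integer entries")
  if (anyDuplicated(rownames(x))) abort("duplicated OTU ids")
  if (anyDuplicated(colnames(x))) abort("duplicated sample ids")
  invisible(x)
}

#' Convert a count table to an OTU-by-sample matrix
#'
#' @param table Count-table tibble (see [count_table()]).
#' @return Integer-valued matrix, OTUs in rows, samples in columns.
#' @export
as_count_matrix <- function(table) {
  stopifnot(is.data.frame(table), "otu_id" %in% names(table))
  m <- as.matrix(table[setdiff(names(table), "otu_id")])
  storage.mode(m) <- "double"
  rownames(m) <- table$otu_id
  validate_counts_matrix(m)
  m
}

sample_ids <- function(table) setdiff(names(table), "otu_id")

#' Read / write tab-separated OTU tables
#'
#' The on-disk format is the plain-text OTU table of amplicon pipelines: a
#' header line whose first field is `#OTU ID` followed by sample identifiers,
#' then one row of integer counts per OTU.
#'
#' @param path File path.
#' @return `read_count_table()` returns a count-table tibble.
#' @export
read_count_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "", show_col_types = FALSE)
  names(tbl)[1] <- "otu_id"
  count_table(as_count_matrix(tbl))
}

#' @rdname read_count_table
#' @param table Count-table tibble.
#' @export
write_count_table <- function(table, path) {
  out <- table
  names(out)[names(out) == "otu_id"] <- "#OTU ID"
  readr::write_tsv(out, path)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by the sample total so that each sample column
#' sums to one.
#'
#' @param table Count-table tibble.
#' @return Tibble of the same shape with proportions in place of counts.
#' @export
relative_abundance <- function(table) {
  m <- as_count_matrix(table)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0(
      "cannot normalise samples with zero total reads: ",
      paste(colnames(m)[tot == 0], collapse = ", ")
    ))
  }
  rel <- sweep(m, 2, tot, "/")
  dplyr::bind_cols(tibble::tibble(otu_id = rownames(rel)), tibble::as_tibble(rel))
}

#' Aggregate OTUs to a higher taxonomic level
#'
#' Sums member-OTU counts per taxon (e.g. genus), conserving each sample's
#' total reads. OTUs without a mapping entry are pooled under `unmapped_label`.
#'
#' @param table Count-table tibble.
#' @param mapping Named character vector, OTU id -> taxon label.
#' @param unmapped_label Sentinel taxon for OTUs absent from `mapping`.
#' @return Count-table tibble whose `otu_id` column holds taxon labels.
#' @export
aggregate_taxa <- function(table, mapping, unmapped_label = "unassigned") {
  m <- as_count_matrix(table)
  taxa <- unname(mapping[rownames(m)])
  taxa[is.na(taxa)] <- unmapped_label
  agg <- rowsum(m, group = taxa)
  # rowsum sorts groups lexically; keep first-appearance order instead
  ord <- unique(taxa)
  agg <- agg[ord, , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(otu_id = rownames(agg)), tibble::as_tibble(agg))
}
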