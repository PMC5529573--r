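#' Parse and serialise Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] so that the
#' package speaks the interchange format used by amplicon pipelines. Parsing a
#' serialised tree round-trips topology, tip names and branch lengths.
#'
#' @param text A Newick string.
#' @return `parse_newick()` returns an [ape] `phylo`; `write_newick()` a string.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort(paste0("malformed Newick string: ", substr(text, 1, 60)))
  }
  tree
}

#' @rdname parse_newick
#' @param tree An [ape] `phylo` object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' @rdname parse_newick
#' @param path Path to a Newick file.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("could not parse Newick file: ", path))
  tree
}

# Shared machinery: per-edge presence/abundance of descendant tips, computed by
# postorder accumulation over the edge table.
tree_postorder <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  re <- ape::reorder.phylo(tree, "postorder")
  list(ntip = length(tree$tip.label), tips = tree$tip.label,
       edge = re$edge, length = re$edge.length)
}

check_taxa <- function(taxa, tips, what = "community") {
  unknown <- setdiff(taxa, tips)
  if (length(unknown) > 0) {
    abort(paste0(what, " contains taxa absent from the tree: ",
                 paste(unknown, collapse = ", ")))
  }
}

# Fraction of each community's total abundance descending from every edge.
# `ab` is a tips x k matrix of per-community tip weights (rows ordered as
# tree$tip.label). Returns an edges x k matrix.
edge_weights <- function(po, ab) {
  n_nodes <- max(po$edge)
  acc <- matrix(0, n_nodes, ncol(ab))
  acc[seq_len(po$ntip), ] <- ab
  for (i in seq_len(nrow(po$edge))) {
    parent <- po$edge[i, 1]; child <- po$edge[i, 2]
    acc[parent, ] <- acc[parent, ] + acc[child, ]
  }
  acc[po$edge[, 2], , drop = FALSE]
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the root to every
#' present taxon — the classic phylogenetic alpha-diversity measure.
#'
#' @param tree Rooted [ape] `phylo` with branch lengths.
#' @param community Character vector of present taxa (tip labels), non-empty.
#' @return PD in branch-length units.
#' @export
faiths_pd <- function(tree, community) {
  if (length(community) == 0) abort("community is empty")
  check_taxa(community, tree$tip.label)
  po <- tree_postorder(tree)
  pres <- matrix(as.numeric(po$tips %in% community), ncol = 1)
  w <- edge_weights(po, pres)
  sum(po$length[w[, 1] > 0])
}

#' Unweighted UniFrac dissimilarity between two communities
#'
#' Fraction of branch length observed by either community that is unique to
#' one of them: 0 when both communities induce the same branch set, 1 when
#' they share no branches.
#'
#' @param tree Rooted [ape] `phylo` with branch lengths.
#' @param a,b Character vectors of present taxa; both non-empty.
#' @return Dissimilarity in \[0, 1\].
#' @export
unweighted_unifrac <- function(tree, a, b) {
  if (length(a) == 0 || length(b) == 0) abort("communities must be non-empty")
  check_taxa(a, tree$tip.label, "community a")
  check_taxa(b, tree$tip.label, "community b")
  po <- tree_postorder(tree)
  pres <- cbind(as.numeric(po$tips %in% a), as.numeric(po$tips %in% b))
  w <- edge_weights(po, pres) > 0
  observed <- w[, 1] | w[, 2]
  unique_br <- xor(w[, 1], w[, 2])
  sum(po$length[unique_br]) / sum(po$length[observed])
}

#' Weighted UniFrac dissimilarity between two communities
#'
#' Sum over branches of branch length times the absolute difference between
#' the fractions of each community's reads descending from the branch.
#' Fractions are relative abundances, so the measure is invariant to
#' sequencing depth. The normalised variant (default) divides by the
#' abundance-weighted maximum attainable value, mapping into \[0, 1\] and
#' making values comparable with unweighted UniFrac.
#'
#' @param tree Rooted [ape] `phylo` with branch lengths.
#' @param a,b Named non-negative abundance vectors (names = tip labels);
#'   positive totals.
#' @param normalized Divide by the abundance-weighted maximum.
#' @return Dissimilarity (>= 0; in \[0, 1\] when normalised).
#' @export
weighted_unifrac <- function(tree, a, b, normalized = TRUE) {
  if (sum(a) <= 0 || sum(b) <= 0) abort("communities must have positive total abundance")
  check_taxa(names(a), tree$tip.label, "community a")
  check_taxa(names(b), tree$tip.label, "community b")
  po <- tree_postorder(tree)
  av <- setNames(numeric(po$ntip), po$tips); av[names(a)] <- a / sum(a)
  bv <- setNames(numeric(po$ntip), po$tips); bv[names(b)] <- b / sum(b)
  w <- edge_weights(po, cbind(av, bv))
  raw <- sum(po$length * abs(w[, 1] - w[, 2]))
  if (!normalized) return(raw)
  # root-to-tip depths weight the maximum attainable segregation
  depth <- node_depths(po)[seq_len(po$ntip)]
  raw / sum(depth * (av + bv))
}

# root-to-node path lengths, preorder over the postorder edge list reversed
node_depths <- function(po) {
  n_nodes <- max(po$edge)
  depth <- numeric(n_nodes)
  for (i in rev(seq_len(nrow(po$edge)))) {
    depth[po$edge[i, 2]] <- depth[po$edge[i, 1]] + po$length[i]
  }
  depth
}

#' Per-sample Faith's PD for a count table
#'
#' @param table Count-table tibble.
#' @param tree Rooted [ape] `phylo`; every OTU in `table` must be a tip
#'   (OTUs missing from the tree are an error, never silently dropped).
#' @return Tibble `sample_id`, `pd`. Samples with no reads get `NA`.
#' @export
pd_samples <- function(table, tree) {
  m <- as_count_matrix(table)
  check_taxa(rownames(m), tree$tip.label, "count table")
  pd <- vapply(colnames(m), function(s) {
    present <- rownames(m)[m[, s] > 0]
    if (length(present) == 0) return(NA_real_)
    faiths_pd(tree, present)
  }, numeric(1))
  tibble::tibble(sample_id = colnames(m), pd = unname(pd))
}

#' Pairwise UniFrac distance matrix over the samples of a count table
#'
#' @param table Count-table tibble.
#' @param tree Rooted [ape] `phylo` containing every OTU as a tip.
#' @param weighted Use abundance-weighted UniFrac.
#' @param normalized Normalise the weighted variant into \[0, 1\].
#' @return Symmetric matrix with sample ids as dimnames and zero diagonal.
#' @export
unifrac_matrix <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  m <- as_count_matrix(table)
  check_taxa(rownames(m), tree$tip.label, "count table")
  if (any(colSums(m) == 0)) abort("samples with zero total reads cannot enter UniFrac")
  po <- tree_postorder(tree)
  # align abundance rows to tip order once, then share edge weights
  ab <- matrix(0, po$ntip, ncol(m), dimnames = list(po$tips, colnames(m)))
  ab[rownames(m), ] <- m
  rel <- sweep(ab, 2, colSums(ab), "/")
  w <- edge_weights(po, rel)
  ns <- ncol(m)
  out <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  depth <- node_depths(po)[seq_len(po$ntip)]
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      if (weighted) {
        d <- sum(po$length * abs(w[, i] - w[, j]))
        if (normalized) d <- d / sum(depth * (rel[, i] + rel[, j]))
      } else {
        pi_ <- w[, i] > 0; pj <- w[, j] > 0
        d <- sum(po$length[xor(pi_, pj)]) / sum(po$length[pi_ | pj])
      }
      out[i, j] <- out[j, i] <- d
    }
  }
  out
}

#' Average a diversity metric over rarefaction replicates
#'
#' Computes the requested metric on every rarefied table and returns the
#' element-wise mean — metric-level averaging across the multiple-rarefaction
#' replicates, never an averaged (non-integer) table.
#'
#' @param tables List of count-table tibbles sharing identical sample ids.
#' @param tree Rooted [ape] `phylo`.
#' @param metric `"pd"`, `"uw_unifrac"` or `"w_unifrac"`.
#' @param normalized Passed to [unifrac_matrix()] for `"w_unifrac"`.
#' @return For `"pd"`, a tibble `sample_id`, `pd`; otherwise a distance matrix.
#' @export
diversity_over_replicates <- function(tables, tree,
                                      metric = c("pd", "uw_unifrac", "w_unifrac"),
                                      normalized = TRUE) {
  metric <- match.arg(metric)
  stopifnot(length(tables) >= 1)
  ids <- purrr::map(tables, sample_ids)
  if (!all(purrr::map_lgl(ids, identical, ids[[1]]))) {
    abort("rarefaction replicates carry different sample sets")
  }
  if (metric == "pd") {
    vals <- purrr::map(tables, function(t) pd_samples(t, tree)$pd)
    tibble::tibble(sample_id = ids[[1]], pd = Reduce(`+`, vals) / length(vals))
  } else {
    mats <- purrr::map(tables, unifrac_matrix, tree = tree,
                       weighted = metric == "w_unifrac", normalized = normalized)
    Reduce(`+`, mats) / length(mats)
  }
}
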