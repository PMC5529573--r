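# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately use different algorithms/libraries than the
# implementation (ape::nodepath, phangorn::Descendants, manual formulas).

make_table <- function(m, otu_ids = NULL, samples = NULL) {
  if (is.null(otu_ids)) otu_ids <- paste0("otu", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(otu_ids, samples)
  count_table(m)
}

random_table <- function(n_otu, n_samp, seed, lambda = 3) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_otu * n_samp, lambda) *
                  rbinom(n_otu * n_samp, 1, 0.4), n_otu, n_samp)
    make_table(m)
  })
}

# Faith's PD as union of root-to-tip edge paths
oracle_pd <- function(tree, community) {
  root <- length(tree$tip.label) + 1L
  paths <- lapply(match(community, tree$tip.label), function(tip) {
    p <- ape::nodepath(tree, root, tip)
    cbind(p[-length(p)], p[-1])
  })
  edges <- unique(do.call(rbind, paths))
  sum(apply(edges, 1, function(e) {
    tree$edge.length[tree$edge[, 1] == e[1] & tree$edge[, 2] == e[2]]
  }))
}

edge_tipsets <- function(tree) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

# unweighted UniFrac by per-branch indicator summation
oracle_uw_unifrac <- function(tree, a, b) {
  sets <- edge_tipsets(tree)
  uniq <- 0; obs <- 0
  for (i in seq_along(sets)) {
    in_a <- any(sets[[i]] %in% a); in_b <- any(sets[[i]] %in% b)
    len <- tree$edge.length[i]
    if (in_a || in_b) obs <- obs + len
    if (xor(in_a, in_b)) uniq <- uniq + len
  }
  uniq / obs
}

# weighted UniFrac by per-branch descending-fraction summation
oracle_w_unifrac <- function(tree, a, b, normalized = TRUE) {
  sets <- edge_tipsets(tree)
  tips <- tree$tip.label
  av <- setNames(numeric(length(tips)), tips); av[names(a)] <- a / sum(a)
  bv <- setNames(numeric(length(tips)), tips); bv[names(b)] <- b / sum(b)
  raw <- sum(vapply(seq_along(sets), function(i) {
    tree$edge.length[i] * abs(sum(av[sets[[i]]]) - sum(bv[sets[[i]]]))
  }, numeric(1)))
  if (!normalized) return(raw)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tips)]
  raw / sum(depths * (av + bv))
}

# type-7 quantile by the explicit order-statistic interpolation formula
oracle_quantile7 <- function(x, p) {
  xs <- sort(x); n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(xs[n])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

random_rooted_tree <- function(n_tips, seed) {
  generate_tree(paste0("L", seq_len(n_tips)), seed = seed)
}

# labelled Euclidean distance matrix from random points
random_dm <- function(n, seed, dims = 3) {
  pts <- withr::with_seed(seed, matrix(rnorm(n * dims), n))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}
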