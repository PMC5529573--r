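test_that("environmental distances are z-scored Euclidean and label-checked", {
  meta <- tibble::tibble(sample_id = c("a", "b"), temperature = c(24, 24),
                         salinity = c(39, 39))
  d <- env_distance(meta, c("temperature", "salinity"))
  expect_equal(d["a", "b"], 0)

  # z-scoring makes the distance scale-free
  m1 <- tibble::tibble(sample_id = c("a", "b"), v = c(0, 3))
  m2 <- tibble::tibble(sample_id = c("a", "b"), v = c(0, 300))
  expect_equal(env_distance(m1, "v"), env_distance(m2, "v"))

  # brute-force double loop on 10 samples x 4 variables
  meta10 <- withr::with_seed(1, tibble::tibble(
    sample_id = paste0("s", 1:10), t = rnorm(10), s = rnorm(10),
    n = rnorm(10), p = rnorm(10)
  ))
  d10 <- env_distance(meta10, c("t", "s", "n", "p"))
  z <- scale(as.matrix(meta10[c("t", "s", "n", "p")]))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(d10[i, j], sqrt(sum((z[i, ] - z[j, ])^2)), tolerance = 1e-12)
  }

  meta_na <- tibble::tibble(sample_id = c("a", "b", "c"), t = c(1, NA, 3))
  expect_error(env_distance(meta_na, "t"), "b")
})

test_that("Mantel statistics, exact p-values and symmetry behave as defined", {
  d1 <- random_dm(12, seed = 1)
  expect_equal(mantel_test(d1, 2 * d1, n_perm = 49)$statistic, 1)

  # exhaustive enumeration oracle on 5 samples
  d5a <- random_dm(5, seed = 2); d5b <- random_dm(5, seed = 3)
  got <- mantel_test(d5a, d5b, exact = TRUE)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  v1 <- d5a[upper.tri(d5a)]
  r_all <- apply(perms, 1, function(p) cor(v1, d5b[p, p][upper.tri(d5b)]))
  r_obs <- cor(v1, d5b[upper.tri(d5b)])
  ident <- apply(perms, 1, function(p) all(p == 1:5))
  p_oracle <- (1 + sum(r_all[!ident] >= r_obs)) / (1 + sum(!ident))
  expect_equal(got$n_perm, 119)
  expect_equal(got$p_value, p_oracle)
  expect_equal(got$statistic, r_obs)

  # statistic is symmetric in its arguments
  expect_equal(mantel_test(d5a, d5b, n_perm = 9)$statistic,
               mantel_test(d5b, d5a, n_perm = 9)$statistic)

  # power: a noisy copy is detected at n = 15
  d2 <- d1 + random_dm(12, seed = 4) * 0.05
  d2 <- (d2 + t(d2)) / 2; diag(d2) <- 0
  dn <- random_dm(15, seed = 5)
  dn2 <- dn + 0.05 * random_dm(15, seed = 6); dn2 <- (dn2 + t(dn2)) / 2; diag(dn2) <- 0
  expect_lte(mantel_test(dn, dn2, n_perm = 999, seed = 7)$p_value, 0.01)

  # rank-based option is exposed
  expect_s3_class(mantel_test(d5a, d5b, n_perm = 9, method = "spearman"),
                  "maxenv_mantel")

  bad <- d5b; rownames(bad) <- colnames(bad) <- letters[1:5]
  expect_error(mantel_test(d5a, bad, n_perm = 9), "labels")
})

test_that("Mantel agrees with vegan on statistic and p-value", {
  skip_if_not_installed("vegan")
  da <- random_dm(10, seed = 8); db <- da + 0.3 * random_dm(10, seed = 9)
  db <- (db + t(db)) / 2; diag(db) <- 0
  ours <- mantel_test(da, db, n_perm = 999, seed = 10)
  theirs <- withr::with_seed(11, vegan::mantel(as.dist(da), as.dist(db), permutations = 999))
  expect_equal(ours$statistic, unname(theirs$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - theirs$signif), 0.02)
})

test_that("seawater density reproduces EOS-80 check values", {
  expect_equal(seawater_density(0, 5), 999.96675, tolerance = 1e-7)
  expect_equal(seawater_density(35, 5), 1027.67547, tolerance = 1e-7)
  expect_equal(seawater_density(35, 25), 1023.34306, tolerance = 1e-7)
  expect_equal(seawater_sigma_t(35, 25), 23.34306, tolerance = 1e-5)
})

test_that("mixed layer depth finds analytic crossings and is threshold-monotone", {
  # two-layer cast built from temperature/salinity: density step at 40 m
  prof <- generate_profile(data.frame(
    depth = c(0, 40, 41, 120),
    temperature = c(29, 29, 24, 24),
    salinity = c(39, 39, 39.5, 39.5)
  ))
  mld <- mixed_layer_depth(prof, criterion = 0.125)
  expect_gte(mld, 40); expect_lte(mld, 41)

  # uniform column never exceeds the criterion: returns max depth
  flat <- generate_profile(data.frame(depth = c(0, 150),
                                      temperature = c(27, 27),
                                      salinity = c(39, 39)))
  expect_equal(mixed_layer_depth(flat), 150)

  # linear density increase of 0.01 kg/m3 per m below the reference
  lin <- tibble::tibble(depth = 0:100,
                        density = 1025 + pmax(0, 0:100 - 10) * 0.01)
  expect_equal(mixed_layer_depth(lin, criterion = 0.125, reference_depth = 10), 22.5)

  # monotone in the criterion
  mlds <- vapply(c(0.03, 0.125, 0.3, 0.5), function(cr) {
    mixed_layer_depth(lin, criterion = cr, reference_depth = 10)
  }, numeric(1))
  expect_true(all(diff(mlds) >= 0))

  shallow <- tibble::tibble(depth = 0:5, density = rep(1025, 6))
  expect_error(mixed_layer_depth(shallow, reference_depth = 10), "span")
})

test_that("scenario classification reproduces the four regime quadrants", {
  # the study's mixed layer depths: north spring 84 m vs fall 10 m,
  # south spring 50 m vs fall 15 m (threshold 30 m separates them)
  got <- scenario_classify(
    mld = c(84, 10, 50, 15), nutrient = c(0.5, 0.4, 2.5, 3.0),
    mld_threshold = 30, nutrient_threshold = 1
  )
  expect_equal(got$turbulence, c("high", "low", "high", "low"))
  expect_equal(got$nutrients, c("low", "low", "high", "high"))
  expect_equal(got$name, c("North_Spring", "North_Fall", "South_Spring", "South_Fall"))

  # invariant to unit changes applied to values and thresholds alike
  scaled <- scenario_classify(c(84, 10, 50, 15) / 1000, c(0.5, 0.4, 2.5, 3.0) * 71,
                              mld_threshold = 0.03, nutrient_threshold = 71)
  expect_equal(scaled$name, got$name)
})

test_that("within-group dissimilarity matches a masked-mean oracle", {
  dm <- random_dm(9, seed = 12)
  groups <- setNames(rep(c("g1", "g2", "g3"), each = 3), rownames(dm))
  got <- within_group_dissimilarity(dm, groups)
  for (g in c("g1", "g2", "g3")) {
    members <- names(groups)[groups == g]
    sub <- dm[members, members]
    expect_equal(got$mean[got$group == g], mean(sub[upper.tri(sub)]), tolerance = 1e-12)
    expect_equal(got$sd[got$group == g], sd(sub[upper.tri(sub)]), tolerance = 1e-12)
  }
  expect_equal(got$rank[which.max(got$mean)], 1L)

  # constant blocks rank as expected
  dm2 <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  dm2[1, 2] <- dm2[2, 1] <- 0.2
  dm2[3, 4] <- dm2[4, 3] <- 0.6
  g2 <- setNames(c("a", "a", "b", "b"), rownames(dm2))
  out2 <- within_group_dissimilarity(dm2, g2)
  expect_equal(out2$rank[out2$group == "b"], 1L)
  expect_equal(out2$mean[out2$group == "a"], 0.2)

  g3 <- setNames(c("a", "a", "a", "solo"), rownames(dm2))
  expect_warning(out3 <- within_group_dissimilarity(dm2, g3), "solo")
  expect_false("solo" %in% out3$group)

  expect_error(within_group_dissimilarity(dm, groups[-1]), "without a group label")
})
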