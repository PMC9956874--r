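test_that("degenerate nulls collapse to zero distance", {
  # uniform expression: every permutation gives the same weighted profile
  cts <- count_aa(proteins_tbl(c("MW", "MMMW", "AAAG")))
  e <- expr_tbl(cts$isoform_id, c(1, 1, 1))
  pn <- permute_null(cts, e, n_perm = 50, seed = 4, level = "isoform")
  expect_equal(pn$distances, rep(0, 50), tolerance = 1e-12)

  # identically composed proteins: profile fixed regardless of expression
  cts2 <- count_aa(proteins_tbl(c("MWG", "MMWWGG", "MWGMWG")))
  e2 <- expr_tbl(cts2$isoform_id, c(5, 1, 3))
  pn2 <- permute_null(cts2, e2, n_perm = 30, seed = 4, level = "isoform")
  expect_equal(pn2$distances, rep(0, 30), tolerance = 1e-12)
  expect_equal(pn2$median_profile[["M"]], 1 / 3, tolerance = 1e-12)
})

test_that("exhaustive enumeration matches an independent brute-force oracle", {
  seqs <- c("MW", "MMMW", "AAAG")
  e <- c(2, 1, 1)
  cts <- count_aa(proteins_tbl(seqs))
  pn <- permute_null(cts, expr_tbl(cts$isoform_id, e), exhaustive = TRUE,
                     level = "isoform")
  expect_equal(pn$n_perm, 6)

  # oracle: enumerate all 3! assignments by hand, recompute everything
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  profs <- t(vapply(perms, function(p) brute_weighted(seqs, e[p]), numeric(20)))
  med <- apply(profs, 2, stats::median)
  dists <- sqrt(rowSums(sweep(profs, 2, med)^2))
  expect_equal(pn$median_profile, med, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sort(pn$distances), sort(dists), tolerance = 1e-12)
})

test_that("gene-level permutation moves isoforms of a gene together", {
  # two genes, one with two isoforms; permuting at gene level swaps gene
  # totals while each gene keeps its internal isoform weighting
  prot <- proteins_tbl(c("MW", "MM", "GGGG"), genes = c("gA", "gA", "gB"))
  e <- expr_tbl(prot$isoform_id, c(3, 1, 4))
  pn <- permute_null(count_aa(prot), e, exhaustive = TRUE, level = "gene")
  expect_equal(pn$n_perm, 2)

  # identity: gA total 4 with weights (3/4, 1/4); swap: gA gets 4, gB gets 4
  comp_gA <- (3 / 4) * aa_vec(M = 1, W = 1) + (1 / 4) * aa_vec(M = 2)
  comp_gB <- aa_vec(G = 4)
  prof_id <- (4 * comp_gA + 4 * comp_gB); prof_id <- prof_id / sum(prof_id)
  prof_sw <- (4 * comp_gA + 4 * comp_gB); prof_sw <- prof_sw / sum(prof_sw)
  # totals are equal here, so both permutations coincide
  expect_equal(pn$profiles[, 1], prof_id, tolerance = 1e-12)

  # unequal totals distinguish the assignments
  e2 <- expr_tbl(prot$isoform_id, c(6, 2, 4))
  pn2 <- permute_null(count_aa(prot), e2, exhaustive = TRUE, level = "gene")
  prof_a <- (8 * comp_gA + 4 * comp_gB); prof_a <- prof_a / sum(prof_a)
  prof_b <- (4 * comp_gA + 8 * comp_gB); prof_b <- prof_b / sum(prof_b)
  got <- pn2$profiles[, order(pn2$profiles["G", ])]
  want <- cbind(prof_a, prof_b)[, order(c(prof_a[["G"]], prof_b[["G"]]))]
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("permutation reassigns the exact multiset of expression values", {
  # exhaustive run on 4 entities: every permuted profile must be reachable
  # by a true rearrangement of the same expression values
  prot4 <- proteins_tbl(c("MW", "AG", "KK", "FFL"))
  e4 <- c(1, 2, 3, 4)
  pn4 <- permute_null(count_aa(prot4), expr_tbl(prot4$isoform_id, e4),
                      exhaustive = TRUE, level = "isoform")
  expect_equal(pn4$n_perm, 24)
  m4 <- as.matrix(count_aa(prot4)[, aa_alphabet()])
  all_perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  all_perms <- all_perms[apply(all_perms, 1, function(r) length(unique(r)) == 4), ]
  cand <- apply(all_perms, 1, function(r) {
    w <- colSums(m4 * e4[as.integer(r)]); w / sum(w)
  })
  for (k in seq_len(24)) {
    dmin <- min(sqrt(colSums((cand - pn4$profiles[, k])^2)))
    expect_lt(dmin, 1e-12)
  }
})

test_that("percentiles rank observed distances against the null", {
  set.seed(12)
  fix <- simulate_proteome(n_genes = 15, isoforms_per_gene = 1, seed = 101,
                           length_range = c(30, 80))
  cts <- count_aa(fix$proteins)
  pn <- permute_null(cts, fix$expression, n_perm = 200, seed = 3, level = "isoform")

  # the median itself is at distance 0: no permutation is strictly closer
  pn0 <- null_percentile(pn, pn$median_profile, "median")
  expect_equal(pn0$observed$percentile[1], 0)

  # a profile farther than everything is at percentile 100
  far <- aa_vec(W = 1)
  pn1 <- null_percentile(pn, far, "far")
  expect_equal(pn1$observed$percentile[1], 100)

  # rank oracle: percentile of each permuted profile equals its strict rank
  for (k in c(1, 50, 200)) {
    d <- profile_distance(pn$profiles[, k], pn$median_profile)
    got <- null_percentile(pn, pn$profiles[, k], "x")$observed$percentile[1]
    expect_equal(got, 100 * sum(pn$distances < d) / pn$n_perm)
  }
})

test_that("per-amino-acid null summaries match order-statistics oracles", {
  set.seed(44)
  fix <- simulate_proteome(n_genes = 10, isoforms_per_gene = 1, seed = 55,
                           length_range = c(30, 60))
  cts <- count_aa(fix$proteins)
  pn <- permute_null(cts, fix$expression, n_perm = 101, seed = 6, level = "isoform")
  s <- null_summary(pn, observed = list(obs = pn$profiles[, 1]))
  for (a in c("A", "K", "W")) {
    vals <- pn$profiles[a, ]
    expect_equal(s$median[s$aa == a], stats::median(vals))
    expect_equal(s$q1[s$aa == a], unname(stats::quantile(vals, 0.25)))
    expect_equal(s$q3[s$aa == a], unname(stats::quantile(vals, 0.75)))
    iqr <- s$q3[s$aa == a] - s$q1[s$aa == a]
    expect_equal(s$upper_fence[s$aa == a], s$q3[s$aa == a] + 1.5 * iqr)
  }
  # an observed profile drawn from the null lies within the null's range
  expect_true(all(s$observed_obs >= apply(pn$profiles, 1, min) - 1e-12))
  expect_true(all(s$observed_obs <= apply(pn$profiles, 1, max) + 1e-12))

  # degenerate null: zero-width boxes
  ctsu <- count_aa(proteins_tbl(c("MW", "MWMW")))
  pnu <- permute_null(ctsu, expr_tbl(ctsu$isoform_id, c(2, 2)),
                      n_perm = 20, seed = 1, level = "isoform")
  su <- null_summary(pnu)
  expect_equal(su$q1, su$q3, tolerance = 1e-12)
})

test_that("nulls are reproducible by seed and guard their preconditions", {
  fix <- simulate_proteome(n_genes = 10, isoforms_per_gene = 1, seed = 8,
                           length_range = c(20, 40))
  cts <- count_aa(fix$proteins)
  a <- permute_null(cts, fix$expression, n_perm = 100, seed = 42)
  b <- permute_null(cts, fix$expression, n_perm = 100, seed = 42)
  expect_identical(a$distances, b$distances)
  c <- permute_null(cts, fix$expression, n_perm = 100, seed = 43)
  expect_false(identical(a$distances, c$distances))

  expect_error(permute_null(cts, fix$expression, n_perm = 0, seed = 1), "at least 1")
  expect_error(permute_null(cts, fix$expression, n_perm = 10), "seed")
  one <- count_aa(proteins_tbl("MW"))
  expect_error(permute_null(one, expr_tbl("i1", 1), n_perm = 5, seed = 1), "identity")
  expect_s3_class(autoplot(a), "ggplot")
  expect_s3_class(plot_null_profiles(a), "ggplot")
})

test_that("null percentiles of null-generated profiles are approximately uniform", {
  # calibration at reduced scale: 300 trials x 200 permutations
  fix <- simulate_proteome(n_genes = 30, isoforms_per_gene = 1, seed = 2024,
                           length_range = c(50, 150))
  cts <- count_aa(fix$proteins)
  e <- rowMeans(as.matrix(fix$expression[-1]))
  names(e) <- fix$expression$isoform_id
  m <- as.matrix(cts[, aa_alphabet()])

  n_trials <- 300
  set.seed(555)
  obs_perms <- replicate(n_trials, sample(length(e)))
  pcts <- vapply(seq_len(n_trials), function(t) {
    pn <- permute_null(cts, e, n_perm = 200, seed = 10000 + t, level = "isoform")
    w <- colSums(m * e[obs_perms[, t]])
    null_percentile(pn, w / sum(w), "obs")$observed$percentile[1]
  }, numeric(1))
  u <- pcts / 100
  ks <- max(abs(sort(u) - (seq_len(n_trials) - 0.5) / n_trials))
  expect_lt(ks, 0.1)
})
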