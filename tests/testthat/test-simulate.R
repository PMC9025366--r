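# Synthetic-data generator: determinism, planted-truth bookkeeping,
# mean fidelity and bridge dominance.

test_that("identical design, archetypes and seed give bit-identical output", {
  d <- cohort_design(n_genes = 120)
  a <- default_archetypes()
  s1 <- simulate_counts(d, a, seed = 42)
  s2 <- simulate_counts(d, a, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$size_factors, s2$size_factors)
  s3 <- simulate_counts(d, a, seed = 43)
  expect_false(identical(s1$counts, s3$counts))

  g1 <- simulate_gene_sets(s1$truth, n_decoy_sets = 20, seed = 5)
  g2 <- simulate_gene_sets(s1$truth, n_decoy_sets = 20, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".gmt")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(g1, f1); write_gmt(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  e1 <- simulate_interactome(s1$truth$gene[1:40], n_communities = 2,
                             bridge_genes = s1$truth$gene[1], seed = 9)
  e2 <- simulate_interactome(s1$truth$gene[1:40], n_communities = 2,
                             bridge_genes = s1$truth$gene[1], seed = 9)
  expect_identical(e1, e2)
})

test_that("archetype bookkeeping: labels count floor(fraction * n_genes), nulls otherwise", {
  d <- cohort_design(n_genes = 3000)
  sim <- simulate_counts(d, default_archetypes(), seed = 1)
  counts <- table(sim$truth$archetype)
  expect_equal(unname(counts[["reversal"]]), 150)
  expect_equal(unname(counts[["aging_concordant"]]), 150)
  expect_equal(unname(counts[["ad_concordant"]]), 150)
  expect_equal(unname(counts[["null"]]), 2550)

  # degenerate: no archetypes -> all null
  s0 <- simulate_counts(cohort_design(n_genes = 50), list(), seed = 3)
  expect_true(all(s0$truth$archetype == "null"))

  # odd fraction floors
  s1 <- simulate_counts(cohort_design(n_genes = 101),
                        list(archetype_spec("reversal", 0.05, -1.5, 1.2)),
                        seed = 3)
  expect_equal(sum(s1$truth$archetype == "reversal"), 5)
})

test_that("planted cohort means follow mean_Young * 2^lfc semantics", {
  arch <- list(
    archetype_spec("reversal", 0.25, lfc_aging = -1.5, lfc_ad = 1.2),
    archetype_spec("aging_concordant", 0.25, lfc_aging = -0.85),
    archetype_spec("ad_concordant", 0.25, lfc_ad = 0.8)
  )
  sim <- simulate_counts(cohort_design(n_genes = 40), arch, seed = 11)
  tr <- sim$truth
  rev <- tr[tr$archetype == "reversal", ]
  expect_equal(rev$mean_Old, rev$mean_Young * 2^-1.5)
  expect_equal(rev$mean_OAD, rev$mean_Young * 2^(-1.5 + 1.2))
  # hand value: mean_Young = 200 -> Old mean 200 * 2^-1.5 = 70.71
  expect_equal(200 * 2^-1.5, 70.71068, tolerance = 1e-6)

  aging <- tr[tr$archetype == "aging_concordant", ]
  expect_equal(aging$mean_Old, aging$mean_OAD)  # OAD shifted like Old
  ad <- tr[tr$archetype == "ad_concordant", ]
  expect_equal(ad$mean_Old, ad$mean_Young)      # Old identical to Young
  expect_equal(ad$mean_OAD, ad$mean_Young * 2^0.8)
  expect_true(all(tr$mean_Young > 0))
})

test_that("invalid designs and archetypes are rejected", {
  expect_error(cohort_design(group_sizes = c(Young = 8, Old = 10)), "Young, Old, OAD")
  expect_error(cohort_design(group_sizes = c(Young = 1, Old = 10, OAD = 12)),
               "at least 2")
  expect_error(cohort_design(dispersion = 0), "positive")
  expect_error(cohort_design(dispersion = -1), "positive")
  expect_error(archetype_spec("reversal", 0.1, lfc_aging = -1, lfc_ad = -1),
               "inconsistent")
  expect_error(archetype_spec("aging_concordant", 0.1, lfc_aging = -1, lfc_ad = 1),
               "inconsistent")
  expect_error(
    simulate_counts(cohort_design(n_genes = 10),
                    list(archetype_spec("reversal", 0.6, -1, 1),
                         archetype_spec("ad_concordant", 0.6, 0, 1)),
                    seed = 1),
    "at most 1")
})

test_that("empirical cohort means match truth within 3 standard errors (scaled-up design)", {
  d <- cohort_design(group_sizes = c(Young = 50, Old = 50, OAD = 50),
                     n_genes = 300)
  sim <- simulate_counts(d, default_archetypes(), seed = 2024)
  norm <- sweep(sim$counts, 2, sim$size_factors, "/")
  frac_ok <- vapply(c("Young", "Old", "OAD"), function(co) {
    cols <- sim$samples$cohort == co
    mu <- sim$truth[[paste0("mean_", co)]]
    emp <- rowMeans(norm[, cols, drop = FALSE])
    # var(K/s) = mu/s + alpha mu^2
    v <- outer(mu, 1 / sim$size_factors[cols]) + d$dispersion * mu^2
    se <- sqrt(rowMeans(v) / sum(cols))
    mean(abs(emp - mu) <= 3 * se)
  }, numeric(1))
  expect_true(all(frac_ok >= 0.99))
})

test_that("gene-set generator plants the archetype set and honours options", {
  sim <- simulate_counts(cohort_design(n_genes = 200), default_archetypes(),
                         seed = 7)
  rev_genes <- sim$truth$gene[sim$truth$archetype == "reversal"]

  gs0 <- simulate_gene_sets(sim$truth, n_decoy_sets = 0, seed = 1)
  expect_length(gs0, 1)
  expect_setequal(gs0[["planted_reversal"]], rev_genes)

  gs <- simulate_gene_sets(sim$truth, n_decoy_sets = 20,
                           set_size_range = c(5, 20), seed = 1,
                           exclude_planted = TRUE)
  expect_length(gs, 21)
  for (nm in setdiff(names(gs), "planted_reversal")) {
    expect_length(intersect(gs[[nm]], rev_genes), 0)
  }
  sizes <- lengths(gs[startsWith(names(gs), "decoy")])
  expect_true(all(sizes >= 5 & sizes <= 20))

  expect_error(simulate_gene_sets(sim$truth, n_decoy_sets = 2,
                                  set_size_range = c(10, 500), seed = 1),
               "exceeds")
  # GMT round trip
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, f)
  back <- read_gmt(f)
  expect_identical(names(back), names(gs))
  for (nm in names(gs)) expect_identical(back[[nm]], gs[[nm]])
})

test_that("interactome generator builds communities with dominant bridges", {
  # 1 community, full density -> complete graph, all betweenness equal (zero)
  members <- paste0("g", 1:6)
  e <- simulate_interactome(members, n_communities = 1, intra_edge_prob = 1,
                            seed = 4)
  expect_equal(nrow(e), choose(6, 2))
  net <- induce_network(filter_edges(e), members)
  bc <- betweenness_centrality(net)
  expect_true(all(bc$betweenness == 0))

  # 2 communities of 5 joined by one bridge: bridge strictly maximal, checked
  # against the exhaustive path-enumeration oracle
  members <- sprintf("m%02d", 1:11)
  e2 <- simulate_interactome(members, n_communities = 2,
                             bridge_genes = "m01", intra_edge_prob = 0.6,
                             seed = 8)
  net2 <- induce_network(filter_edges(e2), members)
  bc2 <- betweenness_centrality(net2)
  g <- net2$graph
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  oracle <- brute_betweenness(adj)
  expect_equal(bc2$betweenness, unname(oracle), tolerance = 1e-12)
  bridge_b <- bc2$betweenness[bc2$node == "m01"]
  expect_true(all(bridge_b > bc2$betweenness[bc2$node != "m01"]))

  # evidence channels all zero on the requested channels -> no edges survive
  e3 <- simulate_interactome(members, n_communities = 2, bridge_genes = "m01",
                             intra_edge_prob = 0.5,
                             channel_profile = c(experiments = 0L,
                                                 database = 0L,
                                                 textmining = 900L),
                             seed = 8)
  expect_equal(nrow(filter_edges(e3)), 0)

  # validation
  expect_error(simulate_interactome(members, n_communities = 0,
                                    bridge_genes = "m01", seed = 1),
               "at least 1")
  expect_error(simulate_interactome(members, n_communities = 2,
                                    bridge_genes = character(), seed = 1),
               "bridge")
  expect_error(simulate_interactome(members, n_communities = 2,
                                    bridge_genes = "zzz", seed = 1),
               "subset")
  expect_error(simulate_interactome(members, n_communities = 2,
                                    bridge_genes = "m01",
                                    intra_edge_prob = 0, seed = 1),
               "intra_edge_prob")
})

test_that("bridge dominance holds across seeds and community counts", {
  members <- sprintf("p%02d", 1:30)
  bridges <- c("p01", "p02")
  for (seed in 1:5) {
    e <- simulate_interactome(members, n_communities = 3,
                              bridge_genes = bridges,
                              intra_edge_prob = 0.4, seed = seed)
    net <- induce_network(filter_edges(e), members)
    bc <- betweenness_centrality(net)
    b_min <- min(bc$betweenness[bc$node %in% bridges])
    b_max_other <- max(bc$betweenness[!bc$node %in% bridges])
    expect_gt(b_min, b_max_other)
  }
})
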