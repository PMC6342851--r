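test_that("config validation catches impossible settings", {
  expect_error(synthetic_config(n_sites = 4, n_streams = 5), "n_streams")
  expect_error(synthetic_config(phi = 1.2), "phi")
  expect_error(synthetic_config(richness_max = 200, n_species = 100),
               "richness")
  expect_error(synthetic_config(flip_prob = 2), "flip_prob")
})

test_that("nested gradients are perfect subset chains with interpolated richness", {
  cfg <- synthetic_config(scenario = "nested", n_species = 20, n_sites = 6,
                          n_streams = 2, richness_max = 12, richness_min = 3,
                          seed = 5)
  g <- generate_nested(cfg)
  m <- unclass(g$incidence)
  rich <- rowSums(m)
  expect_identical(rich[[1]], 12)
  expect_identical(rich[[length(rich)]], 3)
  expect_true(all(diff(rich) <= 0))
  # exhaustive pairwise set-inclusion oracle
  for (i in 1:6) for (j in 1:6) {
    poorer <- if (rich[i] <= rich[j]) i else j
    richer <- i + j - poorer
    expect_true(all(which(m[poorer, ] == 1) %in% which(m[richer, ] == 1)))
  }
  # richness-4 to richness-2 gradient: all pairs nested, mean turnover 0
  cfg2 <- synthetic_config(scenario = "nested", n_species = 10, n_sites = 4,
                           richness_max = 8, richness_min = 2, n_streams = 1)
  bp <- pairwise_beta(generate_nested(cfg2)$incidence)
  expect_identical(mean(bp$components$beta_sim[lower.tri(diag(4))]), 0)
  # equal bounds give identical sites, every component zero
  cfg3 <- synthetic_config(scenario = "nested", n_species = 10, n_sites = 2,
                           richness_max = 5, richness_min = 5, n_streams = 1)
  bp3 <- pairwise_beta(generate_nested(cfg3)$incidence)
  expect_true(all(sapply(bp3$components, function(d) all(d == 0))))
  # two empty sites by construction are rejected
  expect_error(generate_nested(
    synthetic_config(scenario = "nested", n_species = 10, n_sites = 5,
                     richness_max = 0, richness_min = 0, n_streams = 1)),
    "empty")
  expect_error(generate_nested(synthetic_config(scenario = "mixed")),
               "scenario")
})

test_that("replacement windows give the hand-computed overlap components", {
  cfg <- synthetic_config(scenario = "replacement", n_species = 8,
                          n_sites = 3, n_streams = 1, k = 4, step = 2)
  g <- generate_replacement(cfg)
  m <- unclass(g$incidence)
  # adjacent windows of length 4 shifted by 2: a=2, b=2, c=2
  expect_identical(matching_components(m[1, ], m[2, ]),
                   c(a = 2L, b = 2L, c = 2L))
  bas <- bas_partition(matching_components(m[1, ], m[2, ]))
  expect_equal(bas$beta_sor, 4 / 8)
  expect_identical(bas$beta_sne, 0)
  pod <- pod_partition(matching_components(m[1, ], m[2, ]))
  expect_equal(pod$beta_jac, 2 / 3)
  expect_identical(pod$beta_rich, 0)
  # step 0 gives identical sites
  m0 <- unclass(generate_replacement(
    synthetic_config(scenario = "replacement", n_species = 8, n_sites = 3,
                     n_streams = 1, k = 4, step = 0))$incidence)
  expect_true(all(m0[1, ] == m0[2, ]))
  # overrunning the species axis is an error
  expect_error(generate_replacement(
    synthetic_config(scenario = "replacement", n_species = 8, n_sites = 3,
                     n_streams = 1, k = 4, step = 3)), "overrun")
})

test_that("equal richness forces zero nestedness and richness difference", {
  for (seed in 1:5) {
    cfg <- synthetic_config(scenario = "replacement", n_species = 40,
                            n_sites = 8, n_streams = 2, k = 10, seed = seed)
    bp <- pairwise_beta(generate_replacement(cfg)$incidence)
    tri <- lower.tri(bp$components$beta_sne)
    expect_true(all(bp$components$beta_sne[tri] == 0))
    expect_true(all(bp$components$beta_rich[tri] == 0))
  }
})

test_that("mixed bundles are deterministic given config + seed", {
  cfg <- synthetic_config(seed = 9, flip_prob = 0.05)
  b1 <- generate_mixed(cfg)
  b2 <- generate_mixed(cfg)
  expect_identical(b1$incidence, b2$incidence)
  expect_identical(b1$env, b2$env)
  expect_identical(b1$taxonomy, b2$taxonomy)
  b3 <- generate_mixed(synthetic_config(seed = 10, flip_prob = 0.05))
  expect_false(identical(b1$incidence, b3$incidence))
})

test_that("mixed bundles carry a coherent taxonomy, grouping and environment", {
  b <- generate_mixed(synthetic_config(seed = 4))
  expect_identical(nrow(b$taxonomy), 113L)
  expect_identical(length(unique(b$taxonomy$family)), 17L)
  expect_identical(min(table(b$taxonomy$family)), 1L)  # singleton family
  expect_identical(nrow(b$grouping), 42L)
  expect_identical(length(unique(b$grouping$stream)), 11L)
  expect_identical(sort(unique(b$grouping$region)), c("ES", "WS"))
  expect_identical(nrow(b$env), 11L)
  expect_true(all(as.matrix(b$env[ENV_VARIABLES]) > 0))
  expect_true(all(b$threat$category %in% THREAT_CATEGORIES))
  # every species occurs somewhere, as in a field checklist
  expect_true(all(colSums(unclass(b$incidence)) > 0))
})

test_that("the phi endpoints reduce to the pure scenarios", {
  b0 <- generate_mixed(synthetic_config(phi = 0, seed = 1))
  bp0 <- pairwise_beta(b0$incidence)
  tri <- lower.tri(diag(42))
  expect_identical(mean(bp0$components$beta_sim[tri]), 0)
  b1 <- generate_mixed(synthetic_config(phi = 1, seed = 1))
  bp1 <- pairwise_beta(b1$incidence)
  expect_identical(mean(bp1$components$beta_sne[tri]), 0)
  expect_identical(mean(bp1$components$beta_rich[tri]), 0)
})

test_that("the pipeline classifies phi endpoints as nestedness- vs turnover-dominated", {
  tri <- lower.tri(diag(20))
  for (seed in 1:20) {
    b0 <- generate_mixed(synthetic_config(phi = 0, n_sites = 20,
                                          n_streams = 5, n_species = 60,
                                          n_families = 6, seed = seed,
                                          flip_prob = 0.02))
    bp <- pairwise_beta(b0$incidence)$components
    expect_lt(mean(bp$beta_sim[tri]), mean(bp$beta_sne[tri]))
    b1 <- generate_mixed(synthetic_config(phi = 1, n_sites = 20,
                                          n_streams = 5, n_species = 60,
                                          n_families = 6, seed = seed,
                                          flip_prob = 0.02))
    bp <- pairwise_beta(b1$incidence)$components
    expect_gt(mean(bp$beta_sim[tri]), mean(bp$beta_sne[tri]))
  }
})

test_that("the gradient-linked covariate is recoverable by Mantel at phi = 1", {
  hits <- 0
  for (seed in 1:20) {
    b <- generate_mixed(synthetic_config(phi = 1, env_noise_sd = 0.1,
                                         seed = seed))
    bp <- pairwise_beta(aggregate_to_streams(b$incidence, b$grouping))
    mt <- mantel_test(bp$components$beta_sim,
                      env_difference(b$env, "altitude",
                                     streams = bp$unit_ids),
                      n_perm = 999, seed = seed)
    hits <- hits + (mt$p < 0.05)
  }
  expect_gte(hits, 16)
})

test_that("bundles write a complete study directory the readers accept", {
  b <- generate_mixed(synthetic_config(n_species = 30, n_sites = 10,
                                       n_streams = 4, n_families = 5,
                                       seed = 6))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_identical(read_incidence(file.path(dir, "incidence.csv")),
                   b$incidence)
  expect_identical(read_env(file.path(dir, "env.csv"))$stream, b$env$stream)
  expect_identical(read_grouping(file.path(dir, "grouping.csv"))$site,
                   b$grouping$site)
  expect_identical(nrow(read_taxonomy(file.path(dir, "taxonomy.csv"))), 30L)
  expect_identical(nrow(read_threat(file.path(dir, "threat.csv"))), 30L)
})
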