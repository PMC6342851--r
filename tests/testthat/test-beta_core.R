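test_that("matching components count shared and unique species", {
  expect_identical(matching_components(c(1, 1, 0, 1), c(1, 0, 1, 1)),
                   c(a = 2L, b = 1L, c = 1L))
  x <- c(1, 0, 1, 1, 0)
  expect_identical(matching_components(x, x), c(a = 3L, b = 0L, c = 0L))
  expect_identical(matching_components(c(1, 1, 0, 0), c(0, 0, 1, 1))[["a"]], 0L)
  expect_error(matching_components(c(1, 0), c(1, 0, 1)), "length")
  expect_error(matching_components(c(1, 2), c(1, 0)), "binary")
})

test_that("BAS partition reproduces hand-evaluated formula values", {
  r <- bas_partition(2, 1, 3)
  expect_equal(r$beta_sor, 0.5)
  expect_equal(r$beta_sim, 1 / 3)
  expect_equal(r$beta_sne, 0.5 - 1 / 3)
  # nested pair: no replacement, all dissimilarity is nestedness
  r <- bas_partition(3, 2, 0)
  expect_identical(r$beta_sim, 0)
  expect_equal(r$beta_sor, 0.25)
  expect_equal(r$beta_sne, 0.25)
  # one empty unit: 0/0 turnover convention gives a pure richness difference
  r <- bas_partition(0, 5, 0)
  expect_identical(r$beta_sim, 0)
  expect_equal(r$beta_sor, 1)
  expect_equal(r$beta_sne, 1)
  # both empty: undefined, flagged NA rather than zeroed
  expect_true(all(is.na(bas_partition(0, 0, 0))))
})

test_that("POD partition reproduces hand-evaluated formula values", {
  r <- pod_partition(2, 1, 3)
  expect_equal(r$beta_jac, 2 / 3)
  expect_equal(r$beta_m3, 1 / 3)
  expect_equal(r$beta_rich, 1 / 3)
  # equal-richness full replacement endpoint
  r <- pod_partition(0, 4, 4)
  expect_equal(r$beta_jac, 1)
  expect_equal(r$beta_m3, 1)
  expect_identical(r$beta_rich, 0)
  # identical units
  r <- pod_partition(6, 0, 0)
  expect_identical(unlist(r, use.names = FALSE), c(0, 0, 0))
  expect_true(all(is.na(pod_partition(0, 0, 0))))
})

test_that("partitions accept a packed c(a,b,c) vector", {
  mc <- matching_components(c(1, 1, 0, 1), c(1, 0, 1, 1))
  expect_equal(bas_partition(mc), bas_partition(2, 1, 1))
  expect_equal(pod_partition(mc), pod_partition(2, 1, 1))
})

test_that("additivity, framework link, symmetry, range and purity hold over a grid", {
  grid <- expand.grid(a = 0:6, b = 0:6, c = 0:6)
  grid <- grid[rowSums(grid) > 0, ]
  bas <- bas_partition(grid$a, grid$b, grid$c)
  pod <- pod_partition(grid$a, grid$b, grid$c)
  expect_true(all(abs(bas$beta_sor - (bas$beta_sim + bas$beta_sne)) < 1e-12))
  expect_true(all(abs(pod$beta_jac - (pod$beta_m3 + pod$beta_rich)) < 1e-12))
  expect_true(all(abs(pod$beta_jac -
                        2 * bas$beta_sor / (1 + bas$beta_sor)) < 1e-12))
  vals <- cbind(bas, pod)
  expect_true(all(vals >= 0 & vals <= 1))
  # swapping the units swaps b and c, leaving every component unchanged
  swapped <- cbind(bas_partition(grid$a, grid$c, grid$b),
                   pod_partition(grid$a, grid$c, grid$b))
  expect_equal(vals, swapped, ignore_attr = TRUE)
  # nestedness purity: subset pairs (min(b,c)=0) have zero turnover
  nested <- grid$b == 0 | grid$c == 0
  expect_true(all(bas$beta_sim[nested] == 0))
  expect_true(all(pod$beta_m3[nested] == 0))
  # replacement purity: equal richness means b=c, zero richness difference
  eq <- grid$b == grid$c
  expect_true(all(bas$beta_sne[eq] == 0))
  expect_true(all(pod$beta_rich[eq] == 0))
})

test_that("total and turnover dissimilarity increase with b when b <= c", {
  for (a in 1:4) for (cc in 1:4) {
    b <- 0:cc
    bas <- bas_partition(rep(a, length(b)), b, rep(cc, length(b)))
    expect_true(all(diff(bas$beta_sor) > 0))
    expect_true(all(diff(bas$beta_sim) > 0))
  }
})

test_that("pairwise matrices agree with a per-pair brute-force oracle", {
  m <- random_incidence(5, 12, seed = 42)
  bp <- pairwise_beta(m)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) {
      for (k in BETA_COMPONENTS) expect_identical(bp$components[[k]][i, j], 0)
      next
    }
    abc <- oracle_abc(unclass(m)[i, ], unclass(m)[j, ])
    want <- oracle_six(abc["a"], abc["b"], abc["c"])
    for (k in BETA_COMPONENTS)
      expect_equal(bp$components[[k]][i, j], want[[k]], tolerance = 1e-14)
  }
  # symmetry and elementwise additivity across whole matrices
  for (k in BETA_COMPONENTS)
    expect_identical(bp$components[[k]], t(bp$components[[k]]))
  expect_equal(bp$components$beta_sor,
               bp$components$beta_sim + bp$components$beta_sne)
  expect_equal(bp$components$beta_jac,
               bp$components$beta_m3 + bp$components$beta_rich)
})

test_that("a two-unit matrix reduces to the single-pair partitions", {
  m <- incidence_matrix(rbind(u1 = c(1, 1, 0, 1, 0), u2 = c(1, 0, 1, 1, 1)))
  bp <- pairwise_beta(m)
  mc <- matching_components(unclass(m)[1, ], unclass(m)[2, ])
  expect_equal(bp$components$beta_sor[2, 1], bas_partition(mc)$beta_sor)
  expect_equal(bp$components$beta_m3[2, 1], pod_partition(mc)$beta_m3)
  expect_error(pairwise_beta(m[1, , drop = FALSE]), "at least 2")
})

test_that("total Sorensen dissimilarity matches vegan's binary Bray-Curtis", {
  skip_if_not_installed("vegan")
  m <- random_incidence(8, 20, seed = 5)
  ours <- pairwise_beta(m)$components$beta_sor
  veg <- as.matrix(vegan::vegdist(unclass(m), method = "bray", binary = TRUE))
  expect_equal(ours, veg, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("double-empty pairs are masked, not silently zeroed", {
  m <- incidence_matrix(rbind(u1 = c(1, 0), u2 = c(0, 0), u3 = c(0, 0)),
                        coerce = FALSE)
  bp <- pairwise_beta(m)
  expect_true(bp$excluded["u2", "u3"])
  expect_identical(bp$n_excluded, 1L)
  expect_true(is.na(bp$components$beta_sor["u2", "u3"]))
  expect_false(is.na(bp$components$beta_sor["u1", "u2"]))
  # sensitivity alternative: treat identical empty communities as 0
  bp0 <- pairwise_beta(m, double_empty = "zero")
  expect_identical(bp0$components$beta_sor["u2", "u3"], 0)
})

test_that("pairwise output writes square, long and mask CSVs", {
  m <- random_incidence(4, 8, seed = 9)
  bp <- pairwise_beta(m)
  pre <- file.path(withr::local_tempdir(), "beta")
  files <- write_beta_pairwise(bp, pre)
  expect_true(all(file.exists(files)))
  long <- read.csv(paste0(pre, "_long.csv"))
  expect_identical(nrow(long), 6L * 6L)  # 6 pairs x 6 components
  sq <- read.csv(paste0(pre, "_beta_sor.csv"), row.names = 1)
  expect_equal(as.matrix(sq), bp$components$beta_sor, ignore_attr = TRUE)
})
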