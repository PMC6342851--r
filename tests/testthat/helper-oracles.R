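# Independent brute-force oracles used across the suite. These recompute
# everything from first principles (loops, sums, explicit formulas) and never
# call the implementation paths they check.

random_incidence <- function(n_units, n_species, seed, p = 0.5) {
  set.seed(seed)
  m <- matrix(rbinom(n_units * n_species, 1, p), n_units, n_species,
              dimnames = list(paste0("u", seq_len(n_units)),
                              paste0("s", seq_len(n_species))))
  incidence_matrix(m)
}

# matching components by explicit element-wise loop
oracle_abc <- function(x, y) {
  a <- b <- cc <- 0L
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) a <- a + 1L
    else if (x[i] == 1) b <- b + 1L
    else if (y[i] == 1) cc <- cc + 1L
  }
  c(a = a, b = b, c = cc)
}

# the six components straight from the literature formulas
oracle_six <- function(a, b, cc) {
  a <- unname(a); b <- unname(b); cc <- unname(cc)
  if (a + b + cc == 0) return(rep(NA_real_, 6))
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- if (a + min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
  jac <- (b + cc) / (a + b + cc)
  m3 <- 2 * min(b, cc) / (a + b + cc)
  c(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim,
    beta_jac = jac, beta_m3 = m3, beta_rich = abs(b - cc) / (a + b + cc))
}

# sample mean/sd recomputed with explicit sums
oracle_mean_sd <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- if (n < 2) 0 else sqrt(sum((v - m)^2) / (n - 1))
  c(mean = m, sd = s)
}

# all permutations of 1..n by recursion (independent of the package's)
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (s in oracle_perms(n - 1)) for (pos in seq_len(n))
    out[[length(out) + 1]] <- append(s, n, after = pos - 1)
  out
}

# exhaustive one-tailed Mantel P by enumerating every relabeling of d2
oracle_mantel_exact <- function(d1, d2) {
  v1 <- d1[lower.tri(d1)]
  r_obs <- cor(v1, d2[lower.tri(d2)])
  rs <- sapply(oracle_perms(nrow(d1)), function(p) {
    dp <- d2[p, p]
    cor(v1, dp[lower.tri(dp)])
  })
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# PCA scores of the rows of d via an explicit eigendecomposition of the
# covariance of the column-centered profiles
oracle_pca_scores <- function(d, n_axes = 2) {
  x <- scale(d, center = TRUE, scale = FALSE)
  ev <- eigen(cov(x), symmetric = TRUE)
  scores <- x %*% ev$vectors[, seq_len(n_axes), drop = FALSE]
  list(scores = scores,
       explained = (ev$values / sum(ev$values))[seq_len(n_axes)])
}

small_taxonomy <- function(species, n_fam = 3) {
  data.frame(species = species,
             family = paste0("F", 1 + (seq_along(species) - 1) %% n_fam),
             order = paste0("O", 1 + (seq_along(species) - 1) %% 2))
}
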