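#' Configuration for the synthetic community generator
#'
#' Bundles every knob of the generator with validation. Defaults mirror the
#' scale of a mountain-range stream survey: 11 streams, 42 sampling sites,
#' 113 species in 17 families, so report layouts are exercised realistically.
#'
#' @param n_species number of species in the pool.
#' @param n_sites number of sampling sites along the gradient.
#' @param n_streams number of streams the sites group into
#'   (`n_streams <= n_sites`).
#' @param n_families number of families in the synthetic taxonomy (always
#'   includes one singleton family).
#' @param scenario `"nested"`, `"replacement"` or `"mixed"`.
#' @param phi fraction of replacement structure in the mixed scenario, in
#'   \[0, 1\]: 0 reduces to a pure nested gradient, 1 to pure replacement.
#' @param richness_max,richness_min per-site richness at the richest and
#'   poorest end of the nested gradient.
#' @param k window richness (species per site) for the replacement scenario.
#' @param step window shift between adjacent sites for replacement; `NULL`
#'   auto-selects the largest feasible shift.
#' @param flip_prob occupancy noise: probability of flipping each cell after
#'   construction. Default 0 so the structural purities (zero turnover under
#'   nesting, zero nestedness under equal-richness replacement) are exact.
#' @param env_noise_sd noise of the gradient-linked environmental covariate,
#'   as a fraction of the covariate's gradient range.
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 113, n_sites = 42, n_streams = 11,
                             n_families = 17,
                             scenario = c("mixed", "nested", "replacement"),
                             phi = 0.5, richness_max = NULL,
                             richness_min = NULL, k = NULL, step = NULL,
                             flip_prob = 0, env_noise_sd = 0.1, seed = 1) {
  scenario <- match.arg(scenario)
  if (n_streams > n_sites) stop("n_streams must not exceed n_sites")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  # default gradient spans about a quarter of the pool down to a twentieth
  if (is.null(richness_max)) richness_max <- max(2L, round(n_species / 4))
  if (is.null(richness_min))
    richness_min <- max(1L, min(richness_max, round(n_species / 20)))
  if (richness_max > n_species || richness_min > n_species)
    stop("richness bounds must not exceed n_species")
  if (richness_min > richness_max) stop("richness_min > richness_max")
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must lie in [0, 1]")
  if (env_noise_sd < 0) stop("env_noise_sd must be non-negative")
  structure(as.list(environment()), class = "synthetic_config")
}

site_gradient <- function(n_sites) {
  if (n_sites == 1L) return(0)
  (seq_len(n_sites) - 1) / (n_sites - 1)
}

label_matrix <- function(x, n_sites, n_species) {
  dimnames(x) <- list(sprintf("site%02d", seq_len(n_sites)),
                      sprintf("sp%03d", seq_len(n_species)))
  x
}

#' Generate a perfectly nested richness gradient
#'
#' Sites are ordered along a gradient; richness interpolates linearly from
#' `richness_max` down to `richness_min`, and every site's species set is a
#' prefix of the pool, so the poorer community is always a subset of the
#' richer one. All pairwise turnover is therefore exactly zero.
#'
#' @param cfg a [synthetic_config()] with `scenario = "nested"`.
#' @return list with `incidence` (an `incidence_matrix`) and `gradient`
#'   (per-site positions in \[0, 1\]).
#' @export
generate_nested <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$scenario != "nested") stop("config scenario is not 'nested'")
  g <- site_gradient(cfg$n_sites)
  rich <- round(cfg$richness_max - (cfg$richness_max - cfg$richness_min) * g)
  if (sum(rich == 0) >= 2L && cfg$n_sites >= 2L)
    stop("richness_min of 0 creates multiple empty sites (double-empty pairs by construction)")
  m <- matrix(0L, cfg$n_sites, cfg$n_species)
  for (i in seq_len(cfg$n_sites))
    if (rich[i] > 0) m[i, seq_len(rich[i])] <- 1L
  m <- apply_flip_noise(m, cfg)
  list(incidence = incidence_matrix(label_matrix(m, cfg$n_sites, cfg$n_species)),
       gradient = g)
}

#' Generate equal-richness species replacement along a gradient
#'
#' Every site holds exactly `k` species; site i occupies a sliding window of
#' the species axis shifted by `step` species per site (no wrap-around).
#' Because richness is constant, the two unique-species counts of every pair
#' are equal, forcing the nestedness and richness-difference components to
#' exactly zero: beta diversity is pure replacement.
#'
#' @param cfg a [synthetic_config()] with `scenario = "replacement"`.
#' @return list with `incidence`, `gradient` and the `step` used.
#' @export
generate_replacement <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$scenario != "replacement") stop("config scenario is not 'replacement'")
  k <- cfg$k %||% max(2L, round(cfg$n_species / 4))
  step <- cfg$step
  if (is.null(step))
    step <- if (cfg$n_sites == 1L) 0L else
      max(0L, (cfg$n_species - k) %/% (cfg$n_sites - 1L))
  if (k > cfg$n_species) stop("window richness k exceeds n_species")
  if (step * (cfg$n_sites - 1L) + k > cfg$n_species)
    stop("windows overrun the species axis: step*(n_sites-1) + k > n_species")
  m <- matrix(0L, cfg$n_sites, cfg$n_species)
  for (i in seq_len(cfg$n_sites))
    m[i, (i - 1L) * step + seq_len(k)] <- 1L
  m <- apply_flip_noise(m, cfg)
  list(incidence = incidence_matrix(label_matrix(m, cfg$n_sites, cfg$n_species)),
       gradient = site_gradient(cfg$n_sites), step = step)
}

apply_flip_noise <- function(m, cfg) {
  if (cfg$flip_prob <= 0) return(m)
  withr_seed(cfg$seed, {
    flips <- matrix(stats::runif(length(m)) < cfg$flip_prob,
                    nrow(m), ncol(m))
    m[flips] <- 1L - m[flips]
  })
  m
}

split_sizes <- function(total, groups) {
  base <- total %/% groups
  extra <- total %% groups
  rep(base, groups) + c(rep(1L, extra), rep(0L, groups - extra))
}

#' Generate a complete synthetic study bundle
#'
#' Builds every input the analysis pipeline consumes: a site-level incidence
#' matrix mixing nested and replacement structure, a taxonomy with varied
#' family sizes (including a singleton family), a threat table with an
#' LC-dominated category distribution, a site-to-stream grouping with two
#' regions, and an environmental table whose `altitude` column tracks the
#' compositional gradient (plus noise) while the other six variables are
#' pure noise.
#'
#' The species pool is split into a replacement block (fraction `phi`) that
#' turns over along the gradient with constant richness, and a nested block
#' (fraction `1 - phi`) whose occupancy thins out along the gradient as
#' perfect subsets. `phi = 0` gives a pure nested gradient (all turnover
#' components exactly 0), `phi = 1` pure replacement (all richness-difference
#' components exactly 0); in between, the replacement share of total beta
#' diversity grows with `phi`.
#'
#' @param cfg a [synthetic_config()] with `scenario = "mixed"`.
#' @return list of class `synthetic_bundle` with elements `incidence`,
#'   `taxonomy`, `threat`, `grouping`, `env`, `gradient`, `regions`, `config`.
#' @export
generate_mixed <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$scenario != "mixed") stop("config scenario is not 'mixed'")
  n_rep <- round(cfg$phi * cfg$n_species)
  n_nest <- cfg$n_species - n_rep
  g <- site_gradient(cfg$n_sites)
  m <- matrix(0L, cfg$n_sites, cfg$n_species)
  # replacement block: sliding window, constant richness
  if (n_rep > 0) {
    k_rep <- max(1L, round(0.4 * n_rep))
    for (i in seq_len(cfg$n_sites)) {
      start <- round(g[i] * (n_rep - k_rep))
      m[i, start + seq_len(k_rep)] <- 1L
    }
  }
  # nested block: prefix subsets thinning along the gradient
  if (n_nest > 0) {
    # richest site holds the whole block: every species occurs somewhere,
    # as in a real checklist
    f_max <- 1; f_min <- 0.2
    rich <- round(n_nest * (f_max - (f_max - f_min) * g))
    for (i in seq_len(cfg$n_sites))
      if (rich[i] > 0) m[i, n_rep + seq_len(rich[i])] <- 1L
  }
  m <- apply_flip_noise(m, cfg)
  inc <- incidence_matrix(label_matrix(m, cfg$n_sites, cfg$n_species))

  withr_seed(cfg$seed + 1L, {
    # taxonomy: one singleton family, the rest a varied random partition
    sizes <- rep(1L, cfg$n_families)
    if (cfg$n_species > cfg$n_families) {
      extra <- stats::rmultinom(
        1, cfg$n_species - cfg$n_families,
        prob = c(0, stats::runif(cfg$n_families - 1L, 0.3, 1.7))
      )[, 1]
      sizes <- sizes + extra
    }
    fams <- sprintf("Family%02d", seq_len(cfg$n_families))
    n_orders <- max(1L, min(6L, cfg$n_families))
    fam_order <- sprintf("Order%d", 1 + (seq_len(cfg$n_families) - 1L) %% n_orders)
    taxonomy <- data.frame(
      species = colnames(inc),
      family = rep(fams, times = sizes),
      order = rep(fam_order, times = sizes)
    )
    # threat: LC-dominated, a few threatened, some DD/NE
    threat <- data.frame(
      species = colnames(inc),
      category = sample(THREAT_CATEGORIES, cfg$n_species, replace = TRUE,
                        prob = c(0.01, 0.01, 0.03, 0.03, 0.78, 0.07, 0.07))
    )
    # grouping: contiguous blocks of sites per stream, two regions
    ssz <- split_sizes(cfg$n_sites, cfg$n_streams)
    streams <- sprintf("ST%02d", seq_len(cfg$n_streams))
    grouping <- data.frame(
      site = rownames(inc),
      stream = rep(streams, times = ssz)
    )
    half <- ceiling(cfg$n_streams / 2)
    region_of <- stats::setNames(
      c(rep("ES", half), rep("WS", cfg$n_streams - half)), streams
    )
    grouping$region <- region_of[grouping$stream]
    # environment: altitude tracks the gradient, the rest pure noise
    gs <- tapply(g[match(grouping$site, rownames(inc))], grouping$stream, mean)
    gs <- gs[streams]
    alt_range <- 1500
    altitude <- pmax(1, 200 + alt_range * as.numeric(gs) +
                       stats::rnorm(cfg$n_streams, 0, cfg$env_noise_sd * alt_range))
    env <- data.frame(
      stream = streams,
      length = stats::runif(cfg$n_streams, 150, 420),
      area = stats::runif(cfg$n_streams, 1300, 15000),
      gradient = stats::runif(cfg$n_streams, 0.2, 2.5),
      precipitation = stats::runif(cfg$n_streams, 1250, 1950),
      temperature = stats::runif(cfg$n_streams, 16, 19),
      runoff = stats::runif(cfg$n_streams, 10, 140),
      altitude = altitude
    )
  })
  regions <- split(names(region_of), region_of)
  structure(list(incidence = inc, taxonomy = taxonomy, threat = threat,
                 grouping = grouping, env = env, gradient = g,
                 regions = regions, config = cfg),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle as a ready-to-run study directory
#'
#' Emits exactly the file formats the readers in this package consume:
#' `incidence.csv`, `taxonomy.csv`, `threat.csv`, `grouping.csv`, `env.csv`.
#'
#' @param bundle a `synthetic_bundle` from [generate_mixed()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_incidence(bundle$incidence, file.path(dir, "incidence.csv"))
  utils::write.csv(bundle$taxonomy, file.path(dir, "taxonomy.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$threat, file.path(dir, "threat.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$grouping, file.path(dir, "grouping.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$env, file.path(dir, "env.csv"), row.names = FALSE)
  invisible(dir)
}
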