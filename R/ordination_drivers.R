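#' PCA of compositional-similarity profiles
#'
#' Ordinates units by their profile of pairwise dissimilarities: each unit's
#' row of the component matrix is treated as an observation, columns are
#' centered (no scaling), and a standard PCA is run. This places units with
#' similar dissimilarity profiles close together. A principal-coordinates
#' mode (`method = "pcoa"`, classical MDS of the dissimilarities themselves)
#' is available since profile-PCA and PCoA are both common readings of
#' "PCA on compositional similarity".
#'
#' Sign convention: each axis is oriented so its largest-magnitude loading
#' (or, for PCoA, score) is positive, making outputs deterministic across
#' platforms.
#'
#' @param d symmetric dissimilarity matrix with unit dimnames, no excluded
#'   (NA) entries.
#' @param n_axes number of axes to return (default 2).
#' @param method `"profiles"` (default) or `"pcoa"`.
#' @return object of class `beta_pca`: list with `scores` (units x axes),
#'   `explained` (variance fraction per axis), `unit_ids`, `method`.
#' @export
pca_profiles <- function(d, n_axes = 2, method = c("profiles", "pcoa")) {
  method <- match.arg(method)
  if (nrow(d) < 3L) stop("ordination needs at least 3 units")
  if (anyNA(d)) stop("dissimilarity matrix has excluded pairs; ordination needs a complete matrix")
  if (all(d == 0)) stop("all-zero dissimilarity matrix: ordination undefined")
  n_axes <- min(n_axes, nrow(d) - 1L)
  if (method == "profiles") {
    p <- stats::prcomp(d, center = TRUE, scale. = FALSE)
    keep <- seq_len(min(n_axes, ncol(p$x)))
    flip <- vapply(keep, function(j) {
      l <- p$rotation[, j]
      sign(l[which.max(abs(l))])
    }, numeric(1))
    scores <- sweep(p$x[, keep, drop = FALSE], 2, flip, "*")
    expl <- (p$sdev^2 / sum(p$sdev^2))[keep]
  } else {
    mds <- stats::cmdscale(stats::as.dist(d), k = n_axes, eig = TRUE)
    keep <- seq_len(ncol(mds$points))
    flip <- vapply(keep, function(j) {
      s <- mds$points[, j]
      sign(s[which.max(abs(s))])
    }, numeric(1))
    scores <- sweep(mds$points, 2, flip, "*")
    pos <- mds$eig[mds$eig > 0]
    expl <- (mds$eig[keep] / sum(pos))
  }
  colnames(scores) <- paste0("axis", seq_len(ncol(scores)))
  structure(list(scores = scores, explained = expl,
                 unit_ids = rownames(d), method = method),
            class = "beta_pca")
}

#' @export
print.beta_pca <- function(x, ...) {
  cat(sprintf("ordination (%s): %d units, %d axes\n",
              x$method, length(x$unit_ids), ncol(x$scores)))
  cat("explained:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = " "),
      "\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Scatter plot of the first two ordination axes
#'
#' @param x a `beta_pca` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.beta_pca <- function(x, ...) {
  s <- x$scores
  graphics::plot(s[, 1], s[, 2], type = "n",
                 xlab = sprintf("Axis 1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("Axis 2 (%.1f%%)", 100 * x$explained[2]), ...)
  graphics::text(s[, 1], s[, 2], labels = x$unit_ids)
  invisible(x)
}

#' Pairwise absolute-difference matrix of one environmental variable
#'
#' Entry (i, j) is |value_i - value_j| for the chosen variable, in that
#' variable's units. Optionally z-score the variable first
#' (`standardize = TRUE`) so differences are in SD units; the default is raw
#' absolute differences.
#'
#' @param env environmental table from [read_env()] (columns `stream` plus
#'   the seven variables).
#' @param variable one of `length`, `area`, `gradient`, `precipitation`,
#'   `temperature`, `runoff`, `altitude`.
#' @param streams optional stream ordering/subset; default = table order.
#' @param standardize z-score the variable before differencing.
#' @return symmetric zero-diagonal matrix with stream dimnames.
#' @export
env_difference <- function(env, variable, streams = NULL, standardize = FALSE) {
  variable <- match.arg(variable, ENV_VARIABLES)
  if (is.null(streams)) streams <- env$stream
  miss <- setdiff(streams, env$stream)
  if (length(miss)) stop("streams missing from table: ", paste(miss, collapse = ", "))
  v <- env[[variable]][match(streams, env$stream)]
  if (anyNA(v)) stop("missing '", variable, "' values")
  v <- as.numeric(v)
  if (standardize) v <- as.numeric(scale(v))
  d <- abs(outer(v, v, "-"))
  dimnames(d) <- list(streams, streams)
  d
}

lower_vec <- function(d) d[lower.tri(d)]

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the lower triangles. The
#' permutation null relabels the units of `d2` (rows and columns together)
#' and recomputes the correlation. With `exact = TRUE` every one of the n!
#' relabelings is enumerated and P is the proportion at least as extreme as
#' observed (the identity included); otherwise `n_perm` random relabelings
#' are drawn and P = (1 + #{as or more extreme}) / (n_perm + 1).
#'
#' Default tail is `"greater"` (one-tailed for positive association), the
#' usual convention for distance-matrix correlation; `"two-sided"` uses
#' |r*| >= |r|.
#'
#' @param d1,d2 symmetric matrices over the same units in the same order.
#' @param n_perm number of random permutations (ignored when exact).
#' @param seed RNG seed, required for random permutations so runs are
#'   reproducible.
#' @param tail `"greater"`, `"less"` or `"two-sided"`.
#' @param exact enumerate all n! relabelings (only sensible for small n).
#' @return object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `seed`, `tail`, `exact`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL,
                        tail = c("greater", "less", "two-sided"),
                        exact = FALSE) {
  tail <- match.arg(tail)
  if (!identical(dim(d1), dim(d2)))
    stop("distance matrices differ in dimension")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrices have different unit orderings")
  n <- nrow(d1)
  if (n < 3L) stop("Mantel test needs at least 3 units")
  v1 <- lower_vec(d1)
  v2 <- lower_vec(d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance distance triangle: correlation undefined")
  r_obs <- stats::cor(v1, v2)
  # precompute pair indices so a permuted triangle is a single matrix index
  pr <- which(lower.tri(d1), arr.ind = TRUE)
  ii <- pr[, 1]; jj <- pr[, 2]
  z1 <- v1 - mean(v1)
  denom1 <- sqrt(sum(z1^2))
  perm_r <- function(p) {
    w <- d2[cbind(p[ii], p[jj])]
    zw <- w - mean(w)
    sum(z1 * zw) / (denom1 * sqrt(sum(zw^2)))
  }
  extreme <- switch(tail,
    greater = function(rs) rs >= r_obs - 1e-12,
    less = function(rs) rs <= r_obs + 1e-12,
    "two-sided" = function(rs) abs(rs) >= abs(r_obs) - 1e-12
  )
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    p <- mean(extreme(rs))
    n_perm <- length(perms)
  } else {
    if (n_perm < 99) stop("n_perm must be at least 99")
    if (is.null(seed)) stop("a seed is required for random permutations")
    rs <- withr_seed(seed, {
      vapply(seq_len(n_perm), function(i) perm_r(sample.int(n)), numeric(1))
    })
    p <- (1 + sum(extreme(rs))) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, seed = seed,
                 tail = tail, exact = exact),
            class = "mantel_result")
}

# evaluate expr under a seed without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

all_permutations <- function(n) {
  if (n > 8L) stop("exact enumeration limited to n <= 8")
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.3f, P = %.4g (%s, %s %d permutations)\n",
              x$r, x$p, x$tail, if (x$exact) "all" else "random", x$n_perm))
  invisible(x)
}

#' Mantel tests of all beta components against environmental drivers
#'
#' Runs [mantel_test()] for every combination of the six pairwise beta
#' components and the requested environmental variables, the screening used
#' to ask which hydrological gradients structure turnover vs richness
#' difference.
#'
#' @param bp a `beta_pairwise` object at stream level (no excluded pairs).
#' @param env environmental table ([read_env()]) covering the streams.
#' @param variables environmental variables to test (default all seven).
#' @param n_perm,seed,tail passed to [mantel_test()].
#' @return data.frame with `component`, `variable`, `r`, `p`, `n_perm`,
#'   `seed`, `tail`.
#' @export
driver_table <- function(bp, env, variables = ENV_VARIABLES,
                         n_perm = 9999, seed = NULL,
                         tail = c("greater", "less", "two-sided")) {
  tail <- match.arg(tail)
  rows <- list()
  for (k in BETA_COMPONENTS) {
    d1 <- bp$components[[k]]
    if (anyNA(d1)) stop("excluded pairs present; driver analysis needs a complete matrix")
    for (v in variables) {
      d2 <- env_difference(env, v, streams = bp$unit_ids)
      if (stats::sd(lower_vec(d1)) == 0 || stats::sd(lower_vec(d2)) == 0) {
        # a constant component (e.g. zero nestedness everywhere) cannot be
        # correlated with anything; report NA rather than abort the screen
        warning("zero variance for ", k, " vs ", v, "; r and p set to NA")
        rows[[length(rows) + 1L]] <- data.frame(
          component = k, variable = v, r = NA_real_, p = NA_real_,
          n_perm = n_perm, seed = seed, tail = tail)
        next
      }
      mt <- mantel_test(d1, d2, n_perm = n_perm, seed = seed, tail = tail)
      rows[[length(rows) + 1L]] <- data.frame(
        component = k, variable = v, r = mt$r, p = mt$p,
        n_perm = mt$n_perm, seed = seed, tail = tail
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
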