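#' Matching components of a pair of presence/absence vectors
#'
#' Computes the classical matching components consumed by every pairwise
#' dissimilarity index: `a` = species present in both units, `b` = present
#' only in the first, `c` = present only in the second. All pair arithmetic
#' downstream stays in exact integers; division happens only in the final
#' index formulas.
#'
#' @param x,y binary vectors over the same ordered species set.
#' @return named integer vector `c(a =, b =, c =)`.
#' @examples
#' matching_components(c(1, 1, 0, 1), c(1, 0, 1, 1))  # a=2 b=1 c=1
#' @export
matching_components <- function(x, y) {
  if (length(x) != length(y))
    stop("presence vectors differ in length (", length(x), " vs ", length(y), ")")
  x <- as.integer(x); y <- as.integer(y)
  if (!all(x %in% 0:1) || !all(y %in% 0:1))
    stop("presence vectors must be binary")
  c(a = sum(x == 1L & y == 1L),
    b = sum(x == 1L & y == 0L),
    c = sum(x == 0L & y == 1L))
}

#' Sorensen-based (BAS) partition of pairwise beta diversity
#'
#' Decomposes total Sorensen dissimilarity into a spatial-turnover and a
#' nestedness-resultant component:
#' \deqn{\beta_{sor} = (b+c)/(2a+b+c)}
#' \deqn{\beta_{sim} = \min(b,c)/(a+\min(b,c))}
#' \deqn{\beta_{sne} = \beta_{sor} - \beta_{sim}}
#'
#' Degenerate pairs follow two documented conventions. If one unit is empty
#' (`a = 0`, `min(b,c) = 0`, `b+c > 0`) the turnover ratio is 0/0; it is set
#' to 0 (turnover requires replacement, and a fully empty unit is a pure
#' richness difference), so `beta_sor = beta_sne = 1`. If both units are
#' empty (`a=b=c=0`) all three components are undefined and returned as `NA`;
#' such pairs are excluded from summaries, never silently zeroed.
#'
#' All arguments are vectorized.
#'
#' @param a,b,c matching components, or a vector `c(a,b,c)` as first argument.
#' @return data.frame with columns `beta_sor`, `beta_sim`, `beta_sne`.
#' @examples
#' bas_partition(2, 1, 3)        # 0.5, 1/3, 1/6
#' bas_partition(3, 2, 0)        # nested pair: turnover exactly 0
#' @export
bas_partition <- function(a, b = NULL, c = NULL) {
  if (is.null(b)) { b <- a[[2]]; c <- a[[3]]; a <- a[[1]] }
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0))
  n <- max(length(a), length(b), length(c))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  tot <- a + b + c
  minbc <- pmin(b, c)
  beta_sor <- ifelse(tot == 0, NA_real_, (b + c) / (2 * a + b + c))
  beta_sim <- ifelse(tot == 0, NA_real_,
                     ifelse(a + minbc == 0, 0, minbc / (a + minbc)))
  data.frame(beta_sor = beta_sor, beta_sim = beta_sim,
             beta_sne = beta_sor - beta_sim)
}

#' Jaccard-based (POD) partition of pairwise beta diversity
#'
#' Decomposes total Jaccard dissimilarity into a species-replacement and a
#' richness-difference component:
#' \deqn{\beta_{jac} = (b+c)/(a+b+c)}
#' \deqn{\beta_{-3} = 2\min(b,c)/(a+b+c)}
#' \deqn{\beta_{rich} = |b-c|/(a+b+c)}
#'
#' The double-empty convention matches [bas_partition()]: `a=b=c=0` yields
#' `NA` for all three components and the pair is excluded downstream.
#'
#' @inheritParams bas_partition
#' @return data.frame with columns `beta_jac`, `beta_m3`, `beta_rich`.
#' @examples
#' pod_partition(2, 1, 3)  # 2/3, 1/3, 1/3
#' @export
pod_partition <- function(a, b = NULL, c = NULL) {
  if (is.null(b)) { b <- a[[2]]; c <- a[[3]]; a <- a[[1]] }
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0))
  n <- max(length(a), length(b), length(c))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  tot <- a + b + c
  data.frame(
    beta_jac  = ifelse(tot == 0, NA_real_, (b + c) / tot),
    beta_m3   = ifelse(tot == 0, NA_real_, 2 * pmin(b, c) / tot),
    beta_rich = ifelse(tot == 0, NA_real_, abs(b - c) / tot)
  )
}

#' Names of the six pairwise beta components
#' @export
BETA_COMPONENTS <- c("beta_sor", "beta_sim", "beta_sne",
                     "beta_jac", "beta_m3", "beta_rich")

#' All pairwise beta components of an incidence matrix
#'
#' Computes, for every unordered pair of units, the three BAS and three POD
#' components, returned as six symmetric zero-diagonal distance matrices.
#' Pairs where both units are empty (possible after subsetting to a family
#' neither unit hosts) are recorded in an exclusion mask; by default their
#' entries are `NA` and summary functions skip them. `double_empty = "zero"`
#' instead treats such pairs as dissimilarity 0 (identical empty
#' communities), a sensitivity alternative.
#'
#' @param m an `incidence_matrix` with at least two units.
#' @param double_empty `"exclude"` (default) or `"zero"`.
#' @return object of class `beta_pairwise`: a list with `components` (named
#'   list of six symmetric matrices), `excluded` (logical matrix marking
#'   double-empty pairs), `unit_ids`, `n_excluded`.
#' @export
pairwise_beta <- function(m, double_empty = c("exclude", "zero")) {
  double_empty <- match.arg(double_empty)
  if (!all(unclass(m) %in% 0:1)) stop("matrix must be binary")
  if (nrow(m) < 2L) stop("pairwise analysis needs at least 2 units")
  x <- unclass(m)
  storage.mode(x) <- "double"
  n <- nrow(x)
  # integer matching components for all pairs at once
  A <- tcrossprod(x)                  # shared species
  rich <- rowSums(x)
  B <- matrix(rich, n, n) - A         # unique to row unit
  C <- t(B)                           # unique to column unit
  pr <- lower.tri(A)
  bas <- bas_partition(A[pr], B[pr], C[pr])
  pod <- pod_partition(A[pr], B[pr], C[pr])
  vals <- cbind(bas, pod)
  comps <- lapply(BETA_COMPONENTS, function(k) {
    d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
    d[pr] <- vals[[k]]
    d[upper.tri(d)] <- t(d)[upper.tri(d)]
    d
  })
  names(comps) <- BETA_COMPONENTS
  excluded <- matrix(FALSE, n, n, dimnames = list(rownames(x), rownames(x)))
  excluded[pr] <- (A + B + C)[pr] == 0
  excluded[upper.tri(excluded)] <- t(excluded)[upper.tri(excluded)]
  if (double_empty == "zero")
    comps <- lapply(comps, function(d) { d[excluded] <- 0; d })
  structure(
    list(components = comps, excluded = excluded,
         unit_ids = rownames(x), n_excluded = sum(excluded[pr]),
         double_empty = double_empty),
    class = "beta_pairwise"
  )
}

#' @export
print.beta_pairwise <- function(x, ...) {
  cat(sprintf(
    "pairwise beta decomposition: %d units, %d pairs (%d excluded)\n",
    length(x$unit_ids), choose(length(x$unit_ids), 2), x$n_excluded
  ))
  tri <- lower.tri(x$components[[1]]) & !x$excluded
  for (k in BETA_COMPONENTS)
    cat(sprintf("  %-9s mean %.4f\n", k, mean(x$components[[k]][tri])))
  invisible(x)
}

#' Extract one component matrix from a pairwise decomposition
#'
#' @param bp a `beta_pairwise` object.
#' @param component one of `beta_sor`, `beta_sim`, `beta_sne`, `beta_jac`,
#'   `beta_m3`, `beta_rich`.
#' @return symmetric numeric matrix (NA where pairs are excluded).
#' @export
beta_matrix <- function(bp, component) {
  component <- match.arg(component, BETA_COMPONENTS)
  bp$components[[component]]
}

#' Write pairwise components as square and long-format CSV
#'
#' Writes one square CSV per component (`<prefix>_<component>.csv`), a
#' long-format table `<prefix>_long.csv` with columns
#' `unit_i,unit_j,component,value`, and the exclusion mask
#' `<prefix>_excluded.csv`.
#'
#' @param bp a `beta_pairwise` object.
#' @param prefix path prefix for output files.
#' @return invisibly, the vector of files written.
#' @export
write_beta_pairwise <- function(bp, prefix) {
  files <- character(0)
  for (k in BETA_COMPONENTS) {
    f <- paste0(prefix, "_", k, ".csv")
    utils::write.csv(data.frame(unit = bp$unit_ids, bp$components[[k]],
                                check.names = FALSE), f, row.names = FALSE)
    files <- c(files, f)
  }
  pr <- which(lower.tri(bp$excluded), arr.ind = TRUE)
  long <- do.call(rbind, lapply(BETA_COMPONENTS, function(k) {
    data.frame(unit_i = bp$unit_ids[pr[, 1]], unit_j = bp$unit_ids[pr[, 2]],
               component = k, value = bp$components[[k]][pr])
  }))
  f <- paste0(prefix, "_long.csv")
  utils::write.csv(long, f, row.names = FALSE)
  files <- c(files, f)
  f <- paste0(prefix, "_excluded.csv")
  utils::write.csv(data.frame(unit = bp$unit_ids, bp$excluded,
                              check.names = FALSE), f, row.names = FALSE)
  invisible(c(files, f))
}
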