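beta_sd <- function(v, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  n <- length(v)
  if (n < 2L) return(0)
  s <- stats::sd(v)
  if (denominator == "n") s <- s * sqrt((n - 1) / n)
  s
}

#' Summarize one unit's pairwise dissimilarities against all others
#'
#' The mean and standard deviation of a unit's row of a component matrix
#' (its distribution of pairwise values against every other unit), skipping
#' excluded (NA) pairs. This is how the per-stream rows of a stream-level
#' summary table are built.
#'
#' @param d symmetric component matrix with unit dimnames (NA marks excluded
#'   pairs), e.g. from [beta_matrix()].
#' @param unit unit label.
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return data.frame with `scope`, `mean`, `sd`, `n_pairs`.
#' @export
summarize_unit <- function(d, unit, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (!unit %in% rownames(d)) stop("unknown unit: ", unit)
  v <- d[unit, setdiff(colnames(d), unit)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all pairs involving '", unit, "' are excluded")
  data.frame(scope = unit, mean = mean(v),
             sd = beta_sd(v, sd_denominator), n_pairs = length(v))
}

#' Summarize all pairs within a set of units
#'
#' Mean and SD over every non-excluded unordered pair with both endpoints in
#' `members` (each pair counted once). Used for regional rows (e.g. eastern
#' vs western streams) and the overall "Total" row.
#'
#' @inheritParams summarize_unit
#' @param members unit labels (>= 2); defaults to all units.
#' @param scope label for the output row.
#' @return data.frame with `scope`, `mean`, `sd`, `n_pairs`.
#' @export
summarize_scope <- function(d, members = rownames(d), scope = "Total",
                            sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  bad <- setdiff(members, rownames(d))
  if (length(bad)) stop("unknown units: ", paste(bad, collapse = ", "))
  if (length(members) < 2L) stop("need at least 2 members")
  sub <- d[members, members, drop = FALSE]
  v <- sub[lower.tri(sub)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all pairs in scope '", scope, "' are excluded")
  data.frame(scope = scope, mean = mean(v),
             sd = beta_sd(v, sd_denominator), n_pairs = length(v))
}

#' Stream-level summary table of all six components
#'
#' Builds the analogue of a per-stream compositional-dissimilarity table:
#' one row per stream (that stream's pairwise values against all others),
#' optional region rows (all pairs within each region), and a Total row
#' (all pairs). Input should normally be a stream-level decomposition from
#' [pairwise_beta()] on an aggregated matrix.
#'
#' @param bp a `beta_pairwise` object at stream level.
#' @param regions optional named list of region label -> character vector of
#'   member streams (regions with < 2 members present are skipped).
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return data.frame with `scope`, `component`, `mean`, `sd`, `n_pairs`.
#' @export
stream_table <- function(bp, regions = NULL,
                         sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  rows <- list()
  for (k in BETA_COMPONENTS) {
    d <- bp$components[[k]]
    for (u in bp$unit_ids)
      rows[[length(rows) + 1L]] <-
        cbind(summarize_unit(d, u, sd_denominator), component = k)
    for (rg in names(regions)) {
      mem <- intersect(regions[[rg]], bp$unit_ids)
      if (length(mem) >= 2L)
        rows[[length(rows) + 1L]] <-
          cbind(summarize_scope(d, mem, rg, sd_denominator), component = k)
    }
    rows[[length(rows) + 1L]] <-
      cbind(summarize_scope(d, bp$unit_ids, "Total", sd_denominator),
            component = k)
  }
  out <- do.call(rbind, rows)
  out[c("scope", "component", "mean", "sd", "n_pairs")]
}

#' Per-family summary table of all six components
#'
#' For each family: restrict the incidence matrix to the family's species
#' (keeping empty units), recompute the pairwise decomposition, and
#' summarize over all non-excluded pairs; an "All species" row uses the full
#' matrix. Families with no species in the matrix are skipped with a
#' warning. Exclusion counts (pairs of units that both lack the family) are
#' reported per family.
#'
#' @param m an `incidence_matrix` (any grain; finer grains give more pairs).
#' @param taxonomy data.frame with `species`, `family` covering all species
#'   of `m`.
#' @param double_empty passed to [pairwise_beta()].
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return data.frame with `scope` (family or "All species"), `component`,
#'   `mean`, `sd`, `n_pairs`, `n_excluded`.
#' @export
family_table <- function(m, taxonomy, double_empty = c("exclude", "zero"),
                         sd_denominator = c("n-1", "n")) {
  double_empty <- match.arg(double_empty)
  sd_denominator <- match.arg(sd_denominator)
  uncovered <- setdiff(colnames(m), taxonomy$species)
  if (length(uncovered))
    stop("species missing from taxonomy: ", paste(uncovered, collapse = ", "))
  fams <- unique(taxonomy$family[taxonomy$species %in% colnames(m)])
  rows <- list()
  summarize_bp <- function(bp, label) {
    do.call(rbind, lapply(BETA_COMPONENTS, function(k) {
      cbind(summarize_scope(bp$components[[k]], bp$unit_ids, label,
                            sd_denominator),
            component = k, n_excluded = bp$n_excluded)
    }))
  }
  for (f in fams) {
    sub <- tryCatch(subset_by_family(m, taxonomy, f, empty_units = "keep"),
                    error = function(e) NULL)
    if (is.null(sub)) {
      warning("family '", f, "' has no species in the matrix; skipped")
      next
    }
    bp <- pairwise_beta(sub, double_empty = double_empty)
    if (bp$n_excluded == choose(nrow(sub), 2)) {
      warning("family '", f, "': every pair excluded; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- summarize_bp(bp, f)
  }
  bp_all <- pairwise_beta(m, double_empty = double_empty)
  rows[[length(rows) + 1L]] <- summarize_bp(bp_all, "All species")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[c("scope", "component", "mean", "sd", "n_pairs", "n_excluded")]
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (2.5 -> 3), matching how printed
#' report tables are usually rounded, unlike R's default round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a long-format summary as a wide mean +/- SD text table
#'
#' @param tab output of [stream_table()] or [family_table()].
#' @param digits decimal places (half-up), default 2 matching report
#'   precision; machine-readable output keeps full precision.
#' @return character matrix (scopes x components) of "mean±sd" strings.
#' @export
format_beta_table <- function(tab, digits = 2) {
  scopes <- unique(tab$scope)
  out <- matrix("", length(scopes), length(BETA_COMPONENTS),
                dimnames = list(scopes, BETA_COMPONENTS))
  for (i in seq_len(nrow(tab)))
    out[tab$scope[i], tab$component[i]] <-
      sprintf("%.*f±%.*f", digits, round_half_up(tab$mean[i], digits),
              digits, round_half_up(tab$sd[i], digits))
  out
}
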