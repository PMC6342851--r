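#' Composition statistics of a species checklist
#'
#' Counts and percentages of a checklist by taxonomic order, by family and
#' by IUCN-style threat category, plus a grouped "threatened" bucket
#' (CR + EN + VU + NT). Percentages are 100*count/total rounded half-up to
#' one decimal, the precision printed in faunal reports.
#'
#' Species absent from the threat table default to NE (Not Evaluated) with a
#' warning rather than an error, since threat coverage of regional
#' checklists is often partial.
#'
#' @param species character vector of species labels.
#' @param taxonomy data.frame with `species`, `family` and `order` columns
#'   covering every species.
#' @param threat optional data.frame with `species`, `category` columns.
#' @return object of class `composition_report`: list with data.frames
#'   `by_order`, `by_family`, `by_threat` (NE included), scalar
#'   `threatened` (count + percent) and `totals` (species, families).
#' @examples
#' tax <- data.frame(species = c("a", "b", "c"),
#'                   family = c("F1", "F1", "F2"),
#'                   order = c("O1", "O1", "O2"))
#' th <- data.frame(species = c("a", "b", "c"),
#'                  category = c("LC", "VU", "LC"))
#' composition_report(c("a", "b", "c"), tax, th)
#' @export
composition_report <- function(species, taxonomy, threat = NULL) {
  species <- unique(species)
  n <- length(species)
  if (n == 0L) stop("empty species list")
  idx <- match(species, taxonomy$species)
  if (anyNA(idx))
    stop("species with no taxonomy entry: ",
         paste(species[is.na(idx)], collapse = ", "))
  if (!"order" %in% names(taxonomy))
    stop("taxonomy table needs an 'order' column for composition reports")
  fam <- taxonomy$family[idx]
  ord <- taxonomy$order[idx]
  pct <- function(k) round_half_up(100 * k / n, 1)
  tab_df <- function(x, name) {
    t <- table(x)
    t <- t[order(-as.vector(t), names(t))]
    d <- data.frame(names(t), count = as.vector(t), percent = pct(as.vector(t)))
    names(d)[1] <- name
    rownames(d) <- NULL
    d
  }
  if (is.null(threat)) threat <- data.frame(species = character(0),
                                            category = character(0))
  cat_idx <- match(species, threat$species)
  if (anyNA(cat_idx))
    warning(sum(is.na(cat_idx)),
            " species missing from the threat table; defaulting to NE")
  cats <- ifelse(is.na(cat_idx), "NE", threat$category[cat_idx])
  bad <- setdiff(unique(cats), THREAT_CATEGORIES)
  if (length(bad)) stop("unknown threat categories: ", paste(bad, collapse = ", "))
  thr_n <- sum(cats %in% c("CR", "EN", "VU", "NT"))
  structure(list(
    by_order = tab_df(ord, "order"),
    by_family = tab_df(fam, "family"),
    by_threat = tab_df(cats, "category"),
    threatened = data.frame(count = thr_n, percent = pct(thr_n)),
    totals = data.frame(species = n, families = length(unique(fam)),
                        orders = length(unique(ord)))
  ), class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("checklist: %d species, %d families, %d orders\n",
              x$totals$species, x$totals$families, x$totals$orders))
  cat("by order:\n"); print(x$by_order)
  cat("by threat category:\n"); print(x$by_threat)
  cat(sprintf("threatened (CR+EN+VU+NT): %d (%.1f%%)\n",
              x$threatened$count, x$threatened$percent))
  invisible(x)
}

#' Write a composition report as CSV files and a markdown summary
#'
#' @param report a `composition_report`.
#' @param prefix output path prefix; writes `<prefix>_by_order.csv`,
#'   `<prefix>_by_family.csv`, `<prefix>_by_threat.csv`,
#'   `<prefix>_summary.md`.
#' @return invisibly, the files written.
#' @export
write_composition_report <- function(report, prefix) {
  files <- c(by_order = paste0(prefix, "_by_order.csv"),
             by_family = paste0(prefix, "_by_family.csv"),
             by_threat = paste0(prefix, "_by_threat.csv"))
  for (k in names(files))
    utils::write.csv(report[[k]], files[[k]], row.names = FALSE)
  md <- paste0(prefix, "_summary.md")
  lines <- c(
    sprintf("# Checklist composition"),
    sprintf("- %d species in %d families (%d orders)",
            report$totals$species, report$totals$families,
            report$totals$orders),
    sprintf("- threatened (CR+EN+VU+NT): %d species (%.1f%%)",
            report$threatened$count, report$threatened$percent),
    "", "| order | count | percent |", "|---|---|---|",
    sprintf("| %s | %d | %.1f |", report$by_order$order,
            report$by_order$count, report$by_order$percent)
  )
  writeLines(lines, md)
  invisible(c(files, summary = md))
}

#' Bar chart of checklist composition by order
#'
#' @param report a `composition_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_composition <- function(report, ...) {
  graphics::barplot(report$by_order$count,
                    names.arg = report$by_order$order, las = 2,
                    ylab = "species", ...)
  invisible(report)
}
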