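## Divergence landscapes, coverage tables, and the genome-size ~ TE-content
## relationship.

#' Jukes-Cantor correction of percent divergence
#'
#' Converts the raw substitution proportion `D` (percent of sites differing
#' between a repeat fragment and its consensus) into the estimated number of
#' substitutions per site `K` (also in percent) under the one-parameter
#' Jukes-Cantor model:
#' \deqn{K = -\frac{300}{4}\,\ln\!\left(1 - \frac{4D}{300}\right)}
#' i.e. `K = -75 * log(1 - D/75)`.  The correction accounts for multiple
#' substitutions at a site, so `K >= D` with equality only at 0.
#'
#' @param D Numeric vector of percent divergences, `0 <= D < 75`.
#' @return `K`, percent substitutions per site.
#' @examples
#' jc_correct(c(0, 10, 20))
#' @export
jc_correct <- function(D) {
  if (any(D < 0)) stop("divergence D must be non-negative")
  if (any(D >= 75))
    stop("D >= 75 is outside the Jukes-Cantor domain (log of non-positive)")
  -75 * log(1 - D / 75)
}

#' Divergence landscape
#'
#' Bins each hit's masked base pairs by its (by default Jukes-Cantor
#' corrected) divergence, per classification group: the per-bin genome
#' fraction read as a proxy for TE activity through time.  Bins are
#' half-open `[k, k + bin_width)`.  Hits with `D >= 75` cannot be corrected
#' and are diverted to a spill bucket with a warning.
#'
#' @param hits Hit data.frame with `divergence_D`, `start`, `end` and the
#'   grouping column.
#' @param genome_length Denominator for genome fractions, bp.
#' @param bin_width Bin width on the divergence axis, percent.
#' @param group_by Name of the grouping column (e.g. `"te_class"`,
#'   `"superfamily"`, `"library_name"`).
#' @param corrected Bin by corrected `K` (default) or by raw `D`.
#' @return Data.frame with columns `group`, `k_low`, `k_high`, `bp`,
#'   `genome_fraction`, plus an attribute `spill_bp` (bp excluded as
#'   uncorrectable).
#' @export
landscape <- function(hits, genome_length, bin_width = 1.0,
                      group_by = "te_class", corrected = TRUE) {
  stopifnot(bin_width > 0, genome_length > 0)
  if (nrow(hits) == 0L) {
    out <- data.frame(group = character(), k_low = numeric(),
                      k_high = numeric(), bp = numeric(),
                      genome_fraction = numeric(), stringsAsFactors = FALSE)
    attr(out, "spill_bp") <- 0
    return(out)
  }
  if (!group_by %in% names(hits)) stop("no column '", group_by, "' in hits")
  spill <- hits$divergence_D >= 75
  if (any(spill))
    warning(sum(spill), " hit(s) with D >= 75 diverted to the spill bucket")
  spill_bp <- sum(hits$end[spill] - hits$start[spill] + 1)
  hits <- hits[!spill, , drop = FALSE]
  k <- if (corrected) jc_correct(hits$divergence_D) else hits$divergence_D
  bin <- floor(k / bin_width)
  bp <- hits$end - hits$start + 1
  grp <- as.character(hits[[group_by]])
  grp[is.na(grp)] <- "Unclassified"
  agg <- stats::aggregate(bp, by = list(group = grp, bin = bin), FUN = sum)
  out <- data.frame(group = agg$group, k_low = agg$bin * bin_width,
                    k_high = (agg$bin + 1) * bin_width, bp = agg$x,
                    genome_fraction = agg$x / genome_length,
                    stringsAsFactors = FALSE)
  out <- out[order(out$group, out$k_low), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spill_bp") <- spill_bp
  out
}

#' Roll child coverage rows up into a parent total
#'
#' Aggregates component coverage rows (e.g. the families of one superfamily)
#' into their parent row: counts and base pairs are summed, the percent
#' recomputed from the summed base pairs.
#'
#' @param children Data.frame with columns `count`, `bp`.
#' @param genome_length Genome length, bp (`NA` allowed: `pct` is `NA`).
#' @param label Parent row label.
#' @return One-row data.frame with columns `group`, `count`, `bp`, `pct`.
#' @export
coverage_rollup <- function(children, genome_length = NA, label = "total") {
  data.frame(group = label, count = sum(children$count),
             bp = sum(children$bp),
             pct = if (is.na(genome_length)) NA_real_ else
               100 * sum(children$bp) / genome_length,
             stringsAsFactors = FALSE)
}

#' Hierarchical coverage table
#'
#' Per-group hit counts, union-collapsed masked base pairs, and percent of
#' genome, at each requested hierarchy level; parent rows are
#' [coverage_rollup()]s of their children (counts and bp add exactly), with
#' `NA` group values reported as `Unclassified`.
#'
#' @param hits Hit data.frame.
#' @param genome_length Genome length, bp.
#' @param hierarchy Character vector of grouping columns, coarse to fine,
#'   e.g. `c("te_class", "superfamily")`.
#' @return Data.frame with columns `level`, `parent`, `group`, `count`,
#'   `bp`, `pct`; level 0 is the grand total over all hits.
#' @export
coverage_table <- function(hits, genome_length,
                           hierarchy = c("te_class", "superfamily")) {
  if (!all(hierarchy %in% c(names(hits), character(0))) && nrow(hits) > 0L)
    stop("unknown hierarchy level: ",
         paste(setdiff(hierarchy, names(hits)), collapse = ", "))
  if (nrow(hits) == 0L)
    return(data.frame(level = integer(), parent = character(),
                      group = character(), count = integer(), bp = numeric(),
                      pct = numeric(), stringsAsFactors = FALSE))
  rows <- list()
  grp_bp <- function(sub) masked_bp(sub, genome_length)$bp
  finest <- hierarchy[length(hierarchy)]
  key <- function(sub, lvl) {
    v <- as.character(sub[[lvl]]); v[is.na(v)] <- "Unclassified"; v
  }
  ## finest level: counts are hit counts, bp union-collapsed per group
  labels <- lapply(hierarchy, function(h) key(hits, h))
  names(labels) <- hierarchy
  fine_split <- split(seq_len(nrow(hits)),
                      do.call(paste, c(labels, list(sep = "\r"))))
  fine <- lapply(fine_split, function(idx) {
    sub <- hits[idx, , drop = FALSE]
    lv <- vapply(hierarchy, function(h) key(sub, h)[1L], "")
    data.frame(level = length(hierarchy),
               parent = if (length(hierarchy) > 1L)
                 lv[length(hierarchy) - 1L] else "all",
               group = lv[length(hierarchy)], count = length(idx),
               bp = grp_bp(sub), pct = 100 * grp_bp(sub) / genome_length,
               path = paste(lv, collapse = "\r"), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, fine)
  rows[[length(hierarchy) + 1L]] <- tab[, 1:6]
  ## coarser levels roll up the level below them
  below <- tab
  for (li in rev(seq_len(length(hierarchy) - 1L))) {
    split_key <- vapply(strsplit(below$path, "\r"), function(p)
      paste(p[seq_len(li)], collapse = "\r"), "")
    up <- lapply(split(seq_len(nrow(below)), split_key), function(idx) {
      r <- coverage_rollup(below[idx, , drop = FALSE], genome_length)
      p <- strsplit(below$path[idx[1L]], "\r")[[1L]]
      r$group <- p[li]
      r$level <- li
      r$parent <- if (li > 1L) p[li - 1L] else "all"
      r$path <- paste(p[seq_len(li)], collapse = "\r")
      r[, c("level", "parent", "group", "count", "bp", "pct", "path")]
    })
    below <- do.call(rbind, up)
    rows[[li + 1L]] <- below[, 1:6]
  }
  total <- coverage_rollup(rows[[2L]], genome_length, label = "Total")
  total$level <- 0L; total$parent <- NA_character_
  rows[[1L]] <- total[, c("level", "parent", "group", "count", "bp", "pct")]
  out <- do.call(rbind, rows)
  out <- out[order(out$level, out$parent, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome size versus TE content regression
#'
#' Ordinary least squares of TE fraction (percent) on genome size (Mb),
#' with the Pearson correlation — the cross-species relationship between
#' assembly size and mobilome expansion.
#'
#' @param points Data.frame with columns `species`, `genome_size` (Mb),
#'   `te_fraction` (percent).
#' @return List with `slope`, `intercept`, `pearson_r`, `n`.
#' @export
size_te_regression <- function(points) {
  if (nrow(points) < 3L) stop("need at least 3 species points")
  if (stats::var(points$genome_size) == 0 ||
      stats::var(points$te_fraction) == 0)
    stop("zero variance in genome size or TE fraction")
  fit <- stats::lm(te_fraction ~ genome_size, data = points)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       pearson_r = stats::cor(points$genome_size, points$te_fraction),
       n = nrow(points))
}
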