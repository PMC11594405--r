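# Fold-flexibility census: per-group aggregation of instance metrics with
# robust location/dispersion statistics and agreement-tier fractions.

#' Aggregate per-instance metrics into census rows
#'
#' For every group at the requested level, computes n, median/min/max RMSD,
#' the scaled median absolute deviation (MAD, consistency constant 1.4826 so
#' it estimates a standard deviation robustly; set `mad_constant = 1` for
#' the raw MAD), the interquartile range, the fractions of instances within
#' the agreement tiers, and medians of the geometry metrics over the
#' instances where they are present.
#'
#' @param metrics data frame with one row per instance; must contain `rmsd`
#'   and the grouping column; `rmsd100`, `av_ratio`, `be_ratio` used when
#'   present.
#' @param group_col name of the grouping column (e.g. `"subcluster_id"`,
#'   `"topology_code"`, `"cath_class"`).
#' @param level label stored in the output (`"subcluster"`, `"topology"`,
#'   `"class"`, ...).
#' @param cutoffs agreement-tier RMSD cutoffs in Angstrom, default
#'   `c(2.5, 5)`.
#' @param mad_constant scale factor for the MAD, default 1.4826.
#' @return data frame of census rows (one per group), ordered by group id.
#' @export
aggregate_groups <- function(metrics, group_col, level = group_col,
                             cutoffs = c(2.5, 5), mad_constant = 1.4826) {
  if (!nrow(metrics)) stop_fc("empty metric table", "fc_validation_error")
  if (!all(c("rmsd", group_col) %in% names(metrics)))
    stop_fc(paste0("metric table needs columns rmsd and ", group_col),
            "fc_validation_error")
  groups <- sort(unique(metrics[[group_col]]))
  med_or_na <- function(x) if (is.null(x) || all(is.na(x))) NA_real_ else
    median(x, na.rm = TRUE)
  rows <- lapply(groups, function(g) {
    sub <- metrics[metrics[[group_col]] == g, , drop = FALSE]
    r <- sub$rmsd
    if (all(is.na(r))) stop_fc(paste0("group ", g, " has no RMSD values"),
                               "fc_validation_error")
    row <- data.frame(group_id = g, level = level, n_instances = nrow(sub),
                      median_rmsd = median(r), mad_rmsd = mad(r, constant = mad_constant),
                      iqr_rmsd = IQR(r), min_rmsd = min(r), max_rmsd = max(r),
                      median_rmsd100 = med_or_na(sub$rmsd100),
                      median_av_ratio = med_or_na(sub$av_ratio),
                      median_be_ratio = med_or_na(sub$be_ratio),
                      stringsAsFactors = FALSE)
    for (k in seq_along(cutoffs))
      row[[sprintf("frac_le_%s", gsub("\\.", "_", format(cutoffs[k])))]] <-
      mean(r <= cutoffs[k])
    row
  })
  do.call(rbind, rows)
}

#' Aggregate a single group
#'
#' @inheritParams aggregate_groups
#' @param group group id to aggregate.
#' @return a single census row.
#' @export
aggregate_group <- function(metrics, group_col, group, level = group_col,
                            cutoffs = c(2.5, 5), mad_constant = 1.4826) {
  sub <- metrics[metrics[[group_col]] == group, , drop = FALSE]
  if (!nrow(sub)) stop_fc(paste0("empty group ", group), "fc_validation_error")
  aggregate_groups(sub, group_col, level, cutoffs, mad_constant)
}

#' Tier census over fold groups
#'
#' For a cutoff c, reports the fraction of groups with at least one member
#' within c (`frac_any_within`), with at least one member beyond c
#' (`frac_any_beyond`), and with all members within c (`frac_all_within`).
#'
#' @param groups census data frame with `min_rmsd` and `max_rmsd`.
#' @param cutoff RMSD cutoff in Angstrom.
#' @return list of the three fractions plus the counts behind them.
#' @export
tier_census <- function(groups, cutoff) {
  n <- nrow(groups)
  list(cutoff = cutoff, n_groups = n,
       frac_any_within = mean(groups$min_rmsd <= cutoff),
       frac_any_beyond = mean(groups$max_rmsd > cutoff),
       frac_all_within = mean(groups$max_rmsd <= cutoff),
       n_any_within = sum(groups$min_rmsd <= cutoff),
       n_any_beyond = sum(groups$max_rmsd > cutoff))
}

#' Distribution of secondary-structure count differences
#'
#' Fraction of instances whose prediction has strictly more than `cutoff`
#' additional residues in helices or sheets, per cutoff.
#'
#' @param diffs signed integers from [sse_count_difference()].
#' @param cutoffs default `c(1, 2, 4, 8)`.
#' @return object of class `sse_diff_distribution`: `cutoffs`,
#'   `frac_exceeding` (non-increasing).
#' @export
sse_diff_distribution <- function(diffs, cutoffs = c(1, 2, 4, 8)) {
  structure(list(cutoffs = cutoffs,
                 frac_exceeding = vapply(cutoffs, function(ct)
                   mean(diffs > ct), 1.0)),
            class = "sse_diff_distribution")
}

#' Order the census along the flexibility spectrum
#'
#' Adds stable rank columns by median RMSD and by MAD (ties broken by group
#' id), so groups can be laid out along the rigidity-to-heterogeneity
#' spectrum.
#'
#' @param groups census data frame.
#' @return the census with `rank_median` and `rank_mad` columns.
#' @export
spectrum_order <- function(groups) {
  ord_med <- order(groups$median_rmsd, groups$group_id)
  ord_mad <- order(groups$mad_rmsd, groups$group_id)
  groups$rank_median <- match(seq_len(nrow(groups)), ord_med)
  groups$rank_mad <- match(seq_len(nrow(groups)), ord_mad)
  groups
}

#' Geometry trends across RMSD tiers
#'
#' Bins fold groups by median RMSD and reports per-bin medians of the
#' surface-to-volume and buried-to-exposed ratios; empty bins yield `NA`.
#'
#' @param groups census data frame with `median_rmsd`, `median_av_ratio`,
#'   `median_be_ratio`.
#' @param breaks bin edges (left-open, right-closed), default
#'   `c(0, 1.5, 2.5, 5, Inf)`.
#' @return data frame `bin`, `n`, `median_av_ratio`, `median_be_ratio`.
#' @export
geometry_trend <- function(groups, breaks = c(0, 1.5, 2.5, 5, Inf)) {
  bins <- cut(groups$median_rmsd, breaks = breaks, include.lowest = TRUE)
  med_or_na <- function(x) if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)
  out <- lapply(levels(bins), function(lv) {
    sel <- !is.na(bins) & bins == lv
    data.frame(bin = lv, n = sum(sel),
               median_av_ratio = if (any(sel)) med_or_na(groups$median_av_ratio[sel]) else NA_real_,
               median_be_ratio = if (any(sel)) med_or_na(groups$median_be_ratio[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
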