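# Biology-facing analyses: region-wise 2D-RMSD conformational clustering
# (the switch-region analysis) and hypergeometric enrichment between
# heterogeneous-fold and consistent-fold protein sets.

#' Region specification
#'
#' @param name label for the region.
#' @param range length-2 numeric `(start, end)` in reference numbering.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(name, range) {
  if (range[1] >= range[2]) stop_fc("region start must precede end",
                                    "fc_validation_error")
  structure(list(name = name, range = range), class = "region_spec")
}

#' Per-instance RMSD of two regions against a common predicted reference
#'
#' Superposes every instance on the predicted reference over all mapped
#' residues (one global fit per instance) and reports the RMSD of each
#' region under that fit. Instances lacking mapped residues in either
#' region are flagged (`complete = FALSE`) and excluded from clustering.
#'
#' @param instances list of `domain_instance` objects.
#' @param ref the predicted reference `domain_instance`.
#' @param regions list of two [region_spec()] objects.
#' @param maps optional list of `residue_map`s (instance onto `ref`),
#'   parallel to `instances`; defaults to matching by residue keys.
#' @return data frame `instance_id`, one RMSD column per region, `complete`.
#' @export
two_region_rmsd <- function(instances, ref, regions, maps = NULL) {
  stopifnot(length(regions) == 2)
  rows <- lapply(seq_along(instances), function(i) {
    inst <- instances[[i]]
    map <- if (is.null(maps)) NULL else maps[[i]]
    sup <- superpose_instances(inst, ref, map)
    vals <- vapply(regions, function(rg)
      suppressWarnings(region_rmsd(sup, rg$range)), 1.0)
    data.frame(instance_id = inst$instance_id,
               r1 = vals[1], r2 = vals[2],
               complete = !anyNA(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- vapply(regions, function(rg) rg$name, "")
  out
}

#' Cluster conformations in the 2D region-RMSD plane
#'
#' Agglomerative clustering (Ward linkage, Euclidean metric) of the
#' two-region RMSD values. With `k = "auto"` the cluster count maximizing
#' the mean silhouette width over 2..min(10, n-1) is chosen; identical
#' points collapse to a single cluster.
#'
#' @param table output of [two_region_rmsd()] (incomplete rows dropped).
#' @param k integer cluster count, or `"auto"`.
#' @return object of class `conformation_clusters`: `labels` (named by
#'   instance id), `k`, `centers` (per-cluster mean of the two RMSDs),
#'   `silhouette` (mean width at the chosen k, `NA` for k = 1).
#' @export
cluster_conformations <- function(table, k = "auto") {
  tab <- table[table$complete, , drop = FALSE]
  if (nrow(tab) < 2) stop_fc("need at least 2 complete instances", "fc_validation_error")
  x <- as.matrix(tab[, 2:3])
  rownames(x) <- tab$instance_id
  d <- dist(x)
  if (max(d) < 1e-9) {
    labels <- setNames(rep(1L, nrow(x)), rownames(x))
    return(structure(list(labels = labels, k = 1L,
                          centers = matrix(colMeans(x), 1,
                                           dimnames = list("1", colnames(x))),
                          silhouette = NA_real_),
                     class = "conformation_clusters"))
  }
  hc <- hclust(d, method = "ward.D2")
  if (identical(k, "auto")) {
    ks <- 2:min(10, nrow(x) - 1)
    sil <- vapply(ks, function(kk) {
      cl <- cutree(hc, k = kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, 1.0)
    k <- ks[which.max(sil)]
    best_sil <- max(sil)
  } else {
    cl <- cutree(hc, k = k)
    best_sil <- if (k >= 2 && k < nrow(x))
      mean(cluster::silhouette(cl, d)[, "sil_width"]) else NA_real_
  }
  labels <- cutree(hc, k = k)
  centers <- do.call(rbind, lapply(sort(unique(labels)), function(g)
    colMeans(x[labels == g, , drop = FALSE])))
  rownames(centers) <- sort(unique(labels))
  structure(list(labels = labels, k = as.integer(k), centers = centers,
                 silhouette = best_sil),
            class = "conformation_clusters")
}

#' Fractions of instances with both regions under a cutoff
#'
#' @param table output of [two_region_rmsd()]; incomplete rows dropped.
#' @param cutoffs RMSD cutoffs in Angstrom, default `c(1, 2.5, 5)`.
#' @return named numeric vector of fractions (non-decreasing in cutoff).
#' @export
threshold_fractions <- function(table, cutoffs = c(1.0, 2.5, 5.0)) {
  tab <- table[table$complete, , drop = FALSE]
  if (!nrow(tab)) stop_fc("no complete instances", "fc_validation_error")
  worst <- pmax(tab[[2]], tab[[3]])
  setNames(vapply(cutoffs, function(ct) mean(worst <= ct), 1.0),
           paste0("le_", cutoffs))
}

#' Select heterogeneous and consistent protein sets from the census
#'
#' A protein is heterogeneous when it owns at least one fold group with
#' median RMSD above `het_cutoff`; it is consistent when it owns a group in
#' the lowest `decile` of group medians (ties at the boundary included).
#' Proteins qualifying for both are assigned to the heterogeneous set.
#'
#' @param census census data frame with `group_id` and `median_rmsd`.
#' @param group_proteins data frame `group_id`, `protein_acc`.
#' @param het_cutoff Angstrom, default 2.5.
#' @param decile lower quantile defining the consistent groups, default 0.1.
#' @return list `het`, `con` (disjoint character vectors of accessions),
#'   `decile_threshold`.
#' @export
select_protein_sets <- function(census, group_proteins, het_cutoff = 2.5,
                                decile = 0.1) {
  med <- census$median_rmsd
  prot_of_group <- function(gids)
    sort(unique(group_proteins$protein_acc[group_proteins$group_id %in% gids]))
  het <- prot_of_group(census$group_id[med > het_cutoff])
  thr <- quantile(med, decile, names = FALSE)
  con <- setdiff(prot_of_group(census$group_id[med <= thr]), het)
  list(het = het, con = con, decile_threshold = thr)
}

#' Hypergeometric enrichment of annotation terms between protein sets
#'
#' For every term annotating at least one protein of the universe (the union
#' of both sets), computes the one-sided hypergeometric tail probability of
#' over-representation in each direction: drawing `|het|` proteins from the
#' universe and observing at least `count_het` annotated ones, and the
#' mirror test for the consistent set. Benjamini-Hochberg adjusted p-values
#' are computed across all reported tests.
#'
#' @param het,con character vectors of protein accessions (disjoint).
#' @param annotations data frame `protein_acc`, `term`.
#' @return data frame with one row per (term, direction): `term`,
#'   `direction` (`"het"`/`"con"`), `count_het`, `count_con`, `count_diff`
#'   (`count_con - count_het`), `p_value`, `adjusted_p`.
#' @export
hypergeom_enrich <- function(het, con, annotations) {
  universe <- union(het, con)
  ann <- annotations[annotations$protein_acc %in% universe, , drop = FALSE]
  terms <- sort(unique(ann$term))
  if (!length(terms))
    return(data.frame(term = character(), direction = character(),
                      count_het = integer(), count_con = integer(),
                      count_diff = integer(), p_value = numeric(),
                      adjusted_p = numeric()))
  N <- length(universe)
  rows <- lapply(terms, function(tm) {
    with_term <- unique(ann$protein_acc[ann$term == tm])
    K <- length(with_term)
    k_het <- sum(het %in% with_term)
    k_con <- sum(con %in% with_term)
    p_het <- phyper(k_het - 1, K, N - K, length(het), lower.tail = FALSE)
    p_con <- phyper(k_con - 1, K, N - K, length(con), lower.tail = FALSE)
    data.frame(term = tm, direction = c("het", "con"),
               count_het = k_het, count_con = k_con,
               count_diff = k_con - k_het,
               p_value = c(p_het, p_con), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p_value, method = "BH")
  out
}
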