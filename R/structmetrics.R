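# Superposition, RMSD / RMSD100, and per-instance geometry metrics.

#' Kabsch least-squares superposition of two matched coordinate sets
#'
#' Finds the proper rotation and translation that minimize the RMSD of `b`
#' onto `a` (rows are matched points). The rotation is applied to
#' centered row coordinates as `b0 %*% rotation`; a reflection is never
#' returned.
#'
#' @param a,b numeric matrices (n x 3), n >= 3, same row order (typically CA
#'   coordinates taken through a residue map).
#' @param ref_pos optional per-row reference residue numbers carried into the
#'   result for region queries.
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `centroid_a`, `centroid_b`, `rmsd`, `rmsd100`,
#'   `n_atoms`, `dev` (per-row deviations) and `ref_pos`.
#' @export
kabsch_superpose <- function(a, b, ref_pos = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3)
    stop_fc("coordinate sets must be equal-size n x 3 matrices", "fc_validation_error")
  n <- nrow(a)
  if (n < 3) stop_fc("need at least 3 points", "fc_degenerate")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (svd(a0)$d[2] < 1e-8 && svd(b0)$d[2] < 1e-8)
    stop_fc("degenerate (collinear) coordinate sets", "fc_degenerate")
  h <- crossprod(b0, a0)            # 3x3: t(b0) %*% a0
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- b0 %*% rot
  dev <- sqrt(rowSums((a0 - fit)^2))
  rmsd <- sqrt(mean(dev^2))
  structure(list(rotation = rot, translation = ca - as.numeric(cb %*% rot),
                 centroid_a = ca, centroid_b = cb,
                 rmsd = rmsd, rmsd100 = rmsd100(rmsd, n), n_atoms = n,
                 dev = dev, ref_pos = ref_pos %||% seq_len(n)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d atoms: RMSD %.3f A (RMSD100 %.3f A)\n",
              x$n_atoms, x$rmsd, x$rmsd100))
  invisible(x)
}

#' Length-normalized RMSD (RMSD100)
#'
#' `rmsd / (1 + ln(sqrt(n / 100)))`, which rescales an RMSD over `n` residues
#' to the value expected for a 100-residue protein so domains of different
#' size are comparable. For `n <= 13` the denominator is non-positive and the
#' value is returned as `NA`.
#'
#' @param rmsd RMSD in Angstrom (vectorized).
#' @param n number of residues.
#' @return normalized RMSD in Angstrom, or `NA` where undefined.
#' @export
rmsd100 <- function(rmsd, n) {
  denom <- 1 + log(sqrt(n / 100))
  out <- ifelse(denom > 0, rmsd / denom, NA_real_)
  out[rmsd == 0 & denom > 0] <- 0
  out
}

#' Superpose a domain instance onto a reference through a residue map
#'
#' Extracts the mapped CA coordinates of both instances (map order) and
#' performs a Kabsch fit of `inst` onto `ref`. With `fit_positions` the
#' rotation is computed from a subset of reference positions (a core fit)
#' while deviations are still reported for every mapped residue.
#'
#' @param inst,ref `domain_instance` objects.
#' @param map a `residue_map` (`ref` side in `model_key`); defaults to
#'   matching residues by identical keys.
#' @param fit_positions optional reference residue numbers to restrict the
#'   fit to (deviations still cover all mapped residues).
#' @return a `superposition` whose `ref_pos` holds reference residue numbers,
#'   enabling [region_rmsd()].
#' @export
superpose_instances <- function(inst, ref, map = NULL, fit_positions = NULL) {
  if (is.null(map)) map <- match_by_keys(inst, ref)
  a <- ca_xyz(ref, map$model_key)
  b <- ca_xyz(inst, map$inst_key)
  ref_pos <- map$ref_pos %||% seq_len(nrow(map))
  if (is.null(fit_positions)) return(kabsch_superpose(a, b, ref_pos = ref_pos))
  sel <- ref_pos %in% fit_positions
  if (sum(sel) < 3) stop_fc("fewer than 3 fit positions", "fc_degenerate")
  core <- kabsch_superpose(a[sel, , drop = FALSE], b[sel, , drop = FALSE])
  bt <- sweep(sweep(b, 2, core$centroid_b) %*% core$rotation, 2,
              core$centroid_a, FUN = "+")
  dev <- sqrt(rowSums((a - bt)^2))
  structure(list(rotation = core$rotation, translation = core$translation,
                 centroid_a = core$centroid_a, centroid_b = core$centroid_b,
                 rmsd = sqrt(mean(dev^2)),
                 rmsd100 = rmsd100(sqrt(mean(dev^2)), length(dev)),
                 n_atoms = length(dev), dev = dev, ref_pos = ref_pos),
            class = "superposition")
}

#' RMSD of a residue region under an already-fixed superposition
#'
#' Computes the RMSD over the residues whose reference numbers fall in
#' `region`, using the per-residue deviations of an existing fit — the
#' superposition is not recomputed for the region.
#'
#' @param sup a `superposition` carrying `dev` and `ref_pos`.
#' @param region length-2 numeric `(start, end)` in reference numbering,
#'   inclusive.
#' @return RMSD in Angstrom, or `NA` (with a warning) when no mapped residue
#'   falls in the region.
#' @export
region_rmsd <- function(sup, region) {
  sel <- sup$ref_pos >= region[1] & sup$ref_pos <= region[2]
  if (!any(sel)) {
    warning("no mapped residues in region [", region[1], ", ", region[2], "]")
    return(NA_real_)
  }
  sqrt(mean(sup$dev[sel]^2))
}

heavy_atoms <- function(atoms) {
  atoms[atoms$elesy != "H", , drop = FALSE]
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic sphere-point SASA over heavy atoms, using Bondi van der
#' Waals radii (unknown elements fall back to a default with a warning) and
#' a golden-spiral test-point lattice.
#'
#' @param inst a `domain_instance` (or anything with an `$atoms` table).
#' @param probe probe radius in Angstrom, default 1.4 (water).
#' @param n_points test points per atom, default 960.
#' @return list with `atom_area` (per heavy atom, Angstrom^2), `total`, and
#'   `residue_area` (named by residue key).
#' @export
shrake_rupley_sasa <- function(inst, probe = 1.4, n_points = 960) {
  at <- heavy_atoms(inst$atoms)
  if (nrow(at) == 0) stop_fc("no heavy atoms", "fc_validation_error")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- element_radius(at$elesy)
  area <- .sasa_cpp(xyz, radii, probe, as.integer(n_points))
  res <- tapply(area, at$key, sum)
  keys <- unique(at$key)
  list(atom_area = area, total = sum(area),
       residue_area = setNames(as.numeric(res[keys]), keys))
}

#' Molecular volume by voxel counting
#'
#' Volume of the union of van der Waals spheres over heavy atoms, counted on
#' a cubic grid.
#'
#' @param inst a `domain_instance`.
#' @param grid voxel edge in Angstrom, default 0.5.
#' @return volume in Angstrom^3.
#' @export
estimate_volume <- function(inst, grid = 0.5) {
  at <- heavy_atoms(inst$atoms)
  if (nrow(at) == 0) return(0)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  .voxel_volume_cpp(xyz, element_radius(at$elesy), grid)
}

#' Classify residues as buried or exposed
#'
#' A residue is buried when its relative SASA — observed SASA divided by the
#' residue type's theoretical maximum — is below `threshold`.
#'
#' @param residue_sasa named per-residue SASA (Angstrom^2), as returned in
#'   `shrake_rupley_sasa()$residue_area`.
#' @param seq one-letter sequence in the same residue order.
#' @param threshold relative-SASA burial cutoff, default 0.25.
#' @return list `n_buried`, `n_exposed`, `be_ratio` (`NA` when nothing is
#'   exposed), `rel_sasa`.
#' @export
classify_buried_exposed <- function(residue_sasa, seq, threshold = 0.25) {
  aa <- strsplit(seq, "")[[1]]
  if (length(aa) != length(residue_sasa))
    stop_fc("sequence length does not match per-residue SASA", "fc_validation_error")
  mx <- MAX_ASA[aa]
  mx[is.na(mx)] <- MAX_ASA_X
  rel <- as.numeric(residue_sasa) / as.numeric(mx)
  n_b <- sum(rel < threshold); n_e <- sum(rel >= threshold)
  list(n_buried = n_b, n_exposed = n_e,
       be_ratio = if (n_e == 0) NA_real_ else n_b / n_e,
       rel_sasa = setNames(rel, names(residue_sasa)))
}

#' Count residues contacting metal ions and ligands
#'
#' A residue is counted once per category when any of its heavy atoms lies
#' within `cutoff` of any atom of a heteroatom group of that category.
#' Metals are identified by element; waters are excluded upstream; every
#' other heteroatom group counts as ligand.
#'
#' @param inst a `domain_instance`.
#' @param het_atoms heteroatom table (as in `structure_model$het_atoms`).
#' @param cutoff contact distance in Angstrom, default 4.0.
#' @return list `n_met`, `n_lig`.
#' @export
contact_counts <- function(inst, het_atoms, cutoff = 4.0) {
  if (is.null(het_atoms) || nrow(het_atoms) == 0)
    return(list(n_met = 0L, n_lig = 0L))
  at <- heavy_atoms(inst$atoms)
  axyz <- as.matrix(at[, c("x", "y", "z")])
  is_metal <- het_atoms$elesy %in% METAL_ELEMENTS
  count_near <- function(hxyz) {
    if (nrow(hxyz) == 0) return(0L)
    d2 <- outer(rowSums(axyz^2), rowSums(hxyz^2), "+") -
      2 * axyz %*% t(hxyz)
    near <- apply(d2 <= cutoff^2 + 1e-12, 1, any)
    length(unique(at$key[near]))
  }
  list(n_met = count_near(as.matrix(het_atoms[is_metal, c("x", "y", "z"), drop = FALSE])),
       n_lig = count_near(as.matrix(het_atoms[!is_metal, c("x", "y", "z"), drop = FALSE])))
}

#' Signed secondary-structure count difference
#'
#' Number of residues in helices or strands in the predicted profile minus
#' the number in the experimental profile; positive values mean the
#' prediction has more secondary structure. Profiles must cover the same
#' (mapped) residues.
#'
#' @param pred,expt `sse_profile` objects from [assign_sse()].
#' @return signed integer.
#' @export
sse_count_difference <- function(pred, expt) {
  pred$n_sse_residues - expt$n_sse_residues
}
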