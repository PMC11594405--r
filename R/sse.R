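# Secondary-structure assignment from backbone hydrogen bonds
# (Kabsch-Sander-style electrostatic criterion).

HB_ENERGY_CUTOFF <- -0.5   # kcal/mol
HB_Q1Q2F <- 0.42 * 0.20 * 332  # partial charges x dimensional factor

# Backbone table: one row per residue with N, CA, C, O coordinates; residues
# missing any of the four atoms get has_bb = FALSE and are assigned coil.
backbone_table <- function(inst) {
  at <- inst$atoms
  keys <- unique(at$key)
  get <- function(el) {
    sub <- at[at$elety == el, , drop = FALSE]
    m <- matrix(NA_real_, length(keys), 3)
    idx <- match(sub$key, keys)
    m[idx[!is.na(idx)], ] <- as.matrix(sub[!is.na(idx), c("x", "y", "z")])
    m
  }
  list(keys = keys, N = get("N"), CA = get("CA"), C = get("C"), O = get("O"))
}

# hb[i, j]: TRUE when the C=O of residue i accepts a hydrogen bond from the
# N-H of residue j. Amide H is placed 1.0 A from N along the preceding
# residue's C=O direction (the standard reconstruction).
hbond_matrix <- function(bb) {
  n <- length(bb$keys)
  has_bb <- !(is.na(bb$N[, 1]) | is.na(bb$CA[, 1]) | is.na(bb$C[, 1]) |
                is.na(bb$O[, 1]))
  H <- matrix(NA_real_, n, 3)
  for (i in 2:max(2, n)) {
    if (i > n) break
    if (!has_bb[i] || !has_bb[i - 1]) next
    # chain break: peptide bond too long
    if (sqrt(sum((bb$N[i, ] - bb$C[i - 1, ])^2)) > 2.5) next
    co <- bb$C[i - 1, ] - bb$O[i - 1, ]
    H[i, ] <- bb$N[i, ] + co / sqrt(sum(co^2))
  }
  hb <- matrix(FALSE, n, n)
  donors <- which(!is.na(H[, 1]))
  acceptors <- which(has_bb)
  if (!length(donors) || !length(acceptors)) return(hb)
  for (j in donors) {
    for (i in acceptors) {
      if (abs(i - j) < 2) next
      rON <- sqrt(sum((bb$O[i, ] - bb$N[j, ])^2))
      if (rON > 5.2) next  # beyond any plausible H-bond
      rCH <- sqrt(sum((bb$C[i, ] - H[j, ])^2))
      rOH <- sqrt(sum((bb$O[i, ] - H[j, ])^2))
      rCN <- sqrt(sum((bb$C[i, ] - bb$N[j, ])^2))
      e <- HB_Q1Q2F * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- e < HB_ENERGY_CUTOFF
    }
  }
  hb
}

#' Assign secondary structure from backbone hydrogen bonds
#'
#' Kabsch-Sander-style assignment: backbone amide hydrogens are
#' reconstructed, hydrogen bonds are scored with the electrostatic energy
#' model (bond when E < -0.5 kcal/mol), helices are runs of at least four
#' residues covered by consecutive i to i+4 bonds, and strands are
#' bridge-paired runs of at least two residues (parallel or antiparallel
#' bridge patterns). Everything else is coil; residues with missing backbone
#' atoms are coil with a warning.
#'
#' @param inst a `domain_instance` with backbone N, CA, C, O atoms.
#' @return object of class `sse_profile`: `per_residue` (string over H/E/C),
#'   `frac_helix`, `frac_sheet`, `n_sse_residues`.
#' @export
assign_sse <- function(inst) {
  bb <- backbone_table(inst)
  n <- length(bb$keys)
  has_bb <- !(is.na(bb$N[, 1]) | is.na(bb$CA[, 1]) | is.na(bb$C[, 1]) |
                is.na(bb$O[, 1]))
  if (any(!has_bb))
    warning(sum(!has_bb), " residue(s) missing backbone atoms; assigned coil")
  ss <- rep("C", n)
  if (n >= 5 && any(has_bb)) {
    hb <- hbond_matrix(bb)
    # helices: 4-turns at i when CO(i) bonds HN(i+4); residues i+1..i+4
    cand <- rep(FALSE, n)
    for (i in seq_len(n - 4)) if (hb[i, i + 4]) cand[(i + 1):(i + 4)] <- TRUE
    ss[in_runs(cand, 4)] <- "H"
    # bridges (Kabsch-Sander parallel / antiparallel patterns)
    bridge <- rep(FALSE, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (abs(i - j) <= 2) next
        par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
        anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
        if (par || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
      }
    }
    bridge[ss == "H"] <- FALSE
    ss[in_runs(bridge, 2)] <- "E"
  }
  profile_from_ss(ss)
}

in_runs <- function(flags, min_len) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- integer(0)
  for (k in seq_along(r$values))
    if (r$values[k] && r$lengths[k] >= min_len)
      out <- c(out, starts[k]:ends[k])
  out
}

profile_from_ss <- function(ss) {
  n <- length(ss)
  structure(list(per_residue = paste(ss, collapse = ""),
                 frac_helix = sum(ss == "H") / n,
                 frac_sheet = sum(ss == "E") / n,
                 n_sse_residues = sum(ss != "C")),
            class = "sse_profile")
}

#' Restrict an SSE profile to a residue subset
#'
#' Used to compare predicted and experimental profiles over their mapped
#' common residues.
#'
#' @param profile an `sse_profile`.
#' @param positions 1-based residue positions to keep.
#' @return an `sse_profile` over the selected positions.
#' @export
subset_sse <- function(profile, positions) {
  ss <- strsplit(profile$per_residue, "")[[1]][positions]
  profile_from_ss(ss)
}
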