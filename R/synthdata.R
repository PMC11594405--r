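# Synthetic multi-conformer ensembles with controlled hinge amplitude and
# thermal noise, plus a matching "predicted" reference, domain definitions,
# mock per-residue confidence and annotation tables. Everything is seeded
# and deterministic so pipeline behaviour can be tested against known
# ground truth.
#
# Fixture realism is deliberately limited: ideal-geometry backbones with CB
# side chains only, rigid hinge/flap motions plus isotropic Gaussian noise.

BOND_N_CA <- 1.458; BOND_CA_C <- 1.525; BOND_C_N <- 1.329
BOND_C_O <- 1.231; BOND_CA_CB <- 1.521
ANG_N_CA_C <- 111.2; ANG_CA_C_N <- 116.2; ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8; ANG_C_CA_CB <- 110.6
TOR_N_C_CA_CB <- -122.6  # L-amino-acid chirality
PHI_HELIX <- -57; PSI_HELIX <- -47
PHI_STRAND <- -119; PSI_STRAND <- 113

#' Ground-truth parameters for one synthetic fold group
#'
#' @param group_id label for the group (one synthetic "fold").
#' @param template_kind one of `"helix-bundle"`, `"sheet-sandwich"`,
#'   `"mixed"`, `"extended"`.
#' @param hinge_residues length-2 interval; the hinge axis runs between the
#'   CA atoms of its endpoints and everything downstream of the interval
#'   rotates.
#' @param hinge_sigma_deg standard deviation of the per-conformer hinge
#'   angle in degrees.
#' @param noise_sigma per-coordinate thermal noise in Angstrom.
#' @param n_conformers conformers to generate.
#' @param prediction_mode `"pick_one"` (the prediction is a copy of one
#'   conformer) or `"average"` (per-atom coordinate mean).
#' @param seed RNG seed for this group.
#' @param n_res template length (>= 20).
#' @param cath_code,protein_acc identifiers written into definitions.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(group_id, template_kind = "helix-bundle",
                            hinge_residues = c(39, 42), hinge_sigma_deg = 10,
                            noise_sigma = 0.2, n_conformers = 12,
                            prediction_mode = c("pick_one", "average"),
                            seed = 1, n_res = 60,
                            cath_code = "1.10.10.10",
                            protein_acc = paste0("SYN", group_id)) {
  prediction_mode <- match.arg(prediction_mode)
  if (hinge_sigma_deg < 0 || noise_sigma < 0 || n_conformers < 1)
    stop_fc("invalid ground-truth parameters", "fc_validation_error")
  structure(list(group_id = group_id, template_kind = template_kind,
                 hinge_residues = hinge_residues,
                 hinge_sigma_deg = hinge_sigma_deg, noise_sigma = noise_sigma,
                 n_conformers = n_conformers, prediction_mode = prediction_mode,
                 seed = as.integer(seed), n_res = n_res,
                 cath_code = cath_code, protein_acc = protein_acc),
            class = "synthetic_truth")
}

# backbone (N, CA, C, O, CB) chain from phi/psi torsions; omega fixed trans
build_backbone <- function(phi, psi, seq) {
  n <- length(phi)
  stopifnot(length(psi) == n, nchar(seq) == n)
  aa <- strsplit(seq, "")[[1]]
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  ang <- ANG_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANG_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANG_C_N_CA, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANG_N_CA_C, phi[i])
  }
  for (i in 1:n) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANG_CA_C_O, psi[i] + 180)
    if (aa[i] != "G")
      CB[i, ] <- place_atom(N[i, ], C[i, ], CA[i, ],
                            BOND_CA_CB, ANG_C_CA_CB, TOR_N_C_CA_CB)
  }
  rows <- list()
  for (i in 1:n) {
    names_i <- c("N", "CA", "C", "O", if (aa[i] != "G") "CB")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ],
                 if (aa[i] != "G") CB[i, ])
    rows[[i]] <- data.frame(chain = "A", resno = i, insert = "",
                            resid = unname(AA1TO3[aa[i]]), aa = aa[i],
                            elety = names_i,
                            elesy = c("N", "C", "C", "O",
                                      if (aa[i] != "G") "C"),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            o = 1, b = 0, stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at$key <- res_key(at$chain, at$resno, at$insert)
  rownames(at) <- NULL
  at
}

# rotate/translate an atom block so its CA end-to-end vector lies on +z and
# its centroid sits at `offset`
align_block <- function(at, offset = c(0, 0, 0), flip = FALSE) {
  ca <- as.matrix(at[at$elety == "CA", c("x", "y", "z")])
  axis <- unit_vec(ca[nrow(ca), ] - ca[1, ])
  z <- c(0, 0, 1)
  v <- pracma_cross(axis, z)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (sqrt(sum(v^2)) > 1e-9) {
    ang <- acos(max(-1, min(1, sum(axis * z)))) * 180 / pi
    xyz <- rotate_about_axis(xyz, colMeans(ca), v, ang)
  } else if (sum(axis * z) < 0) {
    xyz <- rotate_about_axis(xyz, colMeans(ca), c(1, 0, 0), 180)
  }
  if (flip) xyz <- rotate_about_axis(xyz, colMeans(xyz), c(1, 0, 0), 180)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  xyz <- sweep(xyz, 2, offset, FUN = "+")
  at[, c("x", "y", "z")] <- xyz
  at
}

# coil placeholder residues along a straight line between two anchor points
loop_block <- function(p_from, p_to, resnos, aa) {
  k <- length(resnos)
  rows <- list()
  for (i in seq_len(k)) {
    t <- i / (k + 1)
    p <- p_from + t * (p_to - p_from)
    off <- rbind(N = c(-0.6, 0.4, 0), CA = c(0, 0, 0), C = c(0.6, 0.4, 0),
                 O = c(0.8, 1.5, 0), CB = c(0, -1.0, 1.0))
    rows[[i]] <- data.frame(chain = "A", resno = resnos[i], insert = "",
                            resid = unname(AA1TO3[aa[i]]), aa = aa[i],
                            elety = rownames(off),
                            elesy = c("N", "C", "C", "O", "C"),
                            x = p[1] + off[, 1], y = p[2] + off[, 2],
                            z = p[3] + off[, 3], o = 1, b = 0,
                            stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at$key <- res_key(at$chain, at$resno, at$insert)
  at
}

random_seq <- function(n) {
  # G and P excluded so every residue has a CB and an amide donor
  paste(sample(setdiff(AA1, c("G", "P")), n, replace = TRUE), collapse = "")
}

#' Build an ideal-geometry template domain
#'
#' Constructs a backbone + CB model of the requested architecture from ideal
#' dihedrals (helix phi -57 / psi -47; strand phi -119 / psi 113), with
#' secondary-structure blocks placed side by side and straight connecting
#' loops. The sequence is a seeded random draw over the 18 non-Gly/Pro
#' amino acids, so coordinates and sequence are bit-reproducible per seed.
#'
#' @param kind `"helix-bundle"`, `"sheet-sandwich"`, `"mixed"` or
#'   `"extended"`.
#' @param n_res template length, >= 20.
#' @param seed RNG seed.
#' @param group_id,cath_code,protein_acc identifiers for the definition.
#' @return a `domain_instance` (experimental flavour, source `template`).
#' @export
build_template <- function(kind, n_res = 60, seed = 1, group_id = "G1",
                           cath_code = "1.10.10.10",
                           protein_acc = paste0("SYN", group_id)) {
  if (n_res < 20) stop_fc("templates need n_res >= 20", "fc_validation_error")
  set.seed(seed)
  seq <- random_seq(n_res)
  aa <- strsplit(seq, "")[[1]]
  if (kind == "extended") {
    at <- build_backbone(rep(PHI_STRAND, n_res), rep(PSI_STRAND, n_res), seq)
  } else {
    spec <- switch(kind,
      "helix-bundle" = block_plan(n_res, n_blocks = 3, loop_len = 4),
      "sheet-sandwich" = block_plan(n_res, n_blocks = 4, loop_len = 4),
      "mixed" = block_plan(n_res, n_blocks = 3, loop_len = 4),
      stop_fc(paste0("unknown template kind: ", kind), "fc_validation_error"))
    is_strand <- switch(kind,
      "helix-bundle" = rep(FALSE, length(spec$blocks)),
      "sheet-sandwich" = rep(TRUE, length(spec$blocks)),
      "mixed" = c(FALSE, TRUE, TRUE))
    spacing <- ifelse(is_strand, 4.9, 10)
    blocks <- list()
    for (b in seq_along(spec$blocks)) {
      idx <- spec$blocks[[b]]
      phi <- rep(if (is_strand[b]) PHI_STRAND else PHI_HELIX, length(idx))
      psi <- rep(if (is_strand[b]) PSI_STRAND else PSI_HELIX, length(idx))
      blk <- build_backbone(phi, psi, paste(aa[idx], collapse = ""))
      blk$resno <- idx[blk$resno]
      blk$key <- res_key(blk$chain, blk$resno, blk$insert)
      off <- c((b - 1) * spacing[b], if (kind == "sheet-sandwich" && b > 2) 9 else 0, 0)
      if (kind == "sheet-sandwich" && b > 2) off[1] <- (b - 3) * spacing[b]
      blocks[[b]] <- align_block(blk, offset = off, flip = (b %% 2 == 0))
    }
    pieces <- list(blocks[[1]])
    for (b in seq_along(spec$loops)) {
      lidx <- spec$loops[[b]]
      if (!length(lidx)) next
      from_blk <- blocks[[b]]; to_blk <- blocks[[b + 1]]
      p_from <- as.numeric(from_blk[from_blk$elety == "CA", c("x", "y", "z")][sum(from_blk$elety == "CA"), ])
      p_to <- as.numeric(to_blk[to_blk$elety == "CA", c("x", "y", "z")][1, ])
      pieces[[length(pieces) + 1]] <- loop_block(p_from, p_to, lidx, aa[lidx])
      pieces[[length(pieces) + 1]] <- blocks[[b + 1]]
    }
    at <- do.call(rbind, pieces)
    at <- at[order(at$resno), , drop = FALSE]
    rownames(at) <- NULL
  }
  d <- domain_definition(paste0(group_id, "_dom"), cath_code, protein_acc,
                         data.frame(chain = "A", start = 1, end = n_res))
  s <- structure(list(source_id = paste0("template_", group_id),
                      method = "SYNTHETIC", resolution = 2.0,
                      atoms = at, het_atoms = at[0, , drop = FALSE]),
                 class = "structure_model")
  inst <- extract_domain_instance(s, d)
  inst$window <- c(1, n_res)
  inst
}

# split n_res into n_blocks secondary-structure blocks joined by loops
block_plan <- function(n_res, n_blocks, loop_len) {
  n_loop <- (n_blocks - 1) * loop_len
  per <- (n_res - n_loop) %/% n_blocks
  extra <- (n_res - n_loop) %% n_blocks
  blocks <- list(); loops <- list(); at <- 1
  for (b in seq_len(n_blocks)) {
    len <- per + (b <= extra)
    blocks[[b]] <- at:(at + len - 1)
    at <- at + len
    if (b < n_blocks) {
      loops[[b]] <- at:(at + loop_len - 1)
      at <- at + loop_len
    }
  }
  list(blocks = blocks, loops = loops)
}

#' Rotate everything downstream of a hinge
#'
#' The axis runs from the CA of `hinge[1]` to the CA of `hinge[2]`; all
#' atoms of residues with author number greater than `hinge[2]` rotate by
#' `angle_deg` about it.
#'
#' @param inst a `domain_instance`.
#' @param hinge length-2 residue-number interval.
#' @param angle_deg rotation in degrees.
#' @return the rotated instance.
#' @export
apply_hinge <- function(inst, hinge, angle_deg) {
  ca <- ca_xyz(inst)
  k1 <- res_key("A", hinge[1], ""); k2 <- res_key("A", hinge[2], "")
  if (!all(c(k1, k2) %in% rownames(ca)))
    stop_fc("hinge residues not found", "fc_validation_error")
  sel <- inst$atoms$resno > hinge[2]
  if (any(sel)) {
    xyz <- as.matrix(inst$atoms[sel, c("x", "y", "z")])
    inst$atoms[sel, c("x", "y", "z")] <-
      rotate_about_axis(xyz, ca[k1, ], ca[k2, ] - ca[k1, ], angle_deg)
  }
  inst
}

#' Rotate the interior of a region about its end-to-end axis (flap motion)
#'
#' The axis runs between the CA atoms of the region endpoints, which stay
#' fixed; residues strictly inside the region rotate. Used to plant
#' switch-like local conformational changes.
#'
#' @param inst a `domain_instance`.
#' @param region length-2 residue-number interval.
#' @param angle_deg rotation in degrees.
#' @return the rotated instance.
#' @export
apply_flap <- function(inst, region, angle_deg) {
  ca <- ca_xyz(inst)
  k1 <- res_key("A", region[1], ""); k2 <- res_key("A", region[2], "")
  if (!all(c(k1, k2) %in% rownames(ca)))
    stop_fc("region endpoints not found", "fc_validation_error")
  sel <- inst$atoms$resno > region[1] & inst$atoms$resno < region[2]
  if (any(sel)) {
    xyz <- as.matrix(inst$atoms[sel, c("x", "y", "z")])
    inst$atoms[sel, c("x", "y", "z")] <-
      rotate_about_axis(xyz, ca[k1, ], ca[k2, ] - ca[k1, ], angle_deg)
  }
  inst
}

#' Generate a conformer ensemble from a template
#'
#' Per conformer, the post-hinge segment rotates by an angle drawn from
#' `Normal(0, hinge_sigma_deg)` and every atom receives iid
#' `Normal(0, noise_sigma)` displacement per coordinate. Fully reproducible
#' from `truth$seed`.
#'
#' @param template a `domain_instance` from [build_template()].
#' @param truth a [synthetic_truth()].
#' @return list of `domain_instance` conformers (instance ids
#'   `<group>_c<j>`).
#' @export
generate_ensemble <- function(template, truth) {
  set.seed(truth$seed)
  lapply(seq_len(truth$n_conformers), function(j) {
    ang <- rnorm(1, 0, truth$hinge_sigma_deg)
    conf <- apply_hinge(template, truth$hinge_residues, ang)
    na <- nrow(conf$atoms)
    conf$atoms[, c("x", "y", "z")] <- conf$atoms[, c("x", "y", "z")] +
      matrix(rnorm(3 * na, 0, truth$noise_sigma), na, 3)
    conf$source <- sprintf("%s_c%02d", truth$group_id, j)
    conf$instance_id <- paste0(conf$source, "_", conf$domain_id)
    conf$resolution <- 2.0
    conf
  })
}

#' Generate the "predicted" reference for an ensemble
#'
#' `pick_one` copies one seeded-random conformer — a prediction locked to a
#' single experimental state; `average` takes the per-atom coordinate mean
#' over conformers — a prediction that blends states. Mock per-residue
#' confidence is written into the B-factor column as
#' `clip(90 - 8 * sd_local, 50, 99)` where `sd_local` is the ensemble RMS
#' fluctuation of the residue's CA.
#'
#' @param template the group template.
#' @param ensemble list of conformers from [generate_ensemble()].
#' @param mode `"pick_one"` or `"average"`.
#' @param seed seed for the pick.
#' @return a predicted `domain_instance`.
#' @export
generate_prediction <- function(template, ensemble,
                                mode = c("pick_one", "average"), seed = 1) {
  mode <- match.arg(mode)
  pred <- if (mode == "pick_one") {
    set.seed(seed)
    ensemble[[sample(length(ensemble), 1)]]
  } else {
    out <- ensemble[[1]]
    xyz <- Reduce(`+`, lapply(ensemble, function(e)
      as.matrix(e$atoms[, c("x", "y", "z")]))) / length(ensemble)
    out$atoms[, c("x", "y", "z")] <- xyz
    out
  }
  ca_stack <- vapply(ensemble, function(e) ca_xyz(e), ca_xyz(template))
  ca_mean <- apply(ca_stack, c(1, 2), mean)
  fluct <- sqrt(apply((ca_stack - array(ca_mean, dim(ca_stack)))^2,
                      1, mean) * 3)
  plddt <- pmin(99, pmax(50, 90 - 8 * fluct))
  pred$atoms$b <- plddt[match(pred$atoms$key, rownames(ca_xyz(template)))]
  pred$is_predicted <- TRUE
  pred$source <- paste0("pred_", pred$protein_acc)
  pred$instance_id <- paste0(pred$source, "_", pred$domain_id)
  pred$resolution <- NA_real_
  pred
}

# view a domain_instance as a structure_model (for extraction / mapping)
#' Convert a domain instance to a structure model
#'
#' @param inst a `domain_instance`.
#' @param source_id optional identifier override.
#' @return a `structure_model` wrapping the instance's atoms.
#' @export
as_structure_model <- function(inst, source_id = NULL) {
  structure(list(source_id = source_id %||% inst$source,
                 method = inst$method %||% "SYNTHETIC",
                 resolution = inst$resolution,
                 atoms = inst$atoms,
                 het_atoms = inst$atoms[0, , drop = FALSE]),
            class = "structure_model")
}

# prepend/append straight low-confidence tails so the full-length predicted
# protein is longer than the domain (exercises glocal window extraction)
add_flanks <- function(pred, flank, seed) {
  if (flank <= 0) return(pred)
  set.seed(seed)
  fseq1 <- random_seq(flank); fseq2 <- random_seq(flank)
  at <- pred$atoms
  ca <- ca_xyz(pred)
  n <- pred$n_res
  dirN <- unit_vec(ca[1, ] - ca[min(4, n), ])
  dirC <- unit_vec(ca[n, ] - ca[max(1, n - 3), ])
  mk <- function(seqs, anchor, dir, resnos, steps) {
    aa <- strsplit(seqs, "")[[1]]
    rows <- lapply(seq_along(aa), function(i) {
      p <- anchor + (steps[i] * 3.6) * dir
      off <- rbind(N = c(-0.6, 0.4, 0), CA = c(0, 0, 0), C = c(0.6, 0.4, 0),
                   O = c(0.8, 1.5, 0), CB = c(0, -1.0, 1.0))
      data.frame(chain = "A", resno = resnos[i], insert = "",
                 resid = unname(AA1TO3[aa[i]]), aa = aa[i], elety = rownames(off),
                 elesy = c("N", "C", "C", "O", "C"),
                 x = p[1] + off[, 1], y = p[2] + off[, 2],
                 z = p[3] + off[, 3], o = 1, b = 55,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$key <- res_key(out$chain, out$resno, out$insert)
    out
  }
  # N flank: residue 1 outermost (flank steps out), residue `flank` adjacent
  pre <- mk(fseq1, ca[1, ], dirN, resnos = seq_len(flank), steps = flank:1)
  core <- at
  core$resno <- core$resno + flank
  post <- mk(fseq2, ca[n, ], dirC, resnos = seq_len(flank) + flank + n,
             steps = seq_len(flank))
  all_at <- rbind(pre, core, post)
  all_at$key <- res_key(all_at$chain, all_at$resno, all_at$insert)
  rownames(all_at) <- NULL
  list(atoms = all_at, seq = paste0(fseq1, pred$seq, fseq2))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits, for every ground-truth group: the conformer ensemble as PDB files,
#' a full-length predicted model (the group prediction with short
#' low-confidence flanking tails) with pLDDT in the B-factor column, a
#' domain-definition row, the reference sequence, and annotation rows. A
#' term `flexible_process` is planted on the proteins of
#' above-median-hinge groups and `rigid_process` on the rest (plus a
#' `ubiquitous_process` on everyone) so enrichment recovery is testable.
#' A JSON manifest records all ground-truth parameters.
#'
#' @param truths list of [synthetic_truth()] objects with unique group ids.
#' @param out_dir output directory (created if needed).
#' @param flank residues of low-confidence tail on each side of the
#'   predicted model, default 6.
#' @return invisible list describing the dataset (paths, truths).
#' @export
emit_dataset <- function(truths, out_dir, flank = 6) {
  ids <- vapply(truths, function(t) t$group_id, "")
  if (anyDuplicated(ids)) stop_fc("group ids must be unique", "fc_validation_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_fc("cannot create output directory", "fc_io_error")
  dir.create(file.path(out_dir, "structures"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "predicted"), showWarnings = FALSE)
  defs <- list(); seqs <- character(); ann <- list(); sp <- list()
  sig <- vapply(truths, function(t) t$hinge_sigma_deg, 1.0)
  flexible <- sig > median(sig)
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    tmpl <- build_template(tr$template_kind, tr$n_res, seed = tr$seed,
                           group_id = tr$group_id, cath_code = tr$cath_code,
                           protein_acc = tr$protein_acc)
    ens <- generate_ensemble(tmpl, tr)
    for (e in ens)
      write_domain_pdb(e, file.path(out_dir, "structures",
                                    paste0(e$source, ".pdb")))
    sp[[i]] <- data.frame(source_id = vapply(ens, function(e) e$source, ""),
                          protein_acc = tr$protein_acc,
                          stringsAsFactors = FALSE)
    pred <- generate_prediction(tmpl, ens, tr$prediction_mode,
                                seed = tr$seed + 1000L)
    fl <- add_flanks(pred, flank, seed = tr$seed + 2000L)
    pm <- pred; pm$atoms <- fl$atoms
    write_domain_pdb(pm, file.path(out_dir, "predicted",
                                   paste0(tr$protein_acc, ".pdb")))
    defs[[i]] <- data.frame(domain_id = paste0(tr$group_id, "_dom"),
                            cath_code = tr$cath_code,
                            protein_acc = tr$protein_acc,
                            segments = paste0("A:1-", tr$n_res),
                            stringsAsFactors = FALSE)
    seqs[tr$protein_acc] <- fl$seq
    ann[[i]] <- data.frame(
      protein_acc = tr$protein_acc,
      term = c("ubiquitous_process",
               if (flexible[i]) "flexible_process" else "rigid_process"),
      stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, defs),
              file.path(out_dir, "domain_definitions.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(do.call(rbind, ann), file.path(out_dir, "annotations.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(do.call(rbind, sp), file.path(out_dir, "structure_proteins.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  fa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(fa, file.path(out_dir, "sequences.fasta"))
  manifest <- list(groups = lapply(truths, unclass), flank = flank)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, truths = truths,
                 n_structures = sum(vapply(truths, function(t)
                   t$n_conformers, 1.0))))
}

#' Default study conditions for the synthetic census
#'
#' Ten synthetic folds with hinge amplitudes evenly spaced from 0 to 30
#' degrees, 12 conformers each, 0.2 Angstrom thermal noise, 60-residue
#' helix-bundle templates with the hinge at the second inter-helix loop.
#' These are the conditions under which parameter recovery (hinge amplitude
#' vs census MAD) and prediction-mode discrimination are evaluated.
#'
#' @param n_groups number of folds, default 10.
#' @param n_conformers conformers per fold, default 12.
#' @param hinge_max largest hinge sigma in degrees, default 30.
#' @param noise_sigma thermal noise in Angstrom, default 0.2.
#' @param prediction_mode `"pick_one"` or `"average"`.
#' @param seed base seed; group g uses `seed * 100 + g`.
#' @return list of [synthetic_truth()] objects.
#' @export
default_truths <- function(n_groups = 10, n_conformers = 12, hinge_max = 30,
                           noise_sigma = 0.2,
                           prediction_mode = "pick_one", seed = 1) {
  sig <- seq(0, hinge_max, length.out = n_groups)
  lapply(seq_len(n_groups), function(g)
    synthetic_truth(group_id = sprintf("G%02d", g),
                    template_kind = "helix-bundle",
                    hinge_residues = c(39, 42), hinge_sigma_deg = sig[g],
                    noise_sigma = noise_sigma, n_conformers = n_conformers,
                    prediction_mode = prediction_mode,
                    seed = as.integer(seed) * 100L + g, n_res = 60,
                    cath_code = sprintf("%d.10.%d.10", (g - 1) %% 3 + 1,
                                        10 * g),
                    protein_acc = sprintf("SYNP%02d", g)))
}

#' Generate an ensemble with planted switch-conformation archetypes
#'
#' Emulates a two-switch GTPase-style ensemble: each archetype is a pair of
#' flap rotations (degrees) applied to the two regions, and every conformer
#' draws its archetype angles with a small jitter plus thermal noise. The
#' closed/closed template doubles as the predicted reference. Defaults plant
#' the six patterns of the switch analysis: switch I closed with three
#' levels of switch II opening, switch I open with switch II closed or open,
#' and a doubly intermediate state.
#'
#' @param template a `domain_instance` (the closed/closed reference).
#' @param regions list of two [region_spec()] objects (flap intervals in the
#'   template's residue numbering).
#' @param archetypes two-column matrix of flap angles (degrees), one row per
#'   pattern.
#' @param n_per conformers per archetype, default 7.
#' @param angle_jitter per-conformer angle sd in degrees, default 2.
#' @param noise_sigma per-coordinate noise in Angstrom, default 0.1.
#' @param seed RNG seed.
#' @return list with `conformers` (list of `domain_instance`), `truth`
#'   (integer archetype label per conformer).
#' @export
generate_switch_ensemble <- function(template, regions,
                                     archetypes = cbind(
                                       c(0, 0, 0, 40, 40, 20),
                                       c(0, 20, 40, 0, 40, 20)),
                                     n_per = 7, angle_jitter = 2,
                                     noise_sigma = 0.1, seed = 1) {
  set.seed(seed)
  conformers <- list(); truth <- integer(0)
  for (a in seq_len(nrow(archetypes))) {
    for (j in seq_len(n_per)) {
      ang <- archetypes[a, ] + rnorm(2, 0, angle_jitter)
      conf <- apply_flap(template, regions[[1]]$range, ang[1])
      conf <- apply_flap(conf, regions[[2]]$range, ang[2])
      na <- nrow(conf$atoms)
      conf$atoms[, c("x", "y", "z")] <- conf$atoms[, c("x", "y", "z")] +
        matrix(rnorm(3 * na, 0, noise_sigma), na, 3)
      conf$source <- sprintf("sw_a%d_c%02d", a, j)
      conf$instance_id <- conf$source
      conformers[[length(conformers) + 1]] <- conf
      truth <- c(truth, a)
    }
  }
  list(conformers = conformers, truth = truth)
}
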