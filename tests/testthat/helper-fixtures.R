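# Fixtures and independent oracles used across the suite. All fixtures are
# built in code; nothing binary ships with the package.

write_tiny_pdb <- function(path) {
  writeLines(c(
    "HEADER    TEST PROTEIN                            01-JAN-20   XXXX",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00 11.00           N",
    "ATOM      6  CA  GLY A   2       3.988   2.839   0.000  1.00 11.00           C",
    "ATOM      7  C   GLY A   2       5.504   2.693   0.000  1.00 11.00           C",
    "ATOM      8  O   GLY A   2       6.030   1.580   0.000  1.00 11.00           O",
    "ATOM      9  N   SER A   3       6.224   3.810   0.000  1.00 12.00           N",
    "ATOM     10  CA  SER A   3       7.684   3.789   0.000  1.00 12.00           C",
    "ATOM     11  C   SER A   3       8.243   5.204   0.000  1.00 12.00           C",
    "ATOM     12  O   SER A   3       7.504   6.191   0.000  1.00 12.00           O",
    "HETATM   13 MG    MG A 101       4.000   0.500   2.000  1.00 20.00          MG",
    "END"), path)
  path
}

write_tiny_cif <- function(path) {
  hdr <- c("data_tiny",
           "_exptl.method 'X-RAY DIFFRACTION'",
           "_refine.ls_d_res_high 1.80",
           "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- c(
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.009 1.420 0.000 1.00 10.00 ? 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 1.251 2.390 0.000 1.00 10.00 ? 1 ALA A O 1",
    "ATOM 5 N N . GLY A 1 2 ? 3.332 1.536 0.000 1.00 11.00 ? 2 GLY A N 1",
    "ATOM 6 C CA . GLY A 1 2 ? 3.988 2.839 0.000 1.00 11.00 ? 2 GLY A CA 1",
    "ATOM 7 C C . GLY A 1 2 ? 5.504 2.693 0.000 1.00 11.00 ? 2 GLY A C 1",
    "ATOM 8 O O . GLY A 1 2 ? 6.030 1.580 0.000 1.00 11.00 ? 2 GLY A O 1",
    "ATOM 9 N N . SER A 1 3 ? 6.224 3.810 0.000 1.00 12.00 ? 3 SER A N 1",
    "ATOM 10 C CA . SER A 1 3 ? 7.684 3.789 0.000 1.00 12.00 ? 3 SER A CA 1",
    "ATOM 11 C C . SER A 1 3 ? 8.243 5.204 0.000 1.00 12.00 ? 3 SER A C 1",
    "ATOM 12 O O . SER A 1 3 ? 7.504 6.191 0.000 1.00 12.00 ? 3 SER A O 1",
    "HETATM 13 MG MG . MG A 2 . ? 4.000 0.500 2.000 1.00 20.00 ? 101 MG A MG 1")
  writeLines(c(hdr, rows), path)
  path
}

# wrap an atom table as a domain_instance covering residues 1..n on chain A
instance_from_atoms <- function(atoms, n, id = "fix",
                                cath = "1.1.1.1", acc = "P1") {
  s <- structure(list(source_id = id, method = "SYNTHETIC", resolution = 2,
                      atoms = atoms, het_atoms = atoms[0, , drop = FALSE]),
                 class = "structure_model")
  d <- domain_definition(paste0(id, "_dom"), cath, acc,
                         data.frame(chain = "A", start = 1, end = n))
  extract_domain_instance(s, d)
}

# --- independent oracle: exhaustive glocal alignment score ----------------
# Enumerates every increasing mapping of query positions onto reference
# positions; unmatched stretches pay affine gap costs, except reference end
# overhangs which are free (query is global, reference is local).
brute_force_glocal <- function(q, r, mat, open, ext) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  nq <- length(qs); nr <- length(rs)
  gap <- function(len) if (len > 0) open + len * ext else 0
  best <- -(open + nq * ext)              # whole query deleted
  for (k in seq_len(min(nq, nr))) {
    iq_sets <- utils::combn(nq, k, simplify = FALSE)
    ir_sets <- utils::combn(nr, k, simplify = FALSE)
    for (iq in iq_sets) {
      for (ir in ir_sets) {
        sc <- sum(vapply(seq_len(k), function(t) mat[qs[iq[t]], rs[ir[t]]], 1.0))
        sc <- sc - gap(iq[1] - 1) - gap(nq - iq[k])        # query ends pay
        if (k > 1) {
          sc <- sc - sum(vapply(seq_len(k - 1), function(t)
            gap(iq[t + 1] - iq[t] - 1) + gap(ir[t + 1] - ir[t] - 1), 1.0))
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# --- independent oracle: hypergeometric upper tail by counting ------------
hyper_tail_count <- function(k, K, N, n) {
  xs <- max(k, 0):min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# --- independent oracle: 1D rotation-grid superposition -------------------
# For coordinate sets relatable by an in-plane (z-axis) rotation +
# translation, scan rotation angles on a grid and return the best RMSD.
grid_rmsd_z <- function(a, b, step_deg = 0.05) {
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  angs <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  best <- Inf
  for (th in angs) {
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    r <- sqrt(mean(rowSums((a0 - b0 %*% R)^2)))
    if (r < best) best <- r
  }
  best
}

# --- independent oracle: DSSP-style backbone H-bond energy ----------------
# Recomputes donor/acceptor energies directly from an instance's atom table
# without using the package's assignment internals.
hbond_energy_direct <- function(inst, donor, acceptor) {
  at <- inst$atoms
  g <- function(resno, el) as.numeric(at[at$resno == resno & at$elety == el,
                                         c("x", "y", "z")][1, ])
  co <- g(donor - 1, "C") - g(donor - 1, "O")
  H <- g(donor, "N") + co / sqrt(sum(co^2))
  O <- g(acceptor, "O"); C <- g(acceptor, "C"); N <- g(donor, "N")
  dd <- function(u, v) sqrt(sum((u - v)^2))
  0.42 * 0.20 * 332 * (1 / dd(O, N) + 1 / dd(C, H) - 1 / dd(O, H) - 1 / dd(C, N))
}

cluster_agreement <- function(labels, truth) {
  m <- table(labels, truth)
  sum(apply(m, 1, max)) / length(truth)
}

blosum62_x0 <- function() foldcensus:::subst_matrix("BLOSUM62")
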