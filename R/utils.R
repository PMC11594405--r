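# Shared low-level helpers: residue keys, 3D geometry, amino-acid tables.

# canonical residue key within a structure: chain + author number + icode
res_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == "?", "", insert)
  paste0(chain, ":", resno, insert)
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "C", PYL = "K")

AA1TO3 <- setNames(names(AA3TO1)[1:20], AA3TO1[1:20])

aa_three_to_one <- function(resid3) {
  out <- AA3TO1[toupper(resid3)]
  out[is.na(out)] <- "X"
  unname(out)
}

# van der Waals radii (Angstrom) by element, Bondi set; default for unknowns
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               SE = 1.90)
VDW_DEFAULT <- 1.80

element_radius <- function(elesy, warn = TRUE) {
  r <- VDW_RADII[toupper(elesy)]
  if (anyNA(r)) {
    unk <- unique(toupper(elesy)[is.na(r)])
    if (warn) warning("unknown element(s) ", paste(unk, collapse = ", "),
                      "; using default radius ", VDW_DEFAULT)
    r[is.na(r)] <- VDW_DEFAULT
  }
  unname(r)
}

# elements counted as metal ions in contact classification
METAL_ELEMENTS <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA",
                    "MN", "FE", "CO", "NI", "CU", "ZN", "MO", "W", "V",
                    "CD", "HG", "AL", "GA", "PT", "AU")

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O")

# Theoretical maximum accessible surface areas per residue (Angstrom^2),
# Tien et al. 2013; used for relative-SASA burial classification.
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
             Q = 225, E = 223, G = 104, H = 224, I = 197,
             L = 201, K = 236, M = 224, F = 240, P = 159,
             S = 155, T = 172, W = 285, Y = 263, V = 174)
MAX_ASA_X <- unname(median(MAX_ASA))

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

# Rodrigues rotation of row-coordinate matrix `xyz` about the axis through
# `point` with direction `axis` (need not be unit), by `angle_deg` degrees.
rotate_about_axis <- function(xyz, point, axis, angle_deg) {
  k <- unit_vec(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  centered <- sweep(xyz, 2, point)
  sweep(centered %*% t(R), 2, point, FUN = "+")
}

# torsion-driven atom placement (natural extension reference frame):
# place atom D bonded to C with given bond length, angle B-C-D (deg) and
# torsion A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- unit_vec(c - b)
  n <- unit_vec(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fc <- function(msg, class) {
  stop(structure(class = c(class, "foldcensus_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
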