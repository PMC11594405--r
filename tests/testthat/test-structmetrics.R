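test_that("Kabsch superposition is exact on rigid transforms and matches a
           rotation-grid oracle", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(a, a)$rmsd, 0, tolerance = 1e-12)
  # arbitrary rigid transform
  axis <- c(1, 2, 0.5)
  b <- foldcensus:::rotate_about_axis(a, c(0.3, -1, 2), axis, 54.3)
  b <- sweep(b, 2, c(5, -3, 11), FUN = "+")
  s <- kabsch_superpose(a, b)
  expect_lt(s$rmsd, 1e-8)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  # 6-point noisy planar pair vs 0.05-degree rotation grid search
  set.seed(2)
  p <- cbind(matrix(rnorm(12, sd = 3), 6, 2), 0)
  th <- 23.7 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  q <- p %*% R + cbind(matrix(rnorm(12, sd = 0.3), 6, 2), 0)
  expect_equal(kabsch_superpose(p, q)$rmsd, grid_rmsd_z(p, q),
               tolerance = 1e-3)
  # degenerate input
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), class = "fc_degenerate")
  expect_error(kabsch_superpose(a[1:2, ], a[1:2, ]), class = "fc_degenerate")
  expect_error(kabsch_superpose(a, a[1:5, ]), class = "fc_validation_error")
})

test_that("superposition RMSD is symmetric and rigid-invariant", {
  set.seed(3)
  a <- matrix(rnorm(45), 15, 3)
  b <- a + matrix(rnorm(45, sd = 0.5), 15, 3)
  r1 <- kabsch_superpose(a, b)$rmsd
  expect_equal(kabsch_superpose(b, a)$rmsd, r1, tolerance = 1e-9)
  rig <- function(x) sweep(foldcensus:::rotate_about_axis(x, c(1, 1, 1),
                                                          c(0, 0, 1), 120),
                           2, c(-2, 4, 7), FUN = "+")
  expect_equal(kabsch_superpose(rig(a), rig(b))$rmsd, r1, tolerance = 1e-9)
})

test_that("RMSD100 normalization follows the length formula", {
  expect_equal(rmsd100(2, 100), 2)
  expect_equal(rmsd100(2, 400), 2 / (1 + log(2)), tolerance = 1e-9)
  expect_equal(rmsd100(2, 400), 1.1813, tolerance = 1e-4)
  expect_equal(rmsd100(0, 37), 0)
  for (r in c(0, 0.5, 3, 10)) expect_equal(rmsd100(r, 100), r)
  expect_true(is.na(rmsd100(2, 13)))   # non-positive denominator flagged
})

test_that("region RMSD uses the fixed global fit and satisfies the
           partition identity", {
  tm <- build_template("helix-bundle", 60, seed = 5)
  conf <- apply_hinge(tm, c(39, 42), 25)
  sup <- superpose_instances(conf, tm)
  expect_equal(region_rmsd(sup, c(1, 60)), sup$rmsd, tolerance = 1e-12)
  expect_equal(region_rmsd(superpose_instances(tm, tm), c(5, 20)), 0,
               tolerance = 1e-12)
  # weighted quadratic mean over a partition recovers the global value
  parts <- list(c(1, 20), c(21, 40), c(41, 60))
  ns <- vapply(parts, function(p) sum(sup$ref_pos >= p[1] &
                                        sup$ref_pos <= p[2]), 1L)
  rs <- vapply(parts, function(p) region_rmsd(sup, p), 1.0)
  expect_equal(sqrt(sum(ns * rs^2) / sum(ns)), sup$rmsd, tolerance = 1e-12)
  expect_warning(v <- region_rmsd(sup, c(200, 210)))
  expect_true(is.na(v))
})

test_that("hinge-rotated region matches the closed-form displacement under a
           core-only fit", {
  tm <- build_template("helix-bundle", 60, seed = 5)
  conf <- apply_flap(tm, c(30, 40), 30)
  sup <- superpose_instances(conf, tm,
                             fit_positions = c(1:30, 40:60))
  ca <- ca_xyz(tm)
  k <- ca["A:40", ] - ca["A:30", ]; k <- k / sqrt(sum(k^2))
  inner <- 31:39
  rel <- sweep(ca[paste0("A:", inner), , drop = FALSE], 2, ca["A:30", ])
  radii <- sqrt(rowSums((rel - outer(as.numeric(rel %*% k), k))^2))
  analytic <- sqrt(mean((2 * radii * sin(15 * pi / 180))^2))
  expect_equal(region_rmsd(sup, c(31, 39)), analytic, tolerance = 1e-6)
})

test_that("Shrake-Rupley SASA matches closed-form sphere areas", {
  lone <- data.frame(chain = "A", resno = 1, insert = "", resid = "CYS",
                     aa = "C", elety = "SG", elesy = "S",
                     x = 0, y = 0, z = 0, o = 1, b = 0, key = "A:1")
  inst <- list(atoms = lone)
  a1 <- shrake_rupley_sasa(inst)
  expect_equal(a1$total, 4 * pi * (1.8 + 1.4)^2, tolerance = 0.01)
  two_far <- rbind(lone, transform(lone, x = 100, resno = 2, key = "A:2"))
  expect_equal(shrake_rupley_sasa(list(atoms = two_far))$total, 2 * a1$total,
               tolerance = 0.01)
  coincident <- rbind(lone, transform(lone, resno = 2, key = "A:2"))
  expect_equal(shrake_rupley_sasa(list(atoms = coincident))$total, a1$total,
               tolerance = 0.01)
  expect_warning(shrake_rupley_sasa(list(atoms = transform(lone, elesy = "ZQ"))),
                 "unknown element")
})

test_that("total SASA decreases monotonically as two bodies approach", {
  lone <- data.frame(chain = "A", resno = 1, insert = "", resid = "CYS",
                     aa = "C", elety = "SG", elesy = "S",
                     x = 0, y = 0, z = 0, o = 1, b = 0, key = "A:1")
  seps <- c(20, 10, 6.5, 5, 4, 3)
  tot <- vapply(seps, function(d) {
    at <- rbind(lone, transform(lone, x = d, resno = 2, key = "A:2"))
    shrake_rupley_sasa(list(atoms = at))$total
  }, 1.0)
  expect_true(all(diff(tot) <= 1e-9))
})

test_that("voxel volume matches closed-form sphere volumes and converges", {
  lone <- data.frame(chain = "A", resno = 1, insert = "", resid = "CYS",
                     aa = "C", elety = "SG", elesy = "S",
                     x = 0, y = 0, z = 0, o = 1, b = 0, key = "A:1")
  v1 <- estimate_volume(list(atoms = lone))
  expect_equal(v1, 4 / 3 * pi * 1.8^3, tolerance = 0.02)
  two <- rbind(lone, transform(lone, x = 50, resno = 2, key = "A:2"))
  expect_equal(estimate_volume(list(atoms = two)), 2 * v1, tolerance = 0.02)
  v_half <- estimate_volume(list(atoms = lone), grid = 0.25)
  expect_lt(abs(v_half - v1) / v1, 0.02)
})

test_that("burial classification follows relative SASA", {
  ext <- build_template("extended", 30, seed = 6)
  sasa <- shrake_rupley_sasa(ext)
  be <- classify_buried_exposed(sasa$residue_area, ext$seq)
  expect_equal(be$n_buried, 0)                     # everything exposed
  lone_res <- ext
  lone_res$atoms <- lone_res$atoms[lone_res$atoms$resno == 15, ]
  s1 <- shrake_rupley_sasa(lone_res)
  be1 <- classify_buried_exposed(s1$residue_area, substr(ext$seq, 15, 15))
  expect_equal(be1$n_exposed, 1)                   # a lone residue is exposed
  expect_equal(be1$be_ratio, 0)
  # nothing exposed: ratio undefined
  allburied <- classify_buried_exposed(c("A:1" = 0, "A:2" = 0), "AA")
  expect_true(is.na(allburied$be_ratio))
  # compact globule vs extended conformer of the same length: globule has
  # the larger buried-to-exposed ratio and the smaller area-to-volume ratio
  glob <- build_template("helix-bundle", 60, seed = 6)
  ext60 <- build_template("extended", 60, seed = 6)
  sg <- shrake_rupley_sasa(glob); se <- shrake_rupley_sasa(ext60)
  beg <- classify_buried_exposed(sg$residue_area, glob$seq)
  bee <- classify_buried_exposed(se$residue_area, ext60$seq)
  expect_gt(beg$n_buried, bee$n_buried)
  av_g <- sg$total / estimate_volume(glob)
  av_e <- se$total / estimate_volume(ext60)
  expect_gt(av_e, av_g)
})

test_that("contact counts classify metals and ligands by distance", {
  tm <- build_template("extended", 20, seed = 7)
  expect_equal(contact_counts(tm, tm$atoms[0, ]), list(n_met = 0L, n_lig = 0L))
  ca <- ca_xyz(tm)
  het <- data.frame(chain = "A", resno = 900, insert = "", resid = "MG",
                    aa = "X", elety = "MG", elesy = "MG",
                    x = ca["A:5", 1] + 2.1, y = ca["A:5", 2],
                    z = ca["A:5", 3], o = 1, b = 0, key = "A:900")
  cc <- contact_counts(tm, het)
  expect_gte(cc$n_met, 1)
  expect_equal(cc$n_lig, 0L)
  far_lig <- transform(het, elesy = "C", resid = "LIG",
                       x = max(tm$atoms$x) + 50)
  expect_equal(contact_counts(tm, far_lig)$n_lig, 0L)
})

test_that("secondary structure assignment matches the hydrogen-bond oracle", {
  # ideal alpha helix: the i -> i+4 bonds must be present per the energy
  # model evaluated independently, and at least 8 of 12 residues helical
  hx <- instance_from_atoms(
    foldcensus:::build_backbone(rep(-57, 12), rep(-47, 12),
                                paste(rep("A", 12), collapse = "")), 12)
  for (i in 1:7) expect_lt(hbond_energy_direct(hx, i + 4, i), -0.5)
  prof <- assign_sse(hx)
  expect_gte(sum(strsplit(prof$per_residue, "")[[1]] == "H"), 8)
  # two antiparallel strands from the sheet construction pair as E
  sh <- build_template("sheet-sandwich", 60, seed = 4)
  ss <- strsplit(assign_sse(sh)$per_residue, "")[[1]]
  expect_gte(sum(ss == "E"), 8)
  # a fully extended isolated chain has no partners: all coil
  ex <- build_template("extended", 30, seed = 4)
  pex <- assign_sse(ex)
  expect_equal(pex$n_sse_residues, 0)
  expect_equal(pex$per_residue, paste(rep("C", 30), collapse = ""))
})

test_that("SSE count differences are signed prediction minus experiment", {
  p1 <- foldcensus:::profile_from_ss(rep("H", 10))
  p2 <- foldcensus:::profile_from_ss(c(rep("H", 5), rep("C", 5)))
  p3 <- foldcensus:::profile_from_ss(c(rep("E", 7), rep("C", 3)))
  expect_equal(sse_count_difference(p1, p1), 0)
  expect_equal(sse_count_difference(p1, p2), 5)
  expect_equal(sse_count_difference(p2, p3), -2)
})
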