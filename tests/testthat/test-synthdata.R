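test_that("templates are deterministic and architecture-faithful", {
  t1 <- build_template("helix-bundle", 60, seed = 21)
  t2 <- build_template("helix-bundle", 60, seed = 21)
  expect_identical(t1$atoms, t2$atoms)
  expect_identical(t1$seq, t2$seq)
  # helix bundle is at least half helical by the H-bond assignment
  expect_gte(assign_sse(t1)$frac_helix, 0.5)
  # extended chains are less compact than bundles of the same length
  ex <- build_template("extended", 60, seed = 21)
  av_bundle <- shrake_rupley_sasa(t1)$total / estimate_volume(t1)
  av_ext <- shrake_rupley_sasa(ex)$total / estimate_volume(ex)
  expect_gt(av_ext, av_bundle)
  expect_error(build_template("helix-bundle", 10), class = "fc_validation_error")
})

test_that("hinge ensembles honour their ground-truth parameters", {
  tm <- build_template("helix-bundle", 60, seed = 22)
  # zero amplitude, zero noise: identical conformers
  tr0 <- synthetic_truth("Z", hinge_sigma_deg = 0, noise_sigma = 0,
                         n_conformers = 4, seed = 5)
  e0 <- generate_ensemble(tm, tr0)
  expect_equal(superpose_instances(e0[[1]], e0[[4]])$rmsd, 0,
               tolerance = 1e-12)
  # forced 30-degree hinge matches the closed-form arm displacement
  conf <- apply_hinge(tm, c(39, 42), 30)
  ca <- ca_xyz(tm)
  k <- ca["A:42", ] - ca["A:39", ]; k <- k / sqrt(sum(k^2))
  arm <- paste0("A:", 43:60)
  rel <- sweep(ca[arm, ], 2, ca["A:39", ])
  disp <- 2 * sqrt(rowSums((rel - outer(as.numeric(rel %*% k), k))^2)) *
    sin(15 * pi / 180)
  obs <- sqrt(rowSums((ca_xyz(conf)[arm, ] - ca[arm, ])^2))
  expect_equal(unname(obs), unname(disp), tolerance = 1e-6)
  # heterogeneity grows monotonically with hinge amplitude
  med_pair <- vapply(c(0, 5, 15, 30), function(sg) {
    tr <- synthetic_truth("G", hinge_sigma_deg = sg, noise_sigma = 0.1,
                          n_conformers = 8, seed = 7)
    ens <- generate_ensemble(tm, tr)
    prs <- c()
    for (i in 1:7) for (j in (i + 1):8)
      prs <- c(prs, superpose_instances(ens[[i]], ens[[j]])$rmsd)
    median(prs)
  }, 1.0)
  expect_true(all(diff(med_pair) > 0))
})

test_that("prediction modes behave as one state versus a blend", {
  tm <- build_template("helix-bundle", 60, seed = 23)
  tr <- synthetic_truth("G", hinge_sigma_deg = 20, noise_sigma = 0.15,
                        n_conformers = 10, seed = 9)
  ens <- generate_ensemble(tm, tr)
  # pick_one of a single-conformer ensemble is that conformer
  one <- generate_prediction(tm, ens[1], "pick_one", seed = 3)
  expect_equal(superpose_instances(one, ens[[1]])$rmsd, 0, tolerance = 1e-12)
  # average of two conformers displaced symmetrically about the template
  # is the template itself
  set.seed(99)
  delta <- matrix(rnorm(nrow(tm$atoms) * 3, sd = 1), ncol = 3)
  up <- tm; up$atoms[, c("x", "y", "z")] <- tm$atoms[, c("x", "y", "z")] + delta
  dn <- tm; dn$atoms[, c("x", "y", "z")] <- tm$atoms[, c("x", "y", "z")] - delta
  avg <- generate_prediction(tm, list(up, dn), "average")
  expect_equal(as.matrix(avg$atoms[, c("x", "y", "z")]),
               as.matrix(tm$atoms[, c("x", "y", "z")]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # averaging a wide ensemble leaves every conformer away from the
  # prediction by more than the thermal noise floor
  noise_floor <- tr$noise_sigma * sqrt(6)
  avg2 <- generate_prediction(tm, ens, "average")
  min_rmsd <- min(vapply(ens, function(e)
    superpose_instances(e, avg2)$rmsd, 1.0))
  expect_gt(min_rmsd, noise_floor)
  # pLDDT is written, bounded, and lower where the ensemble fluctuates
  expect_true(all(avg2$atoms$b >= 50 & avg2$atoms$b <= 99))
  plddt <- avg2$atoms$b[avg2$atoms$elety == "CA"]
  expect_lt(mean(plddt[43:60]), mean(plddt[1:38]))   # mobile arm less confident
})

test_that("emitted datasets are complete, deterministic, and re-readable", {
  truths <- default_truths(n_groups = 3, n_conformers = 4, seed = 31)
  d1 <- tempfile("ds1"); d2 <- tempfile("ds2")
  emit_dataset(truths, d1)
  emit_dataset(truths, d2)
  expect_equal(length(list.files(file.path(d1, "structures"))), 12)
  expect_equal(length(list.files(file.path(d1, "predicted"))), 3)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  expect_identical(readLines(file.path(d1, "structures", "G01_c01.pdb")),
                   readLines(file.path(d2, "structures", "G01_c01.pdb")))
  # generated PDB round-trips through the reader with full counts
  s <- read_structure(file.path(d1, "structures", "G02_c03.pdb"))
  expect_equal(length(unique(s$atoms$key)), truths[[2]]$n_res)
  defs <- read_domain_definitions(file.path(d1, "domain_definitions.tsv"))
  expect_equal(length(defs), 3)
  fa <- Biostrings::readAAStringSet(file.path(d1, "sequences.fasta"))
  expect_equal(length(fa), 3)
  expect_equal(unique(nchar(as.character(fa))), 60 + 12)  # flanked reference
  ann <- read.delim(file.path(d1, "annotations.tsv"))
  expect_true(all(c("flexible_process", "rigid_process") %in% ann$term))
})

test_that("planted annotations are recoverable by the enrichment test", {
  # ten proteins, the five above-median-amplitude ones carry the planted
  # term; drawing those five recovers the textbook 1/252 tail
  truths <- default_truths(n_groups = 10, n_conformers = 1, seed = 33)
  d <- tempfile("ds")
  emit_dataset(truths, d)
  ann <- read.delim(file.path(d, "annotations.tsv"))
  flex <- sort(unique(ann$protein_acc[ann$term == "flexible_process"]))
  expect_equal(length(flex), 5)
  rigid <- setdiff(sprintf("SYNP%02d", 1:10), flex)
  res <- hypergeom_enrich(flex, rigid, ann)
  p <- res$p_value[res$term == "flexible_process" & res$direction == "het"]
  expect_equal(p, 1 / 252, tolerance = 1e-12)
})
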